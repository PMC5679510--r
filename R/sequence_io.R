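#' Clean a raw nucleotide sequence
#'
#' Upper-cases the input and strips every character outside \code{A/C/G/T}
#' (IUPAC ambiguity codes, gaps, whitespace). A sequence is rejected when
#' more than 10\% of its characters had to be stripped -- at that point the
#' surviving k-mer statistics no longer represent the gene -- or when fewer
#' than 3 bases remain.
#'
#' @param raw A single character string of nucleotides.
#' @return A list with elements \code{ok} (logical), \code{sequence} (the
#'   cleaned string, or \code{NA} on rejection) and \code{reason}
#'   (\code{NA} when accepted).
#' @examples
#' clean_sequence("atgACGT")$sequence
#' clean_sequence("AC")$reason
#' @export
clean_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  up <- toupper(raw)
  cleaned <- gsub("[^ACGT]", "", up)
  n_raw <- nchar(up)
  n_kept <- nchar(cleaned)
  if (n_raw == 0L) {
    return(list(ok = FALSE, sequence = NA_character_, reason = "empty input"))
  }
  frac_removed <- (n_raw - n_kept) / n_raw
  if (frac_removed > 0.10) {
    return(list(ok = FALSE, sequence = NA_character_,
                reason = sprintf("%.1f%% non-ACGT characters removed (> 10%%)",
                                 100 * frac_removed)))
  }
  if (n_kept < 3L) {
    return(list(ok = FALSE, sequence = NA_character_,
                reason = "fewer than 3 bases after cleaning"))
  }
  list(ok = TRUE, sequence = cleaned, reason = NA_character_)
}

new_organism_dataset <- function(organism, genes) {
  stopifnot(is.data.frame(genes),
            all(c("gene_id", "sequence", "label") %in% names(genes)))
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  }
  structure(list(organism = organism, genes = genes),
            class = "organism_dataset")
}

#' @export
print.organism_dataset <- function(x, ...) {
  cat(sprintf("<organism_dataset> %s: %d genes (%d essential, %d non-essential, %d unknown)\n",
              x$organism, nrow(x$genes), n_essential(x), n_non_essential(x),
              sum(x$genes$label == "unknown")))
  invisible(x)
}

#' Class counts of a labeled dataset
#'
#' @param dataset An \code{organism_dataset}.
#' @return Integer count of essential (resp. non-essential) genes.
#' @export
n_essential <- function(dataset) sum(dataset$genes$label == "essential")

#' @rdname n_essential
#' @export
n_non_essential <- function(dataset) sum(dataset$genes$label == "non_essential")

#' Read gene sequences from a multi-FASTA file
#'
#' One record per FASTA entry; the gene identifier is the first
#' whitespace-delimited token of the header. Sequences are cleaned with
#' \code{\link{clean_sequence}}; records failing cleaning are dropped with a
#' message stating the reason. Labels are set to \code{"unknown"} until
#' \code{\link{attach_labels}} is applied.
#'
#' @param path Path to a readable multi-FASTA file of coding-strand gene
#'   sequences.
#' @param organism Short organism tag attached to the dataset.
#' @return An \code{organism_dataset}.
#' @export
read_gene_fasta <- function(path, organism) {
  if (!file.exists(path)) stop("cannot read FASTA file: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  ids <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  if (any(!nzchar(ids)) || anyNA(ids)) stop("FASTA header with empty gene id in ", path)
  if (anyDuplicated(ids)) {
    stop("duplicate gene_id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  raw <- as.character(ss)
  keep <- character(0)
  kept_ids <- character(0)
  for (i in seq_along(raw)) {
    cl <- clean_sequence(raw[[i]])
    if (cl$ok) {
      keep <- c(keep, cl$sequence)
      kept_ids <- c(kept_ids, ids[[i]])
    } else {
      message("dropping gene ", ids[[i]], ": ", cl$reason)
    }
  }
  if (length(keep) == 0L) stop("no records survived cleaning in ", path)
  new_organism_dataset(organism,
                       data.frame(gene_id = kept_ids, sequence = keep,
                                  label = "unknown", stringsAsFactors = FALSE))
}

#' Write an organism dataset back to FASTA (and labels to TSV)
#'
#' @param dataset An \code{organism_dataset}.
#' @param path Output FASTA path.
#' @return Invisibly, \code{path}.
#' @export
write_gene_fasta <- function(dataset, path) {
  ss <- Biostrings::DNAStringSet(dataset$genes$sequence)
  names(ss) <- dataset$genes$gene_id
  Biostrings::writeXStringSet(ss, filepath = path)
  invisible(path)
}

#' Attach essentiality labels from a two-column TSV
#'
#' The label file is a headerless two-column TSV mapping \code{gene_id} to
#' \code{E} (essential) or \code{NE} (non-essential). Genes without a label
#' stay \code{"unknown"} and are excluded from training and testing;
#' mismatches in either direction are reported via \code{message()}.
#'
#' @param dataset An \code{organism_dataset}.
#' @param labels Path to the TSV file, or a data frame with columns
#'   \code{gene_id} and \code{label} (values \code{E}/\code{NE}).
#' @return The dataset with labels filled in.
#' @export
attach_labels <- function(dataset, labels) {
  if (is.character(labels)) {
    labels <- read.table(labels, sep = "\t", header = FALSE,
                         col.names = c("gene_id", "label"),
                         colClasses = "character", quote = "")
  }
  stopifnot(all(c("gene_id", "label") %in% names(labels)))
  bad <- setdiff(unique(labels$label), c("E", "NE"))
  if (length(bad)) {
    stop("invalid label value(s): ", paste(bad, collapse = ", "),
         " (expected E or NE)")
  }
  if (anyDuplicated(labels$gene_id)) {
    stop("duplicate gene_id in label table: ",
         paste(unique(labels$gene_id[duplicated(labels$gene_id)]), collapse = ", "))
  }
  idx <- match(dataset$genes$gene_id, labels$gene_id)
  lab <- ifelse(is.na(idx), "unknown",
                ifelse(labels$label[idx] == "E", "essential", "non_essential"))
  unmatched_genes <- dataset$genes$gene_id[is.na(idx)]
  unmatched_labels <- setdiff(labels$gene_id, dataset$genes$gene_id)
  if (length(unmatched_genes)) {
    message(length(unmatched_genes), " gene(s) without a label left unknown: ",
            paste(head(unmatched_genes, 5), collapse = ", "),
            if (length(unmatched_genes) > 5) ", ..." else "")
  }
  if (length(unmatched_labels)) {
    message(length(unmatched_labels), " label(s) with no matching gene: ",
            paste(head(unmatched_labels, 5), collapse = ", "),
            if (length(unmatched_labels) > 5) ", ..." else "")
  }
  dataset$genes$label <- lab
  dataset
}

#' Background k-mer distribution of a genome
#'
#' Counts overlapping k-mers (every position, step 1) of a DNA string and
#' normalizes to a probability mass function over the 4^k possible k-mers.
#' Windows containing non-ACGT symbols are skipped.
#'
#' @param genome A DNA string (character scalar).
#' @param k k-mer size, one of 1, 2, 3.
#' @return Named numeric vector of length 4^k summing to 1.
#' @export
compute_background <- function(genome, k) {
  stopifnot(k %in% 1:3)
  if (nchar(genome) < k) stop("genome shorter than k = ", k)
  cnt <- kmer_counts(toupper(genome), k)
  tot <- sum(cnt)
  if (tot == 0) stop("no valid ", k, "-mer windows in genome")
  cnt / tot
}

#' Build the per-k background distributions for an organism
#'
#' When a genome sequence is supplied the background is computed from it;
#' otherwise from the pooled k-mer counts of the supplied (training) gene
#' sequences. The active choice is reported via \code{message()}.
#'
#' @param organism Organism tag.
#' @param genome Optional genome DNA string.
#' @param sequences Optional character vector of gene sequences (used when
#'   \code{genome} is \code{NULL}); counting never spans gene boundaries.
#' @return A \code{background_distribution}: list with \code{organism} and
#'   \code{pmf}, a list of pmfs for k = 1, 2, 3.
#' @export
background_distribution <- function(organism, genome = NULL, sequences = NULL) {
  pmf <- if (!is.null(genome)) {
    message("background for ", organism, " computed from genome sequence")
    lapply(1:3, function(k) compute_background(genome, k))
  } else {
    if (is.null(sequences) || length(sequences) == 0L) {
      stop("need a genome or at least one gene sequence for the background")
    }
    message("background for ", organism,
            " computed from pooled training gene sequences")
    lapply(1:3, function(k) {
      cnt <- colSums(kmer_count_matrix(sequences, k))
      if (sum(cnt) == 0) stop("no valid ", k, "-mer windows in gene pool")
      cnt / sum(cnt)
    })
  }
  names(pmf) <- as.character(1:3)
  structure(list(organism = organism, pmf = pmf),
            class = "background_distribution")
}
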