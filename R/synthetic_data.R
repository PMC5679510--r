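#' Specify an order-1 Markov sequence source
#'
#' @param transition_matrix 4x4 row-stochastic matrix over A/C/G/T
#'   (rows = current base, columns = next base).
#' @param initial_dist Distribution of the first base; default is the
#'   stationary distribution of the matrix.
#' @param min_len,max_len Uniform integer bounds on gene length (nt);
#'   \code{min_len} >= 30.
#' @return A \code{source_spec}.
#' @export
source_spec <- function(transition_matrix, initial_dist = NULL,
                        min_len = 300, max_len = 1500) {
  P <- as.matrix(transition_matrix)
  stopifnot(all(dim(P) == c(4, 4)), all(P >= 0),
            all(abs(rowSums(P) - 1) <= 1e-12),
            min_len >= 30, max_len >= min_len)
  dimnames(P) <- list(DNA_BASES, DNA_BASES)
  if (is.null(initial_dist)) {
    ev <- eigen(t(P))
    v <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
    initial_dist <- v / sum(v)
  }
  stopifnot(length(initial_dist) == 4, all(initial_dist >= 0),
            abs(sum(initial_dist) - 1) <= 1e-9)
  structure(list(transition_matrix = P,
                 initial_dist = setNames(as.numeric(initial_dist), DNA_BASES),
                 min_len = as.integer(min_len), max_len = as.integer(max_len)),
            class = "source_spec")
}

# One sequence from an order-1 source, using the current RNG stream.
.gen_markov_seq <- function(P, init, n) {
  cum <- t(apply(P, 1, cumsum))
  out <- integer(n)
  out[1] <- findInterval(runif(1), cumsum(init)) + 1L
  u <- runif(n)
  for (i in seq_len(n - 1L)) {
    out[i + 1L] <- findInterval(u[i], cum[out[i], ]) + 1L
  }
  paste(DNA_BASES[out], collapse = "")
}

#' Configure a synthetic organism
#'
#' Essential genes are drawn from \code{pos_source}; non-essential genes
#' from a source whose transition matrix is the linear mixture
#' (1 - divergence) * M_pos + divergence * M_alt, so \code{divergence = 0}
#' makes the two classes exchangeable and \code{divergence = 1} maximally
#' distinct. The genome is drawn from the 50/50 mixture of the two class
#' matrices.
#'
#' @param n_essential,n_non_essential Gene counts (each >= 5).
#' @param pos_source,neg_source \code{source_spec}s for the essential
#'   class and the alternative (fully diverged) class.
#' @param divergence Mixing weight in [0, 1].
#' @param genome_length Genome length in nt (>= 1000).
#' @param seed RNG seed; the generated organism is fully determined by it.
#' @param organism Organism tag (default "SYN").
#' @return A \code{synth_config}.
#' @export
synth_config <- function(n_essential, n_non_essential, pos_source, neg_source,
                         divergence, genome_length = 50000, seed = 1,
                         organism = "SYN") {
  stopifnot(n_essential >= 5, n_non_essential >= 5,
            inherits(pos_source, "source_spec"),
            inherits(neg_source, "source_spec"),
            divergence >= 0, divergence <= 1, genome_length >= 1000)
  structure(list(n_essential = as.integer(n_essential),
                 n_non_essential = as.integer(n_non_essential),
                 pos_source = pos_source, neg_source = neg_source,
                 divergence = divergence,
                 genome_length = as.integer(genome_length),
                 seed = as.integer(seed), organism = organism),
            class = "synth_config")
}

#' Generate a synthetic organism
#'
#' Draws the labeled gene set and a background genome from the configured
#' class-conditional Markov sources. Gene lengths are uniform integers in
#' each source's bounds. The output is byte-identical for identical
#' configurations (including the seed).
#'
#' @param config A \code{\link{synth_config}}.
#' @return List with \code{dataset} (a labeled \code{organism_dataset})
#'   and \code{genome} (a DNA string).
#' @export
generate_organism <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  M_pos <- config$pos_source$transition_matrix
  M_alt <- config$neg_source$transition_matrix
  M_neg <- (1 - config$divergence) * M_pos + config$divergence * M_alt
  gen_class <- function(n, M, spec) {
    lens <- sample(spec$min_len:spec$max_len, n, replace = TRUE)
    vapply(lens, function(L) .gen_markov_seq(M, spec$initial_dist, L),
           character(1))
  }
  ess <- gen_class(config$n_essential, M_pos, config$pos_source)
  non <- gen_class(config$n_non_essential, M_neg, config$neg_source)
  M_genome <- 0.5 * M_pos + 0.5 * M_neg
  genome <- .gen_markov_seq(M_genome,
                            0.5 * config$pos_source$initial_dist +
                              0.5 * config$neg_source$initial_dist,
                            config$genome_length)
  ids <- sprintf("%s_g%04d", config$organism,
                 seq_len(config$n_essential + config$n_non_essential))
  genes <- data.frame(gene_id = ids, sequence = c(ess, non),
                      label = rep(c("essential", "non_essential"),
                                  c(config$n_essential,
                                    config$n_non_essential)),
                      stringsAsFactors = FALSE)
  list(dataset = new_organism_dataset(config$organism, genes),
       genome = genome)
}

#' Frozen synthetic-organism presets
#'
#' Three fixed study conditions built from the bundled pair of source
#' matrices (a 0.4/0.2 preferred-successor contrast, shipped in
#' \code{extdata/preset_source_matrices.tsv}): \code{"separable"}
#' (divergence 1.0, strongly distinct classes), \code{"weak"} (0.3) and
#' \code{"null"} (0.0, exchangeable classes). All presets use 60 essential
#' and 240 non-essential genes (a typical bacterial class imbalance of
#' ~1:4), gene lengths uniform in [300, 1500] nt, and a 50 kb genome.
#'
#' @param name Preset name: \code{"separable"}, \code{"weak"} or
#'   \code{"null"}.
#' @param seed RNG seed stored in the config.
#' @param organism Organism tag (default the preset name, upper-cased).
#' @return A \code{\link{synth_config}}.
#' @export
preset <- function(name, seed = 1, organism = toupper(name)) {
  div <- c(separable = 1.0, weak = 0.3, null = 0.0)
  if (!name %in% names(div)) {
    stop("unknown preset '", name, "'; valid presets: ",
         paste(names(div), collapse = ", "))
  }
  path <- system.file("extdata", "preset_source_matrices.tsv",
                      package = "itess", mustWork = TRUE)
  tab <- read.table(path, sep = "\t", header = TRUE)
  mat <- function(src) {
    m <- as.matrix(tab[tab$source == src, DNA_BASES])
    rownames(m) <- tab$from[tab$source == src]
    m[DNA_BASES, ]
  }
  synth_config(n_essential = 60, n_non_essential = 240,
               pos_source = source_spec(mat("pos")),
               neg_source = source_spec(mat("alt")),
               divergence = div[[name]], genome_length = 50000,
               seed = seed, organism = organism)
}

#' Write a synthetic organism to disk
#'
#' Emits the exact formats the ingestion functions consume: a gene
#' multi-FASTA, a two-column E/NE label TSV and a genome FASTA.
#'
#' @param org List from \code{\link{generate_organism}}.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
write_synthetic_organism <- function(org, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  genes_path <- file.path(dir, "genes.fasta")
  labels_path <- file.path(dir, "labels.tsv")
  genome_path <- file.path(dir, "genome.fasta")
  write_gene_fasta(org$dataset, genes_path)
  g <- org$dataset$genes
  write.table(data.frame(g$gene_id,
                         ifelse(g$label == "essential", "E", "NE")),
              labels_path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  gs <- Biostrings::DNAStringSet(org$genome)
  names(gs) <- paste0(org$dataset$organism, "_genome")
  Biostrings::writeXStringSet(gs, filepath = genome_path)
  invisible(c(genes = genes_path, labels = labels_path, genome = genome_path))
}
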