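# Boltzmann constant expressed per mole in kcal/(mol K): kB * N_A / 4184.
# Energy tables are in kcal/mol, so E(i) / (.KB_KCAL_MOL * T) is dimensionless.
.KB_JK <- 1.380649e-23
.KB_KCAL_MOL <- .KB_JK * 6.02214076e23 / 4184

#' Nearest-neighbor dinucleotide free-energy table
#'
#' Loads a 16-entry dinucleotide free-energy table used for the
#' Boltzmann-weighted (Gibbs) entropy features. The bundled default is the
#' unified nearest-neighbor DNA/DNA duplex free-energy set of SantaLucia
#' (1998), Proc. Natl. Acad. Sci. 95:1460 (delta-G at 37 C, kcal/mol); any
#' 16-line TSV \code{dinucleotide<TAB>energy_kcal_per_mol} can be supplied
#' instead.
#'
#' @param path Optional path to an energy TSV; default uses the bundled table.
#' @param temperature_K Temperature in Kelvin for the Boltzmann weights
#'   (default 310.15, i.e. 37 C).
#' @return An \code{energy_table}: list with \code{energies} (named numeric,
#'   all 16 dinucleotides), \code{temperature_K} and \code{boltzmann_kB}
#'   (J/K).
#' @export
energy_table <- function(path = NULL, temperature_K = 310.15) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_dG37_santalucia1998.tsv",
                        package = "itess", mustWork = TRUE)
  }
  tab <- read.table(path, sep = "\t", header = FALSE,
                    col.names = c("dinucleotide", "energy"),
                    colClasses = c("character", "numeric"))
  e <- setNames(tab$energy, tab$dinucleotide)
  missing <- setdiff(all_kmers(2), names(e))
  if (length(missing)) {
    stop("energy table missing dinucleotide(s): ", paste(missing, collapse = ", "))
  }
  stopifnot(temperature_K > 0)
  structure(list(energies = e[all_kmers(2)], temperature_K = temperature_K,
                 boltzmann_kB = .KB_JK),
            class = "energy_table")
}

# ---- internal computations on k-mer count vectors -------------------------

.mi_from_counts <- function(cnt16) {
  joint <- matrix(cnt16 / sum(cnt16), nrow = 4, ncol = 4, byrow = TRUE,
                  dimnames = list(DNA_BASES, DNA_BASES))
  px <- rowSums(joint)
  py <- colSums(joint)
  denom <- outer(px, py)
  terms <- matrix(0, 4, 4, dimnames = dimnames(joint))
  nz <- joint > 0
  terms[nz] <- joint[nz] * log2(joint[nz] / denom[nz])
  flat <- as.vector(t(terms))
  names(flat) <- all_kmers(2)
  structure(list(total = sum(flat), terms = flat), class = "pair_term_set")
}

.cmi_from_counts <- function(cnt64) {
  p <- cnt64 / sum(cnt64)
  # array indexed [y, z, x]: lexicographic order varies the last base fastest
  arr <- array(p, dim = c(4, 4, 4))
  pz <- apply(arr, 2, sum)
  mxz <- apply(arr, c(2, 3), sum)  # [z, x]
  mzy <- apply(arr, c(1, 2), sum)  # [y, z]
  pz_a <- array(rep(pz, each = 4), dim = c(4, 4, 4))
  mxz_a <- array(rep(as.vector(mxz), each = 4), dim = c(4, 4, 4))
  mzy_a <- array(as.vector(mzy), dim = c(4, 4, 4))
  terms <- array(0, dim = c(4, 4, 4))
  nz <- arr > 0
  terms[nz] <- arr[nz] * log2(pz_a[nz] * arr[nz] / (mxz_a[nz] * mzy_a[nz]))
  flat <- as.vector(terms)
  names(flat) <- all_kmers(3)
  structure(list(total = sum(flat), terms = flat), class = "triplet_term_set")
}

.shannon_from_counts <- function(cnt) {
  p <- cnt / sum(cnt)
  p <- p[p > 0]
  -sum(p * log2(p))
}

.word_energies <- function(N, energies) {
  words <- all_kmers(N)
  if (N == 2) {
    unname(energies[words])
  } else {
    # energy of a longer word is the sum of its overlapping dinucleotides
    e <- numeric(length(words))
    for (i in seq_len(N - 1)) {
      e <- e + energies[substr(words, i, i + 1)]
    }
    unname(e)
  }
}

.gibbs_from_counts <- function(cnt, word_e, temperature_K) {
  w <- cnt * exp(-word_e / (.KB_KCAL_MOL * temperature_K))
  p <- w / sum(w)
  p <- p[p > 0]
  -sum(p * log(p))
}

.kld_from_counts <- function(cnt, q, epsilon = 1e-6, label = "") {
  p <- cnt / sum(cnt)
  if (any(p > 0 & q <= 0)) {
    message("background has zero mass on observed ", label,
            "-mer(s); flooring at epsilon = ", epsilon, " and renormalizing")
    q <- pmax(q, epsilon)
    q <- q / sum(q)
  }
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / q[nz]))
}

# ---- exported single-sequence operations ----------------------------------

#' Mutual information between consecutive bases
#'
#' Estimates the joint distribution P(x, y) of ordered base pairs from all
#' overlapping consecutive pairs of the sequence; the marginals are the row
#' and column sums of that joint, which makes the plug-in mutual information
#' nonnegative by construction. Returns the total MI (bits) together with
#' the 16 per-pair summands P(x,y) log2 P(x,y)/(P(x)P(y)), each of which is
#' used as a classification feature.
#'
#' @param seq DNA string (A/C/G/T), length >= 2.
#' @return A \code{pair_term_set}: list with \code{total} and the 16 named
#'   \code{terms} (bits).
#' @export
mi_features <- function(seq) {
  if (nchar(seq) < 2) stop("sequence shorter than 2")
  .mi_from_counts(kmer_counts(seq, 2))
}

#' Conditional mutual information across a base triplet
#'
#' Treats the first, middle and last positions of every overlapping triplet
#' as random variables X, Z and Y and computes I(X; Y | Z) -- the
#' information shared by the outer bases given the middle one -- along with
#' the 64 per-triplet summands P(x,z,y) log2 P(z)P(x,z,y)/(P(x,z)P(z,y)).
#'
#' @param seq DNA string, length >= 3.
#' @return A \code{triplet_term_set}: list with \code{total} and the 64
#'   named \code{terms} (bits); names are the triplets in sequence order
#'   (first, middle, last base).
#' @export
cmi_features <- function(seq) {
  if (nchar(seq) < 3) stop("sequence shorter than 3")
  .cmi_from_counts(kmer_counts(seq, 3))
}

#' Shannon block entropy of a sequence
#'
#' Plug-in Shannon entropy of the distribution of overlapping N-mers.
#'
#' @param seq DNA string, length >= N.
#' @param N Block size, 2 or 3.
#' @return Entropy in bits, in [0, 2N].
#' @export
shannon_entropy <- function(seq, N) {
  stopifnot(N %in% 2:3)
  if (nchar(seq) < N) stop("sequence shorter than N = ", N)
  .shannon_from_counts(kmer_counts(seq, N))
}

#' Gibbs (Boltzmann-weighted) block entropy of a sequence
#'
#' Entropy of the Boltzmann state distribution over N-mer words, where the
#' energy of a word is its nearest-neighbor dinucleotide free energy (for
#' N = 3, the sum of the two constituent overlapping dinucleotide energies)
#' and each word's weight is its occurrence count times
#' exp(-E/(kB T)). The value is reported in units of kB (the kB prefactor
#' is divided out, leaving a dimensionless entropy in nats); with a
#' constant-energy table it reduces to ln(2) times the Shannon entropy.
#'
#' @param seq DNA string, length >= N.
#' @param N Block size, 2 or 3.
#' @param table An \code{\link{energy_table}}.
#' @return Gibbs entropy in units of kB.
#' @export
gibbs_entropy <- function(seq, N, table = energy_table()) {
  stopifnot(N %in% 2:3, inherits(table, "energy_table"))
  if (nchar(seq) < N) stop("sequence shorter than N = ", N)
  .gibbs_from_counts(kmer_counts(seq, N),
                     .word_energies(N, table$energies), table$temperature_K)
}

#' Kullback-Leibler divergence from the background genome
#'
#' For k = 1, 2, 3, compares the gene's overlapping k-mer distribution P to
#' the training organism's background distribution Q and returns
#' KLD(P || Q) in bits. Terms with P = 0 contribute nothing; background
#' cells that are zero where the gene has mass are floored at
#' \code{epsilon} and Q renormalized (reported via \code{message()}).
#'
#' @param seq DNA string, length >= 3.
#' @param background A \code{\link{background_distribution}}.
#' @param epsilon Floor applied to zero background cells (default 1e-6).
#' @return Named numeric vector \code{c(KLD1, KLD2, KLD3)}, each >= 0.
#' @export
kld_features <- function(seq, background, epsilon = 1e-6) {
  stopifnot(inherits(background, "background_distribution"))
  if (nchar(seq) < 3) stop("sequence shorter than 3")
  out <- vapply(1:3, function(k) {
    .kld_from_counts(kmer_counts(seq, k), background$pmf[[as.character(k)]],
                     epsilon = epsilon, label = k)
  }, numeric(1))
  names(out) <- paste0("KLD", 1:3)
  out
}
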