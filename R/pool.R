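#' Peptide pool
#'
#' A pool is the multiset of molecular species present at one generation:
#' a data frame with columns `sequence` (oriented peptide string, N-to-C)
#' and `occurrences` (non-negative integer copy number). Duplicate
#' sequences are aggregated on construction; reversal of a sequence yields
#' a distinct species because peptides are oriented.
#'
#' @param sequences Character vector of peptide strings.
#' @param occurrences Integer copy numbers (recycled if length 1).
#' @return Object of class `"peptide_pool"` (a data frame).
#' @examples
#' p <- peptide_pool(c("G", "A", "G"), c(2, 1, 3))
#' pool_molecules(p)  # 6
#' @export
peptide_pool <- function(sequences = character(), occurrences = 1L) {
  stopifnot(is.character(sequences))
  occurrences <- as.integer(rep_len(occurrences, length(sequences)))
  if (any(is.na(occurrences)) || any(occurrences < 0))
    stop("occurrences must be non-negative integers")
  if (any(nchar(sequences) == 0L)) stop("sequences must be non-empty")
  if (length(sequences)) {
    agg <- rowsum(occurrences, sequences)
    pool <- data.frame(sequence = rownames(agg),
                       occurrences = as.integer(agg[, 1]),
                       stringsAsFactors = FALSE)
  } else {
    pool <- data.frame(sequence = character(), occurrences = integer(),
                       stringsAsFactors = FALSE)
  }
  rownames(pool) <- NULL
  class(pool) <- c("peptide_pool", "data.frame")
  pool
}

#' @rdname peptide_pool
#' @param pool A `peptide_pool`.
#' @export
pool_molecules <- function(pool) sum(pool$occurrences)

#' @rdname peptide_pool
#' @export
pool_residues <- function(pool) sum(pool$occurrences * nchar(pool$sequence))

#' @export
print.peptide_pool <- function(x, ...) {
  cat("peptide pool:", nrow(x), "species,", pool_molecules(x), "molecules,",
      pool_residues(x), "residues\n")
  if (nrow(x)) {
    shown <- utils::head(x[order(-x$occurrences), , drop = FALSE], 10L)
    print.data.frame(shown, row.names = FALSE)
    if (nrow(x) > 10L) cat("...", nrow(x) - 10L, "more species\n")
  }
  invisible(x)
}

# Drop zero-occurrence species.
.pool_compact <- function(pool) {
  out <- pool[pool$occurrences > 0L, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("peptide_pool", "data.frame")
  out
}

# Expand a pool into one string per molecule instance.
.pool_expand <- function(pool) rep(pool$sequence, pool$occurrences)

#' Default prebiotic starting pool
#'
#' The six prebiotic amino acids at the standard starting copy numbers:
#' 38 A, 4 D, 11 E, 100 G, 1 S and 10 V (164 molecules in total).
#'
#' @param glycine Copy number of glycine, varied by [glycine_sweep()].
#' @return A [peptide_pool()] of monomers.
#' @export
default_prebiotic_pool <- function(glycine = 100L) {
  stopifnot(glycine >= 0)
  peptide_pool(c("A", "D", "E", "G", "S", "V"),
               c(38L, 4L, 11L, as.integer(glycine), 1L, 10L))
}

#' Seeded random fixture pool
#'
#' Generates a deterministic random pool over the prebiotic alphabet:
#' uniform residues, uniform lengths within `length_range`, occurrence
#' counts uniform in 1..10.
#'
#' @param n_species Number of species to draw (>= 1).
#' @param length_range Integer vector `c(min, max)` of sequence lengths.
#' @param seed Integer RNG seed.
#' @return A [peptide_pool()].
#' @export
generate_fixture_pool <- function(n_species, length_range = c(1L, 8L),
                                  seed = 1L) {
  stopifnot(n_species >= 1, length(length_range) == 2L)
  length_range <- as.integer(length_range)
  if (any(length_range < 1L) || length_range[1] > length_range[2])
    stop("invalid length_range")
  ab <- prebiotic_alphabet()
  seqs <- withr::with_seed(seed, {
    lens <- length_range[1] - 1L +
      sample.int(length_range[2] - length_range[1] + 1L, n_species,
                 replace = TRUE)
    vapply(lens, function(L)
      paste(sample(ab, L, replace = TRUE), collapse = ""), character(1))
  })
  counts <- withr::with_seed(seed + 1L,
                             sample.int(10L, length(seqs), replace = TRUE))
  peptide_pool(seqs, counts)
}

#' Reference hypercycle cluster sequences
#'
#' Seven representative cluster sequences from one realized hypercycle
#' (labels alpha..gamma), useful as realistic long-peptide fixtures: alpha
#' and beta are knockout targets whose deletion co-extinguishes chi, delta
#' and epsilon.
#'
#' @return Named character vector of 7 peptide sequences.
#' @export
hypercycle_examples <- function() {
  c(alpha   = "AAGGAGGGGGGGGGGGGGAGGGAAGGGAAVGGGGG",
    beta    = "EGAAGGGGGGAGGGGVGGGVAGGGGDGGAGGGGAGAGGGA",
    chi     = "GAAEGGVGGDGVAGGGGVGGVAAGAGAGGAGGAVAGGG",
    delta   = "AAGGAGAGAGGGGGVGGAGGGVGGAGAGGGGGAGGGG",
    epsilon = "AGGAAGGEAGGGGAEGEAGAGAGG",
    phi     = "GEGEAGAGAGGGAAAGGGGAAGAGVADGGGGAGAAGAGGGAVDGVGAAGGGGG",
    gamma   = "GEAGGSGAAGGGGGAVGGGGVEGGGEGGGGGGGGGGAGGGG")
}
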