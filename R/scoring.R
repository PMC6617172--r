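#' Physico-chemical residue similarity coefficients
#'
#' Per-residue similarity coefficients derived from side-chain polarity and
#' free energy of solvation. The coefficient of a residue is a single
#' dimensionless number; residues with close coefficients behave as
#' chemically interchangeable during alignment scoring. The six amino acids
#' regarded as prebiotically available (A, V, G, E, D, S) are a subset of the
#' full 20-letter table.
#'
#' @return Named numeric vector of length 20; names are one-letter
#'   amino-acid codes.
#' @examples
#' residue_coefficients()[c("A", "G", "E")]
#' @export
residue_coefficients <- function() {
  c(L = 0,    I = 0,   F = 0.1, W = 0.2, V = 0.4,
    M = 0.4,  Y = 0.6, C = 0.6, A = 0.7, T = 2,
    G = 2.5,  H = -6,  R = -6,  S = 3,   Q = 5,
    D = 8,    N = -8,  K = -8,  E = -9,  P = 12)
}

#' Six-letter prebiotic amino-acid alphabet
#'
#' @return Character vector `c("A","V","G","E","D","S")`.
#' @export
prebiotic_alphabet <- function() c("A", "V", "G", "E", "D", "S")

#' Alignment parameters
#'
#' Bundles the linear gap penalty and the residue coefficient table used by
#' the local-alignment similarity score. The default gap penalty of 2
#' exceeds the maximum attainable per-residue match score (1), so gapped
#' paths are never optimal under the defaults; the gap branches are kept in
#' the recursion regardless.
#'
#' @param gap Non-negative linear gap penalty (default 2).
#' @param coefficients Named numeric vector of residue coefficients, as
#'   [residue_coefficients()].
#' @return Object of class `"alignment_params"`.
#' @export
alignment_params <- function(gap = 2, coefficients = residue_coefficients()) {
  stopifnot(is.numeric(gap), length(gap) == 1L, gap >= 0)
  if (is.null(names(coefficients)) || anyDuplicated(names(coefficients)))
    stop("coefficients must be uniquely named by one-letter residue code")
  structure(
    list(gap = as.numeric(gap),
         coefficients = coefficients,
         sim = residue_similarity_matrix(coefficients)),
    class = "alignment_params")
}

#' Pairwise residue similarity
#'
#' Similarity of two residues from their coefficients:
#' `10 / (10 + |S_a - S_b|)`. The score lies in (0, 1], is symmetric, and
#' equals 1 exactly when the two coefficients are equal.
#'
#' @param a,b One-letter amino-acid codes.
#' @param coefficients Residue coefficient table.
#' @return Numeric score in (0, 1].
#' @examples
#' residue_similarity("G", "G")  # 1
#' residue_similarity("A", "G")  # 10 / 11.8
#' @export
residue_similarity <- function(a, b, coefficients = residue_coefficients()) {
  sa <- .coef_lookup(a, coefficients)
  sb <- .coef_lookup(b, coefficients)
  10 / (10 + abs(sa - sb))
}

.coef_lookup <- function(code, coefficients) {
  i <- match(code, names(coefficients))
  if (anyNA(i))
    stop("unknown residue code: ", paste(code[is.na(i)], collapse = ", "))
  unname(coefficients[i])
}

#' Full residue-similarity matrix
#'
#' @param coefficients Residue coefficient table.
#' @return Symmetric numeric matrix with unit diagonal, dimnames the residue
#'   codes.
#' @export
residue_similarity_matrix <- function(coefficients = residue_coefficients()) {
  s <- outer(coefficients, coefficients, function(x, y) 10 / (10 + abs(x - y)))
  dimnames(s) <- list(names(coefficients), names(coefficients))
  s
}

# Integer-encode a peptide string against the coefficient alphabet.
.encode <- function(sequence, params) {
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stop("sequence must be a single non-empty string")
  ch <- strsplit(sequence, "", fixed = TRUE)[[1]]
  i <- match(ch, rownames(params$sim))
  if (anyNA(i))
    stop("unknown residue code: ", paste(unique(ch[is.na(i)]), collapse = ", "))
  i
}

#' Local-alignment score matrix
#'
#' Builds the (n1+1) x (n2+1) score matrix H of the local alignment of two
#' oriented peptides, with zero boundary row/column and the recursion
#' `H[i,j] = max(0, H[i-1,j-1] + S(a_i, b_j), H[i-1,j] - d, H[i,j-1] - d)`,
#' where S is the pairwise residue similarity and d the gap penalty.
#'
#' @param s1,s2 Non-empty peptide strings (N-to-C orientation).
#' @param params [alignment_params()].
#' @return Numeric matrix of non-negative scores.
#' @export
alignment_matrix <- function(s1, s2, params = alignment_params()) {
  a <- .encode(s1, params); b <- .encode(s2, params)
  align_matrix_cpp(a, b, params$sim, params$gap)
}

#' Normalized local-alignment similarity of two peptides
#'
#' The maximum entry of the local-alignment score matrix divided by the
#' length of the shorter sequence, clamped at 1. Symmetric in its
#' arguments; equals 1 exactly for identical sequences.
#'
#' @inheritParams alignment_matrix
#' @return Numeric score in \[0, 1\].
#' @examples
#' simil("AG", "AG")  # 1
#' simil("AG", "GG")  # ~0.924
#' @export
simil <- function(s1, s2, params = alignment_params()) {
  a <- .encode(s1, params); b <- .encode(s2, params)
  mh <- align_max_cpp(a, b, params$sim, params$gap)
  min(1, mh / min(length(a), length(b)))
}

#' Pairwise sequence distance
#'
#' `1 - simil(s1, s2)`: identical sequences have distance 0; all distances
#' lie in \[0, 1\]. Because `simil` normalizes by the shorter sequence, a
#' peptide has distance 0 to every longer peptide that locally contains
#' it; epoch clustering therefore thresholds the length-aware
#' [cluster_distance()] instead.
#'
#' @inheritParams alignment_matrix
#' @return Numeric distance in \[0, 1\].
#' @export
sequence_distance <- function(s1, s2, params = alignment_params()) {
  1 - simil(s1, s2, params)
}

#' Length-aware cluster distance
#'
#' `1 - min(1, maxH / max(len1, len2))`: the distance thresholded during
#' epoch clustering. Normalizing the local-alignment score by the longer
#' sequence makes the distance sensitive to both composition and length
#' ("clustered by length and similarity"): a short peptide embedded in a
#' much longer one scores near 1 even though their [sequence_distance()]
#' is 0. Identical sequences have distance 0; all values lie in \[0, 1\].
#'
#' @inheritParams alignment_matrix
#' @return Numeric distance in \[0, 1\].
#' @export
cluster_distance <- function(s1, s2, params = alignment_params()) {
  a <- .encode(s1, params); b <- .encode(s2, params)
  mh <- align_max_cpp(a, b, params$sim, params$gap)
  1 - min(1, mh / max(length(a), length(b)))
}

# Pairwise cluster-distance matrix over a character vector of sequences.
.cluster_distance_matrix <- function(sequences, params = alignment_params()) {
  enc <- lapply(sequences, .encode, params = params)
  h <- maxh_matrix_cpp(enc, params$sim, params$gap)
  len <- lengths(enc)
  d <- 1 - pmin(h / outer(len, len, pmax), 1)
  dimnames(d) <- list(sequences, sequences)
  d
}

# Cross cluster-distance matrix between two sequence sets.
.cluster_distance_cross <- function(seqs1, seqs2, params = alignment_params()) {
  e1 <- lapply(seqs1, .encode, params = params)
  e2 <- lapply(seqs2, .encode, params = params)
  h <- maxh_cross_cpp(e1, e2, params$sim, params$gap)
  1 - pmin(h / outer(lengths(e1), lengths(e2), pmax), 1)
}

#' Export the residue-similarity matrix in BLOSUM-style text format
#'
#' Writes the 20 x 20 residue-similarity matrix (and the underlying
#' coefficients as comments) as a whitespace-delimited square matrix with a
#' one-letter header row and row labels, the layout used by NCBI scoring
#' matrices, for interoperability checks with alignment tools.
#'
#' @param path Output file path.
#' @param coefficients Residue coefficient table.
#' @param digits Decimal places written (default 5).
#' @return `path`, invisibly.
#' @export
write_similarity_matrix <- function(path, coefficients = residue_coefficients(),
                                    digits = 5) {
  s <- residue_similarity_matrix(coefficients)
  codes <- rownames(s)
  lines <- c(
    "# Residue-similarity matrix 10 / (10 + |S_i - S_j|)",
    paste0("# coefficients: ",
           paste(codes, formatC(coefficients[codes], format = "fg"),
                 sep = "=", collapse = " ")),
    paste(c(" ", codes), collapse = " "))
  body <- vapply(codes, function(r) {
    paste(c(r, formatC(s[r, ], format = "f", digits = digits)), collapse = " ")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}
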