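# Independent oracles and fixture helpers shared across the suite.

# Random peptide over the prebiotic alphabet.
random_peptide <- function(len_range = c(1L, 6L)) {
  n <- len_range[1] - 1L + sample.int(len_range[2] - len_range[1] + 1L, 1L)
  paste(sample(pepcycle::prebiotic_alphabet(), n, replace = TRUE),
        collapse = "")
}

# Brute-force local-alignment maximum: enumerate every pair of non-empty
# contiguous substrings and score each with a plain Needleman-Wunsch
# recursion (linear gap d, end gaps inside the window penalized), keeping
# the best non-negative value. Independent of the package's DP.
brute_local_max <- function(s1, s2, d = 2,
                            coef = pepcycle::residue_coefficients()) {
  sim <- function(a, b) 10 / (10 + abs(coef[[a]] - coef[[b]]))
  nw <- function(a, b) {
    n <- length(a); m <- length(b)
    g <- matrix(0, n + 1, m + 1)
    g[, 1] <- -d * (0:n); g[1, ] <- -d * (0:m)
    for (i in seq_len(n)) for (j in seq_len(m))
      g[i + 1, j + 1] <- max(g[i, j] + sim(a[i], b[j]),
                             g[i, j + 1] - d, g[i + 1, j] - d)
    g[n + 1, m + 1]
  }
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  best <- 0
  for (i in seq_along(c1)) for (k in i:length(c1))
    for (j in seq_along(c2)) for (l in j:length(c2))
      best <- max(best, nw(c1[i:k], c2[j:l]))
  best
}

# Connected components of the thresholded distance graph by breadth-first
# search; the single-linkage clustering oracle.
components_oracle <- function(dmat, threshold) {
  n <- nrow(dmat)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      nb <- which(dmat[v, ] <= threshold & is.na(comp))
      queue <- c(queue, nb)
    }
  }
  comp
}

# Partition as a canonical signature (sorted member sets) for comparing
# clusterings that may label groups differently.
partition_signature <- function(groups) {
  sig <- vapply(groups, function(g) paste(sort(g), collapse = "|"),
                character(1))
  sort(sig)
}

# Small protocol used across experiment tests.
desk_protocol <- function(epochs = 4L, gens = 30L) {
  pepcycle::protocol_config(epochs = epochs, generations_per_epoch = gens)
}
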