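#' Length-dependent interaction coefficients
#'
#' The coefficient c(L) scales the probability that a molecule of length L
#' ligates: longer peptides interact more readily. Lengths 1 to 10 use the
#' tabulated constants; beyond 10 the logistic curve
#' `1 / (1 + exp(-0.8 (L - 4)))` extends the table (it reproduces the
#' tabulated values within 0.008 and stays strictly below 1).
#'
#' @return Numeric vector of the tabulated coefficients for lengths 1..10.
#' @export
interaction_coefficients <- function() {
  c(0.083, 0.168, 0.310, 0.500, 0.690,
    0.832, 0.917, 0.968, 0.982, 0.992)
}

#' @rdname interaction_coefficients
#' @param length Integer peptide length(s), >= 1.
#' @param table Tabulated coefficients for lengths 1..10.
#' @return `interaction_coefficient()`: coefficient(s) in (0, 1).
#' @examples
#' interaction_coefficient(4)   # 0.500
#' interaction_coefficient(12)  # logistic extension, ~0.998
#' @export
interaction_coefficient <- function(length, table = interaction_coefficients()) {
  if (any(length < 1)) stop("length must be >= 1")
  length <- as.integer(length)
  ifelse(length <= length(table),
         table[pmin.int(length, length(table))],
         1 / (1 + exp(-0.8 * (length - 4))))
}

#' Engine configuration
#'
#' Collects everything one Monte Carlo generation needs: the initial
#' monomer inventory (used for chemostat-style replenishment), the
#' fragmentation threshold (the length at and beyond which a peptide is
#' certain to fragment), alignment parameters and the interaction
#' coefficient table.
#'
#' @param initial_monomers Named integer vector, one-letter code -> copy
#'   number. Defaults to the standard prebiotic inventory.
#' @param fragmentation_threshold Integer >= 2; a peptide of this length
#'   fragments with probability 1. Default 60 so that the longest observed
#'   representatives (50+ residues) remain reachable.
#' @param replenish If `TRUE` (default) monomer counts are restored up to
#'   their initial values at the end of each generation.
#' @param alignment [alignment_params()].
#' @param interaction Tabulated interaction coefficients (lengths 1..10).
#' @return Object of class `"engine_config"`.
#' @export
engine_config <- function(initial_monomers = NULL,
                          fragmentation_threshold = 60L,
                          replenish = TRUE,
                          alignment = alignment_params(),
                          interaction = interaction_coefficients()) {
  if (is.null(initial_monomers)) {
    p <- default_prebiotic_pool()
    initial_monomers <- stats::setNames(p$occurrences, p$sequence)
  }
  if (is.null(names(initial_monomers)) || any(nchar(names(initial_monomers)) != 1L))
    stop("initial_monomers must be named by one-letter residue codes")
  fragmentation_threshold <- as.integer(fragmentation_threshold)
  if (is.na(fragmentation_threshold) || fragmentation_threshold < 2L)
    stop("fragmentation_threshold must be an integer >= 2")
  structure(
    list(initial_monomers = initial_monomers,
         fragmentation_threshold = fragmentation_threshold,
         replenish = isTRUE(replenish),
         alignment = alignment,
         interaction = interaction),
    class = "engine_config")
}

#' Ligation probability of a molecule pair
#'
#' For two peptides of lengths L1, L2 the acceptance probability is
#' `c(L1) * c(L2)` when both are short (length <= 3), and
#' `c(L1) * c(L2) * simil(s1, s2)` otherwise: similarity only gates the
#' ligation of longer partners, which is the template effect that lets
#' similar sequences amplify each other.
#'
#' @param s1,s2 Non-empty peptide strings.
#' @param config [engine_config()].
#' @return Probability in \[0, 1\].
#' @examples
#' synthesis_probability("G", "A")  # 0.083^2, no similarity factor
#' @export
synthesis_probability <- function(s1, s2, config = engine_config()) {
  l1 <- nchar(s1); l2 <- nchar(s2)
  if (l1 == 0L || l2 == 0L) stop("sequences must be non-empty")
  p <- interaction_coefficient(l1, config$interaction) *
       interaction_coefficient(l2, config$interaction)
  if (l1 > 3L || l2 > 3L) p <- p * simil(s1, s2, config$alignment)
  p
}

#' Single synthesis attempt
#'
#' Draws one uniform variate; with probability
#' [synthesis_probability()] one occurrence of each reactant is consumed
#' and one occurrence of the concatenation `s1 + s2` (s1 N-terminal) is
#' added. Residue mass is conserved either way. Uses the current R RNG
#' stream; seed with `set.seed()` for reproducibility.
#'
#' @param pool A [peptide_pool()] containing both reactants.
#' @param s1,s2 Reactant sequences (must each have occurrences >= 1).
#' @param config [engine_config()].
#' @return List with elements `pool` (updated) and `product` (the new
#'   sequence, or `NULL` if the attempt was rejected).
#' @export
attempt_synthesis <- function(pool, s1, s2, config = engine_config()) {
  i1 <- match(s1, pool$sequence); i2 <- match(s2, pool$sequence)
  if (is.na(i1) || is.na(i2)) stop("reactant absent from pool")
  need <- if (i1 == i2) 2L else 1L
  if (pool$occurrences[i1] < need || pool$occurrences[i2] < 1L)
    stop("reactant absent from pool")
  p <- synthesis_probability(s1, s2, config)
  if (stats::runif(1) <= p) {
    pool$occurrences[i1] <- pool$occurrences[i1] - 1L
    pool$occurrences[i2] <- pool$occurrences[i2] - 1L
    product <- paste0(s1, s2)
    j <- match(product, pool$sequence)
    if (is.na(j)) {
      pool <- peptide_pool(c(pool$sequence, product),
                           c(pool$occurrences, 1L))
    } else {
      pool$occurrences[j] <- pool$occurrences[j] + 1L
      pool <- .pool_compact(pool)
    }
    list(pool = .pool_compact(pool), product = product)
  } else {
    list(pool = pool, product = NULL)
  }
}

#' Fragmentation probability
#'
#' `min(1, length / threshold)`: fragmentation is certain at and beyond
#' the threshold length and proportional to length below it.
#'
#' @param length Peptide length(s) >= 1.
#' @param threshold Integer threshold >= 2.
#' @return Probability in \[0, 1\], non-decreasing in `length`.
#' @export
fragmentation_probability <- function(length, threshold) {
  if (any(length < 1)) stop("length must be >= 1")
  threshold <- as.integer(threshold)
  if (is.na(threshold) || threshold < 2L) stop("threshold must be >= 2")
  pmin(1, length / threshold)
}

#' Fragment a peptide at a random bond
#'
#' Cuts one molecule at a uniformly random internal bond, preserving
#' N-to-C orientation in both fragments. Residue count is conserved.
#'
#' @param sequence Peptide string of length >= 2.
#' @return Character vector `c(prefix, suffix)`.
#' @export
fragment_sequence <- function(sequence) {
  n <- nchar(sequence)
  if (n < 2L) stop("cannot fragment a monomer: no bond to cut")
  cut <- if (n == 2L) 1L else sample.int(n - 1L, 1L)
  c(substr(sequence, 1L, cut), substr(sequence, cut + 1L, n))
}

#' Run one Monte Carlo generation
#'
#' One generation is: (1) a synthesis sweep — all molecule instances are
#' shuffled and partitioned into disjoint pairs (an odd molecule idles),
#' each pair attempting ligation once at [synthesis_probability()], the
#' first-drawn molecule becoming the N-terminal part of the product;
#' (2) a fragmentation sweep — every multi-residue species is tested once
#' at [fragmentation_probability()] and, if it fires, one occurrence is
#' cut at a uniformly random bond (abundant species thus lose at most one
#' copy per generation, which is what lets large clusters persist);
#' (3) optional replenishment of monomers up to
#' their initial counts. Residue mass is invariant through (1) and (2);
#' only (3) adds mass. RNG draws occur in that fixed order (shuffle,
#' per-pair acceptance, per-molecule fragmentation, cut sites), so a
#' seeded run is fully reproducible.
#'
#' @param pool Non-empty [peptide_pool()].
#' @param config [engine_config()].
#' @param simil_cache Optional environment memoising pairwise similarity
#'   scores across calls (keyed on the unordered sequence pair).
#' @return List with `pool` (updated) and `stats`, a one-row data frame:
#'   syntheses attempted/accepted, fragmentations, distinct species, and
#'   residue counts before/after replenishment.
#' @export
run_generation <- function(pool, config = engine_config(),
                           simil_cache = NULL) {
  if (!nrow(pool) || pool_molecules(pool) == 0L) stop("empty pool")
  residues_in <- pool_residues(pool)

  # synthesis sweep over shuffled molecule instances
  mols <- .pool_expand(pool)
  mols <- mols[sample.int(length(mols))]
  n_pairs <- length(mols) %/% 2L
  attempted <- n_pairs
  accepted <- 0L
  products <- character(0)
  consumed <- character(0)
  if (n_pairs) {
    for (k in seq_len(n_pairs)) {
      s1 <- mols[2L * k - 1L]; s2 <- mols[2L * k]
      p <- .synthesis_probability_cached(s1, s2, config, simil_cache)
      if (stats::runif(1) <= p) {
        accepted <- accepted + 1L
        products <- c(products, paste0(s1, s2))
        consumed <- c(consumed, s1, s2)
      }
    }
  }
  if (accepted) {
    drop <- rowsum(rep(1L, length(consumed)), consumed)
    i <- match(rownames(drop), pool$sequence)
    pool$occurrences[i] <- pool$occurrences[i] - as.integer(drop[, 1])
    pool <- peptide_pool(c(pool$sequence, products),
                         c(pool$occurrences, rep(1L, length(products))))
    pool <- .pool_compact(pool)
  }

  # fragmentation sweep: each multi-residue species tested once; on
  # success one occurrence is cut at a random bond
  fragments <- 0L
  multi <- which(nchar(pool$sequence) >= 2L)
  if (length(multi)) {
    add <- character(0)
    for (i in multi) {
      s <- pool$sequence[i]
      pfrag <- fragmentation_probability(nchar(s), config$fragmentation_threshold)
      if (stats::runif(1) <= pfrag) {
        fragments <- fragments + 1L
        pool$occurrences[i] <- pool$occurrences[i] - 1L
        add <- c(add, fragment_sequence(s))
      }
    }
    if (fragments) {
      pool <- peptide_pool(c(pool$sequence, add),
                           c(pool$occurrences, rep(1L, length(add))))
      pool <- .pool_compact(pool)
    }
  }
  residues_pre_replenish <- pool_residues(pool)

  # chemostat replenishment of monomers up to initial counts
  if (config$replenish) {
    init <- config$initial_monomers
    cur <- stats::setNames(rep(0L, length(init)), names(init))
    have <- pool$sequence %in% names(init)
    cur[pool$sequence[have]] <- pool$occurrences[have]
    top_up <- pmax(init - cur, 0L)
    top_up <- top_up[top_up > 0L]
    if (length(top_up)) {
      pool <- peptide_pool(c(pool$sequence, names(top_up)),
                           c(pool$occurrences, as.integer(top_up)))
      pool <- .pool_compact(pool)
    }
  }

  stats <- data.frame(
    attempted = attempted, accepted = accepted, fragmentations = fragments,
    species = nrow(pool), molecules = pool_molecules(pool),
    residues_in = residues_in,
    residues_pre_replenish = residues_pre_replenish,
    residues_out = pool_residues(pool))
  list(pool = pool, stats = stats)
}

.synthesis_probability_cached <- function(s1, s2, config, cache) {
  l1 <- nchar(s1); l2 <- nchar(s2)
  p <- interaction_coefficient(l1, config$interaction) *
       interaction_coefficient(l2, config$interaction)
  if (l1 <= 3L && l2 <= 3L) return(p)
  if (is.null(cache)) return(p * simil(s1, s2, config$alignment))
  key <- if (s1 <= s2) paste(s1, s2) else paste(s2, s1)
  sm <- cache[[key]]
  if (is.null(sm)) {
    sm <- simil(s1, s2, config$alignment)
    cache[[key]] <- sm
  }
  p * sm
}
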