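test_that("interaction coefficients match the table and extend smoothly", {
  tab <- interaction_coefficients()
  expect_identical(tab, c(0.083, 0.168, 0.310, 0.500, 0.690,
                          0.832, 0.917, 0.968, 0.982, 0.992))
  expect_identical(interaction_coefficient(4), 0.500)
  expect_identical(interaction_coefficient(1), 0.083)
  expect_equal(interaction_coefficient(12), 1 / (1 + exp(-0.8 * 8)),
               tolerance = 1e-12)
  # non-decreasing across the table boundary and strictly below 1
  co <- interaction_coefficient(1:40)
  expect_true(all(diff(co) >= 0))
  expect_true(all(co > 0 & co < 1))
  expect_error(interaction_coefficient(0), ">= 1")
})

test_that("synthesis probability branches on the short-pair rule", {
  cfg <- engine_config()
  expect_equal(synthesis_probability("G", "A", cfg), 0.083^2)
  expect_equal(synthesis_probability("GGG", "AAA", cfg), 0.310^2)
  expect_equal(synthesis_probability("GGGG", "GGGG", cfg), 0.500^2 * 1)
  # the similarity factor only gates pairs with a long member
  s_short <- synthesis_probability("GGG", "EEE", cfg)
  expect_equal(s_short, 0.310^2)
  s_long <- synthesis_probability("GGGG", "EEEE", cfg)
  expect_lt(s_long, 0.500^2)
  set.seed(21)
  for (i in 1:25) {
    p <- synthesis_probability(random_peptide(), random_peptide(), cfg)
    expect_gte(p, 0); expect_lte(p, 1)
  }
})

test_that("attempt_synthesis consumes reactants and conserves residues", {
  pool <- peptide_pool(c("G", "A"), c(5L, 5L))
  forced <- engine_config(interaction = rep(1, 10))
  blocked <- engine_config(interaction = rep(0, 10))
  set.seed(22)
  res <- attempt_synthesis(pool, "G", "A", forced)
  expect_identical(res$product, "GA")
  expect_identical(res$pool$occurrences[match(c("A", "G", "GA"),
                                              res$pool$sequence)],
                   c(4L, 4L, 1L))
  expect_identical(pool_residues(res$pool), pool_residues(pool))
  res0 <- attempt_synthesis(pool, "G", "A", blocked)
  expect_null(res0$product)
  expect_identical(res0$pool, pool)
  expect_error(attempt_synthesis(pool, "V", "A", forced), "absent")
  # self-reaction needs two copies
  expect_error(attempt_synthesis(peptide_pool("G", 1L), "G", "G", forced),
               "absent")
  # fixed seed reproduces the accept/reject stream
  draw <- function() {
    set.seed(23)
    replicate(20, is.null(attempt_synthesis(pool, "G", "A",
                                            engine_config())$product))
  }
  expect_identical(draw(), draw())
})

test_that("fragmentation probability is the clamped length ratio", {
  expect_identical(fragmentation_probability(60, 60), 1)
  expect_identical(fragmentation_probability(25, 50), 0.5)
  expect_identical(fragmentation_probability(120, 60), 1)
  expect_true(all(diff(fragmentation_probability(1:100, 60)) >= 0))
  expect_error(fragmentation_probability(5, 1), ">= 2")
  expect_error(fragmentation_probability(0, 60), ">= 1")
})

test_that("fragment_sequence cuts one bond uniformly, conserving residues", {
  set.seed(24)
  expect_identical(fragment_sequence("AG"), c("A", "G"))
  expect_error(fragment_sequence("A"), "monomer")
  for (i in 1:20) {
    parent <- random_peptide(c(2, 8))
    fr <- fragment_sequence(parent)
    expect_identical(paste0(fr[1], fr[2]), parent)
  }
  # empirical cut-site frequencies for a 4-mer: 1/3 each within 3 sigma
  n <- 10000
  cuts <- replicate(n, nchar(fragment_sequence("AAAA")[1]))
  p <- 1 / 3
  sigma <- sqrt(n * p * (1 - p))
  for (k in 1:3)
    expect_lt(abs(sum(cuts == k) - n * p), 3 * sigma)
})

test_that("run_generation conserves residue mass before replenishment", {
  pool <- default_prebiotic_pool()
  set.seed(25)
  for (g in 1:50) {
    res <- run_generation(pool)
    expect_identical(res$stats$residues_pre_replenish, res$stats$residues_in)
    pool <- res$pool
  }
  expect_error(run_generation(peptide_pool()), "empty pool")
})

test_that("a blocked pool is unchanged except for replenishment", {
  pool <- default_prebiotic_pool()
  blocked <- engine_config(interaction = rep(0, 10))
  set.seed(26)
  res <- run_generation(pool, blocked)
  expect_identical(res$pool, pool)  # monomers cannot fragment either
  expect_identical(res$stats$accepted, 0L)
})

test_that("forced synthesis without fragmentation halves the pool each sweep", {
  # all interaction coefficients 1 => P = 1 for short pairs; an immense
  # fragmentation threshold makes cuts essentially impossible at these sizes
  # a glycine homopolymer pool keeps simil = 1 for every pair, so the
  # acceptance probability is exactly 1 at any length
  cfg <- engine_config(interaction = rep(1, 10),
                       fragmentation_threshold = .Machine$integer.max,
                       replenish = FALSE)
  pool <- peptide_pool("G", 164L)
  set.seed(27)
  for (expected in c(82L, 41L, 21L)) {
    pool <- run_generation(pool, cfg)$pool
    expect_identical(pool_molecules(pool), expected)
  }
})

test_that("seeded generations are exactly reproducible", {
  run <- function() {
    set.seed(28)
    pool <- default_prebiotic_pool()
    for (g in 1:30) pool <- run_generation(pool)$pool
    pool
  }
  expect_identical(run(), run())
})

test_that("oriented sequences are distinct species", {
  pool <- peptide_pool(c("GENESYS", "SYSENEG"), c(1L, 1L))
  expect_identical(nrow(pool), 2L)
})
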