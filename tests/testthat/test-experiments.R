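test_that("protocol configuration validates its dimensions", {
  cfg <- protocol_config(epochs = 5, generations_per_epoch = 10)
  expect_identical(cfg$total_generations, 50L)
  expect_error(protocol_config(epochs = 0), "positive")
  expect_error(protocol_config(generations_per_epoch = 0), "positive")
})

test_that("run_protocol records one cluster table and snapshot per epoch", {
  h <- run_protocol(protocol_config(epochs = 1, generations_per_epoch = 1),
                    seed = 41)
  expect_s3_class(h, "epoch_history")
  expect_length(h$epochs, 1L)
  expect_length(h$snapshots, 1L)
  h3 <- run_protocol(desk_protocol(3, 20), seed = 41)
  expect_identical(nrow(h3$stats), 3L)
  # snapshot pool equals monomers plus that epoch's cluster table
  tab <- h3$epochs[[3]]
  snap <- h3$snapshots[[3]]
  poly <- snap[nchar(snap$sequence) >= 2, ]
  expect_setequal(poly$sequence, tab$representative)
  expect_identical(sum(poly$occurrences), sum(tab$occurrences))
})

test_that("identical seed and config reproduce the history exactly", {
  h1 <- run_protocol(desk_protocol(), seed = 42)
  h2 <- run_protocol(desk_protocol(), seed = 42)
  expect_identical(h1$epochs, h2$epochs)
  expect_identical(h1$snapshots, h2$snapshots)
  expect_identical(occurrence_matrix(h1), occurrence_matrix(h2))
  h3 <- run_protocol(desk_protocol(), seed = 43)
  expect_false(identical(h1$epochs, h3$epochs))
})

test_that("occurrence matrix and trajectory agree with the epoch tables", {
  h <- run_protocol(desk_protocol(5, 30), seed = 44)
  m_exact <- occurrence_matrix(h, match = "exact")
  for (e in seq_len(5)) {
    tab <- h$epochs[[e]]
    for (r in seq_len(nrow(tab)))
      expect_identical(m_exact[tab$representative[r], e], tab$occurrences[r])
  }
  # threshold matching reproduces each representative's own epoch count
  m <- occurrence_matrix(h)
  for (e in seq_len(5)) {
    tab <- h$epochs[[e]]
    for (r in seq_len(nrow(tab)))
      expect_identical(m[tab$representative[r], e], tab$occurrences[r])
  }
  # a sequence never near the pool has an all-zero trajectory
  expect_identical(trajectory(h, "PPPPPPPPPP"), integer(5))
  # trajectories match matrix rows for observed representatives
  rep1 <- rownames(m)[1]
  expect_identical(trajectory(h, rep1), unname(m[rep1, ]))
})

test_that("null knockout replays the baseline exactly", {
  h <- run_protocol(desk_protocol(5, 30), seed = 45)
  r <- knockout_and_restart(h, NULL, epoch = 3)
  expect_identical(r$co_extinct, character(0))
  base_later <- lapply(h$epochs[4:5], function(e) e[, names(e) != "epoch"])
  ko_later <- lapply(r$knockout_epochs, function(e) e[, names(e) != "epoch"])
  expect_identical(base_later, ko_later)
})

test_that("knockout reports are coherent set partitions of later epochs", {
  h <- run_protocol(desk_protocol(6, 40), seed = 46)
  target <- select_knockout_target(h, 4)
  expect_false(is.na(target))
  r <- knockout_and_restart(h, target, epoch = 4)
  base_later <- unique(unlist(lapply(h$epochs[5:6],
                                     function(e) e$representative)))
  expect_length(intersect(r$co_extinct, r$surviving), 0L)
  expect_true(all(c(r$co_extinct, r$surviving, r$reformed) %in% base_later))
  expect_setequal(c(r$co_extinct, r$surviving, r$reformed), base_later)
  expect_false(target %in% r$surviving)
  # independent recomputation of the co-extinct set from the two histories
  ko_later <- unique(unlist(lapply(r$knockout_epochs,
                                   function(e) e$representative)))
  gone <- vapply(base_later, function(s) {
    if (!length(ko_later)) return(TRUE)
    all(vapply(ko_later, function(k) cluster_distance(s, k) > 0.300,
               logical(1)))
  }, logical(1))
  expect_setequal(r$co_extinct, base_later[gone])
  expect_error(knockout_and_restart(h, "PPPP", epoch = 4),
               "not a representative")
})

test_that("direction-change counting skips plateaus and flags alternation", {
  dc <- pepcycle:::.direction_changes
  expect_identical(dc(c(5, 5, 5)), 0L)
  expect_identical(dc(c(1, 3, 1, 3, 1)), 3L)
  expect_identical(dc(c(1, 2, 2, 3)), 0L)
  expect_identical(dc(c(1, 4, 4, 2, 5)), 2L)
})

test_that("oscillation detection agrees with a scan of the matrix", {
  h <- run_protocol(desk_protocol(6, 40), seed = 47)
  osc <- detect_oscillations(h, min_changes = 2)
  m <- occurrence_matrix(h)
  for (i in seq_len(nrow(m))) {
    d <- diff(m[i, ]); d <- d[d != 0]
    changes <- if (length(d) < 2) 0L else
      sum(sign(d[-1]) != sign(d[-length(d)]))
    row <- osc[osc$representative == rownames(m)[i], ]
    expect_identical(row$n_changes, changes)
    expect_identical(row$oscillating, changes >= 2)
  }
  expect_error(
    detect_oscillations(run_protocol(desk_protocol(2, 5), seed = 1)),
    "at least 3")
})

test_that("hypercycle grouping unions overlapping co-extinct sets", {
  fake <- function(target, co, id = "base") {
    structure(list(target = target, epoch = 4L, co_extinct = co,
                   surviving = character(), reformed = character(),
                   baseline_id = id),
              class = "knockout_report")
  }
  r1 <- fake("AAA", c("X1", "X2"))
  r2 <- fake("BBB", c("X2", "X3"))
  r3 <- fake("CCC", "Y1")
  g <- hypercycle_membership(list(r1, r2, r3))
  expect_length(g, 2L)
  expect_identical(partition_signature(g),
                   partition_signature(list(
                     c("AAA", "BBB", "X1", "X2", "X3"),
                     c("CCC", "Y1"))))
  # order independence
  g2 <- hypercycle_membership(list(r3, r2, r1))
  expect_identical(partition_signature(g2), partition_signature(g))
  expect_identical(hypercycle_membership(list(r3))[[1]], c("CCC", "Y1"))
  expect_error(hypercycle_membership(list(r1, fake("D", "Z", id = "other"))),
               "different baseline")
})

test_that("sweep conditions enumerate consecutive glycine counts", {
  sc <- sweep_conditions(75, 124, seed = 2)
  expect_identical(nrow(sc), 50L)
  expect_identical(sc$glycine, 75:124)
  expect_identical(sc$seed, 2L + 1:50)
  expect_error(sweep_conditions(10, 5), "invalid")
})

test_that("a degenerate sweep condition reproduces a plain protocol run", {
  cfg <- desk_protocol(3, 20)
  sw <- glycine_sweep(cfg, 100, 100, seed = 7)
  expect_identical(nrow(sw$conditions), 1L)
  h <- run_protocol(cfg, seed = 8)  # condition 1 uses seed 7 + 1
  expect_identical(sw$final_clusters[[1]], h$epochs[[3]])
})

test_that("sweep abundance summary conserves per-condition occurrence mass", {
  cfg <- desk_protocol(3, 20)
  sw <- glycine_sweep(cfg, 98, 102, seed = 11)
  expect_identical(nrow(sw$conditions), 5L)
  ab <- sw$abundance
  expect_true(all(diff(ab$mean_occurrences) <= 0))
  expect_true(all(ab$n_conditions_present >= 1))
  # the group means partition the occurrence mass: their sum equals the
  # mean over conditions of the final-epoch occurrence totals
  totals <- vapply(sw$final_clusters, function(tab)
    sum(tab$occurrences), numeric(1))
  expect_equal(sum(ab$mean_occurrences), mean(totals), tolerance = 1e-9)
  # every abundance sequence is a representative somewhere in the sweep
  all_reps <- unique(unlist(lapply(sw$final_clusters,
                                   function(tab) tab$representative)))
  expect_true(all(ab$sequence %in% all_reps))
})
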