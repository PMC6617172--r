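#' Protocol configuration
#'
#' A full experiment is `epochs` blocks of `generations_per_epoch` Monte
#' Carlo generations, each block terminated by similarity clustering of
#' the pool; the reduced pool of representatives seeds the next epoch.
#' Defaults: 20 epochs of 400 generations (8000 generations in total).
#'
#' @param epochs Positive integer number of epochs (default 20).
#' @param generations_per_epoch Positive integer (default 400).
#' @param engine [engine_config()].
#' @param clustering [clustering_params()].
#' @return Object of class `"protocol_config"`.
#' @export
protocol_config <- function(epochs = 20L, generations_per_epoch = 400L,
                            engine = engine_config(),
                            clustering = clustering_params()) {
  epochs <- as.integer(epochs)
  generations_per_epoch <- as.integer(generations_per_epoch)
  if (is.na(epochs) || epochs < 1L) stop("epochs must be a positive integer")
  if (is.na(generations_per_epoch) || generations_per_epoch < 1L)
    stop("generations_per_epoch must be a positive integer")
  structure(
    list(epochs = epochs,
         generations_per_epoch = generations_per_epoch,
         total_generations = epochs * generations_per_epoch,
         engine = engine,
         clustering = clustering),
    class = "protocol_config")
}

#' Run a full multi-epoch protocol
#'
#' Runs `epochs x generations_per_epoch` generations with end-of-epoch
#' clustering and records, per epoch, the cluster table and a snapshot of
#' the reduced pool. Each epoch consumes its own RNG seed drawn once from
#' the master seed, so a run can be replayed bit-exactly from any epoch
#' snapshot (the paired-seed restart used by [knockout_and_restart()]).
#'
#' @param config [protocol_config()].
#' @param seed Integer master seed.
#' @param initial_pool Optional starting [peptide_pool()]; defaults to the
#'   monomer inventory of the engine config.
#' @param verbose If `TRUE`, print a one-line summary per epoch.
#' @return Object of class `"epoch_history"`: per-epoch cluster tables,
#'   epoch-boundary pool snapshots, per-epoch generation statistics, the
#'   master and per-epoch seeds, and the configuration.
#' @export
run_protocol <- function(config = protocol_config(), seed = 1L,
                         initial_pool = NULL, verbose = FALSE) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer")
  if (is.null(initial_pool)) {
    initial_pool <- peptide_pool(names(config$engine$initial_monomers),
                                 as.integer(config$engine$initial_monomers))
  }
  epoch_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, config$epochs))
  state <- .run_epochs(initial_pool, config, epoch_seeds,
                       from_epoch = 1L, verbose = verbose)
  structure(
    list(epochs = state$epochs,
         snapshots = state$snapshots,
         stats = state$stats,
         seed = seed,
         epoch_seeds = epoch_seeds,
         config = config,
         initial_pool = initial_pool,
         baseline_id = .history_id(seed, config, state$epochs)),
    class = "epoch_history")
}

# Replay epochs from_epoch..epochs starting from `pool`, using the given
# per-epoch seeds. Shared by run_protocol and knockout_and_restart.
.run_epochs <- function(pool, config, epoch_seeds, from_epoch, verbose = FALSE) {
  epochs_list <- vector("list", config$epochs)
  snapshots <- vector("list", config$epochs)
  stats_list <- vector("list", config$epochs)
  cache <- new.env(parent = emptyenv())
  for (e in seq(from_epoch, config$epochs)) {
    set.seed(epoch_seeds[e])
    attempted <- accepted <- fragmentations <- 0L
    for (g in seq_len(config$generations_per_epoch)) {
      res <- run_generation(pool, config$engine, simil_cache = cache)
      pool <- res$pool
      attempted <- attempted + res$stats$attempted
      accepted <- accepted + res$stats$accepted
      fragmentations <- fragmentations + res$stats$fragmentations
    }
    # clustering reduces the generated polymers; the monomer food set
    # passes through epochs untouched
    mono <- pool[nchar(pool$sequence) == 1L, , drop = FALSE]
    poly <- pool[nchar(pool$sequence) >= 2L, , drop = FALSE]
    if (nrow(poly)) {
      cl <- cluster_pool(poly, config$clustering, config$engine$alignment)
      tab <- cl$clusters
      pool <- peptide_pool(c(mono$sequence, cl$pool$sequence),
                           c(mono$occurrences, cl$pool$occurrences))
    } else {
      tab <- data.frame(representative = character(),
                        occurrences = integer(), n_members = integer(),
                        stringsAsFactors = FALSE)
      pool <- peptide_pool(mono$sequence, mono$occurrences)
    }
    tab$epoch <- rep(e, nrow(tab))
    epochs_list[[e]] <- tab
    snapshots[[e]] <- pool
    stats_list[[e]] <- data.frame(
      epoch = e, clusters = nrow(tab), occurrences = sum(tab$occurrences),
      syntheses = accepted, attempted = attempted,
      fragmentations = fragmentations)
    if (verbose)
      message(sprintf("epoch %d: %d clusters, %d occurrences, %d syntheses, %d fragmentations",
                      e, nrow(tab), sum(tab$occurrences), accepted, fragmentations))
  }
  list(epochs = epochs_list, snapshots = snapshots,
       stats = do.call(rbind, stats_list))
}

.history_id <- function(seed, config, epochs_list) {
  occ <- vapply(epochs_list, function(e)
    if (is.null(e)) NA_integer_ else sum(e$occurrences), integer(1))
  paste(seed, config$epochs, config$generations_per_epoch,
        paste(occ, collapse = ","), sep = "/")
}

#' @export
print.epoch_history <- function(x, ...) {
  cat("epoch history:", x$config$epochs, "epochs x",
      x$config$generations_per_epoch, "generations (seed", x$seed, ")\n")
  print(x$stats, row.names = FALSE)
  invisible(x)
}

#' Occurrence matrix of an epoch history
#'
#' Rows are the distinct representatives observed across the history,
#' columns are epochs; entries are per-epoch occurrence counts. With
#' `match = "threshold"` (default) a representative's count at an epoch is
#' that of the nearest epoch cluster within the clustering distance
#' threshold (clusters are tracked as entities even when their
#' representative string drifts); with `match = "exact"` only exact string
#' matches count.
#'
#' @param history An `epoch_history`.
#' @param match `"threshold"` or `"exact"`.
#' @return Integer matrix, rownames the representatives.
#' @export
occurrence_matrix <- function(history, match = c("threshold", "exact")) {
  match <- match.arg(match)
  reps <- unique(unlist(lapply(history$epochs, function(e) e$representative)))
  E <- history$config$epochs
  out <- matrix(0L, nrow = length(reps), ncol = E,
                dimnames = list(reps, paste0("epoch", seq_len(E))))
  params <- history$config$engine$alignment
  thr <- history$config$clustering$distance_threshold
  for (e in seq_len(E)) {
    tab <- history$epochs[[e]]
    if (is.null(tab) || !nrow(tab)) next
    if (match == "exact") {
      i <- match(tab$representative, reps)
      out[i, e] <- tab$occurrences
    } else {
      d <- .cluster_distance_cross(reps, tab$representative, params)
      for (r in seq_along(reps)) {
        j <- which.min(d[r, ])
        if (d[r, j] <= thr) out[r, e] <- tab$occurrences[j]
      }
    }
  }
  out
}

#' Occurrence trajectory of one sequence
#'
#' For each epoch, the occurrence count of the cluster whose
#' representative lies within the clustering distance threshold of the
#' query (the nearest such cluster), or 0 when none does.
#'
#' @param history An `epoch_history`.
#' @param sequence Query peptide string.
#' @return Integer vector, one entry per epoch.
#' @export
trajectory <- function(history, sequence) {
  params <- history$config$engine$alignment
  thr <- history$config$clustering$distance_threshold
  E <- history$config$epochs
  out <- integer(E)
  for (e in seq_len(E)) {
    tab <- history$epochs[[e]]
    if (is.null(tab) || !nrow(tab)) next
    d <- .cluster_distance_cross(sequence, tab$representative, params)[1, ]
    j <- which.min(d)
    if (d[j] <= thr) out[e] <- tab$occurrences[j]
  }
  out
}
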