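#' Knockout-and-restart perturbation
#'
#' Deletes one cluster from an epoch-boundary snapshot of a baseline run
#' and replays the remaining epochs with the baseline's own per-epoch
#' seeds (paired-seed restart: the two runs are identical up to the
#' knockout epoch, so every later divergence is caused by the deletion
#' alone). A baseline representative "persists" in the knockout run when
#' any later knockout representative lies within the clustering distance
#' threshold; representatives present after the knockout epoch in the
#' baseline but never in the knockout run form the co-extinct set — the
#' operational signature that they shared an autocatalytic hypercycle
#' with the target. The co-extinct set includes the target's own cluster
#' when it fails to re-form; a target-like cluster that is rebuilt de
#' novo is reported in the `reformed` field instead of `surviving`.
#' `target = NULL` performs a null knockout, which reproduces the
#' baseline exactly.
#'
#' @param history Baseline `epoch_history` from [run_protocol()].
#' @param target Representative sequence present at `epoch`, or `NULL`.
#' @param epoch Knockout epoch index (default 4).
#' @return Object of class `"knockout_report"`: target, epoch, co-extinct
#'   and surviving representative sets, and the replayed epoch tables.
#' @export
knockout_and_restart <- function(history, target, epoch = 4L) {
  epoch <- as.integer(epoch)
  config <- history$config
  if (epoch < 1L || epoch > config$epochs) stop("invalid knockout epoch")
  snapshot <- history$snapshots[[epoch]]
  if (!is.null(target)) {
    i <- match(target, snapshot$sequence)
    if (is.na(i)) stop("target is not a representative at epoch ", epoch)
    snapshot$occurrences[i] <- 0L
    snapshot <- .pool_compact(snapshot)
    if (!nrow(snapshot)) {
      if (!config$engine$replenish)
        stop("knockout empties the pool and replenishment is disabled")
      # the chemostat keeps feeding monomers even when the pool is emptied
      snapshot <- peptide_pool(names(config$engine$initial_monomers),
                               as.integer(config$engine$initial_monomers))
    }
  }
  if (epoch == config$epochs) {
    ko_epochs <- list()
  } else {
    state <- .run_epochs(snapshot, config, history$epoch_seeds,
                         from_epoch = epoch + 1L)
    ko_epochs <- state$epochs[seq(epoch + 1L, config$epochs)]
  }

  later <- function(epochs_list) {
    tabs <- Filter(Negate(is.null), epochs_list)
    unique(unlist(lapply(tabs, function(e) e$representative)))
  }
  base_later <- if (epoch < config$epochs)
    later(history$epochs[seq(epoch + 1L, config$epochs)]) else character(0)
  ko_later <- later(ko_epochs)

  params <- config$engine$alignment
  thr <- config$clustering$distance_threshold
  co_extinct <- character(0); surviving <- character(0)
  reformed <- character(0)
  if (length(base_later)) {
    if (length(ko_later)) {
      d <- .cluster_distance_cross(base_later, ko_later, params)
      persisted <- apply(d, 1L, function(r) any(r <= thr))
    } else {
      persisted <- rep(FALSE, length(base_later))
    }
    target_like <- if (is.null(target)) rep(FALSE, length(base_later)) else
      .cluster_distance_cross(base_later, target, params)[, 1] <= thr
    co_extinct <- base_later[!persisted]
    # a target-like cluster that persists was rebuilt de novo after the
    # deletion; it is reported apart, never as "surviving"
    surviving <- base_later[persisted & !target_like]
    reformed <- base_later[persisted & target_like]
  }
  structure(
    list(target = target, epoch = epoch,
         co_extinct = co_extinct, surviving = surviving,
         reformed = reformed,
         knockout_epochs = ko_epochs,
         baseline_id = history$baseline_id),
    class = "knockout_report")
}

#' Choose a knockout target
#'
#' Selects the representative to delete in a knockout experiment,
#' mirroring how perturbation targets are chosen in practice: a prominent
#' cluster whose abundance has been varying rather than growing
#' monotonically. The default `"variable"` rule takes, among the polymer
#' clusters at the knockout epoch whose trajectory up to that epoch shows
#' at least one direction change, the longest sequence (the
#' most-developed variable cluster); when none varies it falls back to
#' the longest overall. Alternative rules: `"longest"` (the
#' most-developed cluster regardless of variability) and `"abundant"`
#' (the largest).
#'
#' @param history Baseline `epoch_history`.
#' @param epoch Knockout epoch.
#' @param rule `"variable"` (default), `"longest"` or `"abundant"`.
#' @return A representative sequence, or `NA_character_` when no polymer
#'   cluster exists at that epoch.
#' @export
select_knockout_target <- function(history, epoch = 4L,
                                   rule = c("variable", "longest", "abundant")) {
  rule <- match.arg(rule)
  tab <- history$epochs[[epoch]]
  cand <- tab[nchar(tab$representative) >= 2L, , drop = FALSE]
  if (!nrow(cand)) return(NA_character_)
  if (rule == "longest") {
    ord <- order(-nchar(cand$representative), -cand$occurrences)
  } else if (rule == "abundant") {
    ord <- order(-cand$occurrences, -nchar(cand$representative))
  } else {
    traj <- lapply(cand$representative, function(s)
      trajectory(history, s)[seq_len(epoch)])
    varies <- vapply(traj, function(x)
      .direction_changes(x) >= 1L, logical(1))
    if (any(varies)) cand <- cand[varies, , drop = FALSE]
    ord <- order(-nchar(cand$representative), -cand$occurrences)
  }
  cand$representative[ord[1L]]
}

#' @export
print.knockout_report <- function(x, ...) {
  cat("knockout report: target",
      if (is.null(x$target)) "<none>" else x$target,
      "at epoch", x$epoch, "\n")
  cat("  co-extinct:", length(x$co_extinct), "representative(s)\n")
  if (length(x$co_extinct))
    cat(paste0("    ", x$co_extinct, collapse = "\n"), "\n")
  cat("  surviving: ", length(x$surviving), "representative(s)\n")
  invisible(x)
}

#' Detect oscillating cluster trajectories
#'
#' Counts strict sign changes in the first differences of each
#' representative's occurrence trajectory (zero differences are skipped).
#' Trajectories with at least `min_changes` direction changes are flagged
#' as oscillation candidates — the necessary-condition signature of
#' hypercycle membership (abundance varying cyclically rather than
#' monotonically).
#'
#' @param history An `epoch_history` with at least 3 epochs.
#' @param min_changes Flagging threshold (default 2).
#' @return Data frame: representative, n_changes, oscillating.
#' @export
detect_oscillations <- function(history, min_changes = 2L) {
  if (history$config$epochs < 3L)
    stop("oscillation detection needs at least 3 epochs")
  m <- occurrence_matrix(history)
  if (!nrow(m))
    return(data.frame(representative = character(), n_changes = integer(),
                      oscillating = logical(), stringsAsFactors = FALSE))
  n_changes <- apply(m, 1L, .direction_changes)
  data.frame(representative = rownames(m),
             n_changes = as.integer(n_changes),
             oscillating = n_changes >= min_changes,
             stringsAsFactors = FALSE, row.names = NULL)
}

.direction_changes <- function(series) {
  d <- diff(series)
  d <- d[d != 0]
  if (length(d) < 2L) return(0L)
  sum(sign(d[-1]) != sign(d[-length(d)]))
}

#' Group knockout targets into hypercycles
#'
#' Two knockout targets whose co-extinct sets share any representative
#' (Jaccard overlap > 0) are inferred to belong to the same hypercycle;
#' each group carries the union of its targets and co-extinct sets. The
#' grouping is independent of report order. All reports must derive from
#' the same baseline history.
#'
#' @param reports List of `knockout_report` objects.
#' @return List of character vectors (one group of member sequences each).
#' @export
hypercycle_membership <- function(reports) {
  if (!length(reports)) stop("no reports supplied")
  ids <- vapply(reports, function(r) r$baseline_id, character(1))
  if (length(unique(ids)) != 1L)
    stop("reports derive from different baseline histories")
  n <- length(reports)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  sets <- lapply(reports, function(r) r$co_extinct)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (length(intersect(sets[[i]], sets[[j]]))) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(unname(split(seq_len(n), roots)), function(idx) {
    members <- unlist(lapply(reports[idx], function(r)
      c(r$target, r$co_extinct)))
    sort(unique(members))
  })
}

#' Enumerate sweep conditions
#'
#' The glycine sweep varies the initial glycine copy number over a range
#' of consecutive integers (default 75..124, i.e. 50 conditions), each
#' with its own derived seed (`seed + condition index`).
#'
#' @param gly_min,gly_max Inclusive glycine range (defaults 75 and 124).
#' @param seed Master seed.
#' @return Data frame: condition, glycine, seed.
#' @export
sweep_conditions <- function(gly_min = 75L, gly_max = 124L, seed = 1L) {
  gly_min <- as.integer(gly_min); gly_max <- as.integer(gly_max)
  if (is.na(gly_min) || is.na(gly_max) || gly_min < 0L || gly_max < gly_min)
    stop("invalid glycine range")
  gly <- seq(gly_min, gly_max)
  data.frame(condition = seq_along(gly), glycine = gly,
             seed = as.integer(seed) + seq_along(gly))
}

#' Glycine initial-condition sweep
#'
#' Runs one full protocol per glycine copy number in the range, each from
#' the standard prebiotic pool with only glycine varied and a distinct
#' derived seed. Per condition it records the final-epoch cluster count
#' and whether any trajectory oscillates; across conditions it summarises
#' sequence abundance (clusters matched across conditions at the
#' clustering threshold; mean and standard deviation of per-condition
#' occurrences, absent conditions counting 0), sorted by mean abundance.
#'
#' @param config [protocol_config()] applied to every condition.
#' @param gly_min,gly_max Inclusive glycine range (defaults 75 and 124).
#' @param seed Master seed; condition i uses `seed + i`.
#' @param min_changes Oscillation flagging threshold.
#' @return Object of class `"sweep_report"`: `conditions` (per-condition
#'   summary), `abundance` (cross-condition abundance table) and
#'   `final_clusters` (per-condition final-epoch cluster tables).
#' @export
glycine_sweep <- function(config = protocol_config(), gly_min = 75L,
                          gly_max = 124L, seed = 1L, min_changes = 2L) {
  conds <- sweep_conditions(gly_min, gly_max, seed)
  final <- vector("list", nrow(conds))
  osc <- logical(nrow(conds))
  nclus <- integer(nrow(conds))
  for (k in seq_len(nrow(conds))) {
    eng <- config$engine
    eng$initial_monomers["G"] <- conds$glycine[k]
    cfg <- protocol_config(config$epochs, config$generations_per_epoch,
                           engine = eng, clustering = config$clustering)
    h <- run_protocol(cfg, seed = conds$seed[k])
    final[[k]] <- h$epochs[[config$epochs]]
    nclus[k] <- nrow(final[[k]])
    osc[k] <- if (config$epochs >= 3L)
      any(detect_oscillations(h, min_changes)$oscillating) else NA
  }
  conds$final_clusters <- nclus
  conds$oscillating <- osc
  structure(
    list(conditions = conds,
         abundance = .sweep_abundance(final, config),
         final_clusters = final),
    class = "sweep_report")
}

# Cross-condition abundance table: match final-epoch clusters across
# conditions at the clustering threshold, then summarise occurrences.
.sweep_abundance <- function(final, config) {
  all_tab <- do.call(rbind, lapply(seq_along(final), function(k) {
    data.frame(condition = k, sequence = final[[k]]$representative,
               occurrences = final[[k]]$occurrences,
               stringsAsFactors = FALSE)
  }))
  if (!nrow(all_tab))
    return(data.frame(sequence = character(), mean_occurrences = numeric(),
                      sd_occurrences = numeric(),
                      n_conditions_present = integer(),
                      stringsAsFactors = FALSE))
  reps <- unique(all_tab$sequence)
  cl <- cluster_pool(peptide_pool(reps, 1L), config$clustering,
                     config$engine$alignment)
  grp_of <- integer(0)
  for (g in seq_along(cl$members))
    grp_of[cl$members[[g]]$sequence] <- g
  all_tab$group <- grp_of[all_tab$sequence]
  n_cond <- length(final)
  rows <- lapply(seq_along(cl$members), function(g) {
    sub <- all_tab[all_tab$group == g, , drop = FALSE]
    per_cond <- numeric(n_cond)
    agg <- rowsum(sub$occurrences, sub$condition)
    per_cond[as.integer(rownames(agg))] <- agg[, 1]
    data.frame(sequence = cl$clusters$representative[g],
               mean_occurrences = mean(per_cond),
               sd_occurrences = stats::sd(per_cond),
               n_conditions_present = sum(per_cond > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_occurrences, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("glycine sweep:", nrow(x$conditions), "conditions, glycine",
      min(x$conditions$glycine), "to", max(x$conditions$glycine), "\n")
  cat("oscillating conditions:", sum(x$conditions$oscillating, na.rm = TRUE),
      "of", nrow(x$conditions), "\n")
  cat("most abundant cross-condition clusters:\n")
  print(utils::head(x$abundance, 10L), row.names = FALSE)
  invisible(x)
}
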