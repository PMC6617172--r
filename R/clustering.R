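#' Clustering parameters
#'
#' Epoch clustering groups sequences whose pairwise [cluster_distance()]
#' falls at or below the threshold. With `linkage = "complete"` (default)
#' clusters are compact groups in which (approximately) every pair of
#' members is within the threshold, which keeps clusters coherent in both
#' length and composition; with `linkage = "single"` clusters are the
#' connected components of the thresholded distance graph. Single linkage
#' chains the densely populated length ladder (a peptide of length L is
#' within 0.3 of one of length L+1 for all L >= 3), collapsing all
#' polymers into one cluster whose representative is the shortest, most
#' abundant member — which erases length accumulation at every epoch
#' boundary; it is therefore not the default.
#'
#' @param distance_threshold Distance cutoff in \[0, 1\] below or at which
#'   two sequences belong to the same cluster (default 0.300).
#' @param linkage `"complete"` (default) or `"single"`.
#' @return Object of class `"clustering_params"`.
#' @export
clustering_params <- function(distance_threshold = 0.300,
                              linkage = c("complete", "single")) {
  stopifnot(is.numeric(distance_threshold), length(distance_threshold) == 1L,
            distance_threshold >= 0, distance_threshold <= 1)
  structure(list(distance_threshold = distance_threshold,
                 linkage = match.arg(linkage)),
            class = "clustering_params")
}

#' Representative of a cluster
#'
#' The member with the highest occurrence count; ties broken by shorter
#' length, then lexicographic order. Deterministic.
#'
#' @param sequences Character vector of member sequences.
#' @param occurrences Their occurrence counts.
#' @return A single sequence.
#' @export
select_representative <- function(sequences, occurrences) {
  if (!length(sequences)) stop("empty member list")
  ord <- order(-occurrences, nchar(sequences), sequences)
  sequences[ord[1L]]
}

#' Cluster a pool by length and sequence similarity
#'
#' Groups the pool's species by hierarchical clustering of the pairwise
#' length-aware [cluster_distance()], cut at the distance threshold
#' (see [clustering_params()] for the linkage choices; under single
#' linkage two species within the threshold always share a cluster and
#' clusters are the connected components of the thresholded distance
#' graph). Each cluster keeps one representative carrying the summed
#' occurrences of all members, so total occurrences are conserved.
#'
#' @param pool Non-empty [peptide_pool()].
#' @param params [clustering_params()].
#' @param alignment [alignment_params()].
#' @return Object of class `"pool_clustering"`: a list with `clusters`
#'   (data frame: representative, occurrences, n_members), `members`
#'   (list of per-cluster member data frames) and `pool` (the reduced
#'   pool of representatives).
#' @export
cluster_pool <- function(pool, params = clustering_params(),
                         alignment = alignment_params()) {
  pool <- .pool_compact(pool)
  if (!nrow(pool)) stop("empty pool")
  n <- nrow(pool)
  if (n == 1L) {
    grp <- 1L
  } else {
    d <- stats::as.dist(.cluster_distance_matrix(pool$sequence, alignment))
    hc <- stats::hclust(d, method = params$linkage)
    grp <- stats::cutree(hc, h = params$distance_threshold)
  }
  idx <- split(seq_len(n), grp)
  members <- lapply(idx, function(i)
    data.frame(sequence = pool$sequence[i],
               occurrences = pool$occurrences[i],
               stringsAsFactors = FALSE))
  reps <- vapply(members, function(m)
    select_representative(m$sequence, m$occurrences), character(1))
  occ <- vapply(members, function(m) sum(m$occurrences), integer(1))
  nm <- vapply(members, nrow, integer(1))
  ord <- order(-occ, nchar(reps), reps)
  clusters <- data.frame(representative = reps[ord],
                         occurrences = occ[ord],
                         n_members = nm[ord],
                         stringsAsFactors = FALSE)
  rownames(clusters) <- NULL
  structure(
    list(clusters = clusters,
         members = members[ord],
         pool = peptide_pool(clusters$representative, clusters$occurrences),
         params = params),
    class = "pool_clustering")
}

#' @export
print.pool_clustering <- function(x, ...) {
  cat("pool clustering:", nrow(x$clusters), "clusters,",
      sum(x$clusters$occurrences), "occurrences, threshold",
      x$params$distance_threshold, "\n")
  print(utils::head(x$clusters, 10L), row.names = FALSE)
  invisible(x)
}
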