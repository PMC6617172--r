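#' Read and write peptide pools as FASTA
#'
#' Pools are serialized as amino-acid FASTA with a running integer record
#' id and the occurrence count carried in the description as `count=N`
#' (FASTA has no native count field). The pair of functions round-trips
#' losslessly. Records without a `count=` tag read as a single copy, with
#' a warning.
#'
#' @param pool A [peptide_pool()].
#' @param path File path.
#' @return `read_pool_fasta()` returns a [peptide_pool()];
#'   `write_pool_fasta()` returns `path` invisibly.
#' @export
write_pool_fasta <- function(pool, path) {
  x <- Biostrings::AAStringSet(pool$sequence)
  names(x) <- sprintf("%d count=%d", seq_len(nrow(pool)), pool$occurrences)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_pool_fasta
#' @export
read_pool_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- tryCatch(Biostrings::readAAStringSet(path),
                error = function(e) stop("malformed FASTA in ", path, ": ",
                                         conditionMessage(e), call. = FALSE))
  if (!length(x)) {
    warning("empty FASTA file: ", path)
    return(peptide_pool())
  }
  seqs <- as.character(x)
  bad <- setdiff(unique(strsplit(paste(seqs, collapse = ""), "")[[1]]),
                 names(residue_coefficients()))
  if (length(bad))
    stop("unknown residue code in ", path, ": ", paste(bad, collapse = ", "))
  m <- regmatches(names(x), regexpr("count=[0-9]+", names(x)))
  counts <- rep(1L, length(x))
  has <- grepl("count=[0-9]+", names(x))
  counts[has] <- as.integer(sub("count=", "", m))
  if (!all(has))
    warning(sum(!has), " record(s) without count= tag read as 1 copy")
  peptide_pool(unname(seqs), counts)
}

#' Read and write peptide pools as two-column TSV
#'
#' Columns `sequence` and `occurrences`; lossless round-trip.
#'
#' @inheritParams write_pool_fasta
#' @export
write_pool_tsv <- function(pool, path) {
  utils::write.table(as.data.frame(pool)[, c("sequence", "occurrences")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pool_tsv
#' @export
read_pool_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer"))
  peptide_pool(df$sequence, df$occurrences)
}

#' Write the per-epoch cluster table of a history
#'
#' TSV with columns epoch, representative, occurrences, n_members.
#'
#' @param history An `epoch_history`.
#' @param path File path.
#' @export
write_cluster_table <- function(history, path) {
  tab <- do.call(rbind, history$epochs)
  tab <- tab[, c("epoch", "representative", "occurrences", "n_members")]
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an occurrence matrix as TSV
#'
#' Rows are representatives, columns epochs (the data behind abundance
#' trajectory plots).
#'
#' @param history An `epoch_history`.
#' @param path File path.
#' @param match Passed to [occurrence_matrix()].
#' @export
write_occurrence_matrix <- function(history, path, match = "threshold") {
  m <- occurrence_matrix(history, match)
  utils::write.table(cbind(representative = rownames(m), as.data.frame(m)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write protocol configurations as YAML
#'
#' The on-disk form mirrors [protocol_config()]: nested keys for the
#' protocol (epochs, generations_per_epoch), engine (initial monomers,
#' fragmentation threshold, replenishment), alignment (gap penalty) and
#' clustering (distance threshold). Every default is written out so a
#' stored file is a complete audit of the run's parameters.
#'
#' @param config A [protocol_config()].
#' @param path File path.
#' @export
write_config <- function(config, path) {
  obj <- list(
    epochs = config$epochs,
    generations_per_epoch = config$generations_per_epoch,
    engine = list(
      initial_monomers = as.list(config$engine$initial_monomers),
      fragmentation_threshold = config$engine$fragmentation_threshold,
      replenish = config$engine$replenish),
    alignment = list(gap = config$engine$alignment$gap),
    clustering = list(
      distance_threshold = config$clustering$distance_threshold))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  obj <- yaml::read_yaml(path)
  eng <- engine_config(
    initial_monomers = unlist(obj$engine$initial_monomers),
    fragmentation_threshold = obj$engine$fragmentation_threshold %||% 60L,
    replenish = obj$engine$replenish %||% TRUE,
    alignment = alignment_params(gap = obj$alignment$gap %||% 2))
  protocol_config(
    epochs = obj$epochs %||% 20L,
    generations_per_epoch = obj$generations_per_epoch %||% 400L,
    engine = eng,
    clustering = clustering_params(
      obj$clustering$distance_threshold %||% 0.300))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Write a run manifest
#'
#' Records the full configuration, the master seed and MD5 checksums of
#' the run's output files, so a run can be audited and reproduced.
#'
#' @param path Manifest file path (YAML).
#' @param config The [protocol_config()] used.
#' @param seed Master seed.
#' @param outputs Character vector of output file paths to checksum.
#' @export
write_manifest <- function(path, config, seed, outputs = character()) {
  sums <- if (length(outputs)) as.list(tools::md5sum(outputs)) else list()
  tmp <- tempfile(fileext = ".yml")
  on.exit(unlink(tmp))
  write_config(config, tmp)
  obj <- list(version = as.character(utils::packageVersion("pepcycle")),
              seed = as.integer(seed),
              config = yaml::read_yaml(tmp),
              checksums = sums)
  yaml::write_yaml(obj, path)
  invisible(path)
}
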