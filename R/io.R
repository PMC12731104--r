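# On-disk epochs container and run manifests.
#
# The canonical container is R native serialization (version 3) of a
# schema-tagged list; no HDF5 binding is available in this stack. The
# layout mirrors the usual epochs containers: `data`
# (trials x channels x samples), `labels`, attributes `fs`,
# `channel_names`, `class_names`. TSV import/export adapters cover
# interchange with other tooling.

EPOCHS_SCHEMA_VERSION <- 1L

#' Write epochs to the canonical container
#' @param epochs an `lpggnet_epochs`.
#' @param path output path (conventionally `.eeg.rds`).
#' @return the path, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  stopifnot(inherits(epochs, "lpggnet_epochs"))
  obj <- list(schema = "lpggnet_epochs",
              schema_version = EPOCHS_SCHEMA_VERSION,
              data = epochs$data, labels = epochs$labels, fs = epochs$fs,
              channel_names = epochs$channel_names,
              class_names = epochs$class_names)
  saveRDS(obj, path, version = 3L)
  invisible(path)
}

#' Read epochs from the canonical container
#' @param path container path.
#' @return An `lpggnet_epochs`.
#' @export
read_epochs <- function(path) {
  if (!file.exists(path))
    stop_schema(sprintf("epochs container not found: %s", path))
  obj <- tryCatch(readRDS(path), error = function(e)
    stop_schema(sprintf("cannot read epochs container: %s",
                        conditionMessage(e))))
  if (!is.list(obj) || !identical(obj$schema, "lpggnet_epochs"))
    stop_schema("not an epochs container (missing schema tag)")
  if (is.null(obj$schema_version) ||
      obj$schema_version > EPOCHS_SCHEMA_VERSION)
    stop_schema(sprintf("unsupported container schema version: %s",
                        obj$schema_version %||% "none"))
  for (field in c("data", "labels", "fs", "channel_names")) {
    if (is.null(obj[[field]]))
      stop_schema(sprintf("epochs container missing field '%s'", field))
  }
  epoched_eeg(obj$data, obj$fs, obj$labels, obj$channel_names,
              obj$class_names)
}

#' Export epochs as plain TSV (long format)
#'
#' One row per (trial, channel): trial, label, channel, then the samples.
#' Loses nothing but is bulky; intended for interchange and inspection.
#'
#' @param epochs an `lpggnet_epochs`.
#' @param path output path.
#' @export
export_epochs_tsv <- function(epochs, path) {
  d <- dim(epochs$data)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# fs=%g", epochs$fs), con)
  for (tr in seq_len(d[1L]))
    for (ch in seq_len(d[2L]))
      writeLines(paste(c(tr, epochs$labels[tr], epochs$channel_names[ch],
                         format(epochs$data[tr, ch, ], digits = 17)),
                       collapse = "\t"), con)
  invisible(path)
}

#' Write a labelled square matrix as TSV
#' @param m matrix with dimnames (or an `lpggnet_adjacency`).
#' @param path output path.
#' @export
write_matrix_tsv <- function(m, path) {
  if (inherits(m, "lpggnet_adjacency")) m <- m$values
  if (inherits(m, "lpggnet_graph_filter")) m <- m$operator
  utils::write.table(as.data.frame(m), path, sep = "\t", quote = FALSE,
                     col.names = NA)
  invisible(path)
}

#' Read a labelled square matrix from TSV
#' @param path file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1L,
                           check.names = FALSE)
  as.matrix(tab)
}

#' Run manifest
#'
#' Records command, configuration snapshot, seed, package version, input
#' file digests and timestamps for a CLI run; digests are stable for
#' identical inputs.
#'
#' @param command command name.
#' @param config list snapshot of the effective configuration.
#' @param seed integer seed.
#' @param inputs character vector of input paths (digested if they exist).
#' @return manifest list.
#' @export
run_manifest <- function(command, config = list(), seed = NA_integer_,
                         inputs = character()) {
  digest_file <- function(p) {
    if (!file.exists(p)) return(NA_character_)
    # dependency-free stable digest: polynomial rolling hash mod 2^31 - 1
    # (all intermediates stay below 2^53, so double arithmetic is exact)
    bytes <- as.integer(readBin(p, "raw", file.info(p)$size))
    m <- 2147483647
    modmul <- function(a, b) {         # both < m; exact in doubles
      hi <- b %/% 32768
      lo <- b %% 32768
      (((a * hi) %% m) * 32768 + a * lo) %% m
    }
    blk <- 1024L
    pow <- numeric(blk)
    pow[1L] <- 1
    for (i in seq_len(blk - 1L)) pow[i + 1L] <- (pow[i] * 257) %% m
    p_blk <- (pow[blk] * 257) %% m
    h <- 0
    for (start in seq(1L, max(1L, length(bytes)), by = blk)) {
      chunk <- bytes[start:min(start + blk - 1L, length(bytes))] + 1
      bh <- sum(chunk * rev(pow[seq_along(chunk)])) %% m
      p_chunk <- if (length(chunk) == blk) p_blk
                 else (pow[length(chunk)] * 257) %% m
      h <- (modmul(h, p_chunk) + bh) %% m
    }
    sprintf("%08x", h)
  }
  list(command = command, config = config, seed = seed,
       package_version = as.character(utils::packageVersion("lpggnet")),
       inputs = as.list(stats::setNames(vapply(inputs, digest_file, ""),
                                        inputs)),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

#' Write a manifest as JSON
#' @param manifest a manifest list.
#' @param path output path.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
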