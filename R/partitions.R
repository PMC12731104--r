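#' Electrode partition scheme
#'
#' A partition scheme names exactly four (possibly overlapping) subsets of
#' montage channels, one per motor-imagery task region. Overlap is a feature:
#' channels sitting on partition boundaries belong to several partitions and
#' are later fused by arithmetic averaging of their per-partition features.
#'
#' @param partitions named list of exactly 4 character vectors (P1..P4 order
#'   is taken from the list order).
#' @param name scheme label.
#' @return An object of class `lpggnet_scheme`.
#' @export
partition_scheme <- function(partitions, name = "custom") {
  if (!is.list(partitions) || length(partitions) != 4L)
    stop_validation("a partition scheme must contain exactly 4 partitions")
  if (is.null(names(partitions)) || any(!nzchar(names(partitions))))
    names(partitions) <- paste0("P", seq_along(partitions))
  partitions <- lapply(partitions, as.character)
  empty <- names(partitions)[vapply(partitions, length, 1L) == 0L]
  if (length(empty))
    stop_validation(sprintf("empty partition(s): %s",
                            paste(empty, collapse = ", ")),
                    )
  dup <- names(partitions)[vapply(partitions, anyDuplicated, 1L) > 0L]
  if (length(dup))
    stop_validation(sprintf("duplicated channels inside partition(s): %s",
                            paste(dup, collapse = ", ")))
  structure(list(name = name, partitions = partitions),
            class = "lpggnet_scheme")
}

#' @export
print.lpggnet_scheme <- function(x, ...) {
  cat(sprintf("<lpggnet_scheme> '%s'\n", x$name))
  for (p in names(x$partitions))
    cat(sprintf("  %s (%d): %s\n", p, length(x$partitions[[p]]),
                paste(x$partitions[[p]], collapse = ", ")))
  invisible(x)
}

#' Built-in four-partition scheme for the 22-channel layout
#'
#' The task-driven partitioning of the 22-channel motor-imagery montage:
#' P1 around C3 (left hand), P2 around Fz/Cz (feet), P3 around C4
#' (right hand), P4 around CPz/Pz (tongue). Sizes are (7, 10, 7, 10) and the
#' union covers all 22 channels; boundary electrodes are shared by two or
#' three partitions.
#'
#' @return An `lpggnet_scheme`.
#' @export
scheme_dataset_a <- function() {
  partition_scheme(list(
    P1 = c("FC3", "FC1", "C5", "C3", "C1", "CP3", "CP1"),
    P2 = c("Fz", "FC1", "FCz", "FC2", "C1", "Cz", "C2", "CP1", "CPz", "CP2"),
    P3 = c("FC2", "FC4", "C6", "C4", "C2", "CP4", "CP2"),
    P4 = c("POz", "P1", "Pz", "P2", "C1", "Cz", "C2", "CP1", "CPz", "CP2")),
    name = "dataset_a_22")
}

#' Overlap bookkeeping for a partition scheme
#'
#' Computes, for every channel mentioned in the scheme, the set of partitions
#' it belongs to (membership) and their number (multiplicity). The result is
#' a pure function of the scheme's set structure: channel order inside a
#' partition is irrelevant.
#'
#' @param scheme an `lpggnet_scheme`.
#' @return An object of class `lpggnet_overlap`: list with `membership`
#'   (named list of partition-id character vectors) and `multiplicity`
#'   (named integer vector), plus `channels` in first-appearance order.
#' @export
overlap_index <- function(scheme) {
  stopifnot(inherits(scheme, "lpggnet_scheme"))
  channels <- unique(unlist(scheme$partitions, use.names = FALSE))
  membership <- lapply(channels, function(ch)
    names(scheme$partitions)[vapply(scheme$partitions,
                                    function(p) ch %in% p, TRUE)])
  names(membership) <- channels
  multiplicity <- vapply(membership, length, 1L)
  structure(list(channels = channels,
                 membership = membership,
                 multiplicity = multiplicity),
            class = "lpggnet_overlap")
}

#' @export
print.lpggnet_overlap <- function(x, ...) {
  cat(sprintf("<lpggnet_overlap> %d channels, multiplicities: %s\n",
              length(x$channels),
              paste(sprintf("%dx%d", as.integer(names(table(x$multiplicity))),
                            as.integer(table(x$multiplicity))), collapse = " ")))
  invisible(x)
}

#' Validate a partition scheme against a montage
#'
#' Checks that every partition is non-empty and that every member channel
#' resolves in the montage; reports per-partition sizes and coverage.
#'
#' @param scheme an `lpggnet_scheme`.
#' @param montage an `lpggnet_montage`.
#' @param error if `TRUE` (default) raise a structured validation error on
#'   failure; otherwise return the report with `valid = FALSE`.
#' @return Invisibly (or visibly on `error = FALSE`) a list with `valid`,
#'   `sizes`, `unknown_channels`, `covered` (channels of the montage in the
#'   union) and `uncovered`.
#' @export
validate_scheme <- function(scheme, montage, error = TRUE) {
  stopifnot(inherits(scheme, "lpggnet_scheme"),
            inherits(montage, "lpggnet_montage"))
  sizes <- vapply(scheme$partitions, length, 1L)
  unknown <- lapply(scheme$partitions, function(p)
    setdiff(p, montage$channel_names))
  unknown_flat <- unique(unlist(unknown, use.names = FALSE))
  union_ch <- unique(unlist(scheme$partitions, use.names = FALSE))
  report <- list(
    valid = length(unknown_flat) == 0L,
    sizes = sizes,
    unknown_channels = unknown_flat,
    covered = intersect(montage$channel_names, union_ch),
    uncovered = setdiff(montage$channel_names, union_ch))
  if (error && !report$valid) {
    bad <- names(unknown)[vapply(unknown, length, 1L) > 0L]
    stop_validation(sprintf(
      "scheme '%s' references channels missing from the montage: %s (in %s)",
      scheme$name, paste(unknown_flat, collapse = ", "),
      paste(bad, collapse = ", ")),
      data = report)
  }
  if (error) invisible(report) else report
}

#' Read a partition scheme from JSON
#'
#' Expects a JSON object mapping partition names to arrays of channel
#' labels, e.g. `{"P1": ["C3", "C1"], ...}`, optionally wrapped as
#' `{"name": ..., "partitions": {...}}`.
#'
#' @param path file path.
#' @return An `lpggnet_scheme`.
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("scheme file not found: %s", path))
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e)
                    stop_schema(sprintf("cannot parse scheme JSON: %s",
                                        conditionMessage(e))))
  if (!is.null(obj$partitions))
    partition_scheme(as.list(obj$partitions),
                     name = if (is.null(obj$name)) "file" else obj$name)
  else
    partition_scheme(as.list(obj), name = "file")
}

#' Write a partition scheme as JSON
#' @param scheme an `lpggnet_scheme`.
#' @param path output path.
#' @export
write_scheme <- function(scheme, path) {
  jsonlite::write_json(list(name = scheme$name, partitions = scheme$partitions),
                       path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
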