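#' Electrode montage
#'
#' A montage binds ordered 10-20-system channel labels to 3-D head-centred
#' positions. Positions use an arbitrary but internally consistent length
#' unit: every spatial quantity derived from a montage (inter-electrode
#' distances, the Gaussian-median-distance bandwidth delta) is scale
#' covariant, so the resulting adjacency matrices are invariant to a global
#' rescaling of the coordinates.
#'
#' @param channel_names character vector of unique, non-empty channel labels.
#' @param coords numeric matrix with one row per channel and columns x, y, z.
#' @return An object of class `lpggnet_montage`: a list with elements
#'   `channel_names` and `coords` (rownames set to the channel names).
#' @examples
#' m <- montage(c("C3", "C4"), rbind(c(-1, 0, 0), c(1, 0, 0)))
#' channel_distances(m)
#' @export
montage <- function(channel_names, coords) {
  channel_names <- as.character(channel_names)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(channel_names) < 2L)
    stop_validation("a montage needs at least 2 channels")
  if (anyDuplicated(channel_names))
    stop_validation(sprintf(
      "duplicated channel names: %s",
      paste(unique(channel_names[duplicated(channel_names)]), collapse = ", ")))
  if (any(!nzchar(channel_names)))
    stop_validation("channel names must be non-empty")
  if (nrow(coords) != length(channel_names) || ncol(coords) != 3L)
    stop_validation("coords must be an n_channels x 3 matrix")
  if (!all(is.finite(coords)))
    stop_validation("montage coordinates must all be finite")
  rownames(coords) <- channel_names
  colnames(coords) <- c("x", "y", "z")
  structure(list(channel_names = channel_names, coords = coords),
            class = "lpggnet_montage")
}

#' @export
print.lpggnet_montage <- function(x, ...) {
  cat(sprintf("<lpggnet_montage> %d channels: %s\n",
              length(x$channel_names),
              paste(utils::head(x$channel_names, 8L), collapse = ", ")))
  invisible(x)
}

#' Pairwise Euclidean channel distances
#'
#' @param m a montage (or a bare coordinate matrix with rownames).
#' @return Symmetric distance matrix with channel-name dimnames.
#' @export
channel_distances <- function(m) {
  coords <- if (inherits(m, "lpggnet_montage")) m$coords else as.matrix(m)
  d <- as.matrix(stats::dist(coords))
  dimnames(d) <- list(rownames(coords), rownames(coords))
  d
}

# Idealized 10-10 grid offsets in degrees for the 22-channel layout:
# u = lateral angle (negative = left), v = anterior-posterior angle
# (negative = anterior), both in 18-degree (10 %) steps from the vertex.
.dataset_a_grid <- function() {
  g <- rbind(
    Fz  = c(0, -36),
    FC3 = c(-36, -18), FC1 = c(-18, -18), FCz = c(0, -18),
    FC2 = c(18, -18),  FC4 = c(36, -18),
    C5  = c(-54, 0), C3 = c(-36, 0), C1 = c(-18, 0), Cz = c(0, 0),
    C2  = c(18, 0),  C4 = c(36, 0),  C6 = c(54, 0),
    CP3 = c(-36, 18), CP1 = c(-18, 18), CPz = c(0, 18),
    CP2 = c(18, 18),  CP4 = c(36, 18),
    P1  = c(-18, 36), Pz = c(0, 36), P2 = c(18, 36),
    POz = c(0, 54))
  colnames(g) <- c("u", "v")
  g
}

#' Built-in 22-channel montage
#'
#' Idealized positions on a unit sphere for the 22 channels of the standard
#' four-class motor-imagery recording layout (central/centro-parietal strip
#' of the 10-10 system). Electrodes are placed by inverting an azimuthal
#' equidistant projection of their 10-10 grid angles; since all downstream
#' spatial quantities depend only on relative distances (the median pairwise
#' distance sets the Gaussian bandwidth), the arbitrary unit radius is
#' immaterial.
#'
#' @return An `lpggnet_montage` with 22 channels.
#' @export
montage_dataset_a <- function() {
  g <- .dataset_a_grid()
  rho <- sqrt(g[, "u"]^2 + g[, "v"]^2) * pi / 180
  az_x <- ifelse(rho > 0, g[, "u"] / sqrt(g[, "u"]^2 + g[, "v"]^2), 0)
  az_y <- ifelse(rho > 0, -g[, "v"] / sqrt(g[, "u"]^2 + g[, "v"]^2), 0)
  coords <- cbind(x = sin(rho) * az_x,   # +x = right
                  y = sin(rho) * az_y,   # +y = anterior
                  z = cos(rho))          # +z = vertex
  montage(rownames(g), coords)
}

#' Read a montage from tabular text
#'
#' Expects a tab- or whitespace-separated file with four columns:
#' label, x, y, z (header optional, detected from the first line).
#'
#' @param path file path.
#' @return An `lpggnet_montage`.
#' @export
read_montage <- function(path) {
  if (!file.exists(path)) stop_schema(sprintf("montage file not found: %s", path))
  first <- readLines(path, n = 1L)
  has_header <- grepl("[A-Za-z]", strsplit(trimws(first), "[\t ]+")[[1]][2])
  tab <- utils::read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) < 4L)
    stop_schema("montage file needs columns: label, x, y, z")
  coords <- as.matrix(tab[, 2:4])
  if (!is.numeric(coords))
    stop_schema("montage coordinate columns must be numeric")
  montage(tab[[1L]], coords)
}

#' Write a montage as tabular text
#'
#' @param m an `lpggnet_montage`.
#' @param path output file path.
#' @export
write_montage <- function(m, path) {
  tab <- data.frame(label = m$channel_names, m$coords, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
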