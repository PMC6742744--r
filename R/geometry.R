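#' Build a hexagonal electrode layout
#'
#' Constructs a triangular ("pointy-top") lattice of electrodes of the kind
#' used by CMOS high-density microelectrode arrays: rows are spaced
#' `pitch * sqrt(3)/2` apart and every other row is offset by `pitch/2`, so
#' that every interior electrode has exactly six nearest neighbours at
#' distance `pitch`. The resulting electrode density is
#' `2 / (sqrt(3) * pitch^2)`.
#'
#' @param n_rows,n_cols Number of electrode rows and columns (>= 1).
#' @param pitch Nearest-neighbour electrode distance in micrometres.
#'   Defaults to 18, the distance between adjacent recording sites assumed
#'   throughout the delay-variance statistics.
#' @return A data frame of class `hex_layout` with columns `id` (0-based
#'   integer electrode identifiers), `x_um`, `y_um`, and attributes `pitch`,
#'   `n_rows`, `n_cols`.
#' @seealso [hex_neighborhood()], [hex_density()]
#' @examples
#' lay <- hex_layout(10, 10)
#' plot(lay$x_um, lay$y_um, asp = 1, pch = 16, cex = 0.5)
#' @export
hex_layout <- function(n_rows, n_cols, pitch = 18) {
  if (length(n_rows) != 1L || length(n_cols) != 1L ||
      is.na(n_rows) || is.na(n_cols) || n_rows < 1 || n_cols < 1)
    stop("'n_rows' and 'n_cols' must be >= 1")
  if (!is.numeric(pitch) || length(pitch) != 1L || pitch <= 0)
    stop("'pitch' must be a positive number")
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  lay <- data.frame(
    id   = row * n_cols + col,
    x_um = (col + 0.5 * (row %% 2L)) * pitch,
    y_um = row * pitch * sqrt(3) / 2
  )
  structure(lay, pitch = pitch, n_rows = n_rows, n_cols = n_cols,
            class = c("hex_layout", "data.frame"))
}

#' Electrode density of a hexagonal lattice
#'
#' @param pitch Nearest-neighbour distance in micrometres.
#' @return Electrode density in electrodes per square millimetre.
#' @export
hex_density <- function(pitch) {
  2 / (sqrt(3) * (pitch * 1e-3)^2)
}

#' Hexagonal neighbourhood of an electrode
#'
#' Returns the electrode itself plus the (up to six) electrodes closest to
#' the six ideal hexagon vertices at radius `scale * pitch` around it. With
#' `scale = 1` on an interior electrode this is the classic 7-member patch
#' used to sample local delay statistics; larger `scale` widens the patch
#' while keeping its size at 7 (N = 7 at r = scale * pitch).
#'
#' Members further than `0.45 * pitch` from their ideal vertex (i.e. missing
#' at the array edge) are dropped, so edge patches have fewer than 7 members;
#' the attached `n_members` / `complete` attributes let callers reject
#' incomplete patches.
#'
#' @param layout A [hex_layout()].
#' @param eid Electrode id (must exist in `layout`).
#' @param scale Positive integer ring radius in units of the pitch.
#' @return Integer vector of member electrode ids (center first), with
#'   attributes `n_members` (its length) and `complete` (`TRUE` iff 7).
#' @export
hex_neighborhood <- function(layout, eid, scale = 1) {
  stopifnot(inherits(layout, "hex_layout"))
  if (length(scale) != 1L || is.na(scale) || scale < 1)
    stop("'scale' must be a positive integer")
  i <- match(eid, layout$id)
  if (is.na(i)) stop("electrode id ", eid, " not found in layout")
  pitch <- attr(layout, "pitch")
  r <- scale * pitch
  theta <- seq(0, 5) * pi / 3
  vx <- layout$x_um[i] + r * cos(theta)
  vy <- layout$y_um[i] + r * sin(theta)
  ids <- layout$id[i]
  for (k in seq_len(6)) {
    d2 <- (layout$x_um - vx[k])^2 + (layout$y_um - vy[k])^2
    j <- which.min(d2)
    if (sqrt(d2[j]) <= 0.45 * pitch) ids <- c(ids, layout$id[j])
  }
  ids <- unique(ids)
  structure(ids, n_members = length(ids), complete = length(ids) == 7L)
}

#' Restrict a layout to a subset of electrodes
#'
#' @param layout A [hex_layout()].
#' @param ids Electrode ids to keep (order preserved).
#' @return A `hex_layout` containing only those electrodes (same pitch).
#' @export
subset_layout <- function(layout, ids) {
  stopifnot(inherits(layout, "hex_layout"))
  i <- match(ids, layout$id)
  if (anyNA(i)) stop("unknown electrode id(s): ",
                     paste(ids[is.na(i)], collapse = ", "))
  structure(as.data.frame(layout)[i, , drop = FALSE],
            pitch = attr(layout, "pitch"),
            class = c("hex_layout", "data.frame"))
}

#' Read / write electrode layout tables
#'
#' CSV interchange format with header `id,x_um,y_um`, one row per electrode.
#' The pitch is recovered as the minimum pairwise distance when reading.
#'
#' @param layout A [hex_layout()] (for writing).
#' @param path File path.
#' @return `read_layout()` returns a `hex_layout`; `write_layout()` returns
#'   `path` invisibly.
#' @export
write_layout <- function(layout, path) {
  stopifnot(inherits(layout, "hex_layout"))
  utils::write.csv(as.data.frame(layout)[, c("id", "x_um", "y_um")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  df <- utils::read.csv(path)
  need <- c("id", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("layout file must have columns id,x_um,y_um: ", path)
  if (anyDuplicated(df$id)) stop("duplicate electrode ids in ", path)
  pitch <- if (nrow(df) > 1) {
    d <- as.matrix(stats::dist(df[, c("x_um", "y_um")]))
    min(d[upper.tri(d)])
  } else NA_real_
  structure(df[, need], pitch = pitch, class = c("hex_layout", "data.frame"))
}

#' @export
print.hex_layout <- function(x, ...) {
  cat(sprintf("Hexagonal electrode layout: %d electrodes, pitch %.3g um\n",
              nrow(x), attr(x, "pitch")))
  cat(sprintf("  extent: x [%.1f, %.1f] um, y [%.1f, %.1f] um\n",
              min(x$x_um), max(x$x_um), min(x$y_um), max(x$y_um)))
  invisible(x)
}
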