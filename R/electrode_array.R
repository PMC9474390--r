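#' Planar electrode array geometry
#'
#' Builds the rectangular electrode lattice that serves as the coordinate
#' frame for all spatial operations. The full single-well HD-MEA layout is a
#' 120 x 220 grid at 17.5 um pitch (26,400 electrodes over roughly
#' 3.85 x 2.10 mm^2); any sub-grid can be generated for block recordings.
#'
#' @param rows,cols number of electrode rows and columns (>= 1).
#' @param pitch center-to-center electrode spacing in micrometers.
#' @return a data.frame of class `electrode_array` with columns
#'   `electrode_id` (0-based integer), `x`, `y` (um), plus `pitch` and `dims`
#'   attributes. Electrode 0 sits at the origin; `x` runs along columns and
#'   `y` along rows, so the bounding box is `pitch * (cols - 1)` by
#'   `pitch * (rows - 1)`.
#' @examples
#' arr <- electrode_array(120, 220)      # full array, 26,400 electrodes
#' nrow(arr)
#' @export
electrode_array <- function(rows, cols, pitch = 17.5) {
  assert_scalar_num(rows, "rows", positive = TRUE)
  assert_scalar_num(cols, "cols", positive = TRUE)
  assert_scalar_num(pitch, "pitch", positive = TRUE)
  if (rows < 1 || cols < 1) stop("rows and cols must be >= 1")
  rows <- as.integer(rows); cols <- as.integer(cols)
  g <- expand.grid(col = seq_len(cols) - 1L, row = seq_len(rows) - 1L)
  arr <- data.frame(
    electrode_id = seq_len(nrow(g)) - 1L,
    x = g$col * pitch,
    y = g$row * pitch
  )
  attr(arr, "pitch") <- pitch
  attr(arr, "dims") <- c(rows = rows, cols = cols)
  class(arr) <- c("electrode_array", "data.frame")
  arr
}

#' @export
print.electrode_array <- function(x, ...) {
  d <- attr(x, "dims")
  cat(sprintf("<electrode_array> %d electrodes (%d x %d, pitch %.3g um)\n",
              nrow(x), d[["rows"]], d[["cols"]], attr(x, "pitch")))
  invisible(x)
}

# Coordinates (x, y) of given electrode ids, in array order.
array_coords <- function(array, electrode_id) {
  idx <- match(electrode_id, array$electrode_id)
  if (anyNA(idx)) stop("unknown electrode id(s): ",
                       paste(electrode_id[is.na(idx)], collapse = ", "))
  cbind(x = array$x[idx], y = array$y[idx])
}
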