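#' Detect nuclei in a single frame
#'
#' Background is suppressed by subtracting a morphological mean filter
#' (radial disk structural element, default radius 50 px, clipped at zero),
#' the result is thresholded (Otsu by default), and connected components of
#' at least `min_area` pixels become detections with intensity-weighted
#' centroids. For z stacks, detection runs on the z sum projection and each
#' detection's z coordinate is the intensity-weighted average plane index
#' within its footprint.
#'
#' Coordinates are 0-based with the pixel-center convention: a blob
#' centered on the first pixel has `x = 0, y = 0`; `z` is in plane units.
#'
#' @param frame Numeric matrix `[y, x]` or 3D array `[y, x, z]` of
#'   non-negative intensities.
#' @param disk_radius Radius of the mean-filter disk in pixels (default 50).
#' @param threshold `"otsu"` (default) or a numeric threshold applied to the
#'   background-suppressed image.
#' @param min_area Minimum component area in pixels (default 30).
#' @return A tibble `x`, `y` (and `z` for stacks), `area`, `intensity`
#'   (integrated background-suppressed intensity), one row per detection.
#' @export
detect_nuclei <- function(frame, disk_radius = 50, threshold = "otsu",
                          min_area = 30) {
  disk_radius <- check_positive_int(disk_radius, "disk_radius")
  is3d <- length(dim(frame)) == 3L
  img <- if (is3d) apply(frame, c(1, 2), sum) else frame
  if (any(img < 0)) abort("Intensities must be non-negative.")
  if (2 * disk_radius + 1 > min(dim(img))) {
    abort("`disk_radius` too large for the frame.")
  }
  fg <- pmax(img - EBImage::filter2(img, disk_kernel(disk_radius),
                                    boundary = "replicate"), 0)
  if (identical(threshold, "otsu")) {
    mx <- max(fg)
    if (mx == 0) return(empty_detections(is3d))
    th <- EBImage::otsu(EBImage::Image(fg / mx), range = c(0, 1)) * mx
  } else {
    th <- check_number(threshold, "threshold", lower = 0)
  }
  mask <- fg > th
  if (!any(mask)) return(empty_detections(is3d))
  labels <- EBImage::bwlabel(mask)
  lab <- as.vector(labels)
  keep <- lab > 0L
  lab <- lab[keep]
  wt <- as.vector(fg)[keep]
  rows <- (seq_along(as.vector(labels)) - 1L) %% nrow(img)
  cols <- (seq_along(as.vector(labels)) - 1L) %/% nrow(img)
  rows <- rows[keep]; cols <- cols[keep]
  area <- tabulate(lab)
  tot <- rowsum(wt, lab)[, 1]
  cy <- rowsum(wt * rows, lab)[, 1] / tot
  cx <- rowsum(wt * cols, lab)[, 1] / tot
  ok <- area >= min_area
  out <- tibble(x = unname(cx[ok]), y = unname(cy[ok]), area = area[ok],
                intensity = unname(tot[ok]))
  if (is3d) {
    nz <- dim(frame)[3]
    plane_mass <- vapply(seq_len(nz), function(z) {
      rowsum(as.vector(frame[, , z])[keep], lab)[, 1]
    }, numeric(length(area)))
    if (is.null(dim(plane_mass))) plane_mass <- matrix(plane_mass, nrow = 1)
    zc <- as.vector(plane_mass %*% (seq_len(nz) - 1)) / rowSums(plane_mass)
    out$z <- unname(zc[ok])
    out <- select(out, "x", "y", "z", "area", "intensity")
  }
  out
}

empty_detections <- function(is3d) {
  out <- tibble(x = numeric(0), y = numeric(0), area = integer(0),
                intensity = numeric(0))
  if (is3d) out$z <- numeric(0)
  out
}

disk_kernel <- function(radius) {
  d <- 2L * radius + 1L
  xy <- seq_len(d) - radius - 1L
  disk <- outer(xy, xy, function(i, j) sqrt(i^2 + j^2) <= radius)
  disk / sum(disk)
}

#' Detect nuclei across a movie
#'
#' Runs [detect_nuclei()] on every frame of a rendered or loaded movie.
#'
#' @param movie Array `[y, x, t]` or `[y, x, z, t]` (see
#'   [render_nuclei_movie()]).
#' @inheritParams detect_nuclei
#' @return A tibble of detections with a leading `t` column (0-based frame
#'   index).
#' @export
detect_movie <- function(movie, disk_radius = 50, threshold = "otsu",
                         min_area = 30) {
  nd <- length(dim(movie))
  if (!nd %in% c(3L, 4L)) abort("`movie` must be [y,x,t] or [y,x,z,t].")
  n_t <- dim(movie)[nd]
  frames <- purrr::map(seq_len(n_t), function(k) {
    fr <- if (nd == 3L) movie[, , k] else movie[, , , k]
    det <- detect_nuclei(fr, disk_radius, threshold, min_area)
    mutate(det, t = k - 1L, .before = 1)
  })
  bind_rows(frames)
}
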