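#' Per-cell migration kinematics
#'
#' Computes non-overlapping step velocities `(pos[t+1] - pos[t]) / dt` and
#' summarises each cell:
#' \describe{
#'   \item{speed}{mean step speed, um/s.}
#'   \item{directed_speed}{mean projection of the step velocity on the
#'     gradient axis, um/s (requires `gradient_axis`).}
#'   \item{angular_bias}{`90 - mean(|angle between step and axis|)` in
#'     degrees; 0 for isotropic motion, positive for motion up the
#'     gradient.}
#' }
#'
#' @param tracks A `track_set` tibble (um; `dt` attribute in seconds).
#' @param gradient_axis Optional unit vector (length 2 or 3) giving the
#'   chemoattractant gradient direction; normalised internally.
#' @return A tibble `cell`, `n_steps`, `speed`, and (given an axis)
#'   `directed_speed`, `angular_bias`.
#' @examples
#' tr <- simulate_tracks(3, 30, q = 0, a = 0.2, seed = 1)
#' track_kinematics(tr)
#' @export
track_kinematics <- function(tracks, gradient_axis = NULL) {
  dt <- attr(tracks, "dt") %||% 1
  v <- track_velocities(tracks, dt = dt)
  vcols <- intersect(c("vx", "vy", "vz"), names(v))
  vm <- as.matrix(v[vcols])
  speed <- sqrt(rowSums(vm^2))
  base <- tibble(cell = v$cell, speed = speed)
  if (!is.null(gradient_axis)) {
    if (length(gradient_axis) != length(vcols)) {
      abort(sprintf("`gradient_axis` must have %d components.", length(vcols)))
    }
    u <- gradient_axis / sqrt(sum(gradient_axis^2))
    proj <- as.vector(vm %*% u)
    cosang <- ifelse(speed > 0, pmin(1, pmax(-1, proj / speed)), NA_real_)
    base$directed <- proj
    base$angle <- acos(cosang) * 180 / pi
  }
  out <- base |>
    group_by(.data$cell) |>
    summarise(n_steps = n(), speed = mean(.data$speed),
              directed_speed = if ("directed" %in% names(base)) {
                mean(.data$directed)
              } else NA_real_,
              angular_bias = if ("angle" %in% names(base)) {
                90 - mean(.data$angle, na.rm = TRUE)
              } else NA_real_,
              .groups = "drop")
  if (is.null(gradient_axis)) {
    out <- select(out, "cell", "n_steps", "speed")
  }
  out
}
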