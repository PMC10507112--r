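#' Link detections between two consecutive frames
#'
#' One-to-one assignment of previous-frame to next-frame detections that
#' minimizes the total Euclidean displacement over matched pairs, subject
#' to every matched displacement being at most `max_disp`. Among feasible
#' assignments, maximum cardinality takes priority (an unmatched pair
#' within the gate is never left unmatched to save distance); ties are
#' broken by total displacement. Solved as a maximum-weight bipartite
#' matching with weights `C - d` for a constant `C` large enough to make
#' cardinality dominate.
#'
#' @param prev,nxt Tibbles of detections with `x`, `y` (and optional `z`)
#'   columns, in consistent metric units.
#' @param max_disp Gating distance: pairs farther apart are never matched
#'   (default `Inf`).
#' @return A list with `matches` (tibble `i`, `j`, `dist`: row indices into
#'   `prev` and `nxt`), `deaths` (unmatched rows of `prev`), and `births`
#'   (unmatched rows of `nxt`).
#' @export
link_frames <- function(prev, nxt, max_disp = Inf) {
  n1 <- nrow(prev); n2 <- nrow(nxt)
  empty <- list(matches = tibble(i = integer(0), j = integer(0),
                                 dist = numeric(0)),
                deaths = seq_len(n1), births = seq_len(n2))
  if (n1 == 0L || n2 == 0L) return(empty)
  axes <- intersect(c("x", "y", "z"), intersect(names(prev), names(nxt)))
  d <- outer_dist(as.matrix(prev[axes]), as.matrix(nxt[axes]))
  feasible <- which(d <= max_disp, arr.ind = TRUE)
  if (!nrow(feasible)) return(empty)
  # weight C - d with C > (max matches + 1) * max feasible distance makes
  # every extra match worth more than any rearrangement of distances
  dmax <- max(d[feasible])
  C <- (min(n1, n2) + 1) * max(dmax, 1e-9) + 1
  g <- igraph::make_bipartite_graph(
    types = c(rep(FALSE, n1), rep(TRUE, n2)),
    edges = as.vector(t(cbind(feasible[, 1], n1 + feasible[, 2]))))
  igraph::E(g)$weight <- C - d[feasible]
  m <- igraph::max_bipartite_match(g)$matching
  i <- seq_len(n1)
  j <- m[i] - n1
  matched <- !is.na(j)
  im <- i[matched]
  jm <- as.integer(j[matched])
  matches <- tibble(i = im, j = jm, dist = d[cbind(im, jm)])
  list(matches = matches,
       deaths = i[!matched],
       births = setdiff(seq_len(n2), matches$j))
}

outer_dist <- function(a, b) {
  d2 <- matrix(0, nrow(a), nrow(b))
  for (k in seq_len(ncol(a))) d2 <- d2 + outer(a[, k], b[, k], "-")^2
  sqrt(d2)
}

#' Build tracks from per-frame detections
#'
#' Chains [link_frames()] over consecutive frames. A missed detection
#' terminates its track (no gap closing); an unmatched detection starts a
#' new track. When `max_disp` is not given it is calibrated as 3x the
#' median nearest-neighbour displacement between consecutive frames.
#'
#' @param detections Tibble with `t` (frame index), `x`, `y` (and optional
#'   `z`) in pixels / plane units.
#' @param max_disp Gating distance in um (after conversion); NULL to
#'   calibrate from the data.
#' @param pixel_size um per pixel (default 1).
#' @param z_spacing um per z plane (default 3).
#' @param dt Frame interval in seconds (default 1).
#' @return A `track_set` tibble `cell`, `t`, `x`, `y` (and `z`) in um,
#'   with `dt` and `pixel_size` attributes.
#' @export
build_tracks <- function(detections, max_disp = NULL, pixel_size = 1,
                         z_spacing = 3, dt = 1) {
  axes <- intersect(c("x", "y", "z"), names(detections))
  det <- detections
  det$x <- det$x * pixel_size
  det$y <- det$y * pixel_size
  if ("z" %in% axes) det$z <- det$z * z_spacing
  frames <- sort(unique(det$t))
  by_frame <- purrr::map(frames, ~ det[det$t == .x, , drop = FALSE])
  if (is.null(max_disp)) max_disp <- calibrate_gate(by_frame, axes)
  track_of <- purrr::map(by_frame, ~ rep(NA_integer_, nrow(.x)))
  next_id <- 1L
  for (k in seq_along(frames)) {
    cur <- by_frame[[k]]
    if (k == 1L) {
      track_of[[1]] <- seq_len(nrow(cur)); next_id <- nrow(cur) + 1L
      next
    }
    consecutive <- frames[k] - frames[k - 1L] == 1L
    lk <- if (consecutive) {
      link_frames(by_frame[[k - 1L]], cur, max_disp)
    } else {
      list(matches = tibble(i = integer(0), j = integer(0)),
           births = seq_len(nrow(cur)))
    }
    ids <- rep(NA_integer_, nrow(cur))
    ids[lk$matches$j] <- track_of[[k - 1L]][lk$matches$i]
    if (length(lk$births)) {
      ids[lk$births] <- next_id + seq_along(lk$births) - 1L
      next_id <- next_id + length(lk$births)
    }
    track_of[[k]] <- ids
  }
  out <- bind_rows(purrr::map2(by_frame, track_of,
                               ~ mutate(.x, cell = .y, .before = 1)))
  out <- arrange(select(out, "cell", "t", dplyr::all_of(axes)),
                 .data$cell, .data$t)
  attr(out, "dt") <- dt
  attr(out, "pixel_size") <- pixel_size
  attr(out, "max_disp") <- max_disp
  class(out) <- c("track_set", class(out))
  out
}

# 3x median nearest-neighbour step between consecutive frames.
calibrate_gate <- function(by_frame, axes) {
  nn <- unlist(purrr::map(seq_len(length(by_frame) - 1L), function(k) {
    a <- as.matrix(by_frame[[k]][axes])
    b <- as.matrix(by_frame[[k + 1L]][axes])
    if (!nrow(a) || !nrow(b)) return(NULL)
    apply(outer_dist(a, b), 1, min)
  }))
  if (!length(nn)) return(Inf)
  3 * median(nn)
}
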