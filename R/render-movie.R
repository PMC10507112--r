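#' Render a track set as a nuclei movie
#'
#' Draws each nucleus as a Gaussian intensity blob (per z-plane for 3D) on
#' every frame, adds Gaussian background noise, and optionally writes a
#' multi-page 32-bit TIFF with a YAML sidecar recording pixel size, frame
#' interval, z spacing and axis order. Positions outside the frame are an
#' error naming the offending cells.
#'
#' @param tracks A `track_set` (positions in um).
#' @param pixel_size um per pixel (default 1).
#' @param frame_shape `c(height, width)` in pixels; default fits all tracks
#'   with a margin.
#' @param z_planes Number of z planes (1 = 2D movie).
#' @param z_spacing um between z planes (default 3, the collagen stack
#'   spacing).
#' @param blob_sigma Blob standard deviation in pixels (default 2).
#' @param blob_sigma_z Blob standard deviation along z, in planes
#'   (default 1).
#' @param amplitude Peak blob intensity (default 1).
#' @param noise_sd Additive Gaussian noise sd (default 0).
#' @param path Optional TIFF output path (sidecar at `<path>.yaml`).
#' @param seed Optional integer seed for the noise.
#' @return Invisibly, the movie array: `[y, x, t]` for 2D or
#'   `[y, x, z, t]` for 3D, with metadata attached as attribute `meta`.
#' @export
render_nuclei_movie <- function(tracks, pixel_size = 1, frame_shape = NULL,
                                z_planes = 1, z_spacing = 3, blob_sigma = 2,
                                blob_sigma_z = 1, amplitude = 1, noise_sd = 0,
                                path = NULL, seed = NULL) {
  pixel_size <- check_number(pixel_size, "pixel_size", lower = 1e-9)
  z_planes <- check_positive_int(z_planes, "z_planes")
  axes <- intersect(c("x", "y", "z"), names(tracks))
  is3d <- z_planes > 1L
  if (is3d && !"z" %in% axes) abort("3D rendering needs a `z` column.")
  px <- tracks$x / pixel_size
  py <- tracks$y / pixel_size
  pz <- if (is3d) tracks$z / z_spacing else rep(0, nrow(tracks))
  if (is.null(frame_shape)) {
    frame_shape <- c(ceiling(max(py)) + 8L, ceiling(max(px)) + 8L)
  }
  h <- frame_shape[1]; w <- frame_shape[2]
  bad <- px < 0 | px > (w - 1) | py < 0 | py > (h - 1) |
    (is3d & (pz < 0 | pz > (z_planes - 1)))
  if (any(bad)) {
    abort(sprintf("Positions outside the frame for cell(s): %s",
                  paste(sort(unique(tracks$cell[bad])), collapse = ", ")))
  }
  frames <- sort(unique(tracks$t))
  n_t <- length(frames)
  dims <- if (is3d) c(h, w, z_planes, n_t) else c(h, w, n_t)
  movie <- array(0, dims)
  for (k in seq_len(n_t)) {
    sel <- which(tracks$t == frames[k])
    if (is3d) {
      for (z in seq_len(z_planes)) {
        zw <- exp(-((z - 1) - pz[sel])^2 / (2 * blob_sigma_z^2))
        movie[, , z, k] <- render_plane(h, w, px[sel], py[sel],
                                        amplitude * zw, blob_sigma)
      }
    } else {
      movie[, , k] <- render_plane(h, w, px[sel], py[sel],
                                   rep(amplitude, length(sel)), blob_sigma)
    }
  }
  if (noise_sd > 0) {
    movie <- with_seed(seed, movie + array(rnorm(length(movie), 0, noise_sd),
                                           dims))
    movie[movie < 0] <- 0
  }
  meta <- list(pixel_size_um = pixel_size, dt_s = attr(tracks, "dt") %||% 1,
               z_spacing_um = z_spacing,
               axis_order = if (is3d) "tzyx" else "tyx",
               height = h, width = w, z_planes = z_planes, n_frames = n_t)
  attr(movie, "meta") <- meta
  if (!is.null(path)) write_movie(movie, path)
  invisible(movie)
}

# Sum of 2D Gaussian blobs, each evaluated on a local +/- 4 sigma window.
render_plane <- function(h, w, px, py, amp, sigma) {
  img <- matrix(0, h, w)
  r <- ceiling(4 * sigma)
  for (i in seq_along(px)) {
    if (amp[i] < 1e-8) next
    cx <- px[i]; cy <- py[i]
    x0 <- max(0L, floor(cx) - r); x1 <- min(w - 1L, ceiling(cx) + r)
    y0 <- max(0L, floor(cy) - r); y1 <- min(h - 1L, ceiling(cy) + r)
    gx <- exp(-((x0:x1) - cx)^2 / (2 * sigma^2))
    gy <- exp(-((y0:y1) - cy)^2 / (2 * sigma^2))
    img[(y0:y1) + 1L, (x0:x1) + 1L] <- img[(y0:y1) + 1L, (x0:x1) + 1L] +
      amp[i] * outer(gy, gx)
  }
  img
}

#' Write / read a movie as multi-page TIFF with YAML sidecar
#'
#' Pages are written t-major (all z planes of frame 1, then frame 2, ...),
#' as recorded in the sidecar's `axis_order`.
#'
#' @param movie Array from [render_nuclei_movie()].
#' @param path TIFF path; metadata goes to `<path>.yaml`.
#' @return `path` (write) or the movie array with `meta` attribute (read).
#' @export
write_movie <- function(movie, path) {
  meta <- attr(movie, "meta")
  if (is.null(meta)) abort("`movie` has no meta attribute.")
  pages <- list()
  if (length(dim(movie)) == 4L) {
    for (k in seq_len(dim(movie)[4])) for (z in seq_len(dim(movie)[3])) {
      pages[[length(pages) + 1L]] <- movie[, , z, k]
    }
  } else {
    for (k in seq_len(dim(movie)[3])) pages[[k]] <- movie[, , k]
  }
  mx <- max(unlist(lapply(pages, max)), 1)
  pages <- lapply(pages, function(p) p / mx)  # tiff expects [0,1] floats
  meta$intensity_scale <- mx
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  yaml::write_yaml(meta, paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_movie
#' @export
read_movie <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yaml"))
  pages <- tiff::readTIFF(path, all = TRUE)
  scale <- meta$intensity_scale %||% 1
  h <- meta$height; w <- meta$width
  nz <- meta$z_planes %||% 1L; nt <- meta$n_frames
  if (nz > 1L) {
    movie <- array(0, c(h, w, nz, nt))
    i <- 1L
    for (k in seq_len(nt)) for (z in seq_len(nz)) {
      movie[, , z, k] <- pages[[i]] * scale; i <- i + 1L
    }
  } else {
    movie <- array(0, c(h, w, nt))
    for (k in seq_len(nt)) movie[, , k] <- pages[[k]] * scale
  }
  attr(movie, "meta") <- meta
  movie
}
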