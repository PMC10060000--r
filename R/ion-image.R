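#' Ion image container
#'
#' One reconstructed 2D channel: a matrix of dwell-normalized intensities
#' (counts/s) with rows = line scans and columns = scan cycles (pixels along
#' the stage axis). `NA` marks missing pixels (ragged line ends, missing
#' transitions, pixels shifted out of frame by re-alignment).
#'
#' @param transition_id Channel id.
#' @param grid Numeric matrix (NA allowed).
#' @param pixel_w_um,pixel_h_um Pixel size (um).
#' @param origin `(x, y)` of the top-left pixel corner (um).
#' @return An object of class `ion_image`.
#' @export
ion_image <- function(transition_id, grid, pixel_w_um, pixel_h_um,
                      origin = c(0, 0)) {
  if (!is.matrix(grid)) abort("grid must be a matrix")
  assert_scalar_num(pixel_w_um, "pixel_w_um", positive = TRUE)
  assert_scalar_num(pixel_h_um, "pixel_h_um", positive = TRUE)
  structure(list(transition_id = transition_id, grid = grid,
                 pixel_w_um = pixel_w_um, pixel_h_um = pixel_h_um,
                 origin = origin),
            class = "ion_image")
}

#' @export
print.ion_image <- function(x, ...) {
  cat(sprintf("<ion_image> %s: %d x %d px (%g x %g um), %d missing\n",
              x$transition_id, nrow(x$grid), ncol(x$grid), x$pixel_w_um,
              x$pixel_h_um, sum(is.na(x$grid))))
  invisible(x)
}

#' @method as_tibble ion_image
#' @export
as_tibble.ion_image <- function(x, ...) {
  g <- x$grid
  tibble(
    transition_id = x$transition_id,
    row = rep(seq_len(nrow(g)) - 1L, times = ncol(g)),
    col = rep(seq_len(ncol(g)) - 1L, each = nrow(g)),
    x_um = x$origin[1] + (rep(seq_len(ncol(g)), each = nrow(g)) - 0.5) *
      x$pixel_w_um,
    y_um = x$origin[2] + (rep(seq_len(nrow(g)), times = ncol(g)) - 0.5) *
      x$pixel_h_um,
    intensity = as.numeric(g)
  )
}

#' @method autoplot ion_image
#' @export
autoplot.ion_image <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_viridis_c(na.value = "black") +
    ggplot2::labs(title = object$transition_id, x = "x (um)", y = "y (um)",
                  fill = "counts/s")
}

#' Reconstruct per-transition ion images from line scans
#'
#' Maps scan cycle `i` of line `l` to pixel `(row = l, col = i)` and
#' dwell-normalizes intensities to counts/s (unless the set is already
#' normalized). Lines with fewer scans than the widest line are padded with
#' `NA`; a transition absent from some line yields an `NA` row and a warning.
#'
#' @param lineset A [line_scan_set()].
#' @return A named list of [ion_image()], one per transition.
#' @export
reconstruct <- function(lineset) {
  stopifnot(inherits(lineset, "line_scan_set"))
  if (nrow(lineset$data) == 0) abort("empty line scan set")
  set <- if (lineset$normalized) lineset else normalize_dwell(lineset)
  cfg <- set$config
  d <- set$data
  lines <- sort(unique(d$line_index))
  n_rows <- length(lines)
  n_cols <- max(d$scan_index) + 1L
  pw <- pixel_width_um(cfg)
  out <- lapply(cfg$transitions$id, function(id) {
    g <- matrix(NA_real_, n_rows, n_cols)
    di <- d[d$transition_id == id, ]
    if (nrow(di) == 0) {
      warn(sprintf("transition '%s' missing from all lines", id))
    } else {
      missing_lines <- setdiff(lines, unique(di$line_index))
      if (length(missing_lines)) {
        warn(sprintf("transition '%s' missing on line(s) %s", id,
                     paste(missing_lines, collapse = ", ")))
      }
      g[cbind(match(di$line_index, lines), di$scan_index + 1L)] <-
        di$intensity
    }
    ion_image(id, g, pixel_w_um = pw, pixel_h_um = cfg$line_spacing_um)
  })
  names(out) <- cfg$transitions$id
  out
}

# normalized cross-correlation of two profiles over finite overlap
profile_ncc <- function(a, b) {
  ok <- is.finite(a) & is.finite(b)
  if (sum(ok) < 3) return(NA_real_)
  a <- a[ok]; b <- b[ok]
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  cor(a, b)
}

shift_vector <- function(x, s) {
  # content recorded with jitter +s is undone by reading position k + s
  n <- length(x)
  idx <- seq_len(n) + s
  out <- rep(NA_real_, n)
  ok <- idx >= 1 & idx <= n
  out[ok] <- x[idx[ok]]
  out
}

#' Re-align line scans by integer-pixel cross-correlation
#'
#' Estimates each line's start offset (line-to-line jitter of a few pixels,
#' caused by de-synchronization between stage motion and acquisition start)
#' and removes it. Each line's reference profile — by default the sum of all
#' dwell-normalized channels, a TIC-like trace that is robust when single
#' channels are sparse — is cross-correlated against a consensus template
#' (the per-pixel median profile across lines, robust to a single bad line)
#' over integer shifts up to `max_shift_px`; the template is then rebuilt
#' from the corrected lines and the estimates are refined over a few rounds.
#' Because random line offsets average out in the median, the consensus
#' approximately anchors the absolute pixel frame instead of inheriting
#' whatever offset the first line happened to have; the global frame
#' translation itself is not identifiable from mutual alignment (see
#' [jitter_recovery()]). Ties are broken toward the smallest
#' `|shift|`, then toward the negative shift. The winning shift is applied
#' to all channels of that line; pixel values are only repositioned, never
#' changed.
#'
#' @param images Named list of [ion_image()] sharing one grid.
#' @param reference `"sum_of_channels"` or a single transition id.
#' @param max_shift_px Maximum absolute shift searched (pixels).
#' @return A list with `images` (re-aligned) and `offsets`, a tibble of the
#'   estimated jitter per line (the applied correction is its negative).
#' @export
realign_lines <- function(images, reference = "sum_of_channels",
                          max_shift_px = 5) {
  stopifnot(is.list(images), length(images) >= 1)
  dims <- dim(images[[1]]$grid)
  if (dims[1] < 2) abort("need at least 2 lines to re-align")
  max_shift_px <- as.integer(max_shift_px)
  if (max_shift_px < 1) abort("max_shift_px must be >= 1")
  for (im in images) {
    if (!identical(dim(im$grid), dims)) abort("images must share one grid")
  }
  prof <- if (identical(reference, "sum_of_channels")) {
    gsum <- Reduce(`+`, lapply(images, function(im) {
      g <- im$grid; g[is.na(g)] <- 0; g
    }))
    n_fin <- Reduce(`+`, lapply(images, function(im) is.finite(im$grid)))
    gsum[n_fin == 0] <- NA_real_
    gsum
  } else {
    if (!reference %in% names(images)) {
      abort(sprintf("reference transition '%s' not among images", reference))
    }
    images[[reference]]$grid
  }

  shifts <- seq(-max_shift_px, max_shift_px)
  # tie-break order: smaller |shift| first, negative before positive
  search <- shifts[order(abs(shifts), shifts)]
  offsets <- integer(dims[1])
  blank <- !apply(is.finite(prof), 1, any)
  if (any(blank)) {
    warn(sprintf("line(s) %s have no finite reference pixels; shift 0",
                 paste(which(blank) - 1L, collapse = ", ")))
  }
  for (round in 1:4) {
    aligned <- prof
    for (l in seq_len(dims[1])) {
      aligned[l, ] <- shift_vector(prof[l, ], offsets[l])
    }
    template <- apply(aligned, 2, median, na.rm = TRUE)
    new_offsets <- offsets
    for (l in seq_len(dims[1])) {
      if (blank[l]) next
      cc <- vapply(search, function(s) {
        profile_ncc(shift_vector(prof[l, ], s), template)
      }, numeric(1))
      new_offsets[l] <- if (all(is.na(cc))) 0L else search[which.max(cc)]
    }
    # re-center on the consensus so estimates keep headroom within the
    # search range instead of inheriting a drifted template frame
    new_offsets <- new_offsets - as.integer(round(median(new_offsets)))
    converged <- identical(new_offsets, offsets) && round > 1
    offsets <- new_offsets
    if (converged) break
  }

  out <- lapply(images, function(im) {
    g <- im$grid
    for (l in seq_len(dims[1])) {
      if (offsets[l] != 0L) g[l, ] <- shift_vector(g[l, ], offsets[l])
    }
    im$grid <- g
    im
  })
  list(images = out,
       offsets = tibble(line_index = seq_len(dims[1]) - 1L,
                        offset_px = offsets))
}

#' Relative intensity scaling
#'
#' Rescales an ion image to `[0, 1]` for display and overlay composition,
#' dividing by either the maximum or (default) the 99th percentile of the
#' finite pixels — percentile scaling keeps a single hotspot from crushing
#' the rest of the dynamic range. The scale used is recorded in attribute
#' `"scaling"` so the operation is reproducible.
#'
#' @param image An [ion_image()].
#' @param method `"percentile"` or `"max"`.
#' @param q Percentile used when `method = "percentile"`.
#' @return The scaled [ion_image()] with values clamped to `[0, 1]`.
#' @export
scale_relative <- function(image, method = c("percentile", "max"), q = 99) {
  stopifnot(inherits(image, "ion_image"))
  method <- match.arg(method)
  vals <- image$grid[is.finite(image$grid)]
  if (!length(vals)) abort("image has no finite pixels")
  scale <- switch(method,
                  max = max(vals),
                  percentile = as.numeric(quantile(vals, q / 100)))
  if (scale <= 0) scale <- 1
  image$grid <- pmin(pmax(image$grid / scale, 0), 1)
  attr(image, "scaling") <- list(method = method, q = q, scale = scale)
  image
}

#' Compose an RGB overlay from scaled ion images
#'
#' Additively blends up to three `[0, 1]`-scaled channels into an RGB image;
#' overlapping red and green signal renders yellow, missing pixels render
#' black.
#'
#' @param images Named list of scaled [ion_image()] (equal grids).
#' @param colors Named character vector or list mapping transition id to an R
#'   color (e.g. `c(drugA = "red", lipB = "green")`); defaults to red, green,
#'   blue in order.
#' @return An object of class `overlay_image` with fields `rgb`
#'   (rows x cols x 3 array in `[0, 1]`), `channel_map` and
#'   `scaling_record`.
#' @export
overlay <- function(images, colors = NULL) {
  stopifnot(is.list(images), length(images) >= 1)
  if (length(images) > 3 && is.null(colors)) {
    abort("more than 3 channels need an explicit color mapping")
  }
  dims <- dim(images[[1]]$grid)
  for (im in images) {
    if (!identical(dim(im$grid), dims)) abort("images must share one grid")
  }
  ids <- vapply(images, function(im) im$transition_id, character(1))
  if (is.null(colors)) {
    colors <- setNames(c("red", "green", "blue")[seq_along(images)], ids)
  }
  rgb <- array(0, c(dims[1], dims[2], 3))
  for (im in images) {
    col <- grDevices::col2rgb(colors[[im$transition_id]])[, 1] / 255
    g <- im$grid
    g[!is.finite(g)] <- 0
    for (ch in 1:3) rgb[, , ch] <- rgb[, , ch] + g * col[ch]
  }
  rgb <- pmin(pmax(rgb, 0), 1)
  structure(list(rgb = rgb,
                 channel_map = setNames(as.character(unlist(colors[ids])),
                                        ids),
                 scaling_record = lapply(images, attr, "scaling")),
            class = "overlay_image")
}

#' @export
print.overlay_image <- function(x, ...) {
  cat(sprintf("<overlay_image> %d x %d px | %s\n", dim(x$rgb)[1],
              dim(x$rgb)[2],
              paste(names(x$channel_map), x$channel_map, sep = "=",
                    collapse = ", ")))
  invisible(x)
}

#' @method autoplot overlay_image
#' @export
autoplot.overlay_image <- function(object, ...) {
  d <- dim(object$rgb)
  df <- tibble(
    row = rep(seq_len(d[1]), times = d[2]),
    col = rep(seq_len(d[2]), each = d[1]),
    fill = grDevices::rgb(as.numeric(object$rgb[, , 1]),
                          as.numeric(object$rgb[, , 2]),
                          as.numeric(object$rgb[, , 3]))
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "pixel", y = "line")
}

#' Write an overlay to a PNG file
#' @param x An [overlay_image()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(x, path) {
  stopifnot(inherits(x, "overlay_image"))
  png::writePNG(x$rgb, path)
  invisible(path)
}

#' Score jitter recovery against known injected offsets
#'
#' Mutual line re-alignment determines offsets only up to one global
#' translation of the pixel frame (no line carries an absolute stage
#' reference), so recovery of simulated jitter is scored after removing the
#' median frame shift between estimated and injected offsets.
#'
#' @param estimated Offsets returned by [realign_lines()].
#' @param injected Ground-truth offsets (e.g.
#'   `sim_result$injected_jitter_px`).
#' @return A one-row tibble: `frame_shift_px` (the removed global
#'   translation) and `recovery_rate` (fraction of lines recovered exactly,
#'   net of the frame shift).
#' @export
jitter_recovery <- function(estimated, injected) {
  if (is.data.frame(estimated)) estimated <- estimated$offset_px
  stopifnot(length(estimated) == length(injected))
  diffs <- estimated - injected
  frame <- round(median(diffs))
  tibble(frame_shift_px = frame, recovery_rate = mean(diffs == frame))
}
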