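#' Synthetic tissue surface model
#'
#' A gridded map of analyte surface density used as simulator ground truth.
#' All maps share one shape; amounts are zero off the tissue mask.
#'
#' @param grid_um Grid spacing (um).
#' @param surface_amount Named list of matrices (one per transition id),
#'   amount per um^2.
#' @param tissue_mask Logical matrix: which cells carry tissue.
#' @param region_labels Integer matrix of region codes (0 = background);
#'   semantics depend on the phantom (e.g. liver zone 1/3, kidney
#'   cortex/medulla, tumor/stroma).
#' @return An object of class `tissue_model`.
#' @export
tissue_model <- function(grid_um, surface_amount, tissue_mask,
                         region_labels = NULL) {
  assert_scalar_num(grid_um, "grid_um", positive = TRUE)
  if (!is.list(surface_amount) || is.null(names(surface_amount))) {
    abort("surface_amount must be a named list of matrices")
  }
  dims <- dim(tissue_mask)
  if (is.null(region_labels)) {
    region_labels <- matrix(as.integer(tissue_mask), dims[1], dims[2])
  }
  for (nm in names(surface_amount)) {
    m <- surface_amount[[nm]]
    if (!identical(dim(m), dims)) abort("surface maps must share one shape")
    if (any(m < 0)) abort("surface amounts must be non-negative")
    m[!tissue_mask] <- 0
    surface_amount[[nm]] <- m
  }
  if (!identical(dim(region_labels), dims)) {
    abort("region_labels must share the mask shape")
  }
  structure(list(grid_um = grid_um, surface_amount = surface_amount,
                 tissue_mask = tissue_mask,
                 region_labels = region_labels),
            class = "tissue_model")
}

#' @export
print.tissue_model <- function(x, ...) {
  d <- dim(x$tissue_mask)
  cat(sprintf("<tissue_model> %d x %d cells @ %g um | %d analytes | regions: %s\n",
              d[1], d[2], x$grid_um, length(x$surface_amount),
              paste(sort(unique(as.integer(x$region_labels))),
                    collapse = ",")))
  invisible(x)
}

# per-region mean amounts with lognormal-ish within-region variability
region_amounts <- function(labels, means, cv) {
  out <- matrix(0, nrow(labels), ncol(labels))
  for (lab in as.integer(names(means))) {
    idx <- which(labels == lab)
    mu <- means[[as.character(lab)]]
    if (length(idx)) {
      out[idx] <- pmax(0, mu * (1 + cv * rnorm(length(idx))))
    }
  }
  out
}

#' Generate a synthetic tissue phantom
#'
#' Deterministic (per seed) tissue models that mimic the spatial contrasts of
#' the biological use cases: a zonated liver lobule pattern (drug-like signal
#' periportal, lipid-like centrilobular), a kidney section with concentric
#' cortex / outer medulla / inner medulla regions, a tumor/stroma section
#' with blob-shaped tumor nests, and a plain labeled pixel table for
#' classifier studies.
#'
#' Region label codes: `zonated_liver` 1 = periportal (zone 1),
#' 3 = centrilobular (zone 3), 2 = mid-zone; `kidney` 1 = cortex,
#' 2 = outer medulla, 3 = inner medulla; `tumor_stroma` 1 = stroma,
#' 2 = tumor.
#'
#' @param kind One of `"zonated_liver"`, `"kidney"`, `"tumor_stroma"`,
#'   `"two_class_pixels"`.
#' @param params Named list overriding the kind's defaults; see Details.
#' @param seed Master seed (substream `"phantom"`).
#' @return A [tissue_model()], or for `"two_class_pixels"` a labeled-pixel
#'   tibble (columns `sample_id`, `label`, `row`, `col`, channels `ch01`...).
#'
#' @details Common parameters: `width_um`, `height_um`, `grid_um`,
#' `analytes` (named list: per-region mean amounts per analyte),
#' `cv` (within-region coefficient of variation).
#' `two_class_pixels` instead takes `n_per_class`, `n_channels`,
#' `separation` (class-mean separation in units of within-class SD),
#' `n_sep_channels` (how many channels carry it), `n_samples`,
#' `tumor_samples` (which samples contain class-2 pixels) and `sample_sd`
#' (SD of sample-level mean shifts, in within-class SD units).
#' @export
#' @examples
#' ph <- make_phantom("tumor_stroma", seed = 7)
#' table(ph$region_labels)
make_phantom <- function(kind = c("zonated_liver", "kidney", "tumor_stroma",
                                  "two_class_pixels"),
                         params = list(), seed = 1L) {
  kind <- match.arg(kind)
  with_substream(seed, "phantom", {
    switch(kind,
           zonated_liver = phantom_liver(params),
           kidney = phantom_kidney(params),
           tumor_stroma = phantom_tumor_stroma(params),
           two_class_pixels = phantom_two_class(params))
  })
}

phantom_defaults <- function(params, defaults) {
  utils::modifyList(defaults, params)
}

phantom_grid <- function(p) {
  nr <- max(2L, round(p$height_um / p$grid_um))
  nc <- max(2L, round(p$width_um / p$grid_um))
  xc <- (seq_len(nc) - 0.5) * p$grid_um
  yc <- (seq_len(nr) - 0.5) * p$grid_um
  list(nr = nr, nc = nc, x = matrix(xc, nr, nc, byrow = TRUE),
       y = matrix(yc, nr, nc))
}

phantom_liver <- function(params) {
  p <- phantom_defaults(params, list(
    width_um = 3000, height_um = 3000, grid_um = 50, lobule_um = 1000,
    cv = 0.15,
    analytes = list(drugA = c(`1` = 1.0, `2` = 0.45, `3` = 0.15),
                    lipB = c(`1` = 0.3, `2` = 0.6, `3` = 1.0))))
  g <- phantom_grid(p)
  # central veins on a square lattice; portal triads on the dual lattice.
  # distance to the nearest lattice point of each family sets the zone.
  L <- p$lobule_um
  d_cv <- sqrt(pmin(g$x %% L, L - g$x %% L)^2 +
                 pmin(g$y %% L, L - g$y %% L)^2)
  xs <- (g$x + L / 2) %% L; ys <- (g$y + L / 2) %% L
  d_pt <- sqrt(pmin(xs, L - xs)^2 + pmin(ys, L - ys)^2)
  labels <- matrix(2L, g$nr, g$nc)
  labels[d_pt < 0.3 * L] <- 1L   # periportal, zone 1
  labels[d_cv < 0.3 * L] <- 3L   # centrilobular, zone 3
  mask <- matrix(TRUE, g$nr, g$nc)
  amounts <- lapply(p$analytes, function(m) region_amounts(labels, m, p$cv))
  tissue_model(p$grid_um, amounts, mask, labels)
}

phantom_kidney <- function(params) {
  p <- phantom_defaults(params, list(
    width_um = 3000, height_um = 3000, grid_um = 50, cv = 0.15,
    analytes = list(lpc = c(`1` = 1.0, `2` = 0.5, `3` = 0.2),
                    fa = c(`1` = 0.2, `2` = 0.6, `3` = 1.0))))
  g <- phantom_grid(p)
  cx <- p$width_um / 2; cy <- p$height_um / 2
  r <- sqrt(((g$x - cx) / (0.48 * p$width_um))^2 +
              ((g$y - cy) / (0.48 * p$height_um))^2)
  labels <- matrix(0L, g$nr, g$nc)
  labels[r <= 1] <- 1L          # cortex
  labels[r <= 0.66] <- 2L       # outer medulla
  labels[r <= 0.33] <- 3L       # inner medulla
  mask <- labels > 0L
  amounts <- lapply(p$analytes, function(m) region_amounts(labels, m, p$cv))
  tissue_model(p$grid_um, amounts, mask, labels)
}

phantom_tumor_stroma <- function(params) {
  p <- phantom_defaults(params, list(
    width_um = 3000, height_um = 3000, grid_um = 50, cv = 0.15,
    n_blobs = 4, blob_um = 600,
    analytes = list(pc341 = c(`1` = 0.4, `2` = 1.0),   # up in tumor
                    pc364 = c(`1` = 0.8, `2` = 0.6)))) # mildly up in stroma
  g <- phantom_grid(p)
  labels <- matrix(1L, g$nr, g$nc)  # stroma everywhere
  for (b in seq_len(p$n_blobs)) {
    cx <- runif(1, 0.2, 0.8) * p$width_um
    cy <- runif(1, 0.2, 0.8) * p$height_um
    rad <- p$blob_um / 2 * runif(1, 0.7, 1.3)
    labels[(g$x - cx)^2 + (g$y - cy)^2 <= rad^2] <- 2L
  }
  mask <- matrix(TRUE, g$nr, g$nc)
  amounts <- lapply(p$analytes, function(m) region_amounts(labels, m, p$cv))
  tissue_model(p$grid_um, amounts, mask, labels)
}

phantom_two_class <- function(params) {
  p <- phantom_defaults(params, list(
    n_per_class = 500, n_channels = 14, separation = 3, n_sep_channels = 3,
    n_samples = 1, tumor_samples = NULL, sample_sd = 0,
    labels = c("stroma", "tumor")))
  if (is.null(p$tumor_samples)) p$tumor_samples <- seq_len(p$n_samples)
  shift <- numeric(p$n_channels)
  shift[seq_len(min(p$n_sep_channels, p$n_channels))] <- p$separation
  rows <- list()
  for (s in seq_len(p$n_samples)) {
    cls <- if (s %in% p$tumor_samples) p$labels else p$labels[1]
    s_shift <- rnorm(p$n_channels, 0, p$sample_sd)
    for (ci in seq_along(cls)) {
      n <- p$n_per_class
      x <- matrix(rnorm(n * p$n_channels), n, p$n_channels)
      if (cls[ci] == p$labels[2]) x <- sweep(x, 2, shift, `+`)
      x <- sweep(x, 2, s_shift, `+`)
      colnames(x) <- sprintf("ch%02d", seq_len(p$n_channels))
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble(sample_id = sprintf("s%02d", s), label = cls[ci],
               row = seq_len(n), col = ci),
        as_tibble(x))
    }
  }
  bind_rows(rows)
}
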