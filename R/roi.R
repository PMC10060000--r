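#' Region-of-interest mask
#'
#' @param name ROI label.
#' @param mask Logical matrix congruent with the image grid.
#' @param group One of `"control"`, `"dosed"`, `"tumor"`, `"stroma"`,
#'   `"custom"`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(name, mask, group = c("custom", "control", "dosed",
                                           "tumor", "stroma")) {
  group <- match.arg(group)
  if (!is.matrix(mask) || !is.logical(mask)) {
    abort("mask must be a logical matrix")
  }
  if (!any(mask)) abort("ROI mask must be non-empty")
  structure(list(name = name, mask = mask, group = group),
            class = "roi_mask")
}

#' Per-ROI summary statistics
#'
#' Mean and standard deviation of the finite pixels of an ion image inside
#' each ROI, as used to report per-region analyte abundances (e.g. the mean
#' of a 36-pixel block, or mean + SD over 4 randomly placed ROIs per
#' anatomical region).
#'
#' @param image An [ion_image()].
#' @param rois A list of [roi_mask()] (a single mask is accepted).
#' @return A tibble with columns `roi`, `group`, `n_pixels`, `mean`, `sd`.
#' @export
roi_summary <- function(image, rois) {
  stopifnot(inherits(image, "ion_image"))
  if (inherits(rois, "roi_mask")) rois <- list(rois)
  rows <- lapply(rois, function(r) {
    stopifnot(inherits(r, "roi_mask"))
    if (!identical(dim(r$mask), dim(image$grid))) {
      abort(sprintf("ROI '%s' shape does not match image", r$name))
    }
    vals <- image$grid[r$mask]
    vals <- vals[is.finite(vals)]
    if (!length(vals)) {
      warn(sprintf("ROI '%s' has no finite pixels", r$name))
      tibble(roi = r$name, group = r$group, n_pixels = 0L,
             mean = NA_real_, sd = NA_real_)
    } else {
      tibble(roi = r$name, group = r$group, n_pixels = length(vals),
             mean = mean(vals), sd = sd(vals))
    }
  })
  bind_rows(rows)
}

# exact two-sided Mann-Whitney p by enumeration of all rank assignments
# (mid-ranks, so ties are handled); U is the statistic of sample a
mw_exact_p <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  pooled <- c(a, b)
  rk <- rank(pooled)
  u_obs <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  combs <- utils::combn(n_a + n_b, n_a)
  u_all <- colSums(matrix(rk[combs], nrow = n_a)) - n_a * (n_a + 1) / 2
  eps <- 1e-9
  p <- 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps))
  list(u = u_obs, p = min(1, p))
}

# normal approximation with mid-ranks, tie-corrected variance and
# continuity correction
mw_approx_p <- function(a, b) {
  n_a <- length(a); n_b <- length(b)
  n <- n_a + n_b
  rk <- rank(c(a, b))
  u <- sum(rk[seq_len(n_a)]) - n_a * (n_a + 1) / 2
  mu <- n_a * n_b / 2
  ties <- table(c(a, b))
  sig2 <- n_a * n_b / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (sig2 <= 0) return(list(u = u, p = 1))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
  list(u = u, p = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Two-group comparison: Mann-Whitney test and fold change
#'
#' Two-tailed nonparametric comparison of per-ROI (or per-pixel) intensities
#' between two groups, reported with the fold change `mean(b) / mean(a)`.
#' The p value is computed by exact enumeration of all rank assignments when
#' `min(n_a, n_b) <= 8`, and by the tie-corrected normal approximation (with
#' continuity correction) otherwise. Significance stars follow the
#' conventional thresholds `*` p < 0.05 and `***` p < 0.0001.
#'
#' @param a,b Numeric vectors (group a = reference / control).
#' @return A one-row tibble: `n_a`, `n_b`, `u`, `p_value`, `fold_change`,
#'   `method`, `significance`.
#' @export
#' @examples
#' compare_groups(c(1, 2, 3, 4), c(10, 20, 30, 40))
compare_groups <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (!length(a) || !length(b)) abort("both groups need at least one value")
  if (length(unique(c(a, b))) == 1L) {
    res <- list(u = length(a) * length(b) / 2, p = 1)
    method <- "degenerate"
  } else if (min(length(a), length(b)) <= 8) {
    res <- mw_exact_p(a, b)
    method <- "exact"
  } else {
    res <- mw_approx_p(a, b)
    method <- "normal_approx"
  }
  fc <- if (mean(a) == 0) {
    warn("mean of group a is 0; fold change undefined")
    NA_real_
  } else {
    mean(b) / mean(a)
  }
  tibble(n_a = length(a), n_b = length(b), u = res$u, p_value = res$p,
         fold_change = fc, method = method,
         significance = if (res$p < 1e-4) "***"
                        else if (res$p < 0.05) "*" else "ns")
}

#' Place square ROIs at random within a region
#'
#' Draws `k` non-overlapping square ROIs of side `size_px`, each fully inside
#' the region mask; placement is deterministic per seed (substream
#' `"rois"`). A 6 x 6 block (36 pixels) is the default sampling unit.
#'
#' @param region Logical matrix (the admissible region), or a [roi_mask()].
#' @param k Number of ROIs.
#' @param size_px Side length in pixels.
#' @param seed Master seed.
#' @param name Region name used in error messages and ROI labels.
#' @return A list of [roi_mask()].
#' @export
random_rois <- function(region, k, size_px = 6, seed = 1L,
                        name = "region") {
  if (inherits(region, "roi_mask")) {
    name <- region$name
    region <- region$mask
  }
  stopifnot(is.matrix(region), is.logical(region))
  k <- as.integer(k); size_px <- as.integer(size_px)
  if (k < 1 || size_px < 1) abort("k and size_px must be >= 1")
  nr <- nrow(region); nc <- ncol(region)
  if (nr < size_px || nc < size_px) {
    abort(sprintf("region '%s' cannot hold %d ROI(s) of %d x %d px", name, k,
                  size_px, size_px))
  }
  # integral image -> candidate top-left corners with an all-TRUE block
  ii <- rbind(0, cbind(0, apply(apply(region, 2, cumsum), 1, cumsum) |> t()))
  blk <- function(r, c) {
    ii[r + size_px, c + size_px] - ii[r, c + size_px] -
      ii[r + size_px, c] + ii[r, c]
  }
  cand <- expand.grid(r = seq_len(nr - size_px + 1),
                      c = seq_len(nc - size_px + 1))
  full <- mapply(blk, cand$r, cand$c) == size_px^2
  cand <- cand[full, , drop = FALSE]
  if (nrow(cand) < k) {
    abort(sprintf("region '%s' cannot hold %d ROI(s) of %d x %d px", name, k,
                  size_px, size_px))
  }
  placed <- with_substream(seed, "rois", {
    best <- NULL
    for (try in seq_len(100)) {
      ord <- sample.int(nrow(cand))
      acc <- matrix(NA_integer_, 0, 2)
      for (idx in ord) {
        r <- cand$r[idx]; c <- cand$c[idx]
        if (nrow(acc) == 0 ||
            all(abs(acc[, 1] - r) >= size_px |
                  abs(acc[, 2] - c) >= size_px)) {
          acc <- rbind(acc, c(r, c))
          if (nrow(acc) == k) break
        }
      }
      if (is.null(best) || nrow(acc) > nrow(best)) best <- acc
      if (nrow(best) == k) break
    }
    best
  })
  if (nrow(placed) < k) {
    abort(sprintf(
      "could not place %d non-overlapping ROI(s) of %d px in region '%s'", k,
      size_px, name))
  }
  lapply(seq_len(k), function(i) {
    m <- matrix(FALSE, nr, nc)
    m[placed[i, 1] + seq_len(size_px) - 1L,
      placed[i, 2] + seq_len(size_px) - 1L] <- TRUE
    roi_mask(sprintf("%s_%d", name, i), m)
  })
}
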