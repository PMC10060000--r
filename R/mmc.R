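#' Fit a maximum margin criterion (MMC) projection
#'
#' Supervised linear projection for pixel classification: channels are
#' z-scored, the between-class scatter `S_b` (class-mean deviations weighted
#' by class size) and pooled within-class scatter `S_w` are formed, and the
#' projection `W` is the top-`d` eigenvectors of the symmetric matrix
#' `S_b - S_w` — directions along which classes are far apart relative to
#' their spread, without inverting `S_w` (so collinear channels are
#' harmless). Classification in the projected space is nearest class mean by
#' Mahalanobis distance under the pooled projected covariance, with a
#' chi-squared rejection cutoff for pixels that resemble no class (rendered
#' as background).
#'
#' @param data Labeled pixel tibble: a `label` column plus one numeric column
#'   per channel (see [images_to_pixels()] and
#'   [make_phantom()]`("two_class_pixels")`).
#' @param d Number of projection components; default `n_classes - 1`.
#' @param channels Channel columns; default all numeric non-reserved columns.
#' @return An object of class `mmc_model`.
#' @export
#' @examples
#' px <- make_phantom("two_class_pixels",
#'                    params = list(n_per_class = 100, n_channels = 5),
#'                    seed = 1)
#' m <- mmc_fit(px)
#' table(predict(m, px), px$label)
mmc_fit <- function(data, d = NULL, channels = NULL) {
  channels <- pixel_channels(data, channels)
  x <- check_labeled_pixels(data, channels)
  y <- as.character(data$label)
  classes <- sort(unique(y))
  if (length(classes) < 2) abort("need >= 2 classes to fit")
  mu <- colMeans(x)
  sg <- apply(x, 2, sd)
  drop <- sg == 0
  if (any(drop)) {
    warn(paste("dropping constant channel(s):",
               paste(channels[drop], collapse = ", ")))
    channels <- channels[!drop]
    x <- x[, !drop, drop = FALSE]
    mu <- mu[!drop]; sg <- sg[!drop]
  }
  if (!length(channels)) abort("no usable (non-constant) channels")
  z <- sweep(sweep(x, 2, mu), 2, sg, `/`)
  n <- nrow(z); p <- ncol(z)
  if (is.null(d)) d <- length(classes) - 1L
  d <- as.integer(d)
  if (d < 1 || d > p) abort("d must be between 1 and the channel count")
  gm <- colMeans(z)
  s_b <- matrix(0, p, p)
  s_w <- matrix(0, p, p)
  for (cl in classes) {
    zi <- z[y == cl, , drop = FALSE]
    if (nrow(zi) < d + 1) {
      abort(sprintf("class '%s' needs at least d + 1 = %d pixels", cl,
                    d + 1))
    }
    dm <- colMeans(zi) - gm
    s_b <- s_b + nrow(zi) / n * tcrossprod(dm)
    s_w <- s_w + crossprod(sweep(zi, 2, colMeans(zi))) / n
  }
  eig <- eigen(s_b - s_w, symmetric = TRUE)
  w <- eig$vectors[, seq_len(d), drop = FALSE]
  # fix eigenvector sign: largest-magnitude entry positive
  for (j in seq_len(d)) {
    i <- which.max(abs(w[, j]))
    if (w[i, j] < 0) w[, j] <- -w[, j]
  }
  scores <- z %*% w
  class_means <- do.call(rbind, lapply(classes, function(cl) {
    colMeans(scores[y == cl, , drop = FALSE])
  }))
  rownames(class_means) <- classes
  resid <- scores - class_means[y, , drop = FALSE]
  pooled_cov <- crossprod(resid) / (n - length(classes))
  # tiny ridge keeps Mahalanobis distances defined when a projected class
  # is (numerically) point-like
  pooled_cov <- pooled_cov + diag(1e-8 * (1 + mean(diag(pooled_cov))),
                                  nrow(pooled_cov))
  structure(
    list(W = w, d = d, channels = channels, center = mu, scale = sg,
         classes = classes, class_means = class_means,
         pooled_cov = pooled_cov, eigenvalues = eig$values,
         reject_threshold = qchisq(0.999, df = d)),
    class = "mmc_model")
}

#' @export
print.mmc_model <- function(x, ...) {
  cat(sprintf(
    "<mmc_model> %d channels -> %d component(s) | classes: %s | leading eigenvalues: %s\n",
    length(x$channels), x$d, paste(x$classes, collapse = ", "),
    paste(signif(head(x$eigenvalues, x$d), 3), collapse = ", ")))
  invisible(x)
}

#' Classify pixels with an MMC model
#'
#' Projects standardized pixels with the stored projection and assigns the
#' nearest class mean by Mahalanobis distance; pixels whose smallest squared
#' distance exceeds the rejection threshold (default the 0.999 chi-squared
#' quantile at `d` degrees of freedom) are labeled `"unclassified"` and are
#' rendered as background in segmentation maps.
#'
#' @param object An [mmc_fit()] model.
#' @param newdata Pixel tibble with the model's channel columns.
#' @param reject_threshold Squared-Mahalanobis cutoff; `Inf` disables
#'   rejection.
#' @param ... Unused.
#' @return Character vector of class labels (or `"unclassified"`), with the
#'   per-pixel minimal squared distance in attribute `"distance"`.
#' @export
predict.mmc_model <- function(object, newdata,
                              reject_threshold = object$reject_threshold,
                              ...) {
  x <- check_labeled_pixels(newdata, object$channels, need_labels = FALSE)
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, `/`)
  scores <- z %*% object$W
  d2 <- vapply(object$classes, function(cl) {
    mahalanobis(scores, object$class_means[cl, ], object$pooled_cov)
  }, numeric(nrow(scores)))
  d2 <- matrix(d2, nrow = nrow(scores))
  best <- max.col(-d2, ties.method = "first")
  lab <- object$classes[best]
  dmin <- d2[cbind(seq_len(nrow(d2)), best)]
  lab[dmin > reject_threshold] <- "unclassified"
  attr(lab, "distance") <- dmin
  lab
}

#' @method tidy mmc_model
#' @export
tidy.mmc_model <- function(x, ...) {
  w <- x$W
  tibble(
    channel = rep(x$channels, times = x$d),
    component = rep(seq_len(x$d), each = length(x$channels)),
    loading = as.numeric(w)
  )
}

#' @method glance mmc_model
#' @export
glance.mmc_model <- function(x, ...) {
  tibble(n_channels = length(x$channels), d = x$d,
         n_classes = length(x$classes),
         margin = sum(head(x$eigenvalues, x$d)),
         reject_threshold = x$reject_threshold)
}

#' Segment an image set with a fitted MMC model
#'
#' Convenience wrapper: classifies every complete pixel of an image set and
#' returns the segmentation as a label matrix (`NA` = rejected/background).
#'
#' @param model An [mmc_fit()] model.
#' @param images Named list of [ion_image()].
#' @param ... Passed to [predict.mmc_model()].
#' @return A character matrix of class labels with `NA` for rejected or
#'   incomplete pixels.
#' @export
mmc_segment <- function(model, images, ...) {
  px <- images_to_pixels(images)
  lab <- predict(model, px, ...)
  dims <- dim(images[[1]]$grid)
  seg <- matrix(NA_character_, dims[1], dims[2])
  seg[cbind(px$row + 1L, px$col + 1L)] <- ifelse(lab == "unclassified",
                                                 NA_character_, lab)
  seg
}
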