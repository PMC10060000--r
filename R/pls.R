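#' Fit PLS-DA (NIPALS partial least squares discriminant analysis)
#'
#' Regresses one-hot class codes on z-scored channels by NIPALS: latent
#' components are extracted iteratively (weight vector, X scores, Y
#' loadings), X and Y are deflated, and successive score vectors are mutually
#' orthogonal. Prediction assigns the class with the highest predicted code.
#' Two components are the default, matching a low-dimensional targeted-panel
#' setting.
#'
#' @param data Labeled pixel tibble (`label` column + channel columns).
#' @param n_components Number of latent components (truncated with a warning
#'   if the channel matrix has lower rank).
#' @param channels Channel columns; default all numeric non-reserved.
#' @param max_iter,tol NIPALS inner-loop controls.
#' @return An object of class `pls_da`.
#' @export
#' @examples
#' px <- make_phantom("two_class_pixels",
#'                    params = list(n_per_class = 100, n_channels = 5),
#'                    seed = 1)
#' fit <- pls_da_fit(px, n_components = 2)
#' glance(fit)
pls_da_fit <- function(data, n_components = 2, channels = NULL,
                       max_iter = 200, tol = 1e-9) {
  channels <- pixel_channels(data, channels)
  x <- check_labeled_pixels(data, channels)
  y_lab <- as.character(data$label)
  classes <- sort(unique(y_lab))
  if (length(classes) < 2) abort("need >= 2 classes to fit")
  mu <- colMeans(x); sg <- apply(x, 2, sd)
  keep <- sg > 0
  if (!all(keep)) {
    warn(paste("dropping constant channel(s):",
               paste(channels[!keep], collapse = ", ")))
    channels <- channels[keep]
    x <- x[, keep, drop = FALSE]; mu <- mu[keep]; sg <- sg[keep]
  }
  z <- sweep(sweep(x, 2, mu), 2, sg, `/`)
  y <- outer(y_lab, classes, `==`) * 1
  y_mean <- colMeans(y)
  yc <- sweep(y, 2, y_mean)

  n_components <- as.integer(n_components)
  p <- ncol(z)
  a_max <- min(n_components, p, nrow(z) - 1L)
  ws <- ps <- NULL
  qs <- NULL
  ts_ <- NULL
  ss_x0 <- sum(z^2); ss_y0 <- sum(yc^2)
  xa <- z; ya <- yc
  a_used <- 0L
  for (a in seq_len(a_max)) {
    if (sum(xa^2) < tol * ss_x0) break
    u <- ya[, which.max(colSums(ya^2))]
    t_old <- rep(Inf, nrow(xa))
    for (it in seq_len(max_iter)) {
      w <- crossprod(xa, u)[, 1]
      w <- w / sqrt(sum(w^2))
      t_ <- xa %*% w
      q <- crossprod(ya, t_)[, 1] / sum(t_^2)
      u <- ya %*% q / sum(q^2)
      if (sum((t_ - t_old)^2) < tol * sum(t_^2)) break
      t_old <- t_
    }
    if (sum(t_^2) < tol) break
    p_ <- crossprod(xa, t_)[, 1] / sum(t_^2)
    xa <- xa - t_ %*% t(p_)
    ya <- ya - t_ %*% t(q)
    ws <- cbind(ws, w); ps <- cbind(ps, p_); qs <- cbind(qs, q)
    ts_ <- cbind(ts_, t_)
    a_used <- a
  }
  if (a_used == 0L) abort("no usable PLS component could be extracted")
  if (a_used < n_components) {
    warn(sprintf("component count truncated to rank %d", a_used))
  }
  # regression coefficients on standardized X: B = W (P'W)^-1 Q'
  b <- ws %*% solve(crossprod(ps, ws), t(qs))
  fitted <- sweep(z %*% b, 2, y_mean, `+`)
  r2y <- 1 - sum((y - fitted)^2) / ss_y0
  structure(
    list(channels = channels, center = mu, scale = sg, classes = classes,
         n_components = a_used, x_weights = ws, x_loadings = ps,
         y_loadings = qs, scores = ts_, coefficients = b, y_mean = y_mean,
         r2y = r2y,
         x_var_explained = 1 - sum(xa^2) / ss_x0),
    class = "pls_da")
}

#' @export
print.pls_da <- function(x, ...) {
  cat(sprintf(
    "<pls_da> %d channels, %d component(s) | classes: %s | R2Y %.3f\n",
    length(x$channels), x$n_components, paste(x$classes, collapse = ", "),
    x$r2y))
  invisible(x)
}

#' Predict class labels (or scores) from a PLS-DA fit
#'
#' @param object A [pls_da_fit()] model.
#' @param newdata Pixel tibble with the model's channels.
#' @param type `"class"` for labels, `"score"` for the predicted class-code
#'   matrix.
#' @param ... Unused.
#' @return Character labels, or a numeric matrix of class scores.
#' @export
predict.pls_da <- function(object, newdata, type = c("class", "score"),
                           ...) {
  type <- match.arg(type)
  x <- check_labeled_pixels(newdata, object$channels, need_labels = FALSE)
  z <- sweep(sweep(x, 2, object$center), 2, object$scale, `/`)
  yhat <- sweep(z %*% object$coefficients, 2, object$y_mean, `+`)
  colnames(yhat) <- object$classes
  if (type == "score") return(yhat)
  object$classes[max.col(yhat, ties.method = "first")]
}

#' @method tidy pls_da
#' @export
tidy.pls_da <- function(x, ...) {
  tibble(
    channel = rep(x$channels, times = x$n_components),
    component = rep(seq_len(x$n_components), each = length(x$channels)),
    weight = as.numeric(x$x_weights),
    loading = as.numeric(x$x_loadings)
  )
}

#' @method glance pls_da
#' @export
glance.pls_da <- function(x, ...) {
  tibble(n_channels = length(x$channels), n_components = x$n_components,
         n_classes = length(x$classes), r2y = x$r2y,
         x_var_explained = x$x_var_explained)
}
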