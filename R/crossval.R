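#' Cross-validate a pixel classifier
#'
#' k-fold cross-validation with the two fold schemes used for tissue
#' classification studies: `random_subset` draws pixel folds stratified by
#' class regardless of origin (within-sample validation), while `by_sample`
#' keeps every tissue sample whole — no sample contributes pixels to both the
#' training and the test side of a fold (inter-sample validation). With fewer
#' samples than folds, `by_sample` leaves some folds empty; accuracy is
#' pooled over the non-empty test folds.
#'
#' Accuracy is the fraction of correctly labeled annotated test pixels,
#' pooled over folds; pixels a classifier rejects (`"unclassified"`) are
#' excluded from the accuracy denominator and counted separately.
#'
#' @param data Labeled pixel tibble (`label`, optionally `sample_id`,
#'   channel columns).
#' @param fitter Function `(train_data, ...)` returning a model with a
#'   [predict()] method that yields labels; e.g. [mmc_fit()] or
#'   [pls_da_fit()].
#' @param k Number of folds.
#' @param scheme `"random_subset"` or `"by_sample"`.
#' @param seed Master seed (substream `"folds"`).
#' @param ... Passed on to `fitter`.
#' @return An object of class `cv_result`: pooled `accuracy` (in percent),
#'   `confusion` (true x predicted table), `n_rejected`, `per_fold` tibble
#'   and the fold assignment.
#' @export
#' @examples
#' px <- make_phantom("two_class_pixels",
#'                    params = list(n_per_class = 60, n_channels = 6),
#'                    seed = 2)
#' cv <- crossvalidate(px, mmc_fit, k = 5, seed = 2)
#' glance(cv)
crossvalidate <- function(data, fitter, k = 10,
                          scheme = c("random_subset", "by_sample"),
                          seed = 1L, ...) {
  scheme <- match.arg(scheme)
  k <- as.integer(k)
  if (k < 2) abort("k must be >= 2")
  if (!"label" %in% names(data)) abort("data must have a `label` column")
  n <- nrow(data)
  y <- as.character(data$label)

  fold <- integer(n)
  with_substream(seed, "folds", {
    if (scheme == "random_subset") {
      for (cl in unique(y)) {
        idx <- which(y == cl)
        fold[idx] <- rep_len(seq_len(k), length(idx))[
          sample.int(length(idx))]
      }
    } else {
      if (!"sample_id" %in% names(data)) {
        abort("by_sample scheme needs a `sample_id` column")
      }
      ids <- unique(data$sample_id)
      assign_ <- setNames(rep_len(seq_len(k), length(ids))[
        sample.int(length(ids))], ids)
      fold <- as.integer(assign_[data$sample_id])
    }
  })

  all_classes <- sort(unique(y))
  pred_all <- rep(NA_character_, n)
  per_fold <- list()
  for (f in sort(unique(fold))) {
    test <- fold == f
    train <- !test
    if (!any(test)) next
    train_classes <- unique(y[train])
    if (length(train_classes) < length(all_classes)) {
      warn(sprintf("fold %d: class(es) %s absent from training; refit without",
                   f, paste(setdiff(all_classes, train_classes),
                            collapse = ", ")))
    }
    if (length(train_classes) < 2) {
      # nothing to discriminate: every test pixel gets the remaining class
      pred_all[test] <- train_classes
    } else {
      model <- fitter(data[train, , drop = FALSE], ...)
      pred_all[test] <- as.character(predict(model,
                                             data[test, , drop = FALSE]))
    }
    ok <- test & pred_all != "unclassified" & !is.na(pred_all)
    per_fold[[length(per_fold) + 1L]] <- tibble(
      fold = f, n_test = sum(test),
      n_rejected = sum(test) - sum(ok),
      accuracy = 100 * mean(pred_all[ok] == y[ok]))
  }
  classified <- !is.na(pred_all) & pred_all != "unclassified"
  acc <- 100 * sum(pred_all[classified] == y[classified]) / sum(classified)
  confusion <- table(truth = y[!is.na(pred_all)],
                     prediction = pred_all[!is.na(pred_all)])
  structure(
    list(accuracy = acc, confusion = confusion,
         n_rejected = sum(!classified & !is.na(pred_all)),
         n_test = sum(!is.na(pred_all)),
         per_fold = bind_rows(per_fold), k = k, scheme = scheme,
         seed = seed, fold = fold),
    class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf(
    "<cv_result> %s, k = %d | pooled accuracy %.1f%% (%d test px, %d rejected)\n",
    x$scheme, x$k, x$accuracy, x$n_test, x$n_rejected))
  print(x$confusion)
  invisible(x)
}

#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble(scheme = x$scheme, k = x$k, accuracy = x$accuracy,
         n_test = x$n_test, n_rejected = x$n_rejected)
}

#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) x$per_fold
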