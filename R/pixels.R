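# labeled-pixel tibbles: reserved columns + channel columns
pixel_reserved <- c("label", "sample_id", "row", "col")

pixel_channels <- function(data, channels = NULL) {
  if (!is.null(channels)) return(channels)
  setdiff(names(data)[vapply(data, is.numeric, logical(1))],
          pixel_reserved)
}

check_labeled_pixels <- function(data, channels, need_labels = TRUE) {
  if (!is.data.frame(data) || nrow(data) == 0) {
    abort("need a non-empty pixel data frame")
  }
  if (need_labels && !"label" %in% names(data)) {
    abort("pixel data must have a `label` column")
  }
  if (!length(channels)) abort("no channel columns found")
  miss <- setdiff(channels, names(data))
  if (length(miss)) {
    abort(paste("missing channel column(s):", paste(miss, collapse = ", ")))
  }
  x <- as.matrix(data[channels])
  if (anyNA(x)) abort("channel values must not be missing; drop such pixels")
  x
}

#' Build a pixel feature table from ion images
#'
#' Stacks a set of equally sized ion images into one tibble with a row per
#' pixel and a column per transition channel, optionally attaching region
#' labels. Pixels with a missing value in any channel are dropped (classifier
#' input must be complete).
#'
#' @param images Named list of [ion_image()] on one grid.
#' @param labels Optional integer/character matrix of per-pixel labels;
#'   label 0 (background) is dropped.
#' @param sample_id Sample identifier attached to every pixel.
#' @return A tibble with columns `sample_id`, `row`, `col`, optional
#'   `label`, and one numeric column per transition.
#' @export
images_to_pixels <- function(images, labels = NULL, sample_id = "s01") {
  stopifnot(is.list(images), length(images) >= 1)
  dims <- dim(images[[1]]$grid)
  for (im in images) {
    if (!identical(dim(im$grid), dims)) abort("images must share one grid")
  }
  df <- tibble(
    sample_id = sample_id,
    row = rep(seq_len(dims[1]) - 1L, times = dims[2]),
    col = rep(seq_len(dims[2]) - 1L, each = dims[1])
  )
  for (im in images) df[[im$transition_id]] <- as.numeric(im$grid)
  if (!is.null(labels)) {
    if (!identical(dim(labels), dims)) {
      abort("labels must share the image grid")
    }
    df$label <- as.vector(labels)
    df <- df[df$label != 0, , drop = FALSE]
  }
  ch <- pixel_channels(df)
  keep <- stats::complete.cases(df[ch])
  df[keep, , drop = FALSE]
}
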