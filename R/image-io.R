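#' Read and write ion images as plain CSV grids
#'
#' A small self-describing text format for a single channel: `#key=value`
#' header lines (`transition_id`, `pixel_w_um`, `pixel_h_um`, `origin_x_um`,
#' `origin_y_um`), then one CSV row per image line; missing pixels are empty
#' fields.
#'
#' @param image An [ion_image()].
#' @param path File path.
#' @return `read_ion_image_csv()` an [ion_image()];
#'   `write_ion_image_csv()` the path, invisibly.
#' @export
write_ion_image_csv <- function(image, path) {
  stopifnot(inherits(image, "ion_image"))
  hdr <- c(sprintf("#transition_id=%s", image$transition_id),
           sprintf("#pixel_w_um=%.17g", image$pixel_w_um),
           sprintf("#pixel_h_um=%.17g", image$pixel_h_um),
           sprintf("#origin_x_um=%.17g", image$origin[1]),
           sprintf("#origin_y_um=%.17g", image$origin[2]))
  rows <- apply(image$grid, 1, function(r) {
    paste(ifelse(is.na(r), "", sprintf("%.17g", r)), collapse = ",")
  })
  writeLines(c(hdr, rows), path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_ion_image_csv
#' @export
read_ion_image_csv <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  is_hdr <- grepl("^#", lines)
  hdr <- list()
  for (h in lines[is_hdr]) {
    kv <- strsplit(sub("^#", "", h), "=", fixed = TRUE)[[1]]
    hdr[[kv[1]]] <- kv[2]
  }
  body <- lines[!is_hdr]
  grid <- do.call(rbind, lapply(body, function(r) {
    v <- strsplit(r, ",", fixed = TRUE)[[1]]
    suppressWarnings(as.numeric(ifelse(v == "", NA, v)))
  }))
  ion_image(hdr$transition_id, grid,
            pixel_w_um = as.numeric(hdr$pixel_w_um),
            pixel_h_um = as.numeric(hdr$pixel_h_um),
            origin = c(as.numeric(hdr$origin_x_um %||% 0),
                       as.numeric(hdr$origin_y_um %||% 0)))
}
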