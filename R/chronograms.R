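#' Bundle chronograms into a line-scan set
#'
#' A chronogram is the intensity-versus-time trace of one MRM transition along
#' one line scan; a `line_scan_set` holds every (line, transition) chronogram
#' of an acquisition together with its [acquisition_config()]. This is the raw
#' data model the rest of the toolkit consumes.
#'
#' @param config An [acquisition_config()].
#' @param data Tibble with columns `line_index` (0-based), `transition_id`,
#'   `scan_index` (0-based), `time_s`, `intensity`.
#' @param normalized Logical; `TRUE` once intensities are counts/s (see
#'   [normalize_dwell()]).
#' @param metadata Free-form provenance list.
#' @return An object of class `line_scan_set`.
#' @export
line_scan_set <- function(config, data, normalized = FALSE,
                          metadata = list()) {
  stopifnot(inherits(config, "acq_config"))
  data <- as_tibble(data)
  attr(data, "out.attrs") <- NULL  # canonical form regardless of source
  need <- c("line_index", "transition_id", "scan_index", "time_s", "intensity")
  miss <- setdiff(need, names(data))
  if (length(miss)) abort(paste("chronogram data missing columns:",
                                paste(miss, collapse = ", ")))
  data$line_index <- as.integer(data$line_index)
  data$scan_index <- as.integer(data$scan_index)
  unknown <- setdiff(unique(data$transition_id), config$transitions$id)
  if (length(unknown)) {
    abort(paste("unknown transition ids:", paste(unknown, collapse = ", ")))
  }
  if (any(data$intensity < 0)) abort("intensities must be non-negative")
  if (anyDuplicated(data[c("line_index", "transition_id", "scan_index")])) {
    abort("duplicate (line_index, transition_id, scan_index) rows")
  }
  data <- arrange(data, .data$line_index, .data$transition_id,
                  .data$scan_index)
  bad_time <- data |>
    group_by(.data$line_index, .data$transition_id) |>
    summarise(ok = all(diff(.data$time_s) > 0) || n() == 1L,
              .groups = "drop")
  if (!all(bad_time$ok)) abort("scan times must be strictly increasing")
  counts <- data |>
    group_by(.data$line_index, .data$transition_id) |>
    summarise(n = n(), .groups = "drop") |>
    group_by(.data$line_index) |>
    summarise(ok = length(unique(.data$n)) == 1L, .groups = "drop")
  if (!all(counts$ok)) {
    abort("all chronograms of one line must share the scan count")
  }
  structure(list(config = config, data = data, normalized = normalized,
                 metadata = metadata),
            class = "line_scan_set")
}

#' @export
print.line_scan_set <- function(x, ...) {
  cat(sprintf(
    "<line_scan_set> %d lines x %d transitions, %d scans (%s)\n",
    length(unique(x$data$line_index)),
    length(unique(x$data$transition_id)),
    nrow(x$data),
    if (x$normalized) "counts/s" else "raw counts"))
  invisible(x)
}

#' @method as_tibble line_scan_set
#' @export
as_tibble.line_scan_set <- function(x, ...) x$data

#' Normalize chronogram intensities to dwell time
#'
#' Divides each intensity (counts accumulated over the transition's dwell
#' window) by the dwell time in seconds, giving counts/s. After this
#' correction analyte abundances are comparable across scan speeds. The
#' operation is flagged on the set and applying it twice is an error.
#'
#' @param x A [line_scan_set()].
#' @return The set with intensities in counts/s and `normalized = TRUE`.
#' @export
#' @examples
#' # 190 counts at 59 ms dwell -> 3220.3 counts/s
#' 190 / 0.059
normalize_dwell <- function(x) {
  stopifnot(inherits(x, "line_scan_set"))
  if (isTRUE(x$normalized)) abort("chronograms are already dwell-normalized")
  dw <- setNames(x$config$transitions$dwell_ms, x$config$transitions$id)
  x$data$intensity <- x$data$intensity /
    unname(dw[x$data$transition_id] / 1000)
  x$normalized <- TRUE
  x
}

# ---- chronogram CSV dialect --------------------------------------------
# header block of "#key=value" lines, then columns
# line_index,transition_id,scan_index,time_s,intensity (UTF-8, "." decimal)

#' Read and write chronogram files
#'
#' Plain-text chronogram interchange: a header block of `#key=value` lines
#' carrying the acquisition geometry, then CSV columns
#' `line_index,transition_id,scan_index,time_s,intensity`. Writing then
#' reading reproduces intensities bit-exactly and times to 1 us; row order in
#' the file is irrelevant (rows are re-keyed on read).
#'
#' @param path File path.
#' @param config An [acquisition_config()] naming the valid transitions.
#' @param x A [line_scan_set()].
#' @return `read_chronograms()` a [line_scan_set()]; `write_chronograms()`
#'   the path, invisibly.
#' @export
read_chronograms <- function(path, config) {
  lines <- readLines(path, encoding = "UTF-8")
  hdr_idx <- grep("^#", lines)
  hdr_idx <- hdr_idx[hdr_idx == seq_along(hdr_idx)]  # leading block only
  hdr <- list()
  for (h in lines[hdr_idx]) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) hdr[[trimws(kv[1])]] <- trimws(kv[2])
  }
  body <- lines[setdiff(seq_along(lines), hdr_idx)]
  if (!length(body)) abort(sprintf("%s: no data rows", path))
  header_line <- length(hdr_idx) + 1L
  cols <- strsplit(body[1], ",", fixed = TRUE)[[1]]
  need <- c("line_index", "transition_id", "scan_index", "time_s", "intensity")
  miss <- setdiff(need, cols)
  if (length(miss)) {
    abort(sprintf("%s:%d: missing columns: %s", path, header_line,
                  paste(miss, collapse = ", ")))
  }
  # base R parsing: strtod is correctly rounded, so intensities written at
  # 17 significant digits round-trip bit-exactly
  df <- as_tibble(utils::read.csv(
    text = paste(body, collapse = "\n"),
    colClasses = c(line_index = "integer", transition_id = "character",
                   scan_index = "integer", time_s = "numeric",
                   intensity = "numeric")))
  unknown <- setdiff(unique(df$transition_id), config$transitions$id)
  if (length(unknown)) {
    first <- which(df$transition_id %in% unknown)[1] + header_line
    abort(sprintf("%s:%d: unknown transition id '%s'", path, first,
                  df$transition_id[which(df$transition_id %in% unknown)[1]]))
  }
  key <- df[c("line_index", "transition_id", "scan_index")]
  if (anyDuplicated(key)) {
    first <- which(duplicated(key))[1] + header_line
    abort(sprintf("%s:%d: duplicate (line, transition, scan) row", path,
                  first))
  }
  ord <- order(df$line_index, df$transition_id, df$scan_index)
  bad <- df[ord, ] |>
    group_by(.data$line_index, .data$transition_id) |>
    summarise(ok = all(diff(.data$time_s) > 0) || n() == 1L,
              .groups = "drop")
  if (!all(bad$ok)) {
    abort(sprintf("%s: non-monotone scan times for line %d, transition '%s'",
                  path, bad$line_index[!bad$ok][1],
                  bad$transition_id[!bad$ok][1]))
  }
  line_scan_set(config, df,
                normalized = identical(hdr$normalized, "TRUE"),
                metadata = hdr[setdiff(names(hdr), "normalized")])
}

#' @rdname read_chronograms
#' @export
write_chronograms <- function(x, path) {
  stopifnot(inherits(x, "line_scan_set"))
  cfg <- x$config
  hdr <- c(
    sprintf("#stage_speed_um_s=%.17g", cfg$stage_speed_um_s),
    sprintf("#line_spacing_um=%.17g", cfg$line_spacing_um),
    sprintf("#line_length_um=%.17g", cfg$line_length_um),
    sprintf("#n_lines=%d", cfg$n_lines),
    sprintf("#inter_transition_ms=%.17g", cfg$inter_transition_ms),
    sprintf("#per_scan_ms=%.17g", cfg$per_scan_ms),
    sprintf("#scan_direction=%s", cfg$scan_direction),
    sprintf("#normalized=%s", x$normalized)
  )
  d <- x$data
  rows <- sprintf("%d,%s,%d,%.9f,%.17g", d$line_index, d$transition_id,
                  d$scan_index, d$time_s, d$intensity)
  writeLines(c(hdr, "line_index,transition_id,scan_index,time_s,intensity",
               rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read and write transition tables
#'
#' CSV mirror of a printed MRM method table with columns
#' `id,analyte,class,polarity,precursor_mz,product_mz,collision_energy,dwell_ms`.
#'
#' @param path File path.
#' @param transitions A transition tibble, see [transition_table()].
#' @return `read_transition_table()` a validated transition tibble.
#' @export
read_transition_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), analyte = readr::col_character(),
    class = readr::col_character(), polarity = readr::col_character(),
    precursor_mz = readr::col_double(), product_mz = readr::col_double(),
    collision_energy = readr::col_double(), dwell_ms = readr::col_double()))
  names(df)[names(df) == "class"] <- "analyte_class"
  validate_transitions(df[c("id", "analyte", "analyte_class", "precursor_mz",
                            "product_mz", "polarity", "collision_energy",
                            "dwell_ms")])
}

#' @rdname read_transition_table
#' @export
write_transition_table <- function(transitions, path) {
  tr <- validate_transitions(transitions)
  out <- tr[c("id", "analyte", "analyte_class", "polarity", "precursor_mz",
              "product_mz", "collision_energy", "dwell_ms")]
  names(out)[names(out) == "analyte_class"] <- "class"
  readr::write_csv(out, path)
  invisible(path)
}
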