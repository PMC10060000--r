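#' Build an MRM transition table
#'
#' A transition is one precursor/product m/z pair monitored on the triple
#' quadrupole; each transition yields one intensity value per scan cycle and
#' therefore one image channel. Vectorised over all arguments.
#'
#' @param id Short unique label per transition.
#' @param analyte Analyte name.
#' @param analyte_class One of `"drug"`, `"lipid"`, `"other"`. Drug-like
#'   compounds dissolve fast in the spray solvent, structural lipids slowly;
#'   the simulator keys its default kinetics off this class.
#' @param precursor_mz,product_mz m/z of the precursor and product ion (Th).
#' @param polarity `"+"` or `"-"`.
#' @param collision_energy Collision energy (V).
#' @param dwell_ms Dwell time per transition per cycle (ms).
#' @return A tibble with one row per transition.
#' @export
#' @examples
#' transition_table(
#'   id = c("terf", "pc342"), analyte = c("terfenadine", "PC(34:2)"),
#'   analyte_class = c("drug", "lipid"),
#'   precursor_mz = c(472.3, 758.6), product_mz = c(436.3, 184.1),
#'   dwell_ms = 3
#' )
transition_table <- function(id, analyte = id, analyte_class = "other",
                             precursor_mz, product_mz, polarity = "+",
                             collision_energy = 20, dwell_ms = 9) {
  tr <- tibble(
    id = as.character(id), analyte = as.character(analyte),
    analyte_class = as.character(analyte_class),
    precursor_mz = as.numeric(precursor_mz),
    product_mz = as.numeric(product_mz),
    polarity = as.character(polarity),
    collision_energy = as.numeric(collision_energy),
    dwell_ms = as.numeric(dwell_ms)
  )
  validate_transitions(tr)
}

validate_transitions <- function(tr) {
  if (!is.data.frame(tr) || nrow(tr) == 0) abort("no transitions")
  need <- c("id", "analyte", "analyte_class", "precursor_mz", "product_mz",
            "polarity", "collision_energy", "dwell_ms")
  miss <- setdiff(need, names(tr))
  if (length(miss)) abort(paste("transition table missing columns:",
                                paste(miss, collapse = ", ")))
  if (anyDuplicated(tr$id)) abort("transition ids must be unique")
  if (any(tr$precursor_mz <= 0) || any(tr$product_mz <= 0)) {
    abort("precursor_mz and product_mz must be > 0")
  }
  if (any(tr$dwell_ms <= 0)) abort("dwell_ms must be > 0")
  if (!all(tr$analyte_class %in% c("drug", "lipid", "other"))) {
    abort("analyte_class must be drug, lipid or other")
  }
  if (!all(tr$polarity %in% c("+", "-"))) abort("polarity must be '+' or '-'")
  as_tibble(tr)
}

#' Describe an MRM line-scan acquisition
#'
#' Bundles the transition list with the cycle timing and stage geometry of a
#' line-by-line DESI imaging run. The scan cycle visits every transition once;
#' its period sets the pixel pitch along the scan axis through the stage
#' speed.
#'
#' @param transitions Transition tibble, see [transition_table()].
#' @param inter_transition_ms Per-transition switching overhead (ms). The
#'   default 3.25 ms makes 16 transitions at 3 ms dwell cycle at 10 scans/s,
#'   matching the published dwell-to-rate pairing (59/27/9/3 ms for
#'   1/2/5/10 pixel/s).
#' @param per_scan_ms Fixed per-cycle overhead (ms).
#' @param stage_speed_um_s Stage speed (um/s).
#' @param line_spacing_um Distance between adjacent line scans (um); this is
#'   the pixel height.
#' @param line_length_um Length of each line (um).
#' @param n_lines Number of line scans.
#' @param scan_direction `"unidirectional"` (separate line scans, the default)
#'   or `"serpentine"`.
#' @return An object of class `acq_config`.
#' @export
#' @examples
#' cfg <- acquisition_config(demo_transitions(), stage_speed_um_s = 100)
#' scan_rate_hz(cfg)
#' pixel_width_um(cfg)
acquisition_config <- function(transitions,
                               inter_transition_ms = 3.25,
                               per_scan_ms = 0,
                               stage_speed_um_s = 100,
                               line_spacing_um = 100,
                               line_length_um = 2000,
                               n_lines = 25,
                               scan_direction = c("unidirectional",
                                                  "serpentine")) {
  transitions <- validate_transitions(transitions)
  assert_scalar_num(inter_transition_ms, "inter_transition_ms", nonneg = TRUE)
  assert_scalar_num(per_scan_ms, "per_scan_ms", nonneg = TRUE)
  assert_scalar_num(stage_speed_um_s, "stage_speed_um_s", positive = TRUE)
  assert_scalar_num(line_spacing_um, "line_spacing_um", positive = TRUE)
  assert_scalar_num(line_length_um, "line_length_um", positive = TRUE)
  assert_scalar_num(n_lines, "n_lines", positive = TRUE)
  structure(
    list(transitions = transitions,
         inter_transition_ms = inter_transition_ms,
         per_scan_ms = per_scan_ms,
         stage_speed_um_s = stage_speed_um_s,
         line_spacing_um = line_spacing_um,
         line_length_um = line_length_um,
         n_lines = as.integer(n_lines),
         scan_direction = match.arg(scan_direction)),
    class = "acq_config"
  )
}

#' @export
print.acq_config <- function(x, ...) {
  cat(sprintf(
    "<acq_config> %d transitions | cycle %.4g s (%.3g scans/s) | %g um/s | %d lines x %g um (pixel %.3g x %g um)\n",
    nrow(x$transitions), scan_period_s(x), scan_rate_hz(x),
    x$stage_speed_um_s, x$n_lines, x$line_length_um,
    pixel_width_um(x), x$line_spacing_um))
  invisible(x)
}

#' Scan-cycle period, rate and pixel size
#'
#' `scan_period_s()` is the duration of one full MRM cycle:
#' sum over transitions of (dwell + switching overhead), plus the fixed
#' per-cycle overhead. `scan_rate_hz()` is its reciprocal — with a moving
#' stage, one cycle is one pixel along the scan axis. `pixel_width_um()` is
#' stage speed times cycle period: at 100 um/s and 1 scan/s every spectrum
#' covers 100 um of sample.
#'
#' @param config An [acquisition_config()].
#' @return A single number (seconds, Hz, or um).
#' @export
scan_period_s <- function(config) {
  stopifnot(inherits(config, "acq_config"))
  if (nrow(config$transitions) == 0) abort("no transitions")
  sum(config$transitions$dwell_ms + config$inter_transition_ms) / 1000 +
    config$per_scan_ms / 1000
}

#' @rdname scan_period_s
#' @export
scan_rate_hz <- function(config) 1 / scan_period_s(config)

#' @rdname scan_period_s
#' @export
pixel_width_um <- function(config) {
  config$stage_speed_um_s * scan_period_s(config)
}

#' Number of scan cycles per line
#' @param config An [acquisition_config()].
#' @return Integer count of pixels along the scan axis.
#' @export
scans_per_line <- function(config) {
  max(1L, as.integer(floor(config$line_length_um / pixel_width_um(config))))
}

#' A small demonstration transition set
#'
#' Four drug-like and three lipid-like channels loosely modelled on a
#' cassette-dosing experiment (terfenadine-, erlotinib-, olanzapine-,
#' moxifloxacin-like drugs; phosphatidylcholine-like structural lipids).
#'
#' @param dwell_ms Dwell time applied to every transition (ms).
#' @return A transition tibble.
#' @export
demo_transitions <- function(dwell_ms = 9) {
  transition_table(
    id = c("drugA", "drugB", "drugC", "drugD", "lipA", "lipB", "lipC"),
    analyte = c("terfenadine-like", "erlotinib-like", "olanzapine-like",
                "moxifloxacin-like", "PC(34:1)-like", "PC(36:2)-like",
                "PC(36:4)-like"),
    analyte_class = c(rep("drug", 4), rep("lipid", 3)),
    precursor_mz = c(472.3, 394.2, 313.2, 402.2, 760.6, 786.6, 782.6),
    product_mz = c(436.3, 278.1, 256.1, 384.2, 184.1, 184.1, 184.1),
    collision_energy = c(25, 28, 25, 22, 30, 30, 30),
    dwell_ms = dwell_ms
  )
}
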