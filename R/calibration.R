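#' Pixel-to-millimeter calibration
#'
#' A bitewing radiograph pipeline reports ACH in millimeters; the conversion
#' factor depends on the sensor and acquisition geometry and must be supplied
#' by the user -- there is no safe default.
#'
#' @param mm_per_px millimeters per pixel, strictly positive.
#' @return an object of class `calibration`.
#' @examples
#' px_to_mm(50, calibration(0.1))  # 5 mm
#' @export
calibration <- function(mm_per_px) {
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1 ||
      !is.finite(mm_per_px) || mm_per_px <= 0)
    stop_achr("mm_per_px must be a single positive finite number",
              class = "achr_domain_error")
  structure(list(mm_per_px = as.numeric(mm_per_px)), class = "calibration")
}

#' Convert a pixel distance to millimeters
#'
#' @param d_px non-negative distance(s) in pixels.
#' @param cal a [calibration()] object (or a bare positive scalar).
#' @return `d_px * mm_per_px`.
#' @export
px_to_mm <- function(d_px, cal) {
  if (!inherits(cal, "calibration")) cal <- calibration(cal)
  if (any(!is.finite(d_px)) || any(d_px < 0))
    stop_achr("pixel distances must be finite and non-negative",
              class = "achr_domain_error")
  d_px * cal$mm_per_px
}

#' Pipeline configuration
#'
#' Collects the tunable parameters of the ACH measurement pipeline.
#' `mm_per_px` has no default and must always be given (see
#' [calibration()]); everything else defaults to the standard settings.
#'
#' @param mm_per_px millimeters per pixel (required, > 0).
#' @param severity_threshold_mm ACH threshold separating severe from
#'   non-severe bone loss, in mm (default 5).
#' @param severity_rule `"ge"` (severe iff ACH >= threshold, the default) or
#'   `"gt"` (severe iff ACH > threshold). The two conventions differ only
#'   when a measurement hits the threshold exactly.
#' @param fusion_radius_px dedup radius for dual-detector landmark fusion in
#'   pixels (default 30, half the 60 px annotation-box side); also the
#'   half-width of the per-tooth side windows used for site pairing.
#' @param curve_degree polynomial degree for the arch curves (default 2).
#' @param min_tooth_area_px minimum connected-component area to count as a
#'   tooth (default 200).
#' @param crossing_tolerance_px tolerance band, in pixels, for the
#'   outline/curve crossing gate (default 1).
#' @param seed integer seed for any stochastic step (default 1).
#' @param verbose emit per-stage counts on stderr (default `FALSE`).
#' @return an object of class `ach_config`.
#' @export
ach_config <- function(mm_per_px,
                       severity_threshold_mm = 5.0,
                       severity_rule = c("ge", "gt"),
                       fusion_radius_px = 30,
                       curve_degree = 2,
                       min_tooth_area_px = 200,
                       crossing_tolerance_px = 1.0,
                       seed = 1L,
                       verbose = FALSE) {
  severity_rule <- match.arg(severity_rule)
  cal <- calibration(mm_per_px)
  num1 <- function(v, name, int = FALSE) {
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop_achr(name, " must be a single positive number",
                class = "achr_domain_error")
    if (int) as.integer(v) else as.numeric(v)
  }
  structure(list(
    mm_per_px = cal$mm_per_px,
    severity_threshold_mm = num1(severity_threshold_mm, "severity_threshold_mm"),
    severity_rule = severity_rule,
    fusion_radius_px = num1(fusion_radius_px, "fusion_radius_px"),
    curve_degree = num1(curve_degree, "curve_degree", int = TRUE),
    min_tooth_area_px = num1(min_tooth_area_px, "min_tooth_area_px", int = TRUE),
    crossing_tolerance_px = num1(crossing_tolerance_px, "crossing_tolerance_px"),
    seed = as.integer(seed),
    verbose = isTRUE(verbose)
  ), class = "ach_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys present in the file override the defaults of [ach_config()]; an
#' empty file yields the same configuration as programmatic construction
#' with defaults. `mm_per_px` must come from either the file or the
#' `mm_per_px` argument.
#'
#' @param path YAML file path.
#' @param mm_per_px calibration used when the file does not provide one.
#' @return an `ach_config`.
#' @export
read_ach_config <- function(path, mm_per_px = NULL) {
  if (!file.exists(path))
    stop_achr("config file not found: ", path, class = "achr_io_error")
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  if (!is.null(mm_per_px) && is.null(vals$mm_per_px))
    vals$mm_per_px <- mm_per_px
  if (is.null(vals$mm_per_px))
    stop_achr("mm_per_px missing: it must be given in the config file or ",
              "as an argument (no default calibration exists)",
              class = "achr_domain_error")
  keep <- intersect(names(vals), names(formals(ach_config)))
  do.call(ach_config, vals[keep])
}

#' @export
print.ach_config <- function(x, ...) {
  cat("ACH pipeline configuration\n")
  cat(sprintf("  calibration:     %g mm/px\n", x$mm_per_px))
  cat(sprintf("  severity:        %s %g mm\n",
              if (x$severity_rule == "ge") ">=" else ">",
              x$severity_threshold_mm))
  cat(sprintf("  fusion radius:   %g px\n", x$fusion_radius_px))
  cat(sprintf("  curve degree:    %d\n", x$curve_degree))
  cat(sprintf("  min tooth area:  %d px\n", x$min_tooth_area_px))
  cat(sprintf("  crossing tol:    %g px\n", x$crossing_tolerance_px))
  invisible(x)
}
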