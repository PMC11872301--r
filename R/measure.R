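#' Classify periodontal bone-loss severity
#'
#' The clinical dichotomy: an alveolar crestal height below 5 mm is not
#' severe, at or above 5 mm severe (`rule = "ge"`, the default). The
#' alternative printed convention `rule = "gt"` (severe strictly above the
#' threshold) differs only when the measurement equals the threshold
#' exactly.
#'
#' @param ach_mm non-negative ACH value(s) in millimeters.
#' @param threshold_mm severity threshold in mm (default 5).
#' @param rule `"ge"` or `"gt"`.
#' @return logical, `TRUE` for severe.
#' @examples
#' classify_severity(c(4.99, 5, 5.01))            # FALSE TRUE TRUE
#' classify_severity(5, rule = "gt")              # FALSE
#' @export
classify_severity <- function(ach_mm, threshold_mm = 5.0, rule = c("ge", "gt")) {
  rule <- match.arg(rule)
  if (any(!is.finite(ach_mm)) || any(ach_mm < 0))
    stop_achr("ach_mm must be finite and non-negative",
              class = "achr_domain_error")
  if (rule == "ge") ach_mm >= threshold_mm else ach_mm > threshold_mm
}

empty_measurements <- function() {
  data.frame(image_id = character(), tooth_id = integer(), site = character(),
             cej_x = numeric(), cej_y = numeric(),
             abcl_x = numeric(), abcl_y = numeric(),
             ach_px = numeric(), ach_mm = numeric(), severe = logical(),
             stringsAsFactors = FALSE)
}

#' Measure ACH at the two sides of one tooth
#'
#' For each tooth side (left: columns within `fusion_radius_px` of `x_min`;
#' right: within `fusion_radius_px` of `x_max` -- proxies for the mesial and
#' distal surfaces, whose true identity would need tooth numbering) the
#' fused, arch-partitioned landmarks whose `x` falls in the side window are
#' searched for a CEJ and an ABCL. Among candidates, the one nearest to the
#' tooth's outline on that side is taken, which keeps a spurious detection
#' floating far from the flank from displacing the anatomical point. If
#' both a CEJ and an ABCL are found, ACH is their Euclidean distance; a
#' side lacking either landmark yields no measurement.
#'
#' @param tooth a `tooth_instance` that passed the crossing gate.
#' @param landmarks_in_arch fused landmarks of the tooth's arch.
#' @param cal a [calibration()] object (or mm-per-px scalar).
#' @param config an [ach_config()].
#' @param image_id identifier copied into the output rows.
#' @return measurement data frame with 0-2 rows (see
#'   [write_measurements()] for the schema).
#' @export
measure_tooth_ach <- function(tooth, landmarks_in_arch, cal, config,
                              image_id = "image") {
  if (!inherits(cal, "calibration")) cal <- calibration(cal)
  lm <- validate_landmarks(landmarks_in_arch)
  w <- config$fusion_radius_px
  out <- empty_measurements()
  sides <- list(left = tooth$x_min, right = tooth$x_max)
  for (side in names(sides)) {
    x_side <- sides[[side]]
    in_win <- lm$x >= x_side - w & lm$x <= x_side + w
    ol <- tooth$outline
    ol_win <- ol[ol[, "x"] >= x_side - w & ol[, "x"] <= x_side + w, ,
                 drop = FALSE]
    if (nrow(ol_win) == 0) ol_win <- ol
    pick <- function(cl) {
      cand <- lm[in_win & lm$cls == cl, , drop = FALSE]
      if (nrow(cand) == 0) return(NULL)
      d <- vapply(seq_len(nrow(cand)), function(i)
        min((ol_win[, "x"] - cand$x[i])^2 + (ol_win[, "y"] - cand$y[i])^2),
        numeric(1))
      cand[which.min(d), , drop = FALSE]
    }
    cej <- pick("CEJ"); abcl <- pick("ABCL")
    if (is.null(cej) || is.null(abcl)) next
    ach_px <- sqrt((cej$x - abcl$x)^2 + (cej$y - abcl$y)^2)
    ach_mm <- px_to_mm(ach_px, cal)
    out <- rbind(out, data.frame(
      image_id = image_id, tooth_id = tooth$tooth_id, site = side,
      cej_x = cej$x, cej_y = cej$y, abcl_x = abcl$x, abcl_y = abcl$y,
      ach_px = ach_px, ach_mm = ach_mm,
      severe = classify_severity(ach_mm, config$severity_threshold_mm,
                                 config$severity_rule),
      stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Measure alveolar crestal height on a bitewing radiograph
#'
#' The full measurement pipeline, composed deterministically:
#' \enumerate{
#'   \item fuse the two detectors' landmarks ([fuse_landmarks()]);
#'   \item fit the arch partition line through the ABCL mask
#'     ([fit_partition_line()]) and split landmarks into arches;
#'   \item fit four polynomial arch curves (ABCL and CEJ in each arch);
#'   \item merge the two teeth masks and extract tooth instances;
#'   \item assign each tooth to the arch holding the majority of its pixels
#'     relative to the partition line;
#'   \item gate each tooth on [tooth_crosses_curves()];
#'   \item measure ACH per tooth side ([measure_tooth_ach()]) and classify
#'     severity.
#' }
#' Stages with insufficient data (no crest pixels, too few landmarks in an
#' arch) degrade gracefully: affected teeth are skipped with a log entry,
#' and the result may hold zero measurements, but the call never fails on
#' structurally valid input.
#'
#' @param landmarks_a,landmarks_b landmark data frames from the two
#'   detectors (see [landmarks()], [read_landmarks()]).
#' @param teeth_mask_1,teeth_mask_2 logical teeth masks of identical shape.
#' @param abcl_mask logical bone-crest mask of the same shape.
#' @param config an [ach_config()] (carries the mm-per-px calibration).
#' @param image optional grayscale image matrix, kept for [plot.ach_fit()].
#' @param image_id identifier used in the measurement table.
#' @return an object of class `ach_fit` with components `measurements`
#'   (data frame), `partition_line`, `curves` (named list
#'   `upper_ABCL`, `upper_CEJ`, `lower_ABCL`, `lower_CEJ`; entries may be
#'   `NULL` when an arch lacks landmarks), `teeth` (tooth instances with
#'   arch assignment and gate flag), `landmarks` (fused), `config`, `log`.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 7))
#' det <- oracle_detect(ph$truth, noise_params())
#' fit <- ach_measure(det$landmarks_a, det$landmarks_b,
#'                    det$teeth_mask_1, det$teeth_mask_2, det$abcl_mask,
#'                    config = ach_config(mm_per_px = 0.1))
#' fit
#' @export
ach_measure <- function(landmarks_a, landmarks_b,
                        teeth_mask_1, teeth_mask_2, abcl_mask,
                        config, image = NULL, image_id = "image") {
  stopifnot(inherits(config, "ach_config"))
  if (!identical(dim(teeth_mask_1), dim(teeth_mask_2)) ||
      !identical(dim(teeth_mask_1), dim(abcl_mask)))
    stop_achr("teeth and ABCL masks must share one shape",
              class = "achr_dimension_error")
  logline <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    logline <<- c(logline, msg)
    if (config$verbose) message("[achr] ", msg)
  }

  fused <- fuse_landmarks(landmarks_a, landmarks_b,
                          fusion_params(config$fusion_radius_px))
  note("fusion: %d + %d detections -> %d landmarks",
       nrow(landmarks_a), nrow(landmarks_b), nrow(fused))

  line <- tryCatch(fit_partition_line(abcl_mask),
                   achr_degenerate_error = function(e) NULL)
  curves <- list(upper_ABCL = NULL, upper_CEJ = NULL,
                 lower_ABCL = NULL, lower_CEJ = NULL)
  parts <- NULL
  if (is.null(line)) {
    note("partition: too few ABCL pixels; no measurements possible")
  } else {
    note("partition line: y = %.4g x + %.4g", line$slope, line$intercept)
    parts <- partition_landmarks(fused, line)
    note("landmarks per arch: upper %d, lower %d",
         nrow(parts$upper), nrow(parts$lower))
    for (arch in c("upper", "lower")) for (cl in ACH_CLASSES) {
      pts <- parts[[arch]][parts[[arch]]$cls == cl, c("x", "y"), drop = FALSE]
      cv <- tryCatch(fit_arch_curve(pts, arch, cl, config$curve_degree),
                     achr_degenerate_error = function(e) NULL)
      if (is.null(cv)) note("arch curve %s %s: too few points, skipped", arch, cl)
      curves[[paste(arch, cl, sep = "_")]] <- cv
    }
  }

  teeth_mask <- merge_teeth_masks(teeth_mask_1, teeth_mask_2)
  teeth <- extract_tooth_instances(teeth_mask, config$min_tooth_area_px)
  note("teeth: %d instance(s) >= %d px", length(teeth), config$min_tooth_area_px)

  measurements <- empty_measurements()
  if (!is.null(line) && length(teeth)) {
    for (i in seq_along(teeth)) {
      tooth <- teeth[[i]]
      n_up <- sum(tooth$pixels[, "y"] <= line_y(line, tooth$pixels[, "x"]))
      tooth$arch <- if (n_up >= tooth$area_px - n_up) "upper" else "lower"
      abcl_cv <- curves[[paste(tooth$arch, "ABCL", sep = "_")]]
      cej_cv <- curves[[paste(tooth$arch, "CEJ", sep = "_")]]
      tooth$gate <- !is.null(abcl_cv) && !is.null(cej_cv) &&
        tooth_crosses_curves(tooth, abcl_cv, cej_cv,
                             config$crossing_tolerance_px)
      teeth[[i]] <- tooth
      if (!tooth$gate) {
        note("tooth %d (%s): fails crossing gate, skipped",
             tooth$tooth_id, tooth$arch)
        next
      }
      m <- measure_tooth_ach(tooth, parts[[tooth$arch]],
                             calibration(config$mm_per_px), config, image_id)
      if (nrow(m) < 2)
        note("tooth %d (%s): %d of 2 sides had a CEJ/ABCL pair",
             tooth$tooth_id, tooth$arch, nrow(m))
      measurements <- rbind(measurements, m)
    }
  }
  rownames(measurements) <- NULL
  note("measurements: %d site(s), %d severe",
       nrow(measurements), sum(measurements$severe))

  structure(list(measurements = measurements, partition_line = line,
                 curves = curves, teeth = teeth, landmarks = fused,
                 config = config, image = image, image_id = image_id,
                 log = logline),
            class = "ach_fit")
}

#' @export
print.ach_fit <- function(x, ...) {
  cat("Alveolar crestal height measurement --", x$image_id, "\n")
  cat(sprintf("  %d fused landmark(s), %d tooth instance(s), %d measured site(s)\n",
              nrow(x$landmarks), length(x$teeth), nrow(x$measurements)))
  if (nrow(x$measurements)) {
    cat(sprintf("  ACH range %.2f - %.2f mm; %d site(s) severe (%s %g mm)\n",
                min(x$measurements$ach_mm), max(x$measurements$ach_mm),
                sum(x$measurements$severe),
                if (x$config$severity_rule == "ge") ">=" else ">",
                x$config$severity_threshold_mm))
  }
  invisible(x)
}

#' @export
summary.ach_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.ach_fit")
}

#' @export
print.summary.ach_fit <- function(x, ...) {
  fit <- x$fit
  print(fit)
  if (!is.null(fit$partition_line)) print(fit$partition_line)
  for (cv in fit$curves) if (!is.null(cv)) print(cv)
  if (nrow(fit$measurements)) {
    cat("measurements:\n")
    m <- fit$measurements
    m$ach_mm <- round(m$ach_mm, 3)
    m$ach_px <- round(m$ach_px, 2)
    print(m[c("tooth_id", "site", "ach_px", "ach_mm", "severe")],
          row.names = FALSE)
  }
  cat("pipeline log:\n")
  cat(paste0("  ", fit$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Arch-curve and partition-line coefficients of a fitted pipeline
#'
#' @param object an `ach_fit`.
#' @param ... ignored.
#' @return named list: `partition_line` (`c(intercept, slope)`) and one
#'   ascending-degree coefficient vector per fitted arch curve.
#' @export
coef.ach_fit <- function(object, ...) {
  out <- list()
  if (!is.null(object$partition_line))
    out$partition_line <- c(intercept = object$partition_line$intercept,
                            slope = object$partition_line$slope)
  for (nm in names(object$curves))
    if (!is.null(object$curves[[nm]])) out[[nm]] <- object$curves[[nm]]$coeffs
  out
}

#' Evaluate a fitted arch curve at new pixel columns
#'
#' @param object an `ach_fit`.
#' @param x pixel columns.
#' @param curve which curve: `"upper_ABCL"`, `"upper_CEJ"`, `"lower_ABCL"`
#'   or `"lower_CEJ"`.
#' @param ... ignored.
#' @return predicted pixel rows `y(x)`.
#' @export
predict.ach_fit <- function(object, x,
                            curve = c("upper_ABCL", "upper_CEJ",
                                      "lower_ABCL", "lower_CEJ"), ...) {
  curve <- match.arg(curve)
  cv <- object$curves[[curve]]
  if (is.null(cv))
    stop_achr("curve ", curve, " was not fitted (insufficient landmarks)",
              class = "achr_domain_error")
  predict(cv, x)
}

#' Plot a fitted ACH measurement
#'
#' Draws the radiograph (when one was supplied to [ach_measure()]) or a
#' blank frame, with the partition line, the four arch curves, and each
#' measured site as a CEJ-ABCL segment -- red for severe, green for
#' non-severe. The y axis is flipped to image convention (row 0 on top).
#'
#' @param x an `ach_fit`.
#' @param ... passed to the initial `plot()`.
#' @export
plot.ach_fit <- function(x, ...) {
  dims <- if (!is.null(x$image)) dim(x$image)
          else if (length(x$teeth)) {
            px <- do.call(rbind, lapply(x$teeth, `[[`, "pixels"))
            c(max(px[, "y"]) + 1, max(px[, "x"]) + 1)
          } else c(869, 1200)
  plot(NA, xlim = c(0, dims[2] - 1), ylim = c(dims[1] - 1, 0),
       xlab = "x (px)", ylab = "y (px)", main = x$image_id, asp = 1, ...)
  if (!is.null(x$image))
    graphics::rasterImage(x$image, 0, dims[1] - 1, dims[2] - 1, 0)
  xs <- seq(0, dims[2] - 1, length.out = 200)
  if (!is.null(x$partition_line))
    lines(xs, line_y(x$partition_line, xs), col = "cyan3", lty = 2)
  for (cv in x$curves) {
    if (is.null(cv)) next
    xr <- seq(cv$support[1], cv$support[2], length.out = 100)
    lines(xr, predict(cv, xr),
          col = if (cv$cls == "ABCL") "orange" else "yellow3")
  }
  m <- x$measurements
  if (nrow(m)) {
    cols <- ifelse(m$severe, "red", "green3")
    graphics::segments(m$cej_x, m$cej_y, m$abcl_x, m$abcl_y, col = cols, lwd = 2)
    text(m$cej_x, m$cej_y, sprintf("%.1f", m$ach_mm), col = cols,
         pos = 3, cex = 0.7)
  }
  invisible(x)
}
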