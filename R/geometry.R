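# Geometric core: arch partition line, per-arch polynomial curves, and the
# tooth-outline crossing gate.

# accept a logical mask or a 2-column x,y object and return an x,y matrix
as_xy_points <- function(obj) {
  if (is.logical(obj) && is.matrix(obj)) {
    idx <- which(obj, arr.ind = TRUE)
    return(cbind(x = idx[, 2] - 1, y = idx[, 1] - 1))
  }
  if (is.data.frame(obj)) obj <- as.matrix(obj[, c("x", "y")])
  stopifnot(is.matrix(obj), ncol(obj) >= 2)
  colnames(obj)[1:2] <- c("x", "y")
  obj[, 1:2, drop = FALSE]
}

#' Fit the arch partition line
#'
#' A bitewing shows the maxillary (upper) and mandibular (lower) arches in
#' one frame. The separator is the ordinary-least-squares line
#' `y = slope * x + intercept` fitted through every bone-crest (ABCL)
#' foreground pixel, which for bitewing geometry falls between the two
#' arches' crests.
#'
#' @param abcl either a logical ABCL mask or a set of points (2-column
#'   matrix or data frame with `x`, `y`).
#' @return an object of class `partition_line` with fields `slope` and
#'   `intercept` (pixels).
#' @export
fit_partition_line <- function(abcl) {
  pts <- as_xy_points(abcl)
  if (nrow(pts) < 2 || length(unique(pts[, "x"])) < 2)
    stop_achr("partition line needs at least 2 points with 2 distinct x values",
              class = "achr_degenerate_error")
  fit <- lsfit(pts[, "x"], pts[, "y"])
  structure(list(slope = unname(fit$coefficients[2]),
                 intercept = unname(fit$coefficients[1])),
            class = "partition_line")
}

#' @export
print.partition_line <- function(x, ...) {
  cat(sprintf("partition line: y = %.4g x + %.4g\n", x$slope, x$intercept))
  invisible(x)
}

line_y <- function(line, x) line$slope * x + line$intercept

#' Split landmarks into upper and lower arches
#'
#' A landmark above the partition line (`y < slope * x + intercept`;
#' smaller `y` is higher in the image) is maxillary (`upper`), below it
#' mandibular (`lower`). A landmark exactly on the line goes to `upper`
#' (fixed tie-break).
#'
#' @param lm landmark data frame.
#' @param line a [fit_partition_line()] result.
#' @return `list(upper = , lower = )` of landmark data frames; their union
#'   is the input.
#' @export
partition_landmarks <- function(lm, line) {
  lm <- validate_landmarks(lm)
  up <- lm$y <= line_y(line, lm$x)
  list(upper = lm[up, , drop = FALSE], lower = lm[!up, , drop = FALSE])
}

polyval_asc <- function(coeffs, x) {
  # Horner, coefficients in ascending degree
  y <- rep(0, length(x))
  for (c_i in rev(coeffs)) y <- y * x + c_i
  y
}

#' Fit a polynomial arch curve
#'
#' Least-squares polynomial `y(x)` through the ABCL or CEJ points of one
#' arch, mirroring the gently curved occlusal plane. When fewer distinct
#' `x` values than `degree + 1` are available the degree is reduced to
#' `(distinct x) - 1` with a warning rather than failing, so sparse
#' detections still yield a usable curve.
#'
#' @param points 2-column matrix or data frame of `x`, `y` pixel
#'   coordinates.
#' @param arch `"upper"` or `"lower"`.
#' @param cls `"ABCL"` or `"CEJ"`.
#' @param degree requested polynomial degree (default 2).
#' @return an object of class `arch_curve`: `coeffs` in ascending degree
#'   (length `degree + 1`), `degree`, `arch`, `cls`, and `support` -- the
#'   fitted x-range.
#' @export
fit_arch_curve <- function(points, arch = c("upper", "lower"),
                           cls = c("ABCL", "CEJ"), degree = 2) {
  arch <- match.arg(arch); cls <- match.arg(cls)
  pts <- as_xy_points(points)
  nx <- length(unique(pts[, "x"]))
  if (nrow(pts) < 2 || nx < 2)
    stop_achr("arch curve needs at least 2 points with 2 distinct x values",
              class = "achr_degenerate_error")
  degree <- as.integer(degree)
  if (degree < 1) stop_achr("degree must be >= 1", class = "achr_domain_error")
  if (nx < degree + 1) {
    warning(sprintf("arch curve (%s %s): only %d distinct x; degree reduced %d -> %d",
                    arch, cls, nx, degree, nx - 1L))
    degree <- nx - 1L
  }
  x <- pts[, "x"]; y <- pts[, "y"]
  fit <- lm(y ~ poly(x, degree, raw = TRUE))
  coeffs <- unname(coef(fit))
  coeffs[is.na(coeffs)] <- 0
  structure(list(arch = arch, cls = cls, coeffs = coeffs,
                 degree = degree, support = range(x)),
            class = "arch_curve")
}

#' @export
print.arch_curve <- function(x, ...) {
  cat(sprintf("arch curve [%s %s], degree %d, support x in [%g, %g]\n",
              x$arch, x$cls, x$degree, x$support[1], x$support[2]))
  cat("  coeffs (ascending):", signif(x$coeffs, 6), "\n")
  invisible(x)
}

#' Evaluate an arch curve
#'
#' @param object an `arch_curve`.
#' @param x pixel columns at which to evaluate `y(x)`.
#' @param ... ignored.
#' @return predicted `y` (pixel rows).
#' @export
predict.arch_curve <- function(object, x, ...) polyval_asc(object$coeffs, x)

#' Does a tooth outline cross both arch curves?
#'
#' A tooth is measured only if its segmented outline crosses both its
#' arch's ABCL curve and its CEJ curve. Crossing holds for a curve when
#' either (a) some outline pixel with `x` inside the curve's support lies
#' within `tol_px` of the curve, or (b) at some tooth column the curve's
#' `y` falls strictly between the tooth's minimum and maximum `y` there
#' (sign-change crossing). The tolerance band makes constant curves that
#' graze an outline deterministic.
#'
#' @param tooth a `tooth_instance`.
#' @param abcl_curve,cej_curve `arch_curve` objects for the tooth's arch.
#' @param tol_px tolerance band in pixels (default 1).
#' @return `TRUE` iff the outline crosses both curves.
#' @export
tooth_crosses_curves <- function(tooth, abcl_curve, cej_curve, tol_px = 1.0) {
  crosses_one <- function(curve) {
    ol <- tooth$outline
    inside <- ol[, "x"] >= curve$support[1] & ol[, "x"] <= curve$support[2]
    if (any(inside)) {
      yc <- polyval_asc(curve$coeffs, ol[inside, "x"])
      if (any(abs(ol[inside, "y"] - yc) <= tol_px)) return(TRUE)
    }
    pix <- tooth$pixels
    cols <- sort(unique(pix[, "x"]))
    cols <- cols[cols >= curve$support[1] & cols <= curve$support[2]]
    if (!length(cols)) return(FALSE)
    ymin <- tapply(pix[, "y"], pix[, "x"], min)
    ymax <- tapply(pix[, "y"], pix[, "x"], max)
    key <- as.character(cols)
    yc <- polyval_asc(curve$coeffs, cols)
    any(yc > ymin[key] & yc < ymax[key])
  }
  crosses_one(abcl_curve) && crosses_one(cej_curve)
}
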