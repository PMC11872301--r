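# Raster overlay output: the measured ACH segments superimposed on the
# input radiograph, as the pipeline's user-facing image product.

# 3x5 bitmap glyphs for the mm labels (rows top-to-bottom, 1 = ink)
.achr_font <- list(
  "0" = c(1,1,1, 1,0,1, 1,0,1, 1,0,1, 1,1,1),
  "1" = c(0,1,0, 1,1,0, 0,1,0, 0,1,0, 1,1,1),
  "2" = c(1,1,1, 0,0,1, 1,1,1, 1,0,0, 1,1,1),
  "3" = c(1,1,1, 0,0,1, 0,1,1, 0,0,1, 1,1,1),
  "4" = c(1,0,1, 1,0,1, 1,1,1, 0,0,1, 0,0,1),
  "5" = c(1,1,1, 1,0,0, 1,1,1, 0,0,1, 1,1,1),
  "6" = c(1,1,1, 1,0,0, 1,1,1, 1,0,1, 1,1,1),
  "7" = c(1,1,1, 0,0,1, 0,1,0, 0,1,0, 0,1,0),
  "8" = c(1,1,1, 1,0,1, 1,1,1, 1,0,1, 1,1,1),
  "9" = c(1,1,1, 1,0,1, 1,1,1, 0,0,1, 1,1,1),
  "." = c(0,0,0, 0,0,0, 0,0,0, 0,0,0, 0,1,0)
)

set_px <- function(rgb, xs, ys, col) {
  h <- dim(rgb)[1]; w <- dim(rgb)[2]
  ok <- xs >= 0 & xs <= w - 1 & ys >= 0 & ys <= h - 1
  xs <- round(xs[ok]); ys <- round(ys[ok])
  for (k in 1:3) rgb[cbind(ys + 1, xs + 1, k)] <- col[k]
  rgb
}

draw_segment <- function(rgb, x0, y0, x1, y1, col) {
  n <- max(abs(x1 - x0), abs(y1 - y0), 1) + 1
  t <- seq(0, 1, length.out = ceiling(n))
  set_px(rgb, x0 + t * (x1 - x0), y0 + t * (y1 - y0), col)
}

draw_label <- function(rgb, x, y, label, col) {
  cx <- round(x)
  for (ch in strsplit(label, "")[[1]]) {
    g <- .achr_font[[ch]]
    if (!is.null(g)) {
      idx <- which(matrix(g, 5, 3, byrow = TRUE) == 1, arr.ind = TRUE)
      rgb <- set_px(rgb, cx + idx[, 2] - 1, round(y) + idx[, 1] - 1, col)
    }
    cx <- cx + 4
  }
  rgb
}

#' Render the measurement overlay
#'
#' Produces the pipeline's image output: the grayscale radiograph converted
#' to RGB, with each measured site drawn as a CEJ-to-ABCL segment plus a
#' numeric mm label (red for severe sites, green for non-severe), and
#' optionally the partition line (cyan) and arch curves (orange ABCL,
#' yellow CEJ). Fully deterministic: identical inputs give bit-identical
#' rasters.
#'
#' @param image grayscale matrix in `[0, 1]` (rows = y, cols = x).
#' @param measurements measurement data frame ([ach_measure()] schema).
#' @param curves optional list of `arch_curve`s (e.g. `fit$curves`).
#' @param line optional `partition_line`.
#' @return an `H x W x 3` numeric array in `[0, 1]`.
#' @export
render_overlay <- function(image, measurements, curves = NULL, line = NULL) {
  stopifnot(is.matrix(image))
  img <- pmin(pmax(image, 0), 1)
  rgb <- array(rep(img, 3), dim = c(nrow(img), ncol(img), 3))
  if (!is.null(line)) {
    xs <- 0:(ncol(img) - 1)
    rgb <- set_px(rgb, xs, line_y(line, xs), c(0, 0.8, 0.8))
  }
  for (cv in curves) {
    if (is.null(cv)) next
    xs <- seq(cv$support[1], cv$support[2], by = 0.5)
    col <- if (cv$cls == "ABCL") c(1, 0.6, 0) else c(0.9, 0.9, 0.2)
    rgb <- set_px(rgb, xs, polyval_asc(cv$coeffs, xs), col)
  }
  if (!is.null(measurements) && nrow(measurements)) {
    for (i in seq_len(nrow(measurements))) {
      m <- measurements[i, ]
      col <- if (isTRUE(m$severe)) c(1, 0.15, 0.15) else c(0.15, 1, 0.3)
      rgb <- draw_segment(rgb, m$cej_x, m$cej_y, m$abcl_x, m$abcl_y, col)
      rgb <- draw_label(rgb, (m$cej_x + m$abcl_x) / 2 + 4,
                        (m$cej_y + m$abcl_y) / 2 - 2,
                        sprintf("%.1f", m$ach_mm), col)
    }
  }
  rgb
}

#' Write an overlay (or any RGB array) as PNG
#'
#' @param rgb `H x W x 3` array in `[0, 1]`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_overlay_png <- function(rgb, path) {
  png::writePNG(rgb, path)
  invisible(path)
}
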