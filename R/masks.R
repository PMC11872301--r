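# Binary masks are logical matrices (rows = y, cols = x, 0-based pixel
# (x, y) at mask[y + 1, x + 1]); PNG files use 0 = background,
# 255 = foreground.

#' Read a binary mask from a single-channel PNG
#'
#' @param path PNG file; any channel value > 0.5 counts as foreground.
#' @return a logical matrix.
#' @export
read_mask_png <- function(path) {
  if (!file.exists(path))
    stop_achr("mask file not found: ", path, class = "achr_io_error")
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3) arr <- arr[, , 1]
  arr > 0.5
}

#' Write a binary mask as a single-channel PNG
#'
#' @param mask logical matrix.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  stopifnot(is.matrix(mask))
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}

#' Merge two teeth masks by pixel-wise union
#'
#' The two tooth-segmentation channels compensate for each other's misses;
#' their union is the working teeth mask.
#'
#' @param mask_1,mask_2 logical matrices of identical shape.
#' @return logical matrix, the union.
#' @export
merge_teeth_masks <- function(mask_1, mask_2) {
  if (!identical(dim(mask_1), dim(mask_2)))
    stop_achr("mask shapes differ: ", paste(dim(mask_1), collapse = "x"),
              " vs ", paste(dim(mask_2), collapse = "x"),
              class = "achr_dimension_error")
  mask_1 | mask_2
}

# 3x3-box binary erosion, applied `px` times (out-of-image is background)
erode_mask <- function(mask, px = 1L) {
  px <- as.integer(px)
  if (px <= 0) return(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  for (i in seq_len(px)) {
    padded <- matrix(FALSE, nr + 2, nc + 2)
    padded[2:(nr + 1), 2:(nc + 1)] <- mask
    m <- padded[2:(nr + 1), 2:(nc + 1)]
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      m <- m & padded[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    }
    mask <- m
  }
  mask
}

# boundary pixels: foreground with at least one 4-neighbor background
# (image border counts as background)
outline_mask <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2, nc + 2)
  padded[2:(nr + 1), 2:(nc + 1)] <- mask
  interior <- padded[1:nr, 2:(nc + 1)] & padded[3:(nr + 2), 2:(nc + 1)] &
    padded[2:(nr + 1), 1:nc] & padded[2:(nr + 1), 3:(nc + 2)]
  mask & !interior
}

# 8-connected component labels. EBImage::bwlabel is 4-connected, so labels
# that touch diagonally are merged afterwards with a small union-find.
label_components_8 <- function(mask) {
  lab <- EBImage::bwlabel(matrix(as.numeric(mask), nrow(mask), ncol(mask)))
  lab <- matrix(as.integer(lab), nrow(mask), ncol(mask))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  nr <- nrow(lab); nc <- ncol(lab)
  pairs <- rbind(
    cbind(as.vector(lab[1:(nr - 1), 1:(nc - 1)]), as.vector(lab[2:nr, 2:nc])),
    cbind(as.vector(lab[1:(nr - 1), 2:nc]), as.vector(lab[2:nr, 1:(nc - 1)]))
  )
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs)) {
    parent <- seq_len(nlab)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (k in seq_len(nrow(pairs))) {
      a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
      if (a != b) parent[max(a, b)] <- min(a, b)
    }
    root <- vapply(seq_len(nlab), find, integer(1))
    # compact to consecutive ids
    root <- match(root, sort(unique(root)))
    lab[lab > 0] <- root[lab[lab > 0]]
  }
  lab
}

#' Extract tooth instances from a teeth mask
#'
#' Finds 8-connected foreground components with area at least
#' `min_tooth_area_px`, orders them by leftmost column and assigns
#' `tooth_id` 1, 2, ... in that order. Each instance carries its pixel set,
#' its outline (foreground pixels with a 4-neighbor background) and its
#' column extents.
#'
#' @param teeth_mask logical matrix.
#' @param min_tooth_area_px minimum component area in pixels (default 200).
#' @return a list of class `tooth_instances`; each element is a
#'   `tooth_instance` list with fields `tooth_id`, `pixels` and `outline`
#'   (two-column `x`,`y` matrices, 0-based), `x_min`, `x_max`, `area_px`,
#'   and `arch` (`NA` until assigned by the pipeline).
#' @export
extract_tooth_instances <- function(teeth_mask, min_tooth_area_px = 200) {
  stopifnot(is.matrix(teeth_mask))
  if (!any(teeth_mask))
    return(structure(list(), class = "tooth_instances"))
  lab <- label_components_8(teeth_mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_tooth_area_px)
  if (!length(keep)) return(structure(list(), class = "tooth_instances"))
  out_mask <- outline_mask(teeth_mask)
  inst <- lapply(keep, function(l) {
    idx <- which(lab == l, arr.ind = TRUE)
    pix <- cbind(x = idx[, 2] - 1L, y = idx[, 1] - 1L)
    on_outline <- out_mask[idx]
    structure(list(
      tooth_id = NA_integer_,
      pixels = pix,
      outline = pix[on_outline, , drop = FALSE],
      arch = NA_character_,
      x_min = min(pix[, 1]), x_max = max(pix[, 1]),
      area_px = nrow(pix)
    ), class = "tooth_instance")
  })
  inst <- inst[order(vapply(inst, `[[`, numeric(1), "x_min"))]
  for (i in seq_along(inst)) inst[[i]]$tooth_id <- i
  structure(inst, class = "tooth_instances")
}

#' @export
print.tooth_instances <- function(x, ...) {
  cat(length(x), "tooth instance(s)\n")
  for (t in x)
    cat(sprintf("  tooth %d: area %d px, columns [%d, %d], arch %s\n",
                t$tooth_id, t$area_px, t$x_min, t$x_max, t$arch))
  invisible(x)
}
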