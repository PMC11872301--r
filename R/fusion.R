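#' Fusion parameters for dual-detector landmark merging
#'
#' @param radius_px dedup radius in pixels (default 30 -- half the 60 px
#'   annotation-box side used to mark ABCL/CEJ points).
#' @return an object of class `fusion_params`.
#' @export
fusion_params <- function(radius_px = 30) {
  if (!is.numeric(radius_px) || length(radius_px) != 1 || radius_px <= 0)
    stop_achr("radius_px must be a single positive number",
              class = "achr_domain_error")
  structure(list(radius_px = as.numeric(radius_px)), class = "fusion_params")
}

#' Fuse landmark detections from two detectors
#'
#' The two object-detection networks compensate for each other's misses in
#' different regions, so their outputs are pooled and deduplicated: within
#' each landmark class, greedy non-maximum suppression ordered by
#' descending confidence keeps the higher-confidence member of any pair
#' closer than `radius_px` (ties broken toward `dets_a`, then lower `x`,
#' then lower `y`). An ABCL never suppresses a CEJ and vice versa.
#'
#' @param dets_a,dets_b landmark data frames (see [landmarks()]).
#' @param params a [fusion_params()] object.
#' @return fused landmark data frame with `source = "fused"`, no two
#'   same-class points closer than `radius_px`, sorted by class, `x`, `y`.
#' @export
fuse_landmarks <- function(dets_a, dets_b, params = fusion_params()) {
  dets_a <- validate_landmarks(dets_a)
  dets_b <- validate_landmarks(dets_b)
  dets_a$.chan <- rep(1L, nrow(dets_a))
  dets_b$.chan <- rep(2L, nrow(dets_b))
  pool <- rbind(dets_a, dets_b)
  if (nrow(pool) == 0) {
    pool$.chan <- NULL
    return(pool)
  }
  keep_all <- lapply(ACH_CLASSES, function(cl) {
    sub <- pool[pool$cls == cl, , drop = FALSE]
    if (nrow(sub) == 0) return(sub)
    sub <- sub[order(-sub$confidence, sub$.chan, sub$x, sub$y), , drop = FALSE]
    kept <- integer(0)
    for (i in seq_len(nrow(sub))) {
      if (length(kept)) {
        d2 <- (sub$x[kept] - sub$x[i])^2 + (sub$y[kept] - sub$y[i])^2
        if (any(d2 < params$radius_px^2)) next
      }
      kept <- c(kept, i)
    }
    sub[kept, , drop = FALSE]
  })
  out <- do.call(rbind, keep_all)
  out$.chan <- NULL
  out$source <- "fused"
  out <- out[order(out$cls, out$x, out$y), , drop = FALSE]
  rownames(out) <- NULL
  out
}
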