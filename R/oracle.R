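# Oracle detector: a test double for the trained landmark-detection and
# segmentation networks. It converts phantom ground truth into two
# independent noisy landmark channels and (optionally eroded) masks, so the
# fusion and measurement logic can be exercised end to end with a known
# answer.

#' Noise model for the oracle detector
#'
#' @param jitter_sigma_px per-axis Gaussian SD of landmark position noise
#'   (default 0).
#' @param dropout_rate probability each true landmark is missed by a
#'   channel, in `[0, 1]` (default 0).
#' @param false_positive_rate expected spurious landmarks per image per
#'   channel (Poisson mean, default 0).
#' @param mask_erosion_px binary erosion applied to the teeth masks
#'   (default 0).
#' @param seed integer seed; outputs are a deterministic function of
#'   `(truth, noise)`.
#' @return an object of class `noise_params`.
#' @export
noise_params <- function(jitter_sigma_px = 0, dropout_rate = 0,
                         false_positive_rate = 0, mask_erosion_px = 0L,
                         seed = 1L) {
  if (jitter_sigma_px < 0) stop_achr("jitter_sigma_px must be >= 0",
                                     class = "achr_domain_error")
  if (dropout_rate < 0 || dropout_rate > 1)
    stop_achr("dropout_rate must lie in [0, 1]", class = "achr_domain_error")
  if (false_positive_rate < 0)
    stop_achr("false_positive_rate must be >= 0", class = "achr_domain_error")
  structure(list(jitter_sigma_px = as.numeric(jitter_sigma_px),
                 dropout_rate = as.numeric(dropout_rate),
                 false_positive_rate = as.numeric(false_positive_rate),
                 mask_erosion_px = as.integer(mask_erosion_px),
                 seed = as.integer(seed)),
            class = "noise_params")
}

#' Simulate detector outputs from phantom ground truth
#'
#' Each channel independently (under its own derived sub-seed): every true
#' CEJ/ABCL point is dropped with probability `dropout_rate`, otherwise
#' jittered by N(0, sigma^2) per axis and clamped to the frame;
#' Poisson(`false_positive_rate`) spurious landmarks of random class are
#' scattered uniformly over the image with confidence in (0.3, 0.8). True
#' landmarks carry confidence 1, so in the zero-noise limit both channels
#' equal the truth exactly. Teeth masks are the truth mask eroded by
#' `mask_erosion_px`; the crest band is passed through unchanged (eroding a
#' 3 px band would sever the partition-line input).
#'
#' @param truth a `phantom_truth` from [generate_phantom()].
#' @param noise a [noise_params()].
#' @return `list(landmarks_a, landmarks_b, teeth_mask_1, teeth_mask_2,
#'   abcl_mask)` -- the exact argument set of [ach_measure()].
#' @export
oracle_detect <- function(truth, noise = noise_params()) {
  stopifnot(inherits(truth, "phantom_truth"), inherits(noise, "noise_params"))
  set.seed(noise$seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, 2)
  h <- nrow(truth$teeth_mask); w <- ncol(truth$teeth_mask)
  pts <- truth_landmarks(truth)

  channel <- function(sub_seed, src) {
    set.seed(sub_seed)
    keep <- runif(nrow(pts)) >= noise$dropout_rate
    det <- pts[keep, , drop = FALSE]
    if (nrow(det) && noise$jitter_sigma_px > 0) {
      det$x <- det$x + rnorm(nrow(det), sd = noise$jitter_sigma_px)
      det$y <- det$y + rnorm(nrow(det), sd = noise$jitter_sigma_px)
      det$x <- pmin(pmax(det$x, 0), w - 1)
      det$y <- pmin(pmax(det$y, 0), h - 1)
    }
    det$source <- rep(src, nrow(det))
    n_fp <- rpois(1, noise$false_positive_rate)
    if (n_fp > 0) {
      fp <- landmarks(runif(n_fp, 0, w - 1), runif(n_fp, 0, h - 1),
                      sample(ACH_CLASSES, n_fp, replace = TRUE),
                      runif(n_fp, 0.3, 0.8), src)
      det <- rbind(det, fp)
    }
    rownames(det) <- NULL
    det
  }

  teeth_mask <- erode_mask(truth$teeth_mask, noise$mask_erosion_px)
  list(landmarks_a = channel(sub_seeds[1], "net_a"),
       landmarks_b = channel(sub_seeds[2], "net_b"),
       teeth_mask_1 = teeth_mask,
       teeth_mask_2 = teeth_mask,
       abcl_mask = truth$abcl_mask)
}
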