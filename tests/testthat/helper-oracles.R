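# Independent brute-force oracles used to cross-check the implementation.
# These deliberately share no code with the package internals.

# Exhaustive confidence-ordered suppression: repeatedly take the highest-
# confidence remaining landmark (ties: channel a first, then lower x, then
# lower y) and delete every same-class landmark strictly closer than radius.
oracle_nms <- function(dets_a, dets_b, radius) {
  dets_a$chan <- rep(1, nrow(dets_a))
  dets_b$chan <- rep(2, nrow(dets_b))
  pool <- rbind(dets_a, dets_b)
  kept <- pool[0, ]
  pool <- pool[order(-pool$confidence, pool$chan, pool$x, pool$y), ]
  while (nrow(pool) > 0) {
    top <- pool[1, ]
    kept <- rbind(kept, top)
    d <- sqrt((pool$x - top$x)^2 + (pool$y - top$y)^2)
    pool <- pool[!(pool$cls == top$cls & d < radius), ]
  }
  kept[order(kept$cls, kept$x, kept$y), c("x", "y", "cls", "confidence")]
}

# Normal-equations polynomial least squares, ascending coefficients.
oracle_polyfit <- function(x, y, degree) {
  X <- outer(x, 0:degree, `^`)
  as.numeric(solve(t(X) %*% X, t(X) %*% y))
}

# Exhaustive crossing check on raw pixels: tolerance band over every
# outline pixel plus per-column sign-change scan over every tooth pixel.
oracle_crosses <- function(tooth, curve, tol) {
  pv <- function(x) {
    y <- 0
    for (cc in rev(curve$coeffs)) y <- y * x + cc
    y
  }
  hit <- FALSE
  for (i in seq_len(nrow(tooth$outline))) {
    x <- tooth$outline[i, "x"]
    if (x >= curve$support[1] && x <= curve$support[2] &&
        abs(tooth$outline[i, "y"] - pv(x)) <= tol) hit <- TRUE
  }
  if (!hit) {
    for (x in unique(tooth$pixels[, "x"])) {
      if (x < curve$support[1] || x > curve$support[2]) next
      ys <- tooth$pixels[tooth$pixels[, "x"] == x, "y"]
      if (pv(x) > min(ys) && pv(x) < max(ys)) hit <- TRUE
    }
  }
  hit
}

# ICC(A,1) via aov() mean squares (variance-components route).
oracle_icc_a1 <- function(r1, r2) {
  n <- length(r1)
  d <- data.frame(y = c(r1, r2),
                  subj = factor(rep(seq_len(n), 2)),
                  occ = factor(rep(1:2, each = n)))
  ms <- summary(stats::aov(y ~ subj + occ, data = d))[[1]][, "Mean Sq"]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}

random_landmarks <- function(n, w = 400, h = 300, source = "net_a") {
  landmarks(runif(n, 0, w - 1), runif(n, 0, h - 1),
            sample(c("ABCL", "CEJ"), n, replace = TRUE),
            round(runif(n), 3), source)
}

# small blocky tooth instance for geometry tests
square_tooth <- function(x0, y0, side, mask_h = 40, mask_w = 40) {
  m <- matrix(FALSE, mask_h, mask_w)
  m[(y0 + 1):(y0 + side), (x0 + 1):(x0 + side)] <- TRUE
  extract_tooth_instances(m, min_tooth_area_px = 1)[[1]]
}

small_phantom_spec <- function(...) {
  phantom_spec(image_shape = c(300, 420), n_teeth_per_arch = 2,
               tooth_width_px = 80, tooth_height_px = 100,
               arch_gap_px = 50, cej_offset_px = 20,
               occlusal_curve_amplitude_px = 6, crown_corner_radius_px = 8,
               mm_per_px = 0.1,
               bone_loss_range_nonsevere = c(2, 4.5) * 0.4,
               bone_loss_range_severe = c(5.5, 8) * 0.4,
               severity_threshold_mm = 2,
               ...)
}
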