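test_that("severity thresholding follows the ge/gt conventions", {
  expect_false(classify_severity(4.99, 5.0, "ge"))
  expect_true(classify_severity(5.0, 5.0, "ge"))
  expect_true(classify_severity(5.01, 5.0, "ge"))
  expect_false(classify_severity(5.0, 5.0, "gt"))
  expect_true(classify_severity(5.01, 5.0, "gt"))
  # the two rules disagree only exactly at the threshold
  vals <- seq(0, 10, by = 0.25)
  diff <- classify_severity(vals, 5, "ge") != classify_severity(vals, 5, "gt")
  expect_equal(vals[diff], 5)
  expect_error(classify_severity(-0.1), class = "achr_domain_error")
})

test_that("per-side ACH is the Euclidean CEJ-ABCL distance in mm", {
  cfg <- ach_config(mm_per_px = 0.1)
  tooth <- square_tooth(90, 190, 21, mask_h = 300, mask_w = 200)
  lm <- landmarks(x = c(100, 100), y = c(200, 250), cls = c("CEJ", "ABCL"))
  m <- measure_tooth_ach(tooth, lm, calibration(0.1), cfg)
  expect_gte(nrow(m), 1)
  expect_equal(unique(m$ach_px), 50)
  expect_equal(unique(m$ach_mm), 5.0)
  expect_true(all(m$severe))

  # 3-4-5 triangle at unit calibration
  cfg1 <- ach_config(mm_per_px = 1)
  tooth2 <- square_tooth(0, 0, 10, mask_h = 50, mask_w = 50)
  lm2 <- landmarks(x = c(0, 3), y = c(0, 4), cls = c("CEJ", "ABCL"))
  m2 <- measure_tooth_ach(tooth2, lm2, calibration(1), cfg1)
  expect_equal(unique(m2$ach_px), 5)
  expect_equal(unique(m2$ach_mm), 5)

  # a side with a CEJ but no ABCL yields nothing
  m3 <- measure_tooth_ach(tooth2, landmarks(0, 0, "CEJ"), calibration(1), cfg1)
  expect_equal(nrow(m3), 0)
})

test_that("noiseless phantoms are recovered to one-pixel accuracy", {
  for (seed in c(2, 9)) {
    ph <- generate_phantom(small_phantom_spec(seed = seed))
    det <- oracle_detect(ph$truth, noise_params())
    cfg <- ach_config(mm_per_px = 0.1, severity_threshold_mm = 2)
    fit <- ach_measure(det$landmarks_a, det$landmarks_b, det$teeth_mask_1,
                       det$teeth_mask_2, det$abcl_mask, config = cfg)
    truth <- ph$truth$sites
    expect_equal(nrow(fit$measurements), nrow(truth))
    j <- merge(truth, fit$measurements, by = c("tooth_id", "site"),
               suffixes = c("_t", "_p"))
    expect_equal(nrow(j), nrow(truth))
    expect_lte(max(abs(j$ach_mm_t - j$ach_mm_p)), 0.1)
    expect_identical(j$severe_t, j$severe_p)
  }
})

test_that("removing one tooth's CEJ detections only silences that tooth", {
  ph <- generate_phantom(small_phantom_spec(seed = 4))
  det <- oracle_detect(ph$truth, noise_params())
  cfg <- ach_config(mm_per_px = 0.1, severity_threshold_mm = 2)
  victim <- ph$truth$teeth[2, ]
  vsites <- ph$truth$sites[ph$truth$sites$tooth_id == victim$tooth_id, ]
  drop_cej <- function(lm) {
    hit <- lm$cls == "CEJ" &
      apply(outer(lm$x, vsites$cej_x, `==`) &
              outer(lm$y, vsites$cej_y, `==`), 1, any)
    lm[!hit, ]
  }
  fit <- suppressWarnings(
    ach_measure(drop_cej(det$landmarks_a), drop_cej(det$landmarks_b),
                det$teeth_mask_1, det$teeth_mask_2, det$abcl_mask,
                config = cfg))
  full <- ach_measure(det$landmarks_a, det$landmarks_b, det$teeth_mask_1,
                      det$teeth_mask_2, det$abcl_mask, config = cfg)
  expect_false(victim$tooth_id %in% fit$measurements$tooth_id)
  others_fit <- fit$measurements[fit$measurements$tooth_id != victim$tooth_id, ]
  others_full <- full$measurements[full$measurements$tooth_id != victim$tooth_id, ]
  expect_equal(others_fit, others_full, ignore_attr = TRUE)
})

test_that("measured ACH never decreases when a site's bone loss grows", {
  base_loss <- rep(1.2, 8)
  prev <- -Inf
  for (loss in c(0.8, 1.4, 2.0, 2.6)) {
    bl <- base_loss; bl[3] <- loss   # tooth 2, left site
    ph <- generate_phantom(small_phantom_spec(seed = 5, bone_loss_mm = bl))
    det <- oracle_detect(ph$truth, noise_params())
    cfg <- ach_config(mm_per_px = 0.1, severity_threshold_mm = 2)
    fit <- ach_measure(det$landmarks_a, det$landmarks_b, det$teeth_mask_1,
                       det$teeth_mask_2, det$abcl_mask, config = cfg)
    m <- fit$measurements
    val <- m$ach_mm[m$tooth_id == 2 & m$site == "left"]
    expect_length(val, 1)
    expect_gte(val, prev)
    prev <- val
  }
})

test_that("every measured tooth satisfied the crossing gate", {
  ph <- generate_phantom(small_phantom_spec(seed = 6))
  det <- oracle_detect(ph$truth,
                       noise_params(jitter_sigma_px = 2, seed = 17))
  cfg <- ach_config(mm_per_px = 0.1, severity_threshold_mm = 2)
  fit <- ach_measure(det$landmarks_a, det$landmarks_b, det$teeth_mask_1,
                     det$teeth_mask_2, det$abcl_mask, config = cfg)
  gates <- setNames(vapply(fit$teeth, function(t) isTRUE(t$gate), logical(1)),
                    vapply(fit$teeth, `[[`, integer(1), "tooth_id"))
  measured <- unique(fit$measurements$tooth_id)
  expect_true(all(gates[as.character(measured)]))
})

test_that("arch partition classifies every landmark correctly under jitter", {
  ph <- generate_phantom(phantom_spec(seed = 21))
  det <- oracle_detect(ph$truth, noise_params(jitter_sigma_px = 2, seed = 22))
  line <- fit_partition_line(det$abcl_mask)
  truth <- ph$truth$sites
  for (ch in c("landmarks_a", "landmarks_b")) {
    lm <- det[[ch]]
    parts <- partition_landmarks(lm, line)
    # match each detection back to the closest truth site (no dropout/FPs)
    for (arch in c("upper", "lower")) {
      p <- parts[[arch]]
      for (i in seq_len(nrow(p))) {
        d <- (truth$cej_x - p$x[i])^2 + (truth$cej_y - p$y[i])^2
        d2 <- (truth$abcl_x - p$x[i])^2 + (truth$abcl_y - p$y[i])^2
        k <- if (min(d) < min(d2)) which.min(d) else which.min(d2)
        expect_equal(truth$arch[k], arch)
      }
    }
  }
})

test_that("degenerate inputs degrade to empty results instead of failing", {
  cfg <- ach_config(mm_per_px = 0.1)
  empty_mask <- matrix(FALSE, 50, 60)
  fit <- ach_measure(landmarks(), landmarks(), empty_mask, empty_mask,
                     empty_mask, config = cfg)
  expect_s3_class(fit, "ach_fit")
  expect_equal(nrow(fit$measurements), 0)
  expect_null(fit$partition_line)
  expect_error(
    ach_measure(landmarks(), landmarks(), empty_mask,
                matrix(FALSE, 10, 10), empty_mask, config = cfg),
    class = "achr_dimension_error")
})

test_that("the fitted pipeline object supports the modelling verbs", {
  ph <- generate_phantom(small_phantom_spec(seed = 8))
  det <- oracle_detect(ph$truth, noise_params())
  cfg <- ach_config(mm_per_px = 0.1, severity_threshold_mm = 2)
  fit <- ach_measure(det$landmarks_a, det$landmarks_b, det$teeth_mask_1,
                     det$teeth_mask_2, det$abcl_mask, config = cfg,
                     image = ph$image)
  expect_output(print(fit), "measured site")
  expect_output(print(summary(fit)), "pipeline log")
  co <- coef(fit)
  expect_named(co, c("partition_line", "upper_ABCL", "upper_CEJ",
                     "lower_ABCL", "lower_CEJ"))
  expect_length(co$upper_CEJ, cfg$curve_degree + 1)
  # predict() evaluates the stored polynomial
  xs <- c(100, 200, 300)
  expect_equal(predict(fit, xs, curve = "upper_CEJ"),
               polyval <- drop(outer(xs, 0:cfg$curve_degree, `^`) %*% co$upper_CEJ))
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(fit))
})
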