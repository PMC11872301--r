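# Synthetic bitewing phantom: two arches of rounded-rectangle teeth on a
# mild occlusal curve, with exact per-site CEJ/ABCL ground truth. Teeth are
# deliberately schematic -- the pipeline consumes only outlines and
# landmarks, so anatomical crown shapes would add nothing to correctness
# testing.

#' Specification of a synthetic bitewing phantom
#'
#' Defaults describe a plausible bitewing at the pipeline's working
#' resolution: an 869 x 1200 px frame, four teeth per arch, a 0.1 mm/px
#' calibration, and per-site bone loss drawn from a 50/50 mixture of
#' Uniform(2, 4.5) and Uniform(5.5, 8) mm so that severity at the 5 mm
#' threshold is unambiguous unless a boundary case is requested explicitly
#' via `bone_loss_mm`.
#'
#' @param image_shape `c(rows, cols)` of the scene (default `c(869, 1200)`).
#' @param n_teeth_per_arch teeth per arch (default 4).
#' @param tooth_width_px,tooth_height_px tooth rectangle size in px.
#' @param arch_gap_px vertical separation between the two arches' occlusal
#'   edges at the frame centre (default 120).
#' @param cej_offset_px CEJ distance from the occlusal (crown) edge along
#'   the flank (default 60).
#' @param occlusal_curve_amplitude_px amplitude of the mild parabolic
#'   occlusal curve (default 20).
#' @param crown_corner_radius_px rounding radius of the occlusal corners
#'   (default 20).
#' @param mm_per_px phantom calibration (default 0.1; a statement about the
#'   phantom only, not about any real sensor).
#' @param p_severe probability a site draws from the severe component of
#'   the bone-loss mixture (default 0.5).
#' @param bone_loss_range_nonsevere,bone_loss_range_severe the two uniform
#'   mixture components, in mm.
#' @param bone_loss_mm optional explicit vector of per-site bone loss in mm
#'   (length `4 * n_teeth_per_arch`, ordered by tooth then left/right
#'   site), overriding the mixture.
#' @param lower_arch_offset_px horizontal shift of the lower arch so the
#'   two arches interdigitate (default: half a tooth gap).
#' @param severity_threshold_mm,severity_rule convention used for the truth
#'   `severe` flags (defaults 5 mm, `"ge"`).
#' @param seed integer RNG seed; the phantom is a deterministic function of
#'   the spec.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_shape = c(869, 1200),
                         n_teeth_per_arch = 4,
                         tooth_width_px = 140,
                         tooth_height_px = 300,
                         arch_gap_px = 120,
                         cej_offset_px = 60,
                         occlusal_curve_amplitude_px = 20,
                         crown_corner_radius_px = 20,
                         mm_per_px = 0.1,
                         p_severe = 0.5,
                         bone_loss_range_nonsevere = c(2, 4.5),
                         bone_loss_range_severe = c(5.5, 8),
                         bone_loss_mm = NULL,
                         lower_arch_offset_px = NULL,
                         severity_threshold_mm = 5.0,
                         severity_rule = c("ge", "gt"),
                         seed = 1L) {
  severity_rule <- match.arg(severity_rule)
  spec <- list(image_shape = as.integer(image_shape),
               n_teeth_per_arch = as.integer(n_teeth_per_arch),
               tooth_width_px = as.integer(tooth_width_px),
               tooth_height_px = as.integer(tooth_height_px),
               arch_gap_px = as.numeric(arch_gap_px),
               cej_offset_px = as.numeric(cej_offset_px),
               occlusal_curve_amplitude_px = as.numeric(occlusal_curve_amplitude_px),
               crown_corner_radius_px = as.numeric(crown_corner_radius_px),
               mm_per_px = as.numeric(mm_per_px),
               p_severe = as.numeric(p_severe),
               bone_loss_range_nonsevere = as.numeric(bone_loss_range_nonsevere),
               bone_loss_range_severe = as.numeric(bone_loss_range_severe),
               bone_loss_mm = bone_loss_mm,
               lower_arch_offset_px = lower_arch_offset_px,
               severity_threshold_mm = as.numeric(severity_threshold_mm),
               severity_rule = severity_rule,
               seed = as.integer(seed))
  if (spec$mm_per_px <= 0) stop_achr("mm_per_px must be > 0",
                                     class = "achr_domain_error")
  if (spec$p_severe < 0 || spec$p_severe > 1)
    stop_achr("p_severe must lie in [0, 1]", class = "achr_domain_error")
  if (!is.null(spec$bone_loss_mm) && any(spec$bone_loss_mm < 0))
    stop_achr("bone_loss_mm must be >= 0", class = "achr_domain_error")
  structure(spec, class = "phantom_spec")
}

phantom_layout <- function(spec) {
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  n <- spec$n_teeth_per_arch; tw <- spec$tooth_width_px
  gap_x <- floor((w - n * tw) / (n + 1))
  if (gap_x < 1)
    stop_achr("phantom teeth do not fit: ", n, " teeth of width ", tw,
              " in ", w, " columns", class = "achr_spec_error")
  off <- spec$lower_arch_offset_px %||% floor(gap_x / 2)
  mid <- (h - 1) / 2
  amp <- spec$occlusal_curve_amplitude_px
  curve <- function(x) amp * (((x - (w - 1) / 2) / ((w - 1) / 2))^2 - 0.5)
  teeth <- do.call(rbind, lapply(seq_len(2 * n), function(k) {
    arch <- if (k <= n) "upper" else "lower"
    i <- if (k <= n) k else k - n
    x0 <- gap_x + (i - 1) * (tw + gap_x) + if (arch == "lower") off else 0
    xc <- x0 + (tw - 1) / 2
    if (arch == "upper") {
      occ <- round(mid - spec$arch_gap_px / 2 + curve(xc))
      y0 <- occ - spec$tooth_height_px + 1; y1 <- occ
    } else {
      occ <- round(mid + spec$arch_gap_px / 2 + curve(xc))
      y0 <- occ; y1 <- occ + spec$tooth_height_px - 1
    }
    data.frame(arch = arch, x0 = x0, x1 = x0 + tw - 1L, y0 = y0, y1 = y1,
               occ = occ, stringsAsFactors = FALSE)
  }))
  if (any(teeth$y0 < 0) || any(teeth$y1 > h - 1) || any(teeth$x1 > w - 1))
    stop_achr("phantom teeth exceed the image frame; enlarge image_shape or ",
              "shrink the teeth", class = "achr_spec_error")
  up_bottom <- max(teeth$y1[teeth$arch == "upper"])
  lo_top <- min(teeth$y0[teeth$arch == "lower"])
  if (up_bottom >= lo_top)
    stop_achr("phantom arches overlap; increase arch_gap_px",
              class = "achr_spec_error")
  teeth <- teeth[order(teeth$x0), ]
  teeth$tooth_id <- seq_len(nrow(teeth))
  rownames(teeth) <- NULL
  teeth
}

rasterize_tooth <- function(mask, tooth, r) {
  rows <- (tooth$y0:tooth$y1) + 1L
  cols <- (tooth$x0:tooth$x1) + 1L
  block <- matrix(TRUE, length(rows), length(cols))
  if (r > 0) {
    # round the two occlusal-edge corners
    yy <- matrix(tooth$y0:tooth$y1, length(rows), length(cols))
    xx <- matrix(tooth$x0:tooth$x1, length(rows), length(cols), byrow = TRUE)
    occ_y <- if (tooth$arch == "upper") tooth$y1 else tooth$y0
    sgn <- if (tooth$arch == "upper") -1 else 1
    for (cx in c(tooth$x0 + r, tooth$x1 - r)) {
      cy <- occ_y + sgn * r
      corner <- (if (cx == tooth$x0 + r) xx < cx else xx > cx) &
        (if (tooth$arch == "upper") yy > cy else yy < cy)
      block[corner & ((xx - cx)^2 + (yy - cy)^2 > r^2)] <- FALSE
    }
  }
  mask[rows, cols] <- mask[rows, cols] | block
  mask
}

#' Generate a synthetic bitewing phantom with ground truth
#'
#' Places two arches of rounded-rectangle teeth on a mild parabolic
#' occlusal curve. On each tooth flank (left/right side), the CEJ sits
#' `cej_offset_px` from the occlusal edge and the ABCL is displaced
#' apically along the flank by the site's bone loss converted to pixels, so
#' the true ACH is exactly the drawn bone loss. Returns the scene image
#' (background texture, brighter teeth, a visible crest band) and a
#' `phantom_truth` object holding exact landmark positions, per-site ACH
#' and severity, and pixel-exact teeth and crest (ABCL) masks.
#'
#' @param spec a [phantom_spec()].
#' @return `list(image = , truth = )`; `truth` has fields `sites`
#'   (measurement-schema data frame), `teeth` (per-tooth geometry),
#'   `teeth_mask`, `abcl_mask`, `mm_per_px`, `spec`.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 3))
#' nrow(ph$truth$sites)  # 16 sites: 8 teeth x 2 sides
#' @export
generate_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  h <- spec$image_shape[1]; w <- spec$image_shape[2]
  teeth <- phantom_layout(spec)
  n_sites <- 2L * nrow(teeth)

  loss <- spec$bone_loss_mm
  if (is.null(loss)) {
    sev <- runif(n_sites) < spec$p_severe
    loss <- ifelse(sev,
                   runif(n_sites, spec$bone_loss_range_severe[1],
                         spec$bone_loss_range_severe[2]),
                   runif(n_sites, spec$bone_loss_range_nonsevere[1],
                         spec$bone_loss_range_nonsevere[2]))
  } else if (length(loss) != n_sites) {
    stop_achr("bone_loss_mm must have length ", n_sites,
              " (2 sites x ", nrow(teeth), " teeth)", class = "achr_spec_error")
  }

  teeth_mask <- matrix(FALSE, h, w)
  abcl_mask <- matrix(FALSE, h, w)
  sites <- vector("list", n_sites)
  for (i in seq_len(nrow(teeth))) {
    t <- teeth[i, ]
    teeth_mask <- rasterize_tooth(teeth_mask, t, spec$crown_corner_radius_px)
    sgn <- if (t$arch == "upper") -1 else 1
    cej_y <- t$occ + sgn * spec$cej_offset_px
    site_x <- c(left = t$x0, right = t$x1)
    abcl_y <- numeric(2)
    for (s in 1:2) {
      k <- 2L * (i - 1L) + s
      loss_px <- loss[k] / spec$mm_per_px
      abcl_y[s] <- cej_y + sgn * loss_px
      ach_mm <- sqrt((abcl_y[s] - cej_y)^2) * spec$mm_per_px
      sites[[k]] <- data.frame(
        image_id = sprintf("phantom_seed%d", spec$seed),
        tooth_id = t$tooth_id, site = names(site_x)[s], arch = t$arch,
        cej_x = as.numeric(site_x[s]), cej_y = cej_y,
        abcl_x = as.numeric(site_x[s]), abcl_y = abcl_y[s],
        ach_px = abs(abcl_y[s] - cej_y), ach_mm = ach_mm,
        severe = classify_severity(ach_mm, spec$severity_threshold_mm,
                                   spec$severity_rule),
        stringsAsFactors = FALSE)
    }
    # crest band: 3 px thick, linear between the two flank ABCL points
    xs <- t$x0:t$x1
    band_y <- round(abcl_y[1] + (abcl_y[2] - abcl_y[1]) *
                      (xs - t$x0) / max(t$x1 - t$x0, 1))
    for (dy in -1:1) {
      ok <- band_y + dy >= 0 & band_y + dy <= h - 1
      abcl_mask[cbind(band_y[ok] + dy + 1L, xs[ok] + 1L)] <- TRUE
    }
  }
  sites <- do.call(rbind, sites)
  rownames(sites) <- NULL

  image <- matrix(pmin(pmax(0.2 + rnorm(h * w, sd = 0.02), 0), 1), h, w)
  image[teeth_mask] <- 0.75
  image[abcl_mask] <- 0.5

  truth <- structure(list(sites = sites, teeth = teeth,
                          teeth_mask = teeth_mask, abcl_mask = abcl_mask,
                          mm_per_px = spec$mm_per_px, spec = spec),
                     class = "phantom_truth")
  list(image = image, truth = truth)
}

#' @export
print.phantom_truth <- function(x, ...) {
  cat(sprintf("bitewing phantom truth: %d teeth, %d sites (%d severe), %g mm/px\n",
              nrow(x$teeth), nrow(x$sites), sum(x$sites$severe), x$mm_per_px))
  invisible(x)
}

#' Landmark table of a phantom's exact ground truth
#'
#' @param truth a `phantom_truth`.
#' @return landmark data frame (source `"oracle"`, confidence 1) with one
#'   CEJ and one ABCL point per tooth site.
#' @export
truth_landmarks <- function(truth) {
  s <- truth$sites
  rbind(
    landmarks(s$cej_x, s$cej_y, "CEJ", 1, "oracle"),
    landmarks(s$abcl_x, s$abcl_y, "ABCL", 1, "oracle")
  )
}

#' Write the phantom gold standard as a measurement-schema CSV
#'
#' @param truth a `phantom_truth`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
truth_to_gold_csv <- function(truth, path) {
  write_measurements(truth$sites, path)
}
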