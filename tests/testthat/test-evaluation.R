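make_records <- function(image_id, n, n_wrong = 0, gold = NULL) {
  gold <- gold %||% rep(c(TRUE, FALSE), length.out = n)
  pred <- gold
  if (n_wrong > 0) pred[seq_len(n_wrong)] <- !pred[seq_len(n_wrong)]
  data.frame(image_id = image_id, tooth_id = seq_len(n), site = "left",
             gold_severe = gold, pred_severe = pred)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("fully concordant and single-discordant images score as expected", {
  r16 <- make_records("bw1", 16)
  expect_equal(evaluate_classification(r16)$accuracy_pct, 100)

  r6 <- make_records("bw2", 6, n_wrong = 1)
  rep6 <- evaluate_classification(r6)
  expect_equal(rep6$accuracy_pct, 100 * 5 / 6, tolerance = 1e-12)
  expect_output(print(rep6), "83%")
})

test_that("total inversion zeroes sensitivity and specificity", {
  r <- make_records("bw", 10)
  r$pred_severe <- !r$gold_severe
  rep <- evaluate_classification(r)
  expect_equal(rep$accuracy_pct, 0)
  expect_equal(rep$sensitivity_severe_pct, 0)
  expect_equal(rep$specificity_pct, 0)
})

test_that("sensitivity is absent without gold-severe sites", {
  r <- make_records("bw", 5, gold = rep(FALSE, 5))
  rep <- evaluate_classification(r)
  expect_true(is.na(rep$sensitivity_severe_pct))
  expect_equal(rep$specificity_pct, 100)
})

test_that("empty input and duplicate keys are rejected", {
  expect_error(evaluate_classification(make_records("a", 3)[0, ]),
               class = "achr_domain_error")
  dup <- rbind(make_records("a", 3), make_records("a", 3))
  expect_error(evaluate_classification(dup), class = "achr_validation_error")
})

test_that("pooled accuracy is the site-weighted mean of per-image accuracies", {
  set.seed(404)
  for (rep_i in 1:20) {
    n_img <- sample(2:5, 1)
    recs <- do.call(rbind, lapply(seq_len(n_img), function(i)
      make_records(paste0("img", i), sample(3:20, 1),
                   n_wrong = sample(0:3, 1))))
    rep <- evaluate_classification(recs)
    w <- rep$per_image
    expect_equal(rep$accuracy_pct, sum(w$n * w$accuracy_pct) / sum(w$n))
    expect_equal(sum(w$n), rep$n_sites)
    # permutation invariance
    shuf <- recs[sample(nrow(recs)), ]
    expect_equal(evaluate_classification(shuf)$accuracy_pct, rep$accuracy_pct)
  }
})

test_that("ICC(A,1) matches independently computed references", {
  r <- c(7.1, 5.2, 8.3, 4.4, 6.0)
  expect_equal(intraclass_correlation(r, r), 1.0)
  # frozen reference values (two-way absolute-agreement single-measure ICC)
  expect_equal(intraclass_correlation(r, r + 2), 0.5428571429, tolerance = 1e-8)
  expect_equal(intraclass_correlation(1:5, 5:1), -5 / 3, tolerance = 1e-10)
  expect_equal(intraclass_correlation(r, c(7.3, 5.0, 8.1, 4.9, 5.8)),
               0.9812870835, tolerance = 1e-8)
})

test_that("ICC agrees with the aov mean-squares oracle on random tables", {
  set.seed(88)
  for (i in 1:25) {
    n <- sample(3:30, 1)
    r1 <- runif(n, 2, 8)
    r2 <- r1 + rnorm(n, sd = runif(1, 0.05, 1)) + runif(1, -1, 1)
    expect_equal(intraclass_correlation(r1, r2), oracle_icc_a1(r1, r2),
                 tolerance = 1e-10)
    # symmetry in the two occasions
    expect_equal(intraclass_correlation(r1, r2),
                 intraclass_correlation(r2, r1), tolerance = 1e-12)
    # invariance to subject relabeling
    perm <- sample(n)
    expect_equal(intraclass_correlation(r1[perm], r2[perm]),
                 intraclass_correlation(r1, r2), tolerance = 1e-12)
  }
})

test_that("independent noise lowers the expected ICC below 1", {
  set.seed(12)
  r1 <- runif(40, 2, 8)
  iccs <- vapply(1:30, function(i)
    intraclass_correlation(r1, r1 + rnorm(40, sd = 0.5)), numeric(1))
  expect_lt(mean(iccs), 1)
  expect_gt(mean(iccs), 0.8)  # still strong agreement at modest noise
})

test_that("ICC guards its domain", {
  expect_error(intraclass_correlation(1:5, 1:4), class = "achr_domain_error")
  expect_error(intraclass_correlation(1:2, 1:2), class = "achr_domain_error")
  expect_error(intraclass_correlation(rep(1, 5), rep(1, 5)),
               class = "achr_degenerate_error")
})

test_that("severity_records joins predictions with gold on site keys", {
  ph <- generate_phantom(small_phantom_spec(seed = 13))
  gold <- ph$truth$sites
  pred <- gold
  pred$severe[1] <- !pred$severe[1]
  pred <- pred[-2, ]   # an unmeasured site is dropped, not scored
  rec <- severity_records(pred, gold)
  expect_equal(nrow(rec), nrow(gold) - 1)
  rep <- evaluate_classification(rec)
  expect_equal(rep$accuracy_pct, 100 * (nrow(rec) - 1) / nrow(rec))
})
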