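test_that("landmark CSV and JSON round-trips preserve records", {
  lm <- landmarks(x = c(100, 3.5, 0), y = c(250, 7.25, 0),
                  cls = c("ABCL", "CEJ", "ABCL"),
                  confidence = c(0.9, 0.5, 1), source = "net_a")
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_landmarks(lm, path)
    back <- read_landmarks(path)
    expect_equal(back, lm, ignore_attr = TRUE)
  }
})

test_that("a single CSV row becomes one landmark, order preserved", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("x,y,cls,confidence,source",
               "100,250,ABCL,0.9,net_a"), path)
  lm <- read_landmarks(path)
  expect_equal(nrow(lm), 1)
  expect_equal(lm$x, 100)
  expect_equal(lm$y, 250)
  expect_equal(lm$cls, "ABCL")
})

test_that("empty and malformed landmark files are handled", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines("x,y,cls,confidence,source", path)
  expect_equal(nrow(read_landmarks(path)), 0)

  writeLines(c("x,y,cls,confidence,source", "1,2,APEX,0.5,net_a"), path)
  expect_error(read_landmarks(path), class = "achr_parse_error")
  expect_error(read_landmarks(path), "row 1")

  writeLines(c("x,y,cls,confidence,source", "1,2,CEJ,1.7,net_a"), path)
  expect_error(read_landmarks(path), class = "achr_parse_error")

  expect_error(read_landmarks(file.path(tempdir(), "nope.csv")),
               class = "achr_io_error")
})

test_that("px_to_mm is linear arithmetic with a guarded domain", {
  expect_equal(px_to_mm(50, calibration(0.1)), 5.0)
  expect_equal(px_to_mm(0, calibration(0.42)), 0.0)
  expect_equal(px_to_mm(50, calibration(0.08)), 4.0)
  a <- runif(20, 0, 100); b <- runif(20, 0, 100)
  cal <- calibration(0.0731)
  expect_equal(px_to_mm(a + b, cal), px_to_mm(a, cal) + px_to_mm(b, cal))
  expect_error(px_to_mm(-1, cal), class = "achr_domain_error")
  expect_error(calibration(0), class = "achr_domain_error")
  expect_error(calibration(-0.1), class = "achr_domain_error")
})

test_that("measurement CSV round-trips random tables to 6 decimals", {
  set.seed(11)
  n <- 10
  m <- data.frame(image_id = "img1", tooth_id = sample(1:8, n, TRUE),
                  site = sample(c("left", "right"), n, TRUE),
                  cej_x = runif(n, 0, 1200), cej_y = runif(n, 0, 869),
                  abcl_x = runif(n, 0, 1200), abcl_y = runif(n, 0, 869),
                  ach_px = runif(n, 0, 90), ach_mm = runif(n, 0, 9),
                  severe = sample(c(TRUE, FALSE), n, TRUE))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurements(m, path)
  back <- read_measurements(path)
  for (cc in c("cej_x", "cej_y", "abcl_x", "abcl_y", "ach_px", "ach_mm"))
    expect_equal(back[[cc]], m[[cc]], tolerance = 1e-6)
  expect_identical(back$severe, m$severe)
  expect_identical(back$site, m$site)

  # empty list -> header-only file; severe rendered lowercase
  write_measurements(m[0, ], path)
  expect_equal(length(readLines(path)), 1)
  write_measurements(data.frame(image_id = "i", tooth_id = 1L, site = "left",
                                cej_x = 0, cej_y = 0, abcl_x = 0, abcl_y = 50,
                                ach_px = 50, ach_mm = 5.0, severe = TRUE),
                     path)
  row <- readLines(path)[2]
  expect_match(row, "5.0")
  expect_match(row, "true")
})

test_that("config defaults from an empty YAML file equal programmatic defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines("", path)
  expect_equal(read_ach_config(path, mm_per_px = 0.1), ach_config(0.1))
  writeLines(c("severity_rule: gt", "curve_degree: 3"), path)
  cfg <- read_ach_config(path, mm_per_px = 0.2)
  expect_equal(cfg$severity_rule, "gt")
  expect_equal(cfg$curve_degree, 3L)
  expect_equal(cfg$mm_per_px, 0.2)
  # calibration is never guessed
  writeLines("", path)
  expect_error(read_ach_config(path), class = "achr_domain_error")
  expect_error(ach_config(), "missing")
})

test_that("binary mask PNG round-trips", {
  m <- matrix(FALSE, 20, 30)
  m[5:10, 7:12] <- TRUE
  path <- withr::local_tempfile(fileext = ".png")
  write_mask_png(m, path)
  expect_identical(read_mask_png(path), m)
})
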