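test_that("centered windows cover every full-context sample and nothing else", {
  w <- extract_windows(1:9, window_spec(5))
  expect_equal(nrow(w$windows), 5)
  expect_equal(w$centers, 3:7)
  # consecutive windows share 4 of 5 samples (80% overlap)
  expect_equal(sum(w$windows[1, ] %in% w$windows[2, ]), 4)
  w1 <- extract_windows(1:5, window_spec(5))
  expect_equal(w1$centers, 3)
  expect_equal(as.numeric(w1$windows), 1:5)
  expect_error(extract_windows(1:4, window_spec(5)), "shorter than window")
  expect_error(window_spec(4), "odd")
})

test_that("MAV and RMS match their definitions", {
  expect_equal(mav(rep(2, 5)), 2)
  expect_equal(mav(c(-1, 1, -1, 1, -1)), 1)
  expect_equal(mav(1:5), 3)
  expect_equal(rms(rep(2, 5)), 2)
  expect_equal(rms(rep(0, 5)), 0)
  expect_equal(rms(1:5), sqrt(11))
  expect_error(mav(numeric(0)), "empty")
  expect_error(rms(numeric(0)), "empty")
})

test_that("linear fit recovers exact and least-squares coefficients", {
  f <- linear_fit(c(3, 5, 7, 9, 11))      # y = 1 + 2i
  expect_equal(f$a, 1)
  expect_equal(f$b, 2)
  expect_equal(f$residual, 0)
  f2 <- linear_fit(rep(4, 5))
  expect_equal(f2$a, 4)
  expect_equal(f2$b, 0)
  f3 <- linear_fit(c(1, 2, 3, 4, 10))     # Sxy = 20, Sxx = 10
  expect_equal(f3$a, -2)
  expect_equal(f3$b, 2)
  expect_error(linear_fit(1), "at least 2")
})

test_that("parabolic fit nests the linear fit and recovers exact quadratics", {
  f <- parabolic_fit(c(3, 6, 11, 18, 27))   # y = 2 + i^2
  expect_equal(f$a, 2)
  expect_equal(f$b, 0)
  expect_equal(f$c, 1)
  expect_equal(f$residual, 0, tolerance = 1e-12)
  lin <- parabolic_fit(c(3, 5, 7, 9, 11))
  expect_equal(lin$c, 0)
  expect_equal(lin$a, 1)
  expect_equal(lin$b, 2)
  expect_error(parabolic_fit(1:2), "at least 3")
})

test_that("fits agree with the normal-equations oracle on random windows", {
  set.seed(17)
  for (i in 1:200) {
    w <- rnorm(sample(5:15, 1), mean = runif(1, -50, 300), sd = runif(1, 0.1, 40))
    lf <- linear_fit(w); o1 <- oracle_polyfit(w, 1)
    expect_equal(c(lf$a, lf$b), o1$coef, tolerance = 1e-9)
    expect_equal(lf$residual, o1$residual, tolerance = 1e-9)
    pf <- parabolic_fit(w); o2 <- oracle_polyfit(w, 2)
    expect_equal(c(pf$a, pf$b, pf$c), o2$coef, tolerance = 1e-9)
    expect_equal(pf$residual, o2$residual, tolerance = 1e-8)
    expect_lte(pf$residual, lf$residual + 1e-9)
  }
})

test_that("translation shifts intercepts and MAV but not slopes or curvature", {
  set.seed(4)
  w <- abs(rnorm(7, 10, 3))
  shift <- 25
  expect_equal(mav(w + shift), mav(w) + shift)
  lf0 <- linear_fit(w); lf1 <- linear_fit(w + shift)
  expect_equal(lf1$a, lf0$a + shift)
  expect_equal(lf1$b, lf0$b)
  pf0 <- parabolic_fit(w); pf1 <- parabolic_fit(w + shift)
  expect_equal(pf1$a, pf0$a + shift)
  expect_equal(pf1$b, pf0$b)
  expect_equal(pf1$c, pf0$c)
})

test_that("RMS dominates MAV with equality only for constant magnitudes", {
  set.seed(9)
  for (i in 1:50) {
    w <- rnorm(5, sample(0:300, 1), runif(1, 0.5, 30))
    expect_gte(rms(w), mav(w))
  }
  expect_equal(rms(c(-3, 3, -3, 3, 3)), mav(c(-3, 3, -3, 3, 3)))
})

test_that("Yule-Walker fit flags degenerate windows and recovers AR(1) processes", {
  d <- ar_fit(rep(7, 5))
  expect_true(d$degenerate)
  expect_equal(d$coefficients, rep(0, 4))
  expect_equal(d$innovation_variance, 0)

  set.seed(23)
  x <- as.numeric(stats::filter(rnorm(10000), 0.6, method = "recursive"))
  f <- ar_fit(x, order = 1)
  expect_false(f$degenerate)
  expect_equal(f$coefficients, 0.6, tolerance = 0.05 / 0.6)
  # closed-form Yule-Walker oracle: r(1)/r(0)
  expect_equal(f$coefficients, oracle_autocov(x, 1) / oracle_autocov(x, 0),
               tolerance = 1e-9)
  expect_gt(f$innovation_variance, 0)

  wn <- rnorm(10000)
  expect_lt(abs(ar_fit(wn, order = 1)$coefficients), 0.05)
})

test_that("Yule-Walker matches stats::ar.yw in sign and value on long series", {
  set.seed(31)
  x <- as.numeric(stats::filter(rnorm(2000), c(0.5, -0.3), method = "recursive")) + 100
  ours <- ar_fit(x, order = 2)
  ref <- stats::ar.yw(x, order.max = 2, aic = FALSE, demean = TRUE)
  expect_equal(ours$coefficients, as.numeric(ref$ar), tolerance = 1e-6)
  expect_gt(ours$coefficients[1], 0)   # prediction sign convention
})

test_that("feature matrices have documented shapes, alignment, and labels", {
  cfg <- tiny_config(seed = 3)
  s <- synthesize_signal(generate_protocol(cfg), cfg)
  s$fmg <- s$fmg[1:100, , drop = FALSE]
  s$thumb <- s$thumb[1:100]
  s$events <- NULL
  lab <- label_from_thumb(s$thumb, suggest_threshold(s$thumb))

  lf <- extract_feature_matrix(s, lab, "lf")
  expect_equal(dim(lf$values), c(96, 32))
  expect_equal(lf$centers, 3:98)
  expect_equal(lf$labels, lab$labels[3:98])

  ar <- extract_feature_matrix(s, lab, "ar")
  expect_equal(ncol(ar$values), 64)

  raw <- extract_feature_matrix(s, lab, "raw")
  expect_equal(unname(raw$values), matrix(as.numeric(s$fmg[3:98, ]), 96, 16))

  m <- extract_feature_matrix(s, lab, "mav")
  expect_equal(unname(m$values[1, 1]), mav(as.numeric(s$fmg[1:5, 1])))
  r <- extract_feature_matrix(s, lab, "rms")
  expect_equal(unname(r$values[10, 16]), rms(as.numeric(s$fmg[10:14, 16])))
  pf <- extract_feature_matrix(s, lab, "pf")
  w1 <- parabolic_fit(as.numeric(s$fmg[1:5, 2]))
  expect_equal(unname(pf$values[1, 4:6]), c(w1$a, w1$b, w1$c), tolerance = 1e-9)
  arf <- ar_fit(as.numeric(s$fmg[1:5, 1]))
  expect_equal(unname(ar$values[1, 1:4]), arf$coefficients, tolerance = 1e-9)

  expect_error(extract_feature_matrix(s, lab, "wavelet"), "'arg'")
  short <- s; short$fmg <- s$fmg[1:3, ]; short$thumb <- s$thumb[1:3]
  shortlab <- label_from_thumb(short$thumb, 1)
  expect_error(extract_feature_matrix(short, shortlab, "mav"), "shorter than window")
})
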