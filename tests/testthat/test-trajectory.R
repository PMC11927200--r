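test_that("trajectories group consecutive identical residues", {
  tr <- toy_trajectory(c("A", "A", "L", "K", "K"))
  expect_identical(tr$groups$residue, c("A", "L", "K"))
  expect_identical(tr$n_transitions, 2L)

  const <- toy_trajectory(rep("W", 6L))
  expect_identical(nrow(const$groups), 1L)
  expect_identical(const$n_transitions, 0L)

  set.seed(13)
  for (i in 1:50) {
    col <- sample(c("A", "L", "K", "V"), sample(2:15, 1L), replace = TRUE)
    got <- toy_trajectory(col)$groups
    ref <- rle_hand(col)
    expect_identical(got$residue, ref$residue)
    expect_identical(got$first, ref$first)
    expect_identical(got$last, ref$last)
    expect_identical(paste(rep(got$residue, got$last - got$first + 1L), collapse = ""),
                     paste(col, collapse = ""))
  }
})

test_that("gap residues are dropped while distances are retained", {
  path <- toy_path(c("A", "-", "L", "-", "K"), positions = c(0, 0.1, 0.3, 0.4, 0.7))
  tr <- build_trajectory(path, 0L)
  expect_identical(tr$residues, c("A", "L", "K"))
  expect_equal(tr$positions, c(0, 0.3, 0.7))
  expect_identical(tr$n_transitions, 2L)
  expect_error(build_trajectory(path, 1L), "out of range")
})

test_that("eligibility requires at least three transitions and a non-gap target", {
  p2 <- toy_path(c("A", "L", "K", "K", "K"))
  expect_false(is_eligible(build_trajectory(p2, 0L), p2))     # 2 transitions
  p3 <- toy_path(c("A", "L", "K", "V", "V"))
  expect_true(is_eligible(build_trajectory(p3, 0L), p3))      # exactly 3
  pc <- toy_path(rep("A", 5L))
  expect_false(is_eligible(build_trajectory(pc, 0L), pc))
  pg <- toy_path(c("A", "L", "K", "V", "-"))
  expect_false(is_eligible(build_trajectory(pg, 0L), pg))     # target gapped
  cfg <- ssp_config(min_transitions = 2L)
  expect_true(is_eligible(build_trajectory(p2, 0L), p2, cfg))
})

test_that("featurization maps groups to (distance, value, weight) points", {
  tab <- load_default_indices()
  mw <- tab[["FASG760101"]]
  path <- toy_path(c("G", "A", "V", "L"), positions = c(0, 1, 2, 3))
  tr <- build_trajectory(path, 0L)
  fs <- featurize(tr, mw, path)
  expect_equal(fs$x, c(0, 1, 2, 3))
  expect_true(all(diff(fs$y) > 0))            # G < A < V < L in molecular weight
  expect_true(all(is.finite(fs$w)) && all(fs$w >= 0))
  # linear recency weighting: root weight 1, target end weight 2
  expect_equal(fs$w, 1 + fs$x / 3)
  fu <- featurize(tr, mw, path, ssp_config(weighting = "uniform"))
  expect_equal(fu$w, rep(1, 4L))

  px <- toy_path(c("G", "X", "V", "L"), positions = c(0, 1, 2, 3))
  trx <- build_trajectory(px, 0L)
  expect_warning(fsx <- featurize(trx, mw, px), "outside the scale")
  expect_length(fsx$y, 3L)
})

test_that("trend fitting recovers exact lines and matches the normal-equation oracle", {
  tab <- load_default_indices()
  mw <- tab[["FASG760101"]]
  cfg_raw <- ssp_config(normalize = FALSE)
  mk_series <- function(x, y, w, nt = length(x) - 1L) {
    structure(list(accession = "FASG760101", x = x, y = y, w = w,
                   n_transitions = nt), class = "feature_series")
  }
  # exact line fits exactly under any weights
  x <- c(0, 0.4, 1.1, 2.0)
  m <- fit_trend(mk_series(x, 2 * x + 1, c(1, 3, 0.5, 2)), 0.5, mw, cfg_raw)
  expect_equal(m$slope, 2, tolerance = 1e-9)
  expect_equal(m$intercept, 1, tolerance = 1e-9)
  expect_equal(m$predicted_value, 2 * 2.5 + 1, tolerance = 1e-9)
  # constant y -> zero slope, residue nearest to the constant
  mc <- fit_trend(mk_series(x, rep(89.09, 4L), rep(1, 4L)), 0.5, mw, cfg_raw)
  expect_equal(mc$slope, 0, tolerance = 1e-12)
  expect_identical(mc$predicted_residue, "A")
  # random series against the closed-form weighted normal equations
  set.seed(23)
  for (i in 1:40) {
    n <- sample(3:9, 1L)
    xs <- sort(runif(n, 0, 2)); ys <- rnorm(n, 100, 30); ws <- runif(n, 0.1, 3)
    got <- fit_trend(mk_series(xs, ys, ws), 0.3, mw, cfg_raw)
    ref <- wols_hand(xs, ys, ws)
    expect_equal(got$slope, unname(ref["slope"]), tolerance = 1e-8)
    expect_equal(got$intercept, unname(ref["intercept"]), tolerance = 1e-8)
    # invariant: extrapolation is the line at x_last + step
    expect_equal(got$predicted_value,
                 got$slope * (got$x_last + got$step) + got$intercept)
    # unit weights reduce to ordinary least squares
    if (i <= 10) {
      ols <- stats::lm(ys ~ xs)
      gu <- fit_trend(mk_series(xs, ys, rep(1, n)), 0.3, mw, cfg_raw)
      expect_equal(gu$slope, unname(coef(ols)[2L]), tolerance = 1e-8)
      expect_equal(gu$intercept, unname(coef(ols)[1L]), tolerance = 1e-8)
    }
  }
  expect_error(fit_trend(mk_series(rep(1, 3L), c(1, 2, 3), rep(1, 3L)), 0.3,
                         mw, cfg_raw), "degenerate")
})

test_that("transition normalization rescales the distance axis and the step", {
  tab <- load_default_indices()
  mw <- tab[["FASG760101"]]
  s <- structure(list(accession = "FASG760101", x = c(0, 1, 2, 3),
                      y = c(80, 100, 120, 140), w = rep(1, 4L),
                      n_transitions = 3L), class = "feature_series")
  raw <- fit_trend(s, 0.6, mw, ssp_config(normalize = FALSE))
  nrm <- fit_trend(s, 0.6, mw, ssp_config(normalize = TRUE))
  expect_equal(nrm$slope, raw$slope * 3, tolerance = 1e-9)
  # the prediction point rescales identically, so the predicted value agrees
  expect_equal(nrm$predicted_value, raw$predicted_value, tolerance = 1e-9)
})

test_that("predictions shift with the scale (affine equivariance)", {
  tab <- load_default_indices()
  mw <- tab[["FASG760101"]]
  shifted <- mw; shifted$values <- mw$values + 57
  path <- toy_path(c("G", "A", "V", "L", "F"), positions = c(0, 0.2, 0.5, 0.9, 1.3))
  tr <- build_trajectory(path, 0L)
  m0 <- fit_trend(featurize(tr, mw, path), 0.3, mw)
  m1 <- fit_trend(featurize(tr, shifted, path), 0.3, shifted)
  expect_equal(m1$predicted_value, m0$predicted_value + 57, tolerance = 1e-9)
  expect_identical(m1$predicted_residue, m0$predicted_residue)
  expect_equal(m1$slope, m0$slope, tolerance = 1e-9)
})

test_that("per-site prediction returns one model per scale at eligible sites", {
  tab <- load_default_indices()
  path <- toy_path(c("G", "A", "V", "L", "F"), positions = c(0, 0.2, 0.5, 0.9, 1.3))
  keep_all <- ssp_config(drop_self = FALSE)
  out <- predict_site(path, 0L, tab, keep_all)
  expect_identical(nrow(out), 9L)
  expect_setequal(out$accession, names(tab))
  expect_identical(unique(out$wild_type), "F")
  expect_identical(unique(out$position), 1L)
  # planted rising molecular-weight trend -> heavier successor than F
  mw_row <- out[out$accession == "FASG760101", ]
  expect_gt(mw_row$slope, 0)
  expect_gt(tab[["FASG760101"]]$values[[mw_row$predicted]],
            tab[["FASG760101"]]$values[["F"]])
  # ineligible site -> no rows
  p_low <- toy_path(c("G", "A", "A", "A", "A"))
  expect_identical(nrow(predict_site(p_low, 0L, tab)), 0L)
  # self-predictions are dropped by default
  dropped <- predict_site(path, 0L, tab)
  expect_false(any(dropped$predicted == dropped$wild_type))
})

test_that("noiseless linear feature series are recovered to machine precision", {
  tab <- load_default_indices()
  mw <- tab[["FASG760101"]]
  set.seed(31)
  for (i in 1:25) {
    a <- runif(1, -60, 60); b <- runif(1, 50, 150)
    x <- sort(runif(sample(4:9, 1L), 0, 2))
    s <- structure(list(accession = "FASG760101", x = x, y = a * x + b,
                        w = 1 + x / max(x), n_transitions = length(x) - 1L),
                   class = "feature_series")
    m <- fit_trend(s, 0.2, mw, ssp_config(normalize = FALSE))
    expect_equal(m$slope, a, tolerance = 1e-9)
    expect_equal(m$intercept, b, tolerance = 1e-9)
  }
})
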