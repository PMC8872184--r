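test_that("rho_from_fst reproduces the worked reduction", {
  expect_equal(rho_from_fst(0.154, 0.082), 1 - 0.082 / 0.154)
  expect_equal(round(100 * rho_from_fst(0.154, 0.082)), 47)
  expect_equal(rho_from_fst(0.2, 0.2), 0)
  expect_equal(rho_from_fst(0.2, 0), 1)
  expect_error(rho_from_fst(0, 0.1), "positive")
  expect_error(rho_from_fst(-0.05, 0.1), "positive")
})

test_that("rho_from_eta matches hand algebra and the literal expression", {
  expect_equal(rho_from_eta(hw = 0.8, hb_or_ht = 1.0, eta = 0.05), 0.20)
  expect_equal(rho_from_eta(0.8, 1.0, 0), 0)

  # closed form eta * hw / (hb - hw) agrees with the literal expression
  set.seed(21)
  for (i in 1:50) {
    hw <- runif(1, 0.01, 0.5)
    hb <- hw + runif(1, 0.01, 0.5)
    eta <- runif(1, 0, 0.3)
    literal <- 1 - (hb - hw * (1 + eta)) / (hb - hw)
    expect_equal(rho_from_eta(hw, hb, eta), literal, tolerance = 1e-12)
    expect_equal(rho_from_eta(hw, hb, eta), eta * hw / (hb - hw),
                 tolerance = 1e-12)
  }

  # basis with neutral FST 0.154 puts eta = 0.0855 at rho ~ 0.47
  expect_equal(rho_from_eta(0.846, 1, 0.0855), 0.47, tolerance = 0.01)
})

test_that("eta_from_rho inverts rho_from_eta exactly", {
  hw <- 0.846; hb <- 1  # hudson basis with neutral FST = 0.154
  eta <- eta_from_rho(hw, hb, rho = 0.47)
  expect_equal(eta, 0.47 * 0.154 / 0.846, tolerance = 1e-12)
  expect_equal(round(100 * eta, 1), 8.6)
  expect_equal(eta_from_rho(hw, hb, 0), 0)
  for (x in c(0.001, 0.05, 0.2)) {
    expect_equal(eta_from_rho(hw, hb, rho_from_eta(hw, hb, x)), x,
                 tolerance = 1e-12)
  }
  expect_warning(eta_from_rho(hw, hb, -0.05), "negative")
})

test_that("degenerate curve bases are rejected", {
  expect_error(rho_from_eta(0.5, 0.5, 0.1), "degenerate")
  expect_error(rho_from_eta(0, 0.5, 0.1), "degenerate")
  expect_error(eta_from_rho(0.6, 0.5, 0.1), "degenerate")
  # neutral sites with p1 = p2 everywhere: hb = hw
  flat <- site_records(p1 = c(0.3, 0.5), p2 = c(0.3, 0.5))
  expect_error(build_theoretical_curve(flat, "hudson"), "degenerate")
})

test_that("theoretical curve uses the estimator's own sums", {
  one <- site_records(p1 = 0.2, p2 = 0.8)
  cv <- build_theoretical_curve(one, "hudson", eta_grid = c(0, 0.1))
  expect_equal(cv$hw, 0.32)
  expect_equal(cv$hb_or_ht, 0.68)
  expect_equal(cv$points$rho, c(0, 0.1 * 0.32 / 0.36), tolerance = 1e-12)
  # determinism: identical inputs, identical curve
  cv2 <- build_theoretical_curve(one, "hudson", eta_grid = c(0, 0.1))
  expect_identical(cv$points, cv2$points)
})

test_that("rho is strictly increasing in eta and steeper for low-FST bases", {
  set.seed(22)
  s <- site_records(p1 = runif(200), p2 = runif(200))
  cv <- build_theoretical_curve(s, "hudson", eta_grid = seq(0, 0.3, 0.01))
  expect_true(all(diff(cv$points$rho) > 0))
  expect_equal(cv$points$rho[1], 0)

  # slope hw/(hb-hw) = (1-FST)/FST for the hudson basis: closely related
  # pairs (small FST) have much steeper rho-eta curves
  slope_for_fst <- function(fst) (1 - fst) / fst
  basis_low <- c(hw = 1 - 0.01, hb = 1)   # FST = 0.01
  basis_high <- c(hw = 1 - 0.15, hb = 1)  # FST = 0.15
  sl_low <- eta_from_rho(basis_low["hw"], basis_low["hb"], 1)^-1
  sl_high <- eta_from_rho(basis_high["hw"], basis_high["hb"], 1)^-1
  expect_equal(unname(sl_low), slope_for_fst(0.01), tolerance = 1e-12)
  expect_gt(sl_low, sl_high)
})

test_that("inflated within-heterozygosity lowers constrained FST", {
  # constrained sites built from neutral sites by shrinking the
  # between-population frequency difference (the purging signature):
  # FST(S) > FST(N), i.e. rho > 0
  set.seed(23)
  p1 <- runif(300); p2 <- runif(300)
  neutral <- site_records(p1 = p1, p2 = p2)
  mid <- (p1 + p2) / 2
  shrink <- 0.5
  constrained <- site_records(p1 = mid + shrink * (p1 - mid),
                              p2 = mid + shrink * (p2 - mid),
                              func_class = "nonsynonymous")
  for (m in c("hudson", "nei")) {
    fst_s <- fst_ratio_of_averages(neutral, m)$value
    fst_n <- fst_ratio_of_averages(constrained, m)$value
    expect_gt(fst_s, fst_n)
    expect_gt(rho_from_fst(fst_s, fst_n), 0)
  }
})
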