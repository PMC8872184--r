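test_that("bootstrap is reproducible and leaves the point estimate alone", {
  s <- site_records(p1 = runif(50, 0.1, 0.9), p2 = runif(50, 0.1, 0.9))
  b1 <- bootstrap_fst(s, "hudson", R = 200, seed = 7)
  b2 <- bootstrap_fst(s, "hudson", R = 200, seed = 7)
  expect_identical(b1$bootstrap$replicates, b2$bootstrap$replicates)
  expect_equal(length(b1$bootstrap$replicates), 200L)
  expect_gte(b1$se, 0)
  # point estimate is the full-data ratio of averages, not the bootstrap mean
  expect_equal(b1$value, fst_ratio_of_averages(s, "hudson")$value)
  b3 <- bootstrap_fst(s, "hudson", R = 200, seed = 8)
  expect_false(identical(b1$bootstrap$replicates, b3$bootstrap$replicates))
})

test_that("resampling a constant panel gives zero standard error", {
  s <- site_records(p1 = rep(0.2, 10), p2 = rep(0.8, 10))
  b <- bootstrap_fst(s, "hudson", R = 100, seed = 1)
  expect_equal(b$se, 0)
  expect_true(all(b$bootstrap$replicates == b$value))
})

test_that("two-site bootstrap matches the enumerated resample distribution", {
  # sites A=(1,0) and B=(0.5,0.5): the four equiprobable resamples give
  # {AA}->1, {AB},{BA}->2/3, {BB}->0; expected replicate mean 7/12
  s <- site_records(p1 = c(1, 0.5), p2 = c(0, 0.5))
  b <- bootstrap_fst(s, "hudson", R = 4000, seed = 5)
  reps <- b$bootstrap$replicates
  expect_true(all(reps %in% c(0, 2 / 3, 1)))
  # sd of the enumerated distribution is ~0.363; R = 4000 puts the
  # Monte Carlo error of the mean near 0.006
  expect_equal(mean(reps), 7 / 12, tolerance = 0.02)
  expect_equal(b$bootstrap$n_redrawn, 0L)
})

test_that("bootstrap se scales like 1/sqrt(n) on iid panels", {
  set.seed(41)
  se_at <- function(n) {
    mean(vapply(1:20, function(i) {
      s <- site_records(p1 = runif(n), p2 = runif(n))
      bootstrap_fst(s, "hudson", R = 200, seed = i)$se
    }, numeric(1)))
  }
  r <- se_at(100) / se_at(400)
  expect_gt(r, 2 * 0.7)  # within 30% of the ideal factor 2
  expect_lt(r, 2 * 1.3)
})

test_that("z test matches normal-theory arithmetic", {
  a <- list(value = 0.154, se = 0.002)
  b <- list(value = 0.082, se = 0.003)
  zt <- z_test(a, b, "one")
  expect_equal(zt$z, 0.072 / sqrt(0.002^2 + 0.003^2), tolerance = 1e-12)
  expect_equal(zt$z, 19.97, tolerance = 0.01)
  expect_lt(zt$p, 0.01)

  same <- z_test(a, a, "one")
  expect_equal(same$z, 0)
  expect_equal(same$p, 0.5)

  sw <- z_test(b, a, "one")
  expect_equal(sw$z, -zt$z)
  two <- z_test(a, b, "two")
  expect_equal(two$p, 2 * zt$p, tolerance = 1e-12)

  expect_error(z_test(list(value = 1, se = 0), list(value = 2, se = 0)),
               "zero")
  expect_error(z_test(list(value = 1, se = NA), b), "standard error")
})

test_that("child seeds are a stable counter scheme", {
  expect_identical(child_seed(1, 1), child_seed(1, 1))
  expect_false(child_seed(1, 1) == child_seed(1, 2))
  expect_false(child_seed(1, 1) == child_seed(2, 1))
  expect_true(child_seed(2147483646, 1000) < 2^31)
})

test_that("paired rho/eta bootstrap propagates both class uncertainties", {
  set.seed(42)
  p1 <- runif(200); p2 <- runif(200)
  mid <- (p1 + p2) / 2
  neutral <- site_records(p1 = p1, p2 = p2)
  constrained <- site_records(p1 = mid + 0.6 * (p1 - mid),
                              p2 = mid + 0.6 * (p2 - mid),
                              func_class = "nonsynonymous")
  br <- bootstrap_rho_eta(neutral, constrained, "hudson", R = 300, seed = 3)
  expect_equal(br$rho, rho_from_fst(br$fst_neutral$value,
                                    br$fst_constrained$value))
  expect_gt(br$rho, 0)
  expect_gt(br$rho_se, 0)
  expect_gt(br$eta_se, 0)
  expect_equal(length(br$rho_replicates), 300L)
  br2 <- bootstrap_rho_eta(neutral, constrained, "hudson", R = 300, seed = 3)
  expect_identical(br$rho_replicates, br2$rho_replicates)
})
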