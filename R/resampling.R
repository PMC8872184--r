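#' Derive a reproducible child seed from a master seed
#'
#' Per-class bootstrap runs are seeded independently so that adding or
#' removing one class never perturbs the replicates of another. The scheme is
#' a plain counter: `(master + 10007 * counter) mod (2^31 - 1)`, where
#' `counter` is the 1-based index of the class in the analysis.
#'
#' @param master Integer master seed.
#' @param counter Positive integer index of the randomness consumer.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(master, counter) {
  as.integer((as.numeric(master) + 10007 * as.numeric(counter)) %% 2147483647)
}

#' Bootstrap standard error for ratio-of-averages FST
#'
#' Resamples SNPs (the sites of the class being estimated) with replacement
#' and recomputes the ratio-of-averages FST for each pseudoreplicate. The
#' standard error is the sample standard deviation (denominator `R - 1`) of
#' the replicate values. The reported point estimate remains the
#' ratio-of-averages on the original sites, not the bootstrap mean.
#'
#' A replicate whose resampled denominator sums to zero is redrawn and
#' counted; more than `R` redraws in total aborts with an error.
#'
#' @param sites A `site_records` table with at least two informative sites.
#' @param method `"hudson"` or `"nei"`.
#' @param R Number of bootstrap replicates (default 1000).
#' @param seed Integer seed recorded in the result; the replicate vector is
#'   bit-identical across runs with the same seed and input.
#' @return An `fst_estimate` (see [fst_ratio_of_averages()]) with `se`
#'   filled in and a `bootstrap` element: list with `replicates`, `R`,
#'   `seed` and `n_redrawn`.
#' @examples
#' s <- site_records(p1 = c(1, 0.5, 0.2), p2 = c(0, 0.5, 0.8))
#' bootstrap_fst(s, "hudson", R = 100, seed = 1)
#' @export
bootstrap_fst <- function(sites, method = c("hudson", "nei"), R = 1000L,
                          seed = 1L) {
  method <- match.arg(method)
  est <- fst_ratio_of_averages(sites, method)
  terms <- fst_terms(sites, method)
  terms <- terms[terms$den > 0, , drop = FALSE]
  n <- nrow(terms)
  if (n < 2L) {
    stop("bootstrap requires at least two informative sites", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  reps <- numeric(R)
  n_redrawn <- 0L
  for (r in seq_len(R)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      den <- sum(terms$den[idx])
      if (den > 0) break
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > R) {
        stop("bootstrap failed: more than R zero-denominator resamples",
             call. = FALSE)
      }
    }
    reps[r] <- sum(terms$num[idx]) / den
  }
  est$se <- stats::sd(reps)
  est$bootstrap <- list(replicates = reps, R = R, seed = seed,
                        n_redrawn = n_redrawn)
  est
}

# Save/restore the global RNG state so seeded helpers do not clobber the
# caller's stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Z-test for a difference between two FST estimates
#'
#' Tests whether one FST estimate (typically the neutral class) exceeds
#' another (a constrained class) using their bootstrap standard errors:
#' \deqn{z = (a - b) / \sqrt{se_a^2 + se_b^2}}
#' with the p-value from the standard normal distribution. The default is
#' one-sided (alternative: `a > b`, the hypothesis that neutral
#' differentiation is higher); `sided = "two"` gives the two-sided p-value.
#'
#' @param fst_a,fst_b `fst_estimate` objects carrying `se` (from
#'   [bootstrap_fst()]), or plain lists with `value` and `se`.
#' @param sided `"one"` or `"two"`.
#' @return List with `z`, `p` and `sided`.
#' @export
z_test <- function(fst_a, fst_b, sided = c("one", "two")) {
  sided <- match.arg(sided)
  se_a <- fst_a$se
  se_b <- fst_b$se
  if (is.na(se_a) || is.na(se_b)) {
    stop("both estimates need a standard error (run bootstrap_fst first)",
         call. = FALSE)
  }
  if (se_a == 0 && se_b == 0) {
    stop("both standard errors are zero; z statistic undefined",
         call. = FALSE)
  }
  z <- (fst_a$value - fst_b$value) / sqrt(se_a^2 + se_b^2)
  p <- if (sided == "one") stats::pnorm(z, lower.tail = FALSE)
       else 2 * stats::pnorm(abs(z), lower.tail = FALSE)
  list(z = z, p = p, sided = sided)
}

#' Bootstrap uncertainty for rho and eta
#'
#' Resamples the neutral and constrained classes independently (a paired
#' resample across classes is impossible, as the classes share no sites),
#' recomputing the reduction `rho` and predicted `eta` for each replicate
#' pair. The curve basis is re-derived from each neutral resample so the
#' replicate chain mirrors the full estimation pipeline.
#'
#' @param neutral_sites,constrained_sites `site_records` tables for the two
#'   classes.
#' @param method `"hudson"` or `"nei"`.
#' @param R Number of replicate pairs.
#' @param seed Integer seed; neutral and constrained streams are derived via
#'   [child_seed()] counters 1 and 2.
#' @return List with point estimates (`rho`, `eta`, `fst_neutral`,
#'   `fst_constrained`), standard errors `rho_se` and `eta_se`, and the
#'   replicate vectors.
#' @export
bootstrap_rho_eta <- function(neutral_sites, constrained_sites,
                              method = c("hudson", "nei"), R = 1000L,
                              seed = 1L) {
  method <- match.arg(method)
  bs_n <- bootstrap_fst(neutral_sites, method, R, child_seed(seed, 1L))
  bs_c <- bootstrap_fst(constrained_sites, method, R, child_seed(seed, 2L))
  hb <- bs_n$denominator_mean
  hw <- hb - bs_n$numerator_mean
  rho_hat <- rho_from_fst(bs_n$value, bs_c$value)
  eta_hat <- suppressWarnings(eta_from_rho(hw, hb, rho_hat))
  fst_n_reps <- bs_n$bootstrap$replicates
  rho_reps <- 1 - bs_c$bootstrap$replicates / fst_n_reps
  # per-replicate basis ratio (hb - hw)/hw = fst/(1 - fst) for hudson;
  # for nei the same identity holds with the (ht, hs) basis
  eta_reps <- rho_reps * fst_n_reps / (1 - fst_n_reps)
  list(
    rho = rho_hat, eta = eta_hat,
    fst_neutral = bs_n, fst_constrained = bs_c,
    rho_se = stats::sd(rho_reps), eta_se = stats::sd(eta_reps),
    rho_replicates = rho_reps, eta_replicates = eta_reps,
    method = method, R = R, seed = seed
  )
}
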