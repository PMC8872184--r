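#' Proportional reduction of FST at constrained sites
#'
#' The reduction statistic
#' \deqn{\rho = 1 - F_{ST}(N) / F_{ST}(S)}
#' measures how much smaller the fixation index of a selectively constrained
#' (nonsynonymous) SNP class is than that of the neutral (synonymous) class.
#' \eqn{\rho = 0} when the two classes are equally differentiated and
#' \eqn{\rho = 1} when differentiation at constrained sites is erased
#' entirely. Empirical \eqn{\rho} can be slightly negative by sampling noise;
#' it is returned as-is.
#'
#' @param fst_neutral Neutral-class FST, must be positive.
#' @param fst_constrained Constrained-class FST.
#' @return The reduction \eqn{\rho} (vectorized over `fst_constrained`).
#' @examples
#' rho_from_fst(0.154, 0.082)  # ~0.47: a 47% reduction
#' @export
rho_from_fst <- function(fst_neutral, fst_constrained) {
  if (any(!is.finite(fst_neutral)) || any(fst_neutral <= 0)) {
    stop("fst_neutral must be positive to define the reduction rho",
         call. = FALSE)
  }
  1 - fst_constrained / fst_neutral
}

check_curve_basis <- function(hw, hb_or_ht) {
  if (!is.finite(hw) || !is.finite(hb_or_ht) || hw <= 0 || hb_or_ht <= hw) {
    stop("degenerate curve basis: need hb (or ht) > hw > 0; got hw = ", hw,
         ", hb_or_ht = ", hb_or_ht, call. = FALSE)
  }
  invisible(NULL)
}

#' Theoretical rho for a given excess fraction eta
#'
#' Under the model in which the fraction of (neutral + slightly deleterious)
#' variation segregating within populations exceeds that segregating between
#' populations by a factor \eqn{1+\eta} (\eqn{f_w = f_b(1+\eta)}), the
#' expected reduction of constrained-site FST is
#' \deqn{\rho = 1 - \frac{H_b - H_w(1+\eta)}{H_b - H_w}
#'            = \eta \frac{H_w}{H_b - H_w}}
#' where \eqn{H_w} and \eqn{H_b} are the neutral-class within- and
#' between-population heterozygosities (for the Nei form, substitute
#' \eqn{H_T} for \eqn{H_b} and \eqn{H_S} for \eqn{H_w}). The slope
#' \eqn{H_w/(H_b - H_w)} equals \eqn{(1 - F_{ST})/F_{ST}} for the Hudson
#' form, so weakly differentiated population pairs have much steeper
#' rho-eta curves.
#'
#' @param hw Within-population neutral heterozygosity average, `> 0`.
#' @param hb_or_ht Between-population (Hudson) or total (Nei) neutral
#'   heterozygosity average; must exceed `hw`.
#' @param eta Excess within-population deleterious fraction(s), nonnegative
#'   in the model (negative values are evaluated algebraically).
#' @return Theoretical \eqn{\rho}, vectorized over `eta`.
#' @examples
#' rho_from_eta(hw = 0.8, hb_or_ht = 1.0, eta = 0.05)  # 0.20
#' @export
rho_from_eta <- function(hw, hb_or_ht, eta) {
  check_curve_basis(hw, hb_or_ht)
  1 - (hb_or_ht - hw * (1 + eta)) / (hb_or_ht - hw)
}

#' Predict eta from an observed reduction rho
#'
#' Exact algebraic inversion of the rho-eta relationship (see
#' [rho_from_eta()]):
#' \deqn{\eta = \rho \frac{H_b - H_w}{H_w}}
#' For the Hudson basis this is \eqn{\eta = \rho \, F_{ST}/(1 - F_{ST})}
#' with the neutral-class FST. A negative empirical `rho` yields a negative
#' `eta`, reported with a warning: it indicates noise, not a real deficit.
#'
#' @inheritParams rho_from_eta
#' @param rho Observed reduction(s), typically from [rho_from_fst()].
#' @return Predicted \eqn{\eta}, vectorized over `rho`.
#' @examples
#' eta_from_rho(hw = 0.846, hb_or_ht = 1, rho = 0.47)  # ~0.0855, i.e. 8.6%
#' @export
eta_from_rho <- function(hw, hb_or_ht, rho) {
  check_curve_basis(hw, hb_or_ht)
  eta <- rho * (hb_or_ht - hw) / hw
  if (any(is.finite(eta) & eta < 0)) {
    warning("negative rho produced negative eta; ",
            "constrained-class FST exceeded neutral-class FST (noise?)",
            call. = FALSE)
  }
  eta
}

#' Theoretical rho-eta curve from neutral sites
#'
#' Builds the basis (`hw`, `hb_or_ht`) of the theoretical rho-eta
#' relationship from the neutral (synonymous) sites of a panel, using the
#' same ratio-of-averages sums as the FST estimator — the numerator and
#' denominator means of [fst_ratio_of_averages()] — so that the empirical
#' reduction and the curve are internally consistent. Evaluates the curve on
#' a grid of eta values.
#'
#' @param neutral_sites A `site_records` table of neutral-class sites.
#' @param method `"hudson"` or `"nei"`.
#' @param eta_grid Numeric vector of eta values at which to evaluate.
#' @return An object of class `theoretical_curve`: list with `hw`,
#'   `hb_or_ht`, `method`, `slope` (`hw / (hb_or_ht - hw)`), `fst_neutral`,
#'   and `points`, a data frame of (`eta`, `rho`) pairs.
#' @export
build_theoretical_curve <- function(neutral_sites, method = c("hudson", "nei"),
                                    eta_grid = seq(0, 0.2, by = 0.005)) {
  method <- match.arg(method)
  est <- fst_ratio_of_averages(neutral_sites, method)
  hb_or_ht <- est$denominator_mean
  hw <- hb_or_ht - est$numerator_mean  # mean(hs) over the retained sites
  check_curve_basis(hw, hb_or_ht)
  eta_grid <- sort(unique(eta_grid))
  structure(
    list(
      hw = hw,
      hb_or_ht = hb_or_ht,
      method = method,
      slope = hw / (hb_or_ht - hw),
      fst_neutral = est$value,
      points = data.frame(eta = eta_grid,
                          rho = rho_from_eta(hw, hb_or_ht, eta_grid))
    ),
    class = "theoretical_curve"
  )
}

#' @export
print.theoretical_curve <- function(x, ...) {
  cat(sprintf(
    "Theoretical rho-eta curve (%s basis)\n  hw = %.6g, %s = %.6g, neutral FST = %.6g\n  slope drho/deta = %.6g over %d grid points\n",
    x$method, x$hw, if (x$method == "hudson") "hb" else "ht",
    x$hb_or_ht, x$fst_neutral, x$slope, nrow(x$points)))
  invisible(x)
}

#' @export
plot.theoretical_curve <- function(x, ..., overlay = NULL) {
  plot(x$points$eta, x$points$rho, type = "l",
       xlab = expression(eta), ylab = expression(rho),
       main = sprintf("rho-eta relationship (%s)", x$method), ...)
  if (!is.null(overlay)) {
    points(overlay$eta, overlay$rho, col = "red", pch = 19)
  }
  invisible(x)
}
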