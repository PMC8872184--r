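#' Per-site heterozygosity components
#'
#' For each site with derived-allele frequencies \eqn{p_1, p_2}, computes the
#' three heterozygosity terms underlying the Hudson and Nei (GST)
#' fixation-index estimators:
#' \deqn{H_S = p_1(1-p_1) + p_2(1-p_2)}
#' \deqn{H_B = p_1(1-p_2) + p_2(1-p_1)}
#' \deqn{H_T = 2\bar p(1-\bar p), \quad \bar p = (p_1+p_2)/2}
#' where \eqn{H_S} is the within-population term (the sum over the two
#' populations), \eqn{H_B} the between-population term, and \eqn{H_T} the
#' total-population term. The identity \eqn{H_B - H_S = (p_1 - p_2)^2} holds
#' exactly.
#'
#' @param sites A `site_records` table, or anything accepted by
#'   [validate_site_records()].
#' @return A data frame with columns `hs`, `hb`, `ht`, one row per site.
#' @examples
#' het_components(site_records(p1 = 0.2, p2 = 0.8))
#' @export
het_components <- function(sites) {
  sites <- validate_site_records(as.data.frame(sites))
  p1 <- sites$p1
  p2 <- sites$p2
  pbar <- (p1 + p2) / 2
  data.frame(
    hs = p1 * (1 - p1) + p2 * (1 - p2),
    hb = p1 * (1 - p2) + p2 * (1 - p1),
    ht = 2 * pbar * (1 - pbar)
  )
}

fst_terms <- function(sites, method = c("hudson", "nei")) {
  method <- match.arg(method)
  h <- het_components(sites)
  if (method == "hudson") {
    data.frame(num = h$hb - h$hs, den = h$hb)
  } else {
    data.frame(num = h$ht - h$hs, den = h$ht)
  }
}

#' Multi-SNP FST by the ratio-of-averages combination
#'
#' Combines per-site heterozygosity terms across SNPs by averaging the
#' numerator and denominator of the estimator separately and taking the ratio
#' of the two averages (Bhatia-style combination), rather than averaging
#' per-site ratios. Per-site terms are `hb - hs` over `hb` for the Hudson
#' estimator and `ht - hs` over `ht` for the Nei (GST) estimator.
#'
#' Sites whose denominator term is zero (monomorphic in both populations for
#' the derived allele, i.e. uninformative) contribute to neither average;
#' their count is recorded in the result. Negative per-site numerators
#' (possible under Nei when `hs > ht`) are retained as-is: the combination is
#' defined on sums, and only the final ratio is the estimate.
#'
#' @param sites A `site_records` table.
#' @param method `"hudson"` or `"nei"`.
#' @return An object of class `fst_estimate`: a list with `value`, `se`
#'   (`NA` here; see [bootstrap_fst()]), `n_sites` (informative sites used),
#'   `n_excluded` (zero-denominator sites dropped), `method`,
#'   `numerator_mean` and `denominator_mean`.
#' @examples
#' s <- site_records(p1 = c(1, 0.5), p2 = c(0, 0.5))
#' fst_ratio_of_averages(s, "hudson")  # 2/3, not the mean of per-site ratios
#' @seealso [bootstrap_fst()] for the bootstrap standard error.
#' @export
fst_ratio_of_averages <- function(sites, method = c("hudson", "nei")) {
  method <- match.arg(method)
  terms <- fst_terms(sites, method)
  keep <- terms$den > 0
  if (!any(keep)) {
    stop("empty class: no informative sites with a nonzero '", method,
         "' denominator", call. = FALSE)
  }
  num_mean <- mean(terms$num[keep])
  den_mean <- mean(terms$den[keep])
  structure(
    list(
      value = num_mean / den_mean,
      se = NA_real_,
      n_sites = sum(keep),
      n_excluded = sum(!keep),
      method = method,
      numerator_mean = num_mean,
      denominator_mean = den_mean
    ),
    class = "fst_estimate"
  )
}

#' @export
print.fst_estimate <- function(x, ...) {
  cat(sprintf("FST (%s, ratio of averages): %.6g", x$method, x$value))
  if (!is.na(x$se)) cat(sprintf(" (bootstrap se %.3g)", x$se))
  cat(sprintf("\n  %d informative sites (%d excluded, zero denominator)\n",
              x$n_sites, x$n_excluded))
  invisible(x)
}
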