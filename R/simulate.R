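#' Configuration for the two-population forward simulator
#'
#' Collects the parameters of the synthetic panel generator (see
#' [simulate_panel()]). Defaults describe a deliberately small but
#' mechanistically faithful scenario: two daughter populations of 2000
#' haploid genomes each, diverged 200 generations, 50,000 neutral plus
#' 50,000 deleterious standing variants, and genic selection of strength
#' `s = 0.005` against each derived deleterious allele (so `2*n_pop*s = 20`,
#' firmly in the purging regime).
#'
#' @param n_pop Haploid population size of each daughter population.
#' @param t_div Divergence time in generations since the split.
#' @param n_neutral,n_deleterious Numbers of neutral (synonymous) and
#'   deleterious (nonsynonymous) segregating sites at the split.
#' @param s Selection coefficient against the derived allele at deleterious
#'   sites, in `[0, 1)`. `s = 0` gives the null model in which the
#'   "deleterious" class is actually neutral.
#' @param seed Integer seed for the whole simulation.
#' @param cadd_slope,cadd_noise_sd Parameters of the synthetic C-score map:
#'   a nonsynonymous site with selection coefficient `s` receives
#'   `cadd_slope * s` plus Gaussian noise (sd `cadd_noise_sd`), truncated at
#'   zero. The defaults put `s = 0.005` sites near C-score 30, so the
#'   default panels exercise the upper deleteriousness bins.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pop = 2000L, t_div = 200L, n_neutral = 50000L,
                       n_deleterious = 50000L, s = 0.005, seed = 20220194L,
                       cadd_slope = 6000, cadd_noise_sd = 2) {
  stopifnot(n_pop >= 2, t_div >= 0, n_neutral >= 1, n_deleterious >= 0,
            s >= 0, s < 1)
  structure(list(n_pop = as.integer(n_pop), t_div = as.integer(t_div),
                 n_neutral = as.integer(n_neutral),
                 n_deleterious = as.integer(n_deleterious),
                 s = s, seed = as.integer(seed),
                 cadd_slope = cadd_slope, cadd_noise_sd = cadd_noise_sd),
            class = "sim_config")
}

# Ancestral frequencies of standing variants. Neutral sites follow the
# classic 1/x site-frequency spectrum on the grid {1/n, ..., (n-1)/n};
# deleterious sites follow the same law reweighted toward low frequency by
# exp(-2 * n_pop * s * x), the mutation-selection skew for genic selection.
draw_initial_freqs <- function(n_sites, n_pop, s) {
  x <- seq_len(n_pop - 1L) / n_pop
  w <- 1 / x
  if (s > 0) w <- w * exp(-2 * n_pop * s * x)
  sample(x, n_sites, replace = TRUE, prob = w / sum(w))
}

# One population, t_div generations of Wright-Fisher reproduction:
# deterministic genic selection against the derived allele,
# p' = p(1 - s) / (1 - p s), followed by binomial drift at size n_pop.
evolve_freqs <- function(p, n_pop, t_div, s) {
  for (g in seq_len(t_div)) {
    if (s > 0) p <- p * (1 - s) / (1 - p * s)
    p <- stats::rbinom(length(p), n_pop, p) / n_pop
  }
  p
}

#' Simulate a two-population SNP panel under purifying selection
#'
#' Forward Wright-Fisher simulation of standing variation in two populations
#' that split from a common ancestor `t_div` generations ago. Each site
#' starts at an ancestral frequency drawn from a 1/x spectrum (deleterious
#' sites reweighted toward rare frequencies by the selection strength), then
#' the two daughter populations evolve independently: at deleterious sites a
#' deterministic genic-selection update precedes binomial drift each
#' generation. No new mutations arise after the split. Purifying selection
#' purges derived deleterious alleles over time, so the deleterious class
#' retains proportionally more of its heterozygosity within populations than
#' between them — the mechanism that depresses constrained-site FST.
#'
#' Neutral sites are labelled `synonymous`; deleterious sites are labelled
#' `nonsynonymous` and receive a synthetic C-score increasing in `s` (see
#' [sim_config()]).
#'
#' @param config A [sim_config()].
#' @return A `simulated_panel`: list with `sites` (a `site_records` table
#'   with truth column `truth_s`), `config`, and `realized` — the truth
#'   summaries `fw`, `fb` (ratios of deleterious- to neutral-class
#'   within/between heterozygosity) and `eta_true = fw/fb - 1`.
#' @examples
#' panel <- simulate_panel(sim_config(n_neutral = 500, n_deleterious = 500,
#'                                    t_div = 50, seed = 1))
#' panel$realized$eta_true
#' @export
simulate_panel <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  n_neu <- config$n_neutral
  n_del <- config$n_deleterious
  p0_neu <- draw_initial_freqs(n_neu, config$n_pop, 0)
  p0_del <- if (n_del > 0) {
    draw_initial_freqs(n_del, config$n_pop, config$s)
  } else numeric(0)

  p0 <- c(p0_neu, p0_del)
  s_vec <- c(rep(0, n_neu), rep(config$s, n_del))
  # evolve both classes jointly per population; selection applied only where
  # s > 0, via the class split below
  evolve_mixed <- function(p) {
    neu <- evolve_freqs(p[seq_len(n_neu)], config$n_pop, config$t_div, 0)
    del <- if (n_del > 0) {
      evolve_freqs(p[n_neu + seq_len(n_del)], config$n_pop, config$t_div,
                   config$s)
    } else numeric(0)
    c(neu, del)
  }
  p1 <- evolve_mixed(p0)
  p2 <- evolve_mixed(p0)
  if (all(p1 == 0 | p1 == 1) && all(p2 == 0 | p2 == 1) && config$t_div == 0) {
    stop("degenerate configuration: all sites fixed at the split",
         call. = FALSE)
  }

  c_score <- rep(NA_real_, n_neu + n_del)
  if (n_del > 0) {
    raw <- config$cadd_slope * config$s +
      stats::rnorm(n_del, 0, config$cadd_noise_sd)
    c_score[n_neu + seq_len(n_del)] <- pmax(raw, 0)
  }
  sites <- site_records(
    p1 = p1, p2 = p2,
    func_class = rep(c("synonymous", "nonsynonymous"), c(n_neu, n_del)),
    c_score = c_score,
    chrom = "sim", pos = seq_len(n_neu + n_del),
    truth_s = s_vec
  )
  structure(list(sites = sites, config = config,
                 realized = realized_summaries(sites)),
            class = "simulated_panel")
}

# Truth summaries defined from realized class heterozygosities: fw and fb
# are the deleterious-to-neutral ratios of the within- and between-population
# heterozygosity sums, and eta_true = fw/fb - 1 restates fw = fb(1 + eta).
realized_summaries <- function(sites) {
  h <- het_components(sites)
  neu <- sites$func_class == "synonymous"
  del <- !neu
  if (!any(del) || sum(h$hs[neu]) == 0 || sum(h$hb[neu]) == 0 ||
      sum(h$hb[del]) == 0) {
    return(list(fw = NA_real_, fb = NA_real_, eta_true = NA_real_))
  }
  fw <- sum(h$hs[del]) / sum(h$hs[neu])
  fb <- sum(h$hb[del]) / sum(h$hb[neu])
  list(fw = fw, fb = fb, eta_true = fw / fb - 1)
}

#' @export
print.simulated_panel <- function(x, ...) {
  cfg <- x$config
  if (is.null(cfg)) {
    cat(sprintf(
      "Archetype panel: %d sites (%d neutral, %d constrained)\n  realized fw = %.4g, fb = %.4g, eta_true = %.4g\n",
      nrow(x$sites), sum(x$sites$func_class == "synonymous"),
      sum(x$sites$func_class == "nonsynonymous"),
      x$realized$fw, x$realized$fb, x$realized$eta_true))
    return(invisible(x))
  }
  cat(sprintf(
    "Simulated two-population panel: %d neutral + %d deleterious sites\n  n_pop = %d (haploid), t_div = %d generations, s = %g, seed = %d\n  realized fw = %.4g, fb = %.4g, eta_true = %.4g\n",
    cfg$n_neutral, cfg$n_deleterious, cfg$n_pop, cfg$t_div, cfg$s, cfg$seed,
    x$realized$fw, x$realized$fb, x$realized$eta_true))
  invisible(x)
}

#' Exact archetype panel with closed-form FST, rho and eta
#'
#' Builds a panel from two elementary site types whose estimator output is
#' computable by hand, for end-to-end verification: "shared" sites with the
#' same derived-allele frequency `p` in both populations (numerator 0,
#' Hudson denominator `2p(1-p)`) and "fixed-difference" sites at `(1, 0)`
#' (numerator and denominator 1). The Hudson FST of a class with `a` shared
#' and `b` fixed sites is exactly `b / (a * 2p(1-p) + b)`, so the target
#' rho and eta of any neutral/constrained composition are known before the
#' pipeline runs.
#'
#' @param n_shared Count of shared-polymorphism sites in the neutral class.
#' @param p_shared Their common derived-allele frequency, in `(0, 1)`.
#' @param n_fixed Count of fixed-difference sites in the neutral class.
#' @param r_shared,r_fixed Multipliers giving the constrained class
#'   `round(r_shared * n_shared)` shared and `round(r_fixed * n_fixed)`
#'   fixed sites. `r_fixed < r_shared` mimics purging of between-population
#'   differences at constrained sites.
#' @param c_score C-score assigned to every constrained site (default 35,
#'   the top default bin).
#' @return A `simulated_panel` (no drift, no randomness; `truth_s` is `NA`).
#' @examples
#' ap <- build_archetype_panel(n_shared = 100, p_shared = 0.5, n_fixed = 50)
#' fst_ratio_of_averages(ap$sites[ap$sites$func_class == "synonymous", ],
#'                       "hudson")$value  # exactly 0.5
#' @export
build_archetype_panel <- function(n_shared, p_shared = 0.5, n_fixed,
                                  r_shared = 1, r_fixed = 1, c_score = 35) {
  stopifnot(n_shared >= 0, n_fixed >= 0, n_shared + n_fixed > 0,
            p_shared > 0, p_shared < 1)
  m_shared <- as.integer(round(r_shared * n_shared))
  m_fixed <- as.integer(round(r_fixed * n_fixed))
  if (m_shared + m_fixed == 0L) {
    stop("degenerate archetype: constrained class has no sites", call. = FALSE)
  }
  p1 <- c(rep(p_shared, n_shared), rep(1, n_fixed),
          rep(p_shared, m_shared), rep(1, m_fixed))
  p2 <- c(rep(p_shared, n_shared), rep(0, n_fixed),
          rep(p_shared, m_shared), rep(0, m_fixed))
  cls <- rep(c("synonymous", "nonsynonymous"),
             c(n_shared + n_fixed, m_shared + m_fixed))
  sites <- site_records(
    p1 = p1, p2 = p2, func_class = cls,
    c_score = ifelse(cls == "nonsynonymous", c_score, NA_real_),
    chrom = "arch", pos = seq_along(p1),
    truth_s = NA_real_
  )
  structure(list(sites = sites, config = NULL,
                 realized = realized_summaries(sites)),
            class = "simulated_panel")
}
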