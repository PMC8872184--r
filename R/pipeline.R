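#' End-to-end FST / rho / eta analysis of a SNP panel
#'
#' Runs the full analysis on a site table: per-class and per-C-score-bin
#' ratio-of-averages FST with bootstrap standard errors, the reduction
#' statistic rho of each constrained class relative to the neutral
#' (synonymous) class, the theoretical rho-eta curve built from the neutral
#' sites, the predicted excess fraction eta for each class, and the Z-test
#' comparing each constrained class against the neutral class. Optionally
#' repeats the class-level analysis on the rare-variant subset (derived
#' allele frequency below `rare_threshold`), the control for
#' frequency-spectrum differences between classes.
#'
#' Randomness is confined to the bootstrap. A single master `seed` drives
#' per-method, per-class child seeds through a fixed counter scheme
#' ([child_seed()] with counter `100 * method_index + class_index`), so the
#' replicates of one class are unaffected by adding or removing another.
#'
#' @param sites A `site_records` table, a `simulated_panel`, or the path to
#'   a frequency-table TSV ([read_freq_table()]).
#' @param methods Estimators to run: subset of `c("hudson", "nei")`, or
#'   `"both"`. Default Hudson.
#' @param scheme C-score [cadd_bin_scheme()] for stratifying nonsynonymous
#'   sites; bin rows appear only for bins holding at least two informative
#'   sites.
#' @param R Bootstrap replicates per class (default 1000).
#' @param seed Master integer seed.
#' @param sided Sidedness of the Z-test (`"one"`: neutral > constrained).
#' @param rare If `TRUE`, add a rare-variant control rerun at the class
#'   level.
#' @param rare_threshold Frequency cutoff of the control (default 0.005).
#' @param eta_grid Grid on which the theoretical curves are evaluated.
#' @return An `fst_report` list:
#'   \describe{
#'     \item{fst}{data frame: method, class, n_sites, n_excluded, fst, se.}
#'     \item{rho_eta}{data frame: method, class, rho, rho_se, eta, eta_se,
#'       z, p — constrained classes against the neutral class.}
#'     \item{curves}{named list of [build_theoretical_curve()] objects.}
#'     \item{rare}{the control `fst_report` (classes only), or `NULL`.}
#'     \item{provenance}{seed, problem sizes, drop counters, input checksum
#'       when a path was given.}
#'   }
#' @examples
#' panel <- build_archetype_panel(n_shared = 100, p_shared = 0.5,
#'                                n_fixed = 50, r_fixed = 0.5)
#' rep <- run_pipeline(panel, R = 100, seed = 1)
#' rep$rho_eta[, c("class", "rho", "eta")]
#' @export
run_pipeline <- function(sites, methods = "hudson",
                         scheme = cadd_bin_scheme(), R = 1000L, seed = 1L,
                         sided = c("one", "two"), rare = FALSE,
                         rare_threshold = 0.005,
                         eta_grid = seq(0, 0.2, by = 0.005)) {
  sided <- match.arg(sided)
  checksum <- NULL
  if (is.character(sites) && length(sites) == 1L) {
    checksum <- unname(tools::md5sum(sites))
    sites <- read_freq_table(sites)
  }
  if (inherits(sites, "simulated_panel")) sites <- sites$sites
  sites <- validate_site_records(as.data.frame(sites))
  if (identical(methods, "both")) methods <- c("hudson", "nei")
  methods <- match.arg(methods, c("hudson", "nei"), several.ok = TRUE)

  neutral <- sites[sites$func_class == "synonymous", , drop = FALSE]
  nsyn <- sites[sites$func_class == "nonsynonymous", , drop = FALSE]
  if (nrow(neutral) == 0L) stop("empty class: no synonymous (neutral) sites",
                                call. = FALSE)
  if (nrow(nsyn) == 0L) stop("empty class: no nonsynonymous sites",
                             call. = FALSE)
  bins <- assign_bin(sites, scheme)
  n_unscored <- sum(bins == "unscored", na.rm = TRUE)

  # constrained classes: the whole nonsynonymous set, then populated bins
  class_sets <- list(nonsynonymous = nsyn)
  for (lab in scheme$labels) {
    sel <- !is.na(bins) & bins == lab
    if (sum(sel & is_informative(sites)) >= 2L) {
      class_sets[[lab]] <- sites[sel, , drop = FALSE]
    }
  }

  fst_rows <- list()
  re_rows <- list()
  curves <- list()
  for (mi in seq_along(methods)) {
    m <- methods[mi]
    bs_n <- bootstrap_fst(neutral, m, R, child_seed(seed, 100L * mi))
    curves[[m]] <- build_theoretical_curve(neutral, m, eta_grid)
    hb <- bs_n$denominator_mean
    hw <- hb - bs_n$numerator_mean
    fst_n_reps <- bs_n$bootstrap$replicates
    fst_rows[[length(fst_rows) + 1L]] <- data.frame(
      method = m, class = "synonymous", n_sites = bs_n$n_sites,
      n_excluded = bs_n$n_excluded, fst = bs_n$value, se = bs_n$se)
    for (ci in seq_along(class_sets)) {
      cl <- names(class_sets)[ci]
      bs_c <- bootstrap_fst(class_sets[[ci]], m, R,
                            child_seed(seed, 100L * mi + ci))
      fst_rows[[length(fst_rows) + 1L]] <- data.frame(
        method = m, class = cl, n_sites = bs_c$n_sites,
        n_excluded = bs_c$n_excluded, fst = bs_c$value, se = bs_c$se)
      rho_hat <- rho_from_fst(bs_n$value, bs_c$value)
      eta_hat <- suppressWarnings(eta_from_rho(hw, hb, rho_hat))
      rho_reps <- 1 - bs_c$bootstrap$replicates / fst_n_reps
      eta_reps <- rho_reps * fst_n_reps / (1 - fst_n_reps)
      zt <- z_test(bs_n, bs_c, sided)
      re_rows[[length(re_rows) + 1L]] <- data.frame(
        method = m, class = cl, rho = rho_hat,
        rho_se = stats::sd(rho_reps), eta = eta_hat,
        eta_se = stats::sd(eta_reps), z = zt$z, p = zt$p)
    }
  }

  rare_report <- NULL
  if (isTRUE(rare)) {
    rare_sites <- rare_filter(sites, rare_threshold)
    rare_report <- run_pipeline(
      rare_sites, methods = methods,
      # class-level control only: a scheme with one edge keeps bins trivial
      scheme = scheme, R = R, seed = child_seed(seed, 9000L),
      sided = sided, rare = FALSE, eta_grid = eta_grid)
    rare_report$provenance$rare_threshold <- rare_threshold
    rare_report$provenance$mean_freq_by_class <-
      as.list(attr(rare_sites, "mean_freq_by_class"))
  }

  structure(
    list(
      fst = do.call(rbind, fst_rows),
      rho_eta = do.call(rbind, re_rows),
      curves = curves,
      rare = rare_report,
      provenance = list(
        seed = seed, R = R, methods = methods, sided = sided,
        n_sites = nrow(sites),
        n_synonymous = nrow(neutral), n_nonsynonymous = nrow(nsyn),
        n_unscored_nonsynonymous = n_unscored,
        bin_edges = scheme$edges,
        input_md5 = checksum
      )
    ),
    class = "fst_report"
  )
}

#' @export
print.fst_report <- function(x, ...) {
  cat("FST / rho / eta report\n")
  cat(sprintf("  %d sites (%d synonymous, %d nonsynonymous), seed %d, R = %d\n",
              x$provenance$n_sites, x$provenance$n_synonymous,
              x$provenance$n_nonsynonymous, x$provenance$seed,
              x$provenance$R))
  cat("\nFST by class:\n")
  print(x$fst, row.names = FALSE, digits = 4)
  cat("\nReduction and predicted excess fraction:\n")
  print(x$rho_eta, row.names = FALSE, digits = 4)
  if (!is.null(x$rare)) cat("\n(rare-variant control attached: $rare)\n")
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Serializes an `fst_report` as machine-readable files: `fst.tsv`,
#' `rho_eta.tsv`, one `curve_<method>.tsv` per estimator, and
#' `provenance.json`. The rare-variant control, when present, goes to a
#' `rare/` subdirectory in the same layout. Output is deterministic: the
#' same report writes byte-identical files.
#'
#' @param report An `fst_report` from [run_pipeline()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "fst_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  tsv(report$fst, "fst.tsv")
  tsv(report$rho_eta, "rho_eta.tsv")
  for (m in names(report$curves)) {
    cv <- report$curves[[m]]
    tsv(cbind(data.frame(method = m, hw = cv$hw, hb_or_ht = cv$hb_or_ht,
                         slope = cv$slope, fst_neutral = cv$fst_neutral),
              cv$points),
        paste0("curve_", m, ".tsv"))
  }
  jsonlite::write_json(report$provenance,
                       file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  if (!is.null(report$rare)) {
    write_report(report$rare, file.path(dir, "rare"))
  }
  invisible(dir)
}
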