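#' C-score bin scheme for nonsynonymous SNPs
#'
#' Defines the deleteriousness strata used to examine how FST declines with
#' selective constraint. The default scheme has seven bins with right-closed
#' edges at 5-point intervals: `<=5`, `(5,10]`, `(10,15]`, `(15,20]`,
#' `(20,25]`, `(25,30]`, `>30`. The lowest bin captures SNPs under relaxed
#' constraint and the top bin the highly constrained SNPs. Edges are
#' configurable; labels are derived from the edges.
#'
#' @param edges Strictly increasing numeric cut points.
#' @return A `bin_scheme` list with `edges`, `labels` and `n_bins`.
#' @examples
#' cadd_bin_scheme()            # the default seven categories
#' cadd_bin_scheme(c(10, 20))   # three coarse bins
#' @export
cadd_bin_scheme <- function(edges = c(5, 10, 15, 20, 25, 30)) {
  edges <- as.numeric(edges)
  if (length(edges) < 1L || is.unsorted(edges, strictly = TRUE)) {
    stop("edges must be strictly increasing", call. = FALSE)
  }
  k <- length(edges)
  labels <- c(
    paste0("<=", edges[1L]),
    if (k > 1L) sprintf("(%g,%g]", edges[-k], edges[-1L]),
    paste0(">", edges[k])
  )
  structure(list(edges = edges, labels = labels, n_bins = k + 1L),
            class = "bin_scheme")
}

#' Assign nonsynonymous SNPs to C-score bins
#'
#' Maps each site's C-score to a bin of `scheme`. Bins are right-closed, so a
#' score exactly on an edge falls in the lower bin (a score of 5 is `<=5`).
#' Only scored nonsynonymous sites receive a bin: synonymous sites get `NA`
#' (they form the neutral class, never binned), and nonsynonymous sites with
#' a missing C-score are routed to the `"unscored"` level, which bin-level
#' analyses exclude.
#'
#' @param sites A `site_records` table.
#' @param scheme A [cadd_bin_scheme()].
#' @return Factor of length `nrow(sites)` with levels
#'   `c(scheme$labels, "unscored")`.
#' @export
assign_bin <- function(sites, scheme = cadd_bin_scheme()) {
  stopifnot(inherits(scheme, "bin_scheme"))
  breaks <- c(-Inf, scheme$edges, Inf)
  bin <- cut(sites$c_score, breaks = breaks, labels = scheme$labels,
             right = TRUE)
  bin <- factor(bin, levels = c(scheme$labels, "unscored"))
  nsyn <- sites$func_class == "nonsynonymous"
  bin[nsyn & is.na(sites$c_score)] <- "unscored"
  bin[!nsyn] <- NA
  bin
}

#' Orient alleles to the derived state
#'
#' Converts alternate-allele frequencies to derived-allele frequencies using
#' an inferred ancestral allele. If the ancestral allele equals the
#' reference, the alternate is derived and its frequency is kept; if it
#' equals the alternate, frequencies are flipped to `1 - freq`. When the
#' ancestral state is unknown or matches neither allele the site is flagged
#' unoriented and the alternate-allele frequency is kept: both FST
#' estimators are invariant under the flip, so orientation only matters for
#' frequency-conditioned analyses such as the rare-allele filter.
#'
#' @param ref,alt Character vectors of reference and alternate alleles.
#' @param ancestral Character vector of ancestral alleles; `NA` (or any
#'   non-matching value) marks an unknown state. Case-insensitive, as
#'   lower-case ancestral calls conventionally flag low confidence.
#' @param alt_freq1,alt_freq2 Alternate-allele frequencies in the two
#'   populations.
#' @return Data frame with columns `p1`, `p2` (derived-allele frequencies)
#'   and `oriented` (logical).
#' @export
orient_derived <- function(ref, alt, ancestral, alt_freq1, alt_freq2) {
  anc <- toupper(as.character(ancestral))
  ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt))
  flip <- !is.na(anc) & anc == alt
  oriented <- !is.na(anc) & (anc == ref | anc == alt)
  data.frame(
    p1 = ifelse(flip, 1 - alt_freq1, alt_freq1),
    p2 = ifelse(flip, 1 - alt_freq2, alt_freq2),
    oriented = oriented
  )
}

#' Rare-variant control filter
#'
#' Restricts a panel to rare derived variants, the control analysis that
#' checks whether FST differences between SNP classes merely reflect their
#' different allele-frequency spectra. A site is kept when its mean
#' derived-allele frequency across the two populations is strictly below
#' `threshold` and strictly above zero. The filter is idempotent and
#' monotone in the threshold.
#'
#' @param sites A `site_records` table.
#' @param threshold Frequency cutoff in `(0, 0.5]`; default 0.005 (0.5%).
#' @param require_oriented If `TRUE` and the table has an `oriented` column,
#'   additionally drop sites whose derived state could not be resolved
#'   (rarity of an unoriented allele is ambiguous).
#' @return The filtered `site_records` table, with attribute
#'   `"mean_freq_by_class"`: the per-functional-class mean frequency of the
#'   retained sites, the diagnostic showing the classes are frequency-matched
#'   after filtering.
#' @export
rare_filter <- function(sites, threshold = 0.005, require_oriented = FALSE) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 0.5) {
    stop("threshold must be a single frequency in (0, 0.5]", call. = FALSE)
  }
  mean_freq <- (sites$p1 + sites$p2) / 2
  keep <- mean_freq > 0 & mean_freq < threshold
  if (require_oriented && !is.null(sites$oriented)) {
    keep <- keep & sites$oriented
  }
  out <- sites[keep, , drop = FALSE]
  attr(out, "mean_freq_by_class") <-
    tapply((out$p1 + out$p2) / 2, out$func_class, mean)
  out
}
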