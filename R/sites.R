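#' Construct a validated table of SNP site records
#'
#' The central data container of the package: one row per biallelic SNP with
#' derived-allele frequencies in two populations, a functional class, and an
#' optional deleteriousness (CADD PHRED-like) score. All downstream
#' estimators consume this table.
#'
#' @param p1,p2 Numeric vectors of derived-allele frequencies in populations
#'   1 and 2, each in \[0, 1\].
#' @param func_class Character vector, each element `"synonymous"` or
#'   `"nonsynonymous"`. Synonymous sites form the neutral class.
#' @param c_score Numeric vector of nonnegative CADD PHRED-like scores, or
#'   `NA`. Missing scores are permitted; nonsynonymous sites without a score
#'   are excluded from bin-level analyses (see [assign_bin()]).
#' @param chrom,pos Optional chromosome labels and 1-based positions; defaults
#'   are synthetic placeholders.
#' @param ... Further per-site columns (e.g. `ref`, `alt`, `ancestral`,
#'   `truth_s`) carried through unchanged.
#'
#' @return A `data.frame` of class `site_records` with at least the columns
#'   `chrom`, `pos`, `p1`, `p2`, `func_class`, `c_score`.
#' @examples
#' site_records(p1 = c(0.2, 0.5), p2 = c(0.8, 0.5),
#'              func_class = c("synonymous", "nonsynonymous"),
#'              c_score = c(NA, 12))
#' @export
site_records <- function(p1, p2, func_class = "synonymous", c_score = NA_real_,
                         chrom = "sim", pos = seq_along(p1), ...) {
  n <- length(p1)
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    pos = rep_len(as.integer(pos), n),
    p1 = as.numeric(p1),
    p2 = rep_len(as.numeric(p2), n),
    func_class = rep_len(as.character(func_class), n),
    c_score = rep_len(as.numeric(c_score), n),
    ...,
    stringsAsFactors = FALSE
  )
  validate_site_records(df)
}

#' @rdname site_records
#' @param x A data frame holding site columns.
#' @export
validate_site_records <- function(x) {
  required <- c("p1", "p2", "func_class")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0L) {
    stop("site table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad_freq <- which(is.na(x$p1) | is.na(x$p2) |
                      x$p1 < 0 | x$p1 > 1 | x$p2 < 0 | x$p2 > 1)
  if (length(bad_freq) > 0L) {
    stop("derived-allele frequencies outside [0, 1] (or missing) at row(s): ",
         paste(utils::head(bad_freq, 10L), collapse = ", "),
         if (length(bad_freq) > 10L) " ...", call. = FALSE)
  }
  bad_class <- which(!x$func_class %in% c("synonymous", "nonsynonymous"))
  if (length(bad_class) > 0L) {
    stop("func_class must be 'synonymous' or 'nonsynonymous'; offending row(s): ",
         paste(utils::head(bad_class, 10L), collapse = ", "), call. = FALSE)
  }
  bad_score <- which(!is.na(x$c_score) & x$c_score < 0)
  if (!is.null(x$c_score) && length(bad_score) > 0L) {
    stop("c_score must be nonnegative; offending row(s): ",
         paste(utils::head(bad_score, 10L), collapse = ", "), call. = FALSE)
  }
  if (!inherits(x, "site_records")) class(x) <- c("site_records", class(x))
  x
}

#' Identify informative sites
#'
#' A site is informative unless the derived allele is absent from both
#' populations or fixed in both: such sites carry no information about either
#' diversity or differentiation.
#'
#' @param sites A `site_records` table (or any data frame with `p1`, `p2`).
#' @return Logical vector, one element per site.
#' @export
is_informative <- function(sites) {
  !((sites$p1 == 0 & sites$p2 == 0) | (sites$p1 == 1 & sites$p2 == 1))
}
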