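#' Read a per-site frequency table
#'
#' Reads the tab-separated "desk mode" input: one row per biallelic SNP with
#' the two population derived-allele frequencies, functional class and
#' (optionally) C-score. Required columns: `p1`, `p2`, `func_class`.
#' Recognised optional columns: `chrom`, `pos`, `ref`, `alt`, `ancestral`,
#' `c_score`, `truth_s`, `oriented`. Malformed rows are reported with their
#' line numbers and abort the read.
#'
#' @param path Path to a TSV file with a header row.
#' @return A validated `site_records` table.
#' @seealso [write_freq_table()], [simulate_panel()]
#' @export
read_freq_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          na.strings = c("NA", "", "."))
  if (nrow(df) == 0L) {
    stop("no sites: frequency table ", path, " is empty", call. = FALSE)
  }
  required <- c("p1", "p2", "func_class")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("frequency table ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (is.null(df$c_score)) df$c_score <- NA_real_
  if (is.null(df$chrom)) df$chrom <- "unknown"
  if (is.null(df$pos)) df$pos <- seq_len(nrow(df))
  bad <- which(is.na(df$p1) | is.na(df$p2) |
                 df$p1 < 0 | df$p1 > 1 | df$p2 < 0 | df$p2 > 1)
  if (length(bad) > 0L) {
    stop("invalid frequencies in ", path, " at line(s) ",
         paste(utils::head(bad + 1L, 10L), collapse = ", "),
         if (length(bad) > 10L) " ...",
         " (header is line 1)", call. = FALSE)
  }
  validate_site_records(df)
}

#' Write a frequency table to TSV
#'
#' Inverse of [read_freq_table()]; the format the simulator emits and the
#' estimation pipeline consumes.
#'
#' @param sites A `site_records` table (or a `simulated_panel`, whose
#'   `$sites` are written).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(sites, path) {
  if (inherits(sites, "simulated_panel")) sites <- sites$sites
  utils::write.table(as.data.frame(sites), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a sample-to-population panel file
#'
#' @param path TSV with columns `sample` and `pop` (header optional when the
#'   file has exactly two unnamed columns).
#' @return Named character vector mapping sample id to population label.
#' @export
read_panel_file <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("\\bsample\\b", first, ignore.case = TRUE)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (!has_header) names(df)[1:2] <- c("sample", "pop")
  names(df) <- tolower(names(df))
  if (!all(c("sample", "pop") %in% names(df))) {
    stop("panel file needs 'sample' and 'pop' columns", call. = FALSE)
  }
  if (anyDuplicated(df$sample)) {
    stop("panel file has duplicated sample ids", call. = FALSE)
  }
  stats::setNames(as.character(df$pop), as.character(df$sample))
}

autosome_chroms <- function() as.character(1:22)

#' Derive-oriented allele frequencies for two populations from a VCF
#'
#' Reads genotypes with \pkg{vcfR}, keeps biallelic autosomal SNVs only
#' (multiallelic records, indels and sex/other chromosomes are dropped and
#' counted), and computes the alternate-allele frequency separately for each
#' of the two requested populations as alternate-allele count over twice the
#' number of called genotypes (missing genotypes leave the denominator).
#' When the VCF carries an `AA` INFO key the ancestral allele is used to
#' orient frequencies to the derived allele (see [orient_derived()]).
#'
#' Functional class and C-score are not part of a VCF; sites default to
#' `nonsynonymous` with no score so that [attach_cadd()] (and any
#' class annotation the caller applies) can fill them in.
#'
#' @param vcf_path Path to a VCF file (plain or bgzipped).
#' @param panel Named character vector from [read_panel_file()].
#' @param pops Character vector of exactly two population labels.
#' @param autosomes Chromosome labels accepted as autosomal; `chr` prefixes
#'   are tolerated. Default `"1"..."22"`.
#' @return A `site_records` table with columns `chrom`, `pos`, `ref`, `alt`,
#'   `ancestral`, `p1`, `p2`, `oriented`, plus attribute `"drop_counts"`
#'   (named counts of records removed by each filter).
#' @export
read_vcf_frequencies <- function(vcf_path, panel, pops,
                                 autosomes = autosome_chroms()) {
  if (length(pops) != 2L) stop("pops must name exactly two populations",
                               call. = FALSE)
  absent <- setdiff(pops, unique(panel))
  if (length(absent) > 0L) {
    stop("population(s) not in panel: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  n0 <- nrow(fix)
  if (n0 == 0L) stop("no records in VCF ", vcf_path, call. = FALSE)

  chrom_plain <- sub("^chr", "", fix$CHROM)
  is_auto <- chrom_plain %in% autosomes
  is_snv <- nchar(fix$REF) == 1L & fix$REF %in% c("A", "C", "G", "T") &
    nchar(fix$ALT) == 1L & fix$ALT %in% c("A", "C", "G", "T")
  is_biallelic <- !grepl(",", fix$ALT, fixed = TRUE)
  keep <- is_auto & is_biallelic & is_snv
  drop_counts <- c(
    non_autosomal = sum(!is_auto),
    multiallelic = sum(is_auto & !is_biallelic),
    not_snv = sum(is_auto & is_biallelic & !is_snv)
  )
  if (!any(keep)) stop("no biallelic autosomal SNVs in ", vcf_path,
                       call. = FALSE)

  gt <- vcfR::extract.gt(vcf, element = "GT")[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]

  pop_freq <- function(pop) {
    samples <- names(panel)[panel == pop]
    cols <- intersect(samples, colnames(gt))
    if (length(cols) == 0L) {
      stop("no samples of population '", pop, "' found in the VCF",
           call. = FALSE)
    }
    g <- gt[, cols, drop = FALSE]
    alt_counts <- rowSums(matrix(
      vapply(g, count_alt_alleles, numeric(1)), nrow = nrow(g)))
    called <- rowSums(matrix(
      vapply(g, count_called_alleles, numeric(1)), nrow = nrow(g)))
    ifelse(called > 0, alt_counts / called, NA_real_)
  }
  f1 <- pop_freq(pops[1L])
  f2 <- pop_freq(pops[2L])

  aa <- extract_ancestral(fix$INFO)
  oriented <- orient_derived(fix$REF, fix$ALT, aa, f1, f2)

  ok <- !is.na(oriented$p1) & !is.na(oriented$p2)
  drop_counts["all_missing_genotypes"] <- sum(!ok)
  sites <- data.frame(
    chrom = fix$CHROM[ok], pos = as.integer(fix$POS[ok]),
    ref = fix$REF[ok], alt = fix$ALT[ok],
    ancestral = aa[ok],
    p1 = oriented$p1[ok], p2 = oriented$p2[ok],
    oriented = oriented$oriented[ok],
    func_class = "nonsynonymous", c_score = NA_real_,
    stringsAsFactors = FALSE
  )
  out <- validate_site_records(sites)
  attr(out, "drop_counts") <- drop_counts
  out
}

# allele tallies for one genotype string like "0/1", "1|1", "./."
count_alt_alleles <- function(g) {
  if (is.na(g)) return(0)
  al <- strsplit(g, "[/|]")[[1]]
  sum(al == "1")
}

count_called_alleles <- function(g) {
  if (is.na(g)) return(0)
  al <- strsplit(g, "[/|]")[[1]]
  sum(al %in% c("0", "1"))
}

extract_ancestral <- function(info) {
  aa <- rep(NA_character_, length(info))
  has <- !is.na(info) & grepl("(^|;)AA=", info)
  val <- sub(".*(^|;)AA=([^;|]*).*", "\\2", info[has])
  val[val == ""] <- NA_character_
  aa[has] <- val
  out <- substr(toupper(aa), 1L, 1L)
  out[out == ""] <- NA_character_
  out
}

#' Attach CADD scores to sites by exact variant key
#'
#' Joins a CADD-style TSV (columns `chrom`, `pos`, `ref`, `alt` and a
#' PHRED-scaled score column) onto a site table by the exact
#' (chrom, pos, ref, alt) key. Unmatched sites keep a missing score and are
#' later routed to the `"unscored"` bucket by [assign_bin()]. Duplicate keys
#' in the score file use the first occurrence, with a warning.
#'
#' @param sites A `site_records` table with `chrom`, `pos`, `ref`, `alt`.
#' @param cadd_tsv_path Path to the score TSV. Column names are matched
#'   case-insensitively; the score column is `phred` (fallback: the last
#'   numeric column).
#' @return `sites` with `c_score` filled where the join matched, plus
#'   attribute `"join_stats"` (matched / unmatched counts).
#' @export
attach_cadd <- function(sites, cadd_tsv_path) {
  cadd <- utils::read.delim(cadd_tsv_path, header = TRUE,
                            stringsAsFactors = FALSE, comment.char = "#")
  names(cadd) <- tolower(names(cadd))
  score_col <- if ("phred" %in% names(cadd)) "phred" else {
    num_cols <- names(cadd)[vapply(cadd, is.numeric, logical(1))]
    num_cols[length(num_cols)]
  }
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(cadd))) {
    stop("CADD table needs columns chrom, pos, ref, alt", call. = FALSE)
  }
  key <- function(df) paste(sub("^chr", "", df$chrom), df$pos, df$ref,
                            df$alt, sep = ":")
  ck <- key(cadd)
  if (anyDuplicated(ck)) {
    warning(sum(duplicated(ck)), " duplicate variant key(s) in CADD table; ",
            "first occurrence used", call. = FALSE)
  }
  idx <- match(key(sites), ck)
  hit <- !is.na(idx)
  sites$c_score[hit] <- cadd[[score_col]][idx[hit]]
  attr(sites, "join_stats") <- c(matched = sum(hit), unmatched = sum(!hit))
  sites
}
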