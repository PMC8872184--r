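# Shared in-code fixtures: tiny panels and a synthetic VCF with known truth.

# sites spanning the interesting cases: shared polymorphism, fixed
# difference, monomorphic-in-one, rare variants
toy_sites <- function() {
  site_records(
    p1 = c(0.2, 0.5, 1.0, 0.0, 0.004, 0.1),
    p2 = c(0.8, 0.5, 0.0, 0.3, 0.004, 0.0),
    func_class = c("synonymous", "synonymous", "nonsynonymous",
                   "nonsynonymous", "synonymous", "nonsynonymous"),
    c_score = c(NA, NA, 35, 12.3, NA, NA)
  )
}

# Deterministic two-population genotype set rendered as VCF text, with the
# genotype matrix kept so tests can tally frequencies independently.
# Includes records that must be filtered: triallelic, indel, chrX.
make_test_vcf <- function(path, n_records = 20L, n_per_pop = 4L, seed = 42L) {
  set.seed(seed)
  samples <- c(paste0("P1S", seq_len(n_per_pop)),
               paste0("P2S", seq_len(n_per_pop)))
  nucs <- c("A", "C", "G", "T")
  recs <- character(0)
  truth <- list()
  for (i in seq_len(n_records)) {
    ref <- sample(nucs, 1)
    alt <- sample(setdiff(nucs, ref), 1)
    # ancestral: ref, alt, other base, or absent
    aa_mode <- sample(c("ref", "alt", "other", "none"), 1)
    aa <- switch(aa_mode, ref = ref, alt = alt,
                 other = sample(setdiff(nucs, c(ref, alt)), 1), none = NA)
    gt_counts <- sample(0:2, 2 * n_per_pop, replace = TRUE)
    gt <- c("0/0", "0/1", "1/1")[gt_counts + 1L]
    miss <- sample(c(TRUE, FALSE), 2 * n_per_pop, replace = TRUE,
                   prob = c(0.1, 0.9))
    gt[miss] <- "./."
    info <- if (is.na(aa)) "DP=100" else paste0("AA=", aa, ";DP=100")
    recs[i] <- paste(c(as.character(1 + (i %% 22)), 1000 + i, ".", ref, alt,
                       "100", "PASS", info, "GT", gt), collapse = "\t")
    truth[[i]] <- list(ref = ref, alt = alt, aa = aa,
                       gt = gt, miss = miss)
  }
  junk <- c(
    paste(c("3", "99991", ".", "A", "G,T", "100", "PASS", "DP=5", "GT",
            rep("0/0", 2 * n_per_pop)), collapse = "\t"),
    paste(c("3", "99992", ".", "AT", "A", "100", "PASS", "DP=5", "GT",
            rep("0/0", 2 * n_per_pop)), collapse = "\t"),
    paste(c("X", "99993", ".", "A", "G", "100", "PASS", "DP=5", "GT",
            rep("0/1", 2 * n_per_pop)), collapse = "\t")
  )
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=AA,Number=1,Type=String,Description=\"Ancestral allele\">",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  writeLines(c(header, recs, junk), path)
  list(path = path, samples = samples, n_per_pop = n_per_pop, truth = truth)
}

write_test_panel <- function(path, n_per_pop = 4L) {
  writeLines(c("sample\tpop",
               paste0("P1S", seq_len(n_per_pop), "\tPOPA"),
               paste0("P2S", seq_len(n_per_pop), "\tPOPB")),
             path)
  path
}

# independent genotype tally oracle for one record of make_test_vcf truth
tally_freqs <- function(rec, n_per_pop) {
  gt <- rec$gt
  split_counts <- function(g) {
    al <- unlist(strsplit(g, "/", fixed = TRUE))
    c(alt = sum(al == "1"), called = sum(al %in% c("0", "1")))
  }
  pop_freq <- function(idx) {
    tc <- rowSums(vapply(gt[idx], split_counts, numeric(2)))
    if (tc["called"] == 0) NA_real_ else unname(tc["alt"] / tc["called"])
  }
  f1 <- pop_freq(seq_len(n_per_pop))
  f2 <- pop_freq(n_per_pop + seq_len(n_per_pop))
  if (!is.na(rec$aa) && rec$aa == rec$alt) {
    c(p1 = 1 - f1, p2 = 1 - f2)
  } else {
    c(p1 = f1, p2 = f2)
  }
}
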