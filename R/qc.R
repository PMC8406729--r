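#' Per-SNP summary statistics
#'
#' Call rate (non-missing fraction), alternate-allele frequency over
#' non-missing calls, minor allele frequency, observed heterozygosity
#' (fraction of code-1 calls among non-missing) and expected
#' heterozygosity `2p(1-p)`.  SNPs with all calls missing get call rate 0
#' and `NA` frequencies (flagged by `maf_defined = FALSE`).
#'
#' @param genotypes a [genotype_matrix()].
#' @param autosomes integer chromosome labels counted as autosomal
#'   (default 1..29, the bovine autosomes).
#' @return data.frame of class `snp_stats`: `snp_id`, `chrom`, `call_rate`,
#'   `p_alt`, `maf`, `het_obs`, `het_exp`, `autosomal`, `maf_defined`.
#' @export
compute_snp_stats <- function(genotypes, autosomes = 1:29) {
  v <- genotypes$values
  if (nrow(v) < 1L) stop("need at least one animal")
  n <- nrow(v)
  nm <- colSums(!is.na(v))
  call_rate <- nm / n
  p <- colSums(v, na.rm = TRUE) / (2 * nm)
  p[nm == 0L] <- NA_real_
  maf <- pmin(p, 1 - p)
  het_obs <- colSums(v == 1L, na.rm = TRUE) / nm
  het_obs[nm == 0L] <- NA_real_
  het_exp <- 2 * p * (1 - p)
  out <- data.frame(snp_id = genotypes$map$snp_id,
                    chrom = genotypes$map$chrom,
                    call_rate = call_rate, p_alt = p, maf = maf,
                    het_obs = het_obs, het_exp = het_exp,
                    autosomal = genotypes$map$chrom %in% autosomes,
                    maf_defined = nm > 0L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("snp_stats", "data.frame")
  out
}

#' Apply the SNP quality-control filters
#'
#' Keeps SNPs with call rate strictly above `call_rate`, minor allele
#' frequency strictly above `maf`, absolute difference between observed and
#' expected heterozygosity strictly below `het_dev`, and an autosomal
#' location.  The strict inequalities follow the published wording
#' ("higher than" / "smaller than"): boundary SNPs are removed.  Removal
#' reasons are assigned by the first failing filter in the order call rate,
#' MAF, heterozygosity deviation, autosome.
#'
#' @param stats output of [compute_snp_stats()] on the same matrix.
#' @param genotypes the [genotype_matrix()] the stats were computed from.
#' @param call_rate,maf,het_dev filter thresholds.
#' @return list with `genotypes` (filtered, map reindexed), `report`
#'   (per-SNP data.frame with `kept` and `reason`), `removed` (named counts
#'   per reason).
#' @export
apply_snp_filters <- function(stats, genotypes, call_rate = 0.95,
                              maf = 0.01, het_dev = 0.15) {
  if (nrow(stats) != ncol(genotypes$values))
    stop("stats do not match the genotype matrix")
  pass_cr <- stats$call_rate > call_rate
  pass_maf <- stats$maf_defined & !is.na(stats$maf) & stats$maf > maf
  dev <- abs(stats$het_obs - stats$het_exp)
  pass_het <- !is.na(dev) & dev < het_dev
  pass_auto <- stats$autosomal
  kept <- pass_cr & pass_maf & pass_het & pass_auto
  reason <- rep(NA_character_, nrow(stats))
  reason[!pass_auto] <- "autosome"
  reason[!pass_het] <- "het_dev"
  reason[!pass_maf] <- "maf"
  reason[!pass_cr] <- "call_rate"
  if (!any(kept))
    stop("all SNPs removed by quality control; scan impossible")
  report <- data.frame(stats[, c("snp_id", "call_rate", "maf", "het_obs",
                                 "het_exp")],
                       kept = kept, reason = reason,
                       stringsAsFactors = FALSE)
  removed <- table(factor(reason[!kept],
                          levels = c("call_rate", "maf", "het_dev",
                                     "autosome")))
  keep_idx <- which(kept)
  map <- genotypes$map[keep_idx, , drop = FALSE]
  newmap <- snp_map(map$snp_id, map$chrom, map$pos_bp)
  g <- genotype_matrix(genotypes$values[, keep_idx, drop = FALSE], newmap)
  list(genotypes = g, report = report, removed = c(removed))
}

#' Write a QC report TSV
#' @param qc result of [apply_snp_filters()].
#' @param path output path.
#' @export
write_qc_report <- function(qc, path) {
  rep <- qc$report
  rep$reason[is.na(rep$reason)] <- ""
  write_tsv(rep, path)
}
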