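#' Calibrate the empirical phenotype cut-off
#'
#' Draws `threshold_samples` windows uniformly over all (chromosome, valid
#' start) positions at the initial window size, classes each window and
#' fits the window mixed model, collecting the raw carrier mean and
#' one-tailed p-value of every qualifying ROH class.  The cut-off is the
#' mean of the carrier means whose p-value falls in the configured
#' significance band (default 0.05-0.10).  If fewer than 20 classes land
#' in the band it is widened symmetrically in 0.01 steps (logged); if the
#' band exhausts (0, 1] with fewer than 20 classes, the mean over all
#' collected carrier means is used.  Deterministic for a fixed seed.
#'
#' @param genotypes QC'd [genotype_matrix()].
#' @param run_index matching [build_run_index()].
#' @param phenotype numeric vector (named by animal id or one per row).
#' @param params a [scan_params()].
#' @param ctx the trait's [model_context()].
#' @param seed RNG seed for the window sampling.
#' @return the cut-off value, with attributes `band` (the band finally
#'   used), `n_in_band`, and `class_means` (all sampled class means).
#' @export
empirical_cutoff <- function(genotypes, run_index, phenotype, params, ctx,
                             seed = 1L) {
  blocks <- chrom_blocks(genotypes$map)
  w <- params$initial_window
  valid <- blocks[blocks$len >= w, , drop = FALSE]
  if (!nrow(valid))
    stop("genome too small to draw windows of ", w, " SNPs")
  nstarts <- valid$len - w + 1L
  tot <- sum(nstarts)
  phen <- align_phen(phenotype, genotypes)
  pick <- with_seed(seed,
                    sample.int(tot, params$threshold_samples, replace = TRUE))
  cumo <- c(0L, cumsum(nstarts))
  bidx <- findInterval(pick - 0.5, cumo)
  start0 <- valid$off0[bidx] + (pick - cumo[bidx] - 1L)
  classings <- vector("list", length(pick))
  for (i in seq_along(pick))
    classings[[i]] <- class_window(genotypes, run_index, valid$chrom[bidx[i]],
                                   start0[i], w, params$min_class_frequency)
  has <- vapply(classings, function(cl) length(cl$classes) > 0L, TRUE)
  if (!any(has))
    stop("no qualifying ROH classes in ", params$threshold_samples,
         " sampled windows; cannot calibrate a cut-off")
  fits <- fit_windows(ctx, classings[has])
  means <- numeric(0)
  pvals <- numeric(0)
  for (i in seq_along(fits)) {
    cl <- classings[has][[i]]
    ft <- fits[[i]]
    mm <- vapply(cl$classes, function(cc) mean(phen[cc], na.rm = TRUE), 0)
    means <- c(means, mm)
    pvals <- c(pvals, ft$p[match(names(cl$classes), ft$class_key)])
  }
  ok <- is.finite(means)
  means <- means[ok]
  pvals <- pvals[ok]
  lo <- params$threshold_sig_range[1]
  hi <- params$threshold_sig_range[2]
  repeat {
    sel <- !is.na(pvals) & pvals >= lo & pvals <= hi
    if (sum(sel) >= 20L || (lo <= 0 && hi >= 1)) break
    lo <- max(0, lo - 0.01)
    hi <- min(1, hi + 0.01)
  }
  if (!isTRUE(all.equal(c(lo, hi), params$threshold_sig_range)))
    message("cut-off significance band widened to [", signif(lo, 3), ", ",
            signif(hi, 3), "] (", sum(sel), " classes)")
  cutoff <- if (sum(sel) > 0L) mean(means[sel]) else mean(means)
  attr(cutoff, "band") <- c(lo, hi)
  attr(cutoff, "n_in_band") <- sum(sel)
  attr(cutoff, "class_means") <- means
  cutoff
}

#' Benjamini-Hochberg step-up FDR control
#'
#' @param pvalues p-values in (0, 1].
#' @param q FDR level.
#' @return list with `reject` (logical flags by the step-up rule: the
#'   largest k with `p_(k) <= k q / m` and everything below) and
#'   `adjusted` (BH-adjusted p-values, capped at 1).
#' @export
bh_fdr <- function(pvalues, q) {
  m <- length(pvalues)
  if (!m) return(list(reject = logical(0), adjusted = numeric(0)))
  if (anyNA(pvalues) || any(pvalues <= 0 | pvalues > 1))
    stop("p-values must lie in (0, 1]")
  adj <- stats::p.adjust(pvalues, method = "BH")
  list(reject = adj <= q, adjusted = adj)
}

#' Run the full discovery procedure
#'
#' Per trait: calibrate the empirical cut-off ([empirical_cutoff()]),
#' scan the genome ([scan_genome()]), discard nested windows
#' ([drop_nested()]), fit the window mixed model for every candidate
#' ([fit_window_model()]), and control the genome-wise FDR over the
#' trait's family of one-tailed p-values with the Benjamini-Hochberg
#' step-up rule at `params$fdr_q`.  The family contains every screened
#' (unfavorable) class that could be fitted; classes skipped during
#' fitting are excluded.
#'
#' @param genotypes QC'd [genotype_matrix()].
#' @param pedigree sorted [as_pedigree()].
#' @param phenotypes phenotype data.frame.
#' @param traits trait column names to analyse.
#' @param vc a single [variance_components()] used for every trait, or a
#'   named list per trait.
#' @param params a [scan_params()].
#' @param directions optional named override of unfavorable directions.
#' @param fixed_factors,random_factors factor column names.
#' @param seed seed for the cut-off calibration.
#' @param ainverse optional precomputed sparse A-inverse.
#' @return object of class `roh_discovery`: list with `records` (one row
#'   per tested class: coordinates, carrier statistics, effect vs non-ROH,
#'   se, one-tailed p, -log10 p, BH-adjusted p and significance flag),
#'   `cutoffs`, `params`.
#' @export
discover <- function(genotypes, pedigree, phenotypes, traits, vc,
                     params = scan_params(), directions = NULL,
                     fixed_factors = character(0),
                     random_factors = c("hy", "hrys", "ss", "ait"),
                     seed = 1L, ainverse = NULL) {
  if (inherits(vc, "variance_components"))
    vc <- setNames(rep(list(vc), length(traits)), traits)
  if (is.null(ainverse) && any(vapply(vc, function(v) v[["animal"]], 0) > 0))
    ainverse <- inbreeding_and_a_inverse(pedigree)$A_inverse
  ri <- build_run_index(genotypes, params$min_run)
  map <- genotypes$map
  recs <- list()
  carrier_sets <- list()
  cutoffs <- setNames(numeric(length(traits)), traits)
  for (ti in seq_along(traits)) {
    tr <- traits[ti]
    dir <- (directions[[tr]] %||% default_direction(tr))
    if (is.na(dir)) stop("no unfavorable direction for trait ", tr)
    ctx <- model_context(genotypes, pedigree, phenotypes, tr, vc[[tr]],
                         direction = dir, fixed_factors = fixed_factors,
                         random_factors = random_factors,
                         ainverse = ainverse)
    phen <- setNames(phenotypes[[tr]], phenotypes$animal)
    cut <- empirical_cutoff(genotypes, ri, phen, params, ctx,
                            seed = seed + ti)
    cutoffs[tr] <- as.numeric(cut)
    cands <- scan_genome(genotypes, ri, phen, cut, dir, params)
    cands <- drop_nested(cands)
    if (!length(cands)) next
    fits <- fit_windows(ctx, lapply(cands, as_classing))
    for (ci in seq_along(cands)) {
      cd <- cands[[ci]]
      ft <- fits[[ci]]
      for (key in cd$screened) {
        row <- ft[ft$class_key == key, , drop = FALSE]
        if (!nrow(row) || is.na(row$p)) next
        str <- class_string(genotypes, cd, key)
        start_bp <- map$pos_bp[cd$start0 + 1L]
        end_bp <- map$pos_bp[cd$end0]
        recs[[length(recs) + 1L]] <- data.frame(
          trait = tr, chrom = cd$chrom,
          start_idx = cd$start0, end_idx = cd$end0,
          start_bp = start_bp, end_bp = end_bp,
          length_mb = (end_bp - start_bp) / 1e6,
          n_snps = cd$end0 - cd$start0,
          rep_start_idx = cd$rep_start0, rep_size = cd$rep_size,
          class_id = class_id_hash(cd$chrom, cd$rep_start0, cd$rep_size,
                                   str),
          class_string = str,
          n_carriers = length(cd$classes[[key]]),
          carrier_freq_pct = 100 * length(cd$classes[[key]]) / cd$n_animals,
          carrier_mean = unname(cd$means[key]),
          effect = row$effect, se = row$se, t = row$t, p = row$p,
          neg_log10_p = -log10(row$p),
          stringsAsFactors = FALSE)
        carrier_sets[[length(carrier_sets) + 1L]] <-
          animal_ids(genotypes)[cd$classes[[key]]]
      }
    }
  }
  records <- if (length(recs)) do.call(rbind, recs) else NULL
  if (!is.null(records)) {
    records$padj <- NA_real_
    records$significant <- FALSE
    for (tr in unique(records$trait)) {
      fam <- which(records$trait == tr)
      bh <- bh_fdr(records$p[fam], params$fdr_q)
      records$padj[fam] <- bh$adjusted
      records$significant[fam] <- bh$reject
    }
    rownames(records) <- NULL
  }
  structure(list(records = records, carrier_sets = carrier_sets,
                 cutoffs = cutoffs, params = params),
            class = "roh_discovery")
}

#' @export
print.roh_discovery <- function(x, ...) {
  n <- if (is.null(x$records)) 0L else nrow(x$records)
  ns <- if (n) sum(x$records$significant) else 0L
  cat("roh_discovery:", n, "tested ROH class(es),", ns,
      "significant at q =", x$params$fdr_q, "\n")
  invisible(x)
}

#' Group significant ROH classes with pleiotropic effects
#'
#' Significant records from different traits are grouped when their SNP
#' intervals overlap on the same chromosome and their carrier sets —
#' re-derived from the genotype matrix as the animals matching the class
#' string over the representative window — are identical.
#'
#' @param discovery a [discover()] result covering two or more traits.
#' @param genotypes the scanned [genotype_matrix()].
#' @return list of groups; each group is a data.frame of the member
#'   records (Table-style: one row per trait) with the shared carrier set
#'   attached as attribute `carriers`.
#' @export
pleiotropy_overlap <- function(discovery, genotypes) {
  rec <- discovery$records
  if (is.null(rec) || !any(rec$significant)) return(list())
  sig <- which(rec$significant)
  if (length(unique(rec$trait[sig])) < 2L) return(list())
  carr <- lapply(sig, function(i) {
    r <- rec[i, ]
    cols <- r$rep_start_idx + seq_len(r$rep_size)
    string <- as.integer(strsplit(r$class_string, "")[[1]])
    gm <- genotypes$values[, cols, drop = FALSE]
    hit <- rowSums(!is.na(gm) & gm == rep(string, each = nrow(gm))) ==
      length(cols)
    sort(animal_ids(genotypes)[hit])
  })
  k <- length(sig)
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    ri <- rec[sig[i], ]; rj <- rec[sig[j], ]
    if (ri$trait == rj$trait || ri$chrom != rj$chrom) next
    if (ri$start_idx < rj$end_idx && rj$start_idx < ri$end_idx &&
        identical(carr[[i]], carr[[j]]))
      parent[find(i)] <- find(j)
  }
  roots <- vapply(seq_len(k), find, 0L)
  out <- list()
  for (r in unique(roots)) {
    mem <- which(roots == r)
    if (length(unique(rec$trait[sig[mem]])) < 2L) next
    g <- rec[sig[mem], , drop = FALSE]
    rownames(g) <- NULL
    attr(g, "carriers") <- carr[[mem[1]]]
    out[[length(out) + 1L]] <- g
  }
  out
}

#' Write discovery records to TSV
#'
#' Effects, -log10 p, carrier frequencies and Mb spans are printed to two
#' decimals.
#'
#' @param discovery a [discover()] result.
#' @param path output path.
#' @export
write_discovery <- function(discovery, path) {
  r <- discovery$records
  if (is.null(r)) {
    write_tsv(data.frame(trait = character(0)), path)
    return(invisible(path))
  }
  out <- data.frame(
    trait = r$trait, chrom = r$chrom,
    start_mb = sprintf("%.2f", r$start_bp / 1e6),
    end_mb = sprintf("%.2f", r$end_bp / 1e6),
    n_snps = r$n_snps, class_id = r$class_id,
    carrier_freq_pct = sprintf("%.2f", r$carrier_freq_pct),
    effect = sprintf("%.2f", r$effect),
    se = sprintf("%.2f", r$se),
    neg_log10_p = sprintf("%.2f", r$neg_log10_p),
    significant = r$significant, stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Write significant intervals as BED
#' @param discovery a [discover()] result.
#' @param path output path.
#' @export
write_significant_bed <- function(discovery, path) {
  r <- discovery$records
  r <- r[r$significant, , drop = FALSE]
  bed <- data.frame(chrom = r$chrom, start = r$start_bp - 1L,
                    end = r$end_bp, name = r$class_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Simulate one study replicate and run the full pipeline
#'
#' One-command demonstration and validation entry point: simulates a
#' desk-scale dataset with [simulate_roh_dataset()] (planted unfavorable
#' classes by default), applies SNP QC, runs [discover()] with the
#' simulation-true variance components, and evaluates the result against
#' the planted truth (a discovery is counted true when its bp interval
#' overlaps a planted interval on the same chromosome).
#'
#' @param seed replicate seed.
#' @param traits traits to simulate and analyse.
#' @param q genome-wise FDR level.
#' @param ... passed to [simulate_roh_dataset()].
#' @return list with `discovery`, `truth`, `n_discoveries`,
#'   `n_false`, `fdp` (V / max(R, 1)), `detected` (logical per planted
#'   class), and `effect_estimates` (best-record effect per planted class,
#'   NA if undetected).
#' @export
run_discovery_replicate <- function(seed = 1L, traits = "MY", q = 0.01,
                                    ...) {
  ds <- simulate_roh_dataset(seed = seed, traits = traits, ...)
  qc <- apply_snp_filters(compute_snp_stats(ds$genotypes), ds$genotypes)
  params <- scan_params(fdr_q = q)
  disc <- discover(qc$genotypes, ds$pedigree, ds$phenotypes, traits,
                   vc = ds$vc, params = params, fixed_factors = "hys",
                   seed = seed)
  rec <- disc$records
  sig <- if (is.null(rec)) rec else rec[rec$significant, , drop = FALSE]
  R <- if (is.null(sig)) 0L else nrow(sig)
  planted <- ds$truth$planted %||% list()
  overlaps_planted <- function(row) {
    any(vapply(planted, function(pl)
      pl$chrom == row$chrom && pl$start_bp <= row$end_bp &&
        row$start_bp <= pl$end_bp, TRUE))
  }
  V <- 0L
  if (R) for (i in seq_len(R)) if (!overlaps_planted(sig[i, ])) V <- V + 1L
  detected <- logical(length(planted))
  eff <- rep(NA_real_, length(planted))
  if (R) for (k in seq_along(planted)) {
    pl <- planted[[k]]
    hit <- which(sig$chrom == pl$chrom & sig$start_bp <= pl$end_bp &
                 pl$start_bp <= sig$end_bp)
    if (length(hit)) {
      detected[k] <- TRUE
      eff[k] <- sig$effect[hit[which.min(sig$p[hit])]]
    }
  }
  list(discovery = disc, truth = ds$truth, n_discoveries = R, n_false = V,
       fdp = V / max(R, 1L), detected = detected, effect_estimates = eff)
}
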