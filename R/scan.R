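#' Index maximal homozygous runs
#'
#' Per animal and chromosome, records every maximal run of consecutive
#' homozygous calls (codes 0 or 2) containing no heterozygote and no
#' missing call; a missing call breaks a run, the conservative reading when
#' upstream genotypes are near-perfectly imputed.  Only runs of at least
#' `min_run` SNPs are stored.  A window is fully homozygous for an animal
#' exactly when it lies inside one stored run, which is how all window
#' queries are answered.
#'
#' @param genotypes a [genotype_matrix()].
#' @param min_run minimum stored run length in SNPs (default 15).
#' @return object of class `run_index`: list with `runs` (data.frame
#'   `animal` (row index), `chrom`, `start0`, `end0` (0-based half-open
#'   global SNP indices), `len`), `n_animals`, `min_run`.
#' @export
build_run_index <- function(genotypes, min_run = 15L) {
  v <- genotypes$values
  blocks <- chrom_blocks(genotypes$map)
  n <- nrow(v)
  pad <- matrix(FALSE, n, 1)
  res <- vector("list", nrow(blocks))
  for (bi in seq_len(nrow(blocks))) {
    off <- blocks$off0[bi]
    len <- blocks$len[bi]
    H <- v[, off + seq_len(len), drop = FALSE]
    H <- !is.na(H) & H != 1L
    startm <- H & !cbind(pad, H[, -len, drop = FALSE])
    endm <- H & !cbind(H[, -1, drop = FALSE], pad)
    sI <- which(startm, arr.ind = TRUE)
    eI <- which(endm, arr.ind = TRUE)
    sI <- sI[order(sI[, 1], sI[, 2]), , drop = FALSE]
    eI <- eI[order(eI[, 1], eI[, 2]), , drop = FALSE]
    rl <- eI[, 2] - sI[, 2] + 1L
    keep <- rl >= min_run
    res[[bi]] <- data.frame(animal = sI[keep, 1],
                            chrom = rep(blocks$chrom[bi], sum(keep)),
                            start0 = off + sI[keep, 2] - 1L,
                            end0 = off + eI[keep, 2],
                            len = rl[keep])
  }
  structure(list(runs = do.call(rbind, res), n_animals = n,
                 min_run = as.integer(min_run)),
            class = "run_index")
}

# Animals (row indices) fully homozygous with no missing call over the
# half-open global window [start0, start0 + size).
window_carriers <- function(run_index, chrom, start0, size) {
  r <- run_index$runs
  r$animal[r$chrom == chrom & r$start0 <= start0 &
           r$end0 >= start0 + size]
}

# Align a phenotype vector (named by animal id, or positional) with the
# rows of a genotype matrix.
align_phen <- function(phenotype, genotypes) {
  if (!is.null(names(phenotype))) {
    out <- phenotype[match(animal_ids(genotypes), names(phenotype))]
  } else {
    if (length(phenotype) != n_animals(genotypes))
      stop("unnamed phenotype vector must have one value per animal")
    out <- phenotype
  }
  as.numeric(out)
}

#' Class animals by unique ROH genotype within one window
#'
#' Carriers are the animals whose stored homozygous run covers the window;
#' they are grouped by the exact homozygote string (the sequence of 0/2
#' codes) over the window.  Groups whose carrier frequency does not
#' strictly exceed `min_class_frequency` are merged into the non-ROH class
#' together with all non-carriers.
#'
#' @param genotypes a [genotype_matrix()].
#' @param run_index a [build_run_index()] built from the same matrix.
#' @param chrom chromosome label.
#' @param start0 0-based global SNP index of the window start.
#' @param size window size in SNPs (> 0).
#' @param min_class_frequency strict frequency threshold (default 0.0075).
#' @return object of class `window_classing`: list with `chrom`, `start0`,
#'   `size`, `classes` (named list of sorted carrier row indices, named by
#'   the homozygote string), `non_roh` (row indices), `n_animals`.
#' @export
class_window <- function(genotypes, run_index, chrom, start0, size,
                         min_class_frequency = 0.0075) {
  if (size <= 0L) stop("window size must be positive")
  n <- n_animals(genotypes)
  carr <- window_carriers(run_index, chrom, start0, size)
  classes <- list()
  if (length(carr)) {
    gm <- genotypes$values[carr, start0 + seq_len(size), drop = FALSE]
    str <- apply(gm, 1, paste, collapse = "")
    grp <- split(carr, str)
    freq <- lengths(grp) / n
    grp <- grp[freq > min_class_frequency]
    classes <- lapply(grp, sort)
    classes <- classes[order(vapply(classes, `[`, 0L, 1L))]
  }
  structure(list(chrom = chrom, start0 = start0, size = size,
                 classes = classes,
                 non_roh = setdiff(seq_len(n), unlist(classes)),
                 n_animals = n),
            class = "window_classing")
}

#' Screen ROH classes against the empirical phenotype cut-off
#'
#' A class is kept when the raw phenotype mean of its carriers (over
#' carriers with a non-missing phenotype) lies strictly on the unfavorable
#' side of the cut-off; classes whose carriers are all missing the
#' phenotype are skipped with a message.  Returns `NULL` when no class
#' survives.
#'
#' @param classing a [class_window()] result (or a scan candidate).
#' @param phenotype numeric vector, named by animal id or aligned with the
#'   genotype rows the classing was built from.
#' @param cutoff trait-scale cut-off from [empirical_cutoff()].
#' @param direction `"lower"` or `"higher"`: the unfavorable side.
#' @return the classing with elements `screened` (names of surviving
#'   classes) and `means` (carrier means), or `NULL`.
#' @export
screen_classes <- function(classing, phenotype, cutoff, direction) {
  direction <- match.arg(direction, c("lower", "higher"))
  if (!length(classing$classes)) return(NULL)
  means <- vapply(classing$classes, function(cc) {
    ph <- phenotype[cc]
    if (all(is.na(ph))) NaN else mean(ph, na.rm = TRUE)
  }, 0)
  if (anyNA(means))
    message(sum(is.na(means)),
            " class(es) skipped: all carriers missing the phenotype")
  keep <- !is.na(means) &
    (if (direction == "lower") means < cutoff else means > cutoff)
  if (!any(keep)) return(NULL)
  classing$screened <- names(classing$classes)[keep]
  classing$means <- means
  classing
}

# Sliding-window hash of the 0/1 matrix B: column s of the result is
# sum_j B[, s+j-1] * 2^(j-1) over j = 1..width (exact in doubles for
# width <= 30).
hash_width <- function(B, width) {
  L <- ncol(B)
  S <- L - width + 1L
  H <- matrix(0, nrow(B), S)
  H[, S] <- B[, S + seq_len(width) - 1L, drop = FALSE] %*% 2^(seq_len(width) - 1)
  if (S > 1L) {
    tw <- 2^width
    for (s in (S - 1L):1L)
      H[, s] <- B[, s] + 2 * H[, s + 1L] - tw * B[, s + width]
  }
  H
}

# Canonical signature of a candidate's qualifying-class partition: classes
# ordered by smallest carrier, carriers sorted.  Two windows with the same
# signature assign exactly the same animals to the same ROH classes.
partition_signature <- function(cand) {
  paste(vapply(cand$classes, paste, collapse = ",", ""), collapse = ";")
}

# Vectorized scan of one chromosome block at one window size: enumerate
# (carrier, window-start) pairs from the run index, group carriers by a
# two-chunk sliding hash of their homozygote string, apply the frequency
# filter and the phenotype screen, and emit one candidate per window that
# retains at least one screened class.
scan_block <- function(v, Bc, runs_c, off, chrom, len, w, params, phen,
                       cutoff, direction) {
  n <- nrow(v)
  rc <- runs_c[runs_c$len >= w, , drop = FALSE]
  if (!nrow(rc)) return(list())
  rs <- rc$start0 - off
  cov <- (rc$end0 - off) - w - rs + 1L
  wst <- sequence(cov) - 1L + rep(rs, cov)
  ani <- rep(rc$animal, cov)
  if (params$slide_step > 1L) {
    keep <- wst %% params$slide_step == 0L
    wst <- wst[keep]
    ani <- ani[keep]
  }
  if (!length(wst)) return(list())
  w1 <- min(30L, w)
  w2 <- w - w1
  H1 <- hash_width(Bc, w1)
  h1 <- H1[cbind(ani, wst + 1L)]
  if (w2 > 0L) {
    H2 <- hash_width(Bc, w2)
    h2 <- H2[cbind(ani, wst + w1 + 1L)]
  } else h2 <- numeric(length(ani))
  o <- order(wst, h1, h2, ani)
  ws <- wst[o]; k1 <- h1[o]; k2 <- h2[o]; a_o <- ani[o]
  np <- length(ws)
  new <- c(TRUE, ws[-1] != ws[-np] | k1[-1] != k1[-np] | k2[-1] != k2[-np])
  grp <- cumsum(new)
  grp_w <- ws[new]
  grp_n <- tabulate(grp)
  qual <- grp_n / n > params$min_class_frequency
  if (!any(qual)) return(list())
  ph <- phen[a_o]
  sm <- rowsum(ifelse(is.na(ph), 0, ph), grp)[, 1]
  nn <- rowsum(as.numeric(!is.na(ph)), grp)[, 1]
  mg <- ifelse(nn > 0, sm / nn, NA_real_)
  passed <- qual & !is.na(mg) &
    (if (direction == "lower") mg < cutoff else mg > cutoff)
  if (!any(passed)) return(list())
  cls_all <- split(a_o, grp)
  keys_all <- paste0("h", formatC(k1[new], format = "fg"), "_",
                     formatC(k2[new], format = "fg"))
  out <- list()
  for (wid in unique(grp_w[passed])) {
    gsel <- which(qual & grp_w == wid)
    classes <- cls_all[gsel]
    names(classes) <- keys_all[gsel]
    ord <- order(vapply(classes, `[`, 0L, 1L))
    classes <- classes[ord]
    gsel <- gsel[ord]
    out[[length(out) + 1L]] <- structure(
      list(chrom = chrom, size = w, rep_start0 = off + wid, rep_size = w,
           start0 = off + wid, end0 = off + wid + w,
           classes = classes,
           screened = keys_all[gsel][passed[gsel]],
           means = setNames(mg[gsel], keys_all[gsel]),
           n_animals = n),
      class = "roh_candidate")
  }
  out
}

#' Scan the genome for candidate unfavorable ROH windows
#'
#' Step (1) of the discovery procedure.  For each window size in
#' `initial_window, initial_window - window_decrement, ..., min_window` the
#' window slides along every chromosome by `slide_step` SNPs; in each
#' window the unique ROH genotype classes are identified
#' ([class_window()] semantics), screened against the phenotype cut-off
#' ([screen_classes()] semantics), and windows retaining at least one
#' unfavorable class are stored.  Within each window size, runs of
#' adjacent windows with identical class partitions are merged
#' ([aggregate_windows()]) before sizes are pooled.  Windows crossing a
#' chromosome end are never formed; chromosomes shorter than `min_window`
#' are skipped with a warning.  The scan is deterministic.
#'
#' @param genotypes QC'd [genotype_matrix()].
#' @param run_index matching [build_run_index()].
#' @param phenotype numeric vector (named by animal id, or one value per
#'   genotype row).
#' @param cutoff trait-scale cut-off value.
#' @param direction `"lower"` or `"higher"`.
#' @param params a [scan_params()].
#' @return list of candidate windows.  Each candidate records its
#'   (possibly merged) SNP-index span `start0`/`end0` (0-based half-open),
#'   the representative window (`rep_start0`, `rep_size`), the qualifying
#'   classes with their carriers, the screened (unfavorable) subset and the
#'   raw carrier means.
#' @export
scan_genome <- function(genotypes, run_index, phenotype, cutoff, direction,
                        params = scan_params()) {
  direction <- match.arg(direction, c("lower", "higher"))
  v <- genotypes$values
  blocks <- chrom_blocks(genotypes$map)
  phen <- align_phen(phenotype, genotypes)
  sizes <- seq(params$initial_window, params$min_window,
               by = -params$window_decrement)
  B <- (!is.na(v)) & v == 2L
  storage.mode(B) <- "double"
  out <- list()
  for (bi in seq_len(nrow(blocks))) {
    ch <- blocks$chrom[bi]
    off <- blocks$off0[bi]
    len <- blocks$len[bi]
    if (len < params$min_window) {
      warning("chromosome ", ch, " has ", len,
              " SNPs (< min_window); skipped")
      next
    }
    Bc <- B[, off + seq_len(len), drop = FALSE]
    rc <- run_index$runs[run_index$runs$chrom == ch, , drop = FALSE]
    for (w in sizes) {
      if (w > len) next
      cands <- scan_block(v, Bc, rc, off, ch, len, w, params, phen,
                          cutoff, direction)
      out <- c(out, aggregate_windows(cands, step = params$slide_step))
    }
  }
  out
}

#' Aggregate equivalent adjacent windows
#'
#' Maximal chains of candidates at consecutive start positions (one
#' `step` apart, same chromosome and window size) whose class partitions —
#' the assignment of carrier animals to unique ROH classes — are identical
#' are merged into a single record spanning the union of their SNP
#' intervals; the chain's first window is kept as the representative
#' classing.
#'
#' @param candidates list of candidates sharing one window size.
#' @param step the slide step the candidates were generated with.
#' @return list of merged candidates.
#' @export
aggregate_windows <- function(candidates, step = 1L) {
  if (length(candidates) < 2L) return(candidates)
  sz <- unique(vapply(candidates, function(x) x$size, 0L))
  if (length(sz) != 1L)
    stop("aggregation requires candidates of a single window size")
  o <- order(vapply(candidates, function(x) x$chrom, 0L),
             vapply(candidates, function(x) x$start0, 0L))
  candidates <- candidates[o]
  sigs <- vapply(candidates, partition_signature, "")
  out <- list()
  cur <- candidates[[1]]
  cur_sig <- sigs[1]
  for (i in seq_along(candidates)[-1]) {
    nx <- candidates[[i]]
    if (nx$chrom == cur$chrom && nx$start0 == cur$end0 - cur$size + step &&
        sigs[i] == cur_sig) {
      cur$end0 <- nx$start0 + nx$size
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- nx
      cur_sig <- sigs[i]
    }
  }
  out[[length(out) + 1L]] <- cur
  out
}

#' Discard nested candidate windows
#'
#' Step (3) of the discovery procedure: a candidate is discarded when
#' another candidate on the same chromosome has a SNP interval containing
#' it and an identical class partition (same animals in the same unique
#' ROH classes).  When two such candidates cover exactly the same
#' interval, the record originating from the larger window size is kept.
#'
#' @param candidates list of candidates (any mix of window sizes, after
#'   aggregation).
#' @return surviving candidates.
#' @export
drop_nested <- function(candidates) {
  k <- length(candidates)
  if (k < 2L) return(candidates)
  sig <- vapply(candidates, partition_signature, "")
  ch <- vapply(candidates, function(x) x$chrom, 0L)
  s <- vapply(candidates, function(x) x$start0, 0L)
  e <- vapply(candidates, function(x) x$end0, 0L)
  rw <- vapply(candidates, function(x) x$rep_size, 0L)
  drop <- logical(k)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i == j || drop[j]) next
      if (ch[i] != ch[j] || sig[i] != sig[j]) next
      if (s[j] <= s[i] && e[j] >= e[i]) {
        if (s[j] == s[i] && e[j] == e[i]) {
          # identical span: keep the larger-window record
          if (rw[j] > rw[i] || (rw[j] == rw[i] && j < i)) drop[i] <- TRUE
        } else drop[i] <- TRUE
      }
      if (drop[i]) break
    }
  }
  candidates[!drop]
}

# Representative classing of a candidate, for model fitting.
as_classing <- function(cand) {
  structure(list(chrom = cand$chrom, start0 = cand$rep_start0,
                 size = cand$rep_size, classes = cand$classes,
                 non_roh = setdiff(seq_len(cand$n_animals),
                                   unlist(cand$classes)),
                 n_animals = cand$n_animals),
            class = "window_classing")
}

# Genotype string of a class over its representative window (all carriers
# share it by construction).
class_string <- function(genotypes, cand, key) {
  carr <- cand$classes[[key]][1]
  paste(genotypes$values[carr, cand$rep_start0 + seq_len(cand$rep_size)],
        collapse = "")
}

# Short stable id for a class: FNV-1a over the window coordinates + string.
class_id_hash <- function(chrom, start0, size, string) {
  s <- paste0(chrom, ":", start0, ":", size, ":", string)
  h <- 2166136261
  for (ch in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), ch)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("R%08x", as.integer(h))
}

#' Write candidate windows to TSV
#'
#' One row per screened class: trait, chromosome, SNP-index span, bp span,
#' size, class id, carrier count, carrier frequency (\%), raw carrier mean.
#'
#' @param candidates list of candidates from [scan_genome()].
#' @param genotypes the scanned [genotype_matrix()].
#' @param trait trait name for the output column.
#' @param path output path.
#' @export
write_candidates <- function(candidates, genotypes, trait, path) {
  map <- genotypes$map
  rows <- list()
  for (cd in candidates) {
    for (key in cd$screened) {
      str <- class_string(genotypes, cd, key)
      rows[[length(rows) + 1L]] <- data.frame(
        trait = trait, chrom = cd$chrom, start_idx = cd$start0,
        end_idx = cd$end0, start_bp = map$pos_bp[cd$start0 + 1L],
        end_bp = map$pos_bp[cd$end0], size = cd$end0 - cd$start0,
        class_id = class_id_hash(cd$chrom, cd$rep_start0, cd$rep_size, str),
        n_carriers = length(cd$classes[[key]]),
        carrier_freq_pct = 100 * length(cd$classes[[key]]) / cd$n_animals,
        carrier_mean = unname(cd$means[key]), stringsAsFactors = FALSE)
    }
  }
  write_tsv(do.call(rbind, rows), path)
}
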