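# Independent oracles used across the suite.  These deliberately use the
# slowest, most literal formulation of each quantity.

# Numerator relationship matrix by the tabular method.
tabular_A <- function(ped) {
  idx <- rohclass:::ped_indices(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    s <- idx$sire[i]
    d <- idx$dam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (s > 0L) row <- row + 0.5 * A[s, j]
      if (d > 0L) row <- row + 0.5 * A[d, j]
      A[i, j] <- row
      A[j, i] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  A
}

# Naive classing of one window: scan every animal's raw genotypes.
brute_class_window <- function(genotypes, chrom, start0, size,
                               min_freq = 0.0075, min_run = 15L) {
  v <- genotypes$values
  map <- genotypes$map
  cols <- start0 + seq_len(size)
  stopifnot(all(map$chrom[cols] == chrom))
  n <- nrow(v)
  gm <- v[, cols, drop = FALSE]
  carr <- if (size >= min_run)
    which(rowSums(is.na(gm) | gm == 1L) == 0L)
  else integer(0)
  if (!length(carr)) return(list())
  str <- apply(v[carr, cols, drop = FALSE], 1, paste, collapse = "")
  grp <- split(carr, str)
  grp <- grp[lengths(grp) / n > min_freq]
  grp <- lapply(grp, sort)
  grp[order(vapply(grp, `[`, 0L, 1L))]
}

# Exhaustive brute-force scan: every (size, start) window classed naively,
# screened, chained by identical partitions (quadratic), then nested
# windows discarded by pairwise containment.
brute_scan <- function(genotypes, phen, cutoff, direction, params) {
  blocks <- rohclass:::chrom_blocks(genotypes$map)
  sizes <- seq(params$initial_window, params$min_window,
               by = -params$window_decrement)
  cands <- list()
  for (b in seq_len(nrow(blocks))) {
    if (blocks$len[b] < params$min_window) next
    for (w in sizes) {
      chain <- list()
      flush <- function() {
        if (length(chain)) {
          first <- chain[[1]]
          last <- chain[[length(chain)]]
          first$end0 <- last$start0 + w
          cands[[length(cands) + 1L]] <<- first
        }
        chain <<- list()
      }
      for (s0 in seq(0, blocks$len[b] - w, by = params$slide_step)) {
        gs0 <- blocks$off0[b] + s0
        cls <- brute_class_window(genotypes, blocks$chrom[b], gs0, w,
                                  params$min_class_frequency,
                                  params$min_run)
        means <- vapply(cls, function(cc) mean(phen[cc], na.rm = TRUE), 0)
        keep <- if (direction == "lower") means < cutoff else means > cutoff
        keep[is.na(keep)] <- FALSE
        if (!any(keep)) { flush(); next }
        cand <- list(chrom = blocks$chrom[b], size = w, rep_start0 = gs0,
                     rep_size = w, start0 = gs0, end0 = gs0 + w,
                     classes = cls, screened = names(cls)[keep],
                     means = means, n_animals = nrow(genotypes$values))
        sig <- paste(vapply(cls, paste, collapse = ",", ""), collapse = ";")
        if (length(chain)) {
          prev <- chain[[length(chain)]]
          prev_sig <- paste(vapply(prev$classes, paste, collapse = ",", ""),
                            collapse = ";")
          if (prev$start0 + params$slide_step == gs0 && prev_sig == sig) {
            chain[[length(chain) + 1L]] <- cand
            next
          }
          flush()
        }
        chain <- list(cand)
      }
      flush()
    }
  }
  # pairwise nested-window discard
  if (length(cands) > 1L) {
    sig <- vapply(cands, function(cd)
      paste(vapply(cd$classes, paste, collapse = ",", ""), collapse = ";"),
      "")
    drop <- logical(length(cands))
    for (i in seq_along(cands)) for (j in seq_along(cands)) {
      if (i == j || drop[j] || drop[i]) next
      ci <- cands[[i]]; cj <- cands[[j]]
      if (ci$chrom != cj$chrom || sig[i] != sig[j]) next
      if (cj$start0 <= ci$start0 && cj$end0 >= ci$end0) {
        if (cj$start0 == ci$start0 && cj$end0 == ci$end0) {
          if (cj$rep_size > ci$rep_size) drop[i] <- TRUE
        } else drop[i] <- TRUE
      }
    }
    cands <- cands[!drop]
  }
  cands
}

# Comparable fingerprint of a candidate set (order-free; class keys differ
# between implementations, so classes are identified by their carrier sets
# and screened classes by their position in first-carrier order).
candidate_fingerprint <- function(cands) {
  sort(vapply(cands, function(cd) {
    scr <- which(names(cd$classes) %in% cd$screened)
    paste(cd$chrom, cd$start0, cd$end0, cd$rep_size,
          paste(scr, collapse = "+"),
          paste(vapply(cd$classes, paste, collapse = ",", ""),
                collapse = ";"),
          sep = "|")
  }, ""))
}

# Dense GLS on V = Z A Z' s2a + sum W W' s2j + I s2e for a window model.
gls_fit <- function(genotypes, ped, phen_df, trait, vc, fixed_factors,
                    random_factors, classing) {
  A <- tabular_A(ped)
  keep <- !is.na(phen_df[[trait]])
  ph <- phen_df[keep, , drop = FALSE]
  y <- ph[[trait]]
  n <- length(y)
  Z <- matrix(0, n, nrow(ped))
  Z[cbind(seq_len(n), match(ph$animal, ped$animal))] <- 1
  V <- Z %*% A %*% t(Z) * vc[["animal"]] + diag(n) * vc[["residual"]]
  for (f in random_factors) {
    if (vc[[f]] <= 0) next
    W <- stats::model.matrix(~ 0 + factor(ph[[f]]))
    V <- V + W %*% t(W) * vc[[f]]
  }
  Xb <- if (length(fixed_factors))
    stats::model.matrix(~ ., data = as.data.frame(
      lapply(ph[fixed_factors], factor)))
  else matrix(1, n, 1)
  gids <- rownames(genotypes$values)
  rec_of <- match(ph$animal, gids)
  D <- matrix(0, n, length(classing$classes))
  for (k in seq_along(classing$classes)) {
    rows <- which(rec_of %in% classing$classes[[k]])
    D[rows, k] <- 1
  }
  G <- genotypes$values[rec_of, classing$start0 + seq_len(classing$size),
                        drop = FALSE]
  storage.mode(G) <- "double"
  G <- scale(G, scale = FALSE)
  X <- cbind(Xb, D, G)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  b <- solve(XtVX, t(X) %*% Vi %*% y)
  C <- solve(XtVX)
  pos <- ncol(Xb) + seq_along(classing$classes)
  list(effect = b[pos], se = sqrt(diag(C)[pos]))
}

# Literal Benjamini-Hochberg step-up: largest k with p_(k) <= k q / m.
brute_bh <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- 0L
  for (i in seq_len(m)) if (ps[i] <= i * q / m) k <- i
  rej <- logical(m)
  if (k > 0L) rej[o[seq_len(k)]] <- TRUE
  rej
}

# Quadratic interval intersection under the half-open rule.
brute_overlap <- function(rec_s0, rec_e0, gene_s0, gene_e0)
  gene_s0 < rec_e0 & rec_s0 < gene_e0

# Small cached fixtures (built once per test run).
.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env))
    assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# Medium simulated dataset shared by scan/model/discovery tests.
medium_dataset <- function() fixture("medium", function() {
  ds <- simulate_roh_dataset(seed = 101, n_founders = 120L,
                             n_generations = 6L, gen_size = 120L,
                             n_chrom = 2L, snps_per_chrom = 300L,
                             n_planted = 1L)
  qc <- apply_snp_filters(compute_snp_stats(ds$genotypes), ds$genotypes)
  ri <- build_run_index(qc$genotypes)
  c(ds, list(qc_genotypes = qc$genotypes, run_index = ri))
})

# Replicates shared by the FDR-control and parameter-recovery acceptance
# checks (full pipeline at reference desk-scale conditions).
acceptance_replicates <- function() fixture("acc_reps", function() {
  lapply(1:25, function(s)
    suppressMessages(suppressWarnings(run_discovery_replicate(seed = s))))
})
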