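hom_row <- function(...) as.integer(c(...))

small_geno <- function(rows, n_snps = NULL, chrom = 1L) {
  v <- do.call(rbind, rows)
  n_snps <- n_snps %||% ncol(v)
  rownames(v) <- sprintf("A%03d", seq_len(nrow(v)))
  genotype_matrix(v, snp_map(sprintf("s%03d", seq_len(ncol(v))),
                             rep(chrom, ncol(v)),
                             seq_len(ncol(v)) * 1000L))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("run index stores only runs meeting the minimum length", {
  r1 <- hom_row(rep(0, 16), 1, rep(2, 5))
  r2 <- hom_row(1, rep(2, 14), 1, rep(0, 6))
  g <- small_geno(list(r1, r2))
  ri <- build_run_index(g, min_run = 15L)
  runs1 <- ri$runs[ri$runs$animal == 1L, ]
  expect_equal(nrow(runs1), 1L)
  expect_equal(runs1$len, 16L)
  expect_equal(c(runs1$start0, runs1$end0), c(0L, 16L))
  expect_equal(nrow(ri$runs[ri$runs$animal == 2L, ]), 0L)
  # a missing call breaks a run exactly like a heterozygote
  r3 <- hom_row(rep(0, 10), NA, rep(0, 11))
  ri3 <- build_run_index(small_geno(list(r3)), min_run = 10L)
  expect_equal(sort(ri3$runs$len), c(10L, 11L))
})

test_that("window containment answers match a naive full-homozygosity scan", {
  set.seed(12)
  v <- matrix(sample(c(0:2, NA), 200 * 300, TRUE,
                     prob = c(.34, .2, .34, .12)), 200, 300)
  rownames(v) <- sprintf("A%03d", 1:200)
  g <- genotype_matrix(v, default_snp_map(1, 300, 1000))
  ri <- build_run_index(g, min_run = 5L)
  for (size in c(5L, 8L, 12L)) {
    for (s0 in seq(0L, 300L - size, by = 7L)) {
      naive <- which(vapply(1:200, function(i) {
        x <- v[i, s0 + seq_len(size)]
        !anyNA(x) && all(x != 1L)
      }, TRUE))
      expect_equal(sort(rohclass:::window_carriers(ri, 1L, s0, size)),
                   naive)
    }
  }
})

test_that("window classing separates strings and enforces the frequency rule", {
  base <- rep(1L, 20)
  s1 <- hom_row(rep(2, 20)); s2 <- hom_row(rep(0, 20))
  rows <- c(replicate(3, s1, simplify = FALSE), list(s2),
            replicate(196, base, simplify = FALSE))
  g <- small_geno(rows)
  ri <- build_run_index(g, min_run = 15L)
  cl <- class_window(g, ri, 1L, 0L, 20L)
  expect_equal(length(cl$classes), 1L)
  expect_equal(cl$classes[[1]], 1:3)               # 1.5% passes, 0.5% not
  expect_equal(length(cl$non_roh), 197L)
  expect_error(class_window(g, ri, 1L, 0L, 0L), "positive")
  # fully heterozygous window -> everything is non-ROH
  gh <- small_geno(replicate(10, base, simplify = FALSE))
  clh <- class_window(gh, build_run_index(gh), 1L, 0L, 20L)
  expect_equal(length(clh$classes), 0L)
  expect_equal(clh$non_roh, 1:10)
})

test_that("classing of random data equals the brute-force partition", {
  set.seed(13)
  v <- matrix(sample(c(0L, 0L, 2L, 2L, 1L), 120 * 60, TRUE), 120, 60)
  rownames(v) <- sprintf("A%03d", 1:120)
  g <- genotype_matrix(v, default_snp_map(1, 60, 1000))
  ri <- build_run_index(g, min_run = 5L)
  for (s0 in c(0L, 13L, 40L)) {
    cl <- class_window(g, ri, 1L, s0, 20L, min_class_frequency = 0.01)
    bf <- brute_class_window(g, 1L, s0, 20L, min_freq = 0.01, min_run = 5L)
    expect_equal(unname(cl$classes), unname(bf))
  }
})

test_that("the phenotype screen keeps strictly unfavorable classes only", {
  g <- small_geno(c(replicate(5, hom_row(rep(2, 20)), simplify = FALSE),
                    replicate(5, hom_row(rep(1, 20)), simplify = FALSE)))
  ri <- build_run_index(g)
  cl <- class_window(g, ri, 1L, 0L, 20L, min_class_frequency = 0.1)
  phen <- c(rep(8500, 5), rep(9000, 5))
  kept <- screen_classes(cl, phen, cutoff = 8800, direction = "lower")
  expect_equal(kept$screened, names(cl$classes))
  expect_null(screen_classes(cl, rep(8800, 10), 8800, "lower"))
  kept_hi <- screen_classes(cl, c(rep(25, 5), rep(10, 5)), 22, "higher")
  expect_equal(length(kept_hi$screened), 1L)
})

test_that("adjacent windows with identical partitions merge into one span", {
  mk <- function(start0, carriers, size = 50L)
    structure(list(chrom = 1L, size = size, rep_start0 = start0,
                   rep_size = size, start0 = start0, end0 = start0 + size,
                   classes = list(k = carriers), screened = "k",
                   means = c(k = 1), n_animals = 200L),
              class = "roh_candidate")
  merged <- aggregate_windows(list(mk(10L, 1:4), mk(11L, 1:4)))
  expect_equal(length(merged), 1L)
  expect_equal(merged[[1]]$end0 - merged[[1]]$start0, 51L)
  expect_equal(merged[[1]]$rep_start0, 10L)
  not_merged <- aggregate_windows(list(mk(10L, 1:4), mk(11L, c(1:3, 5L))))
  expect_equal(length(not_merged), 2L)
  # random chains against a quadratic union-find on the merge relation
  set.seed(14)
  for (rep in 1:20) {
    starts <- sort(sample(0:30, 12))
    sets <- lapply(sample(3, 12, TRUE), function(k) seq_len(k))
    cands <- Map(mk, as.integer(starts), sets)
    got <- aggregate_windows(cands)
    # union-find
    parent <- seq_along(cands)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_along(cands)[-1])
      if (starts[i] == starts[i - 1] + 1 &&
          identical(sets[[i]], sets[[i - 1]]))
        parent[find(i)] <- find(i - 1L)
    roots <- vapply(seq_along(cands), function(i) as.integer(find(i)), 0L)
    spans <- lapply(unique(roots), function(r) {
      mem <- which(roots == r)
      c(min(starts[mem]), max(starts[mem]) + 50L)
    })
    expect_equal(sort(vapply(got, function(x) x$start0, 0L)),
                 sort(vapply(spans, `[`, 0, 1)))
    expect_equal(sort(vapply(got, function(x) x$end0, 0L)),
                 sort(vapply(spans, function(x) as.integer(x[2]), 0L)))
  }
})

test_that("nested windows with identical carrier sets are discarded", {
  mk <- function(start0, end0, rep_size, carriers)
    structure(list(chrom = 1L, size = rep_size, rep_start0 = start0,
                   rep_size = rep_size, start0 = start0, end0 = end0,
                   classes = list(k = carriers), screened = "k",
                   means = c(k = 1), n_animals = 200L),
              class = "roh_candidate")
  out <- drop_nested(list(mk(100L, 150L, 50L, 1:5),
                          mk(90L, 160L, 60L, 1:5)))
  expect_equal(length(out), 1L)
  expect_equal(out[[1]]$start0, 90L)
  both <- drop_nested(list(mk(0L, 50L, 50L, 1:5), mk(60L, 110L, 50L, 1:5)))
  expect_equal(length(both), 2L)
  # identical spans keep the larger-window record
  tie <- drop_nested(list(mk(0L, 60L, 50L, 1:5), mk(0L, 60L, 60L, 1:5)))
  expect_equal(length(tie), 1L)
  expect_equal(tie[[1]]$rep_size, 60L)
  # randomized nests against quadratic containment
  set.seed(15)
  for (rep in 1:15) {
    k <- 8L
    ss <- sample(0:40, k, TRUE)
    ee <- ss + sample(50:80, k, TRUE)
    sets <- lapply(sample(2, k, TRUE), seq_len)
    cands <- Map(mk, as.integer(ss), as.integer(ee),
                 rep(50L, k), sets)
    got <- candidate_fingerprint(drop_nested(cands))
    drop <- logical(k)
    for (i in seq_len(k)) for (j in seq_len(k)) {
      if (i == j || drop[j]) next
      if (!identical(sets[[i]], sets[[j]])) next
      if (ss[j] <= ss[i] && ee[j] >= ee[i] &&
          !(ss[j] == ss[i] && ee[j] == ee[i])) drop[i] <- TRUE
      if (ss[j] == ss[i] && ee[j] == ee[i] && j < i) drop[i] <- TRUE
    }
    expect_equal(got, candidate_fingerprint(cands[!drop]))
  }
})

test_that("the optimized scan reproduces the brute-force scan exactly", {
  ds <- medium_dataset()
  g <- ds$qc_genotypes
  phen <- setNames(ds$phenotypes$MY, ds$phenotypes$animal)
  params <- scan_params(initial_window = 60L, min_window = 50L)
  cutoff <- mean(phen) - 0.2 * sd(phen)
  got <- scan_genome(g, ds$run_index, phen, cutoff, "lower", params)
  got <- drop_nested(got)
  bf <- brute_scan(g, rohclass:::align_phen(phen, g), cutoff, "lower",
                   params)
  expect_gt(length(got), 0L)
  expect_equal(candidate_fingerprint(got), candidate_fingerprint(bf))
  # every emitted candidate re-verifies from raw genotypes
  for (cd in got) {
    for (key in names(cd$classes)) {
      carr <- cd$classes[[key]]
      gm <- g$values[carr, cd$rep_start0 + seq_len(cd$rep_size),
                     drop = FALSE]
      expect_true(all(!is.na(gm) & gm != 1L))
      expect_true(all(apply(gm, 2, function(x) length(unique(x)) == 1L)))
      expect_gt(length(carr) / cd$n_animals,
                params$min_class_frequency)
    }
    expect_gte(cd$end0 - cd$start0, params$min_window)
  }
})

test_that("no homozygous runs means an empty scan", {
  g <- small_geno(replicate(30, rep(1L, 120), simplify = FALSE))
  ri <- build_run_index(g)
  expect_equal(length(scan_genome(g, ri, rnorm(30), 0, "lower",
                                  scan_params(initial_window = 60L))), 0L)
  # chromosome shorter than the minimum window is skipped with a warning
  gs <- small_geno(replicate(30, rep(1L, 30), simplify = FALSE))
  expect_warning(scan_genome(gs, build_run_index(gs), rnorm(30), 0, "lower",
                             scan_params()), "skipped")
})

test_that("classes below the frequency floor never become candidates", {
  # a 0.5% class (1 of 200) qualifies nowhere at the 0.75% default
  base <- rep(1L, 60)
  rows <- c(list(hom_row(rep(2, 60))),
            replicate(199, base, simplify = FALSE))
  g <- small_geno(rows)
  ri <- build_run_index(g)
  phen <- c(0, rnorm(199, 10))
  got <- scan_genome(g, ri, phen, cutoff = 5, direction = "lower",
                     scan_params(initial_window = 60L, min_window = 50L))
  expect_equal(length(got), 0L)
})

test_that("lowering the frequency floor only adds classes", {
  ds <- medium_dataset()
  g <- ds$qc_genotypes
  blocks <- rohclass:::chrom_blocks(g$map)
  checked <- 0L
  for (b in seq_len(nrow(blocks))) {
    for (s0 in seq(0L, blocks$len[b] - 60L, by = 10L)) {
      hi <- class_window(g, ds$run_index, blocks$chrom[b],
                         blocks$off0[b] + s0, 60L,
                         min_class_frequency = 0.0075)
      if (!length(hi$classes)) next
      lo <- class_window(g, ds$run_index, blocks$chrom[b],
                         blocks$off0[b] + s0, 60L,
                         min_class_frequency = 0.002)
      for (k in seq_along(hi$classes))
        expect_true(any(vapply(lo$classes, identical, TRUE,
                               hi$classes[[k]])))
      checked <- checked + length(hi$classes)
    }
  }
  expect_gt(checked, 0L)
})
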