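toy_pedigree <- function(n_founders, n_off, seed = 1) {
  set.seed(seed)
  as_pedigree(data.frame(
    animal = as.character(seq_len(n_founders + n_off)),
    sire = c(rep(NA, n_founders),
             as.character(sample(seq_len(n_founders %/% 2), n_off, TRUE))),
    dam = c(rep(NA, n_founders),
            as.character(sample(n_founders %/% 2 + seq_len(n_founders %/% 2),
                                n_off, TRUE))),
    stringsAsFactors = FALSE))
}

test_that("A-inverse matches the hand-derived trio and founder identity", {
  trio <- as_pedigree(data.frame(animal = c("1", "2", "3"),
                                 sire = c(NA, NA, "1"),
                                 dam = c(NA, NA, "2")))
  ai <- inbreeding_and_a_inverse(trio)
  expect_equal(unname(as.matrix(ai$A_inverse)),
               matrix(c(1.5, 0.5, -1, 0.5, 1.5, -1, -1, -1, 2), 3, 3),
               tolerance = 1e-12)
  founders <- as_pedigree(data.frame(animal = as.character(1:5),
                                     sire = NA, dam = NA))
  expect_equal(unname(as.matrix(
    inbreeding_and_a_inverse(founders)$A_inverse)), diag(5))
})

test_that("A-inverse inverts the tabular-method A on random pedigrees", {
  for (s in 1:5) {
    ped <- simulate_pedigree(30, 5, sire_fraction = 0.1, seed = s,
                             gen_size = 25)
    ai <- inbreeding_and_a_inverse(ped)
    A <- tabular_A(ped)
    expect_lt(max(abs(as.matrix(ai$A_inverse) %*% A - diag(nrow(A)))),
              1e-8)
    expect_equal(unname(ai$F), diag(A) - 1, tolerance = 1e-10)
  }
})

test_that("with zero variance ratios the class contrasts reduce to OLS", {
  ped <- toy_pedigree(20, 20, seed = 2)
  g <- simulate_genotypes(ped, default_snp_map(1, 30), seed = 3)
  set.seed(4)
  phen <- data.frame(animal = ped$animal, MY = rnorm(40, 100, 5),
                     f = sample(c("a", "b"), 40, TRUE),
                     stringsAsFactors = FALSE)
  vc <- variance_components(animal = 0, residual = 25)
  ctx <- model_context(g, ped, phen, "MY", vc, fixed_factors = "f")
  cl <- structure(list(chrom = 1L, start0 = 5L, size = 4L,
                       classes = list(c1 = c(1L, 4L, 8L, 12L, 20L)),
                       non_roh = setdiff(1:40, c(1, 4, 8, 12, 20)),
                       n_animals = 40L), class = "window_classing")
  ft <- fit_window_model(ctx, cl)
  D <- as.integer(seq_len(40) %in% cl$classes$c1)
  G <- g$values[, 6:9]
  storage.mode(G) <- "double"
  ols <- lm(phen$MY ~ factor(phen$f) + D + scale(G, scale = FALSE))
  expect_equal(ft$effect, unname(coef(ols)["D"]), tolerance = 1e-9)
})

test_that("window-model contrasts equal dense GLS on small pedigrees", {
  for (s in 1:3) {
    ped <- toy_pedigree(20, 28, seed = s)
    g <- simulate_genotypes(ped, default_snp_map(1, 40), seed = s + 10)
    set.seed(s + 20)
    n <- nrow(ped)
    phen <- data.frame(animal = ped$animal, MY = rnorm(n, 50, 4),
                       f = sample(c("u", "v", "w"), n, TRUE),
                       hy = sample(sprintf("h%d", 1:4), n, TRUE),
                       hrys = sample(sprintf("r%d", 1:3), n, TRUE),
                       stringsAsFactors = FALSE)
    phen$MY[3] <- NA  # partial records are tolerated
    vc <- variance_components(animal = 3, hy = 1.5, hrys = 0.8,
                              residual = 4)
    ctx <- model_context(g, ped, phen, "MY", vc, fixed_factors = "f")
    cl <- structure(list(chrom = 1L, start0 = 10L, size = 6L,
                         classes = list(c1 = seq(1L, n, by = 7L),
                                        c2 = seq(2L, n, by = 9L)),
                         non_roh = integer(0), n_animals = n),
                    class = "window_classing")
    ft <- fit_window_model(ctx, cl)
    or <- gls_fit(g, ped, phen, "MY", vc, "f", c("hy", "hrys"), cl)
    expect_equal(ft$effect, unname(or$effect), tolerance = 1e-8)
    expect_equal(ft$se, unname(or$se), tolerance = 1e-8)
  }
})

test_that("shifting the response leaves class contrasts unchanged", {
  ped <- toy_pedigree(16, 24, seed = 6)
  g <- simulate_genotypes(ped, default_snp_map(1, 30), seed = 7)
  set.seed(8)
  phen <- data.frame(animal = ped$animal, MY = rnorm(40, 10),
                     hy = sample(c("x", "y"), 40, TRUE),
                     stringsAsFactors = FALSE)
  vc <- variance_components(animal = 1, hy = 0.5, residual = 2)
  cl <- structure(list(chrom = 1L, start0 = 2L, size = 5L,
                       classes = list(c1 = c(2L, 9L, 16L, 23L, 37L)),
                       non_roh = integer(0), n_animals = 40L),
                  class = "window_classing")
  ctx1 <- model_context(g, ped, phen, "MY", vc)
  phen2 <- phen
  phen2$MY <- phen2$MY + 1000
  ctx2 <- model_context(g, ped, phen2, "MY", vc)
  f1 <- fit_window_model(ctx1, cl)
  f2 <- fit_window_model(ctx2, cl)
  expect_equal(f1$effect, f2$effect, tolerance = 1e-6)
  expect_equal(f1$se, f2$se, tolerance = 1e-8)
})

test_that("swapping class and reference flips the contrast sign", {
  ped <- toy_pedigree(16, 24, seed = 9)
  g <- simulate_genotypes(ped, default_snp_map(1, 20), seed = 10)
  set.seed(11)
  phen <- data.frame(animal = ped$animal, MY = rnorm(40, 10),
                     stringsAsFactors = FALSE)
  vc <- variance_components(animal = 1, residual = 2)
  grp <- c(3L, 7L, 21L, 30L, 33L)
  mkcl <- function(classes) structure(
    list(chrom = 1L, start0 = 4L, size = 5L, classes = classes,
         non_roh = integer(0), n_animals = 40L),
    class = "window_classing")
  ctx <- model_context(g, ped, phen, "MY", vc)
  a <- fit_window_model(ctx, mkcl(list(k = grp)))
  b <- fit_window_model(ctx, mkcl(list(k = setdiff(1:40, grp))))
  expect_equal(a$effect, -b$effect, tolerance = 1e-9)
})

test_that("standard errors shrink as carrier counts grow", {
  ped <- simulate_pedigree(200, 0, seed = 12)
  g <- simulate_genotypes(ped, default_snp_map(1, 10), seed = 13)
  set.seed(14)
  phen <- data.frame(animal = ped$animal, MY = rnorm(200),
                     stringsAsFactors = FALSE)
  vc <- variance_components(animal = 0, residual = 1)
  ctx <- model_context(g, ped, phen, "MY", vc)
  ses <- vapply(c(10L, 30L, 80L), function(k) {
    cl <- structure(list(chrom = 1L, start0 = 0L, size = 1L,
                         classes = list(k = seq_len(k)),
                         non_roh = integer(0), n_animals = 200L),
                    class = "window_classing")
    fit_window_model(ctx, cl)$se
  }, 0)
  expect_true(all(diff(ses) < 0))
})

test_that("classes with too few phenotyped carriers are skipped", {
  ped <- simulate_pedigree(50, 0, seed = 15)
  g <- simulate_genotypes(ped, default_snp_map(1, 10), seed = 16)
  phen <- data.frame(animal = ped$animal, MY = rnorm(50),
                     stringsAsFactors = FALSE)
  phen$MY[1] <- NA
  ctx <- model_context(g, ped, phen, "MY",
                       variance_components(animal = 0, residual = 1))
  cl <- structure(list(chrom = 1L, start0 = 0L, size = 2L,
                       classes = list(k1 = c(1L, 2L), k2 = c(5L, 9L, 11L)),
                       non_roh = integer(0), n_animals = 50L),
                  class = "window_classing")
  expect_message(ft <- fit_window_model(ctx, cl), "skipped")
  expect_true(is.na(ft$p[ft$class_key == "k1"]))
  expect_false(is.na(ft$p[ft$class_key == "k2"]))
})

test_that("EM-REML is deterministic and recovers a null additive variance", {
  ped <- simulate_pedigree(50, 2, sire_fraction = 0.1, seed = 17,
                           gen_size = 50)
  g <- simulate_genotypes(ped, default_snp_map(1, 10), seed = 18)
  set.seed(19)
  phen <- data.frame(animal = ped$animal,
                     MY = rnorm(nrow(ped), 0, 2),
                     hy = sample(sprintf("h%d", 1:8), nrow(ped), TRUE),
                     stringsAsFactors = FALSE)
  v1 <- estimate_variance_components(ped, phen, "MY",
                                     random_factors = "hy", tol = 1e-6,
                                     max_iter = 5000L)
  v2 <- estimate_variance_components(ped, phen, "MY",
                                     random_factors = "hy", tol = 1e-6,
                                     max_iter = 5000L)
  expect_identical(as.numeric(v1), as.numeric(v2))
  expect_lt(v1[["animal"]], 0.10 * v1[["residual"]])
})

test_that("EM-REML recovers a moderate heritability on a deep pedigree", {
  h2hat <- vapply(1:3, function(s) {
    ds <- simulate_roh_dataset(seed = 300 + s, n_founders = 60L,
                               n_generations = 5L, gen_size = 60L,
                               n_chrom = 1L, snps_per_chrom = 30L,
                               n_planted = 0L, h2 = 0.3)
    vch <- estimate_variance_components(
      ds$pedigree, ds$phenotypes, "MY", fixed_factors = "hys",
      random_factors = c("hy", "hrys", "ss", "ait"), tol = 1e-5)
    vch[["animal"]] / sum(as.numeric(vch))
  }, 0)
  expect_true(mean(h2hat) > 0.1 && mean(h2hat) < 0.55)
})

test_that("EM-REML agrees with direct restricted-likelihood maximisation", {
  ped <- toy_pedigree(30, 70, seed = 23)
  ds <- list(pedigree = ped)
  g <- simulate_genotypes(ped, default_snp_map(1, 10), seed = 24)
  # simulate y with known components through the phenotype generator
  vc_true <- variance_components(animal = 2, residual = 3)
  phen <- simulate_phenotypes(ped, g, vc = vc_true, traits = "MY",
                              n_fixed_levels = NULL, seed = 25)
  phen$MY <- phen$MY - 9074
  em <- estimate_variance_components(ped, phen, "MY",
                                     random_factors = character(0),
                                     tol = 1e-7, max_iter = 2000L)
  A <- tabular_A(ped)
  n <- nrow(ped)
  X <- matrix(1, n, 1)
  y <- phen$MY
  negll <- function(lv) {
    V <- A * exp(lv[1]) + diag(n) * exp(lv[2])
    ch <- chol(V)
    Vi <- chol2inv(ch)
    XtVX <- t(X) %*% Vi %*% X
    b <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% b
    as.numeric(2 * sum(log(diag(ch))) + determinant(XtVX)$modulus +
                 t(r) %*% Vi %*% r) / 2
  }
  opt <- optim(log(c(1, 1)), negll, method = "L-BFGS-B")
  expect_equal(em[["animal"]], exp(opt$par[1]), tolerance = 0.05)
  expect_equal(em[["residual"]], exp(opt$par[2]), tolerance = 0.05)
})
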