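# Ordered rank-revealing Cholesky: columns are admitted in the given order
# and a column whose pivot falls below tol * |diag| is dropped (so SNP
# covariates, placed last, are sacrificed before class indicators).
sel_chol <- function(S, tol = 1e-8) {
  p <- nrow(S)
  R <- matrix(0, p, p)
  kept <- integer(0)
  d0 <- pmax(abs(diag(S)), .Machine$double.xmin)
  for (k in seq_len(p)) {
    m <- length(kept)
    if (m) {
      Rk <- R[seq_len(m), seq_len(m), drop = FALSE]
      r <- forwardsolve(t(Rk), S[kept, k])
      d <- S[k, k] - sum(r * r)
    } else {
      r <- numeric(0)
      d <- S[k, k]
    }
    if (!is.finite(d) || d <= tol * d0[k]) next
    if (m) R[seq_len(m), m + 1L] <- r
    R[m + 1L, m + 1L] <- sqrt(d)
    kept <- c(kept, k)
  }
  list(kept = kept,
       R = R[seq_along(kept), seq_along(kept), drop = FALSE])
}

#' Build a per-trait mixed-model context
#'
#' Assembles everything that is constant across window fits for one trait:
#' the response, the base fixed-effect design, the random-effect incidence
#' matrices (animal effect with covariance `A * sigma2_a` plus the i.i.d.
#' factors), the sparse Cholesky factor of the absorbed random-effect block
#' of Henderson's mixed-model equations, and the projections of the
#' response, base design and all centered SNP covariates through the
#' absorption operator.  Variance components are treated as known and held
#' fixed across windows (the null-hypothesis convention); window fits then
#' reduce to small dense solves.
#'
#' @param genotypes QC'd [genotype_matrix()].
#' @param pedigree sorted [as_pedigree()]; every phenotyped animal must
#'   appear in it.
#' @param phenotypes data.frame with `animal`, the trait column and the
#'   factor columns.
#' @param trait trait column name.
#' @param vc a [variance_components()] object.
#' @param direction `"lower"` or `"higher"` (defaulted from
#'   [trait_defaults()] when known).
#' @param fixed_factors,random_factors factor column names; random factors
#'   with a zero variance component are dropped from the model.
#' @param ainverse optional precomputed `A_inverse` (from
#'   [inbreeding_and_a_inverse()]); computed if `NULL` and `sigma2_a > 0`.
#' @return an object of class `roh_model_context`.
#' @export
model_context <- function(genotypes, pedigree, phenotypes, trait, vc,
                          direction = NULL,
                          fixed_factors = character(0),
                          random_factors = c("hy", "hrys", "ss", "ait"),
                          ainverse = NULL) {
  check_sorted(pedigree)
  if (is.null(direction)) {
    direction <- default_direction(trait)
    if (is.na(direction))
      stop("no default unfavorable direction for trait ", trait,
           "; supply one")
  }
  direction <- match.arg(direction, c("lower", "higher"))
  if (!trait %in% names(phenotypes))
    stop("phenotype table has no column ", trait)
  miss <- setdiff(phenotypes$animal, pedigree$animal)
  if (length(miss))
    stop("phenotyped animal(s) missing from pedigree: ",
         paste(utils::head(miss, 3), collapse = ", "))
  gids <- animal_ids(genotypes)
  rec <- which(!is.na(phenotypes[[trait]]) & phenotypes$animal %in% gids)
  if (!length(rec))
    stop("no phenotyped, genotyped animals for trait ", trait)
  n_pheno <- sum(!is.na(phenotypes[[trait]]))
  if (n_pheno > length(rec))
    message(n_pheno - length(rec),
            " phenotyped animal(s) without genotypes excluded for ", trait)
  ph <- phenotypes[rec, , drop = FALSE]
  y <- as.numeric(ph[[trait]])
  n <- length(y)
  if (length(fixed_factors)) {
    fd <- ph[fixed_factors]
    fd[] <- lapply(fd, function(x) droplevels(factor(x)))
    Xb <- stats::model.matrix(~ ., data = fd)
  } else {
    Xb <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  }
  s2e <- vc[["residual"]]
  Ulist <- list()
  pen <- list()
  if (vc[["animal"]] > 0) {
    if (is.null(ainverse))
      ainverse <- inbreeding_and_a_inverse(pedigree)$A_inverse
    Ulist$animal <- Matrix::sparseMatrix(
      i = seq_len(n), j = match(ph$animal, pedigree$animal), x = 1,
      dims = c(n, nrow(pedigree)))
    pen$animal <- (s2e / vc[["animal"]]) * ainverse
  }
  for (f in random_factors) {
    s2 <- vc[[f]]
    if (is.na(s2) || s2 <= 0) next
    if (!f %in% names(ph)) stop("phenotype table has no column ", f)
    lev <- droplevels(factor(ph[[f]]))
    Ulist[[f]] <- Matrix::sparseMatrix(
      i = seq_len(n), j = as.integer(lev), x = 1,
      dims = c(n, nlevels(lev)))
    pen[[f]] <- (s2e / s2) * Matrix::Diagonal(nlevels(lev))
  }
  if (length(Ulist)) {
    U <- do.call(cbind, Ulist)
    K <- Matrix::forceSymmetric(Matrix::crossprod(U) + Matrix::bdiag(pen))
    Kf <- Matrix::Cholesky(K, LDL = FALSE, perm = TRUE)
    papply <- function(M)
      M - as.matrix(U %*% Matrix::solve(Kf, Matrix::crossprod(U, M),
                                        system = "A"))
  } else {
    U <- NULL
    Kf <- NULL
    papply <- identity
  }
  G <- genotypes$values[match(ph$animal, gids), , drop = FALSE]
  storage.mode(G) <- "double"
  cm <- colMeans(G, na.rm = TRUE)
  cm[is.nan(cm)] <- 0
  G <- G - matrix(cm, n, ncol(G), byrow = TRUE)
  G[is.na(G)] <- 0
  colnames(G) <- genotypes$map$snp_id
  P_all <- papply(cbind(y, Xb, G))
  rec_of_geno <- rep(NA_integer_, length(gids))
  rec_of_geno[match(ph$animal, gids)] <- seq_len(n)
  structure(list(
    trait = trait, direction = direction, vc = vc, sigma2_e = s2e,
    y = y, n = n, animals = ph$animal,
    Xb = Xb, G = G,
    Py = P_all[, 1L],
    PXb = P_all[, 1L + seq_len(ncol(Xb)), drop = FALSE],
    PG = P_all[, -seq_len(1L + ncol(Xb)), drop = FALSE],
    papply = papply, U = U, Kf = Kf,
    rec_of_geno = rec_of_geno),
    class = "roh_model_context")
}

# Fit the window mixed model for a batch of classings sharing one context.
# Returns one data.frame per classing with a row per class (reference =
# non-ROH).
fit_windows <- function(ctx, classings, min_carriers = 2L, tol = 1e-8) {
  # gather class indicator columns for all windows, project them in one go
  meta <- list()
  for (ci in seq_along(classings)) {
    cl <- classings[[ci]]
    for (key in names(cl$classes)) {
      rr <- ctx$rec_of_geno[cl$classes[[key]]]
      rr <- rr[!is.na(rr)]
      meta[[length(meta) + 1L]] <- list(ci = ci, key = key, rows = rr)
    }
  }
  K <- length(meta)
  if (K) {
    D_all <- matrix(0, ctx$n, K)
    for (k in seq_len(K)) D_all[meta[[k]]$rows, k] <- 1
    PD_all <- ctx$papply(D_all)
  }
  col_of <- split(seq_len(K), vapply(meta, function(m) m$ci, 0L))
  pXb <- ncol(ctx$Xb)
  out <- vector("list", length(classings))
  empty <- data.frame(class_key = character(0), n_carriers = integer(0),
                      effect = numeric(0), se = numeric(0), t = numeric(0),
                      p = numeric(0), df = numeric(0),
                      dropped_covariates = character(0),
                      stringsAsFactors = FALSE)
  for (ci in seq_along(classings)) {
    cl <- classings[[ci]]
    cols <- col_of[[as.character(ci)]]
    if (is.null(cols)) { out[[ci]] <- empty; next }
    keys <- vapply(meta[cols], function(m) m$key, "")
    ncarr <- vapply(meta[cols], function(m) length(m$rows), 0L)
    usable <- ncarr >= min_carriers
    if (any(!usable))
      message(sum(!usable), " class(es) with < ", min_carriers,
              " phenotyped carriers skipped in window chr", cl$chrom,
              ":", cl$start0)
    res <- data.frame(class_key = keys, n_carriers = ncarr,
                      effect = NA_real_, se = NA_real_, t = NA_real_,
                      p = NA_real_, df = NA_real_,
                      dropped_covariates = "", stringsAsFactors = FALSE)
    if (any(usable)) {
      ucols <- cols[usable]
      kk <- length(ucols)
      wcols <- cl$start0 + seq_len(cl$size)
      X <- cbind(ctx$Xb, D_all[, ucols, drop = FALSE],
                 ctx$G[, wcols, drop = FALSE])
      PX <- cbind(ctx$PXb, PD_all[, ucols, drop = FALSE],
                  ctx$PG[, wcols, drop = FALSE])
      S <- crossprod(X, PX)
      S <- (S + t(S)) / 2
      q <- crossprod(X, ctx$Py)[, 1]
      sc <- sel_chol(S, tol = tol)
      if (!length(sc$kept))
        stop("singular coefficient matrix in window chr", cl$chrom, ":",
             cl$start0, "-", cl$start0 + cl$size)
      beta <- rep(NA_real_, ncol(S))
      bk <- backsolve(sc$R, forwardsolve(t(sc$R), q[sc$kept]))
      beta[sc$kept] <- bk
      Cdiag <- rep(NA_real_, ncol(S))
      Cdiag[sc$kept] <- diag(chol2inv(sc$R))
      class_pos <- pXb + seq_len(kk)
      snp_pos <- pXb + kk + seq_len(cl$size)
      dropped_snps <- colnames(X)[setdiff(snp_pos, sc$kept)]
      if (length(setdiff(class_pos, sc$kept)))
        message("inestimable ROH class contrast in window chr", cl$chrom,
                ":", cl$start0, " (confounded with fixed effects)")
      dfree <- ctx$n - length(sc$kept)
      eff <- beta[class_pos]
      se <- sqrt(ctx$sigma2_e * Cdiag[class_pos])
      tt <- eff / se
      pp <- if (ctx$direction == "lower") pt(tt, dfree)
            else pt(tt, dfree, lower.tail = FALSE)
      res$effect[usable] <- eff
      res$se[usable] <- se
      res$t[usable] <- tt
      res$p[usable] <- pmax(pp, .Machine$double.xmin)
      res$df[usable] <- dfree
      res$dropped_covariates[usable] <- paste(dropped_snps, collapse = ",")
    }
    out[[ci]] <- res
  }
  out
}

#' Fit the animal mixed model for one window
#'
#' Solves Henderson's mixed-model equations for the model
#' `y = Xb + Za + sum_j W c_j + e` with the window's unique ROH classes as
#' a fixed class effect (reference level = the non-ROH class) and centered
#' allele-count covariates for every SNP inside the window (correcting for
#' their additive effects).  Covariates rendered collinear with each other
#' or with the class indicators are dropped by rank detection (class
#' indicators are never sacrificed).  Contrasts of each class against
#' non-ROH are returned with standard errors from the inverse coefficient
#' matrix, and one-tailed p-values in the trait's unfavorable direction on
#' a t distribution with `N - rank(fixed block)` degrees of freedom.
#' Classes with fewer than `min_carriers` phenotyped carriers are skipped
#' with a message.
#'
#' @param ctx a [model_context()].
#' @param classing a [class_window()] result or a scan candidate.
#' @param min_carriers minimum phenotyped carriers per fitted class.
#' @param tol relative pivot tolerance for rank detection.
#' @return data.frame with one row per class: `class_key`, `n_carriers`,
#'   `effect`, `se`, `t`, `p`, `df`, `dropped_covariates`.
#' @export
fit_window_model <- function(ctx, classing, min_carriers = 2L, tol = 1e-8) {
  if (inherits(classing, "roh_candidate")) classing <- as_classing(classing)
  fit_windows(ctx, list(classing), min_carriers = min_carriers, tol = tol)[[1]]
}

#' Estimate variance components by EM-REML
#'
#' Expectation-maximisation REML for the null model (no ROH term):
#' `y = Xb + Za + sum_j W c_j + e` with `a ~ N(0, A sigma2_a)` and i.i.d.
#' random factors.  Iterates Henderson's mixed-model equations with the
#' standard EM updates until the largest relative change in any component
#' falls below `tol`.  Intended for modest data sizes (the coefficient
#' matrix is inverted densely each round); in routine use the components
#' are supplied from an external evaluation and held fixed.
#'
#' @param pedigree sorted [as_pedigree()].
#' @param phenotypes phenotype data.frame (`animal`, trait, factor columns).
#' @param trait trait column to analyse.
#' @param fixed_factors,random_factors factor column names.
#' @param ainverse optional precomputed sparse A-inverse.
#' @param init optional [variance_components()] starting values.
#' @param tol convergence tolerance: largest absolute component change per
#'   round, relative to the current total variance.
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   iteration trace.
#' @return a [variance_components()] with attributes `iterations`, `trace`
#'   and `clamped`.
#' @export
estimate_variance_components <- function(pedigree, phenotypes, trait,
                                         fixed_factors = character(0),
                                         random_factors = c("hy", "hrys",
                                                            "ss", "ait"),
                                         ainverse = NULL, init = NULL,
                                         tol = 1e-6, max_iter = 500L) {
  check_sorted(pedigree)
  keep <- !is.na(phenotypes[[trait]])
  ph <- phenotypes[keep, , drop = FALSE]
  if (!all(ph$animal %in% pedigree$animal))
    stop("phenotyped animal(s) missing from pedigree")
  y <- as.numeric(ph[[trait]])
  n <- length(y)
  if (length(fixed_factors)) {
    fd <- ph[fixed_factors]
    fd[] <- lapply(fd, function(x) droplevels(factor(x)))
    X <- stats::model.matrix(~ ., data = fd)
  } else X <- matrix(1, n, 1)
  rX <- qr(X)$rank
  if (is.null(ainverse))
    ainverse <- inbreeding_and_a_inverse(pedigree)$A_inverse
  Ainv <- as.matrix(ainverse)
  np <- nrow(pedigree)
  Z <- matrix(0, n, np)
  Z[cbind(seq_len(n), match(ph$animal, pedigree$animal))] <- 1
  random_factors <- random_factors[random_factors %in% names(ph)]
  Ws <- lapply(random_factors, function(f) {
    lev <- droplevels(factor(ph[[f]]))
    W <- matrix(0, n, nlevels(lev))
    W[cbind(seq_len(n), as.integer(lev))] <- 1
    W
  })
  names(Ws) <- random_factors
  blocks <- c(list(animal = Z), Ws)
  qs <- vapply(blocks, ncol, 0L)
  Tmat <- cbind(X, do.call(cbind, blocks))
  TtT <- crossprod(Tmat)
  Tty <- crossprod(Tmat, y)[, 1]
  yy <- sum(y * y)
  pX <- ncol(X)
  offs <- pX + c(0L, cumsum(qs))
  vy <- stats::var(y)
  comp <- if (!is.null(init))
    c(init[["animal"]], unlist(init[random_factors], use.names = FALSE),
      init[["residual"]])
  else c(vy / 3, rep(vy / 10, length(Ws)), vy / 2)
  nb <- length(blocks)
  trace <- matrix(NA_real_, 0, nb + 1L)
  clamped <- FALSE
  for (it in seq_len(max_iter)) {
    s2e <- comp[nb + 1L]
    M <- TtT
    for (b in seq_len(nb)) {
      rng <- (offs[b] + 1L):offs[b + 1L]
      lam <- s2e / comp[b]
      if (b == 1L) M[rng, rng] <- M[rng, rng] + lam * Ainv
      else M[rng, rng] <- M[rng, rng] + diag(lam, length(rng))
    }
    C <- solve(M)
    sol <- C %*% Tty
    newc <- numeric(nb + 1L)
    for (b in seq_len(nb)) {
      rng <- (offs[b] + 1L):offs[b + 1L]
      ub <- sol[rng, 1]
      Cb <- C[rng, rng, drop = FALSE]
      if (b == 1L)
        newc[b] <- (sum(ub * (Ainv %*% ub)) + s2e * sum(Ainv * Cb)) / qs[b]
      else
        newc[b] <- (sum(ub * ub) + s2e * sum(diag(Cb))) / qs[b]
    }
    newc[nb + 1L] <- (yy - sum(sol[, 1] * Tty)) / (n - rX)
    if (any(newc < 1e-12)) {
      newc <- pmax(newc, 1e-12)
      clamped <- TRUE
    }
    trace <- rbind(trace, newc)
    # convergence is judged against the total variance so that components
    # decaying to the zero boundary (where EM slows geometrically) do not
    # stall the criterion
    rel <- max(abs(newc - comp)) / max(sum(comp), .Machine$double.xmin)
    comp <- newc
    if (rel < tol) {
      vcout <- variance_components(
        animal = comp[1],
        hy = if ("hy" %in% names(Ws)) comp[1L + match("hy", names(Ws))] else 0,
        hrys = if ("hrys" %in% names(Ws)) comp[1L + match("hrys", names(Ws))] else 0,
        ss = if ("ss" %in% names(Ws)) comp[1L + match("ss", names(Ws))] else 0,
        ait = if ("ait" %in% names(Ws)) comp[1L + match("ait", names(Ws))] else 0,
        residual = comp[nb + 1L])
      attr(vcout, "iterations") <- it
      attr(vcout, "trace") <- trace
      attr(vcout, "clamped") <- clamped
      return(vcout)
    }
  }
  stop("EM-REML did not converge in ", max_iter, " iterations; last values: ",
       paste(signif(comp, 6), collapse = ", "))
}

#' Write variance components to TSV
#' @param vc a [variance_components()].
#' @param path output path.
#' @export
write_variance_components <- function(vc, path) {
  write_tsv(data.frame(component = names(unclass(vc)),
                       value = as.numeric(vc)), path)
}
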