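#' Simulate an overlapping-generation livestock pedigree
#'
#' Founders form generation 0 and are assumed unrelated.  Each later
#' generation is produced by mating a small, randomly chosen set of sires
#' (a fraction `sire_fraction` of the available males, mimicking intense
#' AI-driven selection and thereby inducing inbreeding) to dams sampled
#' from the previous two generations (overlapping generations).
#'
#' @param n_founders number of founders (>= 2).
#' @param n_generations number of descendant generations (0 = founders only).
#' @param offspring_per_dam litter size per mated dam.
#' @param sire_fraction fraction of available males used as sires.
#' @param seed RNG seed; the pedigree is reproducible for a fixed seed.
#' @param gen_size number of animals born per generation (default
#'   `n_founders`).
#' @return a sorted [as_pedigree()] with extra columns `sex` and
#'   `generation`.
#' @export
simulate_pedigree <- function(n_founders, n_generations,
                              offspring_per_dam = 2L, sire_fraction = 0.05,
                              seed = 1L, gen_size = n_founders) {
  if (n_founders < 2) stop("need at least 2 founders")
  if (n_generations > 0 &&
      (offspring_per_dam < 1 || sire_fraction <= 0 || gen_size < 1))
    stop("parameters imply zero matings")
  with_seed(seed, {
    id <- sprintf("G00_%05d", seq_len(n_founders))
    sex <- sample(rep(c("M", "F"), length.out = n_founders))
    ped <- data.frame(animal = id, sire = NA_character_,
                      dam = NA_character_, sex = sex, generation = 0L,
                      stringsAsFactors = FALSE)
    for (g in seq_len(n_generations)) {
      pool <- ped[ped$generation >= g - 2L & ped$generation <= g - 1L, ]
      males <- pool$animal[pool$sex == "M"]
      females <- pool$animal[pool$sex == "F"]
      if (!length(males) || !length(females))
        stop("no available matings in generation ", g)
      n_sires <- max(1L, round(sire_fraction * length(males)))
      sires <- sample(males)[seq_len(min(n_sires, length(males)))]
      n_dams <- min(length(females), ceiling(gen_size / offspring_per_dam))
      dams <- sample(females)[seq_len(n_dams)]
      off_dam <- rep(dams, each = offspring_per_dam)[seq_len(
        min(gen_size, n_dams * offspring_per_dam))]
      n_off <- length(off_dam)
      off_sire <- sires[sample.int(length(sires), n_off, replace = TRUE)]
      born <- data.frame(
        animal = sprintf("G%02d_%05d", g, seq_len(n_off)),
        sire = off_sire, dam = off_dam,
        sex = sample(rep(c("M", "F"), length.out = n_off)),
        generation = g, stringsAsFactors = FALSE)
      ped <- rbind(ped, born)
    }
    as_pedigree(ped)
  })
}

#' Evenly spaced SNP map
#'
#' @param n_chrom number of autosomes.
#' @param snps_per_chrom SNPs per chromosome.
#' @param spacing_bp inter-SNP distance in bp.
#' @return a [snp_map()].
#' @export
default_snp_map <- function(n_chrom = 5L, snps_per_chrom = 600L,
                            spacing_bp = 50000L) {
  chrom <- rep(seq_len(n_chrom), each = snps_per_chrom)
  pos <- rep(seq_len(snps_per_chrom) * spacing_bp, n_chrom)
  snp_map(sprintf("C%dS%04d", chrom, rep(seq_len(snps_per_chrom), n_chrom)),
          chrom, pos)
}

#' Simulate genotypes by gene dropping
#'
#' Founder haplotypes are drawn in linkage equilibrium from per-SNP allele
#' frequencies whose minor-allele frequency is uniform on
#' `founder_maf`; descendants receive Mendelian gametes with crossovers as
#' a Poisson process on the genetic map (Haldane, no interference, at
#' `cM_per_Mb` centimorgan per megabase).  Runs of homozygosity therefore
#' arise only through identity by descent.
#'
#' @param pedigree sorted [as_pedigree()].
#' @param map a [snp_map()].
#' @param founder_maf length-2 range of founder minor-allele frequencies.
#' @param cM_per_Mb recombination rate; 0 gives unrecombined parental
#'   haplotypes.
#' @param seed RNG seed.
#' @return a [genotype_matrix()] for every pedigree animal (no missing
#'   calls).
#' @export
simulate_genotypes <- function(pedigree, map, founder_maf = c(0.05, 0.5),
                               cM_per_Mb = 1, seed = 1L) {
  check_sorted(pedigree)
  if (nrow(map) == 0L) stop("empty SNP map")
  n <- nrow(pedigree)
  m <- nrow(map)
  blocks <- chrom_blocks(map)
  cols <- lapply(seq_len(nrow(blocks)),
                 function(b) blocks$off0[b] + seq_len(blocks$len[b]))
  gpos <- lapply(cols, function(cc) map$pos_bp[cc] / 1e6 * cM_per_Mb)
  with_seed(seed, {
    f <- runif(m, founder_maf[1], founder_maf[2])
    flip <- runif(m) < 0.5
    f[flip] <- 1 - f[flip]
    H1 <- matrix(0L, n, m)
    H2 <- matrix(0L, n, m)
    idx <- ped_indices(pedigree)
    founder_gamete <- function() as.integer(rbinom(m, 1L, f))
    gamete <- function(p) {
      h1 <- H1[p, ]
      h2 <- H2[p, ]
      out <- integer(m)
      for (b in seq_along(cols)) {
        cc <- cols[[b]]
        gp <- gpos[[b]]
        len_cM <- gp[length(gp)] - gp[1]
        k <- if (len_cM > 0) rpois(1L, len_cM / 100) else 0L
        start <- sample.int(2L, 1L) - 1L
        phase <- if (k == 0L) rep(start, length(cc)) else
          (start + findInterval(gp, sort(runif(k, gp[1], gp[length(gp)])))) %% 2L
        out[cc] <- ifelse(phase == 0L, h1[cc], h2[cc])
      }
      out
    }
    for (i in seq_len(n)) {
      s <- idx$sire[i]
      d <- idx$dam[i]
      H1[i, ] <- if (s == 0L) founder_gamete() else gamete(s)
      H2[i, ] <- if (d == 0L) founder_gamete() else gamete(d)
    }
    v <- H1 + H2
    rownames(v) <- pedigree$animal
    g <- genotype_matrix(v, map)
    # phased haplotypes kept for validation (Mendelian / recombination checks)
    attr(g, "haplotypes") <- list(H1 = H1, H2 = H2)
    g
  })
}

#' Plant unfavorable ROH-class effects
#'
#' Selects (or, in force mode, constructs) a homozygote string over a SNP
#' window and records it, with its realized carrier set, as a planted
#' ground-truth class.  In the default (non-force) mode an *existing* fully
#' homozygous class with carrier frequency within +/-50\% of the target is
#' chosen; no genotype is edited.  In force mode a random window is
#' overwritten with a chosen homozygote string for `ceiling(frac * N)`
#' randomly chosen animals, guaranteeing the target frequency.  Carrier
#' sets are always re-counted from the emitted genotype matrix, so extra
#' animals that happen to match the string are included.
#'
#' @param genotypes a [genotype_matrix()].
#' @param requests list of requests, each a list with `chrom`, `length`
#'   (SNPs), `frac` (target carrier fraction), `effects` (named per-trait
#'   effect sizes in trait units) and optionally `start` (0-based window
#'   start within the chromosome block; chosen automatically if omitted).
#' @param seed RNG seed.
#' @param force overwrite genotypes to create the class (default FALSE).
#' @return list with the (possibly modified) `genotypes` and `truth`, a
#'   `sim_truth` object listing each planted class.
#' @export
plant_roh_effects <- function(genotypes, requests, seed = 1L, force = FALSE) {
  v <- genotypes$values
  map <- genotypes$map
  blocks <- chrom_blocks(map)
  n <- nrow(v)
  taken <- data.frame(chrom = integer(0), s = integer(0), e = integer(0))
  overlaps <- function(ch, s, e)
    any(taken$chrom == ch & taken$s < e & s < taken$e)
  used_carriers <- integer(0)  # planted classes get disjoint carrier sets
  planted <- list()
  with_seed(seed, {
    for (rq in requests) {
      ch <- rq$chrom
      w <- rq$length
      b <- which(blocks$chrom == ch)
      if (!length(b)) stop("no such chromosome: ", ch)
      off <- blocks$off0[b]
      len <- blocks$len[b]
      if (w > len) stop("window longer than chromosome ", ch)
      if (!is.null(rq$start)) {
        s0 <- rq$start
        if (overlaps(ch, s0, s0 + w))
          stop("planted interval chr", ch, ":", s0, "-", s0 + w,
               " overlaps a previous request")
      }
      if (force) {
        # plant a *real* haplotype on essentially random carriers: copy an
        # existing homozygote string (so the class behaves like natural
        # identity-by-descent sharing under the additive-SNP correction,
        # with single copies and partial segments present elsewhere) but
        # prefer a string with very few existing homozygotes, so the
        # realized carrier set is dominated by the randomly drawn animals
        # and carries no co-inherited flanking segments
        starts <- if (is.null(rq$start)) sample(0:(len - w)) else rq$start
        # at most two pre-existing homozygotes: the realized carrier set is
        # then essentially a random draw of animals, so the planted effect
        # cannot leak, via a related carrier family, into classes elsewhere
        # in the genome - the rest of the genome stays effect-free
        cap <- 2L
        s0 <- NULL
        string <- NULL
        for (cand in starts) {
          if (overlaps(ch, cand, cand + w)) next
          ccols <- off + cand + seq_len(w)
          gm <- v[, ccols, drop = FALSE]
          hom <- rowSums(!is.na(gm) & gm != 1L) == w
          if (!any(hom)) next
          str <- apply(gm[hom, , drop = FALSE], 1, paste, collapse = "")
          tab <- sort(table(str))
          if (tab[1] > cap) next
          s0 <- cand
          string <- as.integer(strsplit(names(tab)[1], "")[[1]])
          break
        }
        if (is.null(s0)) {
          # no homozygote exists anywhere (e.g. unrelated animals in linkage
          # equilibrium): synthesize a homozygote string from the allele
          # frequencies instead
          for (cand in starts) {
            if (!overlaps(ch, cand, cand + w)) { s0 <- cand; break }
          }
          if (is.null(s0))
            stop("could not place a non-overlapping interval on chromosome ",
               ch)
          ccols <- off + s0 + seq_len(w)
          pfreq <- colMeans(v[, ccols, drop = FALSE], na.rm = TRUE) / 2
          string <- 2L * as.integer(rbinom(w, 1L,
                                           pmin(pmax(pfreq, 0.05), 0.95)))
          message("no existing homozygote string on chromosome ", ch,
                  "; planted a synthesized one")
        }
        ccols <- off + s0 + seq_len(w)
        gm <- v[, ccols, drop = FALSE]
        existing <- which(rowSums(!is.na(gm) & gm ==
                                    rep(string, each = n)) == w)
        n_add <- max(0L, ceiling(rq$frac * n) - length(existing))
        pool <- setdiff(seq_len(n), c(existing, used_carriers))
        add <- pool[sample.int(length(pool), n_add)]
        if (n_add)
          v[add, ccols] <- rep(string, each = n_add)
        used_carriers <- c(used_carriers, existing, add)
      } else {
        # choose an existing class close to the target frequency
        ccand <- NULL
        hom <- !is.na(v) & v != 1L
        cs <- cbind(0L, t(apply(hom[, off + seq_len(len), drop = FALSE], 1,
                                cumsum)))
        best <- NULL
        starts <- if (is.null(rq$start)) 0:(len - w) else rq$start
        for (s0 in starts) {
          if (overlaps(ch, s0, s0 + w)) next
          carr <- which(cs[, s0 + w + 1L] - cs[, s0 + 1L] == w)
          if (length(carr) < 2L) next
          str <- apply(v[carr, off + s0 + seq_len(w), drop = FALSE], 1,
                       paste, collapse = "")
          tab <- table(str)
          fr <- as.numeric(tab) / n
          ok <- which(fr >= 0.5 * rq$frac & fr <= 1.5 * rq$frac)
          for (k in ok) {
            d <- abs(fr[k] - rq$frac)
            if (is.null(best) || d < best$d)
              best <- list(d = d, s0 = s0, str = names(tab)[k])
          }
        }
        if (is.null(best))
          stop("no homozygote class with carrier frequency within 50% of ",
               rq$frac, " found on chromosome ", ch,
               " (window of ", w, " SNPs); consider force mode")
        s0 <- best$s0
        ccols <- off + s0 + seq_len(w)
        string <- as.integer(strsplit(best$str, "")[[1]])
      }
      # realized carriers: exact string match, no missing calls
      gm <- v[, ccols, drop = FALSE]
      match_mat <- !is.na(gm) & gm == rep(string, each = n)
      carriers <- which(rowSums(match_mat) == w)
      taken <- rbind(taken,
                     data.frame(chrom = ch, s = s0, e = s0 + w))
      planted[[length(planted) + 1L]] <- list(
        chrom = ch, start0 = s0 + off, end0 = s0 + off + w,
        start_bp = map$pos_bp[off + s0 + 1L],
        end_bp = map$pos_bp[off + s0 + w],
        string = paste(string, collapse = ""),
        effects = as.list(rq$effects),
        carriers = rownames(v)[carriers],
        frequency = length(carriers) / n)
    }
  })
  truth <- structure(list(planted = planted, seed = seed, forced = force,
                          note = paste("synthetic ground truth; all",
                                       "distributions are simulator choices")),
                     class = "sim_truth")
  list(genotypes = genotype_matrix(v, map), truth = truth)
}

#' Write the simulation ground truth as JSON
#' @param truth a `sim_truth` object.
#' @param path output path.
#' @export
write_sim_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Simulate phenotypes from the animal mixed model
#'
#' Generates traits from `y = Xb + Za + sum_j W c_j + e`: a pedigree-wide
#' additive genetic value with covariance `A * sigma2_a` (sampled by the
#' Mendelian-sampling recursion, founders `N(0, sigma2_a)`), one optional
#' categorical fixed factor set with random level means, four i.i.d. random
#' factors, planted ROH-class effects added to carriers, and a residual.
#' Binary and count traits are produced on a latent Gaussian scale (56-day
#' non-return rate by thresholding at its configured incidence, number of
#' services by rounding capped to 1..10).
#'
#' @param pedigree sorted [as_pedigree()].
#' @param genotypes a [genotype_matrix()]; its animals define the phenotyped
#'   set and must all appear in the pedigree.
#' @param truth optional `sim_truth` from [plant_roh_effects()].
#' @param vc `NULL` (derive per trait from `h2` and the variance fractions),
#'   a single [variance_components()] applied to every trait, or a named
#'   list per trait.
#' @param traits character vector of trait names from [trait_defaults()].
#' @param n_fixed_levels named integer vector of level counts for the fixed
#'   factors (NULL for none).
#' @param n_random_levels named integer vector of level counts for the four
#'   i.i.d. random factors.
#' @param h2 narrow-sense heritability used when `vc` is derived.
#' @param factor_var_frac fraction of phenotypic variance per random factor
#'   when `vc` is derived.
#' @param fixed_var_frac fraction of phenotypic variance taken up by fixed
#'   factor level spread (only when fixed factors are present).
#' @param seed RNG seed.
#' @return data.frame: `animal`, one column per trait, one column per
#'   factor; attribute `vc` holds the per-trait components used.
#' @export
simulate_phenotypes <- function(pedigree, genotypes, truth = NULL, vc = NULL,
                                traits = "MY",
                                n_fixed_levels = c(hys = 25L),
                                n_random_levels = c(hy = 30L, hrys = 40L,
                                                    ss = 25L, ait = 20L),
                                h2 = 0.3, factor_var_frac = 0.05,
                                fixed_var_frac = 0.1, seed = 1L) {
  check_sorted(pedigree)
  ids <- animal_ids(genotypes)
  if (!all(ids %in% pedigree$animal))
    stop("animal(s) in genotypes missing from pedigree: ",
         paste(utils::head(setdiff(ids, pedigree$animal), 3), collapse = ", "))
  td <- trait_defaults()
  if (!all(traits %in% td$trait))
    stop("unknown trait(s): ", paste(setdiff(traits, td$trait), collapse = ", "))
  td <- td[match(traits, td$trait), ]
  has_fixed <- !is.null(n_fixed_levels) && length(n_fixed_levels) > 0
  vclist <- lapply(seq_along(traits), function(k) {
    if (is.null(vc)) {
      s2 <- td$sd[k]^2
      ffrac <- if (has_fixed) fixed_var_frac else 0
      resid <- 1 - h2 - 4 * factor_var_frac - ffrac
      stopifnot(resid > 0)
      variance_components(animal = h2 * s2, hy = factor_var_frac * s2,
                          hrys = factor_var_frac * s2,
                          ss = factor_var_frac * s2,
                          ait = factor_var_frac * s2, residual = resid * s2)
    } else if (inherits(vc, "variance_components")) vc
    else vc[[traits[k]]]
  })
  names(vclist) <- traits
  n_ped <- nrow(pedigree)
  idx <- ped_indices(pedigree)
  Fi <- ml_inbreeding_cpp(idx$sire, idx$dam)
  with_seed(seed, {
    # additive values for all pedigree animals, one column per trait
    sig_a <- sqrt(vapply(vclist, function(v) v[["animal"]], 0))
    a <- matrix(0, n_ped, length(traits))
    for (i in seq_len(n_ped)) {
      s <- idx$sire[i]; d <- idx$dam[i]
      if (s == 0L && d == 0L) {
        a[i, ] <- rnorm(length(traits)) * sig_a
      } else {
        pm <- 0
        msv <- 1
        if (s > 0L && d > 0L) {
          pm <- 0.5 * (a[s, ] + a[d, ])
          msv <- 0.5 - 0.25 * (Fi[s] + Fi[d])
        } else if (s > 0L) {
          pm <- 0.5 * a[s, ]
          msv <- 0.75 - 0.25 * Fi[s]
        } else {
          pm <- 0.5 * a[d, ]
          msv <- 0.75 - 0.25 * Fi[d]
        }
        a[i, ] <- pm + rnorm(length(traits)) * sig_a * sqrt(msv)
      }
    }
    rownames(a) <- pedigree$animal
    n <- length(ids)
    out <- data.frame(animal = ids, stringsAsFactors = FALSE)
    fac_assign <- list()
    if (has_fixed)
      for (f in names(n_fixed_levels))
        fac_assign[[f]] <- sample.int(n_fixed_levels[[f]], n, replace = TRUE)
    for (f in names(n_random_levels))
      fac_assign[[f]] <- sample.int(n_random_levels[[f]], n, replace = TRUE)
    for (k in seq_along(traits)) {
      v <- vclist[[k]]
      y <- td$mean[k] + a[match(ids, pedigree$animal), k]
      if (has_fixed) {
        fsd <- sqrt(fixed_var_frac / length(n_fixed_levels)) * td$sd[k]
        for (f in names(n_fixed_levels)) {
          lev_mean <- rnorm(n_fixed_levels[[f]]) * fsd
          y <- y + lev_mean[fac_assign[[f]]]
        }
      }
      for (f in names(n_random_levels)) {
        sj <- sqrt(v[[f]])
        if (sj > 0) {
          eff <- rnorm(n_random_levels[[f]]) * sj
          y <- y + eff[fac_assign[[f]]]
        }
      }
      if (!is.null(truth)) {
        for (pl in truth$planted) {
          ek <- pl$effects[[traits[k]]]
          if (!is.null(ek)) {
            carr <- match(pl$carriers, ids)
            carr <- carr[!is.na(carr)]
            y[carr] <- y[carr] + ek
          }
        }
      }
      y <- y + rnorm(n) * sqrt(v[["residual"]])
      if (td$type[k] == "binary") {
        thr <- td$mean[k] + qnorm(1 - td$mean[k]) * td$sd[k]
        y <- as.integer(y >= thr)
      } else if (td$type[k] == "count") {
        y <- pmin(10L, pmax(1L, as.integer(round(y))))
      }
      out[[traits[k]]] <- y
    }
    for (f in names(fac_assign))
      out[[f]] <- sprintf("L%02d", fac_assign[[f]])
    attr(out, "vc") <- vclist
    out
  })
}

#' Simulate a complete study dataset
#'
#' Convenience wrapper chaining [simulate_pedigree()],
#' [simulate_genotypes()], [plant_roh_effects()] (force mode, so target
#' carrier frequencies are met exactly) and [simulate_phenotypes()] under
#' the package's reference desk-scale conditions: a ~2,000-animal pedigree
#' over 8 overlapping generations with 5\% sire usage, 5 chromosomes x 600
#' SNPs at 50 kb spacing (1 cM/Mb), and 3 planted unfavorable ROH classes
#' of 60 SNPs at ~3\% carrier frequency with an effect of -1 phenotypic SD
#' on each requested trait.
#'
#' @param seed RNG seed driving every stage.
#' @param traits traits to simulate.
#' @param n_founders,n_generations,offspring_per_dam,sire_fraction,gen_size
#'   pedigree shape; `gen_size` defaults to twice the founder count, giving
#'   about 2,000 animals under the default settings.
#' @param n_chrom,snps_per_chrom,spacing_bp,cM_per_Mb,founder_maf genome
#'   shape.
#' @param n_planted number of planted classes (0 for a null genome).
#' @param planted_frac,planted_len,planted_effect_sd planted-class carrier
#'   fraction, window length (SNPs) and effect size in phenotypic SD units.
#' @param h2 heritability used for the derived variance components.
#' @return list with `pedigree`, `genotypes`, `phenotypes`, `truth`, `vc`.
#' @export
simulate_roh_dataset <- function(seed = 1L, traits = "MY",
                                 n_founders = 120L, n_generations = 8L,
                                 offspring_per_dam = 2L, sire_fraction = 0.05,
                                 gen_size = NULL,
                                 n_chrom = 5L, snps_per_chrom = 600L,
                                 spacing_bp = 50000L, cM_per_Mb = 1,
                                 founder_maf = c(0.05, 0.5),
                                 n_planted = 3L, planted_frac = 0.03,
                                 planted_len = 60L, planted_effect_sd = -1,
                                 h2 = 0.3) {
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, 4L))
  gen_size <- gen_size %||% (2L * n_founders)
  ped <- simulate_pedigree(n_founders, n_generations, offspring_per_dam,
                           sire_fraction, seed = seeds[1],
                           gen_size = gen_size)
  map <- default_snp_map(n_chrom, snps_per_chrom, spacing_bp)
  geno <- simulate_genotypes(ped, map, founder_maf, cM_per_Mb,
                             seed = seeds[2])
  truth <- NULL
  if (n_planted > 0) {
    td <- trait_defaults()
    chroms <- rep(seq_len(n_chrom), length.out = n_planted)
    reqs <- lapply(seq_len(n_planted), function(i) {
      eff <- planted_effect_sd * td$sd[match(traits, td$trait)]
      list(chrom = chroms[i], length = planted_len, frac = planted_frac,
           effects = setNames(as.list(eff), traits))
    })
    pl <- plant_roh_effects(geno, reqs, seed = seeds[3], force = TRUE)
    geno <- pl$genotypes
    truth <- pl$truth
  }
  phen <- simulate_phenotypes(ped, geno, truth, traits = traits, h2 = h2,
                              seed = seeds[4])
  list(pedigree = ped, genotypes = geno, phenotypes = phen, truth = truth,
       vc = attr(phen, "vc"))
}
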