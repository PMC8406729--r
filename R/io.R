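#' Read PLINK text genotypes (.ped/.map)
#'
#' Alleles are recoded per SNP to alternate-allele counts, where the
#' alternate allele is the lexicographically later of the two observed
#' alleles (a fixed, documented convention; ROH classing is invariant to
#' allele polarity because it works on homozygote strings).  A `0 0` allele
#' pair becomes a missing call.  The map is sorted by (chromosome, position)
#' and the genotype columns are reordered to match.
#'
#' @param ped_path,map_path paths to the .ped and .map files.  The .map has
#'   4 columns (chrom, snp id, cM, bp); the .ped has 6 leading columns (only
#'   the second, the individual id, is used) followed by two allele columns
#'   per SNP with alleles in \{A, C, G, T, 0\}.
#' @return a [genotype_matrix()].
#' @export
read_plink_text <- function(ped_path, map_path) {
  if (!file.exists(ped_path)) stop("no such file: ", ped_path)
  if (!file.exists(map_path)) stop("no such file: ", map_path)
  mp <- utils::read.table(map_path, header = FALSE,
                          colClasses = c("integer", "character", "numeric",
                                         "integer"))
  if (ncol(mp) != 4L) stop(".map must have 4 columns")
  m <- nrow(mp)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  toks <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(toks)
  if (any(nf != 6L + 2L * m))
    stop("mismatched SNP count between .ped and .map (row with ",
         (nf[nf != 6L + 2L * m][1] - 6L) / 2, " SNPs, map has ", m, ")")
  tk <- matrix(unlist(toks), nrow = length(toks), byrow = TRUE)
  ids <- tk[, 2L]
  a1 <- tk[, 6L + 2L * seq_len(m) - 1L, drop = FALSE]
  a2 <- tk[, 6L + 2L * seq_len(m), drop = FALSE]
  vals <- matrix(NA_integer_, nrow = length(ids), ncol = m)
  for (j in seq_len(m)) {
    x1 <- a1[, j]; x2 <- a2[, j]
    miss <- x1 == "0" | x2 == "0"
    obs <- sort(unique(c(x1[!miss], x2[!miss])))
    if (length(obs) > 2L)
      stop("triallelic SNP ", mp[[2]][j], ": alleles ",
           paste(obs, collapse = "/"))
    if (length(obs) == 0L) next
    alt <- obs[length(obs)]
    vals[, j] <- (x1 == alt) + (x2 == alt)
    vals[miss, j] <- NA_integer_
  }
  rownames(vals) <- ids
  map <- snp_map(mp[[2]], mp[[1]], mp[[4]])
  # reorder columns into sorted map order
  vals <- vals[, match(map$snp_id, mp[[2]]), drop = FALSE]
  genotype_matrix(vals, map)
}

#' Write PLINK text genotypes
#'
#' Inverse of [read_plink_text()]: code 0 is written as the `A` homozygote,
#' 2 as the `C` homozygote (so that `C`, being lexicographically later, is
#' re-read as the alternate allele and the code matrix round-trips exactly),
#' missing as `0 0`.
#'
#' @param genotypes a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @export
write_plink_text <- function(genotypes, ped_path, map_path) {
  map <- genotypes$map
  utils::write.table(data.frame(map$chrom, map$snp_id, 0, map$pos_bp),
                     map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  v <- genotypes$values
  ids <- rownames(v)
  code_str <- c("A A", "A C", "C C")
  con <- file(ped_path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(v))) {
    g <- v[i, ]
    al <- ifelse(is.na(g), "0 0", code_str[g + 1L])
    writeLines(paste(ids[i], ids[i], 0, 0, 0, -9,
                     paste(al, collapse = " ")), con)
  }
  invisible(NULL)
}

#' Read / write genotype and SNP-map TSV
#'
#' The genotype TSV has a header `animal_id` plus one 0/1/2/NA column per
#' SNP (columns named by SNP id); the map TSV has columns
#' `snp_id`, `chrom`, `pos_bp`.
#'
#' @param geno_path,map_path file paths.
#' @return a [genotype_matrix()].
#' @export
read_genotype_tsv <- function(geno_path, map_path) {
  mp <- utils::read.table(map_path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  map <- snp_map(mp$snp_id, mp$chrom, mp$pos_bp)
  g <- utils::read.table(geno_path, header = TRUE, sep = "\t",
                         check.names = FALSE, stringsAsFactors = FALSE)
  v <- as.matrix(g[, -1, drop = FALSE])
  storage.mode(v) <- "integer"
  rownames(v) <- as.character(g[[1]])
  if (!setequal(colnames(v), map$snp_id))
    stop("genotype TSV columns do not match the SNP map")
  v <- v[, map$snp_id, drop = FALSE]
  genotype_matrix(v, map)
}

#' @rdname read_genotype_tsv
#' @param genotypes a [genotype_matrix()] to write.
#' @export
write_genotype_tsv <- function(genotypes, geno_path, map_path) {
  map <- genotypes$map
  utils::write.table(map[, c("snp_id", "chrom", "pos_bp")], map_path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  df <- data.frame(animal_id = rownames(genotypes$values),
                   genotypes$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, geno_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Load a pipeline configuration
#'
#' YAML file with up to four top-level sections: `scan` (keys of
#' [scan_params()]), `traits` (per-trait `direction` and optional `unit`),
#' `variance_components` (per-trait named components, see
#' [variance_components()]) and `factors` (`fixed` and `random` column
#' names).  Unspecified scan keys take their defaults; trait directions
#' default to lower-unfavorable for MY, FY, PY and NRR and
#' higher-unfavorable for NS, FSTC and AFS.  Unknown keys raise an error.
#'
#' @param path YAML file.
#' @return list with elements `scan` ([scan_params()]), `traits`
#'   (data.frame trait/direction/unit), `variance_components` (named list of
#'   [variance_components()] or NULL), `factors` (list of `fixed`/`random`
#'   character vectors).
#' @export
load_config <- function(path) {
  cfg <- yaml::read_yaml(path) %||% list()
  known <- c("scan", "traits", "variance_components", "factors")
  extra <- setdiff(names(cfg), known)
  if (length(extra))
    stop("unknown config section(s): ", paste(extra, collapse = ", "))
  sc <- cfg$scan %||% list()
  bad <- setdiff(names(sc), names(formals(scan_params)))
  if (length(bad))
    stop("unknown scan key(s): ", paste(bad, collapse = ", "))
  params <- do.call(scan_params, sc)
  tr <- cfg$traits %||% list()
  traits <- NULL
  if (length(tr)) {
    rows <- lapply(names(tr), function(nm) {
      e <- tr[[nm]] %||% list()
      bad <- setdiff(names(e), c("direction", "unit"))
      if (length(bad))
        stop("unknown trait key(s) for ", nm, ": ",
             paste(bad, collapse = ", "))
      dir <- e$direction %||% default_direction(nm)
      if (is.na(dir))
        stop("no unfavorable direction configured (or defaulted) for trait ",
             nm)
      if (!dir %in% c("lower", "higher"))
        stop("direction must be 'lower' or 'higher' for trait ", nm)
      data.frame(trait = nm, direction = dir, unit = e$unit %||% "",
                 stringsAsFactors = FALSE)
    })
    traits <- do.call(rbind, rows)
  }
  vcs <- NULL
  if (!is.null(cfg$variance_components)) {
    vcs <- lapply(cfg$variance_components, function(v) {
      bad <- setdiff(names(v), c("animal", "hy", "hrys", "ss", "ait",
                                 "residual"))
      if (length(bad))
        stop("unknown variance component(s): ", paste(bad, collapse = ", "))
      do.call(variance_components, v)
    })
  }
  fac <- cfg$factors %||% list()
  bad <- setdiff(names(fac), c("fixed", "random"))
  if (length(bad))
    stop("unknown factor key(s): ", paste(bad, collapse = ", "))
  list(scan = params, traits = traits, variance_components = vcs,
       factors = list(fixed = as.character(fac$fixed %||% character(0)),
                      random = as.character(fac$random %||% character(0))))
}

#' Read a phenotype/covariate CSV
#'
#' One row per animal: `animal` id column, numeric trait columns, and
#' categorical factor columns.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  names(df)[1] <- "animal"
  df$animal <- as.character(df$animal)
  df
}

# All writers emit tab-separated UTF-8 with a header line.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
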