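#' Construct a SNP map
#'
#' A SNP map describes the columns of a genotype matrix: one row per SNP with
#' its identifier, chromosome and physical position.  Rows are sorted by
#' (chromosome, position) and indexed 0..M-1 so that `index` is the 0-based
#' column of the SNP in the genotype matrix.
#'
#' @param snp_id character vector of unique SNP names.
#' @param chrom integer chromosome labels (autosomes are labelled 1..29 for
#'   cattle; anything outside that range is treated as non-autosomal by QC).
#' @param pos_bp integer base-pair positions, strictly increasing within a
#'   chromosome after sorting.
#' @return a `data.frame` of class `snp_map` with columns `snp_id`, `chrom`,
#'   `pos_bp`, `index`.
#' @export
snp_map <- function(snp_id, chrom, pos_bp) {
  stopifnot(length(snp_id) == length(chrom), length(chrom) == length(pos_bp))
  if (anyDuplicated(snp_id))
    stop("duplicate SNP ids in map")
  chrom <- as.integer(chrom)
  pos_bp <- as.integer(pos_bp)
  if (any(is.na(chrom)) || any(is.na(pos_bp)) || any(pos_bp < 0))
    stop("chromosome and position must be non-negative integers")
  o <- order(chrom, pos_bp)
  map <- data.frame(snp_id = as.character(snp_id)[o], chrom = chrom[o],
                    pos_bp = pos_bp[o], stringsAsFactors = FALSE)
  dup <- duplicated(map[, c("chrom", "pos_bp")])
  if (any(dup))
    stop("positions not strictly increasing within chromosome (duplicate at ",
         map$snp_id[which(dup)[1]], ")")
  map$index <- seq_len(nrow(map)) - 1L
  class(map) <- c("snp_map", "data.frame")
  map
}

#' Construct a genotype matrix
#'
#' Genotypes are stored as an integer matrix of alternate-allele counts
#' (0/1/2, `NA` = missing call) with one row per animal; columns follow the
#' SNP map order.
#'
#' @param values integer matrix, animals x SNPs, entries in \{0, 1, 2, NA\}.
#'   Row names are the animal ids.
#' @param map a [snp_map()] with as many rows as `values` has columns.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `values` and `map`.
#' @export
genotype_matrix <- function(values, map) {
  values <- as.matrix(values)
  storage.mode(values) <- "integer"
  if (is.null(rownames(values)))
    stop("genotype matrix must carry animal ids as row names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate animal ids in genotype matrix")
  if (ncol(values) != nrow(map))
    stop("genotype matrix has ", ncol(values), " columns but map has ",
         nrow(map), " SNPs")
  bad <- values[!is.na(values)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype codes must be 0, 1, 2 or NA")
  colnames(values) <- map$snp_id
  structure(list(values = values, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$values), "animals x", ncol(x$values),
      "SNPs on", length(unique(x$map$chrom)), "chromosome(s)\n")
  invisible(x)
}

n_animals <- function(g) nrow(g$values)
n_snps <- function(g) ncol(g$values)
animal_ids <- function(g) rownames(g$values)

# Chromosome blocks of a sorted map: 0-based column offset and length per
# chromosome.  Windows never cross block boundaries.
chrom_blocks <- function(map) {
  r <- rle(map$chrom)
  ends <- cumsum(r$lengths)
  data.frame(chrom = r$values, off0 = ends - r$lengths, len = r$lengths)
}

#' Scan parameters
#'
#' Tuning constants of the sliding-window scan and the discovery procedure.
#' Defaults follow the published procedure: windows start at 60 SNPs and
#' shrink by 5 down to 50, sliding one SNP at a time; a run needs at least 15
#' consecutive homozygous calls; a unique ROH genotype class must exceed a
#' 0.75\% carrier frequency; the genome-wise FDR is controlled at 1\%; the
#' empirical phenotype cut-off is calibrated from 1000 randomly sampled
#' windows using classes whose one-tailed significance falls in (0.05, 0.10).
#'
#' @param initial_window,window_decrement,min_window,slide_step window size
#'   schedule (SNPs).
#' @param min_run minimum run length (SNPs) stored in the run index.
#' @param min_class_frequency strict lower bound on class carrier frequency.
#' @param fdr_q genome-wise FDR level.
#' @param threshold_samples number of random windows for cut-off calibration.
#' @param threshold_sig_range significance band used for the cut-off.
#' @return a list of class `scan_params`.
#' @export
scan_params <- function(initial_window = 60L, window_decrement = 5L,
                        min_window = 50L, slide_step = 1L, min_run = 15L,
                        min_class_frequency = 0.0075, fdr_q = 0.01,
                        threshold_samples = 1000L,
                        threshold_sig_range = c(0.05, 0.10)) {
  p <- list(initial_window = as.integer(initial_window),
            window_decrement = as.integer(window_decrement),
            min_window = as.integer(min_window),
            slide_step = as.integer(slide_step),
            min_run = as.integer(min_run),
            min_class_frequency = min_class_frequency,
            fdr_q = fdr_q,
            threshold_samples = as.integer(threshold_samples),
            threshold_sig_range = as.numeric(threshold_sig_range))
  if (p$min_window > p$initial_window)
    stop("min_window must not exceed initial_window")
  if (p$min_class_frequency <= 0 || p$min_class_frequency >= 1)
    stop("min_class_frequency must lie in (0, 1)")
  if (p$fdr_q <= 0 || p$fdr_q >= 1)
    stop("fdr_q must lie in (0, 1)")
  if (p$window_decrement < 1L || p$slide_step < 1L || p$min_run < 1L)
    stop("window_decrement, slide_step and min_run must be positive")
  if (length(p$threshold_sig_range) != 2L ||
      p$threshold_sig_range[1] > p$threshold_sig_range[2])
    stop("threshold_sig_range must be an increasing pair")
  class(p) <- "scan_params"
  p
}

#' Default trait table
#'
#' The seven analyzed dairy traits with their observed scales (mean, SD),
#' measurement type and unfavorable direction.  Production traits (MY, FY,
#' PY) and the 56-day non-return rate are unfavorable when *lower*; number
#' of services, first-service-to-conception interval and age at first
#' service are unfavorable when *higher*.
#'
#' @return data.frame with columns `trait`, `mean`, `sd`, `direction`,
#'   `type`, `unit`.
#' @export
trait_defaults <- function() {
  data.frame(
    trait = c("MY", "FY", "PY", "AFS", "NS", "NRR", "FSTC"),
    mean = c(9074, 362, 295.50, 449.20, 1.59, 0.69, 19.32),
    sd = c(1732.2, 73.85, 54.58, 49.16, 0.93, 0.46, 33.37),
    direction = c("lower", "lower", "lower", "higher", "higher", "lower",
                  "higher"),
    type = c("continuous", "continuous", "continuous", "continuous", "count",
             "binary", "continuous"),
    unit = c("kg", "kg", "kg", "days", "services", "0/1", "days"),
    stringsAsFactors = FALSE)
}

# Default unfavorable direction for a trait name; NA if not a known trait.
default_direction <- function(trait) {
  td <- trait_defaults()
  td$direction[match(trait, td$trait)]
}

#' Variance components of the animal mixed model
#'
#' One additive genetic component (covariance `A * sigma2_a`), four i.i.d.
#' non-genetic random factors, and a residual.
#'
#' @param animal additive genetic variance.
#' @param hy,hrys,ss,ait variances of the four i.i.d. random factors.
#' @param residual residual variance (must be positive).
#' @return named numeric vector of class `variance_components`.
#' @export
variance_components <- function(animal, hy = 0, hrys = 0, ss = 0, ait = 0,
                                residual) {
  v <- c(animal = animal, hy = hy, hrys = hrys, ss = ss, ait = ait,
         residual = residual)
  if (any(v < 0)) stop("variance components must be non-negative")
  if (v["residual"] <= 0) stop("residual variance must be positive")
  class(v) <- "variance_components"
  v
}
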