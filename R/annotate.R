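#' Read a gene table from BED or GFF3
#'
#' BED rows are 0-based half-open (`chrom`, `start`, `end`, optional
#' `name`); GFF3 rows are 1-based inclusive and are converted internally
#' to the half-open convention.  When a GFF3 file contains `gene` features
#' only those are used, otherwise every feature row is kept.  Malformed
#' lines are skipped with a warning.
#'
#' @param path file path; format is chosen by extension (`.bed` vs
#'   `.gff`/`.gff3`).
#' @return data.frame with `chrom` (integer), `start0`, `end0` (0-based
#'   half-open bp) and `name`.
#' @export
read_gene_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  is_gff <- grepl("\\.gff3?$", path, ignore.case = TRUE)
  rows <- list()
  bad <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "\t")[[1]]
    if (is_gff) {
      s <- suppressWarnings(as.integer(f[4]))
      e <- suppressWarnings(as.integer(f[5]))
      ch <- suppressWarnings(as.integer(sub("^chr", "", f[1])))
      if (length(f) < 9L || is.na(s) || is.na(e) || is.na(ch) || e < s) {
        bad <- bad + 1L
        next
      }
      nm <- sub(".*Name=([^;]+).*", "\\1", f[9])
      if (nm == f[9]) nm <- sub(".*ID=([^;]+).*", "\\1", f[9])
      if (nm == f[9]) nm <- paste0(f[3], ":", f[1], ":", f[4])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start0 = s - 1L, end0 = e, name = nm, type = f[3],
        stringsAsFactors = FALSE)
    } else {
      s <- suppressWarnings(as.integer(f[2]))
      e <- suppressWarnings(as.integer(f[3]))
      ch <- suppressWarnings(as.integer(sub("^chr", "", f[1])))
      if (length(f) < 3L || is.na(s) || is.na(e) || is.na(ch) || e < s) {
        bad <- bad + 1L
        next
      }
      nm <- if (length(f) >= 4L) f[4] else paste0(f[1], ":", f[2])
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start0 = s, end0 = e, name = nm, type = "region",
        stringsAsFactors = FALSE)
    }
  }
  if (bad)
    warning(bad, " malformed annotation line(s) skipped")
  if (!length(rows)) stop("no usable annotation rows in ", path)
  g <- do.call(rbind, rows)
  if (is_gff && any(g$type == "gene")) g <- g[g$type == "gene", ]
  g$type <- NULL
  rownames(g) <- NULL
  g
}

#' Annotate discovery records with overlapping genes
#'
#' Lists, for each record, the genes whose span intersects the record's bp
#' interval.  Intersection is half-open: a gene that merely abuts an
#' interval end is not listed.
#'
#' @param records discovery records (a [discover()] result or its
#'   `records` data.frame) with `chrom`, `start_bp`, `end_bp`.
#' @param annotation_path gene table in BED or GFF3 ([read_gene_table()]).
#' @return the records data.frame with a `genes` column (comma-separated)
#'   plus attribute `gene_lists` (character vector per record).
#' @export
annotate_genes <- function(records, annotation_path) {
  if (inherits(records, "roh_discovery")) records <- records$records
  genes <- read_gene_table(annotation_path)
  lists <- vector("list", nrow(records))
  for (i in seq_len(nrow(records))) {
    s0 <- records$start_bp[i] - 1L
    e0 <- records$end_bp[i]
    hit <- genes$chrom == records$chrom[i] & genes$start0 < e0 &
      s0 < genes$end0
    lists[[i]] <- genes$name[hit]
  }
  records$genes <- vapply(lists, paste, collapse = ",", "")
  attr(records, "gene_lists") <- lists
  records
}
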