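#' Build a pedigree object
#'
#' Validates and topologically sorts a table of animal/sire/dam triples so
#' that every parent precedes its offspring.  Unknown parents are coded `NA`
#' (accepted input codes: `NA`, `""`, `"0"`).  Parents that appear only in
#' the sire/dam columns are added as founder records with a warning; the
#' founding population is assumed unrelated.
#'
#' @param df data.frame with columns `animal`, `sire`, `dam` (character or
#'   coercible); extra columns are carried along.
#' @return data.frame of class `pedigree`, topologically sorted, with
#'   attribute `sorted = TRUE`.
#' @export
as_pedigree <- function(df) {
  stopifnot(all(c("animal", "sire", "dam") %in% names(df)))
  df$animal <- as.character(df$animal)
  df$sire <- as.character(df$sire)
  df$dam <- as.character(df$dam)
  df$sire[df$sire %in% c("0", "") | is.na(df$sire)] <- NA_character_
  df$dam[df$dam %in% c("0", "") | is.na(df$dam)] <- NA_character_
  if (anyDuplicated(df$animal))
    stop("duplicate animal ids in pedigree")
  parents <- setdiff(stats::na.omit(c(df$sire, df$dam)), df$animal)
  if (length(parents)) {
    warning(length(parents),
            " parent(s) without own record added as founders")
    add <- df[rep(1L, length(parents)), , drop = FALSE]
    add[] <- NA
    add$animal <- parents
    add$sire <- NA_character_
    add$dam <- NA_character_
    df <- rbind(add, df)
    rownames(df) <- NULL
  }
  # Kahn-style topological sort in generational passes, stable within a pass.
  n <- nrow(df)
  si <- match(df$sire, df$animal)
  di <- match(df$dam, df$animal)
  placed <- logical(n)
  ord <- integer(0)
  repeat {
    ok <- !placed &
      (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
      (is.na(di) | placed[ifelse(is.na(di), 1L, di)])
    if (!any(ok)) {
      if (all(placed)) break
      # cycle: walk parent links among the unplaced until a repeat
      cur <- which(!placed)[1]
      path <- integer(0)
      while (!cur %in% path) {
        path <- c(path, cur)
        nxt <- c(si[cur], di[cur])
        nxt <- nxt[!is.na(nxt) & !placed[nxt]]
        cur <- nxt[1]
      }
      cyc <- df$animal[path[which(path == cur)[1]:length(path)]]
      stop("pedigree contains a cycle: ", paste(cyc, collapse = " -> "))
    }
    ord <- c(ord, which(ok))
    placed[ok] <- TRUE
  }
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pedigree", "data.frame")
  attr(out, "sorted") <- TRUE
  out
}

#' Read a pedigree CSV
#'
#' Expects a header `animal,sire,dam`; unknown parents coded `0` or empty.
#'
#' @param path file path.
#' @return a [as_pedigree()] object.
#' @export
read_pedigree <- function(path) {
  df <- utils::read.csv(path, colClasses = "character",
                        stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  as_pedigree(df)
}

# 1-based parent positions (0 = unknown) for a sorted pedigree.
ped_indices <- function(ped) {
  si <- match(ped$sire, ped$animal)
  di <- match(ped$dam, ped$animal)
  si[is.na(si)] <- 0L
  di[is.na(di)] <- 0L
  list(sire = as.integer(si), dam = as.integer(di))
}

check_sorted <- function(ped) {
  if (!isTRUE(attr(ped, "sorted")))
    stop("pedigree must be topologically sorted (use as_pedigree())")
}

#' Pedigree inbreeding coefficients
#'
#' Computes F by the Meuwissen-Luo recursion on the sorted pedigree.
#'
#' @param pedigree a sorted [as_pedigree()] object.
#' @return named numeric vector of inbreeding coefficients.
#' @export
pedigree_inbreeding <- function(pedigree) {
  check_sorted(pedigree)
  idx <- ped_indices(pedigree)
  setNames(ml_inbreeding_cpp(idx$sire, idx$dam), pedigree$animal)
}

#' Inbreeding coefficients and the inverse numerator relationship matrix
#'
#' F by the Meuwissen-Luo recursion; the sparse A-inverse assembled directly
#' by Henderson's rules with the inbreeding adjustment (the Mendelian
#' sampling variance of animal i is `0.5 - 0.25 (F_s + F_d)` when both
#' parents are known, `0.75 - 0.25 F_p` with one known parent, 1 for
#' founders).
#'
#' @param pedigree a sorted [as_pedigree()] object.
#' @return list with elements `F` (named numeric) and `A_inverse` (sparse
#'   symmetric `Matrix`, one row/column per pedigree animal).
#' @export
inbreeding_and_a_inverse <- function(pedigree) {
  check_sorted(pedigree)
  idx <- ped_indices(pedigree)
  Fi <- ml_inbreeding_cpp(idx$sire, idx$dam)
  n <- nrow(pedigree)
  s <- idx$sire
  d <- idx$dam
  Fs <- ifelse(s > 0, Fi[pmax(s, 1L)], 0)
  Fd <- ifelse(d > 0, Fi[pmax(d, 1L)], 0)
  dii <- ifelse(s > 0 & d > 0, 0.5 - 0.25 * (Fs + Fd),
         ifelse(s > 0, 0.75 - 0.25 * Fs,
         ifelse(d > 0, 0.75 - 0.25 * Fd, 1)))
  al <- 1 / dii
  i <- seq_len(n)
  ii <- i; jj <- i; xx <- al
  hs <- s > 0
  hd <- d > 0
  # parent-offspring and parent-parent contributions
  ii <- c(ii, i[hs], s[hs], s[hs])
  jj <- c(jj, s[hs], i[hs], s[hs])
  xx <- c(xx, -al[hs] / 2, -al[hs] / 2, al[hs] / 4)
  ii <- c(ii, i[hd], d[hd], d[hd])
  jj <- c(jj, d[hd], i[hd], d[hd])
  xx <- c(xx, -al[hd] / 2, -al[hd] / 2, al[hd] / 4)
  hb <- hs & hd
  ii <- c(ii, s[hb], d[hb])
  jj <- c(jj, d[hb], s[hb])
  xx <- c(xx, al[hb] / 4, al[hb] / 4)
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(pedigree$animal,
                                               pedigree$animal))
  list(F = setNames(Fi, pedigree$animal),
       A_inverse = Matrix::forceSymmetric(Ainv))
}
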