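# Percent identity is the study's only similarity measure. The denominator
# convention is fixed package-wide: columns where BOTH sequences are non-gap.
# The convention tag travels with every identity matrix so alternative
# denominators could be added later without ambiguity.

#' Needleman-Wunsch global alignment with linear gap penalty
#'
#' Deterministic traceback: ties are broken by preferring the diagonal move
#' (match/mismatch), then a gap in `b`, then a gap in `a`.
#'
#' @param a,b ungapped sequences (single strings, or named length-1 vectors).
#' @param match,mismatch,gap scores (gap is the per-column gap score, usually
#'   negative).
#' @return list with `a`, `b` (gapped strings of equal length) and `score`.
#' @examples
#' global_align("ACGT", "AGT", match = 1, mismatch = -1, gap = -1)
#' @export
global_align <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  sa <- strsplit(toupper(as.character(a)[1]), "")[[1]]
  sb <- strsplit(toupper(as.character(b)[1]), "")[[1]]
  if (any(sa == "-") || any(sb == "-")) stop("global_align expects ungapped input")
  n <- length(sa); m <- length(sb)
  F <- matrix(0, n + 1, m + 1)
  F[, 1] <- gap * (0:n)
  F[1, ] <- gap * (0:m)
  # move codes: 1 = diagonal, 2 = up (gap in b), 3 = left (gap in a)
  TB <- matrix(0L, n + 1, m + 1)
  TB[-1, 1] <- 2L
  TB[1, -1] <- 3L
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d <- F[i, j] + if (sa[i] == sb[j]) match else mismatch
      u <- F[i, j + 1] + gap
      l <- F[i + 1, j] + gap
      best <- max(d, u, l)
      F[i + 1, j + 1] <- best
      TB[i + 1, j + 1] <- if (d == best) 1L else if (u == best) 2L else 3L
    }
  }
  ra <- character(0); rb <- character(0)
  i <- n + 1L; j <- m + 1L
  while (i > 1L || j > 1L) {
    mv <- TB[i, j]
    if (mv == 1L) {
      ra <- c(sa[i - 1L], ra); rb <- c(sb[j - 1L], rb); i <- i - 1L; j <- j - 1L
    } else if (mv == 2L) {
      ra <- c(sa[i - 1L], ra); rb <- c("-", rb); i <- i - 1L
    } else {
      ra <- c("-", ra); rb <- c(sb[j - 1L], rb); j <- j - 1L
    }
  }
  list(a = paste(ra, collapse = ""), b = paste(rb, collapse = ""),
       score = F[n + 1L, m + 1L])
}

#' Percent identity of two aligned (gapped) sequences
#'
#' `100 * matches / columns where both sequences are non-gap`, optionally
#' restricted to a region of alignment columns. Computed at full precision;
#' round only for display (the package convention is 1 decimal).
#'
#' @param a,b gapped sequences of equal length.
#' @param region optional alignment-column [region()].
#' @return the percentage in `[0, 100]`; `NA` with a classed warning
#'   (`coildiverge_undefined_identity`) when no column has both sequences
#'   non-gap.
#' @export
percent_identity <- function(a, b, region = NULL) {
  ca <- strsplit(as.character(a)[1], "")[[1]]
  cb <- strsplit(as.character(b)[1], "")[[1]]
  if (length(ca) != length(cb)) {
    stop(sprintf("gapped lengths differ (%d vs %d)", length(ca), length(cb)))
  }
  keep <- seq_along(ca)
  if (!is.null(region)) {
    region <- as_region(region, "alignment_column")
    if (region$end > length(ca)) stop("region exceeds alignment width")
    keep <- region_seq(region)
  }
  ca <- ca[keep]; cb <- cb[keep]
  both <- ca != "-" & cb != "-"
  denom <- sum(both)
  if (denom == 0L) {
    warning(structure(class = c("coildiverge_undefined_identity", "warning", "condition"),
                      list(message = "no mutually ungapped columns: identity undefined",
                           call = sys.call(-1))))
    return(NA_real_)
  }
  100 * sum(ca[both] == cb[both]) / denom
}

#' Pairwise percent-identity matrix over an alignment
#'
#' @param x an [msa()].
#' @param region optional alignment-column [region()] (e.g. the mapped
#'   functional domain) restricting every comparison.
#' @return symmetric numeric matrix (diagonal 100) of class
#'   `"identity_matrix"` with attributes `region` and `convention`
#'   (`"both-ungapped"`). Undefined pairs are `NA`.
#' @export
identity_matrix <- function(x, region = NULL) {
  stopifnot(inherits(x, "msa"))
  ids <- x$ids
  n <- length(ids)
  m <- matrix(100, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      v <- percent_identity(x$seqs[[i]], x$seqs[[j]], region)
      m[i, j] <- v
      m[j, i] <- v
    }
  }
  structure(m, class = c("identity_matrix", class(m)),
            region = region, convention = "both-ungapped")
}

#' @export
print.identity_matrix <- function(x, digits = 1, ...) {
  r <- attr(x, "region")
  cat(sprintf("<identity_matrix> %d species, convention: %s%s\n",
              nrow(x), attr(x, "convention"),
              if (!is.null(r)) sprintf(", columns %s", format(r)) else ""))
  print(round(unclass(x), digits))
  invisible(x)
}

#' Two-triangle identity table (whole sequence below, region above)
#'
#' Writes a TSV mirroring the classic figure layout: whole-sequence
#' identities in the lower-left triangle, region-restricted identities in
#' the upper-right, blank diagonal. Values are rounded to 1 decimal.
#'
#' @param whole identity matrix for the full alignment.
#' @param domain identity matrix restricted to the domain region.
#' @param path output TSV path.
#' @return the character matrix written, invisibly.
#' @export
write_identity_tsv <- function(whole, domain, path) {
  stopifnot(identical(rownames(whole), rownames(domain)))
  ids <- rownames(whole)
  n <- length(ids)
  out <- matrix("", n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    v <- if (i > j) whole[i, j] else domain[i, j]
    out[i, j] <- ifelse(is.na(v), "NA", sprintf("%.1f", v))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(out)
}

#' Residues specific to one lineage against a conserved background
#'
#' Reports alignment columns where the target sequence differs from a set of
#' background sequences that all agree with each other, everything non-gap.
#' This is the classic human-specific-residue scan: the background is the
#' other members of the target's clade.
#'
#' @param x an [msa()].
#' @param target id of the focal sequence.
#' @param background ids of the comparison sequences (non-empty, excluding
#'   the target).
#' @return data frame with `column` (1-based alignment column),
#'   `target_residue`, `background_residue`.
#' @export
find_lineage_specific_residues <- function(x, target, background) {
  stopifnot(inherits(x, "msa"))
  if (!(target %in% x$ids)) stop(sprintf("target '%s' not in alignment", target))
  background <- setdiff(background, target)
  missing <- setdiff(background, x$ids)
  if (length(missing)) stop(sprintf("background id(s) not in alignment: %s",
                                    paste(missing, collapse = ", ")))
  if (!length(background)) stop("background must contain at least one other id")
  m <- msa_matrix(x)
  tg <- m[target, ]
  bg <- m[background, , drop = FALSE]
  bg_same <- apply(bg, 2, function(col) all(col != "-") && length(unique(col)) == 1L)
  hit <- which(tg != "-" & bg_same & tg != bg[1, ])
  data.frame(column = hit,
             target_residue = unname(tg[hit]),
             background_residue = unname(bg[1, hit]),
             row.names = NULL, stringsAsFactors = FALSE)
}
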