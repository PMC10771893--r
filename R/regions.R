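#' Half-open interval on a sequence, alignment, or codon coordinate system
#'
#' Regions are 0-based half-open internally; human-readable reports render
#' them 1-based closed. The coordinate space records what the indices count:
#' ungapped residues of one sequence (`"sequence"`), columns of an alignment
#' (`"alignment_column"`), or codons of a CDS (`"codon"`).
#'
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end; must satisfy `start < end`.
#' @param space one of `"sequence"`, `"alignment_column"`, `"codon"`.
#' @return An object of class `"region"`: a list with `start`, `end`, `space`.
#' @examples
#' region(10, 38)                      # residues 11..38, 1-based closed
#' region(110, 190, space = "codon")   # a codon-resolved domain
#' @export
region <- function(start, end, space = c("sequence", "alignment_column", "codon")) {
  space <- match.arg(space)
  start <- as.integer(start)
  end <- as.integer(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end)) {
    stop("region start/end must be single non-missing integers")
  }
  if (start < 0L) stop("region start must be >= 0")
  if (start >= end) stop(sprintf("region start (%d) must be < end (%d)", start, end))
  structure(list(start = start, end = end, space = space), class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("<region> [%d, %d) in %s space (1-based closed: %d-%d)\n",
              x$start, x$end, x$space, x$start + 1L, x$end))
  invisible(x)
}

#' @export
length.region <- function(x) x$end - x$start

#' @export
format.region <- function(x, ...) sprintf("%d-%d", x$start + 1L, x$end)

is_region <- function(x) inherits(x, "region")

as_region <- function(x, space) {
  if (is_region(x)) return(x)
  if (is.numeric(x) && length(x) == 2L) return(region(x[1], x[2], space))
  stop("expected a region() or a numeric (start, end) pair")
}

#' Indices (1-based) covered by a region
#' @param x a `region`.
#' @return integer vector `seq(start + 1, end)`.
#' @keywords internal
region_seq <- function(x) seq.int(x$start + 1L, x$end)
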