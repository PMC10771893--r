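# Windowed heptad-propensity scoring of coiled-coil regions. A window of
# length 28 (four heptads) slides over the protein; at each start and register
# phase the positional log-odds of its residues are summed, and each residue
# keeps the best score of any window/phase covering it. Runs of residues at or
# above the table's threshold become calls. Downstream analyses accept
# user-supplied domain coordinates, so the caller is a convenience, not a
# dependency.

HEPTAD <- c("a", "b", "c", "d", "e", "f", "g")

#' Read a heptad propensity table
#'
#' The file is TSV: `#`-prefixed metadata lines (`window`, `threshold`,
#' `unknown_score`), a header, then 20 rows (one per amino acid) of log-odds
#' scores for heptad positions a-g. `unknown_score: min` scores unknown
#' residues (`X`, `*`) at the table minimum.
#'
#' @param path table file; default is the table shipped with the package.
#' @return object of class `"propensity_table"`: list with `scores` (20x7
#'   matrix), `window`, `threshold`, `unknown_score`.
#' @export
read_propensity_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "coil_propensity.tsv", package = "coildiverge")
  }
  if (!file.exists(path)) stop(sprintf("propensity table not found: %s", path))
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default = NULL) {
    hit <- grep(sprintf("^#\\s*%s:", key), meta, value = TRUE)
    if (!length(hit)) return(default)
    trimws(sub(sprintf("^#\\s*%s:\\s*", key), "", hit[1]))
  }
  window <- as.integer(get_meta("window", "28"))
  threshold <- as.numeric(get_meta("threshold", "21"))
  unknown <- get_meta("unknown_score", "min")
  body <- utils::read.delim(text = paste(grep("^#", lines, value = TRUE, invert = TRUE),
                                         collapse = "\n"),
                            stringsAsFactors = FALSE, check.names = FALSE)
  if (!identical(colnames(body), c("aa", HEPTAD))) {
    stop("propensity table must have columns: aa, a, b, c, d, e, f, g")
  }
  scores <- as.matrix(body[, HEPTAD])
  rownames(scores) <- body$aa
  if (nrow(scores) != 20L || !setequal(rownames(scores), AA_CHARS)) {
    stop("propensity table must have one row per standard amino acid")
  }
  if (any(!is.finite(scores))) stop("propensity table entries must be finite")
  if (window < 7L || window %% 7L != 0L) stop("window must be a positive multiple of 7")
  unknown_score <- if (identical(unknown, "min")) min(scores) else as.numeric(unknown)
  structure(list(scores = scores, window = window, threshold = threshold,
                 unknown_score = unknown_score),
            class = "propensity_table")
}

#' @export
print.propensity_table <- function(x, ...) {
  cat(sprintf("<propensity_table> window %d, threshold %.2f, unknown residues score %.2f\n",
              x$window, x$threshold, x$unknown_score))
  invisible(x)
}

residue_scores <- function(chars, phase, table) {
  pos <- HEPTAD[((seq_along(chars) - 1L + phase) %% 7L) + 1L]
  known <- chars %in% rownames(table$scores)
  s <- rep(table$unknown_score, length(chars))
  s[known] <- table$scores[cbind(chars[known], pos[known])]
  s
}

#' Score one window at one heptad register phase
#'
#' Sums `table[residue, heptad position]` over the window, with heptad
#' position `(offset + phase) mod 7` (phase 0 puts the first residue at
#' position a). Unknown residues (`X`, `*`) get the table's unknown score.
#'
#' @param seq ungapped protein sequence (single string).
#' @param start 0-based start of the window.
#' @param phase register phase 0-6.
#' @param table a [read_propensity_table()] table.
#' @return the window score.
#' @export
window_score <- function(seq, start, phase, table) {
  chars <- strsplit(toupper(as.character(seq)[1]), "")[[1]]
  if (any(chars == "-")) stop("window_score expects ungapped input")
  start <- as.integer(start)
  phase <- as.integer(phase) %% 7L
  if (start < 0L || start + table$window > length(chars)) {
    stop("window does not fit in the sequence")
  }
  idx <- seq.int(start + 1L, start + table$window)
  sum(residue_scores(chars[idx], phase, table))
}

#' Call coiled-coil regions in a protein
#'
#' Every residue gets the maximum score of any window (any phase) covering
#' it; maximal runs of residues with score >= threshold become calls, and
#' adjacent calls separated by fewer than 7 residues are merged (a single
#' broken heptad should not split a domain). Sequences shorter than the
#' window yield no calls.
#'
#' @param seq ungapped protein (single string or named length-1 vector).
#' @param table a [read_propensity_table()] table (default: shipped table).
#' @return list of calls, each a list with `region` (sequence-space
#'   [region()]), `best_phase`, `max_score`; the full per-residue score
#'   track is attached as attribute `"score_track"`.
#' @export
predict_coiled_coil <- function(seq, table = read_propensity_table()) {
  chars <- strsplit(toupper(as.character(seq)[1]), "")[[1]]
  n <- length(chars)
  w <- table$window
  if (n < w) {
    out <- list()
    attr(out, "score_track") <- rep(-Inf, n)
    return(out)
  }
  n_windows <- n - w + 1L
  # per-phase residue scores, reused across windows via cumulative sums
  track <- rep(-Inf, n)
  win_best <- rep(-Inf, n_windows)
  win_phase <- rep(NA_integer_, n_windows)
  for (phase in 0:6) {
    rs <- residue_scores(chars, phase, table)
    cs <- c(0, cumsum(rs))
    ws <- cs[(w + 1L):(n + 1L)] - cs[1:n_windows]
    better <- ws > win_best
    win_best[better] <- ws[better]
    win_phase[better] <- phase
  }
  for (s in seq_len(n_windows)) {
    idx <- seq.int(s, s + w - 1L)
    track[idx] <- pmax(track[idx], win_best[s])
  }
  above <- track >= table$threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  calls <- data.frame(start = starts[runs$values], end = ends[runs$values])
  if (nrow(calls) > 1L) {
    merged <- calls[1, , drop = FALSE]
    for (k in 2:nrow(calls)) {
      if (calls$start[k] - merged$end[nrow(merged)] - 1L < 7L) {
        merged$end[nrow(merged)] <- calls$end[k]
      } else {
        merged <- rbind(merged, calls[k, ])
      }
    }
    calls <- merged
  }
  out <- lapply(seq_len(nrow(calls)), function(k) {
    covering <- which(calls$start[k] <= seq_len(n_windows) + w - 1L &
                        seq_len(n_windows) >= calls$start[k] - w + 1L &
                        seq_len(n_windows) <= calls$end[k])
    covering <- covering[win_best[covering] >= table$threshold]
    best <- covering[which.max(win_best[covering])]
    list(region = region(calls$start[k] - 1L, calls$end[k], "sequence"),
         best_phase = win_phase[best],
         max_score = win_best[best])
  })
  attr(out, "score_track") <- track
  out
}

#' Write coiled-coil calls as BED and a score TSV
#'
#' @param calls result of [predict_coiled_coil()].
#' @param id sequence name for the BED chrom column.
#' @param bed_path,tsv_path output paths (either may be NULL to skip).
#' @return invisibly, a data frame of the calls.
#' @export
write_coil_calls <- function(calls, id, bed_path = NULL, tsv_path = NULL) {
  df <- if (length(calls)) {
    data.frame(id = id,
               start = vapply(calls, function(cl) cl$region$start, integer(1)),
               end = vapply(calls, function(cl) cl$region$end, integer(1)),
               best_phase = vapply(calls, function(cl) cl$best_phase, integer(1)),
               max_score = vapply(calls, function(cl) cl$max_score, numeric(1)))
  } else {
    data.frame(id = character(0), start = integer(0), end = integer(0),
               best_phase = integer(0), max_score = numeric(0))
  }
  if (!is.null(bed_path)) {
    bed <- df[, c("id", "start", "end")]
    utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(df)
}

#' Map a reference-sequence region across an alignment
#'
#' Converts a residue interval on one (gapped) member of an alignment to
#' alignment columns, then projects it onto every other member as the
#' interval of its own residues falling in those columns.
#'
#' @param x an [msa()].
#' @param reference id of the sequence carrying the region.
#' @param reg sequence-space [region()] on the reference's ungapped residues.
#' @return list with `alignment_region` (alignment-column [region()]) and
#'   `per_species`: per id, a sequence-space [region()] or `NULL` (flagged
#'   all-gap) when the species has no residues in the mapped columns.
#' @export
map_region_across_msa <- function(x, reference, reg) {
  stopifnot(inherits(x, "msa"))
  if (!(reference %in% x$ids)) stop(sprintf("reference '%s' not in alignment", reference))
  reg <- as_region(reg, "sequence")
  chars <- strsplit(x$seqs[[reference]], "")[[1]]
  res_cols <- which(chars != "-")  # alignment column of each reference residue
  if (reg$end > length(res_cols)) {
    stop(sprintf("region %s exceeds reference ungapped length %d",
                 format(reg), length(res_cols)))
  }
  cols <- res_cols[region_seq(reg)]
  aln_reg <- region(min(cols) - 1L, max(cols), "alignment_column")
  per_species <- lapply(x$ids, function(id) {
    sc <- strsplit(x$seqs[[id]], "")[[1]]
    resn <- cumsum(sc != "-")  # residue count up to each column
    inside <- which(sc != "-" & seq_along(sc) >= (aln_reg$start + 1L) &
                      seq_along(sc) <= aln_reg$end)
    if (!length(inside)) return(NULL)
    region(resn[inside[1]] - 1L, resn[inside[length(inside)]], "sequence")
  })
  names(per_species) <- x$ids
  list(alignment_region = aln_reg, per_species = per_species)
}
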