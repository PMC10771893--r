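# Sequence sets are plain named character vectors (names = record ids) with a
# "descriptions" attribute carrying the remainder of each FASTA header.
# Alignments get the light S3 wrapper `msa` so width invariants are enforced
# once, at construction.

AA_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
DNA_CHARS <- c("A", "C", "G", "T")
GAP_CHAR <- "-"

seq_set <- function(residues, descriptions = NULL) {
  ids <- names(residues)
  if (is.null(ids) || any(!nzchar(ids)) || anyNA(ids)) {
    stop("every sequence record needs a non-empty id")
  }
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop(sprintf("duplicate sequence id(s): %s",
                                paste(unique(dup), collapse = ", ")))
  res <- toupper(as.character(residues))
  names(res) <- ids
  if (is.null(descriptions)) descriptions <- setNames(rep("", length(ids)), ids)
  attr(res, "descriptions") <- descriptions
  res
}

detect_alphabet <- function(seqs) {
  chars <- unique(strsplit(paste(gsub("-", "", seqs), collapse = ""), "")[[1]])
  if (length(chars) == 0L || all(chars %in% DNA_CHARS)) "dna" else "protein"
}

legal_chars <- function(alphabet, gapped) {
  chars <- switch(alphabet,
    dna = DNA_CHARS,
    protein = c(AA_CHARS, "*"),
    stop("alphabet must be 'dna' or 'protein'"))
  if (gapped) chars <- c(chars, GAP_CHAR)
  chars
}

validate_residues <- function(seqs, alphabet, gapped, context = "sequence") {
  ok <- legal_chars(alphabet, gapped)
  for (id in names(seqs)) {
    chars <- strsplit(seqs[[id]], "")[[1]]
    bad <- which(!(chars %in% ok))
    if (length(bad)) {
      stop(sprintf("illegal %s character '%s' in record '%s' at position %d",
                   alphabet, chars[bad[1]], id, bad[1]))
    }
  }
  invisible(seqs)
}

#' Read a FASTA file of ungapped sequences
#'
#' Residues are uppercased; record order is preserved. The id is the header
#' token up to the first whitespace, the rest is kept as the description.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"auto"` (default), `"dna"`, or `"protein"`; with
#'   `"auto"`, records made only of A/C/G/T are taken as nucleotide.
#' @param gapped allow `-` characters (alignment context). `read_fasta()`
#'   itself rejects gaps; see [read_alignment()].
#' @return named character vector of residues (one element per record) with a
#'   `descriptions` attribute.
#' @seealso [write_fasta()], [read_alignment()]
#' @export
read_fasta <- function(path, alphabet = c("auto", "dna", "protein"), gapped = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (file.size(path) == 0L) stop(sprintf("parse error: '%s' is empty", path))
  set <- tryCatch(Biostrings::readBStringSet(path, format = "fasta"),
                  error = function(e) stop(sprintf("parse error in '%s': %s",
                                                   path, conditionMessage(e))))
  if (length(set) == 0L) stop(sprintf("parse error: no FASTA records in '%s'", path))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  out <- seq_set(seqs, setNames(desc, ids))
  if (alphabet == "auto") alphabet <- detect_alphabet(out)
  validate_residues(out, alphabet, gapped)
  attr(out, "alphabet") <- alphabet
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector (ids as names); a `descriptions`
#'   attribute, if present, is appended to each header.
#' @param path output path.
#' @param width line-wrap width for the sequence body.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  ids <- names(seqs)
  if (is.null(ids)) stop("seqs must be a named character vector")
  desc <- attr(seqs, "descriptions")
  headers <- vapply(ids, function(id) {
    d <- if (!is.null(desc) && !is.na(desc[id]) && nzchar(desc[id])) paste0(" ", desc[id]) else ""
    paste0(id, d)
  }, character(1))
  set <- Biostrings::BStringSet(setNames(as.character(seqs), headers))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Construct a multiple sequence alignment
#'
#' @param seqs named character vector of gapped sequences, all the same
#'   length, `-` as the only gap character, at least two records.
#' @param alphabet `"auto"`, `"dna"`, or `"protein"`.
#' @return an object of class `"msa"`: list with `seqs` (named character
#'   vector), `ids`, `n_cols`, `alphabet`.
#' @export
msa <- function(seqs, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  seqs <- seq_set(seqs, attr(seqs, "descriptions"))
  if (length(seqs) < 2L) stop("an alignment needs at least 2 records")
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) {
    stop(sprintf("alignment records differ in length: %s",
                 paste(sprintf("%s=%d", names(seqs), lens), collapse = ", ")))
  }
  if (any(grepl(".", seqs, fixed = TRUE))) {
    stop("'.' is not accepted as a gap character; use '-'")
  }
  if (alphabet == "auto") alphabet <- detect_alphabet(seqs)
  validate_residues(seqs, alphabet, gapped = TRUE)
  structure(list(seqs = seqs, ids = names(seqs),
                 n_cols = unname(lens[1]), alphabet = alphabet),
            class = "msa")
}

#' Read an aligned FASTA file
#'
#' `-` is the gap character; `.` is rejected. All records must share one
#' length and there must be at least two of them.
#'
#' @inheritParams read_fasta
#' @return an [msa()] object.
#' @export
read_alignment <- function(path, alphabet = c("auto", "dna", "protein")) {
  alphabet <- match.arg(alphabet)
  raw <- read_fasta(path, alphabet = "auto", gapped = TRUE)
  if (any(grepl(".", raw, fixed = TRUE))) {
    stop("'.' is not accepted as a gap character; use '-'")
  }
  msa(raw, alphabet = if (alphabet == "auto") detect_alphabet(raw) else alphabet)
}

#' Write an alignment to aligned FASTA
#' @param x an [msa()] object.
#' @param path output path.
#' @export
write_alignment <- function(x, path) {
  stopifnot(inherits(x, "msa"))
  write_fasta(x$seqs, path)
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d records x %d columns (%s)\n",
              length(x$ids), x$n_cols, x$alphabet))
  show <- utils::head(x$ids, 9)
  for (id in show) {
    s <- x$seqs[[id]]
    cat(sprintf("  %-12s %s%s\n", id, substr(s, 1, 50),
                if (nchar(s) > 50) "..." else ""))
  }
  if (length(x$ids) > length(show)) cat(sprintf("  ... %d more\n", length(x$ids) - length(show)))
  invisible(x)
}

# matrix of single characters, rows = records, cols = alignment columns
msa_matrix <- function(x) {
  stopifnot(inherits(x, "msa"))
  m <- do.call(rbind, strsplit(unname(x$seqs), ""))
  rownames(m) <- x$ids
  m
}

# drop gaps from one record of an alignment
ungap <- function(s) gsub("-", "", s, fixed = TRUE)
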