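# Trees are ape "phylo" objects throughout. Unrooted trees follow the
# trifurcating-root convention. Bootstrap / consensus support lives in
# tree$node.label as a number in [0, 1].

#' Parse a Newick string or file into a phylo tree
#'
#' Internal node labels are retained; numeric labels are the convention for
#' clade support (fractions in `[0, 1]`).
#'
#' @param text a Newick string (must end in `;`). Give either `text` or `path`.
#' @param path a file containing one Newick tree.
#' @return an `ape::phylo` tree.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  if (is.null(text) && is.null(path)) stop("give either text or path")
  if (is.null(text)) {
    if (!file.exists(path)) stop(sprintf("file not found: %s", path))
    text <- paste(readLines(path, warn = FALSE), collapse = "")
  }
  depth <- 0L
  chars <- strsplit(text, "")[[1]]
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) stop(sprintf("malformed Newick: unmatched ')' at character %d", i))
    }
  }
  if (depth != 0L) stop(sprintf("malformed Newick: %d unclosed '(' at end of input", depth))
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL)
  if (is.null(tree)) stop("malformed Newick: could not be parsed")
  tree
}

# print a branch length with 6 significant digits, always with a decimal point
format_brlen <- function(x) {
  s <- sprintf("%.6g", x)
  if (!grepl("[.e]", s)) s <- paste0(s, ".0")
  s
}

#' Write a tree as canonical Newick text
#'
#' Children of every node are ordered by their lexicographically smallest
#' descendant leaf label, and a tree carrying the unrooted (trifurcating
#' root) convention is serialized from the internal node adjacent to the
#' smallest leaf — so topologically identical trees serialize to the same
#' string regardless of taxon input order. Branch lengths are printed with 6
#' significant digits; support values (from `node.label`) travel with their
#' edge and are printed as internal node labels. Trees with a binary root
#' keep their root.
#'
#' @param tree an `ape::phylo` tree.
#' @param path optional file to write to.
#' @return the Newick string (invisibly when `path` is given).
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  bad <- grepl("[(),:;\\[\\]\\s]", tree$tip.label, perl = TRUE)
  if (any(bad)) stop(sprintf("tip label unsafe for Newick: %s", tree$tip.label[bad][1]))
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  nn <- ntip + nnode
  has_len <- !is.null(tree$edge.length)
  nlab <- tree$node.label

  # undirected adjacency; per-edge length and support label (support belongs
  # to the bipartition, i.e. the edge, not to a rooted child node)
  adj <- vector("list", nn)
  ekey <- function(a, b) paste(min(a, b), max(a, b))
  elen <- list()
  elab <- list()
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    adj[[p]] <- c(adj[[p]], ch)
    adj[[ch]] <- c(adj[[ch]], p)
    if (has_len) elen[[ekey(p, ch)]] <- tree$edge.length[e]
    if (!is.null(nlab) && ch > ntip && !is.na(nlab[ch - ntip]) &&
          nzchar(nlab[ch - ntip])) {
      elab[[ekey(p, ch)]] <- nlab[ch - ntip]
    }
  }

  old_root <- ntip + 1L
  rooted <- length(adj[[old_root]]) == 2L && ntip > 2L
  root <- if (rooted || ntip <= 2L) {
    old_root
  } else {
    adj[[which(tree$tip.label == min(tree$tip.label))[1]]][1]  # neighbor of smallest leaf
  }

  min_lab <- character(nn)
  fill_min <- function(v, parent) {
    if (v <= ntip) {
      min_lab[v] <<- tree$tip.label[v]
      return(invisible())
    }
    for (w in setdiff(adj[[v]], parent)) fill_min(w, v)
    min_lab[v] <<- min(min_lab[setdiff(adj[[v]], parent)])
  }
  emit <- function(v, parent) {
    if (v <= ntip) return(tree$tip.label[v])
    ch <- setdiff(adj[[v]], parent)
    ch <- ch[order(min_lab[ch])]
    parts <- vapply(ch, function(w) {
      s <- emit(w, v)
      key <- ekey(v, w)
      if (w > ntip && !is.null(elab[[key]])) s <- paste0(s, elab[[key]])
      if (!is.null(elen[[key]]) && !is.na(elen[[key]])) {
        s <- paste0(s, ":", format_brlen(elen[[key]]))
      }
      s
    }, character(1))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  fill_min(root, integer(0))
  root_lab <- if (rooted && !is.null(nlab) && nnode >= 1L &&
                    !is.na(nlab[old_root - ntip]) && nzchar(nlab[old_root - ntip])) {
    nlab[old_root - ntip]
  } else ""
  out <- paste0(emit(root, integer(0)), root_lab, ";")
  if (!is.null(path)) {
    writeLines(out, path)
    return(invisible(out))
  }
  out
}

# ---- bipartitions -----------------------------------------------------------

# Descendant tip labels for every node, as a list indexed by node number.
node_tipsets <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- vector("list", ntip + nnode)
  for (i in seq_len(ntip)) sets[[i]] <- tree$tip.label[i]
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    p <- ord$edge[e, 1]; ch <- ord$edge[e, 2]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  sets
}

split_key <- function(tips, all_tips) {
  ref <- min(all_tips)
  side <- if (ref %in% tips) setdiff(all_tips, tips) else tips
  paste(sort(side), collapse = "|")
}

#' Non-trivial bipartitions of an unrooted tree
#'
#' Each internal edge splits the leaves in two; the split is keyed by the
#' sorted labels of the side not containing the alphabetically first leaf.
#'
#' @param tree an `ape::phylo` tree (interpreted as unrooted).
#' @return named character vector: keys are split strings, values the child
#'   node number of the corresponding internal edge.
#' @export
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  sets <- node_tipsets(tree)
  all_tips <- tree$tip.label
  keys <- character(0)
  nodes <- integer(0)
  for (e in seq_len(nrow(tree$edge))) {
    ch <- tree$edge[e, 2]
    if (ch <= ntip) next
    tips <- sets[[ch]]
    if (length(tips) < 2L || length(tips) > ntip - 2L) next
    keys <- c(keys, split_key(tips, all_tips))
    nodes <- c(nodes, ch)
  }
  setNames(nodes, keys)
}
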