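# Desk-scale distance phylogenetics: p/JC/K2P distances with pairwise
# deletion, Saitou-Nei neighbor joining with deterministic tie-breaking,
# column-resampling bootstrap, strict majority-rule consensus, and Fitch
# parsimony scoring of a fixed topology. All authored here; ape/phangorn are
# used in the test suite as independent cross-checks only.

#' Pairwise distance matrix from an alignment
#'
#' Columns with a gap in either sequence of a pair are excluded for that
#' pair (pairwise deletion). `p` is the raw mismatch proportion; `JC` is the
#' Jukes-Cantor correction `-(3/4) log(1 - 4p/3)`; `K2P` the Kimura
#' two-parameter correction from transition and transversion proportions
#' (nucleotide alignments only). Saturated pairs (log-domain violations) are
#' returned as `NA` and listed in the `"saturated"` attribute rather than as
#' infinities.
#'
#' @param x an [msa()].
#' @param model `"p"`, `"JC"`, or `"K2P"`.
#' @return symmetric matrix with zero diagonal, attributes `model` and
#'   `saturated` (two-column matrix of offending id pairs).
#' @export
distance_matrix <- function(x, model = c("p", "JC", "K2P")) {
  model <- match.arg(model)
  stopifnot(inherits(x, "msa"))
  if (model == "K2P" && x$alphabet != "dna") {
    stop("K2P distances require a nucleotide alignment")
  }
  m <- msa_matrix(x)
  ids <- x$ids
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  sat <- NULL
  purine <- c("A", "G")
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      a <- m[i, ]; b <- m[j, ]
      ok <- a != "-" & b != "-"
      nn <- sum(ok)
      if (nn == 0L) { d[i, j] <- d[j, i] <- NA_real_; sat <- rbind(sat, c(ids[i], ids[j])); next }
      diff <- a[ok] != b[ok]
      p <- sum(diff) / nn
      v <- switch(model,
        p = p,
        JC = if (p >= 3 / 4) NA_real_ else -0.75 * log(1 - 4 * p / 3),
        K2P = {
          ti <- sum(diff & ((a[ok] %in% purine) == (b[ok] %in% purine))) / nn
          tv <- p - ti
          if (1 - 2 * ti - tv <= 0 || 1 - 2 * tv <= 0) NA_real_ else
            -0.5 * log(1 - 2 * ti - tv) - 0.25 * log(1 - 2 * tv)
        })
      if (is.na(v)) sat <- rbind(sat, c(ids[i], ids[j]))
      d[i, j] <- d[j, i] <- v
    }
  }
  attr(d, "model") <- model
  attr(d, "saturated") <- sat
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the standard Q criterion. Ties in Q are
#' broken by the smallest (row, column) index pair, so the result is
#' deterministic. Negative branch-length estimates are clamped to zero with
#' the deficit transferred to the sister edge. The output is unrooted
#' (trifurcating root).
#'
#' @param D symmetric distance matrix with ids as dimnames (>= 3 taxa, no
#'   `NA`).
#' @return an `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  D <- unclass(D)
  ids <- rownames(D)
  if (is.null(ids)) stop("D needs ids as dimnames")
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (anyNA(D)) stop("distance matrix contains NA (saturated or undefined pairs)")
  fmt <- function(x) sprintf("%.12g", x)
  labels <- ids          # Newick subtree per active node
  act <- D               # working distance matrix
  while (nrow(act) > 3L) {
    n <- nrow(act)
    r <- rowSums(act)
    Q <- (n - 2) * act - outer(r, r, `+`)
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1] < best[, 2], , drop = FALSE]
    best <- best[order(best[, 1], best[, 2]), , drop = FALSE]
    i <- best[1, 1]; j <- best[1, 2]
    dij <- act[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- dij - li
    if (li < 0) { li <- 0; lj <- dij }
    if (lj < 0) { lj <- 0; li <- dij }
    newlab <- paste0("(", labels[i], ":", fmt(li), ",", labels[j], ":", fmt(lj), ")")
    du <- (act[i, ] + act[j, ] - dij) / 2
    du <- du[-c(i, j)]
    act <- act[-c(i, j), -c(i, j), drop = FALSE]
    act <- rbind(cbind(act, du), c(du, 0))
    labels <- c(labels[-c(i, j)], newlab)
  }
  la <- max(0, (act[1, 2] + act[1, 3] - act[2, 3]) / 2)
  lb <- max(0, (act[1, 2] + act[2, 3] - act[1, 3]) / 2)
  lc <- max(0, (act[1, 3] + act[2, 3] - act[1, 2]) / 2)
  txt <- paste0("(", labels[1], ":", fmt(la), ",", labels[2], ":", fmt(lb),
                ",", labels[3], ":", fmt(lc), ");")
  ape::read.tree(text = txt)
}

#' Column bootstrap with NJ and bipartition support
#'
#' Each replicate resamples alignment columns with replacement (same width),
#' recomputes distances under `model`, and rebuilds the NJ tree. The support
#' of an internal edge of the reference (full-alignment) NJ tree is the
#' fraction of successful replicates whose tree contains its bipartition.
#' Replicates with a saturated or undefined pair are skipped and counted.
#'
#' @param x an [msa()].
#' @param n_reps number of bootstrap replicates (>= 1); 2000 is the
#'   conventional full-study setting, tests use far fewer.
#' @param seed integer seed; results are deterministic given it.
#' @param model distance model, see [distance_matrix()].
#' @return list with `tree` (reference NJ tree, support in `node.label`),
#'   `support` (named vector, split key -> fraction), `replicates` (list of
#'   phylo trees), `n_used`, `n_skipped`.
#' @export
bootstrap_support <- function(x, n_reps = 2000L, seed = 1L, model = "p") {
  stopifnot(inherits(x, "msa"))
  n_reps <- as.integer(n_reps)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  ref <- neighbor_joining(distance_matrix(x, model))
  cols <- msa_matrix(x)
  set.seed(stream_seed(seed, "bootstrap"))
  reps <- vector("list", n_reps)
  n_skipped <- 0L
  counts <- integer(0)
  for (r in seq_len(n_reps)) {
    idx <- sample.int(ncol(cols), ncol(cols), replace = TRUE)
    boot <- msa(setNames(apply(cols[, idx, drop = FALSE], 1, paste, collapse = ""),
                         x$ids), alphabet = x$alphabet)
    D <- distance_matrix(boot, model)
    if (anyNA(D)) { n_skipped <- n_skipped + 1L; next }
    tr <- neighbor_joining(D)
    reps[[r]] <- tr
    for (key in names(tree_bipartitions(tr))) {
      counts[key] <- (if (is.na(counts[key])) 0L else counts[key]) + 1L
    }
  }
  reps <- reps[!vapply(reps, is.null, logical(1))]
  n_used <- length(reps)
  if (n_used == 0L) stop("all bootstrap replicates were skipped")
  support_all <- counts / n_used
  ref_splits <- tree_bipartitions(ref)
  support <- setNames(rep(0, length(ref_splits)), names(ref_splits))
  hit <- intersect(names(ref_splits), names(support_all))
  support[hit] <- support_all[hit]
  nlab <- rep("", ref$Nnode)
  ntip <- length(ref$tip.label)
  nlab[ref_splits - ntip] <- sprintf("%.6g", support)
  ref$node.label <- nlab
  list(tree = ref, support = support, replicates = reps,
       n_used = n_used, n_skipped = n_skipped)
}

#' Majority-rule consensus tree
#'
#' Contains exactly the bipartitions whose frequency across the input trees
#' is strictly greater than `cutoff` (cutoff >= 0.5 guarantees pairwise
#' compatibility), annotated with their frequencies as node labels.
#'
#' @param trees list of `ape::phylo` trees on the same leaf set.
#' @param cutoff frequency cutoff, `>= 0.5`.
#' @return an `ape::phylo` tree; node labels hold split frequencies.
#' @export
majority_rule_consensus <- function(trees, cutoff = 0.5) {
  if (!length(trees)) stop("no trees given")
  if (cutoff < 0.5) stop("cutoff must be >= 0.5")
  tips <- sort(trees[[1]]$tip.label)
  for (tr in trees) {
    if (!identical(sort(tr$tip.label), tips)) {
      stop("all trees must share the same leaf set")
    }
  }
  ref <- min(tips)
  counts <- list()  # split key -> count; clade = side not containing ref
  for (tr in trees) {
    for (key in names(tree_bipartitions(tr))) {
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
    }
  }
  freq <- vapply(counts, function(k) k / length(trees), numeric(1))
  keep <- freq[freq > cutoff]
  clades <- strsplit(names(keep), "|", fixed = TRUE)
  ord <- order(-lengths(clades))
  clades <- clades[ord]; keep <- keep[ord]

  # containment forest: every kept clade nests inside the smallest kept
  # clade that contains it (compatibility guarantees this is well defined)
  nodes <- list(list(tips = setdiff(tips, character(0)), freq = NA_real_,
                     children = integer(0)))  # node 1 = root (all tips)
  parent_of <- function(set) {
    cand <- which(vapply(nodes, function(nd) all(set %in% nd$tips), logical(1)))
    cand[which.min(lengths(lapply(nodes[cand], `[[`, "tips")))]
  }
  for (k in seq_along(clades)) {
    set <- clades[[k]]
    p <- parent_of(set)
    new_id <- length(nodes) + 1L
    nodes[[new_id]] <- list(tips = set, freq = keep[[k]], children = integer(0))
    moved <- nodes[[p]]$children[vapply(nodes[[p]]$children, function(c2)
      all(nodes[[c2]]$tips %in% set), logical(1))]
    nodes[[p]]$children <- c(setdiff(nodes[[p]]$children, moved), new_id)
    nodes[[new_id]]$children <- moved
  }
  emit <- function(id) {
    nd <- nodes[[id]]
    leaf_tips <- setdiff(nd$tips, unlist(lapply(nd$children, function(c2) nodes[[c2]]$tips)))
    parts <- c(sort(leaf_tips), vapply(nd$children, emit, character(1)))
    lab <- if (is.na(nd$freq)) "" else sprintf("%.6g", nd$freq)
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  ape::read.tree(text = paste0(emit(1L), ";"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fitch parsimony score of an alignment on a fixed topology
#'
#' Sum over columns of the minimum number of state changes, treating
#' characters as unordered states and gaps (`-`, `?`) as missing (a missing
#' leaf never forces a change, equivalent to excluding it column-wise). The
#' score is invariant under re-rooting.
#'
#' @param tree `ape::phylo` tree whose tip labels match the alignment ids.
#' @param x an [msa()].
#' @return integer parsimony score.
#' @export
fitch_score <- function(tree, x) {
  stopifnot(inherits(tree, "phylo"), inherits(x, "msa"))
  if (!setequal(tree$tip.label, x$ids)) {
    stop("tree tips and alignment ids do not match")
  }
  m <- msa_matrix(x)[tree$tip.label, , drop = FALSE]
  ntip <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "postorder")
  edges <- ord$edge
  total <- 0L
  for (col in seq_len(ncol(m))) {
    chars <- m[, col]
    obs <- sort(unique(chars[chars != "-" & chars != "?"]))
    if (length(obs) < 2L) next
    code <- stats::setNames(bitwShiftL(1L, seq_along(obs) - 1L), obs)
    full <- sum(code)
    sets <- integer(ntip + tree$Nnode)
    sets[seq_len(ntip)] <- ifelse(chars %in% obs, code[chars], full)
    score <- 0L
    for (e in seq_len(nrow(edges))) {
      p <- edges[e, 1]; ch <- edges[e, 2]
      if (sets[p] == 0L) { sets[p] <- sets[ch]; next }
      inter <- bitwAnd(sets[p], sets[ch])
      if (inter != 0L) {
        sets[p] <- inter
      } else {
        sets[p] <- bitwOr(sets[p], sets[ch])
        score <- score + 1L
      }
    }
    total <- total + score
  }
  total
}
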