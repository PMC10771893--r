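# The study's central statistic: each species pair becomes a point
# (x = whole-protein % identity, y = domain % identity). Distance from the
# (100, 100) full-conservation corner measures total divergence; position
# relative to the slope-1 diagonal y = x says whether the domain evolves
# slower (above: domain-conserved) or faster (below: domain-accelerated)
# than the protein as a whole.

BALANCE_LEVELS <- c("domain_accelerated", "balanced", "domain_conserved")

#' Euclidean distance from the 100% conservation point
#'
#' @param x whole-protein percent identity (vectorized).
#' @param y domain percent identity.
#' @return `sqrt((100 - x)^2 + (100 - y)^2)`, full precision (round to 2
#'   decimals for display).
#' @examples
#' round(conservation_distance(88.4, 99.1), 2)  # 11.63
#' @export
conservation_distance <- function(x, y) {
  stopifnot(length(x) == length(y))
  sqrt((100 - x)^2 + (100 - y)^2)
}

#' Classify a point against the slope-1 balanced-evolution diagonal
#'
#' @param x,y identities as in [conservation_distance()].
#' @param tol nonnegative tie tolerance; the default `1e-9` only guards
#'   exact ties, treating the diagonal as a strict demarcation.
#' @return factor with levels `domain_accelerated` (below the line),
#'   `balanced`, `domain_conserved` (above the line).
#' @export
classify_balance <- function(x, y, tol = 1e-9) {
  stopifnot(tol >= 0, length(x) == length(y))
  d <- y - x
  cls <- ifelse(d > tol, "domain_conserved",
                ifelse(d < -tol, "domain_accelerated", "balanced"))
  factor(cls, levels = BALANCE_LEVELS)
}

canonical_group_pair <- function(g1, g2) {
  paste(pmin(g1, g2), pmax(g1, g2), sep = ":")
}

#' Per-species-pair divergence points
#'
#' @param x an [msa()] of protein sequences.
#' @param domain alignment-column [region()] of the functional domain.
#' @param groups named character vector mapping every alignment id to a
#'   group label.
#' @param tol diagonal tie tolerance, see [classify_balance()].
#' @return data frame with one row per unordered species pair: `id1`, `id2`,
#'   `group_pair`, `x`, `y`, `distance`, `class`.
#' @export
divergence_points <- function(x, domain, groups, tol = 1e-9) {
  stopifnot(inherits(x, "msa"))
  domain <- as_region(domain, "alignment_column")
  unmapped <- setdiff(x$ids, names(groups))
  if (length(unmapped)) {
    stop(sprintf("species without a group label: %s", paste(unmapped, collapse = ", ")))
  }
  whole <- identity_matrix(x)
  dom <- identity_matrix(x, domain)
  ids <- x$ids
  pairs <- utils::combn(ids, 2)
  id1 <- pairs[1, ]; id2 <- pairs[2, ]
  xs <- whole[cbind(id1, id2)]
  ys <- dom[cbind(id1, id2)]
  data.frame(id1 = id1, id2 = id2,
             group_pair = canonical_group_pair(groups[id1], groups[id2]),
             x = xs, y = ys,
             distance = conservation_distance(xs, ys),
             class = classify_balance(xs, ys, tol),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Cluster summaries of divergence points
#'
#' Aggregates points by a partition of group pairs into clusters, reporting
#' per cluster the number of pairs, the mean conservation distance, its SEM
#' (sample SD with n-1 denominator over sqrt(n); absent for a single pair),
#' and the tally of points above/on/below the diagonal. Clusters are
#' numbered by ascending mean distance.
#'
#' @param points data frame from [divergence_points()].
#' @param partition named list: cluster name -> character vector of
#'   group-pair labels (e.g. `list("D:D+D:P" = c("D:D", "D:P"))`). `NULL`
#'   puts each distinct group pair in its own cluster.
#' @return data frame with `cluster` (rank), `name`, `group_pairs`, `n`,
#'   `mean_distance`, `sem` (`NA` when n = 1), `n_above`, `n_on`, `n_below`.
#' @export
cluster_summaries <- function(points, partition = NULL) {
  gp <- unique(points$group_pair)
  if (is.null(partition)) {
    partition <- stats::setNames(as.list(gp), gp)
  }
  assigned <- unlist(partition, use.names = FALSE)
  if (anyDuplicated(assigned)) {
    stop(sprintf("group pair assigned to more than one cluster: %s",
                 paste(unique(assigned[duplicated(assigned)]), collapse = ", ")))
  }
  orphan <- setdiff(gp, assigned)
  if (length(orphan)) {
    stop(sprintf("group pair(s) not assigned to any cluster: %s",
                 paste(orphan, collapse = ", ")))
  }
  rows <- lapply(names(partition), function(nm) {
    sel <- points[points$group_pair %in% partition[[nm]], ]
    if (!nrow(sel)) return(NULL)
    d <- sel$distance
    n <- length(d)
    data.frame(name = nm,
               group_pairs = paste(sort(unique(sel$group_pair)), collapse = ","),
               n = n,
               mean_distance = mean(d),
               sem = if (n > 1L) stats::sd(d) / sqrt(n) else NA_real_,
               n_above = sum(sel$class == "domain_conserved"),
               n_on = sum(sel$class == "balanced"),
               n_below = sum(sel$class == "domain_accelerated"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mean_distance), , drop = FALSE]
  out <- cbind(cluster = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Domain-versus-whole-protein divergence analysis
#'
#' The end-to-end computation: per-pair whole and domain identities from one
#' alignment, conservation distances, diagonal classification, and cluster
#' summaries.
#'
#' @inheritParams divergence_points
#' @param partition optional cluster partition, see [cluster_summaries()];
#'   merged clusters (several group pairs in one cluster) reflect observed
#'   overlap and are supplied explicitly, never inferred.
#' @return object of class `"divergence_analysis"`: list with `points`,
#'   `clusters`, `domain`, `groups`, `tol`.
#' @export
divergence_analysis <- function(x, domain, groups, partition = NULL, tol = 1e-9) {
  points <- divergence_points(x, domain, groups, tol)
  clusters <- cluster_summaries(points, partition)
  structure(list(points = points, clusters = clusters,
                 domain = as_region(domain, "alignment_column"),
                 groups = groups, tol = tol),
            class = "divergence_analysis")
}

#' @export
print.divergence_analysis <- function(x, ...) {
  cat(sprintf("<divergence_analysis> %d species pairs, domain columns %s\n",
              nrow(x$points), format(x$domain)))
  tab <- table(x$points$class)
  cat(sprintf("  above diagonal (domain conserved): %d, on: %d, below (domain accelerated): %d\n",
              tab[["domain_conserved"]], tab[["balanced"]], tab[["domain_accelerated"]]))
  cat(sprintf("  %d cluster(s) by ascending mean conservation distance:\n",
              nrow(x$clusters)))
  for (i in seq_len(nrow(x$clusters))) {
    cl <- x$clusters[i, ]
    sem <- if (is.na(cl$sem)) "SEM n/a (single pair)" else sprintf("SEM %.2f", cl$sem)
    cat(sprintf("   %d. %s: n=%d, mean %.2f, %s\n",
                cl$cluster, cl$group_pairs, cl$n, cl$mean_distance, sem))
  }
  invisible(x)
}

#' @export
summary.divergence_analysis <- function(object, ...) {
  print(object)
  invisible(object$clusters)
}

#' Scatter plot of divergence points with the slope-1 diagonal
#'
#' @param x a [divergence_analysis()] object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.divergence_analysis <- function(x, ...) {
  pts <- x$points
  gp <- factor(pts$group_pair)
  cols <- grDevices::hcl.colors(max(3L, nlevels(gp)), "Dark 3")[as.integer(gp)]
  graphics::plot(pts$x, pts$y, pch = 19, col = cols,
                 xlim = c(0, 100), ylim = c(0, 100),
                 xlab = "% identity, whole protein",
                 ylab = "% identity, domain", ...)
  graphics::abline(0, 1, lty = 2, col = "grey40")
  graphics::points(100, 100, pch = 3, cex = 1.2)
  graphics::legend("bottomright", legend = levels(gp), col =
                     grDevices::hcl.colors(max(3L, nlevels(gp)), "Dark 3")[seq_len(nlevels(gp))],
                   pch = 19, bty = "n", cex = 0.8)
  invisible(x)
}

#' Write divergence tables as TSV
#'
#' @param x a [divergence_analysis()] object.
#' @param points_path,clusters_path output paths (NULL to skip either).
#' @return `x`, invisibly. Identities and distances are rounded to 1 and 2
#'   decimals respectively in the written tables.
#' @export
write_divergence_tsv <- function(x, points_path = NULL, clusters_path = NULL) {
  stopifnot(inherits(x, "divergence_analysis"))
  if (!is.null(points_path)) {
    p <- x$points
    p$x <- round(p$x, 1); p$y <- round(p$y, 1); p$distance <- round(p$distance, 2)
    utils::write.table(p, points_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(clusters_path)) {
    cl <- x$clusters
    cl$mean_distance <- round(cl$mean_distance, 2)
    cl$sem <- round(cl$sem, 2)
    utils::write.table(cl, clusters_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(x)
}
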