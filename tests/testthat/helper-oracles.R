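# Independent oracles and fixture builders. Everything here is deliberately
# naive (enumeration, closed forms, exact laws) and shares no code with the
# implementation paths it checks.

# Optimal global-alignment score by exhaustive enumeration of all alignments.
bf_align_score <- function(a, b, match = 1, mismatch = -1, gap = -1) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  rec <- function(i, j) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, (if (ca[i] == cb[j]) match else mismatch) + rec(i + 1, j + 1))
    }
    if (i <= n) best <- max(best, gap + rec(i + 1, j))
    if (j <= m) best <- max(best, gap + rec(i, j + 1))
    best
  }
  rec(1, 1)
}

# Minimum-mutation count by exhaustive enumeration of internal-node states.
bf_fitch <- function(tree, aln) {
  m <- do.call(rbind, strsplit(unname(aln$seqs[tree$tip.label]), ""))
  ntip <- length(tree$tip.label); nnode <- tree$Nnode
  total <- 0
  for (col in seq_len(ncol(m))) {
    chars <- m[, col]
    obs <- unique(chars[chars != "-"])
    if (length(obs) < 2) next
    grid <- expand.grid(rep(list(obs), nnode), stringsAsFactors = FALSE)
    best <- Inf
    for (r in seq_len(nrow(grid))) {
      states <- c(chars, unlist(grid[r, ], use.names = FALSE))
      changes <- 0
      for (e in seq_len(nrow(tree$edge))) {
        ch <- tree$edge[e, 2]
        if (ch <= ntip && chars[ch] == "-") next  # missing leaf: excluded
        if (states[tree$edge[e, 1]] != states[ch]) changes <- changes + 1
      }
      best <- min(best, changes)
    }
    total <- total + best
  }
  total
}

random_msa <- function(n_seq, n_col, alphabet = c("A", "C", "G", "T"),
                       gap_prob = 0, seed = 1) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_seq), function(i) {
    ch <- sample(alphabet, n_col, replace = TRUE)
    if (gap_prob > 0) ch[stats::runif(n_col) < gap_prob] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  names(seqs) <- paste0("t", seq_len(n_seq))
  msa(seqs)
}

random_string <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Exact per-codon law of the generator for a 2-taxon tree: root codons are
# products of base_freqs conditioned on non-stop; each edge applies the
# site-product transition matrix (independent matrix exponential via
# Matrix::expm) conditioned on a non-stop child. Returns the expected
# nucleotide p-distance between the two leaves and the exact leaf nucleotide
# frequencies, averaged over equiprobable gamma category triples.
codon_law_oracle <- function(base_freqs, ti_tv, gamma_shape, k, t_edge) {
  NUC <- c("A", "C", "G", "T")
  pi <- stats::setNames(base_freqs, NUC)
  Q <- unclass(hky_rate_matrix(list(base_freqs = base_freqs, ti_tv = ti_tv)))
  rates <- discrete_gamma_rates(gamma_shape, k)
  cods <- as.matrix(expand.grid(s3 = NUC, s2 = NUC, s1 = NUC,
                                stringsAsFactors = FALSE))[, 3:1]
  is_stop <- paste0(cods[, 1], cods[, 2], cods[, 3]) %in% c("TAA", "TAG", "TGA")
  D <- outer(seq_len(64), seq_len(64),
             Vectorize(function(i, j) sum(cods[i, ] != cods[j, ])))
  q <- pi[cods[, 1]] * pi[cods[, 2]] * pi[cods[, 3]]
  q[is_stop] <- 0; q <- q / sum(q)
  e_p <- 0
  leaf_law <- rep(0, 64)
  n_combo <- length(rates)^3
  for (r1 in rates) for (r2 in rates) for (r3 in rates) {
    Ps <- lapply(c(r1, r2, r3), function(r)
      as.matrix(Matrix::expm(Matrix::Matrix(Q * t_edge * r))))
    Pc <- Ps[[1]] %x% Ps[[2]] %x% Ps[[3]]
    Pc[, is_stop] <- 0
    rs <- rowSums(Pc)
    rs[rs == 0] <- 1  # stop-codon rows: never reached (q = 0 there)
    Pc <- Pc / rs
    e_p <- e_p + sum(q * diag(Pc %*% D %*% t(Pc))) / 3 / n_combo
    leaf_law <- leaf_law + as.vector(q %*% Pc) / n_combo
  }
  nuc_freq <- vapply(NUC, function(nc) sum(leaf_law * rowSums(cods == nc)) / 3,
                     numeric(1))
  list(expected_p = e_p, leaf_nuc_freqs = nuc_freq)
}

# p-distance between two ungapped equal-length sequences
p_dist <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  mean(ca != cb)
}

jaccard_region <- function(reg, start, end) {
  a <- max(reg$start, start); b <- min(reg$end, end)
  inter <- max(0, b - a)
  inter / ((reg$end - reg$start) + (end - start) - inter)
}

# sequences derived from one ancestor by independent substitution, so
# pairwise divergence stays below distance-correction saturation
related_msa <- function(n_seq, n_col, sub_prob = 0.15, gap_prob = 0, seed = 1) {
  set.seed(seed)
  nuc <- c("A", "C", "G", "T")
  base <- sample(nuc, n_col, replace = TRUE)
  seqs <- vapply(seq_len(n_seq), function(i) {
    ch <- base
    hit <- stats::runif(n_col) < sub_prob
    ch[hit] <- sample(nuc, sum(hit), replace = TRUE)
    if (gap_prob > 0) ch[stats::runif(n_col) < gap_prob] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  names(seqs) <- paste0("t", seq_len(n_seq))
  msa(seqs)
}

# canonical split key (side not containing the alphabetically first leaf)
split_key_for <- function(all_tips, side) {
  ref <- min(all_tips)
  s <- if (ref %in% side) setdiff(all_tips, side) else side
  paste(sort(s), collapse = "|")
}

write_temp_fasta <- function(lines) {
  path <- tempfile(fileext = ".fasta")
  writeLines(lines, path)
  path
}
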