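# CDS evolution under HKY85 + discrete-gamma rate variation along a fixed
# tree, with an optional codon-resolved region whose substitution rate is
# multiplied on selected edges. Rates across sites are drawn once at the root
# and shared by the whole tree; edges consume independent RNG streams keyed by
# the clade below them, so traversal order never changes the output.

NUC <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration for CDS evolution under HKY+G
#'
#' Defaults for the substitution model are the parameter values estimated for
#' the SIP30 coding-region alignment (base frequencies, Ti/Tv ratio, gamma
#' shape, no invariable sites).
#'
#' @param tree `ape::phylo` tree with branch lengths in expected
#'   substitutions/site.
#' @param n_codons number of codons to simulate.
#' @param base_freqs equilibrium frequencies (A, C, G, T); must sum to 1.
#' @param ti_tv transition/transversion ratio (not kappa; see
#'   [hky_rate_matrix()] for the conversion).
#' @param gamma_shape shape of the gamma distribution of site rates.
#' @param p_invariable proportion of invariable sites in `[0, 1)`.
#' @param n_gamma_categories number of equiprobable discrete gamma categories.
#' @param domain_region optional [region()] in codon space: the functional
#'   domain whose rate can be scaled per edge.
#' @param domain_multiplier named numeric vector of per-edge rate factors for
#'   domain sites. Names are edge keys: a tip label for a terminal edge, or
#'   the sorted tip labels of the clade below an internal edge joined by
#'   `"|"`; the name `".default"` sets the factor for unlisted edges
#'   (default 1). `NULL` means 1 everywhere.
#' @param seed master integer seed; every stream is derived from it.
#' @return object of class `"simulation_config"`.
#' @export
simulation_config <- function(tree, n_codons,
                              base_freqs = c(0.2844, 0.2519, 0.2947, 0.1690),
                              ti_tv = 2.2233,
                              gamma_shape = 0.9665,
                              p_invariable = 0,
                              n_gamma_categories = 4L,
                              domain_region = NULL,
                              domain_multiplier = NULL,
                              seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  if (any(tree$edge.length < 0)) stop("branch lengths must be nonnegative")
  n_codons <- as.integer(n_codons)
  if (n_codons < 1L) stop("n_codons must be positive")
  base_freqs <- as.numeric(base_freqs)
  if (length(base_freqs) != 4L || any(base_freqs <= 0)) {
    stop("base_freqs must be 4 positive numbers (A, C, G, T)")
  }
  if (abs(sum(base_freqs) - 1) > 1e-9) stop("base_freqs must sum to 1 (tolerance 1e-9)")
  if (ti_tv <= 0) stop("ti_tv must be positive")
  if (gamma_shape <= 0) stop("gamma_shape must be positive")
  if (p_invariable < 0 || p_invariable >= 1) stop("p_invariable must be in [0, 1)")
  n_gamma_categories <- as.integer(n_gamma_categories)
  if (n_gamma_categories < 1L) stop("n_gamma_categories must be >= 1")
  if (!is.null(domain_region)) {
    domain_region <- as_region(domain_region, "codon")
    if (domain_region$space != "codon") stop("domain_region must be in codon space")
    if (domain_region$end > n_codons) stop("domain_region must lie within [0, n_codons)")
  }
  if (!is.null(domain_multiplier)) {
    if (is.null(names(domain_multiplier)) || any(!nzchar(names(domain_multiplier)))) {
      stop("domain_multiplier must be a named numeric vector (edge keys)")
    }
    if (any(domain_multiplier <= 0)) stop("domain rate multipliers must be positive")
  }
  structure(list(tree = tree, n_codons = n_codons, base_freqs = base_freqs,
                 ti_tv = ti_tv, gamma_shape = gamma_shape,
                 p_invariable = p_invariable,
                 n_gamma_categories = n_gamma_categories,
                 domain_region = domain_region,
                 domain_multiplier = domain_multiplier,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' HKY85 instantaneous rate matrix
#'
#' Off-diagonal rates are `kappa * pi_j` for transitions (A<->G, C<->T) and
#' `pi_j` for transversions, scaled so the expected substitution rate at
#' equilibrium is one per unit branch length. `kappa` is derived from the
#' transition/transversion ratio via
#' `TiTv = kappa (piA piG + piC piT) / ((piA + piG)(piC + piT))`.
#'
#' @param config a [simulation_config()], or any list with `base_freqs` and
#'   `ti_tv` entries.
#' @return 4x4 rate matrix (rows/cols A, C, G, T; rows sum to zero) with the
#'   stationary distribution attached as attribute `"pi"` and the derived
#'   `"kappa"`.
#' @export
hky_rate_matrix <- function(config) {
  pi <- as.numeric(config$base_freqs)
  if (length(pi) != 4L || any(pi <= 0) || abs(sum(pi) - 1) > 1e-9) {
    stop("base frequencies must be 4 positive numbers summing to 1")
  }
  names(pi) <- NUC
  ti_tv <- config$ti_tv
  piA <- pi[1]; piC <- pi[2]; piG <- pi[3]; piT <- pi[4]
  kappa <- ti_tv * (piA + piG) * (piC + piT) / (piA * piG + piC * piT)
  Q <- matrix(0, 4, 4, dimnames = list(NUC, NUC))
  for (i in 1:4) for (j in 1:4) {
    if (i == j) next
    transition <- (NUC[i] == "A" && NUC[j] == "G") || (NUC[i] == "G" && NUC[j] == "A") ||
      (NUC[i] == "C" && NUC[j] == "T") || (NUC[i] == "T" && NUC[j] == "C")
    Q[i, j] <- if (transition) kappa * pi[j] else pi[j]
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  attr(Q, "pi") <- pi
  attr(Q, "kappa") <- unname(kappa)
  Q
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by symmetrized eigendecomposition (the HKY chain is reversible),
#' which is exact and stable for any `t >= 0`.
#'
#' @param Q rate matrix from [hky_rate_matrix()] (needs the `"pi"` attribute).
#' @param t branch length (expected substitutions/site), `t >= 0`.
#' @return 4x4 stochastic matrix; rows sum to 1.
#' @export
transition_probabilities <- function(Q, t) {
  if (t < 0) stop("branch length t must be >= 0")
  pi <- attr(Q, "pi")
  if (is.null(pi)) stop("Q must carry its stationary distribution as attr 'pi'")
  sq <- sqrt(pi)
  S <- diag(sq) %*% Q %*% diag(1 / sq)
  S <- (S + t(S)) / 2  # symmetrize away rounding asymmetry
  es <- eigen(S, symmetric = TRUE)
  P <- diag(1 / sq) %*% es$vectors %*% diag(exp(es$values * t)) %*%
    t(es$vectors) %*% diag(sq)
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

#' Discrete-gamma site rate categories
#'
#' Equiprobable categories represented by their quantile midpoints (the
#' median-of-category rule), rescaled to mean exactly 1.
#'
#' @param shape gamma shape parameter.
#' @param k number of categories.
#' @return numeric vector of `k` rates with mean 1.
#' @export
discrete_gamma_rates <- function(shape, k = 4L) {
  if (shape <= 0) stop("shape must be positive")
  k <- as.integer(k)
  if (k < 1L) stop("k must be >= 1")
  if (k == 1L) return(1)
  q <- (2 * seq_len(k) - 1) / (2 * k)
  r <- stats::qgamma(q, shape = shape, rate = shape)
  r / mean(r)
}

# ---- RNG stream derivation --------------------------------------------------

# Deterministic 31-bit stream seed from the master seed and a string key, so
# per-edge streams do not depend on traversal order.
stream_seed <- function(master, key) {
  bytes <- utf8ToInt(paste0(master, ":", key))
  h <- 17
  for (b in bytes) h <- (h * 131 + b) %% 2147483629
  as.integer(h)
}

# Edge keys: tip label for terminal edges, sorted clade tip labels joined by
# "|" for internal edges.
edge_keys <- function(tree) {
  sets <- node_tipsets(tree)
  ntip <- length(tree$tip.label)
  vapply(seq_len(nrow(tree$edge)), function(e) {
    ch <- tree$edge[e, 2]
    if (ch <= ntip) tree$tip.label[ch] else paste(sort(sets[[ch]]), collapse = "|")
  }, character(1))
}

resolve_multipliers <- function(config) {
  keys <- edge_keys(config$tree)
  mult <- rep(1, length(keys))
  dm <- config$domain_multiplier
  if (!is.null(dm)) {
    if (".default" %in% names(dm)) mult[] <- dm[[".default"]]
    named <- setdiff(names(dm), ".default")
    unknown <- setdiff(named, keys)
    if (length(unknown)) {
      stop(sprintf("domain_multiplier names not matching any edge: %s",
                   paste(unknown, collapse = ", ")))
    }
    for (nm in named) mult[keys == nm] <- dm[[nm]]
  }
  setNames(mult, keys)
}

# ---- simulation -------------------------------------------------------------

sample_states <- function(n, prob) sample.int(4L, n, replace = TRUE, prob = prob)

# indices (1-based, site space) of the 3 sites of each codon in `codons`
codon_sites <- function(codons) as.vector(t(outer(3L * (codons - 1L), 1:3, `+`)))

has_stop <- function(states, codon_idx) {
  s <- codon_sites(codon_idx)
  cod <- matrix(NUC[states[s]], ncol = 3, byrow = TRUE)
  codon_idx[paste0(cod[, 1], cod[, 2], cod[, 3]) %in% STOP_CODONS]
}

#' Simulate coding-sequence evolution along a tree
#'
#' The root sequence is drawn from the equilibrium base frequencies (stop
#' codons rejected); each site gets a discrete-gamma rate category at the
#' root, shared across the tree. Along an edge of length `t`, a site evolves
#' with `P(t * rate)`, where domain sites on flagged edges get the extra
#' domain multiplier. Codons that mutate into a stop are resampled at the
#' node where the stop arises, so translation stays clean. Output is
#' bit-identical for a fixed seed.
#'
#' @param config a [simulation_config()].
#' @return object of class `"cds_simulation"`: list with `nt` (ungapped
#'   nucleotide [msa()]), `aa` (translated protein [msa()]), `sites`
#'   (per-site annotation data frame: 1-based site, codon, gamma category,
#'   rate, in-domain flag), and `config`.
#' @export
simulate_cds <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  tree <- config$tree
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("tree must have at least 2 leaves")
  n_sites <- 3L * config$n_codons
  Q <- hky_rate_matrix(config)
  gamma_rates <- discrete_gamma_rates(config$gamma_shape, config$n_gamma_categories)
  mult <- resolve_multipliers(config)

  in_domain_codon <- rep(FALSE, config$n_codons)
  if (!is.null(config$domain_region)) {
    in_domain_codon[region_seq(config$domain_region)] <- TRUE
  }
  in_domain <- rep(in_domain_codon, each = 3L)

  # root state: categories, invariable flags, equilibrium sequence
  set.seed(stream_seed(config$seed, "root"))
  cat_idx <- sample.int(config$n_gamma_categories, n_sites, replace = TRUE)
  invariable <- stats::runif(n_sites) < config$p_invariable
  site_rate <- ifelse(invariable, 0, gamma_rates[cat_idx] / (1 - config$p_invariable))
  root <- sample_states(n_sites, config$base_freqs)
  repeat {
    stops <- has_stop(root, seq_len(config$n_codons))
    if (!length(stops)) break
    root[codon_sites(stops)] <- sample_states(3L * length(stops), config$base_freqs)
  }

  # preorder traversal; child states derived from parent states
  states <- vector("list", ntip + tree$Nnode)
  states[[ntip + 1L]] <- root
  keys <- edge_keys(tree)
  ord <- ape::reorder.phylo(tree, "cladewise")
  ord_keys <- edge_keys(ord)
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    bl <- ord$edge.length[e]
    key <- ord_keys[e]
    m <- mult[[key]]
    t_eff <- bl * site_rate * ifelse(in_domain, m, 1)
    set.seed(stream_seed(config$seed, key))
    ps <- states[[parent]]
    cs <- ps
    groups <- split(seq_len(n_sites), t_eff)
    pmats <- list()
    for (gt in names(groups)) {
      tt <- as.numeric(gt)
      idx <- groups[[gt]]
      if (tt == 0) next
      P <- transition_probabilities(Q, tt)
      pmats[[gt]] <- P
      for (a in 1:4) {
        ai <- idx[ps[idx] == a]
        if (length(ai)) cs[ai] <- sample_states(length(ai), P[a, ])
      }
    }
    # resample codons that mutated into a stop at this node
    tries <- 0L
    repeat {
      stops <- has_stop(cs, seq_len(config$n_codons))
      if (!length(stops)) break
      tries <- tries + 1L
      if (tries > 200L) stop("could not resample away internal stop codons")
      for (s in codon_sites(stops)) {
        tt <- t_eff[s]
        if (tt == 0) next  # inherited stop-free parent state, cannot be the cause
        cs[s] <- sample_states(1L, pmats[[as.character(tt)]][states[[parent]][s], ])
      }
    }
    states[[child]] <- cs
  }

  leaf_seqs <- vapply(seq_len(ntip), function(i) paste(NUC[states[[i]]], collapse = ""),
                      character(1))
  names(leaf_seqs) <- tree$tip.label
  nt <- msa(leaf_seqs, alphabet = "dna")
  aa <- msa(vapply(leaf_seqs, translate_cds, character(1)), alphabet = "protein")
  sites <- data.frame(site = seq_len(n_sites),
                      codon = rep(seq_len(config$n_codons), each = 3L),
                      gamma_category = ifelse(invariable, NA_integer_, cat_idx),
                      rate = site_rate,
                      in_domain = in_domain)
  structure(list(nt = nt, aa = aa, sites = sites, config = config),
            class = "cds_simulation")
}

#' @export
print.cds_simulation <- function(x, ...) {
  cat(sprintf("<cds_simulation> %d taxa, %d codons, seed %d\n",
              length(x$nt$ids), x$config$n_codons, x$config$seed))
  if (!is.null(x$config$domain_region)) {
    cat(sprintf("  domain codons %s\n", format(x$config$domain_region)))
  }
  invisible(x)
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param cds ungapped nucleotide string; length must be a multiple of 3;
#'   only A/C/G/T accepted (no ambiguity codes). Stops become `*`.
#' @return the protein sequence as a character string.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(as.character(cds))
  if (length(cds) != 1L) stop("translate_cds expects a single sequence")
  n <- nchar(cds)
  if (n %% 3L != 0L) stop(sprintf("CDS length %d is not divisible by 3", n))
  chars <- strsplit(cds, "")[[1]]
  bad <- which(!(chars %in% NUC))
  if (length(bad)) {
    stop(sprintf("ambiguous or illegal base '%s' at position %d", chars[bad[1]], bad[1]))
  }
  codons <- substring(cds, seq(1, n, 3), seq(3, n, 3))
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# ---- packaged study conditions ---------------------------------------------

#' Nine-taxon mammal tree used as the default simulation scenario
#'
#' Three primates (Hsa, Ptr, Mml), four domesticated animals (Cfa, Eca, Bta,
#' Ssc) and two rodents (Mmu, Rno) on an unrooted (trifurcating-root) tree
#' with branch lengths in substitutions/site chosen to reproduce the
#' characteristic identity pattern of a fast-evolving mammalian protein:
#' high within-group identity, 40-70% between groups. The human terminal
#' branch is longer than the chimpanzee one.
#'
#' @return an `ape::phylo` tree with 9 tips.
#' @export
mammal_tree <- function() {
  read_newick(paste0(
    "(((Hsa:0.015,Ptr:0.012):0.01,Mml:0.028):0.06,",
    "((Cfa:0.055,Eca:0.05):0.02,(Bta:0.05,Ssc:0.045):0.025):0.04,",
    "(Mmu:0.03,Rno:0.03):0.12);"))
}

#' Species-to-group map for the mammal scenario
#' @return named character vector: `P` (primate), `D` (domesticated), `R` (rodent).
#' @export
mammal_groups <- function() {
  c(Hsa = "P", Ptr = "P", Mml = "P",
    Cfa = "D", Eca = "D", Bta = "D", Ssc = "D",
    Mmu = "R", Rno = "R")
}

#' Default simulation scenario for the mammal dataset
#'
#' `scenario = "accelerated"` is the headline condition: the coiled-coil
#' domain evolves at 1/3 the background rate on every edge (purifying
#' selection on a functional domain) except the three primate terminal
#' edges, where it evolves at 3x background (lineage-specific acceleration).
#' `scenario = "null"` leaves the domain rate untouched everywhere, for
#' calibration and symmetry checks.
#'
#' @param seed master seed.
#' @param scenario `"accelerated"` or `"null"`.
#' @param n_codons number of codons (default 280, a SIP30-sized protein).
#' @param domain_region codon-space [region()] of the domain (default codons
#'   111-190, a centrally placed 80-codon coiled-coil).
#' @return a [simulation_config()].
#' @export
mammal_config <- function(seed = 1L, scenario = c("accelerated", "null"),
                          n_codons = 280L,
                          domain_region = region(110, 190, "codon")) {
  scenario <- match.arg(scenario)
  mult <- switch(scenario,
    accelerated = c(".default" = 1 / 3, Hsa = 3, Ptr = 3, Mml = 3),
    null = NULL)
  simulation_config(tree = mammal_tree(), n_codons = n_codons,
                    domain_region = domain_region,
                    domain_multiplier = mult, seed = seed)
}

#' Random protein with an implanted ideal heptad repeat
#'
#' Test-support generator for the coiled-coil caller: residues are uniform
#' over the 20 amino acids except inside `coil_region`, which carries the
#' idealized heptad pattern `LEELEEK` (leucines at the hydrophobic a/d
#' positions, glutamates/lysines elsewhere) starting at register position a.
#'
#' @param n protein length.
#' @param coil_region a sequence-space [region()] (NULL for no implant).
#' @param seed integer seed.
#' @return named character vector of length 1 (id `"synthetic"`), with the
#'   implant region attached as attribute `"coil_region"`.
#' @export
simulate_coil_protein <- function(n, coil_region = NULL, seed = 1L) {
  set.seed(stream_seed(seed, "coil-protein"))
  res <- sample(AA_CHARS, n, replace = TRUE)
  if (!is.null(coil_region)) {
    coil_region <- as_region(coil_region, "sequence")
    idx <- region_seq(coil_region)
    pattern <- c("L", "E", "E", "L", "E", "E", "K")
    res[idx] <- pattern[((seq_along(idx) - 1L) %% 7L) + 1L]
  }
  out <- setNames(paste(res, collapse = ""), "synthetic")
  attr(out, "coil_region") <- coil_region
  out
}
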