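default_freqs <- c(0.2844, 0.2519, 0.2947, 0.1690)

test_that("HKY rate matrix is a proper reversible generator", {
  Q <- hky_rate_matrix(list(base_freqs = default_freqs, ti_tv = 2.2233))
  expect_lt(max(abs(rowSums(Q))), 1e-12)
  pi <- attr(Q, "pi")
  expect_lt(abs(-sum(pi * diag(Q)) - 1), 1e-12)  # one substitution per unit t
  flux <- diag(pi) %*% unclass(Q)
  expect_lt(max(abs(flux - t(flux))), 1e-12)     # detailed balance

  # uniform frequencies: kappa = 2 * TiTv, so TiTv = 0.5 is the JC limit
  Qjc <- hky_rate_matrix(list(base_freqs = rep(0.25, 4), ti_tv = 0.5))
  expect_equal(attr(Qjc, "kappa"), 1)
  off <- unclass(Qjc); diag(off) <- NA
  expect_equal(max(off, na.rm = TRUE), min(off, na.rm = TRUE))
})

test_that("transition probabilities satisfy P(0)=I, equilibrium, semigroup", {
  Q <- hky_rate_matrix(list(base_freqs = default_freqs, ti_tv = 2.2233))
  expect_equal(transition_probabilities(Q, 0), diag(4), ignore_attr = TRUE)
  expect_error(transition_probabilities(Q, -0.1), ">= 0")

  P <- transition_probabilities(Q, 1e6)
  expect_lt(max(abs(sweep(P, 2, attr(Q, "pi")))), 1e-6)

  # against an independent matrix exponential
  Pref <- as.matrix(Matrix::expm(Matrix::Matrix(unclass(Q) * 0.37)))
  expect_lt(max(abs(transition_probabilities(Q, 0.37) - Pref)), 1e-10)

  # Chapman-Kolmogorov
  P1 <- transition_probabilities(Q, 0.1)
  P2 <- transition_probabilities(Q, 0.25)
  expect_lt(max(abs(P1 %*% P2 - transition_probabilities(Q, 0.35))), 1e-9)
  expect_lt(max(abs(rowSums(P1) - 1)), 1e-10)
})

test_that("discrete gamma categories are equiprobable with mean exactly 1", {
  for (shape in c(0.2, 0.9665, 5)) {
    for (k in c(1, 4, 8)) {
      r <- discrete_gamma_rates(shape, k)
      expect_length(r, k)
      expect_lt(abs(mean(r) - 1), 1e-9)
      expect_true(all(diff(r) >= 0))
    }
  }
})

test_that("translation follows the standard genetic code", {
  expect_equal(translate_cds("ATGAAA"), "MK")
  expect_equal(translate_cds("TAA"), "*")
  expect_error(translate_cds("ATGA"), "divisible by 3")
  expect_error(translate_cds("ATGNNN"), "ambiguous")
})

test_that("simulation is deterministic under a seed and seed-sensitive", {
  cfg1 <- mammal_config(seed = 3, n_codons = 200, domain_region = region(60, 120, "codon"))
  s1 <- simulate_cds(cfg1)
  s2 <- simulate_cds(cfg1)
  expect_identical(s1$nt$seqs, s2$nt$seqs)
  expect_identical(s1$aa$seqs, s2$aa$seqs)
  s3 <- simulate_cds(mammal_config(seed = 4, n_codons = 200,
                                   domain_region = region(60, 120, "codon")))
  expect_false(identical(s1$nt$seqs, s3$nt$seqs))
})

test_that("zero branch lengths give identical leaves; translation has no stops", {
  star <- read_newick("(A:0.0,B:0.0,C:0.0);")
  sim <- simulate_cds(simulation_config(star, n_codons = 120, seed = 9))
  expect_identical(unname(sim$nt$seqs[["A"]]), unname(sim$nt$seqs[["B"]]))
  expect_identical(unname(sim$nt$seqs[["A"]]), unname(sim$nt$seqs[["C"]]))
  expect_false(any(grepl("*", sim$aa$seqs, fixed = TRUE)))
})

test_that("leaf base composition follows the generator's exact stop-free law", {
  law <- codon_law_oracle(default_freqs, 2.2233, 0.9665, 4, 0)
  for (s in 1:3) {
    sim <- simulate_cds(simulation_config(read_newick("(A:0.0,B:0.0);"),
                                          n_codons = 10000, seed = s))
    chars <- strsplit(sim$nt$seqs[["A"]], "")[[1]]
    counts <- table(factor(chars, levels = c("A", "C", "G", "T")))
    expect_gt(stats::chisq.test(counts, p = law$leaf_nuc_freqs)$p.value, 0.01)
    # and it converges on the nominal base frequencies up to the small
    # stop-exclusion shift
    expect_lt(max(abs(counts / sum(counts) - default_freqs)), 0.015)
  }
})

test_that("domain and background substitution counts are exchangeable at multiplier 1", {
  tree <- read_newick("(A:0.05,B:0.05);")
  dom <- region(100, 200, "codon")
  pd <- pb <- numeric(50)
  for (s in 1:50) {
    sim <- simulate_cds(simulation_config(tree, n_codons = 300,
                                          domain_region = dom, seed = 500 + s))
    m <- do.call(rbind, strsplit(unname(sim$nt$seqs), ""))
    diff <- m[1, ] != m[2, ]
    pd[s] <- mean(diff[sim$sites$in_domain])
    pb[s] <- mean(diff[!sim$sites$in_domain])
  }
  expect_gt(stats::wilcox.test(pd, pb)$p.value, 0.01)
})

test_that("per-edge rate multipliers act on domain sites only", {
  tree <- read_newick("(A:0.05,B:0.05);")
  dom <- region(100, 200, "codon")
  pd <- pb <- numeric(30)
  for (s in 1:30) {
    sim <- simulate_cds(simulation_config(tree, n_codons = 300, domain_region = dom,
                                          domain_multiplier = c(A = 4, B = 4),
                                          seed = 800 + s))
    m <- do.call(rbind, strsplit(unname(sim$nt$seqs), ""))
    diff <- m[1, ] != m[2, ]
    pd[s] <- mean(diff[sim$sites$in_domain])
    pb[s] <- mean(diff[!sim$sites$in_domain])
  }
  expect_gt(mean(pd), 2 * mean(pb))
  expect_error(simulation_config(tree, 300, domain_region = dom,
                                 domain_multiplier = c(A = -1)), "positive")
})

test_that("coil-protein generator implants the heptad pattern where asked", {
  p <- simulate_coil_protein(120, region(30, 72), seed = 5)
  chars <- strsplit(unname(p), "")[[1]]
  expect_equal(paste(chars[31:37], collapse = ""), "LEELEEK")
  expect_equal(paste(chars[66:72], collapse = ""), "LEELEEK")
  p2 <- simulate_coil_protein(120, region(30, 72), seed = 5)
  expect_identical(p, p2)
})
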