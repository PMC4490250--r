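test_that("phased haplotype frequencies are direct counts", {
  a <- c(rep(1, 50), rep(0, 50))
  b <- c(rep(1, 50), rep(0, 50))
  fr <- estimate_haplotype_freqs(a, b, phased = TRUE)
  expect_equal(fr$p_A, 0.5)
  expect_equal(fr$p_B, 0.5)
  expect_equal(fr$p_AB, 0.5)

  # all four haplotypes equally frequent -> p_AB = 0.25
  a2 <- c(1, 1, 0, 0); b2 <- c(1, 0, 1, 0)
  expect_equal(estimate_haplotype_freqs(a2, b2, phased = TRUE)$p_AB, 0.25)
})

test_that("EM matches an exhaustive-likelihood grid search on ambiguous data", {
  # genotype data rich in double heterozygotes (phase truly ambiguous)
  set.seed(21)
  true <- list(AB = 0.42, Ab = 0.08, aB = 0.08, ab = 0.42)
  haps <- sample(names(true), 2 * 300, replace = TRUE,
                 prob = unlist(true))
  h1 <- haps[seq(1, 600, 2)]; h2 <- haps[seq(2, 600, 2)]
  a <- (h1 %in% c("AB", "Ab")) + (h2 %in% c("AB", "Ab"))
  b <- (h1 %in% c("AB", "aB")) + (h2 %in% c("AB", "aB"))
  em <- estimate_haplotype_freqs(a, b)
  grid <- oracle_em_grid(a, b)
  expect_equal(em$p_AB, grid, tolerance = 1e-4)
})

test_that("monomorphic SNPs raise a distinct condition", {
  expect_error(estimate_haplotype_freqs(rep(0, 10), rbinom(10, 2, 0.5)),
               class = "snphub_monomorphic")
  expect_error(ld_pair(1, 0.5, 0.5), class = "snphub_monomorphic")
})

test_that("LD coefficients match hand-worked values", {
  perfect <- ld_pair(0.5, 0.5, 0.5)
  expect_equal(perfect$D, 0.25)
  expect_equal(perfect$d_prime, 1)
  expect_equal(perfect$r2, 1)

  eq <- ld_pair(0.5, 0.5, 0.25)
  expect_equal(eq$D, 0)
  expect_equal(eq$d_prime, 0)
  expect_equal(eq$r2, 0)

  mid <- ld_pair(0.5, 0.5, 0.4)
  expect_equal(mid$D, 0.15)
  expect_equal(mid$d_prime, 0.6)
  expect_equal(mid$r2, 0.36)
})

test_that("r2 <= d_prime^2 and both lie in [0,1] on fuzzed triples", {
  set.seed(31)
  for (i in 1:2000) {
    pA <- runif(1, 0.02, 0.98); pB <- runif(1, 0.02, 0.98)
    lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
    pAB <- runif(1, lo, hi)
    ld <- ld_pair(pA, pB, pAB)
    expect_gte(ld$r2, 0); expect_lte(ld$r2, 1)
    expect_gte(ld$d_prime, 0); expect_lte(ld$d_prime, 1)
    expect_lte(ld$r2, ld$d_prime^2 + 1e-12)
  }
})

test_that("phased and EM-based LD agree on simulated genotypes", {
  # with near-complete LD almost no genotype is phase-ambiguous and the EM
  # reproduces the phased counts to 1e-3; at moderate LD the double
  # heterozygotes carry genuine ambiguity and agreement is at the sampling
  # scale (~1/sqrt(n))
  run <- function(level, seed) {
    cfg <- sim_config(data.frame(rsid = c("rs1", "rs2"), chrom = "1",
                                 pos = c(1e6, 1.05e6)),
                      n_populations = 1, n_samples_per_pop = 500,
                      block_spec = list(list(snps = 1:2, level = level)),
                      seed = seed)
    p <- simulate_genotypes(cfg)
    fr_ph <- estimate_haplotype_freqs(p[[1]]$haplotypes[, 1],
                                      p[[1]]$haplotypes[, 2], phased = TRUE)
    fr_em <- estimate_haplotype_freqs(p[[1]]$dosage[, 1], p[[1]]$dosage[, 2])
    c(abs(ld_pair(fr_ph)$r2 - ld_pair(fr_em)$r2),
      abs(ld_pair(fr_ph)$d_prime - ld_pair(fr_em)$d_prime))
  }
  for (seed in 1:5) expect_lt(max(run(0.99, seed)), 1e-3)
  for (seed in 1:5) expect_lt(max(run(0.7, seed)), 0.05)
})

make_snps <- function(ids, pos) {
  data.frame(rsid = ids, chrom = "1", pos = pos, stringsAsFactors = FALSE)
}

make_ld <- function(a, b, r2, dp) {
  n <- length(a)
  data.frame(snp_a = a, snp_b = b, p_A = rep(NA_real_, n),
             p_B = rep(NA_real_, n), p_AB = rep(NA_real_, n),
             D = rep(NA_real_, n), d_prime = rep(dp, length.out = n),
             r2 = rep(r2, length.out = n), status = rep("ok", n),
             stringsAsFactors = FALSE)
}

test_that("collapse_blocks applies the 0.8 r2 OR 0.8 D' rule transitively", {
  snps <- make_snps(c("A", "B", "C"), c(100, 200, 300))
  # all pairwise r2 = 1 -> one locus of 3
  ld_all <- make_ld(c("A", "A", "B"), c("B", "C", "C"), 1, 1)
  loci <- collapse_blocks(snps, ld_all)
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$members, "A,B,C")

  # nothing reaches either threshold -> three singletons
  ld_none <- make_ld(c("A", "A", "B"), c("B", "C", "C"), 0.1, 0.2)
  expect_equal(nrow(collapse_blocks(snps, ld_none)), 3L)

  # chain A-B (r2), B-C (D') with weak A-C still collapses into one locus
  ld_chain <- make_ld(c("A", "B", "A"), c("B", "C", "C"),
                      c(0.9, 0.1, 0.1), c(0.9, 0.85, 0.1))
  loci <- collapse_blocks(snps, ld_chain)
  expect_equal(nrow(loci), 1L)
})

test_that("a missing within-window LD entry is an explicit error", {
  snps <- make_snps(c("A", "B", "C"), c(100, 200, 300))
  ld <- make_ld(c("A", "A"), c("B", "C"), 1, 1)   # B-C missing
  expect_error(collapse_blocks(snps, ld), "missing LD")
  # out-of-window pairs need no entry
  far <- make_snps(c("A", "B"), c(100, 1e7))
  expect_silent(collapse_blocks(far, make_ld(character(), character(),
                                             numeric(), numeric())))
})

test_that("collapse_blocks equals a brute-force components oracle", {
  for (seed in 1:25) {
    inst <- random_ld_instance(sample(3:20, 1), seed)
    loci <- collapse_blocks(inst$snps, inst$ld, window_kb = 1e6)
    got <- lapply(strsplit(loci$members, ","), sort)
    edges <- inst$ld[inst$ld$r2 >= 0.8 | inst$ld$d_prime >= 0.8, ]
    want <- lapply(oracle_components(inst$snps$rsid, edges$snp_a,
                                     edges$snp_b), sort)
    key <- function(xs) sort(vapply(xs, paste, character(1), collapse = ","))
    expect_equal(key(got), key(want))
  }
})

test_that("raising either threshold never merges loci (monotone refinement)", {
  for (seed in 26:35) {
    inst <- random_ld_instance(12, seed)
    lo <- collapse_blocks(inst$snps, inst$ld, r2_min = 0.8,
                          dprime_min = 0.8, window_kb = 1e6)
    hi <- collapse_blocks(inst$snps, inst$ld, r2_min = 0.95,
                          dprime_min = 0.95, window_kb = 1e6)
    expect_gte(nrow(hi), nrow(lo))
    # every stricter-threshold locus is contained in a looser-threshold one
    lo_sets <- strsplit(lo$members, ",")
    for (m in strsplit(hi$members, ",")) {
      expect_true(any(vapply(lo_sets, function(s) all(m %in% s),
                             logical(1))))
    }
  }
})

test_that("loci are named by overlapping genes in genomic order", {
  genes <- data.frame(chrom = "1", start = c(150, 50), end = c(250, 120),
                      name = c("PSRC1", "CELSR2"), stringsAsFactors = FALSE)
  expect_equal(name_locus("1", 100, 200, genes), "CELSR2/PSRC1")
  expect_equal(name_locus("10", 91352000, 91353000, genes),
               "10:91352000-91353000")
  one <- data.frame(chrom = "10", start = 91300000, end = 91400000,
                    name = "PANK1", stringsAsFactors = FALSE)
  expect_equal(name_locus("10", 91352850, 91352850, one), "PANK1")
})

test_that("cross-chromosome merging never occurs", {
  snps <- data.frame(rsid = c("A", "B"), chrom = c("1", "2"),
                     pos = c(100, 100), stringsAsFactors = FALSE)
  ld <- make_ld("A", "B", 1, 1)   # present but cross-chromosome
  loci <- collapse_blocks(snps, ld)
  expect_equal(nrow(loci), 2L)
})
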