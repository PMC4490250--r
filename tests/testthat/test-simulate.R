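toy_map <- function(n = 3, chrom = "1", gap = 50000L) {
  data.frame(rsid = sprintf("rs%d", seq_len(n)), chrom = chrom,
             pos = 1000000L + gap * (seq_len(n) - 1L),
             stringsAsFactors = FALSE)
}

test_that("a block planted at correlation level 1 gives pairwise r2 = 1", {
  cfg <- sim_config(toy_map(3), n_populations = 1, n_samples_per_pop = 50,
                    block_spec = list(list(snps = 1:3, level = 1)), seed = 11)
  panels <- simulate_genotypes(cfg)
  H <- panels[[1]]$haplotypes
  for (pair in list(c(1, 2), c(1, 3), c(2, 3))) {
    fr <- estimate_haplotype_freqs(H[, pair[1]], H[, pair[2]], phased = TRUE)
    expect_equal(ld_pair(fr)$r2, 1)
  }
  # haplotype columns are literal copies
  expect_identical(H[, 1], H[, 2])
})

test_that("SNPs in different blocks are independent (Monte-Carlo r2)", {
  cfg <- sim_config(toy_map(2), n_populations = 1,
                    n_samples_per_pop = 10000, seed = 5)
  panels <- simulate_genotypes(cfg)
  H <- panels[[1]]$haplotypes
  fr <- estimate_haplotype_freqs(H[, 1], H[, 2], phased = TRUE)
  expect_lt(ld_pair(fr)$r2, 0.01)
})

test_that("identical config and seed reproduce byte-identical panels", {
  cfg <- sim_config(toy_map(4), n_populations = 2, n_samples_per_pop = 30,
                    block_spec = list(list(snps = 1:2, level = 0.9)),
                    seed = 99)
  p1 <- simulate_genotypes(cfg)
  p2 <- simulate_genotypes(cfg)
  expect_identical(p1, p2)
  e1 <- simulate_expression(p1, cfg)
  e2 <- simulate_expression(p2, cfg)
  expect_identical(e1, e2)
})

test_that("overlapping block groups are rejected", {
  expect_error(sim_config(toy_map(3),
                          block_spec = list(list(snps = 1:2, level = 1),
                                            list(snps = 2:3, level = 1))),
               "overlap")
})

test_that("a probe may not carry two planted effects from the same SNP", {
  es <- data.frame(snp_id = c("rs1", "rs1"), probe_id = c("p1", "p1"),
                   beta = c(1, 2), populations = "all",
                   stringsAsFactors = FALSE)
  expect_error(sim_config(toy_map(2), eqtl_spec = es), "one planted effect")
})

test_that("expression degenerate cases: zero effect and noise-free additivity", {
  es <- data.frame(snp_id = "rs1", probe_id = "p1", beta = 0,
                   populations = "all", stringsAsFactors = FALSE)
  cfg0 <- sim_config(toy_map(2), n_populations = 1, n_samples_per_pop = 20,
                     eqtl_spec = es, noise_sd = 0, seed = 3)
  panels <- simulate_genotypes(cfg0)
  expr <- simulate_expression(panels, cfg0)
  expect_true(all(expr[[1]] == 0))

  es$beta <- 1
  cfg1 <- sim_config(toy_map(2), n_populations = 1, n_samples_per_pop = 20,
                     eqtl_spec = es, noise_sd = 0, seed = 3)
  expr1 <- simulate_expression(simulate_genotypes(cfg1), cfg1)
  expect_equal(unname(expr1[[1]][, "p1"]),
               unname(simulate_genotypes(cfg1)[[1]]$dosage[, "rs1"]))
})

test_that("planted effect size is recovered by least squares at the oracle rate", {
  # beta = 1.5, sd = 1, n = 60: the OLS slope error is ~N(0, 1/sqrt(n*2p(1-p)))
  # given the drawn allele frequency p, so the oracle rate of landing within
  # +/- 0.4 integrates that normal band over p ~ U(0.05, 0.95).  The observed
  # recovery rate must match it (common alleles recover essentially always;
  # rare alleles dilute the average below certainty).
  set.seed(909)
  p_draw <- runif(2e5, 0.05, 0.95)
  oracle_rate <- mean(2 * pnorm(0.4 * sqrt(60 * 2 * p_draw * (1 - p_draw))) - 1)

  es <- data.frame(snp_id = "rs1", probe_id = "p1", beta = 1.5,
                   populations = "all", stringsAsFactors = FALSE)
  ok <- 0L; used <- 0L
  n_rep <- 200L
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(toy_map(2), n_populations = 1, n_samples_per_pop = 60,
                      eqtl_spec = es, noise_sd = 1, seed = 1000 + s)
    panels <- simulate_genotypes(cfg)
    expr <- simulate_expression(panels, cfg)
    d <- panels[[1]]$dosage[, "rs1"]
    if (max(d) == min(d)) next
    used <- used + 1L
    slope <- unname(coef(lm(expr[[1]][, "p1"] ~ d))[2])
    if (abs(slope - 1.5) <= 0.4) ok <- ok + 1L
  }
  emp <- ok / used
  se <- sqrt(oracle_rate * (1 - oracle_rate) / used)
  expect_lt(abs(emp - oracle_rate), 4 * se)
  expect_gt(emp, 0.8)
})

test_that("contact generation is forced by the hub spec", {
  loci <- data.frame(locus_id = c("G1", "G2", "I1"), chrom = c("1", "2", "3"),
                     start = c(1e6, 2e6, 3e6), end = c(1.1e6, 2.1e6, 3.1e6),
                     gwas_flag = c(TRUE, TRUE, FALSE),
                     stringsAsFactors = FALSE)
  cfg <- sim_config(toy_map(2),
                    hub_spec = list(list(gwas = c("G1", "G2"),
                                         intermediary = "I1")), seed = 2)
  out <- simulate_contacts(loci, cfg)
  expect_equal(nrow(out$contacts), 2L)
  expect_equal(nrow(out$functional), 0L)

  cfg0 <- sim_config(toy_map(2), seed = 2)
  expect_equal(nrow(simulate_contacts(loci, cfg0)$contacts), 0L)
})

test_that("background contacts avoid loci and fail loudly when impossible", {
  loci <- data.frame(locus_id = c("G1", "G2"), chrom = "1",
                     start = c(1e6, 3e6), end = c(1.2e6, 3.2e6),
                     gwas_flag = TRUE, stringsAsFactors = FALSE)
  cfg <- sim_config(toy_map(2), n_background_contacts = 10, seed = 8)
  out <- simulate_contacts(loci, cfg)
  bg <- out$contacts
  expect_equal(nrow(bg), 10L)
  for (i in seq_len(nrow(bg))) {
    expect_false(any(loci$start <= bg$end_a[i] + 1 &
                     loci$end >= bg$start_a[i] - 1 &
                     loci$chrom == bg$chrom_a[i]))
  }
  # loci covering (almost) the whole simulated chromosome: placement fails
  tight <- data.frame(locus_id = "G1", chrom = "1", start = 1,
                      end = 2e6, gwas_flag = TRUE, stringsAsFactors = FALSE)
  cfg2 <- sim_config(toy_map(2), n_background_contacts = 1, seed = 8)
  expect_error(simulate_contacts(tight, cfg2, guard = 2e6, max_tries = 20),
               class = "snphub_rejection")
})

test_that("truth tables record a partition of the SNPs", {
  cfg <- sim_config(toy_map(5),
                    block_spec = list(list(snps = 1:2, level = 1),
                                      list(snps = 3:4, level = 1)),
                    seed = 4)
  blocks <- simulate_contacts(
    data.frame(locus_id = "G1", chrom = "1", start = 1e6, end = 1.1e6,
               gwas_flag = TRUE, stringsAsFactors = FALSE),
    cfg)$truth$planted_blocks
  members <- unlist(blocks)
  expect_setequal(members, cfg$snp_map$rsid)
  expect_equal(anyDuplicated(members), 0L)
})
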