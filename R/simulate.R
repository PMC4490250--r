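# Synthetic-data generator with planted ground truth.
#
# Emulates the study design of the real analysis: eight population panels
# with haplotype-block LD structure, additive SNP effects on expression with
# Gaussian noise, and chromatin-contact lists containing planted
# GWAS-intermediary-GWAS hubs plus random background contacts.

HAPMAP8 <- c("CEU", "CHB", "GIH", "JPT", "LWK", "MEX", "MKK", "YRI")

#' Simulation configuration
#'
#' Declares the study design for the synthetic generator: population panels,
#' SNP map, planted haplotype blocks, planted additive eQTL effects, planted
#' hubs and background contact noise.  All stages draw from deterministic
#' streams derived from the single `seed`.
#'
#' @param snp_map data.frame with columns `rsid`, `chrom`, `pos` (1-based).
#' @param n_populations Number of population panels (default 8; with 8 the
#'   panels carry the HapMap population labels).
#' @param n_samples_per_pop Diploid samples per population.
#' @param block_spec List of planted haplotype blocks, each a list with
#'   `snps` (rsids or indices into `snp_map`) and `level`, the within-block
#'   haplotype-correlation level in `[0, 1]` (1 = perfect LD).  SNPs not
#'   covered by any block are independent singletons.
#' @param eqtl_spec data.frame with columns `snp_id`, `probe_id`, `beta`
#'   (expression units per allele copy) and `populations` (comma-separated
#'   population labels, or `"all"`).
#' @param noise_sd Gaussian expression noise standard deviation.
#' @param hub_spec List of planted hubs, each a list with `gwas` (locus ids),
#'   `intermediary` (one locus id) and `layers` (edge layer per GWAS member,
#'   recycled; `"spatial"` or `"functional"`).
#' @param n_background_contacts Random background contact pairs placed in
#'   non-locus regions.
#' @param probe_ids Optional extra probe ids that receive pure noise.
#' @param freq_range Per-population allele-frequency range (uniform draw).
#' @param seed Integer seed driving every random stage.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(snp_map,
                       n_populations = 8,
                       n_samples_per_pop = 60,
                       block_spec = list(),
                       eqtl_spec = NULL,
                       noise_sd = 1,
                       hub_spec = list(),
                       n_background_contacts = 0,
                       probe_ids = NULL,
                       freq_range = c(0.05, 0.95),
                       seed = 1L) {
  stopifnot(is.data.frame(snp_map),
            all(c("rsid", "chrom", "pos") %in% names(snp_map)))
  snp_map <- data.frame(rsid = as.character(snp_map$rsid),
                        chrom = norm_chrom(snp_map$chrom),
                        pos = as.integer(snp_map$pos),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(snp_map$rsid))
    stop_snphub("duplicated rsids in snp_map")
  if (any(snp_map$pos < 1L))
    stop_snphub("SNP positions must be >= 1")
  if (n_populations < 1)
    stop_snphub("n_populations must be >= 1")
  pops <- if (n_populations == 8) HAPMAP8 else
    sprintf("pop%d", seq_len(n_populations))

  # resolve block members to rsids; reject overlap
  block_spec <- lapply(block_spec, function(b) {
    snps <- b$snps
    if (is.numeric(snps)) snps <- snp_map$rsid[snps]
    if (!all(snps %in% snp_map$rsid))
      stop_snphub("block_spec references unknown SNPs")
    level <- b$level %||% 1
    if (level < 0 || level > 1)
      stop_snphub("block correlation level must be in [0, 1]")
    list(snps = as.character(snps), level = level)
  })
  members <- unlist(lapply(block_spec, `[[`, "snps"))
  if (anyDuplicated(members))
    stop_snphub("block_spec groups overlap: a SNP may belong to one block only")

  if (is.null(eqtl_spec)) {
    eqtl_spec <- data.frame(snp_id = character(), probe_id = character(),
                            beta = numeric(), populations = character(),
                            stringsAsFactors = FALSE)
  }
  stopifnot(all(c("snp_id", "probe_id", "beta") %in% names(eqtl_spec)))
  if (is.null(eqtl_spec$populations)) eqtl_spec$populations <- "all"
  if (!all(eqtl_spec$snp_id %in% snp_map$rsid))
    stop_snphub("eqtl_spec references unknown SNPs")
  if (anyDuplicated(eqtl_spec[, c("snp_id", "probe_id")]))
    stop_snphub("a probe may carry at most one planted effect per SNP")
  for (p in eqtl_spec$populations) {
    if (identical(p, "all")) next
    ps <- strsplit(p, ",", fixed = TRUE)[[1]]
    if (!all(ps %in% pops))
      stop_snphub("eqtl_spec population subset refers to undeclared populations")
  }

  structure(list(snp_map = snp_map,
                 n_populations = as.integer(n_populations),
                 populations = pops,
                 n_samples_per_pop = as.integer(n_samples_per_pop),
                 block_spec = block_spec,
                 eqtl_spec = eqtl_spec,
                 noise_sd = noise_sd,
                 hub_spec = hub_spec,
                 n_background_contacts = as.integer(n_background_contacts),
                 probe_ids = probe_ids,
                 freq_range = freq_range,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Planted block partition of a simulation config
#'
#' Declared blocks plus one singleton block per uncovered SNP: the ground
#' truth [collapse_blocks()] is expected to recover.
#'
#' @param config A [sim_config()].
#' @return List of character vectors partitioning the rsids.
#' @export
config_blocks <- function(config) {
  blocks <- lapply(config$block_spec, `[[`, "snps")
  covered <- unlist(blocks)
  singles <- setdiff(config$snp_map$rsid, covered)
  c(blocks, as.list(singles))
}

#' Simulate genotype panels with planted haplotype-block LD
#'
#' Draws phased haplotypes per population.  Within a planted block all SNPs
#' copy a shared latent haplotype, each with per-SNP flip probability
#' `f = (1 - sqrt(level)) / 2`, so the pairwise haplotype correlation is
#' monotone in `level` and equals 1 exactly at `level = 1` (identical
#' columns).  SNPs in different blocks are drawn independently.  Allele
#' frequencies are drawn per population from `config$freq_range`.
#'
#' @param config A [sim_config()].
#' @return Named list (one element per population) of lists with `dosage`
#'   (samples x SNPs matrix of 0/1/2) and `haplotypes` (2n x SNPs matrix of
#'   0/1), plus attribute `planted_blocks` (the block partition).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "genotypes"))
  blocks <- config_blocks(config)
  levels <- c(vapply(config$block_spec, `[[`, numeric(1), "level"),
              rep(1, length(blocks) - length(config$block_spec)))
  m <- nrow(config$snp_map)
  n <- config$n_samples_per_pop
  fr <- config$freq_range
  out <- list()
  for (pop in config$populations) {
    H <- matrix(0L, nrow = 2L * n, ncol = m,
                dimnames = list(NULL, config$snp_map$rsid))
    for (bi in seq_along(blocks)) {
      p <- runif(1, fr[1], fr[2])
      z <- rbinom(2L * n, 1L, p)
      f <- (1 - sqrt(levels[bi])) / 2
      for (s in blocks[[bi]]) {
        col <- if (f == 0) z else (z + rbinom(2L * n, 1L, f)) %% 2L
        H[, s] <- col
      }
    }
    samples <- sprintf("%s_s%03d", pop, seq_len(n))
    rownames(H) <- paste0(rep(samples, each = 2L), c("_h1", "_h2"))
    dosage <- H[seq(1L, 2L * n, by = 2L), , drop = FALSE] +
      H[seq(2L, 2L * n, by = 2L), , drop = FALSE]
    rownames(dosage) <- samples
    out[[pop]] <- list(dosage = dosage, haplotypes = H)
  }
  attr(out, "planted_blocks") <- blocks
  out
}

#' Simulate expression matrices with planted additive eQTL effects
#'
#' Expression is `sum(beta * dosage) + Gaussian(0, noise_sd)` per probe;
#' probes without a planted effect (and extra `probe_ids`) are pure noise.
#'
#' @param panels Output of [simulate_genotypes()] from the same config.
#' @param config A [sim_config()].
#' @return Named list of samples x probes expression matrices.
#' @export
simulate_expression <- function(panels, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "expression"))
  probes <- unique(c(config$eqtl_spec$probe_id, config$probe_ids))
  out <- list()
  for (pop in config$populations) {
    dosage <- panels[[pop]]$dosage
    n <- nrow(dosage)
    E <- matrix(if (config$noise_sd > 0)
                  rnorm(n * length(probes), 0, config$noise_sd) else 0,
                nrow = n, ncol = length(probes),
                dimnames = list(rownames(dosage), probes))
    es <- config$eqtl_spec
    for (i in seq_len(nrow(es))) {
      pp <- es$populations[i]
      if (!identical(pp, "all") &&
          !pop %in% strsplit(pp, ",", fixed = TRUE)[[1]]) next
      E[, es$probe_id[i]] <- E[, es$probe_id[i]] +
        es$beta[i] * dosage[, es$snp_id[i]]
    }
    out[[pop]] <- E
  }
  out
}

#' Simulate chromatin contacts, functional edges and truth tables
#'
#' Every planted hub contributes one anchor pair (or functional edge) per
#' GWAS member, linking it to the hub's intermediary locus.  Background
#' contacts are placed uniformly over non-locus regions (rejection-resampled
#' with a guard band around loci), so they can never create additional
#' GWAS-GWAS connections.
#'
#' @param loci Locus table: data.frame with `locus_id`, `chrom`, `start`,
#'   `end`, `gwas_flag` (1-based inclusive coordinates).
#' @param config A [sim_config()].
#' @param anchor_width Width of background contact anchors (bp).
#' @param guard Exclusion flank around loci for background anchors (bp).
#' @param max_tries Rejection-sampling retries per background anchor.
#' @return List with `contacts` (data.frame `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, `contact_id`; 1-based inclusive),
#'   `functional` (data.frame `locus_u`, `locus_v`, `type`, `citation`) and
#'   `truth` (list `planted_blocks`, `planted_eqtl_pairs`,
#'   `planted_hub_members`).
#' @export
simulate_contacts <- function(loci, config, anchor_width = 5000L,
                              guard = 20000L, max_tries = 1000L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "contacts"))
  loci$chrom <- norm_chrom(loci$chrom)
  ids <- loci$locus_id
  contacts <- list()
  functional <- list()
  for (hi in seq_along(config$hub_spec)) {
    h <- config$hub_spec[[hi]]
    refs <- c(h$gwas, h$intermediary)
    if (!all(refs %in% ids))
      stop_snphub(sprintf("hub_spec references unknown loci: %s",
                          paste(setdiff(refs, ids), collapse = ", ")))
    layers <- rep(h$layers %||% "spatial", length.out = length(h$gwas))
    ir <- loci[match(h$intermediary, ids), ]
    for (gi in seq_along(h$gwas)) {
      gr <- loci[match(h$gwas[gi], ids), ]
      if (layers[gi] == "spatial") {
        contacts[[length(contacts) + 1L]] <- data.frame(
          chrom_a = gr$chrom, start_a = gr$start, end_a = gr$end,
          chrom_b = ir$chrom, start_b = ir$start, end_b = ir$end,
          contact_id = sprintf("hub%d_%s", hi, h$gwas[gi]),
          stringsAsFactors = FALSE)
      } else if (layers[gi] == "functional") {
        functional[[length(functional) + 1L]] <- data.frame(
          locus_u = h$gwas[gi], locus_v = h$intermediary,
          type = "protein", citation = sprintf("planted_hub%d", hi),
          stringsAsFactors = FALSE)
      } else stop_snphub(sprintf("unknown hub edge layer '%s'", layers[gi]))
    }
  }

  if (config$n_background_contacts > 0) {
    chroms <- unique(loci$chrom)
    chrom_len <- vapply(chroms, function(ch)
      max(loci$end[loci$chrom == ch]) + 1e6, numeric(1))
    draw_anchor <- function() {
      for (t in seq_len(max_tries)) {
        ch <- sample(chroms, 1L)
        start <- floor(runif(1, 1, chrom_len[[ch]] - anchor_width))
        end <- start + anchor_width - 1L
        sel <- loci$chrom == ch
        hit <- any(start <= loci$end[sel] + guard &
                   end >= loci$start[sel] - guard)
        if (!hit) return(list(chrom = ch, start = as.integer(start),
                              end = as.integer(end)))
      }
      stop_snphub("could not place background contact outside loci",
                  class = "snphub_rejection")
    }
    for (k in seq_len(config$n_background_contacts)) {
      a <- draw_anchor(); b <- draw_anchor()
      contacts[[length(contacts) + 1L]] <- data.frame(
        chrom_a = a$chrom, start_a = a$start, end_a = a$end,
        chrom_b = b$chrom, start_b = b$start, end_b = b$end,
        contact_id = sprintf("bg%d", k), stringsAsFactors = FALSE)
    }
  }

  empty_contacts <- data.frame(chrom_a = character(), start_a = integer(),
                               end_a = integer(), chrom_b = character(),
                               start_b = integer(), end_b = integer(),
                               contact_id = character(),
                               stringsAsFactors = FALSE)
  empty_fun <- data.frame(locus_u = character(), locus_v = character(),
                          type = character(), citation = character(),
                          stringsAsFactors = FALSE)
  blocks <- config_blocks(config)
  truth <- list(
    planted_blocks = blocks,
    planted_eqtl_pairs = config$eqtl_spec[, c("snp_id", "probe_id")],
    planted_hub_members = lapply(config$hub_spec,
                                 function(h) sort(as.character(h$gwas))))
  list(contacts = if (length(contacts)) do.call(rbind, contacts)
                  else empty_contacts,
       functional = if (length(functional)) do.call(rbind, functional)
                    else empty_fun,
       truth = truth)
}

# Default synthetic study scenario ---------------------------------------

#' Default synthetic study design
#'
#' The scenario [simulate_study()] uses: 12 GWAS SNPs on three chromosomes in
#' four perfect-LD blocks plus singletons, two planted eQTLs (one trans, one
#' cis) at effect size 1.5, and three planted hubs (one bridged by an eQTL
#' as well as contacts, one of three GWAS loci, one mixing spatial and
#' functional layers through a gene-desert locus).
#'
#' @param seed,noise_sd,n_background_contacts,n_samples_per_pop,n_populations
#'   Passed through to [sim_config()].
#' @return A [sim_config()].
#' @export
default_study_config <- function(seed = 1L, noise_sd = 1,
                                 n_background_contacts = 0L,
                                 n_samples_per_pop = 60L,
                                 n_populations = 8L) {
  snp_map <- data.frame(
    rsid = sprintf("rs%d", 1:12),
    chrom = c("1", "1", "1", "1", "1", "2", "2", "2", "2", "3", "3", "1"),
    pos = c(1000000L, 1050000L, 1100000L, 1400000L, 1450000L,
            2000000L, 2040000L, 2450000L, 2500000L,
            3000000L, 3600000L, 5000000L),
    stringsAsFactors = FALSE)
  block_spec <- list(list(snps = c("rs1", "rs2", "rs3"), level = 1),
                     list(snps = c("rs4", "rs5"), level = 1),
                     list(snps = c("rs6", "rs7"), level = 1),
                     list(snps = c("rs8", "rs9"), level = 1))
  eqtl_spec <- data.frame(
    snp_id = c("rs1", "rs10"),
    probe_id = c("probe_P1", "probe_C1"),
    beta = c(1.5, 1.5),
    populations = "all", stringsAsFactors = FALSE)
  hub_spec <- list(
    list(gwas = c("GENE_A", "GENE_C"), intermediary = "INT_X",
         layers = "spatial"),
    list(gwas = c("GENE_B", "GENE_D", "GENE_E"), intermediary = "INT_Y",
         layers = "spatial"),
    list(gwas = c("GENE_F", "1:5000000-5000000"), intermediary = "INT_Z",
         layers = c("spatial", "functional")))
  sim_config(snp_map = snp_map,
             n_populations = n_populations,
             n_samples_per_pop = n_samples_per_pop,
             block_spec = block_spec,
             eqtl_spec = eqtl_spec,
             noise_sd = noise_sd,
             hub_spec = hub_spec,
             n_background_contacts = n_background_contacts,
             probe_ids = c("probe_N1"),
             seed = seed)
}

study_genes <- function() {
  data.frame(
    chrom = c("1", "1", "2", "2", "3", "3", "2", "3", "1"),
    start = c(950000L, 1380000L, 1990000L, 2440000L, 2990000L, 3590000L,
              8000000L, 9000000L, 9500000L),
    end = c(1150000L, 1470000L, 2060000L, 2510000L, 3010000L, 3610000L,
            8050000L, 9050000L, 9550000L),
    name = c("GENE_A", "GENE_B", "GENE_C", "GENE_D", "GENE_E", "GENE_F",
             "INT_X", "INT_Y", "INT_Z"),
    stringsAsFactors = FALSE)
}

study_probes <- function() {
  data.frame(
    probe_id = c("probe_P1", "probe_N1", "probe_C1"),
    chrom = c("2", "3", "3"),
    start = c(8010000L, 7000000L, 3000500L),
    end = c(8011000L, 7001000L, 3001500L),
    stringsAsFactors = FALSE)
}

# Planted locus table (ground truth the generator plants hubs against):
# SNP blocks collapsed to spans named by overlapping genes, plus each
# annotation gene that overlaps no SNP block as its own (non-GWAS) locus.
planted_loci <- function(config, genes) {
  blocks <- config_blocks(config)
  sm <- config$snp_map
  rows <- lapply(blocks, function(b) {
    pos <- sm$pos[match(b, sm$rsid)]
    chrom <- unique(sm$chrom[match(b, sm$rsid)])
    stopifnot(length(chrom) == 1L)
    data.frame(chrom = chrom, start = min(pos), end = max(pos),
               gwas_flag = TRUE,
               members = paste(b[order(pos)], collapse = ","),
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, rows)
  loci$locus_id <- vapply(seq_len(nrow(loci)), function(i)
    name_locus(loci$chrom[i], loci$start[i], loci$end[i], genes),
    character(1))
  extra <- genes[!vapply(seq_len(nrow(genes)), function(i)
    any(loci$chrom == genes$chrom[i] & loci$start <= genes$end[i] &
        loci$end >= genes$start[i]), logical(1)), ]
  if (nrow(extra)) {
    loci <- rbind(loci, data.frame(chrom = extra$chrom, start = extra$start,
                                   end = extra$end, gwas_flag = FALSE,
                                   members = "", locus_id = extra$name,
                                   stringsAsFactors = FALSE))
  }
  loci[, c("locus_id", "chrom", "start", "end", "members", "gwas_flag")]
}

#' Generate and write a complete synthetic study
#'
#' Builds the default synthetic scenario (8 population panels of 60 samples,
#' 12 GWAS SNPs in 4 planted blocks plus singletons, 2 planted eQTLs and 3
#' planted hubs), simulates all stages and writes every input file the
#' pipeline consumes, plus a truth-table JSON.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param noise_sd Expression noise SD (0 for noise-free runs).
#' @param n_background_contacts Background contact pairs.
#' @param n_samples_per_pop,n_populations Panel dimensions.
#' @param config Optional pre-built [sim_config()]; overrides the scenario
#'   arguments (the default gene/probe annotation is still used).
#' @return List with `files` (named paths), `config` (the `sim_config`),
#'   `truth` and `loci` (the planted locus table).
#' @export
simulate_study <- function(dir, seed = 1L, noise_sd = 1,
                           n_background_contacts = 0L,
                           n_samples_per_pop = 60L, n_populations = 8L,
                           config = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(config))
    config <- default_study_config(seed = seed, noise_sd = noise_sd,
                                   n_background_contacts = n_background_contacts,
                                   n_samples_per_pop = n_samples_per_pop,
                                   n_populations = n_populations)
  genes <- study_genes()
  probes <- study_probes()
  loci <- planted_loci(config, genes)
  panels <- simulate_genotypes(config)
  expr <- simulate_expression(panels, config)
  cont <- simulate_contacts(loci, config)

  files <- list()
  for (pop in config$populations) {
    fv <- file.path(dir, sprintf("genotypes_%s.vcf", pop))
    fd <- file.path(dir, sprintf("dosage_%s.tsv", pop))
    fe <- file.path(dir, sprintf("expression_%s.tsv", pop))
    write_vcf_panel(panels[[pop]], config$snp_map, fv)
    write_dosage(panels[[pop]]$dosage, fd)
    write_expression(expr[[pop]], fe)
    files$panels[[pop]] <- fd
    files$vcf[[pop]] <- fv
    files$expression[[pop]] <- fe
  }
  files$gwas_snps <- file.path(dir, "gwas_snps.tsv")
  snps <- config$snp_map
  snps$study <- "synthetic"
  write_tsv(snps, files$gwas_snps)
  files$genes <- file.path(dir, "genes.bed")
  write_bed(genes[, c("chrom", "start", "end", "name")], files$genes)
  files$probes <- file.path(dir, "probes.tsv")
  write_tsv(probes, files$probes)
  files$contacts <- file.path(dir, "contacts.bedpe")
  write_bedpe(cont$contacts, files$contacts)
  files$functional <- file.path(dir, "functional_edges.tsv")
  write_tsv(cont$functional, files$functional)
  files$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(
    list(planted_blocks = cont$truth$planted_blocks,
         planted_eqtl_pairs = cont$truth$planted_eqtl_pairs,
         planted_hub_members = cont$truth$planted_hub_members),
    files$truth, auto_unbox = FALSE, pretty = TRUE)
  list(files = files, config = config, truth = cont$truth, loci = loci)
}
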