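# Pairwise linkage disequilibrium and haplotype-block locus collapsing.
#
# A haplotype block is the connected component of the graph whose edges join
# SNP pairs with r2 >= 0.8 OR D' >= 0.8 (both thresholds configurable).
# Standard definitions: D = p_AB - p_A p_B; D' = |D| / D_max with
# D_max = min(p_A (1-p_B), (1-p_A) p_B) for D > 0 and
# D_max = min(p_A p_B, (1-p_A)(1-p_B)) for D < 0;
# r2 = D^2 / (p_A (1-p_A) p_B (1-p_B)).

#' Estimate two-locus haplotype frequencies
#'
#' For phased input (per-haplotype 0/1 vectors) frequencies are counted
#' directly.  For unphased input (dosage 0/1/2 vectors) the classic EM
#' algorithm over the two-locus genotype table is used: only the
#' double-heterozygote class is phase-ambiguous; the E step splits it between
#' the coupling (AB/ab) and repulsion (Ab/aB) configurations.  EM is
#' initialized at linkage equilibrium (which also breaks likelihood ties
#' toward smaller |D|) and iterated to `tol` or `max_iter`.
#'
#' Missing values are removed pairwise (complete cases).  A monomorphic SNP
#' raises a condition of class `"snphub_monomorphic"`, distinct from any
#' numeric failure.
#'
#' @param a,b Numeric vectors: haplotype alleles in `{0,1}` when
#'   `phased = TRUE`, else dosages in `{0,1,2}`.  The counted allele (allele
#'   "A"/"B") is the allele coded 1 (alt).
#' @param phased Logical; `TRUE` when `a`, `b` are per-haplotype vectors.
#' @param tol EM convergence tolerance on haplotype frequencies.
#' @param max_iter Maximum EM iterations.
#' @return List with `p_A`, `p_B`, `p_AB`, `n_used` (haplotypes counted),
#'   `method` (`"phased"` or `"em"`) and `n_iter`.
#' @export
estimate_haplotype_freqs <- function(a, b, phased = FALSE,
                                     tol = 1e-8, max_iter = 1000L) {
  stopifnot(length(a) == length(b))
  keep <- complete.cases(a, b)
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2L)
    stop_snphub("need at least 2 non-missing pairs for LD estimation")

  if (phased) {
    if (!all(a %in% c(0, 1)) || !all(b %in% c(0, 1)))
      stop_snphub("phased input must be 0/1 haplotype alleles")
    p_A <- mean(a); p_B <- mean(b)
    if (p_A %in% c(0, 1) || p_B %in% c(0, 1))
      stop_monomorphic("LD undefined: monomorphic SNP")
    return(list(p_A = p_A, p_B = p_B, p_AB = mean(a == 1 & b == 1),
                n_used = length(a), method = "phased", n_iter = 0L))
  }

  if (!all(a %in% 0:2) || !all(b %in% 0:2))
    stop_snphub("unphased input must be dosages in {0,1,2}")
  N <- length(a)
  p_A <- mean(a) / 2; p_B <- mean(b) / 2
  if (p_A %in% c(0, 1) || p_B %in% c(0, 1))
    stop_monomorphic("LD undefined: monomorphic SNP")

  cnt <- function(i, j) sum(a == i & b == j)
  n_dh <- cnt(1, 1)
  # phase-determined haplotype counts
  cAB <- 2 * cnt(2, 2) + cnt(2, 1) + cnt(1, 2)
  cAb <- 2 * cnt(2, 0) + cnt(2, 1) + cnt(1, 0)
  caB <- 2 * cnt(0, 2) + cnt(1, 2) + cnt(0, 1)
  cab <- 2 * cnt(0, 0) + cnt(1, 0) + cnt(0, 1)

  f <- c(AB = p_A * p_B, Ab = p_A * (1 - p_B),
         aB = (1 - p_A) * p_B, ab = (1 - p_A) * (1 - p_B))
  it <- 0L
  repeat {
    it <- it + 1L
    den <- f["AB"] * f["ab"] + f["Ab"] * f["aB"]
    w <- if (den > 0) unname(f["AB"] * f["ab"] / den) else 0.5
    f_new <- c(AB = (cAB + n_dh * w) / (2 * N),
               Ab = (cAb + n_dh * (1 - w)) / (2 * N),
               aB = (caB + n_dh * (1 - w)) / (2 * N),
               ab = (cab + n_dh * w) / (2 * N))
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol || it >= max_iter) break
  }
  # clamp to the Frechet bounds against floating-point drift
  p_AB <- min(max(unname(f["AB"]), max(0, p_A + p_B - 1)), min(p_A, p_B))
  list(p_A = p_A, p_B = p_B, p_AB = p_AB,
       n_used = 2L * N, method = "em", n_iter = it)
}

#' Pairwise LD coefficients from a haplotype-frequency triple
#'
#' @param p_A,p_B Allele frequencies in `(0, 1)`; may also be passed as a
#'   single list (the output of [estimate_haplotype_freqs()]) in `p_A`.
#' @param p_AB Haplotype frequency within its Frechet bounds.
#' @return List with `p_A`, `p_B`, `p_AB`, `D`, `d_prime`, `r2`.
#' @export
ld_pair <- function(p_A, p_B = NULL, p_AB = NULL) {
  if (is.list(p_A)) {
    f <- p_A; p_A <- f$p_A; p_B <- f$p_B; p_AB <- f$p_AB
  }
  if (any(c(p_A, p_B) <= 0) || any(c(p_A, p_B) >= 1))
    stop_monomorphic("LD undefined for allele frequency 0 or 1")
  lo <- max(0, p_A + p_B - 1); hi <- min(p_A, p_B)
  if (p_AB < lo - 1e-9 || p_AB > hi + 1e-9)
    stop_snphub("p_AB outside its Frechet bounds")
  D <- p_AB - p_A * p_B
  d_max <- if (D >= 0) min(p_A * (1 - p_B), (1 - p_A) * p_B)
           else min(p_A * p_B, (1 - p_A) * (1 - p_B))
  d_prime <- if (D == 0) 0 else abs(D) / d_max
  r2 <- D^2 / (p_A * (1 - p_A) * p_B * (1 - p_B))
  list(p_A = p_A, p_B = p_B, p_AB = p_AB, D = D,
       d_prime = min(d_prime, 1), r2 = min(r2, 1))
}

#' All within-window pairwise LD for a genotype panel
#'
#' Computes LD for every same-chromosome SNP pair whose positions are within
#' `window_kb` of each other.  Monomorphic pairs are kept in the table with
#' `status = "monomorphic"` and `NA` coefficients, so downstream collapsing
#' can verify completeness.
#'
#' @param geno Samples x SNPs dosage matrix (or 2n x SNPs 0/1 haplotype
#'   matrix when `phased = TRUE`); column names are rsids.
#' @param snps data.frame with `rsid`, `chrom`, `pos`.
#' @param window_kb Maximum pair distance (kb).
#' @param phased Logical, see [estimate_haplotype_freqs()].
#' @return data.frame: `snp_a`, `snp_b`, `p_A`, `p_B`, `p_AB`, `D`,
#'   `d_prime`, `r2`, `status`.
#' @export
ld_table <- function(geno, snps, window_kb = 500, phased = FALSE) {
  stopifnot(all(snps$rsid %in% colnames(geno)))
  snps <- snps[order(snps$chrom, snps$pos), ]
  rows <- list()
  win <- window_kb * 1000
  for (ch in unique(snps$chrom)) {
    s <- snps[snps$chrom == ch, ]
    if (nrow(s) < 2L) next
    for (i in seq_len(nrow(s) - 1L)) {
      for (j in seq((i + 1L), nrow(s))) {
        if (s$pos[j] - s$pos[i] > win) break
        res <- tryCatch({
          fr <- estimate_haplotype_freqs(geno[, s$rsid[i]], geno[, s$rsid[j]],
                                         phased = phased)
          c(ld_pair(fr), status = "ok")
        }, snphub_monomorphic = function(e) {
          list(p_A = NA_real_, p_B = NA_real_, p_AB = NA_real_, D = NA_real_,
               d_prime = NA_real_, r2 = NA_real_, status = "monomorphic")
        })
        rows[[length(rows) + 1L]] <- data.frame(
          snp_a = s$rsid[i], snp_b = s$rsid[j],
          p_A = res$p_A, p_B = res$p_B, p_AB = res$p_AB, D = res$D,
          d_prime = res$d_prime, r2 = res$r2, status = res$status,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows))
    return(data.frame(snp_a = character(), snp_b = character(),
                      p_A = numeric(), p_B = numeric(), p_AB = numeric(),
                      D = numeric(), d_prime = numeric(), r2 = numeric(),
                      status = character(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Collapse SNPs into haplotype-block loci
#'
#' Builds a graph over SNPs with an edge whenever `r2 >= r2_min` OR
#' `d_prime >= dprime_min` (same chromosome, within `window_kb`), then takes
#' connected components as loci.  Every same-chromosome pair within the
#' window must be present in `ld` (any order); a missing entry is an error,
#' never a silent non-edge.  Cross-chromosome merging cannot occur.
#'
#' @param snps data.frame with `rsid`, `chrom`, `pos` and optionally
#'   `gwas_flag` (defaults to `TRUE`: input SNPs come from GWAS lists).
#' @param ld LD pair table as from [ld_table()].
#' @param r2_min,dprime_min Block thresholds (defaults 0.8 and 0.8).
#' @param window_kb Window within which LD must be available.
#' @param genes Optional gene annotation (`chrom`, `start`, `end`, `name`)
#'   used to name loci via [name_locus()].
#' @return Locus table: data.frame `locus_id`, `chrom`, `start`, `end`,
#'   `members` (comma-separated rsids in genomic order), `gene_labels`,
#'   `gwas_flag`, ordered by chromosome and start.
#' @export
collapse_blocks <- function(snps, ld, r2_min = 0.8, dprime_min = 0.8,
                            window_kb = 500, genes = NULL) {
  stopifnot(is.data.frame(snps), all(c("rsid", "chrom", "pos") %in% names(snps)))
  if (r2_min < 0 || r2_min > 1 || dprime_min < 0 || dprime_min > 1)
    stop_snphub("LD thresholds must lie in [0, 1]")
  snps$chrom <- norm_chrom(snps$chrom)
  if (is.null(snps$gwas_flag)) snps$gwas_flag <- TRUE

  have <- pair_key(ld$snp_a, ld$snp_b)
  win <- window_kb * 1000
  missing <- character()
  for (ch in unique(snps$chrom)) {
    s <- snps[snps$chrom == ch, ]
    if (nrow(s) < 2L) next
    for (i in seq_len(nrow(s) - 1L)) for (j in seq(i + 1L, nrow(s))) {
      if (abs(s$pos[j] - s$pos[i]) > win) next
      if (!pair_key(s$rsid[i], s$rsid[j]) %in% have)
        missing <- c(missing, paste(s$rsid[i], s$rsid[j], sep = "-"))
    }
  }
  if (length(missing))
    stop_snphub(sprintf("missing LD entries within window: %s",
                        paste(missing, collapse = ", ")))

  chrom_of <- setNames(snps$chrom, snps$rsid)
  ok <- !is.na(ld$r2) & (ld$r2 >= r2_min | ld$d_prime >= dprime_min) &
    ld$snp_a %in% snps$rsid & ld$snp_b %in% snps$rsid &
    chrom_of[ld$snp_a] == chrom_of[ld$snp_b]
  g <- igraph::graph_from_data_frame(ld[ok, c("snp_a", "snp_b"), drop = FALSE],
                                     directed = FALSE,
                                     vertices = data.frame(name = snps$rsid))
  comp <- igraph::components(g)
  rows <- lapply(seq_len(comp$no), function(k) {
    mem <- names(comp$membership)[comp$membership == k]
    sub <- snps[match(mem, snps$rsid), ]
    sub <- sub[order(sub$pos), ]
    data.frame(chrom = sub$chrom[1], start = min(sub$pos), end = max(sub$pos),
               members = paste(sub$rsid, collapse = ","),
               gwas_flag = any(sub$gwas_flag), stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, rows)
  named <- vapply(seq_len(nrow(loci)), function(i)
    name_locus(loci$chrom[i], loci$start[i], loci$end[i], genes), character(1))
  labels <- vapply(seq_len(nrow(loci)), function(i) {
    g <- overlapping_genes(loci$chrom[i], loci$start[i], loci$end[i], genes)
    paste(g, collapse = ",")
  }, character(1))
  loci$locus_id <- make.unique(named, sep = "#")
  loci$gene_labels <- labels
  loci <- loci[order(loci$chrom, loci$start), ]
  rownames(loci) <- NULL
  loci[, c("locus_id", "chrom", "start", "end", "members", "gene_labels",
           "gwas_flag")]
}

overlapping_genes <- function(chrom, start, end, genes) {
  if (is.null(genes) || !nrow(genes)) return(character())
  g <- genes[norm_chrom(genes$chrom) == norm_chrom(chrom) &
             genes$start <= end & genes$end >= start, , drop = FALSE]
  g$name[order(g$start)]
}

#' Name a locus from the genes its span overlaps
#'
#' The locus id joins the names of overlapping genes with `"/"` in genomic
#' order (e.g. `"CELSR2/PSRC1"`); when no gene overlaps, the fallback id is
#' `"chrom:start-end"`.
#'
#' @param chrom,start,end Locus span (1-based inclusive).
#' @param genes Gene annotation data.frame (`chrom`, `start`, `end`, `name`)
#'   or `NULL`.
#' @return Character locus id.
#' @export
name_locus <- function(chrom, start, end, genes = NULL) {
  g <- overlapping_genes(chrom, start, end, genes)
  if (length(g)) paste(g, collapse = "/")
  else sprintf("%s:%d-%d", norm_chrom(chrom), as.integer(start),
               as.integer(end))
}
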