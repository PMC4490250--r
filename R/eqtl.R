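# Per-population Spearman SNP-expression association and the compound
# cross-population significance verdict:
#   significant iff  (p < 0.05 in at least 3 testable populations)
#                 or (p < 0.001 in a single population).

# cache of permutation-index matrices for the exact test, keyed by n
.perm_cache <- new.env(parent = emptyenv())

all_permutations <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_cache[[key]])) return(.perm_cache[[key]])
  rec <- function(k) {
    if (k == 1L) return(matrix(1L, 1L, 1L))
    sub <- rec(k - 1L)
    p <- nrow(sub)
    out <- matrix(0L, k * p, k)
    for (i in seq_len(k)) {
      shifted <- sub + (sub >= i)
      out[(i - 1L) * p + seq_len(p), ] <- cbind(rep(i, p), shifted)
    }
    out
  }
  m <- rec(as.integer(n))
  .perm_cache[[key]] <- m
  m
}

#' Spearman rank association between dosage and expression
#'
#' Tie-corrected (average-rank) Spearman correlation with a two-sided
#' p-value: exact by full permutation enumeration for `n <= exact_n_max`
#' (default 9), t-approximation (`t = rho * sqrt((n-2)/(1-rho^2))` on `n-2`
#' df) otherwise.  Complete cases only.  A constant vector (after deletion)
#' or `n < min_n` yields an untestable signal, not a p-value.
#'
#' @param dosage,expression Equal-length numeric vectors.
#' @param exact_n_max Largest n for which the exact permutation p is used.
#' @param min_n Minimum usable sample size (smaller is untestable).
#' @return List with `rho`, `p`, `n`, `method`
#'   (`"exact"`/`"t-approx"`/`"none"`), `status` (`"ok"`/`"untestable"`).
#' @export
spearman_assoc <- function(dosage, expression, exact_n_max = 9L, min_n = 5L) {
  stopifnot(length(dosage) == length(expression))
  keep <- complete.cases(dosage, expression)
  x <- dosage[keep]; y <- expression[keep]
  n <- length(x)
  untestable <- list(rho = NA_real_, p = NA_real_, n = n, method = "none",
                     status = "untestable")
  if (n < min_n) return(untestable)
  rx <- rank(x); ry <- rank(y)
  if (max(rx) == min(rx) || max(ry) == min(ry)) return(untestable)
  rho <- cor(rx, ry)

  if (n <= exact_n_max) {
    # rho is a strictly increasing linear function of S = sum(rx * ry[perm]),
    # so the permutation tail of |rho| is the tail of |S - E S|.
    perms <- all_permutations(n)
    ry_perm <- matrix(ry[perms], nrow = nrow(perms))
    s_all <- as.vector(ry_perm %*% rx)
    centre <- n * mean(rx) * mean(ry)
    p <- mean(abs(s_all - centre) >= abs(sum(rx * ry) - centre) - 1e-9)
    return(list(rho = rho, p = p, n = n, method = "exact", status = "ok"))
  }
  if (abs(rho) >= 1) {
    # a two-sided p is never exactly 0; report the smallest positive double
    p <- .Machine$double.xmin
  } else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- max(2 * pt(-abs(tt), df = n - 2), .Machine$double.xmin)
  }
  list(rho = rho, p = p, n = n, method = "t-approx", status = "ok")
}

#' Compound cross-population significance verdict
#'
#' Declares a SNP-probe pair significant when (1) `p < alpha_rep` in at least
#' `k_rep` of the testable populations (replication rule), or (2) the minimum
#' p-value is below `alpha_single` (single-population rule).  Replication
#' takes precedence when both fire.  Untestable populations (`NA`) are
#' excluded before counting; an empty list is untestable.
#'
#' @param p_values Numeric vector of per-population p-values in `(0, 1]`;
#'   `NA` marks an untestable population.
#' @param alpha_rep Replication threshold (default 0.05).
#' @param k_rep Minimum number of replicating populations (default 3).
#' @param alpha_single Single-population threshold (default 0.001).
#' @return List with `verdict` (`"significant"`, `"not_significant"`,
#'   `"untestable"`) and `rule_fired` (`"replication"`, `"single_pop"`,
#'   `"none"`).
#' @export
compound_verdict <- function(p_values, alpha_rep = 0.05, k_rep = 3,
                             alpha_single = 0.001) {
  p <- p_values[!is.na(p_values)]
  if (!length(p))
    return(list(verdict = "untestable", rule_fired = "none"))
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop_snphub("p-values must be finite and in (0, 1]")
  if (sum(p < alpha_rep) >= k_rep)
    return(list(verdict = "significant", rule_fired = "replication"))
  if (min(p) < alpha_single)
    return(list(verdict = "significant", rule_fired = "single_pop"))
  list(verdict = "not_significant", rule_fired = "none")
}

#' Classify a SNP-probe pair as cis or trans
#'
#' Trans iff the probe lies on a different chromosome or farther than
#' `cis_window` from the SNP (distance to the nearest probe edge, 0 inside
#' the probe).  A distance exactly equal to the window is cis.  A probe
#' without a genomic location is `"unclassified"`.
#'
#' @param snp_chrom,snp_pos SNP location (1-based).
#' @param probe_chrom,probe_start,probe_end Probe location; `NA` chrom for an
#'   unlocated probe.
#' @param cis_window Cis window in bp (default 1 Mb).
#' @return `"cis"`, `"trans"` or `"unclassified"`.
#' @export
classify_cis_trans <- function(snp_chrom, snp_pos, probe_chrom,
                               probe_start, probe_end, cis_window = 1e6) {
  if (is.na(probe_chrom)) return("unclassified")
  if (norm_chrom(snp_chrom) != norm_chrom(probe_chrom)) return("trans")
  d <- if (snp_pos >= probe_start && snp_pos <= probe_end) 0
       else min(abs(snp_pos - probe_start), abs(snp_pos - probe_end))
  if (d > cis_window) "trans" else "cis"
}

#' Scan SNP-probe pairs across population panels
#'
#' Runs [spearman_assoc()] per population for every pair, applies
#' [compound_verdict()] over the testable populations, and classifies each
#' pair cis/trans from the annotations.  Sample ids are aligned between the
#' genotype and expression matrices within each population; populations where
#' the SNP is monomorphic (or too small) are untestable and excluded from the
#' verdict count.
#'
#' @param panels Named list per population: a dosage matrix (samples x SNPs)
#'   or a list with element `dosage`.
#' @param expression_sets Named list per population of expression matrices
#'   (samples x probes), population names matching `panels`.
#' @param pairs data.frame with `snp_id`, `probe_id`; `NULL` means all-vs-all.
#' @param snps Optional SNP annotation (`rsid`, `chrom`, `pos`) for
#'   cis/trans classification.
#' @param probes Optional probe annotation (`probe_id`, `chrom`, `start`,
#'   `end`).
#' @param alpha_rep,k_rep,alpha_single See [compound_verdict()].
#' @param cis_window See [classify_cis_trans()].
#' @return data.frame with one row per pair: `snp_id`, `probe_id`, per
#'   population `rho_<pop>` and `p_<pop>`, `n_testable`, `n_rep`, `min_p`,
#'   `verdict`, `rule_fired`, `cis_trans`, and a Benjamini-Hochberg-adjusted
#'   `bh_min_p` column (informational; never used in verdicts).
#' @export
eqtl_scan <- function(panels, expression_sets, pairs = NULL,
                      snps = NULL, probes = NULL,
                      alpha_rep = 0.05, k_rep = 3, alpha_single = 0.001,
                      cis_window = 1e6) {
  pops <- names(panels)
  stopifnot(!is.null(pops), setequal(pops, names(expression_sets)))
  get_dosage <- function(p) if (is.list(p) && !is.null(p$dosage)) p$dosage else p

  shared <- lapply(pops, function(pop) {
    intersect(rownames(get_dosage(panels[[pop]])),
              rownames(expression_sets[[pop]]))
  })
  names(shared) <- pops
  if (all(vapply(shared, length, integer(1)) == 0L))
    stop_snphub("no shared sample ids between genotypes and expression in any population")

  if (is.null(pairs)) {
    snp_ids <- colnames(get_dosage(panels[[1]]))
    probe_ids <- colnames(expression_sets[[1]])
    pairs <- expand.grid(snp_id = snp_ids, probe_id = probe_ids,
                         stringsAsFactors = FALSE)
  }
  if (!nrow(pairs)) {
    return(data.frame(snp_id = character(), probe_id = character(),
                      verdict = character(), rule_fired = character(),
                      cis_trans = character(), stringsAsFactors = FALSE))
  }

  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    sid <- pairs$snp_id[k]; pid <- pairs$probe_id[k]
    rho <- setNames(rep(NA_real_, length(pops)), pops)
    pv <- rho
    for (pop in pops) {
      ids <- shared[[pop]]
      if (!length(ids)) next
      d <- get_dosage(panels[[pop]])[ids, sid]
      e <- expression_sets[[pop]][ids, pid]
      res <- spearman_assoc(d, e)
      if (res$status == "ok") { rho[pop] <- res$rho; pv[pop] <- res$p }
    }
    v <- compound_verdict(pv, alpha_rep = alpha_rep, k_rep = k_rep,
                          alpha_single = alpha_single)
    ct <- "unclassified"
    if (!is.null(snps) && !is.null(probes)) {
      si <- match(sid, snps$rsid); pi <- match(pid, probes$probe_id)
      if (!is.na(si)) {
        if (is.na(pi)) {
          ct <- "unclassified"
        } else {
          ct <- classify_cis_trans(snps$chrom[si], snps$pos[si],
                                   probes$chrom[pi], probes$start[pi],
                                   probes$end[pi], cis_window = cis_window)
        }
      }
    }
    row <- data.frame(snp_id = sid, probe_id = pid, stringsAsFactors = FALSE)
    for (pop in pops) {
      row[[paste0("rho_", pop)]] <- rho[[pop]]
      row[[paste0("p_", pop)]] <- pv[[pop]]
    }
    row$n_testable <- sum(!is.na(pv))
    row$n_rep <- sum(pv < alpha_rep, na.rm = TRUE)
    row$min_p <- if (all(is.na(pv))) NA_real_ else min(pv, na.rm = TRUE)
    row$verdict <- v$verdict
    row$rule_fired <- v$rule_fired
    row$cis_trans <- ct
    rows[[k]] <- row
  }
  out <- do.call(rbind, rows)
  out$bh_min_p <- p.adjust(out$min_p, method = "BH")
  rownames(out) <- NULL
  out
}
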