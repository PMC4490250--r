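# Independent oracles used to cross-check the implementation.  These are
# deliberately written by different routes than the package code paths.

# Exhaustive-permutation two-sided Spearman p, enumerating permutations by
# recursive element removal and scoring each with stats::cor.
oracle_spearman_p <- function(x, y) {
  perm_list <- function(v) {
    if (length(v) == 1L) return(list(v))
    unlist(lapply(seq_along(v), function(i)
      lapply(perm_list(v[-i]), function(p) c(v[i], p))), recursive = FALSE)
  }
  rho_obs <- stats::cor(x, y, method = "spearman")
  perms <- perm_list(seq_along(y))
  hits <- vapply(perms, function(p)
    abs(stats::cor(x, y[p], method = "spearman")) >= abs(rho_obs) - 1e-12,
    logical(1))
  mean(hits)
}

# Brute-force connected components by boolean transitive closure.
oracle_components <- function(ids, edge_a, edge_b) {
  n <- length(ids)
  A <- diag(TRUE, n)
  for (k in seq_along(edge_a)) {
    i <- match(edge_a[k], ids); j <- match(edge_b[k], ids)
    A[i, j] <- TRUE; A[j, i] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A > 0)) break
    A <- A2
  }
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    comp[which(A[i, ] > 0)] <- cur
  }
  unname(split(ids, comp))
}

# Brute-force hub detection: enumerate all simple GWAS-GWAS paths of length
# <= max_path_len with non-GWAS interiors via igraph::all_simple_paths,
# restrict to their edges, and read off components.
oracle_hubs <- function(graph, max_path_len = 3, min_gwas = 2) {
  vn <- igraph::V(graph)$name
  gwas <- igraph::V(graph)$gwas
  gv <- vn[gwas]
  ends <- igraph::as_edgelist(graph)
  edge_between <- function(a, b)
    which((ends[, 1] == a & ends[, 2] == b) | (ends[, 1] == b & ends[, 2] == a))
  eids <- integer()
  for (u in gv) for (v in gv) {
    if (u >= v) next
    sp <- igraph::all_simple_paths(graph, from = u, to = v,
                                   cutoff = max_path_len)
    for (p in sp) {
      nodes <- p$name
      interior <- nodes[-c(1, length(nodes))]
      if (length(interior) && any(gwas[match(interior, vn)])) next
      for (i in seq_len(length(nodes) - 1L))
        eids <- c(eids, edge_between(nodes[i], nodes[i + 1L]))
    }
  }
  eids <- sort(unique(eids))
  if (!length(eids)) return(list())
  sub <- igraph::subgraph_from_edges(graph, eids, delete.vertices = TRUE)
  comp <- igraph::components(sub)
  out <- list()
  for (k in seq_len(comp$no)) {
    mem <- igraph::V(sub)$name[comp$membership == k]
    gm <- sort(mem[gwas[match(mem, vn)]])
    if (length(gm) < min_gwas) next
    out[[length(out) + 1L]] <- list(gwas_members = gm,
                                    intermediaries = sort(setdiff(mem, gm)))
  }
  ord <- order(-vapply(out, function(h) length(h$gwas_members), numeric(1)),
               vapply(out, function(h) paste(h$gwas_members, collapse = ","),
                      character(1)))
  out[ord]
}

# Analytic false-positive rate of the compound verdict under a global null
# with continuous uniform p-values in npop independent populations.
oracle_null_rate <- function(npop = 8, alpha_rep = 0.05, k_rep = 3,
                             alpha_single = 0.001) {
  # neither rule fires: no p below alpha_single and fewer than k_rep below
  # alpha_rep; per-population category probabilities are alpha_single,
  # (alpha_rep - alpha_single) and (1 - alpha_rep)
  p_mid <- alpha_rep - alpha_single
  p_hi <- 1 - alpha_rep
  neither <- sum(vapply(0:(k_rep - 1), function(k)
    choose(npop, k) * p_mid^k * p_hi^(npop - k), numeric(1)))
  1 - neither
}

# Exhaustive-likelihood grid search for the two-locus haplotype frequency
# (marginal allele frequencies fixed at their sample values).
oracle_em_grid <- function(a, b, step = 1e-5) {
  n <- length(a)
  pA <- mean(a) / 2; pB <- mean(b) / 2
  lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
  grid <- seq(lo + 1e-12, hi - 1e-12, by = step)
  ll <- vapply(grid, function(fAB) {
    fAb <- pA - fAB; faB <- pB - fAB; fab <- 1 - pA - pB + fAB
    if (min(fAb, faB, fab) < 0) return(-Inf)
    gp <- matrix(0, 3, 3)   # genotype probabilities [gA+1, gB+1]
    gp[3, 3] <- fAB^2;                 gp[3, 2] <- 2 * fAB * fAb
    gp[3, 1] <- fAb^2;                 gp[2, 3] <- 2 * fAB * faB
    gp[2, 2] <- 2 * fAB * fab + 2 * fAb * faB
    gp[2, 1] <- 2 * fAb * fab;         gp[1, 3] <- faB^2
    gp[1, 2] <- 2 * faB * fab;         gp[1, 1] <- fab^2
    s <- 0
    for (i in 0:2) for (j in 0:2) {
      cnt <- sum(a == i & b == j)
      if (cnt > 0) s <- s + cnt * log(gp[i + 1, j + 1])
    }
    s
  }, numeric(1))
  grid[which.max(ll)]
}

# Small helpers shared across tests -------------------------------------

fixture_graph <- function(stem) {
  read_graph_fixture(snphub_fixture(paste0(stem, "_edges.tsv")),
                     snphub_fixture(paste0(stem, "_loci.tsv")))
}

random_ld_instance <- function(n_snps, seed) {
  set.seed(seed)
  snps <- data.frame(rsid = sprintf("s%02d", seq_len(n_snps)),
                     chrom = "1",
                     pos = sort(sample.int(400000, n_snps)),
                     stringsAsFactors = FALSE)
  pairs <- t(combn(snps$rsid, 2))
  ld <- data.frame(snp_a = pairs[, 1], snp_b = pairs[, 2],
                   p_A = 0.5, p_B = 0.5, p_AB = 0.25,
                   D = 0, stringsAsFactors = FALSE)
  ld$r2 <- sample(c(0, 0.5, 0.85, 1), nrow(ld), replace = TRUE,
                  prob = c(.55, .2, .15, .1))
  ld$d_prime <- pmin(1, sqrt(ld$r2) + sample(c(0, 0.3), nrow(ld), TRUE))
  ld$status <- "ok"
  list(snps = snps, ld = ld)
}

random_hub_graph <- function(seed, n_max = 15) {
  set.seed(seed)
  n <- sample(4:n_max, 1)
  ids <- sprintf("L%02d", seq_len(n))
  am <- matrix(runif(n * n) < 0.2, n, n)
  am[lower.tri(am, diag = TRUE)] <- FALSE
  idx <- which(am, arr.ind = TRUE)
  edges <- data.frame(locus_u = ids[idx[, 1]], locus_v = ids[idx[, 2]],
                      layer = sample(c("spatial", "eqtl", "functional"),
                                     nrow(idx), replace = TRUE),
                      evidence = rep("sim", nrow(idx)),
                      stringsAsFactors = FALSE)
  loci <- data.frame(locus_id = ids, gwas_flag = runif(n) < 0.4,
                     stringsAsFactors = FALSE)
  build_graph(edges, loci)
}
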