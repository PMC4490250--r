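# Multilayer locus graph: spatial edges from chromatin-contact anchors,
# eqtl edges from significant trans verdicts, functional edges from a
# curated table.  Nodes are loci; GWAS status is a node attribute; parallel
# edges across layers are preserved as distinct edges.

empty_edges <- function() {
  data.frame(locus_u = character(), locus_v = character(),
             layer = character(), evidence = character(),
             stringsAsFactors = FALSE)
}

# canonicalize endpoint order and merge duplicate edges within one layer
merge_edges <- function(rows) {
  if (!nrow(rows)) return(empty_edges())
  u <- pmin(rows$locus_u, rows$locus_v)
  v <- pmax(rows$locus_u, rows$locus_v)
  key <- paste(u, v, rows$layer, sep = "\r")
  ev <- vapply(split(rows$evidence, key), function(e)
    paste(unique(unlist(strsplit(e, ";", fixed = TRUE))), collapse = ";"),
    character(1))
  parts <- do.call(rbind, strsplit(names(ev), "\r", fixed = TRUE))
  out <- data.frame(locus_u = parts[, 1], locus_v = parts[, 2],
                    layer = parts[, 3], evidence = unname(ev),
                    stringsAsFactors = FALSE)
  out <- out[order(out$locus_u, out$locus_v, out$layer), ]
  rownames(out) <- NULL
  out
}

#' Map contact anchor pairs onto locus-locus spatial edges
#'
#' Emits a spatial edge between loci X and Y whenever one anchor of a
#' contact overlaps X (extended by `flank`) and the other overlaps Y, with
#' X != Y.  Duplicate contacts merge into one edge with accumulated
#' evidence; contacts whose anchors fall in the same locus (self-loops) or
#' outside all loci produce nothing.
#'
#' @param contacts data.frame with `chrom_a`, `start_a`, `end_a`, `chrom_b`,
#'   `start_b`, `end_b` (1-based inclusive, as returned by [read_bedpe()])
#'   and optionally `contact_id` and `support`.
#' @param loci Locus table (`locus_id`, `chrom`, `start`, `end`).
#' @param flank Anchor/locus flank in bp (default 10 kb; 0 for strict
#'   overlap).
#' @param min_support Minimum `support` to keep a contact (default 1 keeps
#'   all; contacts without a support column always pass).
#' @param auto_normalize Normalize "chr"-prefixed and bare chromosome names
#'   to a common convention.  When `FALSE`, mixed conventions between the
#'   two inputs raise an error.
#' @return Edge table (`locus_u`, `locus_v`, `layer = "spatial"`,
#'   `evidence`).
#' @export
map_contacts_to_loci <- function(contacts, loci, flank = 10000,
                                 min_support = 1, auto_normalize = TRUE) {
  if (!nrow(contacts)) return(empty_edges())
  if (!auto_normalize &&
      !chrom_conventions_match(c(contacts$chrom_a, contacts$chrom_b),
                               loci$chrom))
    stop_snphub(paste("chromosome naming conventions differ between contacts",
                      "and loci (chr1 vs 1); enable auto_normalize"))
  contacts$chrom_a <- norm_chrom(contacts$chrom_a)
  contacts$chrom_b <- norm_chrom(contacts$chrom_b)
  loci$chrom <- norm_chrom(loci$chrom)
  if (!is.null(contacts$support))
    contacts <- contacts[is.na(contacts$support) |
                         contacts$support >= min_support, , drop = FALSE]
  if (!nrow(contacts)) return(empty_edges())
  if (is.null(contacts$contact_id))
    contacts$contact_id <- sprintf("contact%d", seq_len(nrow(contacts)))

  loci_gr <- GenomicRanges::GRanges(
    loci$chrom, IRanges::IRanges(pmax(1L, loci$start - flank),
                                 loci$end + flank))
  hits <- function(chrom, start, end) {
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end))
    ov <- GenomicRanges::findOverlaps(gr, loci_gr)
    split(loci$locus_id[S4Vectors::subjectHits(ov)],
          factor(S4Vectors::queryHits(ov), levels = seq_along(gr)))
  }
  ha <- hits(contacts$chrom_a, contacts$start_a, contacts$end_a)
  hb <- hits(contacts$chrom_b, contacts$start_b, contacts$end_b)
  rows <- list()
  for (i in seq_len(nrow(contacts))) {
    xs <- ha[[i]]; ys <- hb[[i]]
    if (!length(xs) || !length(ys)) next
    pairs <- expand.grid(u = xs, v = ys, stringsAsFactors = FALSE)
    pairs <- pairs[pairs$u != pairs$v, , drop = FALSE]
    if (!nrow(pairs)) next
    rows[[length(rows) + 1L]] <- data.frame(
      locus_u = pairs$u, locus_v = pairs$v, layer = "spatial",
      evidence = contacts$contact_id[i], stringsAsFactors = FALSE)
  }
  merge_edges(if (length(rows)) do.call(rbind, rows) else empty_edges())
}

#' Build eQTL edges from significant scan results
#'
#' One edge between the SNP's locus and the probe's locus for every
#' `verdict == "significant"` result whose loci differ; same-locus results
#' stay in the result table but yield no edge, and probes that map to no
#' locus are skipped (with a message).
#'
#' @param results Scan results from [eqtl_scan()].
#' @param snp_locus Named character vector: snp_id -> locus_id.
#' @param probe_locus Named character vector: probe_id -> locus_id
#'   (`NA`/absent for unmapped probes).
#' @return Edge table (`layer = "eqtl"`, evidence `"snp->probe"`).
#' @export
eqtl_edges <- function(results, snp_locus, probe_locus) {
  sig <- results[results$verdict == "significant", , drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(sig))) {
    u <- snp_locus[[sig$snp_id[i]]] %||% NA_character_
    v <- if (sig$probe_id[i] %in% names(probe_locus))
      probe_locus[[sig$probe_id[i]]] else NA_character_
    if (is.na(v)) {
      message(sprintf("eqtl_edges: probe %s maps to no locus; result skipped",
                      sig$probe_id[i]))
      next
    }
    if (is.na(u) || u == v) next
    rows[[length(rows) + 1L]] <- data.frame(
      locus_u = u, locus_v = v, layer = "eqtl",
      evidence = paste0(sig$snp_id[i], "->", sig$probe_id[i]),
      stringsAsFactors = FALSE)
  }
  merge_edges(if (length(rows)) do.call(rbind, rows) else empty_edges())
}

#' Functional edges from a curated table
#'
#' Curated protein/phenotype links (e.g. a documented protein-protein
#' interaction between the products of two loci) are read as given, never
#' inferred.
#'
#' @param tab data.frame with `locus_u`, `locus_v` and optional `type`,
#'   `citation`.
#' @return Edge table (`layer = "functional"`).
#' @export
functional_edges <- function(tab) {
  if (is.null(tab) || !nrow(tab)) return(empty_edges())
  ev <- if (!is.null(tab$citation)) tab$citation
        else if (!is.null(tab$type)) tab$type
        else rep("curated", nrow(tab))
  merge_edges(data.frame(locus_u = tab$locus_u, locus_v = tab$locus_v,
                         layer = "functional", evidence = ev,
                         stringsAsFactors = FALSE))
}

#' Assemble the multilayer locus graph
#'
#' Nodes are all loci touched by at least one edge plus every GWAS-flagged
#' locus (so isolated GWAS loci remain visible).  Parallel edges across
#' layers are preserved as distinct edges; `gwas_flag` is carried onto nodes
#' as the vertex attribute `gwas`.
#'
#' @param edges Edge table (`locus_u`, `locus_v`, `layer`, `evidence`), e.g.
#'   rbind of [map_contacts_to_loci()], [eqtl_edges()],
#'   [functional_edges()] output.
#' @param loci Locus table with `locus_id` and `gwas_flag`.
#' @return An undirected [igraph::igraph] multigraph with vertex attributes
#'   `name`, `gwas` and edge attributes `layer`, `evidence`.
#' @export
build_graph <- function(edges, loci) {
  if (is.null(edges)) edges <- empty_edges()
  unknown <- setdiff(unique(c(edges$locus_u, edges$locus_v)), loci$locus_id)
  if (length(unknown))
    stop_snphub(sprintf("edges reference loci absent from the locus table: %s",
                        paste(sort(unknown), collapse = ", ")))
  if (any(edges$locus_u == edges$locus_v))
    stop_snphub("self-loop edges are not allowed")
  if (nrow(edges) && any(!nzchar(edges$evidence) | is.na(edges$evidence)))
    stop_snphub("every edge must carry non-empty evidence")
  touched <- unique(c(edges$locus_u, edges$locus_v))
  keep <- union(touched, loci$locus_id[as.logical(loci$gwas_flag)])
  vdf <- data.frame(name = sort(keep), stringsAsFactors = FALSE)
  vdf$gwas <- as.logical(loci$gwas_flag[match(vdf$name, loci$locus_id)])
  edf <- edges[order(edges$locus_u, edges$locus_v, edges$layer), , drop = FALSE]
  igraph::graph_from_data_frame(edf, directed = FALSE, vertices = vdf)
}

#' Flat edge table of a locus graph
#'
#' @param graph Graph from [build_graph()].
#' @return data.frame `locus_u`, `locus_v`, `layer`, `evidence`, sorted.
#' @export
graph_edge_table <- function(graph) {
  if (igraph::ecount(graph) == 0) return(empty_edges())
  ends <- igraph::as_edgelist(graph)
  out <- data.frame(locus_u = pmin(ends[, 1], ends[, 2]),
                    locus_v = pmax(ends[, 1], ends[, 2]),
                    layer = igraph::E(graph)$layer,
                    evidence = igraph::E(graph)$evidence,
                    stringsAsFactors = FALSE)
  out <- out[order(out$locus_u, out$locus_v, out$layer), ]
  rownames(out) <- NULL
  out
}
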