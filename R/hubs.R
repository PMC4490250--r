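# Hub discovery: sets of >= 2 GWAS loci connected directly or through
# intermediary (non-GWAS) loci.  A bridging path is a simple path between
# two distinct GWAS loci whose interior nodes are all non-GWAS, of length
# (in edges) at most max_path_len.  Hubs are the connected components of the
# subgraph restricted to edges lying on some bridging path.

# Enumerate bridging node-paths.  Each path is recorded once, oriented from
# the lexicographically smaller endpoint.
bridging_node_paths <- function(graph, max_path_len) {
  vnames <- igraph::V(graph)$name
  gwas <- igraph::V(graph)$gwas
  gwas[is.na(gwas)] <- FALSE
  nbr <- lapply(seq_along(vnames), function(v)
    unique(as.integer(igraph::neighbors(graph, v))))
  paths <- list()
  walk <- function(path) {
    last <- path[length(path)]
    for (nb in nbr[[last]]) {
      if (nb %in% path) next
      if (gwas[nb]) {
        if (vnames[path[1]] < vnames[nb])
          paths[[length(paths) + 1L]] <<- c(path, nb)
      } else if (length(path) < max_path_len) {
        walk(c(path, nb))
      }
    }
  }
  for (s in which(gwas)) walk(s)
  lapply(paths, function(p) vnames[p])
}

# Parallel-edge lookup: map unordered node-pair key -> edge indices.
edge_index <- function(graph) {
  if (igraph::ecount(graph) == 0) return(list())
  ends <- igraph::as_edgelist(graph)
  split(seq_len(nrow(ends)), pair_key(ends[, 1], ends[, 2]))
}

# Expand a node path over parallel edges -> list of edge-id vectors.
expand_path_edges <- function(nodes, eidx) {
  steps <- lapply(seq_len(length(nodes) - 1L), function(i)
    eidx[[pair_key(nodes[i], nodes[i + 1L])]])
  grid <- expand.grid(steps, KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(r) as.integer(unlist(grid[r, ])))
}

#' Detect hubs of GWAS loci
#'
#' Restricts the graph to edges lying on some bridging path (simple
#' GWAS-to-GWAS path of length <= `max_path_len` whose interior nodes are
#' non-GWAS), takes connected components of that restriction, and reports
#' every component containing at least `min_gwas` GWAS loci together with
#' all its bridging paths and their edge-layer sequences.  Hubs are ordered
#' by descending GWAS count, then lexicographically by member ids.
#'
#' @param graph Multilayer locus graph from [build_graph()].
#' @param max_path_len Maximum bridging-path length in edges (default 3).
#' @param min_gwas Minimum GWAS loci per hub (default 2).
#' @param layers Optional character vector restricting traversable edge
#'   layers (default: all layers).
#' @return List of hub reports (class `hub_report_list`); each report is a
#'   list with `hub_id`, `gwas_members`, `intermediaries`, `paths` (each a
#'   list with `nodes` and `layers`) and `n_layers_used`.
#' @export
find_hubs <- function(graph, max_path_len = 3, min_gwas = 2, layers = NULL) {
  if (max_path_len < 1) stop_snphub("max_path_len must be >= 1")
  if (!is.null(layers))
    graph <- igraph::subgraph_from_edges(
      graph, igraph::E(graph)[igraph::E(graph)$layer %in% layers],
      delete.vertices = FALSE)
  node_paths <- bridging_node_paths(graph, max_path_len)
  eidx <- edge_index(graph)
  path_edges <- lapply(node_paths, expand_path_edges, eidx = eidx)
  used <- sort(unique(unlist(path_edges)))
  if (!length(used))
    return(structure(list(), class = "hub_report_list"))

  sub <- igraph::subgraph_from_edges(graph, used, delete.vertices = TRUE)
  comp <- igraph::components(sub)
  membership <- setNames(comp$membership, igraph::V(sub)$name)
  gwas <- setNames(igraph::V(graph)$gwas, igraph::V(graph)$name)
  elayer <- igraph::E(graph)$layer

  hubs <- list()
  for (k in seq_len(comp$no)) {
    members <- names(membership)[membership == k]
    gm <- sort(members[gwas[members]])
    if (length(gm) < min_gwas) next
    inter <- sort(members[!gwas[members]])
    sel <- vapply(node_paths, function(p) p[1] %in% members, logical(1))
    paths <- list()
    for (i in which(sel)) {
      for (eids in path_edges[[i]]) {
        paths[[length(paths) + 1L]] <- list(nodes = node_paths[[i]],
                                            layers = elayer[eids])
      }
    }
    ord <- order(vapply(paths, function(p)
      paste(c(p$nodes, p$layers), collapse = "|"), character(1)))
    paths <- paths[ord]
    hubs[[length(hubs) + 1L]] <- list(
      gwas_members = gm, intermediaries = inter, paths = paths,
      n_layers_used = length(unique(unlist(lapply(paths, `[[`, "layers")))))
  }
  ord <- order(-vapply(hubs, function(h) length(h$gwas_members), numeric(1)),
               vapply(hubs, function(h) paste(h$gwas_members, collapse = ","),
                      character(1)))
  hubs <- hubs[ord]
  for (i in seq_along(hubs)) {
    hubs[[i]]$hub_id <- sprintf("hub_%02d", i)
    class(hubs[[i]]) <- "hub_report"
  }
  structure(hubs, class = "hub_report_list")
}

#' @export
print.hub_report <- function(x, ...) {
  cat(sprintf("%s: %d GWAS loci [%s]\n", x$hub_id, length(x$gwas_members),
              paste(x$gwas_members, collapse = ", ")))
  if (length(x$intermediaries))
    cat(sprintf("  intermediaries: %s\n",
                paste(x$intermediaries, collapse = ", ")))
  for (p in x$paths)
    cat(sprintf("  path: %s  (%s)\n", paste(p$nodes, collapse = " - "),
                paste(p$layers, collapse = ",")))
  invisible(x)
}

#' @export
print.hub_report_list <- function(x, ...) {
  cat(sprintf("%d hub(s)\n", length(x)))
  for (h in x) print(h)
  invisible(x)
}

#' GWAS locus pairs sharing an intermediary
#'
#' All triples `(gwas_u, gwas_v, intermediary)` where two distinct GWAS loci
#' both have an edge (any layer) to the same non-GWAS locus.  Each symmetric
#' pair is reported once, lexicographically ordered.
#'
#' @param graph Graph from [build_graph()].
#' @return data.frame `gwas_u`, `gwas_v`, `intermediary`.
#' @export
shared_intermediary_pairs <- function(graph) {
  gwas <- setNames(igraph::V(graph)$gwas, igraph::V(graph)$name)
  out <- list()
  for (w in igraph::V(graph)$name[!gwas]) {
    nb <- unique(igraph::neighbors(graph, w)$name)
    gn <- sort(nb[gwas[nb]])
    if (length(gn) < 2L) next
    cmb <- t(combn(gn, 2L))
    out[[length(out) + 1L]] <- data.frame(gwas_u = cmb[, 1], gwas_v = cmb[, 2],
                                          intermediary = w,
                                          stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(gwas_u = character(), gwas_v = character(),
                      intermediary = character(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$gwas_u, res$gwas_v, res$intermediary), ]
  rownames(res) <- NULL
  res
}

#' Evaluate detected hubs against planted truth
#'
#' A detected hub matches a planted hub iff their GWAS member sets are
#' equal.  Precision = matched / detected (1 by convention when nothing is
#' detected); recall = matched planted / planted (1 when nothing was
#' planted).
#'
#' @param reports Hubs from [find_hubs()].
#' @param truth List of character vectors: planted GWAS member sets.
#' @return List `precision`, `recall`, `n_detected`, `n_planted`,
#'   `n_matched`.
#' @export
evaluate_hubs <- function(reports, truth) {
  det <- vapply(reports, function(h)
    paste(sort(h$gwas_members), collapse = "|"), character(1))
  pla <- vapply(truth, function(s) paste(sort(s), collapse = "|"),
                character(1))
  n_det <- length(det); n_pla <- length(pla)
  matched_det <- sum(det %in% pla)
  matched_pla <- sum(pla %in% det)
  list(precision = if (n_det == 0) 1 else matched_det / n_det,
       recall = if (n_pla == 0) 1 else matched_pla / n_pla,
       n_detected = n_det, n_planted = n_pla, n_matched = matched_det)
}
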