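# End-to-end pipeline: collapse -> eqtl -> graph -> hubs, with validated
# declarative configuration, stage-level logging and reproducible artifacts.

config_defaults <- function() {
  list(r2_min = 0.8, dprime_min = 0.8, window_kb = 500,
       alpha_rep = 0.05, k_rep = 3, alpha_single = 0.001,
       cis_window = 1e6, flank = 10000, min_support = 1,
       max_path_len = 3, min_gwas = 2,
       layers = c("spatial", "eqtl", "functional"),
       panel_format = "dosage", seed = 1L)
}

path_keys <- function() {
  c("gwas_snps", "panels", "expression", "probes", "genes", "contacts",
    "functional", "truth", "out_dir")
}

#' Build and validate a pipeline configuration
#'
#' A single declarative object: input paths plus every stage parameter.
#' Unknown keys are rejected; every threshold is checked against its
#' documented domain before any computation runs.
#'
#' @param gwas_snps Path to the GWAS SNP list TSV.
#' @param panels Named list (population -> path) of dosage TSVs or VCFs.
#' @param expression Named list (population -> path) of expression TSVs.
#' @param probes Path to the probe annotation TSV.
#' @param genes Path to the gene annotation (BED or GFF3).
#' @param contacts Path to the contact BEDPE.
#' @param functional Optional path to the curated functional edge TSV.
#' @param truth Optional path to a planted-truth JSON (enables evaluation).
#' @param out_dir Output directory for artifacts.
#' @param ... Stage parameters overriding the defaults: `r2_min`,
#'   `dprime_min`, `window_kb`, `alpha_rep`, `k_rep`, `alpha_single`,
#'   `cis_window`, `flank`, `min_support`, `max_path_len`, `min_gwas`,
#'   `layers`, `panel_format` (`"dosage"` or `"vcf"`), `seed`.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(gwas_snps, panels, expression, probes, genes,
                            contacts, functional = NULL, truth = NULL,
                            out_dir = tempfile("snphub_run"), ...) {
  extra <- list(...)
  defaults <- config_defaults()
  unknown <- setdiff(names(extra), names(defaults))
  if (length(unknown))
    stop_snphub(sprintf("unknown configuration keys: %s",
                        paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(defaults, extra)
  cfg$gwas_snps <- gwas_snps
  cfg$panels <- panels
  cfg$expression <- expression
  cfg$probes <- probes
  cfg$genes <- genes
  cfg$contacts <- contacts
  cfg$functional <- functional
  cfg$truth <- truth
  cfg$out_dir <- out_dir
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  in01 <- function(x) is.numeric(x) && length(x) == 1 && x >= 0 && x <= 1
  if (!in01(cfg$r2_min)) stop_snphub("r2_min must lie in [0, 1]")
  if (!in01(cfg$dprime_min)) stop_snphub("dprime_min must lie in [0, 1]")
  for (k in c("alpha_rep", "alpha_single"))
    if (!(is.numeric(cfg[[k]]) && cfg[[k]] > 0 && cfg[[k]] < 1))
      stop_snphub(sprintf("%s must lie in (0, 1)", k))
  for (k in c("window_kb", "cis_window", "flank"))
    if (!(is.numeric(cfg[[k]]) && cfg[[k]] >= 0))
      stop_snphub(sprintf("%s must be >= 0", k))
  if (cfg$k_rep < 1) stop_snphub("k_rep must be >= 1")
  if (cfg$max_path_len < 1) stop_snphub("max_path_len must be >= 1")
  if (cfg$min_gwas < 1) stop_snphub("min_gwas must be >= 1")
  if (!cfg$panel_format %in% c("dosage", "vcf"))
    stop_snphub("panel_format must be 'dosage' or 'vcf'")
  if (!all(cfg$layers %in% c("spatial", "eqtl", "functional")))
    stop_snphub("layers must be among spatial, eqtl, functional")
  if (!setequal(names(cfg$panels), names(cfg$expression)))
    stop_snphub("panel and expression population names must match")
  invisible(cfg)
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the [pipeline_config()]
#'   arguments.
#' @param ... Overrides applied on top of the file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  y <- yaml::read_yaml(path)
  over <- list(...)
  y[names(over)] <- over
  do.call(pipeline_config, y)
}

#' Read and validate every pipeline input
#'
#' Applies the coordinate conventions (BED/BEDPE to 1-based inclusive),
#' normalizes chromosome names and checks sample-id alignment.
#'
#' @param config A [pipeline_config()].
#' @return List of in-memory datasets (`snps`, `panels`, `expression`,
#'   `probes`, `genes`, `contacts`, `functional`, `truth`) plus `log`
#'   (per-file record counts).
#' @export
read_inputs <- function(config) {
  log <- character()
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  snps <- read_gwas_snps(config$gwas_snps)
  note("gwas_snps: %d SNPs", nrow(snps))
  panels <- lapply(config$panels, function(p) {
    if (config$panel_format == "vcf") read_vcf_panel(p)
    else list(dosage = read_dosage(p), haplotypes = NULL)
  })
  expression <- lapply(config$expression, read_expression)
  for (pop in names(panels)) {
    shared <- intersect(rownames(panels[[pop]]$dosage),
                        rownames(expression[[pop]]))
    note("population %s: %d samples genotyped, %d expressed, %d shared",
         pop, nrow(panels[[pop]]$dosage), nrow(expression[[pop]]),
         length(shared))
  }
  probes <- read_probe_annotation(config$probes)
  note("probes: %d annotated", nrow(probes))
  genes <- read_genes(config$genes)
  note("genes: %d intervals", nrow(genes))
  contacts <- read_bedpe(config$contacts)
  note("contacts: %d anchor pairs", nrow(contacts))
  functional <- if (!is.null(config$functional))
    read_functional_edges(config$functional) else NULL
  note("functional: %d curated links",
       if (is.null(functional)) 0L else nrow(functional))
  truth <- if (!is.null(config$truth))
    jsonlite::read_json(config$truth, simplifyVector = TRUE) else NULL
  list(snps = snps, panels = panels, expression = expression,
       probes = probes, genes = genes, contacts = contacts,
       functional = functional, truth = truth, log = log)
}

# map each SNP / probe to its locus (probe: first overlapping locus)
snp_locus_map <- function(loci) {
  mem <- strsplit(loci$members, ",", fixed = TRUE)
  map <- character()
  for (i in seq_along(mem))
    if (length(mem[[i]]) && nzchar(mem[[i]][1]))
      map[mem[[i]]] <- loci$locus_id[i]
  map
}

probe_locus_map <- function(probes, loci, genes = NULL) {
  map <- setNames(rep(NA_character_, nrow(probes)), probes$probe_id)
  gene_of_locus <- if (!is.null(loci$gene_labels))
    strsplit(loci$gene_labels, ",", fixed = TRUE) else NULL
  for (i in seq_len(nrow(probes))) {
    hit <- which(loci$chrom == probes$chrom[i] &
                 loci$start <= probes$end[i] & loci$end >= probes$start[i])
    if (length(hit)) { map[i] <- loci$locus_id[hit[1]]; next }
    # fall back on gene identity: a probe inside a gene named on a locus
    # belongs to that locus even when the SNP-block span is tighter
    if (is.null(genes) || is.null(gene_of_locus)) next
    gh <- which(norm_chrom(genes$chrom) == probes$chrom[i] &
                genes$start <= probes$end[i] & genes$end >= probes$start[i])
    for (g in genes$name[gh]) {
      li <- which(vapply(gene_of_locus, function(gl) g %in% gl, logical(1)))
      if (length(li)) { map[i] <- loci$locus_id[li[1]]; break }
    }
  }
  map
}

#' Run the full pipeline
#'
#' Stages execute in order: collapse (LD over the pooled panel, blocks at
#' the configured thresholds, gene-based naming) -> eQTL scan (every GWAS
#' SNP against every probe, compound verdict) -> multilayer graph (spatial +
#' eqtl + functional) -> hub discovery, then artifact writing.  Any stage
#' failure aborts with the stage name; previously written artifacts are
#' preserved.  Re-running with an identical configuration reproduces
#' identical artifacts.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `loci`, `ld`, `eqtl`, `edges`, `graph`,
#'   `hubs`, `evaluation` (when truth was supplied) and `out_dir`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_config(config)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log <- character()
  note <- function(fmt, ...) log <<- c(log, sprintf(fmt, ...))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_snphub(sprintf("pipeline stage '%s' failed: %s", name,
                          conditionMessage(e))))
  }

  # parameters actually used (no silent defaults)
  for (k in sort(names(config_defaults())))
    note("param %s = %s", k, paste(config[[k]], collapse = ","))

  inputs <- stage("read", read_inputs(config))
  log <- c(log, inputs$log)

  loci <- stage("collapse", {
    pooled <- do.call(rbind, lapply(inputs$panels, `[[`, "dosage"))
    ld <- ld_table(pooled, inputs$snps, window_kb = config$window_kb)
    blocks <- collapse_blocks(inputs$snps, ld, r2_min = config$r2_min,
                              dprime_min = config$dprime_min,
                              window_kb = config$window_kb,
                              genes = inputs$genes)
    note("collapse: %d SNPs -> %d loci (%d LD pairs computed)",
         nrow(inputs$snps), nrow(blocks), nrow(ld))
    # annotation genes untouched by any SNP block become candidate
    # (non-GWAS) loci: the intermediaries of the locus graph
    extra <- inputs$genes[!vapply(seq_len(nrow(inputs$genes)), function(i)
      any(blocks$chrom == inputs$genes$chrom[i] &
          blocks$start <= inputs$genes$end[i] &
          blocks$end >= inputs$genes$start[i]), logical(1)), , drop = FALSE]
    all_loci <- rbind(blocks,
                      if (nrow(extra)) data.frame(
                        locus_id = make.unique(c(blocks$locus_id, extra$name),
                                               sep = "#")[-seq_len(nrow(blocks))],
                        chrom = extra$chrom, start = extra$start,
                        end = extra$end, members = "",
                        gene_labels = extra$name, gwas_flag = FALSE,
                        stringsAsFactors = FALSE))
    note("collapse: %d gene-only candidate loci added", nrow(extra))
    attr(all_loci, "ld") <- ld
    all_loci
  })

  eqtl <- stage("eqtl", {
    pairs <- expand.grid(snp_id = inputs$snps$rsid,
                         probe_id = inputs$probes$probe_id,
                         stringsAsFactors = FALSE)
    res <- eqtl_scan(inputs$panels, inputs$expression, pairs,
                     snps = inputs$snps, probes = inputs$probes,
                     alpha_rep = config$alpha_rep, k_rep = config$k_rep,
                     alpha_single = config$alpha_single,
                     cis_window = config$cis_window)
    note("eqtl: %d pairs tested, %d significant (%d trans)",
         nrow(res), sum(res$verdict == "significant"),
         sum(res$verdict == "significant" & res$cis_trans == "trans"))
    res
  })

  graph <- stage("graph", {
    spatial <- map_contacts_to_loci(inputs$contacts, loci,
                                    flank = config$flank,
                                    min_support = config$min_support)
    eq <- eqtl_edges(eqtl, snp_locus_map(loci),
                     probe_locus_map(inputs$probes, loci, inputs$genes))
    fun <- functional_edges(inputs$functional)
    edges <- rbind(spatial, eq, fun)
    note("graph: %d spatial, %d eqtl, %d functional edges",
         nrow(spatial), nrow(eq), nrow(fun))
    build_graph(edges, loci)
  })

  hubs <- stage("hubs", {
    h <- find_hubs(graph, max_path_len = config$max_path_len,
                   min_gwas = config$min_gwas, layers = config$layers)
    note("hubs: %d detected", length(h))
    h
  })

  evaluation <- NULL
  if (!is.null(inputs$truth)) {
    truth_sets <- lapply(inputs$truth$planted_hub_members, as.character)
    evaluation <- evaluate_hubs(hubs, truth_sets)
    note("evaluation: precision %.3f recall %.3f",
         evaluation$precision, evaluation$recall)
  }

  out <- config$out_dir
  stage("write", {
    write_locus_table(loci, file.path(out, "loci.tsv"))
    write_tsv(attr(loci, "ld"), file.path(out, "ld_pairs.tsv"))
    write_tsv(eqtl, file.path(out, "eqtl_results.tsv"))
    write_graph_artifacts(graph, file.path(out, "graph.graphml"),
                          file.path(out, "edges.tsv"))
    write_hub_reports(hubs, file.path(out, "hubs.json"),
                      file.path(out, "hubs.tsv"))
    if (!is.null(evaluation))
      jsonlite::write_json(evaluation, file.path(out, "evaluation.json"),
                           auto_unbox = TRUE, digits = NA)
    cfg_plain <- unclass(config)
    yaml::write_yaml(cfg_plain, file.path(out, "run_config.yaml"))
    stamp <- unname(tools::md5sum(file.path(out, "run_config.yaml")))
    note("config md5 %s seed %d", stamp, config$seed)
    writeLines(log, file.path(out, "run_log.txt"))
    write_report(out)
  })

  invisible(list(loci = loci, ld = attr(loci, "ld"), eqtl = eqtl,
                 graph = graph, hubs = hubs, evaluation = evaluation,
                 out_dir = out))
}

#' Write a human-readable run summary
#'
#' Every number is recounted from the artifact files themselves, so the
#' report always agrees with what was written.
#'
#' @param out_dir Directory containing pipeline artifacts.
#' @return Invisibly, the report lines.
#' @export
write_report <- function(out_dir) {
  loci <- read_locus_table(file.path(out_dir, "loci.tsv"))
  edges <- read_tsv(file.path(out_dir, "edges.tsv"))
  eqtl <- read_tsv(file.path(out_dir, "eqtl_results.tsv"))
  hubs <- jsonlite::read_json(file.path(out_dir, "hubs.json"))
  n_snps <- sum(lengths(strsplit(loci$members[nzchar(loci$members) &
                                              !is.na(loci$members)], ",")))
  lines <- c(
    "snphub run summary",
    sprintf("SNPs: %d", n_snps),
    sprintf("loci: %d (%d GWAS-flagged)", nrow(loci), sum(loci$gwas_flag)),
    sprintf("eQTL pairs tested: %d; significant: %d", nrow(eqtl),
            sum(eqtl$verdict == "significant")))
  for (lay in c("spatial", "eqtl", "functional"))
    lines <- c(lines, sprintf("edges [%s]: %d", lay,
                              sum(edges$layer == lay)))
  lines <- c(lines, sprintf("hubs: %d", length(hubs)))
  for (h in hubs) {
    lines <- c(lines, sprintf("  %s: %d GWAS loci (%s); %d bridging path(s)",
                              h$hub_id, length(h$gwas_members),
                              paste(unlist(h$gwas_members), collapse = ", "),
                              length(h$paths)))
    for (p in h$paths)
      lines <- c(lines, sprintf("    %s (%s)",
                                paste(unlist(p$nodes), collapse = " - "),
                                paste(unlist(p$layers), collapse = ",")))
  }
  writeLines(lines, file.path(out_dir, "report.txt"))
  invisible(lines)
}
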