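# Format readers and writers.  Internal coordinates are 1-based inclusive;
# BED and BEDPE are converted at the boundary (0-based half-open on disk).
# TSV round trips are lossless for every artifact the pipeline writes.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, check.names = FALSE, ...)
}

#' Read a GWAS SNP list
#'
#' Tab-separated, with a header containing at least `rsid`, `chrom`, `pos`;
#' optional `ref`, `alt`, `study`, `p_value`.  All rows are GWAS-flagged.
#'
#' @param path TSV file.
#' @return data.frame `rsid`, `chrom`, `pos`, `ref`, `alt`, `study`,
#'   `p_value`, `gwas_flag`.
#' @export
read_gwas_snps <- function(path) {
  df <- read_tsv(path)
  need <- c("rsid", "chrom", "pos")
  if (!all(need %in% names(df)))
    stop_snphub(sprintf("%s: GWAS SNP list needs columns %s", path,
                        paste(need, collapse = ", ")))
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(pos) | pos < 1L)
  if (length(bad))
    stop_snphub(sprintf("%s: line %d: invalid position '%s'", path,
                        bad[1] + 1L, df$pos[bad[1]]))
  data.frame(rsid = as.character(df$rsid), chrom = norm_chrom(df$chrom),
             pos = pos,
             ref = if (is.null(df$ref)) NA_character_ else df$ref,
             alt = if (is.null(df$alt)) NA_character_ else df$alt,
             study = if (is.null(df$study)) NA_character_ else df$study,
             p_value = if (is.null(df$p_value)) NA_real_
                       else as.numeric(df$p_value),
             gwas_flag = TRUE, stringsAsFactors = FALSE)
}

#' Read / write a dosage panel
#'
#' TSV with a `sample` column followed by one column per SNP, values in
#' `{0, 1, 2}` (or `NA`).  An out-of-range value is rejected with the file,
#' row and column of the first offender.
#'
#' @param path TSV file.
#' @return Samples x SNPs integer matrix with sample-id rownames.
#' @export
read_dosage <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "sample")
    stop_snphub(sprintf("%s: first column must be 'sample'", path))
  m <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(m %in% c(0, 1, 2) | is.na(m)))
  if (length(bad)) {
    rc <- arrayInd(bad[1], dim(m))
    stop_snphub(sprintf("%s: row %d, column '%s': dosage value '%s' not in {0,1,2}",
                        path, rc[1] + 1L, colnames(m)[rc[2]], m[bad[1]]))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$sample
  m
}

#' @rdname read_dosage
#' @param dosage Samples x SNPs matrix.
#' @export
write_dosage <- function(dosage, path) {
  df <- data.frame(sample = rownames(dosage), dosage, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read / write an expression matrix
#'
#' TSV with a `sample` column followed by one numeric column per probe.
#'
#' @param path TSV file.
#' @return Samples x probes numeric matrix.
#' @export
read_expression <- function(path) {
  df <- read_tsv(path)
  if (names(df)[1] != "sample")
    stop_snphub(sprintf("%s: first column must be 'sample'", path))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df$sample
  m
}

#' @rdname read_expression
#' @param expr Samples x probes matrix.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(sample = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Write a phased genotype panel as VCF
#'
#' Minimal VCFv4.2 with phased GT entries built from the haplotype matrix.
#'
#' @param panel List with `dosage` and `haplotypes` as produced by
#'   [simulate_genotypes()] (haplotype rows alternate `_h1`/`_h2` per
#'   sample).
#' @param snp_map data.frame `rsid`, `chrom`, `pos` (column order defines
#'   the record order).
#' @param path Output file.
#' @param ref,alt Allele labels written to the REF/ALT columns.
#' @export
write_vcf_panel <- function(panel, snp_map, path, ref = "A", alt = "G") {
  H <- panel$haplotypes
  n <- nrow(H) / 2L
  samples <- rownames(panel$dosage)
  lines <- c("##fileformat=VCFv4.2",
             "##source=snphub",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_len(nrow(snp_map))) {
    h1 <- H[seq(1L, 2L * n, 2L), snp_map$rsid[i]]
    h2 <- H[seq(2L, 2L * n, 2L), snp_map$rsid[i]]
    gt <- paste(h1, h2, sep = "|")
    lines <- c(lines, paste(c(snp_map$chrom[i], snp_map$pos[i],
                              snp_map$rsid[i], ref, alt, ".", "PASS", ".",
                              "GT", gt), collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a genotype panel from VCF
#'
#' Parses GT fields via \pkg{vcfR}; accepts phased (`0|1`) or unphased
#' (`0/1`) biallelic records.  A VCF without GT is an error.
#'
#' @param path VCF file.
#' @return List with `dosage` (samples x SNPs), `haplotypes` (2n x SNPs, or
#'   `NULL` when any record is unphased), `snps` (`rsid`, `chrom`, `pos`)
#'   and `phased` flag.
#' @export
read_vcf_panel <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- tryCatch(vcfR::extract.gt(v, element = "GT"),
                 error = function(e) NULL)
  if (is.null(gt) || !nrow(gt) || !ncol(gt))
    stop_snphub(sprintf("%s: VCF has no GT genotypes", path))
  fix <- vcfR::getFIX(v)
  snps <- data.frame(rsid = fix[, "ID"], chrom = norm_chrom(fix[, "CHROM"]),
                     pos = as.integer(fix[, "POS"]), stringsAsFactors = FALSE)
  phased <- all(grepl("|", gt, fixed = TRUE), na.rm = TRUE)
  a1 <- suppressWarnings(as.integer(substr(gt, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3, 3)))
  dosage <- matrix(a1 + a2, nrow = ncol(gt), ncol = nrow(gt), byrow = TRUE,
                   dimnames = list(colnames(gt), snps$rsid))
  haplos <- NULL
  if (phased) {
    n <- ncol(gt)
    haplos <- matrix(0L, nrow = 2L * n, ncol = nrow(gt),
                     dimnames = list(paste0(rep(colnames(gt), each = 2L),
                                            c("_h1", "_h2")), snps$rsid))
    haplos[seq(1L, 2L * n, 2L), ] <- t(matrix(a1, nrow = nrow(gt)))
    haplos[seq(2L, 2L * n, 2L), ] <- t(matrix(a2, nrow = nrow(gt)))
  }
  list(dosage = dosage, haplotypes = haplos, snps = snps, phased = phased)
}

#' Read / write contact pairs (BEDPE)
#'
#' BEDPE on disk is 0-based half-open; internally anchors are 1-based
#' inclusive.  Column 7 (when present) is the contact name, column 8 the
#' support score.
#'
#' @param path BEDPE file.
#' @return data.frame `chrom_a`, `start_a`, `end_a`, `chrom_b`, `start_b`,
#'   `end_b`, `contact_id`, `support` (internal coordinates).
#' @export
read_bedpe <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 6)
    stop_snphub(sprintf("%s: BEDPE needs at least 6 columns", path))
  bad <- which(df[[2]] >= df[[3]] | df[[5]] >= df[[6]])
  if (length(bad))
    stop_snphub(sprintf("%s: line %d: anchor start must be < end", path,
                        bad[1]))
  a <- bed_to_internal(df[[2]], df[[3]])
  b <- bed_to_internal(df[[5]], df[[6]])
  data.frame(chrom_a = as.character(df[[1]]), start_a = a$start, end_a = a$end,
             chrom_b = as.character(df[[4]]), start_b = b$start, end_b = b$end,
             contact_id = if (ncol(df) >= 7) as.character(df[[7]])
                          else sprintf("contact%d", seq_len(nrow(df))),
             support = if (ncol(df) >= 8) as.numeric(df[[8]]) else NA_real_,
             stringsAsFactors = FALSE)
}

#' @rdname read_bedpe
#' @param contacts Internal-coordinate contact data.frame.
#' @export
write_bedpe <- function(contacts, path) {
  a <- internal_to_bed(contacts$start_a, contacts$end_a)
  b <- internal_to_bed(contacts$start_b, contacts$end_b)
  df <- data.frame(contacts$chrom_a, a$start, a$end,
                   contacts$chrom_b, b$start, b$end,
                   contacts$contact_id %||% sprintf("contact%d",
                                                    seq_len(nrow(contacts))))
  if (!is.null(contacts$support) && !all(is.na(contacts$support)))
    df <- cbind(df, contacts$support)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write simple BED intervals
#'
#' @param path BED file (chrom, start, end, name).
#' @return data.frame `chrom`, `start`, `end`, `name` (1-based inclusive).
#' @export
read_bed <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3)
    stop_snphub(sprintf("%s: BED needs at least 3 columns", path))
  cc <- bed_to_internal(df[[2]], df[[3]])
  data.frame(chrom = as.character(df[[1]]), start = cc$start, end = cc$end,
             name = if (ncol(df) >= 4) as.character(df[[4]])
                    else sprintf("region%d", seq_len(nrow(df))),
             stringsAsFactors = FALSE)
}

#' @rdname read_bed
#' @param intervals data.frame `chrom`, `start`, `end`, `name` (internal
#'   coordinates).
#' @export
write_bed <- function(intervals, path) {
  cc <- internal_to_bed(intervals$start, intervals$end)
  df <- data.frame(intervals$chrom, cc$start, cc$end,
                   intervals$name %||% intervals[[4]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read gene annotation (BED or GFF3)
#'
#' BED names come from column 4; GFF3 (via \pkg{rtracklayer}) uses the
#' `Name`, `gene_name` or `ID` attribute of `gene`-type records.
#'
#' @param path `.bed`, `.gff`, `.gff3` file.
#' @return data.frame `chrom`, `start`, `end`, `name` (1-based inclusive).
#' @export
read_genes <- function(path) {
  if (grepl("\\.gff3?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop_snphub("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path)
    if ("type" %in% names(S4Vectors::mcols(gr)))
      gr <- gr[as.character(gr$type) == "gene"]
    nm <- S4Vectors::mcols(gr)
    name <- nm$Name %||% nm$gene_name %||% nm$ID
    return(data.frame(chrom = norm_chrom(as.character(GenomicRanges::seqnames(gr))),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      name = as.character(name), stringsAsFactors = FALSE))
  }
  df <- read_bed(path)
  df$chrom <- norm_chrom(df$chrom)
  df
}

#' Read a curated functional edge table
#'
#' @param path TSV with header `locus_u`, `locus_v` and optional `type`,
#'   `citation`.
#' @return data.frame of functional links.
#' @export
read_functional_edges <- function(path) {
  df <- read_tsv(path)
  if (!all(c("locus_u", "locus_v") %in% names(df)))
    stop_snphub(sprintf("%s: functional edges need locus_u, locus_v", path))
  df
}

#' Read a probe annotation table
#'
#' @param path TSV with header `probe_id`, `chrom`, `start`, `end`.
#' @return data.frame of probe locations (normalized chromosomes).
#' @export
read_probe_annotation <- function(path) {
  df <- read_tsv(path)
  if (!all(c("probe_id", "chrom", "start", "end") %in% names(df)))
    stop_snphub(sprintf("%s: probe annotation needs probe_id, chrom, start, end",
                        path))
  df$chrom <- norm_chrom(df$chrom)
  df
}

#' Read / write the locus table
#'
#' @param path TSV artifact.
#' @return Locus table as produced by [collapse_blocks()].
#' @export
read_locus_table <- function(path) {
  df <- read_tsv(path)
  df$gwas_flag <- as.logical(df$gwas_flag)
  df$chrom <- as.character(df$chrom)
  df
}

#' @rdname read_locus_table
#' @param loci Locus table.
#' @export
write_locus_table <- function(loci, path) {
  write_tsv(loci, path)
}

#' Write the graph as GraphML plus a flat edge list
#'
#' @param graph Graph from [build_graph()].
#' @param graphml_path,edges_path Output files (either may be `NULL`).
#' @export
write_graph_artifacts <- function(graph, graphml_path = NULL,
                                  edges_path = NULL) {
  if (!is.null(graphml_path))
    igraph::write_graph(graph, graphml_path, format = "graphml")
  if (!is.null(edges_path))
    write_tsv(graph_edge_table(graph), edges_path)
  invisible(NULL)
}

#' Write hub reports as JSON and TSV
#'
#' @param hubs Hub list from [find_hubs()].
#' @param json_path,tsv_path Output files (either may be `NULL`).
#' @export
write_hub_reports <- function(hubs, json_path = NULL, tsv_path = NULL) {
  if (!is.null(json_path)) {
    payload <- lapply(hubs, function(h)
      list(hub_id = h$hub_id, gwas_members = h$gwas_members,
           intermediaries = h$intermediaries,
           paths = lapply(h$paths, function(p)
             list(nodes = p$nodes, layers = p$layers)),
           n_layers_used = h$n_layers_used))
    jsonlite::write_json(payload, json_path, auto_unbox = FALSE, pretty = TRUE)
  }
  if (!is.null(tsv_path)) {
    df <- if (length(hubs)) data.frame(
      hub_id = vapply(hubs, `[[`, character(1), "hub_id"),
      gwas_members = vapply(hubs, function(h)
        paste(h$gwas_members, collapse = ","), character(1)),
      intermediaries = vapply(hubs, function(h)
        paste(h$intermediaries, collapse = ","), character(1)),
      n_paths = vapply(hubs, function(h) length(h$paths), integer(1)),
      n_layers_used = vapply(hubs, `[[`, integer(1), "n_layers_used"),
      stringsAsFactors = FALSE)
    else data.frame(hub_id = character(), gwas_members = character(),
                    intermediaries = character(), n_paths = integer(),
                    n_layers_used = integer(), stringsAsFactors = FALSE)
    write_tsv(df, tsv_path)
  }
  invisible(NULL)
}

#' Read a packaged graph fixture (locus table + typed edge list)
#'
#' Fixtures are two TSVs: a node table (`locus_id`, `gwas_flag`, optional
#' coordinates) and a typed edge table (`locus_u`, `locus_v`, `layer`,
#' optional `evidence`).
#'
#' @param edges_path,loci_path TSV files.
#' @return Graph from [build_graph()].
#' @export
read_graph_fixture <- function(edges_path, loci_path) {
  loci <- read_tsv(loci_path)
  loci$gwas_flag <- as.logical(loci$gwas_flag)
  edges <- read_tsv(edges_path)
  if (is.null(edges$evidence)) edges$evidence <- "fixture"
  build_graph(edges[, c("locus_u", "locus_v", "layer", "evidence")], loci)
}

#' Path to a packaged example fixture
#'
#' @param name File name under the package's `extdata` directory; with no
#'   argument, lists the available fixtures.
#' @return File path (or vector of available names).
#' @export
snphub_fixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "snphub")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path))
    stop_snphub(sprintf("no packaged fixture '%s'", name))
  path
}
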