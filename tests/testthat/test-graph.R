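toy_loci <- function() {
  data.frame(locus_id = c("L1", "L2", "L3"), chrom = c("1", "1", "2"),
             start = c(1e6, 5e6, 3e6), end = c(1.1e6, 5.1e6, 3.1e6),
             gwas_flag = c(TRUE, TRUE, FALSE), stringsAsFactors = FALSE)
}

contact_row <- function(ca, sa, ea, cb, sb, eb, id) {
  data.frame(chrom_a = ca, start_a = sa, end_a = ea,
             chrom_b = cb, start_b = sb, end_b = eb,
             contact_id = id, stringsAsFactors = FALSE)
}

test_that("anchors in two distinct loci yield one spatial edge", {
  edges <- map_contacts_to_loci(
    contact_row("1", 1.02e6, 1.03e6, "1", 5.02e6, 5.03e6, "c1"), toy_loci())
  expect_equal(nrow(edges), 1L)
  expect_equal(edges$locus_u, "L1")
  expect_equal(edges$locus_v, "L2")
  expect_equal(edges$layer, "spatial")
})

test_that("same-locus anchor pairs are dropped as self-loops", {
  edges <- map_contacts_to_loci(
    contact_row("1", 1.01e6, 1.02e6, "1", 1.05e6, 1.06e6, "c1"), toy_loci())
  expect_equal(nrow(edges), 0L)
})

test_that("duplicate contacts merge with accumulated evidence", {
  contacts <- rbind(
    contact_row("1", 1.02e6, 1.03e6, "1", 5.02e6, 5.03e6, "c1"),  # L1-L2
    contact_row("1", 5.05e6, 5.06e6, "1", 1.05e6, 1.06e6, "c2"),  # L2-L1 dup
    contact_row("1", 1.02e6, 1.03e6, "2", 3.02e6, 3.03e6, "c3"),  # L1-L3
    contact_row("2", 3.02e6, 3.03e6, "1", 1.02e6, 1.03e6, "c4"),  # L3-L1 dup
    contact_row("9", 1e6, 1.1e6, "9", 2e6, 2.1e6, "c5"))          # outside
  edges <- map_contacts_to_loci(contacts, toy_loci())
  expect_equal(nrow(edges), 2L)
  ev <- strsplit(edges$evidence, ";")
  expect_setequal(ev[[1]], c("c1", "c2"))
  expect_setequal(ev[[2]], c("c3", "c4"))
})

test_that("flank extends locus overlap and 0 means strict overlap", {
  near <- contact_row("1", 1.105e6, 1.106e6, "1", 5.02e6, 5.03e6, "c1")
  expect_equal(nrow(map_contacts_to_loci(near, toy_loci(), flank = 10000)), 1L)
  expect_equal(nrow(map_contacts_to_loci(near, toy_loci(), flank = 0)), 0L)
})

test_that("mixed chromosome conventions error unless auto-normalized", {
  chr <- contact_row("chr1", 1.02e6, 1.03e6, "chr1", 5.02e6, 5.03e6, "c1")
  expect_error(map_contacts_to_loci(chr, toy_loci(), auto_normalize = FALSE),
               "convention")
  expect_equal(nrow(map_contacts_to_loci(chr, toy_loci())), 1L)
})

test_that("map_contacts_to_loci agrees with a brute-force overlap oracle", {
  set.seed(61)
  for (rep in 1:10) {
    n_loci <- sample(3:6, 1)
    loci <- data.frame(locus_id = sprintf("L%d", 1:n_loci), chrom = "1",
                       start = sort(sample.int(1e6, n_loci)) * 10,
                       gwas_flag = TRUE, stringsAsFactors = FALSE)
    loci$end <- loci$start + sample(1e4:5e4, n_loci, replace = TRUE)
    contacts <- do.call(rbind, lapply(1:8, function(i) {
      s1 <- sample.int(1.2e7, 1); s2 <- sample.int(1.2e7, 1)
      contact_row("1", s1, s1 + 5e3, "1", s2, s2 + 5e3, sprintf("c%d", i))
    }))
    flank <- 2000
    got <- map_contacts_to_loci(contacts, loci, flank = flank)
    want <- character()
    ov <- function(s, e, i) s <= loci$end[i] + flank & e >= loci$start[i] - flank
    for (k in 1:nrow(contacts)) for (i in 1:n_loci) for (j in 1:n_loci) {
      if (i == j) next
      if (ov(contacts$start_a[k], contacts$end_a[k], i) &&
          ov(contacts$start_b[k], contacts$end_b[k], j))
        want <- c(want, paste(sort(c(loci$locus_id[i], loci$locus_id[j])),
                              collapse = "-"))
    }
    expect_setequal(paste(got$locus_u, got$locus_v, sep = "-"), unique(want))
  }
})

test_that("significant trans results become eqtl edges; cis and unmapped do not", {
  res <- data.frame(snp_id = c("rs174535", "rs2", "rs3"),
                    probe_id = c("ILMN_USP6", "pX", "pY"),
                    verdict = c("significant", "not_significant",
                                "significant"),
                    stringsAsFactors = FALSE)
  snp_locus <- c(rs174535 = "MYRF", rs2 = "MYRF", rs3 = "MYRF")
  probe_locus <- c(ILMN_USP6 = "USP6", pX = "USP6", pY = NA)
  expect_message(edges <- eqtl_edges(res, snp_locus, probe_locus),
                 "no locus")
  expect_equal(nrow(edges), 1L)
  expect_equal(sort(c(edges$locus_u, edges$locus_v)), c("MYRF", "USP6"))
  expect_equal(edges$layer, "eqtl")

  # significant result with SNP and probe in the same locus -> no edge
  res2 <- data.frame(snp_id = "rs174535", probe_id = "pZ",
                     verdict = "significant", stringsAsFactors = FALSE)
  expect_equal(nrow(eqtl_edges(res2, snp_locus, c(pZ = "MYRF"))), 0L)
})

test_that("the three-way-hub transcription builds a 10-node 9-edge graph", {
  g <- fixture_graph("hub3way")
  expect_equal(igraph::vcount(g), 10L)
  expect_equal(igraph::ecount(g), 9L)
  expect_equal(sum(igraph::V(g)$gwas), 3L)
  expect_setequal(unique(igraph::E(g)$layer), c("spatial", "functional"))
})

test_that("isolated GWAS loci stay in the graph; unknown loci are rejected", {
  loci <- toy_loci()
  g <- build_graph(NULL, loci)
  expect_equal(sort(igraph::V(g)$name), c("L1", "L2"))
  expect_equal(igraph::ecount(g), 0L)

  bad <- data.frame(locus_u = "L1", locus_v = "NOPE", layer = "spatial",
                    evidence = "x", stringsAsFactors = FALSE)
  expect_error(build_graph(bad, loci), "NOPE")
  loop <- data.frame(locus_u = "L1", locus_v = "L1", layer = "spatial",
                     evidence = "x", stringsAsFactors = FALSE)
  expect_error(build_graph(loop, loci), "self-loop")
})

test_that("the same locus pair may carry parallel edges in distinct layers", {
  edges <- data.frame(locus_u = c("L1", "L1"), locus_v = c("L2", "L2"),
                      layer = c("spatial", "eqtl"), evidence = c("c1", "e1"),
                      stringsAsFactors = FALSE)
  g <- build_graph(edges, toy_loci())
  expect_equal(igraph::ecount(g), 2L)
  expect_setequal(igraph::E(g)$layer, c("spatial", "eqtl"))
})

test_that("graph construction is order-independent", {
  edges <- read.delim(snphub_fixture("hub3way_edges.tsv"),
                      stringsAsFactors = FALSE)
  edges$evidence <- "fixture"
  loci <- read.delim(snphub_fixture("hub3way_loci.tsv"),
                     stringsAsFactors = FALSE)
  g1 <- build_graph(edges, loci)
  set.seed(71)
  g2 <- build_graph(edges[sample(nrow(edges)), ],
                    loci[sample(nrow(loci)), ])
  expect_identical(graph_edge_table(g1), graph_edge_table(g2))
  expect_identical(sort(igraph::V(g1)$name), sort(igraph::V(g2)$name))
})
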