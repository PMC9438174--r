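write_pairs <- function(rows, path) {
  writeLines(c("mirna_id\tgene_id\tconfidence\tscore\tsource", rows), path)
}

test_that("interaction tables are parsed, validated, and deduplicated", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "ints.tsv")
  write_pairs(c("hsa-miR-1\tGA\thigh\t0.9\tdb1",
                "hsa-miR-1\tGB\tlow\t0.2\tdb1",
                "hsa-miR-2\tGA\tvery_high\t0.95\tdb1",
                "hsa-miR-2\tGC\tmoderate\t0.5\tdb2",
                "hsa-miR-3\tGC\thigh\t0.8\tdb1"), p)
  tab <- load_interactions(p)
  expect_equal(nrow(tab), 5)
  expect_s3_class(tab$confidence, "ordered")

  # duplicate (mirna, gene, source) keeps the highest confidence
  write_pairs(c("hsa-miR-1\tGA\thigh\t0.9\tdb1",
                "hsa-miR-1\tGA\tlow\t0.2\tdb1"), p)
  dedup <- load_interactions(p)
  expect_equal(nrow(dedup), 1)
  expect_equal(as.character(dedup$confidence), "high")

  # unknown labels error and list the accepted ones
  write_pairs("hsa-miR-1\tGA\tmedium\t0.5\tdb1", p)
  expect_error(load_interactions(p), "low/moderate/high/very_high")
})

test_that("the shipped curated cardiomyocyte pair table loads cleanly", {
  path <- system.file("extdata", "cardiomyocyte_validated_pairs.tsv",
                      package = "mirfunnel")
  tab <- load_interactions(path)
  expect_equal(nrow(tab), 16)
  expect_true(all(as.integer(tab$confidence) >=
                    match("high", confidence_levels())))
  expect_true(all(grepl("^hsa-", tab$mirna_id)))
  expect_equal(sum(tab$gene_id == "EPM2AIP1"), 4)
  expect_false(any(grepl("^hsa-", normalize_mirna_ids(tab$mirna_id))))
})

test_that("restriction keeps pairs with both endpoints surviving and enough confidence", {
  pairs <- data.frame(
    mirna_id = paste0("m", 1:10),
    gene_id = paste0("g", 1:10),
    confidence = factor(c("high", "very_high", "high", "low", "moderate",
                          "high", "low", "very_high", "moderate", "high"),
                        levels = confidence_levels(), ordered = TRUE),
    score = NA_real_, source = "t", stringsAsFactors = FALSE)
  # endpoints 1..6 survive filtering; of those, pairs 1,2,3,6 are >= high
  surv_g <- paste0("g", 1:6)
  surv_m <- paste0("m", 1:6)
  kept <- restrict_and_filter(pairs, surv_g, surv_m, "high")
  expect_equal(kept$gene_id, paste0("g", c(1, 2, 3, 6)))

  # a pair whose gene was filtered out is excluded even at high confidence
  expect_false("g10" %in% kept$gene_id)

  # min_confidence = low is restriction-only and monotone in the threshold
  low <- restrict_and_filter(pairs, surv_g, surv_m, "low")
  expect_equal(nrow(low), 6)
  prev <- low
  for (lvl in confidence_levels()[-1]) {
    cur <- restrict_and_filter(pairs, surv_g, surv_m, lvl)
    expect_true(all(paste(cur$mirna_id, cur$gene_id) %in%
                      paste(prev$mirna_id, prev$gene_id)))
    prev <- cur
  }
})

test_that("the exported network is a bipartite GraphML round trip", {
  pairs <- data.frame(
    mirna_id = c("m1", "m2", "m3", "m1"),
    gene_id = c("g1", "g1", "g2", "g2"),
    confidence = factor(c("high", "high", "very_high", "high"),
                        levels = confidence_levels(), ordered = TRUE),
    score = c(0.9, 0.8, 0.95, 0.7), source = "t", stringsAsFactors = FALSE)
  fc <- c(g1 = 2.0, g2 = 0.5, m1 = 0.8, m2 = 1.5, m3 = 0.9)
  path <- withr::local_tempfile(fileext = ".graphml")
  g <- export_network(pairs, fc, path)
  expect_equal(igraph::vcount(g), 5)
  expect_equal(igraph::ecount(g), 4)

  back <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(back), 5)
  v <- igraph::vertex_attr(back)
  expect_setequal(v$kind, c("gene", "mirna"))
  expect_equal(v$fold_change[v$name == "g1"], 2.0)
  expect_equal(v$regulation[v$name == "g2"], "down")
  expect_setequal(igraph::edge_attr(back, "confidence"),
                  c("high", "very_high"))

  # strictly bipartite: every edge joins a miRNA to a gene
  kind <- setNames(v$kind, v$name)
  ends <- igraph::ends(back, igraph::E(back))
  expect_true(all(kind[ends[, 1]] == "mirna" & kind[ends[, 2]] == "gene"))

  # a node without a fold change gets 1.0 with a warning
  expect_warning(export_network(pairs, fc[-1], path), "g1")
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vertex_attr(g2, "fold_change",
                                   igraph::V(g2)[igraph::V(g2)$name == "g1"]), 1.0)

  # empty pair list still writes a valid (empty) graph
  empty <- pairs[0, ]
  ge <- export_network(empty, fc, path)
  expect_equal(igraph::vcount(ge), 0)
})
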