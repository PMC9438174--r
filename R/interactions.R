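#' Ordered confidence classes for validated interactions
#'
#' Ordinal strength of a curated miRNA-target interaction, from `low` to
#' `very_high`.
#' @export
confidence_levels <- function() c("low", "moderate", "high", "very_high")

#' Load a validated miRNA-target interaction table
#'
#' Reads a TSV with columns `mirna_id`, `gene_id`, `confidence`, optional
#' `score`, and `source` (the style of a curated-database export). Rows are
#' validated against the accepted confidence labels and deduplicated on
#' (mirna_id, gene_id, source), keeping the highest confidence.
#'
#' @param path Path to the interaction TSV.
#' @return Data frame of interaction pairs with `confidence` as an ordered
#'   factor.
#' @export
load_interactions <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("mirna_id", "gene_id", "confidence", "source")
  if (!all(req %in% names(tab))) {
    stop("interaction table must have columns ", paste(req, collapse = ", "))
  }
  if (!"score" %in% names(tab)) tab$score <- NA_real_
  bad <- setdiff(unique(tab$confidence), confidence_levels())
  if (length(bad)) {
    stop("unknown confidence label(s): ", paste(bad, collapse = ", "),
         " (accepted: ", paste(confidence_levels(), collapse = "/"), ")")
  }
  tab$confidence <- factor(tab$confidence, levels = confidence_levels(),
                           ordered = TRUE)
  tab <- tab[order(tab$mirna_id, tab$gene_id, tab$source, -as.integer(tab$confidence)), ]
  key <- paste(tab$mirna_id, tab$gene_id, tab$source, sep = "\r")
  tab <- tab[!duplicated(key), c("mirna_id", "gene_id", "confidence", "score",
                                 "source")]
  rownames(tab) <- NULL
  tab
}

#' Restrict interactions to filtered transcripts and a confidence floor
#'
#' Keeps pairs whose gene *and* miRNA both survived the filter cascade and
#' whose confidence class is at least `min_confidence`. With
#' `min_confidence = "low"` this is restriction-only.
#'
#' @param pairs Interaction data frame from [load_interactions()].
#' @param gene_ids,mirna_ids Surviving transcript ids from the filters.
#' @param min_confidence Minimum confidence class (default `"high"`).
#' @return The filtered interaction data frame.
#' @export
restrict_and_filter <- function(pairs, gene_ids, mirna_ids,
                                min_confidence = "high") {
  min_confidence <- match.arg(min_confidence, confidence_levels())
  floor_i <- match(min_confidence, confidence_levels())
  keep <- pairs$gene_id %in% gene_ids & pairs$mirna_id %in% mirna_ids &
    as.integer(pairs$confidence) >= floor_i
  out <- pairs[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strip the species prefix from miRNA mature names
#'
#' Turns e.g. `"hsa-miR-124-3p"` into `"miR-124-3p"`.
#'
#' @param x Character vector of miRNA ids.
#' @return Normalized ids.
#' @export
normalize_mirna_ids <- function(x) sub("^[a-z]{3}-", "", x)

#' Export the gene-miRNA bipartite network as GraphML
#'
#' Nodes carry `kind` (gene/mirna), `fold_change` (linear scale) and
#' `regulation` (up/down from the fold change); edges carry `confidence` and
#' `score`. Nodes without a supplied fold change get 1.0 with a warning.
#'
#' @param pairs Interaction data frame (gene_id, mirna_id, confidence,
#'   score).
#' @param fold_changes Named numeric vector mapping node ids to linear fold
#'   changes.
#' @param path Output GraphML path.
#' @return The `igraph` graph, invisibly.
#' @export
export_network <- function(pairs, fold_changes, path) {
  genes <- unique(pairs$gene_id)
  mirnas <- unique(pairs$mirna_id)
  nodes <- c(genes, mirnas)
  fc <- fold_changes[nodes]
  if (any(is.na(fc))) {
    warning("node(s) without fold change set to 1.0: ",
            paste(nodes[is.na(fc)], collapse = ", "))
    fc[is.na(fc)] <- 1.0
  }
  g <- igraph::make_empty_graph(directed = TRUE)
  if (length(nodes)) {
    g <- igraph::add_vertices(
      g, length(nodes), name = nodes,
      kind = rep(c("gene", "mirna"), c(length(genes), length(mirnas))),
      fold_change = as.numeric(fc),
      regulation = ifelse(fc >= 1, "up", "down"))
    if (nrow(pairs)) {
      conf <- if (is.null(pairs$confidence)) rep("unknown", nrow(pairs)) else
        as.character(pairs$confidence)
      score <- if (is.null(pairs$score)) rep(NA_real_, nrow(pairs)) else
        pairs$score
      g <- igraph::add_edges(
        g, rbind(match(pairs$mirna_id, nodes), match(pairs$gene_id, nodes)),
        confidence = conf, score = ifelse(is.na(score), -1, score))
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(g)
}
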