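#' Specify one planted gene-miRNA pair
#'
#' A planted pair shares a latent trajectory `f(t)` scaled to `amplitude`
#' log2 units: in Profile 1 the gene follows `+f` and the miRNA `-f`
#' (gene up, miRNA down); Profile 2 is the mirror. The `exp2` shape is a
#' saturating exponential (so planted transcripts also pass the exponential
#' filter); `linear` and `sigmoid` shapes exist to probe filter specificity.
#'
#' @param gene_id,mirna_id Transcript ids (must not collide with background
#'   ids).
#' @param profile `"profile1"` or `"profile2"`.
#' @param amplitude Trajectory amplitude in log2 units (> 0, default 3).
#' @param confidence Confidence class of the planted interaction.
#' @param shape Latent trajectory shape.
#' @return A `pair_spec` list.
#' @export
pair_spec <- function(gene_id, mirna_id, profile = c("profile1", "profile2"),
                      amplitude = 3, confidence = "high",
                      shape = c("exp2", "linear", "sigmoid")) {
  profile <- match.arg(profile)
  shape <- match.arg(shape)
  confidence <- match.arg(confidence, confidence_levels())
  if (amplitude <= 0) stop("'amplitude' must be > 0")
  structure(list(gene_id = gene_id, mirna_id = mirna_id, profile = profile,
                 amplitude = amplitude, confidence = confidence,
                 shape = shape),
            class = "pair_spec")
}

#' Default planted pairs
#'
#' Ten saturating-exponential pairs alternating Profile 1 / Profile 2 and
#' high / very high confidence, amplitude 3 log2 units.
#'
#' @param n Number of pairs (default 10).
#' @return List of [pair_spec()] objects.
#' @export
default_pair_specs <- function(n = 10) {
  lapply(seq_len(n), function(i) {
    pair_spec(sprintf("GENE_P%02d", i), sprintf("hsa-miR-P%02d-3p", i),
              profile = if (i %% 2 == 1) "profile1" else "profile2",
              amplitude = 3,
              confidence = if (i %% 2 == 1) "high" else "very_high",
              shape = "exp2")
  })
}

#' Configure the synthetic time-course generator
#'
#' Defaults emulate a replicated 30-day differentiation design sampled at
#' days 0/2/4/6/8/15/30 with three biological replicates per day,
#' homoscedastic Gaussian log2 noise, a background of non-informative
#' transcripts, planted inverse pairs, and a matching interaction table with
#' decoy edges.
#'
#' @param days Sampled differentiation days.
#' @param n_replicates Replicates per day (default 3).
#' @param n_background_genes,n_background_mirnas Background transcript
#'   counts (defaults 500 and 200).
#' @param planted_pairs List of [pair_spec()] objects (default
#'   [default_pair_specs()]).
#' @param noise_sd Gaussian noise SD in log2 units (default 0.2).
#' @param decoy_edges Number of random background-background interaction
#'   edges (default 500).
#' @param baseline_range Uniform range of background baseline log2 levels
#'   (default `c(4, 12)`, mimicking array intensity spread).
#' @param planted_baseline_range Baseline range for planted transcripts
#'   (default `c(8, 11)`: signature transcripts are well expressed, so they
#'   remain above detection over the full trajectory swing).
#' @param seed Mandatory integer seed; generation is fully deterministic.
#' @return A `synth_config` list.
#' @export
synth_config <- function(days = c(0, 2, 4, 6, 8, 15, 30), n_replicates = 3,
                         n_background_genes = 500, n_background_mirnas = 200,
                         planted_pairs = default_pair_specs(),
                         noise_sd = 0.2, decoy_edges = 500,
                         baseline_range = c(4, 12),
                         planted_baseline_range = c(8, 11), seed) {
  if (missing(seed)) stop("'seed' is mandatory")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (length(days) < 2 || any(diff(sort(days)) == 0)) {
    stop("'days' must be >= 2 distinct values")
  }
  structure(list(days = sort(days), n_replicates = as.integer(n_replicates),
                 n_background_genes = as.integer(n_background_genes),
                 n_background_mirnas = as.integer(n_background_mirnas),
                 planted_pairs = planted_pairs, noise_sd = noise_sd,
                 decoy_edges = as.integer(decoy_edges),
                 baseline_range = baseline_range,
                 planted_baseline_range = planted_baseline_range,
                 seed = as.integer(seed)),
            class = "synth_config")
}

latent_shape <- function(shape, t01, amplitude) {
  switch(shape,
         exp2 = amplitude * (1 - exp(-3 * t01)) / (1 - exp(-3)),
         linear = amplitude * t01,
         sigmoid = {
           lo <- stats::plogis(-5)
           hi <- stats::plogis(5)
           amplitude * (stats::plogis(10 * (t01 - 0.5)) - lo) / (hi - lo)
         })
}

#' Generate a synthetic paired gene/miRNA time course
#'
#' Background transcripts are baseline plus i.i.d. Gaussian noise. Each
#' planted pair shares a latent trajectory of the configured shape and
#' amplitude with the gene and miRNA on opposite signs. The interaction
#' table holds the true pairs at their stated confidence plus decoy edges
#' between background transcripts with confidence drawn uniformly over the
#' classes. Output is fully determined by the config seed.
#'
#' @param config A [synth_config()].
#' @return A `synth_bundle` list: `genes` and `mirnas`
#'   (`expression_dataset`s), `interactions` (data frame), `truth` (list
#'   with `true_pairs` and per-transcript `labels`), `config`.
#' @export
generate_timecourse <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  days <- config$days
  reps <- config$n_replicates
  day_vec <- rep(days, each = reps)
  rep_vec <- rep(seq_len(reps), times = length(days))
  samples <- data.frame(
    sample_id = sprintf("d%g_r%d", day_vec, rep_vec),
    day = day_vec, replicate = rep_vec, stringsAsFactors = FALSE)
  t01 <- (day_vec - min(days)) / (max(days) - min(days))

  pg <- vapply(config$planted_pairs, `[[`, character(1), "gene_id")
  pm <- vapply(config$planted_pairs, `[[`, character(1), "mirna_id")
  bg <- sprintf("GENE_B%04d", seq_len(config$n_background_genes))
  bm <- sprintf("hsa-miR-B%04d", seq_len(config$n_background_mirnas))
  all_ids <- c(pg, pm, bg, bm)
  if (anyDuplicated(all_ids)) {
    stop("duplicate transcript id(s) across specs: ",
         paste(unique(all_ids[duplicated(all_ids)]), collapse = ", "))
  }

  n_samp <- nrow(samples)
  noise <- function() stats::rnorm(n_samp, 0, config$noise_sd)
  base_in <- function(range) stats::runif(1, range[1], range[2])

  gene_rows <- list()
  mirna_rows <- list()
  for (ps in config$planted_pairs) {
    f <- latent_shape(ps$shape, t01, ps$amplitude)
    sgn <- if (ps$profile == "profile1") 1 else -1
    gene_rows[[ps$gene_id]] <-
      base_in(config$planted_baseline_range) + sgn * f + noise()
    mirna_rows[[ps$mirna_id]] <-
      base_in(config$planted_baseline_range) - sgn * f + noise()
  }
  for (id in bg) gene_rows[[id]] <- base_in(config$baseline_range) + noise()
  for (id in bm) mirna_rows[[id]] <- base_in(config$baseline_range) + noise()

  mk <- function(rows, kind) {
    m <- do.call(rbind, rows)
    colnames(m) <- samples$sample_id
    expression_dataset(m, samples, kind)
  }
  genes <- mk(gene_rows, "gene")
  mirnas <- mk(mirna_rows, "mirna")

  true_tab <- data.frame(
    mirna_id = pm, gene_id = pg,
    confidence = vapply(config$planted_pairs, `[[`, character(1), "confidence"),
    score = round(stats::runif(length(pg), 0.7, 1), 3),
    source = "synthetic", stringsAsFactors = FALSE)
  n_decoy <- config$decoy_edges
  decoy_tab <- NULL
  if (n_decoy > 0) {
    max_edges <- length(bg) * length(bm)
    if (n_decoy > max_edges) stop("decoy_edges exceeds possible background edges")
    edge_ix <- sample.int(max_edges, n_decoy)  # unique edges
    decoy_tab <- data.frame(
      mirna_id = bm[(edge_ix - 1) %% length(bm) + 1],
      gene_id = bg[(edge_ix - 1) %/% length(bm) + 1],
      confidence = sample(confidence_levels(), n_decoy, replace = TRUE),
      score = round(stats::runif(n_decoy), 3),
      source = "synthetic", stringsAsFactors = FALSE)
  }
  interactions <- rbind(true_tab, decoy_tab)
  interactions$confidence <- factor(interactions$confidence,
                                    levels = confidence_levels(),
                                    ordered = TRUE)

  labels <- data.frame(
    transcript_id = all_ids,
    kind = rep(c("gene", "mirna", "gene", "mirna"),
               c(length(pg), length(pm), length(bg), length(bm))),
    class = rep(c("planted_gene", "planted_mirna", "background", "background"),
                c(length(pg), length(pm), length(bg), length(bm))),
    stringsAsFactors = FALSE)
  truth <- list(
    true_pairs = data.frame(
      mirna_id = pm, gene_id = pg,
      profile = vapply(config$planted_pairs, `[[`, character(1), "profile"),
      stringsAsFactors = FALSE),
    labels = labels)
  structure(list(genes = genes, mirnas = mirnas, interactions = interactions,
                 truth = truth, config = config),
            class = "synth_bundle")
}

#' Write a synthetic bundle to disk in the pipeline's input formats
#'
#' Writes the gene and miRNA expression/metadata TSVs, the interaction
#' table, the truth tables, and a manifest JSON echoing the configuration
#' with per-file MD5 hashes. Refuses to overwrite a directory holding a
#' manifest with different hashes unless `overwrite = TRUE`.
#'
#' @param bundle A `synth_bundle` from [generate_timecourse()].
#' @param out_dir Output directory (created if needed).
#' @param overwrite Allow replacing a conflicting fixture (default FALSE).
#' @return Named character vector of written paths, invisibly.
#' @export
write_fixture <- function(bundle, out_dir, overwrite = FALSE) {
  files <- c(gene_expr = "gene_expr.tsv", gene_meta = "gene_meta.tsv",
             mirna_expr = "mirna_expr.tsv", mirna_meta = "mirna_meta.tsv",
             interactions = "interactions.tsv",
             truth_pairs = "truth_pairs.tsv",
             truth_labels = "truth_labels.tsv", manifest = "manifest.json")
  stage <- tempfile("fixture_stage_")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  sp <- file.path(stage, files)
  names(sp) <- names(files)
  write_expression(bundle$genes, sp["gene_expr"], sp["gene_meta"])
  write_expression(bundle$mirnas, sp["mirna_expr"], sp["mirna_meta"])
  itab <- bundle$interactions
  itab$confidence <- as.character(itab$confidence)
  utils::write.table(itab, sp["interactions"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(bundle$truth$true_pairs, sp["truth_pairs"],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$truth$labels, sp["truth_labels"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  hashes <- tools::md5sum(unname(sp[names(sp) != "manifest"]))
  names(hashes) <- names(sp)[names(sp) != "manifest"]
  cfg <- bundle$config
  manifest <- list(
    config = list(days = cfg$days, n_replicates = cfg$n_replicates,
                  n_background_genes = cfg$n_background_genes,
                  n_background_mirnas = cfg$n_background_mirnas,
                  n_planted_pairs = length(cfg$planted_pairs),
                  noise_sd = cfg$noise_sd, decoy_edges = cfg$decoy_edges,
                  seed = cfg$seed),
    md5 = as.list(hashes))
  jsonlite::write_json(manifest, sp["manifest"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  if (file.exists(paths["manifest"]) && !overwrite) {
    old <- jsonlite::read_json(paths["manifest"], simplifyVector = TRUE)
    if (!identical(unlist(old$md5), unlist(manifest$md5))) {
      stop("existing manifest in ", out_dir,
           " has different content hashes; use overwrite = TRUE")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  file.copy(sp, paths, overwrite = TRUE)
  invisible(paths)
}
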