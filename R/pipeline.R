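#' Run the full interaction-mining cascade
#'
#' Executes detection filtering, segmental fold-change filtering,
#' exponential-trajectory filtering, interaction restriction, inverse
#' fold-change (iFC) scoring, and optionally cross-dataset concordance and
#' random-forest stage evaluation, from a single configuration. The
#' configuration is a named list or the path to a YAML file with the same
#' structure; see Details.
#'
#' @details Recognized configuration entries (defaults in parentheses):
#' `gene_expr`, `gene_meta`, `mirna_expr`, `mirna_meta` (input TSV paths;
#' alternatively `genes` / `mirnas` may hold in-memory
#' `expression_dataset`s), `interactions` (TSV path or data frame;
#' required), `normalize` (FALSE; quantile-normalize inputs),
#' `min_timepoints` (6), `detect_thr` (NULL = matrix 10th percentile),
#' `segments` (`"short"`, `"long"`, or a data frame with `name`/`day_lo`/
#' `day_hi`), `skip_segmental` (FALSE), `low_thr` (0.8), `high_thr` (1.2),
#' `r_threshold` (0.7), `goodness` (`"r2"`), `min_confidence` (`"high"`),
#' `r_cut` (-0.5), `p_cut` (1), `externals` (list of
#' `list(expr =, meta =, kind =)` entries for concordance), `pass_pct` (50),
#' `rf_eval` (FALSE), `seed` (1; all randomness funnels through it),
#' `n_trees` (500), `n_folds` (10), `out_dir` (NULL; when set, all stage
#' TSVs, the GraphML network and a JSON run report are written there; on a
#' stage error a `.partial` marker is left next to any partial outputs).
#'
#' @param config Named list or path to a YAML config file.
#' @return A `run_report` list: `funnel` (per-stage transcript/pair counts,
#'   non-increasing along the cascade), `tables` (stage outputs), `timings`
#'   (seconds per stage), `config` echo, `seed`, and `output_files` when
#'   `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  cfg <- utils::modifyList(list(
    normalize = FALSE, min_timepoints = 6, detect_thr = NULL,
    segments = NULL, skip_segmental = FALSE, low_thr = 0.8, high_thr = 1.2,
    r_threshold = 0.7, goodness = "r2", min_confidence = "high",
    r_cut = -0.5, p_cut = 1, externals = NULL, pass_pct = 50,
    rf_eval = FALSE, seed = 1, n_trees = 500, n_folds = 10, out_dir = NULL),
    config, keep.null = TRUE)

  # -- validate inputs before any computation
  if (is.null(cfg$interactions)) stop("config is missing 'interactions'")
  if (is.character(cfg$interactions) && !file.exists(cfg$interactions)) {
    stop("interaction table not found: ", cfg$interactions)
  }
  for (p in c("gene_expr", "gene_meta", "mirna_expr", "mirna_meta")) {
    if (!is.null(cfg[[p]]) && !file.exists(cfg[[p]])) {
      stop("input file not found (", p, "): ", cfg[[p]])
    }
  }

  out_dir <- cfg$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, showWarnings = FALSE,
                                    recursive = TRUE)
  mark_partial <- function(stage) {
    if (!is.null(out_dir)) {
      writeLines(stage, file.path(out_dir, ".partial"))
    }
  }
  timings <- c()
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(force(expr), error = function(e) {
      mark_partial(stage)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    timings[[stage]] <<- proc.time()[["elapsed"]] - t0
    res
  }

  # -- load
  loaded <- run_stage("load", {
    genes <- if (!is.null(cfg$genes)) cfg$genes else
      read_expression(cfg$gene_expr, cfg$gene_meta, "gene")
    mirnas <- if (!is.null(cfg$mirnas)) cfg$mirnas else
      read_expression(cfg$mirna_expr, cfg$mirna_meta, "mirna")
    pairs <- if (is.data.frame(cfg$interactions)) cfg$interactions else
      load_interactions(cfg$interactions)
    list(genes = genes, mirnas = mirnas, pairs = pairs)
  })
  genes <- loaded$genes; mirnas <- loaded$mirnas; pairs <- loaded$pairs
  if (isTRUE(cfg$normalize)) {
    genes <- run_stage("normalize", quantile_normalize(genes))
    mirnas <- quantile_normalize(mirnas)
  }
  scheme <- if (inherits(cfg$segments, "segment_scheme")) cfg$segments
  else if (is.data.frame(cfg$segments)) {
    segment_scheme(cfg$segments$name, cfg$segments$day_lo, cfg$segments$day_hi)
  } else if (is.list(cfg$segments) && !is.null(cfg$segments$name)) {
    segment_scheme(unlist(cfg$segments$name), unlist(cfg$segments$day_lo),
                   unlist(cfg$segments$day_hi))
  } else if (identical(cfg$segments, "long")) segments_long()
  else if (identical(cfg$segments, "short")) segments_short()
  else if (max(dataset_days(genes)) > 30) segments_long() else segments_short()

  funnel <- data.frame(stage = character(), n_genes = integer(),
                       n_mirnas = integer(), n_pairs = integer())
  note <- function(stage, ng, nm, np = NA_integer_) {
    funnel <<- rbind(funnel, data.frame(stage = stage, n_genes = ng,
                                        n_mirnas = nm, n_pairs = np))
  }
  note("input", nrow(genes$values), nrow(mirnas$values), nrow(pairs))

  # -- detection
  det <- run_stage("detection", list(
    genes = detection_filter(genes, cfg$min_timepoints, cfg$detect_thr),
    mirnas = detection_filter(mirnas, cfg$min_timepoints, cfg$detect_thr)))
  note("detection", nrow(det$genes$values), nrow(det$mirnas$values))

  gene_prof <- to_profiles(det$genes)
  mirna_prof <- to_profiles(det$mirnas)

  # -- segmental fold change
  if (isTRUE(cfg$skip_segmental)) {
    seg_calls <- NULL
    seg_gene_ids <- names(gene_prof)
    seg_mirna_ids <- names(mirna_prof)
  } else {
    seg <- run_stage("segmental", {
      gc <- segmental_fold_change(gene_prof, scheme, cfg$low_thr, cfg$high_thr)
      mc <- segmental_fold_change(mirna_prof, scheme, cfg$low_thr, cfg$high_thr)
      list(gene_calls = gc, mirna_calls = mc)
    })
    seg_calls <- rbind(cbind(seg$gene_calls, kind = "gene"),
                       cbind(seg$mirna_calls, kind = "mirna"))
    seg_gene_ids <- informative_ids(seg$gene_calls)
    seg_mirna_ids <- informative_ids(seg$mirna_calls)
  }
  note("segmental", length(seg_gene_ids), length(seg_mirna_ids))

  # -- exponential trajectory filter
  expf <- run_stage("exponential", {
    gf <- fit_exp2_all(gene_prof[seg_gene_ids], cfg$r_threshold,
                       goodness = cfg$goodness)
    mf <- fit_exp2_all(mirna_prof[seg_mirna_ids], cfg$r_threshold,
                       goodness = cfg$goodness)
    list(gene_fits = gf, mirna_fits = mf)
  })
  exp_gene_ids <- expf$gene_fits$transcript_id[expf$gene_fits$passed]
  exp_mirna_ids <- expf$mirna_fits$transcript_id[expf$mirna_fits$passed]
  note("exponential", length(exp_gene_ids), length(exp_mirna_ids))

  # -- interaction restriction
  cand <- run_stage("interactions", restrict_and_filter(
    pairs, exp_gene_ids, exp_mirna_ids, cfg$min_confidence))
  note("interaction_restriction", length(unique(cand$gene_id)),
       length(unique(cand$mirna_id)), nrow(cand))
  if (nrow(cand) == 0) {
    warning("no interaction pairs survive restriction; ",
            "downstream tables will be empty")
  }

  # -- iFC scoring
  scores <- run_stage("ifc", score_pairs(
    cand, gene_prof, mirna_prof, r_cut = cfg$r_cut, p_cut = cfg$p_cut))
  hs <- scores[scores$high_stringency, , drop = FALSE]
  note("ifc_high_stringency", length(unique(hs$gene_id)),
       length(unique(hs$mirna_id)), nrow(hs))

  # -- optional concordance
  conc <- NULL
  if (!is.null(cfg$externals) && length(cfg$externals)) {
    conc <- run_stage("concordance", {
      ext <- lapply(cfg$externals, function(e) {
        if (inherits(e, "expression_dataset")) e else
          read_expression(e$expr, e$meta, e$kind)
      })
      kinds <- vapply(ext, `[[`, character(1), "kind")
      res <- list()
      if (any(kinds == "gene") && length(unique(hs$gene_id))) {
        res$genes <- concordance(det$genes, ext[kinds == "gene"],
                                 unique(hs$gene_id), cfg$pass_pct)
      }
      if (any(kinds == "mirna") && length(unique(hs$mirna_id))) {
        res$mirnas <- concordance(det$mirnas, ext[kinds == "mirna"],
                                  unique(hs$mirna_id), cfg$pass_pct)
      }
      res
    })
  }

  # -- optional random-forest stage evaluation
  rf <- NULL
  if (isTRUE(cfg$rf_eval)) {
    rf <- run_stage("rf_eval", {
      stages <- list(segmental = seg_gene_ids, exponential = exp_gene_ids)
      if (length(unique(hs$gene_id)) >= 1) stages$ifc <- unique(hs$gene_id)
      evals <- lapply(names(stages), function(nm) {
        evaluate_stage(det$genes, stages[[nm]], n_folds = cfg$n_folds,
                       n_trees = cfg$n_trees, seed = cfg$seed,
                       stage_name = nm)
      })
      list(evals = evals, comparison = if (length(evals) >= 2)
        compare_stages(evals) else NULL)
    })
  }

  report <- structure(list(
    funnel = funnel,
    tables = list(segmental_calls = seg_calls,
                  exp_fits = rbind(cbind(expf$gene_fits, kind = "gene"),
                                   cbind(expf$mirna_fits, kind = "mirna")),
                  candidate_pairs = cand, scores = scores,
                  high_stringency = hs, concordance = conc,
                  rf = rf),
    timings = timings, seed = cfg$seed,
    config = cfg[setdiff(names(cfg), c("genes", "mirnas", "interactions"))]),
    class = "run_report")

  if (!is.null(out_dir)) {
    report$output_files <- write_report_outputs(report, det, out_dir)
    unlink(file.path(out_dir, ".partial"))
  }
  report
}

write_report_outputs <- function(report, det, out_dir) {
  tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    utils::write.table(x, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  tb <- report$tables
  out <- c()
  if (!is.null(tb$segmental_calls)) {
    out["segmental_calls"] <- tsv(tb$segmental_calls, "segmental_calls.tsv")
  }
  out["exp_fits"] <- tsv(tb$exp_fits, "exp_fits.tsv")
  out["ranked_pairs"] <- tsv(tb$scores, "ranked_pairs.tsv")
  if (!is.null(tb$concordance$genes)) {
    out["concordance_genes"] <- tsv(tb$concordance$genes,
                                    "concordance_genes.tsv")
  }
  if (!is.null(tb$concordance$mirnas)) {
    out["concordance_mirnas"] <- tsv(tb$concordance$mirnas,
                                     "concordance_mirnas.tsv")
  }
  if (nrow(tb$high_stringency)) {
    hs_net <- merge(tb$high_stringency,
                    tb$candidate_pairs[, c("mirna_id", "gene_id",
                                           "confidence", "score")],
                    by = c("mirna_id", "gene_id"), sort = FALSE)
    dm_g <- day_means(det$genes)
    dm_m <- day_means(det$mirnas)
    fc <- c(2^(dm_g[, ncol(dm_g)] - dm_g[, 1]),
            2^(dm_m[, ncol(dm_m)] - dm_m[, 1]))
    gpath <- file.path(out_dir, "network.graphml")
    export_network(hs_net, fc, gpath)
    out["network"] <- gpath
  }
  if (!is.null(tb$rf)) {
    for (ev in tb$rf$evals) {
      out[paste0("roc_", ev$stage_name)] <-
        tsv(ev$roc_points, paste0("roc_", ev$stage_name, ".tsv"))
    }
    if (!is.null(tb$rf$comparison)) {
      out["rf_comparison"] <- tsv(tb$rf$comparison, "rf_comparison.tsv")
    }
  }
  rep_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(list(
    funnel = report$funnel,
    timings = as.list(report$timings),
    seed = report$seed,
    config = report$config[!vapply(report$config, is.null, logical(1))],
    output_files = as.list(out)),
    rep_path, auto_unbox = TRUE, digits = NA, pretty = TRUE, force = TRUE)
  out["report"] <- rep_path
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("run_report: filter funnel\n")
  print(x$funnel, row.names = FALSE)
  invisible(x)
}
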