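#' Fold-change direction between a profile's first and final days
#'
#' @param profile A [time_profile()] with >= 2 days.
#' @param epsilon Absolute log2 difference below which the transcript is
#'   called flat (default 1e-9).
#' @return `"up"`, `"down"` or `"flat"`.
#' @export
endpoint_direction <- function(profile, epsilon = 1e-9) {
  if (length(profile$days) < 2) {
    stop("endpoint_direction needs a profile with >= 2 days")
  }
  delta <- profile$mean_log2[length(profile$mean_log2)] - profile$mean_log2[1]
  if (abs(delta) < epsilon) "flat" else if (delta > 0) "up" else "down"
}

#' Cross-dataset fold-change direction concordance
#'
#' For each transcript of interest, compares the day-0-to-final-day
#' fold-change direction in the reference dataset against every external
#' dataset containing the transcript (case-insensitive id match; each
#' dataset's "final day" is its own maximum sampled day). The concordance
#' percentage is the share of available datasets agreeing with the
#' reference; a flat call on either side never counts as agreement.
#' Transcripts absent from a dataset do not count toward `n_available`.
#'
#' @param reference The reference `expression_dataset`.
#' @param externals Non-empty list of external `expression_dataset` objects.
#' @param ids Transcript ids to evaluate (default: all reference
#'   transcripts).
#' @param pass_pct Concordance percentage required to pass (default 50).
#' @param epsilon Flat-call tolerance passed to [endpoint_direction()].
#' @return Data frame: `transcript_id`, `reference_direction`,
#'   `n_available`, `n_same_direction`, `pct` (NA when the transcript is in
#'   no external dataset), `pass`.
#' @export
concordance <- function(reference, externals, ids = transcript_ids(reference),
                        pass_pct = 50, epsilon = 1e-9) {
  if (!length(externals)) stop("concordance needs >= 1 external dataset")
  ref_ids <- transcript_ids(reference)
  idx <- match(tolower(ids), tolower(ref_ids))
  if (anyNA(idx)) {
    stop("transcript(s) not in reference: ", paste(ids[is.na(idx)],
                                                   collapse = ", "))
  }
  ref_prof <- to_profiles(reference, ref_ids[idx])
  ref_dir <- vapply(ref_prof, endpoint_direction, character(1),
                    epsilon = epsilon)
  ext_dirs <- lapply(externals, function(ds) {
    prof <- to_profiles(ds)
    d <- vapply(prof, endpoint_direction, character(1), epsilon = epsilon)
    names(d) <- tolower(names(d))
    d
  })
  rows <- lapply(seq_along(ids), function(i) {
    id_lc <- tolower(ids[i])
    avail <- 0L
    same <- 0L
    for (d in ext_dirs) {
      if (!id_lc %in% names(d)) next
      avail <- avail + 1L
      if (ref_dir[i] != "flat" && d[[id_lc]] == ref_dir[i]) same <- same + 1L
    }
    pct <- if (avail > 0) 100 * same / avail else NA_real_
    data.frame(transcript_id = ids[i], reference_direction = ref_dir[i],
               n_available = avail, n_same_direction = same, pct = pct,
               pass = !is.na(pct) && pct >= pass_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Unsupervised grouping diagnostics for a transcript subset
#'
#' Quantifies how well a transcript signature separates samples by
#' differentiation day: PCA scores on the subset (first three components),
#' a Euclidean average-linkage dendrogram (also serialized as Newick so
#' grouping claims are file-diffable), and the mean silhouette width of
#' samples grouped by day.
#'
#' @param ds An `expression_dataset` with >= 3 samples.
#' @param ids Transcript subset (>= 2 ids).
#' @return List with `scores` (samples x <=3 PC matrix), `dendrogram`
#'   (`hclust`), `newick` (character), `silhouette` (scalar mean width; NA
#'   when there is only one day group).
#' @export
grouping_diagnostics <- function(ds, ids = transcript_ids(ds)) {
  if (ncol(ds$values) < 2) stop("grouping_diagnostics needs >= 2 samples")
  if (length(ids) < 2) stop("transcript subset must have >= 2 ids")
  sub <- subset_transcripts(ds, ids)
  x <- t(sub$values)
  pca <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(3L, ncol(pca$x))
  scores <- pca$x[, seq_len(k), drop = FALSE]
  d <- stats::dist(x)
  hc <- stats::hclust(d, method = "average")
  newick <- ape::write.tree(ape::as.phylo(hc))
  grp <- as.integer(factor(sub$samples$day))
  sil <- NA_real_
  if (length(unique(grp)) >= 2) {
    sw <- cluster::silhouette(grp, d)
    # silhouette is undefined when every cluster is a singleton
    if (is.matrix(sw)) sil <- mean(sw[, "sil_width"])
  }
  list(scores = scores, dendrogram = hc, newick = newick, silhouette = sil)
}
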