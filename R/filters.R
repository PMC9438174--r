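#' Define differentiation-phase segments
#'
#' A segment scheme partitions the differentiation timeline into named,
#' non-overlapping, ascending day ranges; the segmental fold-change filter is
#' applied per segment. All sampled days falling inside `[day_lo, day_hi]`
#' (inclusive) belong to the segment.
#'
#' @param name Character vector of segment names.
#' @param day_lo,day_hi Numeric vectors of segment bounds (inclusive).
#' @return A `segment_scheme` data frame.
#' @export
segment_scheme <- function(name, day_lo, day_hi) {
  if (length(name) != length(day_lo) || length(name) != length(day_hi)) {
    stop("'name', 'day_lo' and 'day_hi' must have equal length")
  }
  if (anyDuplicated(name)) stop("segment names must be unique")
  if (any(day_hi < day_lo)) stop("each segment needs day_lo <= day_hi")
  o <- order(day_lo)
  name <- name[o]; day_lo <- day_lo[o]; day_hi <- day_hi[o]
  if (length(name) > 1 && any(day_lo[-1] <= day_hi[-length(day_hi)])) {
    stop("segments must be non-overlapping and ascending")
  }
  structure(data.frame(name = as.character(name), day_lo = day_lo,
                       day_hi = day_hi, stringsAsFactors = FALSE),
            class = c("segment_scheme", "data.frame"))
}

#' Preset segment schemes for the two supported time-course designs
#'
#' `segments_long()` covers a 0-120 day course with phases: mesoderm
#' commitment (days 0-7), cardiac specification (days 10-14) and maturation
#' (days 20-120). `segments_short()` adapts the same three phases to a
#' 30-day course sampled at days 0/2/4/6/8/15/30: days 0-4, 5-8 and 9-30.
#'
#' @return A [segment_scheme()].
#' @export
segments_long <- function() {
  segment_scheme(c("mesoderm", "specification", "maturation"),
                 c(0, 10, 20), c(7, 14, 120))
}

#' @rdname segments_long
#' @export
segments_short <- function() {
  segment_scheme(c("mesoderm", "specification", "maturation"),
                 c(0, 5, 9), c(4, 8, 30))
}

#' Detection filter: require expression at a minimum number of days
#'
#' Keeps transcripts whose replicate-mean log2 value exceeds the detection
#' threshold at `min_timepoints` or more distinct days. By default the
#' threshold is the 10th percentile of the whole matrix, a deterministic
#' data-adaptive stand-in for an array detection call.
#'
#' @param ds An `expression_dataset`.
#' @param min_timepoints Minimum number of distinct days above threshold
#'   (default 6).
#' @param detect_thr Log2 detection threshold; `NULL` uses the matrix 10th
#'   percentile.
#' @return The filtered `expression_dataset` (row order preserved).
#' @export
detection_filter <- function(ds, min_timepoints = 6, detect_thr = NULL) {
  if (min_timepoints < 1) stop("'min_timepoints' must be >= 1")
  n_days <- length(dataset_days(ds))
  if (min_timepoints > n_days) {
    stop("min_timepoints (", min_timepoints, ") exceeds number of distinct days (",
         n_days, ")")
  }
  if (is.null(detect_thr)) {
    detect_thr <- stats::quantile(ds$values, 0.10, names = FALSE)
  }
  dm <- day_means(ds)
  n_detected <- rowSums(dm > detect_thr)
  keep <- rownames(dm)[n_detected >= min_timepoints]
  subset_transcripts(ds, keep)
}

#' Segmental fold-change filter
#'
#' For each transcript and each segment, computes the linear-scale fold
#' change across the segment and calls the transcript informative in that
#' segment when the fold change falls outside the `(low_thr, high_thr)`
#' window (boundaries inclusive: FC <= `low_thr` or >= `high_thr`). The
#' default `"endpoints"` strategy exponentiates the difference in day-mean
#' log2 expression between the segment's last and first sampled days; the
#' `"mean_vs_day0"` strategy compares the segment's mean level against the
#' transcript's level at the earliest sampled day of the whole course.
#'
#' @param profiles List of [time_profile()] objects (all on one day grid).
#' @param scheme A [segment_scheme()]; every segment must contain at least
#'   two distinct sampled days.
#' @param low_thr,high_thr Informative window bounds, `0 < low_thr < 1 <
#'   high_thr` (defaults 0.8 and 1.2).
#' @param strategy Fold-change definition (see above).
#' @return Data frame of calls: `transcript_id`, `segment`, `fold_change`,
#'   `direction` (`up`/`down`/`flat`), `informative`.
#' @export
segmental_fold_change <- function(profiles, scheme, low_thr = 0.8,
                                  high_thr = 1.2,
                                  strategy = c("endpoints", "mean_vs_day0")) {
  strategy <- match.arg(strategy)
  if (!(low_thr > 0 && low_thr < 1 && high_thr > 1)) {
    stop("thresholds must satisfy 0 < low_thr < 1 < high_thr")
  }
  if (!length(profiles)) {
    return(data.frame(transcript_id = character(), segment = character(),
                      fold_change = numeric(), direction = character(),
                      informative = logical()))
  }
  days <- profiles[[1]]$days
  seg_days <- lapply(seq_len(nrow(scheme)), function(i) {
    which(days >= scheme$day_lo[i] & days <= scheme$day_hi[i])
  })
  short <- lengths(seg_days) < 2
  if (any(short)) {
    stop("segment(s) with fewer than 2 sampled days: ",
         paste(scheme$name[short], collapse = ", "))
  }
  calls <- lapply(profiles, function(p) {
    if (!identical(p$days, days)) stop("profiles are not on a shared day grid")
    lfc <- vapply(seg_days, function(ix) {
      if (strategy == "endpoints") {
        p$mean_log2[ix[length(ix)]] - p$mean_log2[ix[1]]
      } else {
        mean(p$mean_log2[ix]) - p$mean_log2[1]
      }
    }, numeric(1))
    fc <- 2^lfc
    data.frame(transcript_id = p$transcript_id, segment = scheme$name,
               fold_change = fc,
               direction = ifelse(fc > 1, "up", ifelse(fc < 1, "down", "flat")),
               informative = fc <= low_thr | fc >= high_thr,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Transcript ids informative in at least one segment
#'
#' @param calls Output of [segmental_fold_change()].
#' @return Character vector of transcript ids, first-appearance order.
#' @export
informative_ids <- function(calls) {
  unique(calls$transcript_id[calls$informative])
}

#' Exact-overlap (Venn) partition of per-segment informative sets
#'
#' For every non-empty subset of segments, lists the transcripts informative
#' in exactly those segments, reproducing the usual Venn-diagram cells. The
#' cells partition the union of the per-segment informative sets.
#'
#' @param calls Output of [segmental_fold_change()] covering >= 2 segments.
#' @return Data frame with `segments` (segment names joined by `+`),
#'   `n_transcripts` and `transcript_ids` (ids joined by `;`); the named
#'   membership list is attached as attribute `"sets"`.
#' @export
segment_overlap <- function(calls) {
  segs <- unique(calls$segment)
  if (length(segs) < 2) stop("segment_overlap needs calls from >= 2 segments")
  inf <- calls[calls$informative, , drop = FALSE]
  member <- split(inf$segment, inf$transcript_id)
  key <- vapply(member, function(s) paste(segs[segs %in% s], collapse = "+"),
                character(1))
  sets <- split(names(member), key)
  keys <- unlist(lapply(seq_along(segs), function(k) {
    utils::combn(segs, k, paste, collapse = "+")
  }))
  keys <- keys[keys %in% names(sets)]
  sets <- sets[keys]
  out <- data.frame(
    segments = keys,
    n_transcripts = vapply(sets, length, integer(1)),
    transcript_ids = vapply(sets, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "sets") <- sets
  out
}
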