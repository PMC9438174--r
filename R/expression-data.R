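#' Construct an expression dataset
#'
#' Bundles a log2 expression matrix (transcripts x samples) with per-sample
#' time-course metadata. This is the container every pipeline stage consumes.
#'
#' @param values Numeric matrix of log2 expression, rows = transcripts (with
#'   unique rownames), columns = samples (with colnames matching
#'   `samples$sample_id`, in the same order).
#' @param samples Data frame with columns `sample_id` (unique character),
#'   `day` (non-negative numeric differentiation day) and `replicate`
#'   (positive integer).
#' @param kind `"gene"` or `"mirna"`; the transcript kind held by the matrix.
#'
#' @return An object of class `expression_dataset` with elements `kind`,
#'   `values` and `samples`.
#' @export
expression_dataset <- function(values, samples, kind = c("gene", "mirna")) {
  kind <- match.arg(kind)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values))) stop("'values' must have transcript rownames")
  if (anyDuplicated(rownames(values))) {
    dup <- unique(rownames(values)[duplicated(rownames(values))])
    stop("duplicate transcript id(s): ", paste(dup, collapse = ", "))
  }
  if (!all(is.finite(values))) stop("expression values must all be finite")
  req <- c("sample_id", "day", "replicate")
  if (!all(req %in% names(samples))) {
    stop("'samples' must have columns ", paste(req, collapse = ", "))
  }
  samples <- as.data.frame(samples)[, req]
  samples$sample_id <- as.character(samples$sample_id)
  samples$day <- as.numeric(samples$day)
  samples$replicate <- as.integer(samples$replicate)
  if (anyDuplicated(samples$sample_id)) stop("duplicate sample_id in metadata")
  if (any(samples$day < 0)) stop("'day' must be non-negative")
  if (any(samples$replicate < 1)) stop("'replicate' must be >= 1")
  if (ncol(values) != nrow(samples)) {
    stop("column count (", ncol(values), ") != sample count (", nrow(samples), ")")
  }
  if (!is.null(colnames(values)) && !identical(colnames(values), samples$sample_id)) {
    stop("matrix column names do not match metadata sample ids (same order required)")
  }
  colnames(values) <- samples$sample_id
  rownames(samples) <- NULL
  structure(list(kind = kind, values = values, samples = samples),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset (%s): %d transcripts x %d samples\n",
              x$kind, nrow(x$values), ncol(x$values)))
  cat(sprintf("  days: %s; replicates per day: %s\n",
              paste(sort(unique(x$samples$day)), collapse = ", "),
              paste(as.integer(table(x$samples$day)), collapse = "/")))
  invisible(x)
}

#' Transcript and sample accessors
#' @param ds An `expression_dataset`.
#' @return `transcript_ids()`: character vector of row ids; `dataset_days()`:
#'   sorted unique differentiation days.
#' @export
transcript_ids <- function(ds) rownames(ds$values)

#' @rdname transcript_ids
#' @export
dataset_days <- function(ds) sort(unique(ds$samples$day))

#' Read a time-course expression dataset from TSV files
#'
#' The matrix file is tab-delimited with a header row of sample ids and a
#' first column (`id`) of transcript ids. The metadata file maps every sample
#' id to its differentiation day and replicate number. Samples are reordered
#' by (day, replicate); transcripts keep file order. Missing values are
#' rejected at load (the cascade assumes complete matrices); `missing =
#' "drop"` removes offending rows instead.
#'
#' @param matrix_path Path to the expression TSV.
#' @param meta_path Path to the metadata TSV (columns `sample_id`, `day`,
#'   `replicate`).
#' @param kind `"gene"` or `"mirna"`.
#' @param missing `"error"` (default) or `"drop"` rows containing NA.
#' @return An [expression_dataset()].
#' @export
read_expression <- function(matrix_path, meta_path, kind = c("gene", "mirna"),
                            missing = c("error", "drop")) {
  kind <- match.arg(kind)
  missing <- match.arg(missing)
  mat <- utils::read.delim(matrix_path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(mat) < 2) stop("expression matrix needs an id column plus samples")
  ids <- as.character(mat[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate transcript id(s) in ", matrix_path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  values <- as.matrix(mat[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- ids
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  req <- c("sample_id", "day", "replicate")
  if (!all(req %in% names(meta))) {
    stop("metadata must have columns ", paste(req, collapse = ", "))
  }
  meta$sample_id <- as.character(meta$sample_id)
  absent <- setdiff(colnames(values), meta$sample_id)
  if (length(absent)) {
    stop("sample(s) in matrix absent from metadata: ",
         paste(absent, collapse = ", "))
  }
  meta <- meta[meta$sample_id %in% colnames(values), , drop = FALSE]
  meta <- meta[order(meta$day, meta$replicate, meta$sample_id), , drop = FALSE]
  values <- values[, meta$sample_id, drop = FALSE]
  bad <- rowSums(is.na(values)) > 0
  if (any(bad)) {
    if (missing == "error") {
      stop("missing values in transcript(s): ",
           paste(utils::head(ids[bad], 5), collapse = ", "))
    }
    values <- values[!bad, , drop = FALSE]
  }
  expression_dataset(values, meta, kind)
}

#' Write an expression dataset back to TSV files
#'
#' Mirrors [read_expression()] bit-exactly for finite doubles: values are
#' printed with `%.17g` so a write/read round trip reproduces the matrix.
#'
#' @param ds An `expression_dataset`.
#' @param matrix_path,meta_path Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_expression <- function(ds, matrix_path, meta_path) {
  vals <- apply(ds$values, 2, function(col) sprintf("%.17g", col))
  out <- cbind(id = rownames(ds$values), vals)
  utils::write.table(out, matrix_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ds$samples, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(matrix_path, meta_path))
}

#' Quantile-normalize an expression dataset
#'
#' Forces every sample (column) onto the identical distribution: the value at
#' each within-column rank becomes the across-column mean of that rank's
#' values. Within-column ties receive the mean of the tied ranks' means.
#'
#' @param ds An `expression_dataset` with at least two samples.
#' @return A quantile-normalized `expression_dataset` with labels preserved.
#' @export
quantile_normalize <- function(ds) {
  if (ncol(ds$values) < 2) stop("quantile normalization needs >= 2 samples")
  norm <- limma::normalizeQuantiles(ds$values, ties = TRUE)
  dimnames(norm) <- dimnames(ds$values)
  expression_dataset(norm, ds$samples, ds$kind)
}

#' Construct a per-transcript time profile
#'
#' @param transcript_id Transcript identifier.
#' @param days Strictly increasing numeric vector of sampled days.
#' @param mean_log2 Per-day replicate-mean log2 expression (same length).
#' @param per_replicate Optional list (one numeric vector per day) of the
#'   replicate-level values behind each mean.
#' @return An object of class `time_profile`.
#' @export
time_profile <- function(transcript_id, days, mean_log2, per_replicate = NULL) {
  if (length(days) != length(mean_log2)) {
    stop("'days' and 'mean_log2' must have equal length")
  }
  if (any(diff(days) <= 0)) stop("'days' must be strictly increasing")
  if (!is.null(per_replicate) && length(per_replicate) != length(days)) {
    stop("'per_replicate' must have one element per day")
  }
  structure(list(transcript_id = as.character(transcript_id),
                 days = as.numeric(days), mean_log2 = as.numeric(mean_log2),
                 per_replicate = per_replicate),
            class = "time_profile")
}

#' @export
print.time_profile <- function(x, ...) {
  cat(sprintf("time_profile %s over %d days [%g..%g]\n", x$transcript_id,
              length(x$days), min(x$days), max(x$days)))
  invisible(x)
}

#' Collapse a dataset to per-transcript day-mean time profiles
#'
#' The mean log2 value at each day is the arithmetic mean across that day's
#' replicates; replicate-level values are retained in `per_replicate`.
#'
#' @param ds An `expression_dataset`.
#' @param ids Optional subset of transcript ids (default: all).
#' @return Named list of [time_profile()] objects, in dataset row order.
#' @export
to_profiles <- function(ds, ids = NULL) {
  if (is.null(ids)) ids <- transcript_ids(ds)
  miss <- setdiff(ids, transcript_ids(ds))
  if (length(miss)) stop("unknown transcript id(s): ", paste(miss, collapse = ", "))
  day <- ds$samples$day
  days <- sort(unique(day))
  cols_by_day <- lapply(days, function(d) which(day == d))
  vals <- ds$values[ids, , drop = FALSE]
  means <- vapply(cols_by_day,
                  function(ix) rowMeans(vals[, ix, drop = FALSE]),
                  numeric(length(ids)))
  if (length(ids) == 1L) means <- matrix(means, nrow = 1)
  profiles <- lapply(seq_along(ids), function(i) {
    per_rep <- lapply(cols_by_day, function(ix) unname(vals[i, ix]))
    time_profile(ids[i], days, means[i, ], per_rep)
  })
  names(profiles) <- ids
  profiles
}

#' Day-mean matrix of a dataset
#'
#' @param ds An `expression_dataset`.
#' @return Numeric matrix transcripts x distinct days (column names are the
#'   days), each entry the replicate-mean log2 expression.
#' @export
day_means <- function(ds) {
  day <- ds$samples$day
  days <- sort(unique(day))
  m <- vapply(days, function(d) {
    rowMeans(ds$values[, day == d, drop = FALSE])
  }, numeric(nrow(ds$values)))
  if (nrow(ds$values) == 1L) m <- matrix(m, nrow = 1)
  dimnames(m) <- list(rownames(ds$values), as.character(days))
  m
}

#' Subset an expression dataset by transcript ids
#'
#' @param ds An `expression_dataset`.
#' @param ids Transcript ids to keep; dataset row order is preserved.
#' @return The subsetted `expression_dataset`.
#' @export
subset_transcripts <- function(ds, ids) {
  keep <- transcript_ids(ds) %in% ids
  if (!any(keep)) stop("no transcripts left after subsetting")
  expression_dataset(ds$values[keep, , drop = FALSE], ds$samples, ds$kind)
}
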