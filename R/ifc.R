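#' Pearson correlation with a t-based two-sided p-value
#'
#' The sample Pearson correlation together with the classical two-sided
#' p-value from the t transform \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on
#' \eqn{n-2} degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length `n >= 3` with non-zero
#'   variance.
#' @return List with elements `r`, `p` and `n`.
#' @export
pearson_with_p <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  n <- length(x)
  if (n < 3) stop("pearson_with_p needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in 'x' or 'y'")
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) {
    p <- 0
  } else {
    t_stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Classify the joint temporal profile of a gene-miRNA pair
#'
#' The trend of each transcript is the sign of the ordinary least-squares
#' slope of day-mean log2 expression on day. Profile 1 is a rising gene with
#' a falling miRNA; Profile 2 is the mirror; anything else is `"none"`.
#'
#' @param gene_profile,mirna_profile [time_profile()] objects on >= 3 days.
#' @return `"profile1"`, `"profile2"` or `"none"`.
#' @export
classify_profile <- function(gene_profile, mirna_profile) {
  slope <- function(p) {
    if (length(p$days) < 3) stop("classify_profile needs profiles on >= 3 days")
    stats::cov(p$days, p$mean_log2) / stats::var(p$days)
  }
  gs <- slope(gene_profile)
  ms <- slope(mirna_profile)
  if (gs > 0 && ms < 0) "profile1" else if (gs < 0 && ms > 0) "profile2" else "none"
}

#' Score candidate pairs for inverse fold-change (iFC) behavior
#'
#' For every interaction pair, correlates the gene and miRNA day-mean log2
#' trajectories over their shared days (Pearson by default). Pairs with a
#' negative correlation are `validated`; the `high_stringency` set further
#' requires `pearson_r < r_cut` (strict) and `p_value < p_cut`. Output is
#' sorted by ascending correlation (most negative first), with ties broken
#' lexicographically by (gene_id, mirna_id) so files are deterministic.
#' Benjamini-Hochberg adjusted p-values are emitted alongside the raw ones.
#'
#' @param pairs Interaction data frame (`mirna_id`, `gene_id`, ...).
#' @param gene_profiles,mirna_profiles Named lists of [time_profile()]
#'   objects covering the pair endpoints.
#' @param r_cut High-stringency correlation cutoff (default -0.5, strict
#'   `<`).
#' @param p_cut High-stringency p-value cutoff (default 1, i.e. inactive:
#'   the selection rule is the correlation threshold alone).
#' @param method `"pearson"` (default) or `"kendall"` (exploratory
#'   alternative statistic).
#' @param use_replicates If `TRUE`, correlate replicate-level values instead
#'   of day means (requires profiles with `per_replicate`).
#' @return Data frame of scores: `mirna_id`, `gene_id`, `pearson_r`,
#'   `p_value`, `p_adj`, `profile`, `validated`, `high_stringency`. Pairs
#'   with zero variance in either endpoint are dropped with a warning.
#' @export
score_pairs <- function(pairs, gene_profiles, mirna_profiles, r_cut = -0.5,
                        p_cut = 1, method = c("pearson", "kendall"),
                        use_replicates = FALSE) {
  method <- match.arg(method)
  rows <- vector("list", nrow(pairs))
  dropped <- character()
  for (i in seq_len(nrow(pairs))) {
    gid <- pairs$gene_id[i]
    mid <- pairs$mirna_id[i]
    gp <- gene_profiles[[gid]]
    mp <- mirna_profiles[[mid]]
    if (is.null(gp) || is.null(mp)) {
      stop("no profile for pair ", mid, " -> ", gid)
    }
    shared <- intersect(gp$days, mp$days)
    if (length(shared) < 3) {
      stop("day grids not alignable (fewer than 3 shared days) for pair ",
           mid, " -> ", gid)
    }
    gi <- match(shared, gp$days)
    mi <- match(shared, mp$days)
    if (use_replicates) {
      if (is.null(gp$per_replicate) || is.null(mp$per_replicate)) {
        stop("use_replicates = TRUE needs per-replicate profiles")
      }
      x <- unlist(gp$per_replicate[gi])
      y <- unlist(mp$per_replicate[mi])
      if (length(x) != length(y)) {
        stop("replicate structure differs between endpoints of pair ",
             mid, " -> ", gid)
      }
    } else {
      x <- gp$mean_log2[gi]
      y <- mp$mean_log2[mi]
    }
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      dropped <- c(dropped, paste0(mid, "->", gid))
      next
    }
    if (method == "pearson") {
      s <- pearson_with_p(x, y)
      r <- s$r; p <- s$p
    } else {
      ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall"))
      r <- unname(ct$estimate); p <- ct$p.value
    }
    gsub <- time_profile(gid, shared, gp$mean_log2[gi])
    msub <- time_profile(mid, shared, mp$mean_log2[mi])
    rows[[i]] <- data.frame(
      mirna_id = mid, gene_id = gid, pearson_r = r, p_value = p,
      profile = classify_profile(gsub, msub), stringsAsFactors = FALSE)
  }
  if (length(dropped)) {
    warning("pair(s) with zero variance excluded: ",
            paste(dropped, collapse = ", "))
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(mirna_id = character(), gene_id = character(),
                      pearson_r = numeric(), p_value = numeric(),
                      profile = character(), stringsAsFactors = FALSE)
  }
  out$p_adj <- stats::p.adjust(out$p_value, method = "BH")
  out$validated <- out$pearson_r < 0
  out$high_stringency <- out$pearson_r < r_cut & out$p_value < p_cut
  out <- out[order(out$pearson_r, out$gene_id, out$mirna_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out[, c("mirna_id", "gene_id", "pearson_r", "p_value", "p_adj", "profile",
          "validated", "high_stringency")]
}
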