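#' Fit a two-term exponential trajectory to a time profile
#'
#' Models the day-mean log2 trajectory as
#' \deqn{y(t') = a e^{b t'} + c e^{d t'}}
#' where \eqn{t'} is the day axis rescaled to \[0, 1\] for conditioning.
#' Fitting uses variable projection: for fixed rate constants `(b, d)` the
#' linear coefficients `(a, c)` have a closed-form least-squares solution, so
#' only `(b, d)` are optimized (L-BFGS-B, box \[-30, 30\]) from a
#' deterministic grid of sign/scale starting points. The best converged start
#' (lowest SSE) is reported, so results are reproducible without seeds.
#'
#' Goodness of fit is reported two ways: `r_goodness`, the Pearson
#' correlation between fitted and observed values, and `r_squared`,
#' \eqn{1 - SSE/SST}. The pass decision uses `r_squared` by default — curve
#' fits are conventionally judged on the fraction of variance explained, and
#' with only a handful of time points a four-parameter model correlates
#' appreciably with pure noise — with `goodness = "r"` available to threshold
#' the correlation instead.
#'
#' @param profile A [time_profile()] with at least 5 time points.
#' @param r_threshold Pass threshold on the chosen goodness statistic
#'   (default 0.7, inclusive).
#' @param n_starts Number of deterministic `(b, d)` initializations (1-8,
#'   default 8).
#' @param goodness `"r2"` (default) or `"r"`: the statistic compared against
#'   `r_threshold`.
#' @return An `exp_fit_result` list: `transcript_id`, coefficients `a`, `b`,
#'   `c`, `d` (in rescaled time), `r_goodness`, `r_squared`, `sse`,
#'   `converged`, `passed`.
#' @export
fit_exp2 <- function(profile, r_threshold = 0.7, n_starts = 8,
                     goodness = c("r2", "r")) {
  goodness <- match.arg(goodness)
  t <- profile$days
  y <- profile$mean_log2
  if (length(t) < 5) {
    stop("fit_exp2 needs >= 5 time points (4 coefficients); got ", length(t))
  }
  tr <- (t - min(t)) / (max(t) - min(t))
  sse_of <- function(bd) {
    X <- cbind(exp(pmin(pmax(bd[1] * tr, -300), 300)),
               exp(pmin(pmax(bd[2] * tr, -300), 300)))
    f <- tryCatch(stats::lm.fit(X, y), error = function(e) NULL)
    if (is.null(f)) return(Inf)
    co <- f$coefficients
    co[is.na(co)] <- 0
    sum((y - X %*% co)^2)
  }
  starts <- list(c(0.5, -0.5), c(2, -2), c(5, -5), c(1, 0),
                 c(-1, 0), c(2, 0.5), c(-2, -0.5), c(5, 1))
  n_starts <- max(1L, min(as.integer(n_starts), length(starts)))
  best <- NULL
  for (s in starts[seq_len(n_starts)]) {
    o <- tryCatch(
      stats::optim(s, sse_of, method = "L-BFGS-B", lower = -30, upper = 30),
      error = function(e) NULL)
    if (is.null(o) || !is.finite(o$value)) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  res <- list(transcript_id = profile$transcript_id,
              a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
              r_goodness = NA_real_, r_squared = NA_real_, sse = NA_real_,
              converged = FALSE, passed = FALSE)
  class(res) <- "exp_fit_result"
  if (is.null(best)) return(res)
  bd <- best$par
  X <- cbind(exp(bd[1] * tr), exp(bd[2] * tr))
  f <- stats::lm.fit(X, y)
  co <- f$coefficients
  co[is.na(co)] <- 0
  fitted <- as.vector(X %*% co)
  sse <- sum((y - fitted)^2)
  sst <- sum((y - mean(y))^2)
  r <- suppressWarnings(stats::cor(fitted, y))
  if (!is.finite(r)) r <- 0
  r2 <- if (sst > 0) 1 - sse / sst else as.numeric(sse < 1e-12)
  res$a <- unname(co[1]); res$b <- bd[1]; res$c <- unname(co[2]); res$d <- bd[2]
  res$r_goodness <- r
  res$r_squared <- r2
  res$sse <- sse
  res$converged <- TRUE
  stat <- if (goodness == "r2") r2 else r
  res$passed <- stat >= r_threshold
  res
}

#' @export
print.exp_fit_result <- function(x, ...) {
  cat(sprintf("exp_fit_result %s: R=%.4f R2=%.4f SSE=%.3g %s\n",
              x$transcript_id, x$r_goodness, x$r_squared, x$sse,
              if (x$passed) "PASSED" else "not passed"))
  invisible(x)
}

#' Fit the two-term exponential model to many profiles
#'
#' @inheritParams fit_exp2
#' @param profiles List of [time_profile()] objects.
#' @return Data frame with one row per profile: `transcript_id`, `a`, `b`,
#'   `c`, `d`, `r_goodness`, `r_squared`, `sse`, `converged`, `passed`.
#' @export
fit_exp2_all <- function(profiles, r_threshold = 0.7, n_starts = 8,
                         goodness = c("r2", "r")) {
  goodness <- match.arg(goodness)
  rows <- lapply(profiles, function(p) {
    f <- fit_exp2(p, r_threshold = r_threshold, n_starts = n_starts,
                  goodness = goodness)
    data.frame(transcript_id = f$transcript_id, a = f$a, b = f$b, c = f$c,
               d = f$d, r_goodness = f$r_goodness, r_squared = f$r_squared,
               sse = f$sse, converged = f$converged, passed = f$passed,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Exponential-trajectory filter
#'
#' Retains the transcripts whose two-term exponential fit passes the goodness
#' threshold, preserving input order.
#'
#' @inheritParams fit_exp2_all
#' @return Character vector of surviving transcript ids.
#' @export
exponential_filter <- function(profiles, r_threshold = 0.7, n_starts = 8,
                               goodness = c("r2", "r")) {
  if (!length(profiles)) return(character())
  fits <- fit_exp2_all(profiles, r_threshold = r_threshold,
                       n_starts = n_starts, goodness = goodness)
  fits$transcript_id[fits$passed]
}
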