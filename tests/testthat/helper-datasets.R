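# Shared fixture builders: everything is generated in code at test time.

# Dataset with the given day/replicate design from a transcripts x samples
# matrix (columns ordered by day, then replicate).
make_ds <- function(values, days, reps = 1, kind = "gene",
                    ids = sprintf("T%02d", seq_len(nrow(values)))) {
  day_vec <- rep(days, each = reps)
  rep_vec <- rep(seq_len(reps), times = length(days))
  samples <- data.frame(sample_id = sprintf("d%g_r%d", day_vec, rep_vec),
                        day = day_vec, replicate = rep_vec)
  rownames(values) <- ids
  colnames(values) <- samples$sample_id
  expression_dataset(values, samples, kind)
}

# A profile from day-mean values on the default 7-day design.
mk_profile <- function(id, mean_log2, days = c(0, 2, 4, 6, 8, 15, 30)) {
  time_profile(id, days, mean_log2)
}

# The saturating latent trajectory used by the generator's exp2 shape,
# recomputed independently for expected-value checks.
sat_exp <- function(days, amplitude = 3) {
  t01 <- (days - min(days)) / (max(days) - min(days))
  amplitude * (1 - exp(-3 * t01)) / (1 - exp(-3))
}

# Long multi-phase reference design (13 time points over 120 days).
long_days <- c(0, 3, 7, 10, 12, 14, 20, 28, 35, 45, 60, 90, 120)

# Small long-design synthetic bundle for RF/grouping checks.
long_bundle <- function(seed = 7, n_bg_genes = 100, n_bg_mirnas = 20) {
  generate_timecourse(synth_config(
    days = long_days, n_background_genes = n_bg_genes,
    n_background_mirnas = n_bg_mirnas, decoy_edges = 50, seed = seed))
}

# Shuffle the day labels of a dataset (stratification-preserving relabel).
permute_days <- function(ds, seed) {
  set.seed(seed)
  s <- ds$samples
  s$day <- sample(s$day)
  expression_dataset(ds$values, s, ds$kind)
}
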