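# Shared fixture builders; everything is generated in code under fixed seeds.

small_config <- function(...) {
  defaults <- list(n_batches = 3, samples_per_batch = c(60, 60, 60),
                   case_fraction_per_batch = c(0.5, 0.6, 0.4),
                   n_probes = 300, n_signal_probes = 20, effect_size_m = 1,
                   batch_mean_shift_sd = 0.5, noise_sd = 0.5, seed = 42)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

# Plain two-group dataset without simulator machinery, for unit tests.
toy_dataset <- function(n = 20, p = 50, effect = 0, seed = 1,
                        scale = "M", n_signal = 5) {
  set.seed(seed)
  v <- matrix(rnorm(n * p), n, p)
  status <- rep(c("case", "control"), length.out = n)
  if (effect != 0 && n_signal > 0)
    v[status == "case", seq_len(n_signal)] <-
      v[status == "case", seq_len(n_signal)] + effect
  if (scale == "beta") v <- m_to_beta(v)
  samples <- data.frame(sample_id = sprintf("s%03d", 1:n), status = status,
                        age = round(runif(n, 20, 70)),
                        sex = sample(c("F", "M"), n, replace = TRUE),
                        batch = "b1")
  chr_idx <- rep(1:5, each = ceiling(p / 5))[1:p]
  probes <- data.frame(probe_id = sprintf("cg%05d", 1:p),
                       chrom = paste0("chr", chr_idx),
                       pos = as.integer(ave(1:p, chr_idx, FUN = seq_along)))
  methyl_dataset(v, scale, samples, probes)
}
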