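#' Configuration for a simulated multi-batch methylation study
#'
#' Defaults emulate the structure of a pooled eight-cohort blood methylation
#' case/control study: 8 batches totalling 1942 samples with a pooled case
#' fraction near 0.58 but per-batch imbalance, per-batch mean/variance shifts
#' on the M scale, a six-cell-type blood mixture, and a desk-scale probe
#' universe of 5000 CpGs.
#'
#' @param n_batches number of cohort batches (default 8).
#' @param samples_per_batch integer vector of per-batch sample counts.
#' @param case_fraction_per_batch per-batch case proportions in \[0, 1\].
#' @param n_probes probe universe size (default 5000).
#' @param n_signal_probes number of probes with a planted case effect.
#' @param effect_size_m planted case-minus-control difference, M-value units.
#' @param batch_mean_shift_sd SD of the per-batch additive mean shift (M units).
#' @param batch_var_scale_range length-2 range from which each batch's noise
#'   variance multiplier is drawn (low <= high).
#' @param batch_confound coefficient coupling a batch's mean shift to its case
#'   fraction (`shift += batch_confound * (cf_b - mean(cf))`); 0 disables
#'   confounding between batch and class.
#' @param n_celltypes number of blood cell types in the mixture (default 6).
#' @param dirichlet_alpha_case,dirichlet_alpha_control Dirichlet concentration
#'   vectors for the per-sample cell mixtures. Defaults are a granulocyte-
#'   dominant whole-blood composition, identical for both classes (no cell
#'   confounding unless the user sets them apart).
#' @param age_range length-2 range of ages (years).
#' @param sex_ratio proportion of female samples.
#' @param noise_sd residual Gaussian noise SD on the M scale.
#' @param seed integer seed governing the whole study.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_batches = 8,
                       samples_per_batch = c(rep(243L, 6), 242L, 242L),
                       case_fraction_per_batch =
                         c(0.70, 0.45, 0.62, 0.50, 0.66, 0.40, 0.75, 0.56),
                       n_probes = 5000,
                       n_signal_probes = 100,
                       effect_size_m = 0.5,
                       batch_mean_shift_sd = 0.5,
                       batch_var_scale_range = c(0.8, 1.25),
                       batch_confound = 0,
                       n_celltypes = 6,
                       dirichlet_alpha_case = c(3, 4.5, 1.5, 2.4, 2.4, 16.2),
                       dirichlet_alpha_control = dirichlet_alpha_case,
                       age_range = c(18, 75),
                       sex_ratio = 0.5,
                       noise_sd = 1.0,
                       seed = 1L) {
  cfg <- list(n_batches = as.integer(n_batches),
              samples_per_batch = as.integer(samples_per_batch),
              case_fraction_per_batch = case_fraction_per_batch,
              n_probes = as.integer(n_probes),
              n_signal_probes = as.integer(n_signal_probes),
              effect_size_m = effect_size_m,
              batch_mean_shift_sd = batch_mean_shift_sd,
              batch_var_scale_range = batch_var_scale_range,
              batch_confound = batch_confound,
              n_celltypes = as.integer(n_celltypes),
              dirichlet_alpha_case = dirichlet_alpha_case,
              dirichlet_alpha_control = dirichlet_alpha_control,
              age_range = age_range,
              sex_ratio = sex_ratio,
              noise_sd = noise_sd,
              seed = as.integer(seed))
  with(cfg, {
    if (n_batches < 1 || n_probes < 1 || n_celltypes < 2)
      stop("counts must be positive (and n_celltypes >= 2)")
    if (length(samples_per_batch) != n_batches ||
        length(case_fraction_per_batch) != n_batches)
      stop("samples_per_batch and case_fraction_per_batch must have length ",
           n_batches)
    if (any(samples_per_batch < 1)) stop("batch sizes must be positive")
    if (any(case_fraction_per_batch < 0 | case_fraction_per_batch > 1))
      stop("case fractions must lie in [0, 1]")
    if (n_signal_probes > n_probes)
      stop("n_signal_probes must not exceed n_probes")
    if (batch_var_scale_range[1] > batch_var_scale_range[2] ||
        batch_var_scale_range[1] <= 0)
      stop("batch_var_scale_range must be positive with low <= high")
    if (length(dirichlet_alpha_case) != n_celltypes ||
        length(dirichlet_alpha_control) != n_celltypes)
      stop("Dirichlet alpha vectors must have length n_celltypes")
    if (any(dirichlet_alpha_case <= 0) || any(dirichlet_alpha_control <= 0))
      stop("Dirichlet alphas must be positive")
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("sim_config:", x$n_batches, "batches,", sum(x$samples_per_batch),
      "samples,", x$n_probes, "probes (", x$n_signal_probes, "signal )\n")
  cat("  effect", x$effect_size_m, "M-units; noise SD", x$noise_sd,
      "; batch shift SD", x$batch_mean_shift_sd, "\n")
  invisible(x)
}

default_celltype_names <- function(k) {
  base <- c("CD8T", "CD4T", "NK", "B", "Mono", "Gran")
  if (k <= length(base)) base[seq_len(k)] else
    c(base, paste0("CT", seq_len(k - length(base))))
}

# Dirichlet draws via normalized gammas.
rdirichlet <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              nrow = n, byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic cell-type methylation reference panel
#'
#' Builds a celltype-by-probe matrix of reference beta-values. A leading
#' block of discriminating probes (at least 100 where the probe universe
#' allows) is constructed with a guaranteed between-celltype beta spread of
#' at least 0.3, so that constrained-projection deconvolution is well posed;
#' the remaining probes carry only small celltype jitter. The indices of the
#' discriminating block are recorded in the `discriminating` element.
#'
#' @param n_probes number of probes in the panel.
#' @param n_celltypes number of cell types (>= 2).
#' @param seed integer seed.
#' @return An object of class `cell_reference_panel` with elements
#'   `celltypes`, `reference_beta` (celltype x probe), `discriminating`.
#' @export
generate_reference_panel <- function(n_probes, n_celltypes = 6, seed = 1L) {
  if (n_probes < 1 || n_celltypes < 2)
    stop("n_probes must be positive and n_celltypes >= 2")
  set.seed(seed)
  k <- n_celltypes
  n_disc <- min(n_probes, max(100L, ceiling(0.1 * n_probes)))
  R <- matrix(NA_real_, k, n_probes)
  # discriminating probes: force one low and one high celltype per probe
  for (j in seq_len(n_disc)) {
    lo <- stats::runif(1, 0.05, 0.35)
    hi <- lo + stats::runif(1, 0.30, 0.55)
    vals <- stats::runif(k, lo, hi)
    which2 <- sample.int(k, 2)
    vals[which2[1]] <- lo
    vals[which2[2]] <- hi
    R[, j] <- vals
  }
  if (n_disc < n_probes) {
    rest <- (n_disc + 1):n_probes
    base <- stats::runif(length(rest), 0.1, 0.9)
    jit <- matrix(stats::rnorm(k * length(rest), 0, 0.02), k)
    R[, rest] <- pmin(pmax(rep(base, each = k) + jit, 0), 1)
  }
  rownames(R) <- default_celltype_names(k)
  colnames(R) <- sprintf("cg%08d", seq_len(n_probes))
  structure(list(celltypes = rownames(R), reference_beta = R,
                 discriminating = seq_len(n_disc)),
            class = "cell_reference_panel")
}

# Per-batch technical parameters, drawn once per study from the config seed so
# that generate_batch() and generate_study() agree.
draw_batch_params <- function(config) {
  set.seed(config$seed + 77003L)
  shift <- stats::rnorm(config$n_batches, 0, config$batch_mean_shift_sd)
  cf <- config$case_fraction_per_batch
  shift <- shift + config$batch_confound * (cf - mean(cf))
  vs <- stats::runif(config$n_batches,
                     config$batch_var_scale_range[1],
                     config$batch_var_scale_range[2])
  data.frame(batch = paste0("batch", seq_len(config$n_batches)),
             mean_shift = shift, var_scale = vs)
}

draw_signal_probes <- function(config) {
  set.seed(config$seed + 90001L)
  sort(sample.int(config$n_probes, config$n_signal_probes))
}

# Probe annotation: contiguous blocks on synthetic autosomes chr1..chr22,
# consecutive 1-based positions within each chromosome.
synthetic_probe_annotation <- function(n_probes) {
  per <- ceiling(n_probes / 22)
  chrom_idx <- rep(seq_len(22), each = per)[seq_len(n_probes)]
  pos <- stats::ave(seq_len(n_probes), chrom_idx, FUN = seq_along)
  data.frame(probe_id = sprintf("cg%08d", seq_len(n_probes)),
             chrom = paste0("chr", chrom_idx),
             pos = as.integer(pos))
}

# Half-up rounding for case counts (round() in R rounds half to even).
round_half_up <- function(x) floor(x + 0.5)

#' Generate one simulated cohort batch
#'
#' The M-scale signal model per sample i and probe j is
#' `M_ij = logit2(mixture beta) + effect * case_i * signal_j + shift_b + e_ij`
#' with `e_ij ~ N(0, noise_sd^2 * var_scale_b)`: a cell-mixture baseline from
#' the reference panel, a planted case effect at the signal probes, a batch
#' mean shift, and batch-scaled Gaussian noise. Case counts are
#' `round_half_up(case_fraction * n)`.
#'
#' @param config a [sim_config].
#' @param batch_index 1-based batch number (<= `n_batches`).
#' @param panel a [generate_reference_panel()] panel with `n_probes` probes.
#' @param seed seed for this batch's draws; defaults to
#'   `config$seed + batch_index`.
#' @return List with elements `dataset` (a [methyl_dataset] on the M scale)
#'   and `truth` (a `ground_truth` for this batch).
#' @export
generate_batch <- function(config, batch_index, panel,
                           seed = config$seed + batch_index) {
  stopifnot(inherits(config, "sim_config"),
            inherits(panel, "cell_reference_panel"))
  if (batch_index < 1 || batch_index > config$n_batches)
    stop("batch_index must lie in 1..n_batches")
  if (ncol(panel$reference_beta) != config$n_probes)
    stop("panel has ", ncol(panel$reference_beta),
         " probes but config expects ", config$n_probes)
  bp <- draw_batch_params(config)[batch_index, ]
  signal <- draw_signal_probes(config)

  set.seed(seed)
  n <- config$samples_per_batch[batch_index]
  n_case <- round_half_up(config$case_fraction_per_batch[batch_index] * n)
  status <- c(rep("case", n_case), rep("control", n - n_case))
  is_case <- status == "case"
  k <- config$n_celltypes

  props <- matrix(NA_real_, n, k, dimnames = list(NULL, panel$celltypes))
  if (any(is_case))
    props[is_case, ] <- rdirichlet(sum(is_case), config$dirichlet_alpha_case)
  if (any(!is_case))
    props[!is_case, ] <- rdirichlet(sum(!is_case),
                                    config$dirichlet_alpha_control)

  M <- beta_to_m(props %*% panel$reference_beta)     # mixture baseline
  M[is_case, signal] <- M[is_case, signal] + config$effect_size_m
  M <- M + bp$mean_shift +
    matrix(stats::rnorm(n * config$n_probes, 0,
                        config$noise_sd * sqrt(bp$var_scale)),
           n, config$n_probes)

  ids <- sprintf("%s_s%03d", bp$batch, seq_len(n))
  samples <- data.frame(
    sample_id = ids, status = status,
    age = round(stats::runif(n, config$age_range[1], config$age_range[2]), 1),
    sex = ifelse(stats::runif(n) < config$sex_ratio, "F", "M"),
    batch = bp$batch)
  rownames(M) <- ids
  rownames(props) <- ids
  probes <- synthetic_probe_annotation(config$n_probes)
  ds <- methyl_dataset(M, "M", samples, probes)

  sig_ids <- probes$probe_id[signal]
  effect <- stats::setNames(rep(config$effect_size_m, length(signal)), sig_ids)
  truth <- structure(list(signal_probe_ids = sig_ids,
                          per_probe_effect = effect,
                          batch_shifts = bp,
                          cell_proportions = props,
                          cell_reference = panel),
                     class = "ground_truth")
  list(dataset = ds, truth = truth)
}

#' Generate a full simulated multi-batch study
#'
#' Calls [generate_batch()] for every batch of the configuration with a shared
#' probe universe, shared signal probes, and per-batch technical parameters
#' drawn once from the study seed, and merges the ground truth.
#'
#' @param config a [sim_config].
#' @param panel optional reference panel; generated from the config seed when
#'   omitted.
#' @return List with elements `batches` (list of [methyl_dataset]) and
#'   `truth` (a merged `ground_truth`).
#' @export
generate_study <- function(config, panel = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(panel))
    panel <- generate_reference_panel(config$n_probes, config$n_celltypes,
                                      seed = config$seed)
  out <- lapply(seq_len(config$n_batches), function(b)
    generate_batch(config, b, panel))
  props <- do.call(rbind, lapply(out, function(x) x$truth$cell_proportions))
  truth <- out[[1]]$truth
  truth$batch_shifts <- draw_batch_params(config)
  truth$cell_proportions <- props
  list(batches = lapply(out, `[[`, "dataset"), truth = truth)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("ground_truth:", length(x$signal_probe_ids), "signal probes,",
      nrow(x$batch_shifts), "batch parameter rows,",
      nrow(x$cell_proportions), "samples with cell proportions\n")
  invisible(x)
}

#' Write simulator ground truth as JSON
#'
#' @param truth a `ground_truth`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  obj <- list(signal_probe_ids = truth$signal_probe_ids,
              per_probe_effect = as.list(truth$per_probe_effect),
              batch_shifts = truth$batch_shifts,
              cell_proportions = as.data.frame(truth$cell_proportions))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
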