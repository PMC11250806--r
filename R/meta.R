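#' Sidik-Jonkman between-study variance estimator
#'
#' Two-step estimator: an initial crude dispersion `tau0^2 =
#' sum((y - mean(y))^2) / k` (unweighted mean), weights
#' `w_i = 1 / (v_i / tau0^2 + 1)`, the weighted mean `mu_w`, and finally
#' `tau^2 = sum(w_i (y_i - mu_w)^2) / (k - 1)`. Returns 0 when the effects
#' are identical (degenerate `tau0^2 = 0`).
#'
#' @param y numeric vector of k >= 2 study effects (log2 fold changes).
#' @param v numeric vector of k sampling variances (SE^2), all positive.
#' @return Non-negative scalar tau-squared.
#' @export
sidik_jonkman_tau2 <- function(y, v) {
  k <- length(y)
  if (k < 2) stop("need at least 2 studies")
  if (length(v) != k || any(v <= 0) || any(!is.finite(y)))
    stop("v must be positive and y finite, both of length k")
  tau0 <- sum((y - mean(y))^2) / k
  if (tau0 == 0) return(0)
  w <- 1 / (v / tau0 + 1)
  mu_w <- sum(w * y) / sum(w)
  sum(w * (y - mu_w)^2) / (k - 1)
}

#' Inverse-variance random-effects meta-analysis of one probe
#'
#' Weights `w_i = 1 / (v_i + tau^2)` with the Sidik-Jonkman `tau^2`
#' ([sidik_jonkman_tau2()]), Wald (normal) inference for the pooled effect,
#' Cochran's Q with fixed-effect weights, and
#' `I^2 = 100 * tau^2 / (tau^2 + s_tilde^2)` where `s_tilde^2 =
#' (k-1) * sum(1/v) / ((sum(1/v))^2 - sum(1/v^2))` is the typical
#' within-study variance.
#'
#' @param y,v study effects and sampling variances (length k >= 2).
#' @param tau2 optional externally supplied tau-squared (defaults to SJ).
#' @return One-row data.frame: `k`, `mu`, `se`, `zval`, `pval`, `tau2`,
#'   `I2` (percent), `Q`.
#' @export
random_effects_meta <- function(y, v, tau2 = NULL) {
  k <- length(y)
  if (is.null(tau2)) tau2 <- sidik_jonkman_tau2(y, v)
  w <- 1 / (v + tau2)
  mu <- sum(w * y) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- mu / se
  p <- 2 * stats::pnorm(-abs(z))
  wf <- 1 / v
  mu_fe <- sum(wf * y) / sum(wf)
  Q <- sum(wf * (y - mu_fe)^2)
  s_tilde2 <- (k - 1) * sum(wf) / (sum(wf)^2 - sum(wf^2))
  I2 <- 100 * tau2 / (tau2 + s_tilde2)
  data.frame(k = k, mu = mu, se = se, zval = z, pval = p,
             tau2 = tau2, I2 = I2, Q = Q)
}

# Vectorized SJ + RE meta over a probes-by-cohorts pair of matrices with NAs
# for missing probe/cohort combinations. Returns a data.frame, one row per
# probe (rows with k < 2 are all-NA).
meta_rowwise <- function(Y, V) {
  ok <- is.finite(Y) & is.finite(V)
  k <- rowSums(ok)
  Y0 <- ifelse(ok, Y, 0)
  ybar <- rowSums(Y0) / k
  tau0 <- rowSums(ok * (Y0 - ybar)^2) / k
  # SJ weights; guard tau0 = 0 (handled by the degenerate branch below)
  tau0s <- ifelse(tau0 > 0, tau0, 1)
  W <- ifelse(ok, 1 / (V / tau0s + 1), 0)
  mu_w <- rowSums(W * Y0) / rowSums(W)
  tau2 <- rowSums(W * (Y0 - mu_w)^2) / (k - 1)
  tau2[tau0 == 0] <- 0

  Wre <- ifelse(ok, 1 / (V + tau2), 0)
  mu <- rowSums(Wre * Y0) / rowSums(Wre)
  se <- 1 / sqrt(rowSums(Wre))
  z <- mu / se
  p <- 2 * stats::pnorm(-abs(z))
  Wf <- ifelse(ok, 1 / V, 0)
  mu_fe <- rowSums(Wf * Y0) / rowSums(Wf)
  Q <- rowSums(Wf * (Y0 - mu_fe)^2)
  s_tilde2 <- (k - 1) * rowSums(Wf) / (rowSums(Wf)^2 - rowSums(Wf^2))
  I2 <- 100 * tau2 / (tau2 + s_tilde2)
  out <- data.frame(k = k, mu = mu, se = se, zval = z, pval = p,
                    tau2 = tau2, I2 = I2, Q = Q)
  out[k < 2, -1] <- NA_real_
  out
}

#' Meta-analysis across per-cohort DM tables
#'
#' Aligns per-cohort `dm_table`s on their probe ids, keeps probes passing the
#' inclusion rule (by default: nominal p < alpha in at least one cohort) that
#' are present in at least two cohorts, runs the Sidik-Jonkman random-effects
#' model per probe on (logFC, SE^2), and BH-adjusts the meta p-values.
#'
#' @param per_cohort_tables list of `dm_table`s (one per cohort).
#' @param alpha nominal significance level of the inclusion rule.
#' @param inclusion_rule optional predicate taking the probes-by-cohorts
#'   p-value matrix and returning a logical per-probe vector; overrides the
#'   default rule.
#' @return A `meta_table` data.frame: `probe_id`, `k`, `mu`, `se`, `zval`,
#'   `pval`, `qval`, `tau2`, `I2`, `Q`. Probes excluded because they appear
#'   in fewer than two cohorts are recorded in the `"excluded"` attribute.
#' @export
meta_ewas <- function(per_cohort_tables, alpha = 0.05,
                      inclusion_rule = NULL) {
  stopifnot(length(per_cohort_tables) >= 2)
  probes <- sort(unique(unlist(lapply(per_cohort_tables, `[[`, "probe_id"))))
  grab <- function(col) {
    m <- vapply(per_cohort_tables, function(t)
      t[[col]][match(probes, t$probe_id)], numeric(length(probes)))
    if (is.null(dim(m))) m <- matrix(m, nrow = length(probes))
    m
  }
  Y <- grab("logFC")
  S <- grab("SE")
  P <- grab("P.Value")
  present <- rowSums(is.finite(Y)) >= 2
  include <- if (is.null(inclusion_rule))
    rowSums(P < alpha, na.rm = TRUE) >= 1 else inclusion_rule(P)
  excluded <- probes[include & !present]
  keep <- include & present
  res <- meta_rowwise(Y[keep, , drop = FALSE], S[keep, , drop = FALSE]^2)
  out <- cbind(data.frame(probe_id = probes[keep]), res)
  out$qval <- bh_fdr(out$pval)
  out <- out[, c("probe_id", "k", "mu", "se", "zval", "pval", "qval",
                 "tau2", "I2", "Q")]
  attr(out, "excluded") <- excluded
  class(out) <- c("meta_table", "data.frame")
  out
}

#' Overlap between pooled and meta-analytic significance
#'
#' @param pooled a pooled-analysis `dm_table`.
#' @param meta a `meta_table`.
#' @param alpha nominal level applied to both unadjusted p-values.
#' @return List with `overlap` (probe ids significant in both), and `counts`
#'   (`pooled_only`, `meta_only`, `both`) for a Venn summary.
#' @export
overlap_analysis <- function(pooled, meta, alpha = 0.05) {
  sig_pooled <- pooled$probe_id[pooled$P.Value < alpha]
  sig_meta <- meta$probe_id[meta$pval < alpha]
  both <- intersect(sig_pooled, sig_meta)
  list(overlap = both,
       counts = c(pooled_only = length(setdiff(sig_pooled, sig_meta)),
                  meta_only = length(setdiff(sig_meta, sig_pooled)),
                  both = length(both)))
}

#' Write a meta table as TSV
#'
#' @param tab a `meta_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_meta_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
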