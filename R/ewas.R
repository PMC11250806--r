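#' Build a design matrix for differential methylation
#'
#' Intercept + status (0 = control, 1 = case) + age + sex indicator, and, in
#' pooled mode, treatment-coded study-factor indicators against the first
#' batch alphabetically.
#'
#' @param samples sample sheet data.frame (`status`, `age`, `sex`, `batch`).
#' @param include_study_factor add batch indicator columns (pooled analysis).
#' @return Numeric design matrix with named columns; errors if rank-deficient.
#' @export
build_design <- function(samples, include_study_factor = FALSE) {
  status <- as.integer(samples$status == "case")
  if (length(unique(status)) < 2)
    stop("both cases and controls are required")
  sexM <- as.integer(samples$sex == "M")
  X <- cbind(`(Intercept)` = 1, status = status,
             age = samples$age, sexM = sexM)
  if (include_study_factor) {
    f <- factor(samples$batch, levels = sort(unique(samples$batch)))
    if (nlevels(f) > 1) {
      Fm <- stats::model.matrix(~f)[, -1, drop = FALSE]
      colnames(Fm) <- paste0("batch_", levels(f)[-1])
      X <- cbind(X, Fm)
    }
  }
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    aliased <- colnames(X)[qd$pivot[(qd$rank + 1):ncol(X)]]
    stop("design matrix is rank-deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  X
}

#' Per-probe ordinary least squares fits
#'
#' Fits the same design to every probe by a single QR decomposition and
#' extracts, for the `status` coefficient: the estimate (the log2 fold change
#' on the analysis scale), the unscaled standard deviation
#' `u = sqrt([ (X'X)^-1 ]_status)`, the residual SD `s`, and the residual
#' degrees of freedom `d = n - rank(X)`.
#'
#' @param ds a [methyl_dataset] (or samples-by-probes matrix).
#' @param design design matrix from [build_design()] containing a `status`
#'   column.
#' @return List of class `probe_fit` with `coef`, `u`, `s`, `df`, `probe_id`,
#'   and the full coefficient matrix.
#' @export
fit_probewise_models <- function(ds, design) {
  Y <- if (inherits(ds, "methyl_dataset")) ds$values else as.matrix(ds)
  X <- as.matrix(design)
  if (nrow(X) != nrow(Y)) stop("design rows must match samples")
  qd <- qr(X)
  if (qd$rank < ncol(X)) {
    aliased <- colnames(X)[qd$pivot[(qd$rank + 1):ncol(X)]]
    stop("design matrix is rank-deficient; aliased columns: ",
         paste(aliased, collapse = ", "))
  }
  d <- nrow(X) - qd$rank
  if (d <= 0) stop("no residual degrees of freedom (n <= rank(X))")
  j <- match("status", colnames(X))
  if (is.na(j)) stop("design must contain a 'status' column")
  coefs <- qr.coef(qd, Y)                       # p x probes
  res <- Y - X %*% coefs
  s2 <- colSums(res^2) / d
  XtXinv <- chol2inv(qr.R(qd))[order(qd$pivot), order(qd$pivot), drop = FALSE]
  u <- sqrt(XtXinv[j, j])
  structure(list(probe_id = colnames(Y), coef = coefs[j, ], u = u,
                 s = sqrt(s2), df = d, n = nrow(X),
                 coefficients = coefs, design_cols = colnames(X)),
            class = "probe_fit")
}

# Newton inversion of the trigamma function (for the EB prior df).
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of probewise fits
#'
#' Estimates the prior degrees of freedom `d0` and prior variance `s0^2` by
#' matching the moments of `log s^2` (digamma/trigamma inversion), shrinks
#' each probe's residual variance to
#' `s_post^2 = (d0 s0^2 + d s^2) / (d0 + d)`, and forms the moderated
#' t-statistic `t = coef / (u * s_post)` with `d0 + d` degrees of freedom.
#'
#' @param fit a [fit_probewise_models()] result (>= 10 probes).
#' @return A `dm_table` data.frame: `probe_id`, `logFC`, `SE`, `t`,
#'   `P.Value`, `adj.P.Val`, `agreement` (NA until filled by a pooled
#'   analysis), with attributes `d0`, `s02`, `df_total`.
#' @export
moderate <- function(fit) {
  stopifnot(inherits(fit, "probe_fit"))
  G <- length(fit$s)
  if (G < 10) stop("need >= 10 probes to estimate the EB hyperparameters")
  s2 <- fit$s^2
  if (all(s2 == 0)) stop("all residual variances are zero; degenerate data")
  d <- fit$df
  ok <- s2 > 0
  e <- log(s2[ok]) - digamma(d / 2) + log(d / 2)
  ebar <- mean(e)
  rhs <- mean((e - ebar)^2 * sum(ok) / (sum(ok) - 1)) - trigamma(d / 2)
  if (rhs > 0) {
    d0 <- 2 * trigamma_inverse(rhs)
    s02 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  } else {
    # no excess dispersion in log s^2: infinite prior df. The prior variance
    # is the geometric mean of the observed s^2, so that exactly equal
    # residual variances shrink to themselves and the moderated t reduces to
    # the ordinary t.
    d0 <- Inf
    s02 <- exp(mean(log(s2[ok])))
  }
  s2_post <- if (is.infinite(d0)) rep(s02, G) else
    (d0 * s02 + d * s2) / (d0 + d)
  se <- fit$u * sqrt(s2_post)
  t <- fit$coef / se
  df_total <- d0 + d
  p <- 2 * stats::pt(-abs(t), df = df_total)
  out <- data.frame(probe_id = fit$probe_id, logFC = fit$coef, SE = se,
                    t = t, P.Value = p, adj.P.Val = bh_fdr(p),
                    agreement = NA_real_, row.names = NULL)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  attr(out, "df_total") <- df_total
  class(out) <- c("dm_table", "data.frame")
  out
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up adjusted p-values with enforced monotonicity (`p.adjust` with
#' method `"BH"`), after validating the input domain.
#'
#' @param p vector of p-values in (0, 1].
#' @return Vector of q-values.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0 | p > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Directional agreement index
#'
#' Fraction of cohorts whose case-minus-control median methylation difference
#' has the same sign as the reference; zero differences count as
#' disagreement.
#'
#' @param per_cohort_median_diffs probes-by-cohorts matrix of median
#'   differences.
#' @param reference_sign per-probe reference sign (+1/-1; 0 never matches).
#' @return Per-probe agreement fractions in \[0, 1\].
#' @export
directional_agreement <- function(per_cohort_median_diffs, reference_sign) {
  D <- as.matrix(per_cohort_median_diffs)
  if (ncol(D) < 1) stop("need at least one cohort")
  if (length(reference_sign) != nrow(D))
    stop("reference_sign must be per-probe")
  match <- sweep(sign(D), 1, reference_sign, `==`) & D != 0 &
    reference_sign != 0
  rowMeans(match)
}

# Case-minus-control median per probe within each cohort batch.
median_diffs_by_cohort <- function(ds) {
  batches <- sort(unique(ds$samples$batch))
  out <- sapply(batches, function(b) {
    idx <- ds$samples$batch == b
    case <- idx & ds$samples$status == "case"
    ctrl <- idx & ds$samples$status == "control"
    if (!any(case) || !any(ctrl)) return(rep(NA_real_, ncol(ds$values)))
    apply(ds$values[case, , drop = FALSE], 2, stats::median) -
      apply(ds$values[ctrl, , drop = FALSE], 2, stats::median)
  })
  rownames(out) <- ds$probes$probe_id
  out
}

#' Run a differential methylation analysis
#'
#' Composes design construction, per-probe OLS, empirical-Bayes moderation
#' and FDR. In pooled mode (`include_study_factor = TRUE`) the design carries
#' the study factor and the directional agreement index is computed against
#' the sign of the pooled logFC (or, with `agreement_reference = "majority"`,
#' against the cross-cohort majority sign).
#'
#' @param ds a [methyl_dataset] whose sample sheet carries status, age, sex
#'   and batch.
#' @param include_study_factor pooled (`TRUE`) vs per-cohort (`FALSE`) design.
#' @param agreement_reference `"pooled"` (default) or `"majority"`.
#' @return A `dm_table` (see [moderate()]); in pooled mode the `agreement`
#'   column is filled. The sample ids used are attached as the
#'   `"sample_ids"` attribute for selection-provenance audits.
#' @export
run_ewas <- function(ds, include_study_factor = FALSE,
                     agreement_reference = c("pooled", "majority")) {
  stopifnot(inherits(ds, "methyl_dataset"))
  agreement_reference <- match.arg(agreement_reference)
  X <- build_design(ds$samples, include_study_factor)
  tab <- moderate(fit_probewise_models(ds, X))
  if (include_study_factor && length(unique(ds$samples$batch)) > 1) {
    D <- median_diffs_by_cohort(ds)
    D <- D[, colSums(is.na(D)) == 0, drop = FALSE]
    if (ncol(D) >= 1) {
      ref <- if (agreement_reference == "pooled") sign(tab$logFC) else
        sign(rowSums(sign(D)))
      tab$agreement <- directional_agreement(D, ref)
    }
  }
  attr(tab, "sample_ids") <- ds$samples$sample_id
  class(tab) <- c("dm_table", "data.frame")
  tab
}

#' Write a DM table as TSV
#'
#' Columns: probe_id, logFC, SE, t, P.Value, adj.P.Val, agreement.
#'
#' @param tab a `dm_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dm_table <- function(tab, path) {
  utils::write.table(as.data.frame(tab), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
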