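#' Estimate blood cell-type proportions by constrained projection
#'
#' Houseman-style reference-based deconvolution: for every sample, solve
#' `min || b - R'w ||^2` subject to `w >= 0` and `sum(w) = 1` over the panel's
#' discriminating probes, where `R` is the celltype-by-probe reference matrix
#' of beta-values. The quadratic program is solved by non-negative least
#' squares (`pracma::lsqnonneg`) followed by a sum-to-one normalization.
#'
#' @param x a [methyl_dataset] (converted to beta internally if on the M
#'   scale) or a samples-by-probes beta matrix with probe ids as column names.
#' @param panel a [generate_reference_panel()]-style `cell_reference_panel`.
#' @return A samples-by-celltype matrix of proportions (rows sum to 1) with a
#'   per-sample `"residual_norm"` attribute; class `cell_proportions`.
#' @export
estimate_cell_proportions <- function(x, panel) {
  stopifnot(inherits(panel, "cell_reference_panel"))
  if (inherits(x, "methyl_dataset")) x <- convert_scale(x, "beta")$values
  x <- as.matrix(x)
  disc <- panel$discriminating
  probes <- colnames(panel$reference_beta)[disc]
  use <- intersect(probes, colnames(x))
  k <- nrow(panel$reference_beta)
  if (length(use) < k)
    stop("sample and panel share only ", length(use),
         " discriminating probes; need at least ", k)
  A <- t(panel$reference_beta[, use, drop = FALSE])     # probes x celltypes
  qrA <- qr(A)
  if (qrA$rank < k) {
    dep <- panel$celltypes[qrA$pivot[(qrA$rank + 1):k]]
    stop("reference panel is rank-deficient; collinear cell types: ",
         paste(dep, collapse = ", "))
  }
  W <- matrix(NA_real_, nrow(x), k,
              dimnames = list(rownames(x), panel$celltypes))
  rn <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    b <- x[i, use]
    w <- pracma::lsqnonneg(A, b)$x
    if (sum(w) <= 0) w <- rep(1 / k, k)
    w <- w / sum(w)
    W[i, ] <- w
    rn[i] <- sqrt(sum((b - A %*% w)^2))
  }
  attr(W, "residual_norm") <- rn
  class(W) <- c("cell_proportions", class(W))
  W
}

#' Adjust methylation values for cell composition
#'
#' Per probe, regresses the methylation values on the cell proportions
#' (intercept plus K-1 proportion columns; the last listed cell type is the
#' reference, avoiding the sum-to-one collinearity) and replaces each value by
#' residual + probe mean. The adjustment is exactly mean-preserving and
#' idempotent, and removes the linear association between methylation and
#' cell proportions.
#'
#' @param ds a [methyl_dataset] (adjustment runs on the dataset's own scale).
#' @param proportions samples-by-celltype matrix row-aligned to `ds` (e.g.
#'   from [estimate_cell_proportions()]).
#' @return The adjusted [methyl_dataset].
#' @export
adjust_for_cell_composition <- function(ds, proportions) {
  stopifnot(inherits(ds, "methyl_dataset"))
  P <- as.matrix(proportions)
  if (nrow(P) != nrow(ds$values))
    stop("proportions must be row-aligned to the samples")
  k <- ncol(P)
  if (nrow(ds$values) < k + 2)
    stop("need at least n_celltypes + 2 samples for the adjustment")
  D <- cbind(intercept = 1, P[, -k, drop = FALSE])   # drop reference celltype
  qd <- qr(D)
  if (qd$rank < ncol(D)) {
    drop_cols <- colnames(D)[qd$pivot[(qd$rank + 1):ncol(D)]]
    message("dropping collinear proportion columns: ",
            paste(drop_cols, collapse = ", "))
    D <- D[, qd$pivot[seq_len(qd$rank)], drop = FALSE]
    qd <- qr(D)
  }
  fitted <- D %*% qr.coef(qd, ds$values)
  means <- colMeans(ds$values)
  out <- ds
  out$values <- ds$values - fitted +
    matrix(means, nrow(ds$values), ncol(ds$values), byrow = TRUE)
  if (out$scale == "beta") out$values <- pmin(pmax(out$values, 0), 1)
  out
}

#' Write / read cell proportions as CSV
#'
#' @param proportions samples-by-celltype matrix with sample ids as row names.
#' @param path CSV path.
#' @return `path` (write) or the proportion matrix (read).
#' @export
write_cell_proportions <- function(proportions, path) {
  df <- data.frame(sample_id = rownames(proportions),
                   as.data.frame(unclass(proportions), check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cell_proportions
#' @export
read_cell_proportions <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$sample_id
  m
}
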