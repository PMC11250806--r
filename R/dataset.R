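#' Methylation dataset container
#'
#' Bundles a sample-by-probe methylation matrix with its scale, the sample
#' sheet, and the probe annotation. This is the currency passed between every
#' stage of the pipeline. The in-memory orientation is always samples in rows
#' and probes in columns; on-disk matrices use the GEO series-matrix
#' convention (probes as rows) and the readers/writers transpose.
#'
#' @param values numeric matrix, samples x probes, with sample ids as row
#'   names and probe ids as column names.
#' @param scale `"M"` or `"beta"`. Beta-values must lie in \[0, 1\].
#' @param samples data.frame with columns `sample_id`, `status`
#'   (`"case"`/`"control"`), `age`, `sex` (`"F"`/`"M"`), `batch`; rows aligned
#'   to the rows of `values`.
#' @param probes data.frame with columns `probe_id`, `chrom`, `pos` (1-based,
#'   Illumina-manifest convention); rows aligned to the columns of `values`.
#'   Probes are stored sorted by genomic position (chrom, pos).
#' @return An object of class `methyl_dataset`.
#' @export
methyl_dataset <- function(values, scale = c("M", "beta"), samples, probes) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  stopifnot(is.numeric(values), is.data.frame(samples), is.data.frame(probes))
  if (nrow(values) != nrow(samples))
    stop("values has ", nrow(values), " rows but samples has ", nrow(samples))
  if (ncol(values) != nrow(probes))
    stop("values has ", ncol(values), " columns but probes has ", nrow(probes))
  req_s <- c("sample_id", "status", "age", "sex", "batch")
  if (!all(req_s %in% names(samples)))
    stop("samples is missing columns: ",
         paste(setdiff(req_s, names(samples)), collapse = ", "))
  req_p <- c("probe_id", "chrom", "pos")
  if (!all(req_p %in% names(probes)))
    stop("probes is missing columns: ",
         paste(setdiff(req_p, names(probes)), collapse = ", "))
  if (anyDuplicated(samples$sample_id)) stop("sample ids must be unique")
  if (anyDuplicated(probes$probe_id)) stop("probe ids must be unique")
  if (any(is.na(samples$status)) || any(is.na(samples$sex)))
    stop("status and sex must be non-missing")
  if (!all(samples$status %in% c("case", "control")))
    stop("status must be 'case' or 'control'")
  if (any(samples$age < 0, na.rm = TRUE)) stop("age must be >= 0")
  if (any(probes$pos < 1)) stop("probe positions are 1-based (pos >= 1)")
  if (scale == "beta") {
    rng <- range(values)
    if (rng[1] < 0 || rng[2] > 1)
      stop("beta-scale values must lie in [0, 1]; observed range [",
           signif(rng[1], 4), ", ", signif(rng[2], 4), "]")
  }
  ord <- probe_order(probes$chrom, probes$pos)
  if (is.unsorted(ord)) {
    o <- order(ord)
    probes <- probes[o, , drop = FALSE]
    values <- values[, o, drop = FALSE]
  }
  rownames(values) <- samples$sample_id
  colnames(values) <- probes$probe_id
  rownames(samples) <- NULL
  rownames(probes) <- NULL
  structure(list(values = values, scale = scale,
                 samples = samples, probes = probes),
            class = "methyl_dataset")
}

# Sortable key for (chrom, pos): chromosomes ordered numerically (chr2 before
# chr10), non-autosomal names after the autosomes in alphabetical order.
probe_order <- function(chrom, pos) {
  num <- suppressWarnings(as.integer(sub("^chr", "", chrom)))
  num[is.na(num)] <- 1000L + as.integer(factor(chrom[is.na(num)]))
  num * 1e9 + as.numeric(pos)
}

#' @export
print.methyl_dataset <- function(x, ...) {
  cat("methyl_dataset:", nrow(x$values), "samples x", ncol(x$values),
      "probes on the", x$scale, "scale\n")
  st <- table(x$samples$status)
  cat("  status:", paste(names(st), st, sep = "=", collapse = ", "), "\n")
  cat("  batches:", length(unique(x$samples$batch)), "\n")
  invisible(x)
}

#' @export
summary.methyl_dataset <- function(object, ...) {
  out <- list(
    n_samples = nrow(object$values), n_probes = ncol(object$values),
    scale = object$scale,
    status = table(object$samples$status),
    batch = table(object$samples$batch),
    value_range = range(object$values))
  class(out) <- "summary.methyl_dataset"
  out
}

#' @export
print.summary.methyl_dataset <- function(x, ...) {
  cat(x$n_samples, "samples x", x$n_probes, "probes (", x$scale, "scale )\n")
  cat("value range:", signif(x$value_range[1], 4), "to",
      signif(x$value_range[2], 4), "\n")
  print(x$batch)
  invisible(x)
}

#' Subset a methylation dataset
#'
#' @param ds a [methyl_dataset].
#' @param samples,probes index vectors (logical, integer, or id character)
#'   into the sample/probe dimension; `NULL` keeps everything.
#' @return A [methyl_dataset].
#' @export
subset_dataset <- function(ds, samples = NULL, probes = NULL) {
  stopifnot(inherits(ds, "methyl_dataset"))
  si <- if (is.null(samples)) seq_len(nrow(ds$values)) else
    resolve_index(samples, ds$samples$sample_id, "sample")
  pi <- if (is.null(probes)) seq_len(ncol(ds$values)) else
    resolve_index(probes, ds$probes$probe_id, "probe")
  methyl_dataset(ds$values[si, pi, drop = FALSE], ds$scale,
                 ds$samples[si, , drop = FALSE],
                 ds$probes[pi, , drop = FALSE])
}

resolve_index <- function(idx, ids, what) {
  if (is.character(idx)) {
    m <- match(idx, ids)
    if (anyNA(m)) stop("unknown ", what, " ids: ",
                       paste(utils::head(idx[is.na(m)], 5), collapse = ", "))
    m
  } else which(rep(TRUE, length(ids)))[idx]
}

#' Convert beta-values to M-values
#'
#' M = log2(b / (1 - b)) with b clipped into \[epsilon, 1 - epsilon\] so that
#' fully (un)methylated probes map to finite values.
#'
#' @param beta numeric vector/matrix of beta-values in \[0, 1\].
#' @param epsilon clipping bound in (0, 0.5); default `1e-6`.
#' @return M-values with the shape of `beta`.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (!is.numeric(epsilon) || length(epsilon) != 1 ||
      epsilon <= 0 || epsilon >= 0.5)
    stop("epsilon must lie in (0, 0.5)")
  if (any(beta < 0 | beta > 1, na.rm = TRUE))
    stop("beta-values must lie in [0, 1]")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

#' Convert M-values to beta-values
#'
#' Inverse of [beta_to_m()]: beta = 2^M / (2^M + 1), strictly monotone and
#' always inside (0, 1).
#'
#' @param m numeric vector/matrix of finite M-values.
#' @return Beta-values with the shape of `m`.
#' @export
m_to_beta <- function(m) {
  if (any(!is.finite(m)))
    stop("M-values must be finite")
  # plogis(x * log 2) = 2^x / (2^x + 1), numerically safe for large |m|
  out <- stats::plogis(m * log(2))
  attributes(out) <- attributes(m)
  out
}

#' Convert a dataset between beta and M scales
#'
#' @param ds a [methyl_dataset].
#' @param scale target scale.
#' @param epsilon clipping bound for the beta-to-M direction.
#' @return A [methyl_dataset] on the requested scale (identity if already there).
#' @export
convert_scale <- function(ds, scale = c("M", "beta"), epsilon = 1e-6) {
  scale <- match.arg(scale)
  stopifnot(inherits(ds, "methyl_dataset"))
  if (ds$scale == scale) return(ds)
  v <- if (scale == "M") beta_to_m(ds$values, epsilon) else m_to_beta(ds$values)
  methyl_dataset(v, scale, ds$samples, ds$probes)
}

#' Quantile-normalize samples of a methylation matrix
#'
#' Forces every sample's empirical distribution onto the cross-sample mean of
#' sorted value vectors; ties within a sample receive the mean of the quantile
#' values they span. Delegates to `limma::normalizeQuantiles` (samples as
#' columns internally).
#'
#' @param x samples-by-probes numeric matrix, or a [methyl_dataset].
#' @return Object of the same kind as `x` with normalized values.
#' @export
quantile_normalize <- function(x) {
  if (inherits(x, "methyl_dataset")) {
    out <- x
    out$values <- quantile_normalize(x$values)
    if (out$scale == "beta") out$values <- pmin(pmax(out$values, 0), 1)
    return(out)
  }
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("quantile normalization needs >= 2 samples")
  if (anyNA(x))
    stop("missing values present; impute or filter probes before ",
         "quantile normalization")
  qn <- t(limma::normalizeQuantiles(t(x), ties = TRUE))
  dimnames(qn) <- dimnames(x)
  qn
}

#' Filter probes by exclusion list and sex chromosomes
#'
#' Drops user-supplied probes (SNP-related, cross-reactive, ...) and,
#' optionally, everything on chrX/chrY. Removal reasons are attached as the
#' `"removed"` attribute of the result.
#'
#' @param ds a [methyl_dataset].
#' @param exclusion_list character vector of probe ids to drop.
#' @param drop_sex_chrom drop chrX/chrY probes; default `TRUE`.
#' @return The filtered [methyl_dataset].
#' @export
filter_probes <- function(ds, exclusion_list = character(),
                          drop_sex_chrom = TRUE) {
  stopifnot(inherits(ds, "methyl_dataset"))
  reason <- rep(NA_character_, nrow(ds$probes))
  if (drop_sex_chrom)
    reason[ds$probes$chrom %in% c("chrX", "chrY")] <- "sex_chromosome"
  reason[ds$probes$probe_id %in% exclusion_list] <- "exclusion_list"
  keep <- is.na(reason)
  if (!any(keep))
    warning("all probes removed by filtering")
  removed <- data.frame(probe_id = ds$probes$probe_id[!keep],
                        reason = reason[!keep])
  out <- subset_dataset(ds, probes = which(keep))
  attr(out, "removed") <- removed
  out
}

#' Merge per-batch datasets over their common probes
#'
#' Keeps the intersection of probe sets across all batches, orders probes by
#' genomic position, and concatenates samples; batch labels are preserved in
#' the sample sheet.
#'
#' @param datasets list of [methyl_dataset] objects on the same scale with
#'   globally unique sample ids.
#' @return A single merged [methyl_dataset].
#' @export
merge_batches <- function(datasets) {
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, TRUE, "methyl_dataset")))
  scales <- unique(vapply(datasets, `[[`, "", "scale"))
  if (length(scales) > 1)
    stop("datasets are on mixed scales: ", paste(scales, collapse = ", "))
  ids <- unlist(lapply(datasets, function(d) d$samples$sample_id))
  if (anyDuplicated(ids)) stop("sample ids must be globally unique")
  common <- Reduce(intersect, lapply(datasets, function(d) d$probes$probe_id))
  if (length(common) == 0) stop("empty probe intersection across batches")
  parts <- lapply(datasets, subset_dataset, probes = common)
  values <- do.call(rbind, lapply(parts, `[[`, "values"))
  samples <- do.call(rbind, lapply(parts, `[[`, "samples"))
  methyl_dataset(values, scales, samples, parts[[1]]$probes)
}

## ---- on-disk formats --------------------------------------------------
## Matrix TSV: probes as rows, first column probe_id (GEO series-matrix
## orientation). Sample sheet CSV and probe annotation TSV as column tables.
## All readers are gzip-transparent (R connections autodetect .gz).

#' Write a methylation dataset to a directory
#'
#' Produces `matrix.tsv` (probes as rows, first column the probe id),
#' `samples.csv`, and `probes.tsv` (1-based coordinates).
#'
#' @param ds a [methyl_dataset].
#' @param dir output directory (created if needed).
#' @param gzip compress the matrix as `matrix.tsv.gz`.
#' @return `dir`, invisibly.
#' @export
write_methylation <- function(ds, dir, gzip = FALSE) {
  stopifnot(inherits(ds, "methyl_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mat <- data.frame(probe_id = ds$probes$probe_id,
                    t(ds$values), check.names = FALSE)
  mfile <- file.path(dir, if (gzip) "matrix.tsv.gz" else "matrix.tsv")
  con <- if (gzip) gzfile(mfile, "w") else file(mfile, "w")
  utils::write.table(mat, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  utils::write.csv(ds$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.table(ds$probes, file.path(dir, "probes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  writeLines(paste0("scale\t", ds$scale), file.path(dir, "scale.tsv"))
  invisible(dir)
}

#' Read a methylation dataset written by [write_methylation()]
#'
#' @param dir directory holding `matrix.tsv[.gz]`, `samples.csv`, `probes.tsv`.
#' @return A [methyl_dataset].
#' @export
read_methylation <- function(dir) {
  mfile <- file.path(dir, "matrix.tsv")
  if (!file.exists(mfile)) mfile <- file.path(dir, "matrix.tsv.gz")
  mat <- utils::read.delim(mfile, check.names = FALSE)
  samples <- utils::read.csv(file.path(dir, "samples.csv"),
                             stringsAsFactors = FALSE)
  probes <- utils::read.delim(file.path(dir, "probes.tsv"),
                              stringsAsFactors = FALSE)
  scale <- sub("^scale\t", "", readLines(file.path(dir, "scale.tsv"))[1])
  values <- t(as.matrix(mat[, -1, drop = FALSE]))
  colnames(values) <- mat$probe_id
  probes <- probes[match(mat$probe_id, probes$probe_id), , drop = FALSE]
  samples <- samples[match(rownames(values), samples$sample_id), , drop = FALSE]
  samples$batch <- as.character(samples$batch)
  methyl_dataset(values, scale, samples, probes)
}
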