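#' Normalized log-intensity table
#'
#' Internal container shared by the normalization and imputation steps:
#' a protein x run matrix of log10 intensities, a mask of imputed cells and
#' an audit trail of every per-run offset applied.
#'
#' @param log_intensity numeric matrix (log10 scale, `NA` = missing)
#' @param imputed logical matrix marking imputed cells
#' @param audit named list of audit records
#' @return object of class `norm_table`
#' @export
norm_table <- function(log_intensity, imputed = NULL, audit = list()) {
  if (is.null(imputed)) {
    imputed <- matrix(FALSE, nrow(log_intensity), ncol(log_intensity),
                      dimnames = dimnames(log_intensity))
  }
  structure(list(log_intensity = log_intensity, imputed = imputed,
                 audit = audit, log_base = 10),
            class = "norm_table")
}

#' @export
print.norm_table <- function(x, ...) {
  cat("norm_table:", nrow(x$log_intensity), "proteins x",
      ncol(x$log_intensity), "runs;",
      sum(x$imputed), "imputed cells;",
      length(x$audit), "audit records\n")
  invisible(x)
}

as_log10 <- function(intensities) {
  stopifnot(is.matrix(intensities))
  if (any(intensities <= 0, na.rm = TRUE)) {
    stop("intensities must be positive (use NA for missing)")
  }
  log10(intensities)
}

#' Spike-in normalization of raw intensities
#'
#' Divides each run by its total spike-in standard intensity and rescales so
#' that the grand mean spike factor is 1 (the overall intensity scale is
#' preserved). Runs in which no spike-in was detected keep a factor of 1,
#' with a warning.
#'
#' @param intensities protein x run matrix on the linear scale
#' @param spike_ids identifiers of the spiked standards (rows of the matrix)
#' @return matrix of the same shape; attribute `spike_factors` records the
#'   per-run divisors
#' @export
spikein_normalize <- function(intensities, spike_ids) {
  stopifnot(length(spike_ids) > 0)
  present <- intersect(spike_ids, rownames(intensities))
  if (length(present) == 0) stop("no spike-in ids present in the table")
  totals <- colSums(intensities[present, , drop = FALSE], na.rm = TRUE)
  missing_runs <- totals == 0
  if (any(missing_runs)) {
    warning("runs without spike-in signal kept unscaled: ",
            paste(colnames(intensities)[missing_runs], collapse = ", "))
  }
  factors <- totals / mean(totals[!missing_runs])
  factors[missing_runs] <- 1
  out <- sweep(intensities, 2, factors, "/")
  attr(out, "spike_factors") <- factors
  out
}

#' Global mean normalization on the log scale
#'
#' Anchors every run on the set of proteins detected in all runs: each run
#' receives an additive log10 offset such that its mean log intensity over
#' that always-detected set equals the grand mean of the set.
#'
#' @param intensities protein x run matrix on the linear scale
#' @param design sample design (run ids checked against the matrix)
#' @return a [norm_table()] (still containing `NA` cells)
#' @export
global_mean_normalize <- function(intensities, design) {
  check_design(intensities, design)
  logm <- as_log10(intensities)[, design$run_id, drop = FALSE]
  anchor <- rowSums(is.na(logm)) == 0
  if (!any(anchor)) stop("no protein detected in every run (empty anchor set)")
  run_means <- colMeans(logm[anchor, , drop = FALSE])
  offsets <- mean(run_means) - run_means
  out <- sweep(logm, 2, offsets, "+")
  norm_table(out, audit = list(global_offsets = offsets,
                               anchor_proteins = rownames(logm)[anchor]))
}

#' Impute missing values from the control-background model
#'
#' For every protein detected in control runs, the mean and SD of its log10
#' control intensities are computed. Missing cells anywhere in the table are
#' then drawn independently from a normal distribution on the log scale
#' centred on the 5th percentile (linear interpolation) of the distribution
#' of those per-protein means, with SD equal to the mean of the per-protein
#' SDs. This places imputed values at the low end of the control background,
#' where undetected proteins are expected to sit.
#'
#' @param norm a [norm_table()] (post global normalization)
#' @param design sample design
#' @param seed integer seed; imputation is deterministic given it
#' @param percentile percentile of the mean distribution used as the
#'   imputation centre (default 5)
#' @return a [norm_table()] with no missing cells and an `imputed` mask
#' @export
impute_missing <- function(norm, design, seed = 1L, percentile = 5) {
  stopifnot(inherits(norm, "norm_table"))
  logm <- norm$log_intensity
  control_runs <- design$run_id[design$background == "control"]
  if (length(control_runs) == 0) stop("no control runs in design")
  ctrl <- logm[, control_runs, drop = FALSE]
  n_obs <- rowSums(!is.na(ctrl))
  means <- rowMeans(ctrl, na.rm = TRUE)[n_obs >= 1]
  sds <- apply(ctrl[n_obs >= 2, , drop = FALSE], 1, stats::sd, na.rm = TRUE)
  if (length(means) == 0) {
    warning("no protein observed in control runs; falling back to the ",
            "global intensity distribution")
    means <- as.vector(logm[!is.na(logm)])
    sds <- stats::sd(means)
  }
  mu0 <- unname(stats::quantile(means, percentile / 100, type = 7))
  sigma0 <- if (length(sds) > 0) mean(sds) else stats::sd(means)
  miss <- is.na(logm)
  set.seed(as.integer(seed))
  logm[miss] <- stats::rnorm(sum(miss), mu0, sigma0)
  imputed <- norm$imputed | miss
  audit <- c(norm$audit, list(imputation = list(mu0 = mu0, sigma0 = sigma0,
                                                percentile = percentile,
                                                n_imputed = sum(miss),
                                                seed = as.integer(seed))))
  norm_table(logm, imputed = imputed, audit = audit)
}

#' Per-condition mean normalization
#'
#' Within each time point, per-run additive offsets equalize the mean log
#' intensity (over all proteins) across that condition's bait and control
#' runs. Applied after imputation so that every run mean is computed over
#' the full protein set.
#'
#' @param norm a [norm_table()] without missing cells
#' @param design sample design
#' @return a [norm_table()]
#' @export
per_condition_normalize <- function(norm, design) {
  stopifnot(inherits(norm, "norm_table"))
  logm <- norm$log_intensity
  offsets <- stats::setNames(numeric(ncol(logm)), colnames(logm))
  for (t in unique(design$time_s)) {
    runs <- design$run_id[design$time_s == t]
    run_means <- colMeans(logm[, runs, drop = FALSE], na.rm = TRUE)
    offsets[runs] <- mean(run_means) - run_means
  }
  out <- sweep(logm, 2, offsets[colnames(logm)], "+")
  norm_table(out, imputed = norm$imputed,
             audit = c(norm$audit, list(per_condition_offsets = offsets)))
}

#' Full preprocessing chain
#'
#' Convenience wrapper running, in order: optional spike-in normalization,
#' global mean normalization, control-background imputation and
#' per-condition normalization.
#'
#' @param intensities protein x run matrix on the linear scale
#' @param design sample design
#' @param spike_ids optional spike-in identifiers (skipped when `NULL`)
#' @param seed seed forwarded to [impute_missing()]
#' @return a [norm_table()] ready for detection
#' @export
preprocess_table <- function(intensities, design, spike_ids = NULL, seed = 1L) {
  if (!is.null(spike_ids)) {
    intensities <- spikein_normalize(intensities, spike_ids)
  }
  norm <- global_mean_normalize(intensities, design)
  norm <- impute_missing(norm, design, seed = seed)
  per_condition_normalize(norm, design)
}
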