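#' Detection configuration
#'
#' Thresholds of the specific-interactor call: a protein is selected at time
#' t in one bootstrap iteration when its ANOVA p-value is below `p_threshold`
#' and its bait/control enrichment exceeds `fold_threshold`; it is a specific
#' interactor when it is selected in at least `detect_frac` of the `n_boot`
#' iterations at some time point.
#'
#' @param p_threshold ANOVA p-value threshold P* (the study used 0.001 for
#'   the more abundant bait and 0.005 for the less abundant one)
#' @param fold_threshold linear enrichment threshold r* (default 2)
#' @param n_boot bootstrap iterations (default 200)
#' @param detect_frac required fraction of selecting iterations (default 0.9;
#'   ties at exactly `detect_frac` count as selected)
#' @param p_adjust `"none"` (raw ANOVA p per time point) or `"BH"`
#'   (Benjamini-Hochberg across proteins within each time point and
#'   iteration)
#' @param seed integer seed for the bootstrap
#' @return list of class `detection_config`
#' @export
detection_config <- function(p_threshold = 0.001, fold_threshold = 2,
                             n_boot = 200L, detect_frac = 0.9,
                             p_adjust = c("none", "BH"), seed = 1L) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(p_threshold > 0, p_threshold < 1, fold_threshold > 1,
            n_boot >= 1, detect_frac > 0, detect_frac <= 1)
  structure(list(p_threshold = p_threshold, fold_threshold = fold_threshold,
                 n_boot = as.integer(n_boot), detect_frac = detect_frac,
                 p_adjust = p_adjust, seed = as.integer(seed)),
            class = "detection_config")
}

# Vectorised two-group one-way ANOVA on the rows of two matrices
# (bait: p x nb, ctrl: p x nc). Returns r (linear fold 10^(mean diff)),
# p-value, F. Degenerate rows (zero within- and between-group variance)
# get p = 1; perfect separation is clamped to the smallest positive double.
two_group_anova <- function(bait, ctrl) {
  nb <- ncol(bait); nc <- ncol(ctrl)
  mb <- rowMeans(bait); mc <- rowMeans(ctrl)
  grand <- (nb * mb + nc * mc) / (nb + nc)
  ssb <- nb * (mb - grand)^2 + nc * (mc - grand)^2
  ssw <- rowSums((bait - mb)^2) + rowSums((ctrl - mc)^2)
  df1 <- 1
  df2 <- nb + nc - 2
  f <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  p[ssw == 0 & ssb == 0] <- 1           # all values identical in both groups
  p[ssw == 0 & ssb > 0] <- 0            # perfect separation
  p <- pmax(p, .Machine$double.xmin)    # keep p in (0, 1]
  list(r = 10^(mb - mc), p = p, f = f)
}

#' Enrichment and ANOVA p-value for one protein at one time point
#'
#' The enrichment r is the ratio of geometric means, `10^(mean log bait -
#' mean log control)`, over the runs of that time point; the p-value comes
#' from a one-way ANOVA (two-group F-test) on the log10 intensities.
#'
#' @param norm a [norm_table()] without missing cells
#' @param design sample design
#' @param protein protein identifier (row name)
#' @param time_s time point (seconds)
#' @return named numeric vector `c(r = ..., p = ...)`
#' @export
enrichment_and_pvalue <- function(norm, design, protein, time_s) {
  stopifnot(inherits(norm, "norm_table"))
  bait_runs <- design$run_id[design$background == "bait" &
                             design$time_s == time_s]
  ctrl_runs <- design$run_id[design$background == "control" &
                             design$time_s == time_s]
  if (length(bait_runs) < 2 || length(ctrl_runs) < 2) {
    stop("need at least 2 bait and 2 control runs at time ", time_s)
  }
  res <- two_group_anova(
    norm$log_intensity[protein, bait_runs, drop = FALSE],
    norm$log_intensity[protein, ctrl_runs, drop = FALSE])
  c(r = unname(res$r), p = unname(res$p))
}

# Resample each row of a matrix with replacement (independently per row)
resample_rows <- function(mat) {
  p <- nrow(mat); n <- ncol(mat)
  idx <- matrix(sample.int(n, p * n, replace = TRUE), nrow = p)
  matrix(mat[cbind(rep(seq_len(p), n), as.vector(idx))], nrow = p,
         dimnames = dimnames(mat))
}

#' Bootstrap-stabilised specific-interactor detection
#'
#' For each bootstrap iteration, run values are resampled with replacement
#' independently within every (protein, time point, background) group; the
#' enrichment r(t) and ANOVA p-value P(t) are recomputed on the resampled
#' data and the selection rule (p < P*, r > r*) applied. `P(Detection)` at a
#' time point is the fraction of iterations in which the protein was
#' selected; a protein is a specific interactor when `P(Detection)` reaches
#' `detect_frac` at some time point. Reported r(t) and P(t) are the bootstrap
#' means of the per-iteration values. Imputed cells are ordinary values in
#' the resampling.
#'
#' The bait protein itself is flagged (`is_bait`) and excluded from the
#' specific-interactor list even though it trivially passes the thresholds.
#'
#' @param norm a [norm_table()] without missing cells
#' @param design sample design
#' @param config a [detection_config()]
#' @param bait bait protein identifier; defaults to the design's `bait_name`
#' @return object of class `detection_result` with matrices `r_mean`,
#'   `p_mean`, `detect_frac` (protein x time), vectors `r_max`, `specific`,
#'   and bookkeeping fields
#' @export
bootstrap_detection <- function(norm, design, config = detection_config(),
                                bait = NULL) {
  stopifnot(inherits(norm, "norm_table"), inherits(config, "detection_config"))
  if (is.null(bait)) {
    bait <- unique(design$bait_name)
    bait <- if (length(bait) == 1 && !is.null(bait) && !is.na(bait)) bait
            else NA_character_
  }
  logm <- norm$log_intensity
  if (anyNA(logm)) stop("detection requires an imputed (complete) table")
  times <- sort(unique(design$time_s))
  proteins <- rownames(logm)
  np <- length(proteins); nt <- length(times)

  dm <- function(x) matrix(0, np, nt, dimnames = list(proteins, times))
  r_sum <- dm(); p_sum <- dm(); sel_count <- dm()

  set.seed(config$seed)
  for (b in seq_len(config$n_boot)) {
    for (ti in seq_len(nt)) {
      bait_runs <- design$run_id[design$background == "bait" &
                                 design$time_s == times[ti]]
      ctrl_runs <- design$run_id[design$background == "control" &
                                 design$time_s == times[ti]]
      res <- two_group_anova(resample_rows(logm[, bait_runs, drop = FALSE]),
                             resample_rows(logm[, ctrl_runs, drop = FALSE]))
      p <- if (config$p_adjust == "BH") stats::p.adjust(res$p, "BH") else res$p
      sel <- p < config$p_threshold & res$r > config$fold_threshold
      r_sum[, ti] <- r_sum[, ti] + res$r
      p_sum[, ti] <- p_sum[, ti] + p
      sel_count[, ti] <- sel_count[, ti] + sel
    }
  }
  r_mean <- r_sum / config$n_boot
  p_mean <- p_sum / config$n_boot
  frac <- sel_count / config$n_boot

  is_bait <- proteins == bait
  specific <- apply(frac, 1, function(v) any(v >= config$detect_frac))
  times_specific <- apply(frac, 1, function(v)
    times[v >= config$detect_frac], simplify = FALSE)
  structure(list(
    r_mean = r_mean, p_mean = p_mean, detect_frac = frac,
    r_max = apply(r_mean, 1, max),
    specific = specific & !is_bait,
    times_specific = times_specific,
    is_bait = is_bait, bait = bait, times = times, proteins = proteins,
    config = config
  ), class = "detection_result")
}

#' @export
print.detection_result <- function(x, ...) {
  cat("detection_result:", length(x$proteins), "proteins,",
      length(x$times), "time points;",
      sum(x$specific), "specific interactors (bait",
      if (is.na(x$bait)) "unknown" else x$bait, "excluded)\n")
  invisible(x)
}

#' Specific interactors called by a detection result
#'
#' @param result a `detection_result`
#' @return character vector of specific interactor identifiers (bait excluded)
#' @export
specific_interactors <- function(result) {
  result$proteins[result$specific]
}

#' Volcano table for one time point
#'
#' Projects a detection result at time t onto the columns used for a volcano
#' plot: bootstrap-mean enrichment, bootstrap-mean p-value, detection
#' fraction and the selected flag, sorted by decreasing enrichment.
#'
#' @param result a `detection_result`
#' @param time_s time point present in the result
#' @return data.frame (protein, r_mean, p_mean, detect_frac, selected)
#' @export
volcano_table <- function(result, time_s) {
  ti <- match(time_s, result$times)
  if (is.na(ti)) stop("unknown time point: ", time_s)
  tab <- data.frame(
    protein = result$proteins,
    r_mean = result$r_mean[, ti],
    p_mean = result$p_mean[, ti],
    detect_frac = result$detect_frac[, ti],
    selected = result$detect_frac[, ti] >= result$config$detect_frac,
    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$r_mean), ]
  rownames(tab) <- NULL
  tab
}

#' Number of specific interactors per time point
#'
#' Counts, for every time point, the proteins whose detection fraction
#' reaches the configured threshold there (bait excluded).
#'
#' @param result a `detection_result`
#' @return data.frame (time_s, n_interactors)
#' @export
interactors_per_time <- function(result) {
  keep <- !result$is_bait
  counts <- colSums(result$detect_frac[keep, , drop = FALSE] >=
                    result$config$detect_frac)
  data.frame(time_s = result$times, n_interactors = as.integer(counts))
}
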