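#' Derive a stage seed from a master seed
#'
#' Deterministic per-stage seeds so individual stages can be re-run in
#' isolation while the end-to-end pipeline stays bit-identical.
#'
#' @param seed master integer seed
#' @param stage stage name
#' @return integer seed in `[0, 2^31 - 1)`
#' @export
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% (2^31 - 1))
}

#' Run the full detection / co-recruitment / benchmarking pipeline
#'
#' Orchestrates preprocessing, bootstrap interactor detection, recruitment
#' profiles, the bootstrap Pearson correlation matrix, network construction
#' and (when a reference is supplied) benchmarking, for one bait experiment.
#' All stage seeds derive from the single master seed, so re-running with
#' the same inputs is bit-identical.
#'
#' @param intensities protein x run matrix (linear scale, `NA` missing)
#' @param design sample design data.frame
#' @param bait bait protein identifier
#' @param reference optional `reference_interactions` data.frame
#' @param detection a [detection_config()] (its seed is overridden by the
#'   derived stage seed)
#' @param alpha network significance level
#' @param hc_r high-confidence correlation threshold
#' @param n_boot_cor bootstrap samples per correlation pair
#' @param spike_ids optional spike-in identifiers
#' @param seed master seed
#' @param outdir optional directory; when given, every stage's tables plus a
#'   JSON manifest of parameters and seeds are written there
#' @return list with elements `norm`, `detection`, `interactors`,
#'   `profiles`, `cmat`, `network`, `hc_network`, `benchmark`, `manifest`
#'   (entries are `NULL` when not computable, e.g. fewer than 2 interactors)
#' @export
run_pipeline <- function(intensities, design, bait,
                         reference = NULL,
                         detection = detection_config(),
                         alpha = 5e-5, hc_r = 0.8, n_boot_cor = 1000L,
                         spike_ids = NULL, seed = 1L,
                         outdir = NULL) {
  check_design(intensities, design)
  seeds <- list(impute = derive_seed(seed, "impute"),
                detect = derive_seed(seed, "detect"),
                correlate = derive_seed(seed, "correlate"))
  norm <- preprocess_table(intensities, design, spike_ids = spike_ids,
                           seed = seeds$impute)
  detection$seed <- seeds$detect
  det <- bootstrap_detection(norm, design, detection, bait = bait)
  interactors <- specific_interactors(det)

  profiles <- cmat <- net <- hc <- bench <- NULL
  if (length(interactors) >= 2) {
    bn <- bait_normalize(norm, design, bait)
    profiles <- build_profiles(bn, design, interactors)
    cmat <- correlation_matrix(profiles, n_boot = n_boot_cor,
                               seed = seeds$correlate)
    net <- build_network(cmat, alpha = alpha, hc_r = hc_r)
    hc <- high_confidence_network(net)
    if (!is.null(reference)) bench <- benchmark_network(net, reference)
  }

  manifest <- list(
    bait = bait, seed = seed, stage_seeds = seeds,
    n_proteins = nrow(intensities), n_runs = ncol(intensities),
    thresholds = list(p_threshold = detection$p_threshold,
                      fold_threshold = detection$fold_threshold,
                      n_boot = detection$n_boot,
                      detect_frac = detection$detect_frac,
                      alpha = alpha, hc_r = hc_r,
                      n_boot_cor = as.integer(n_boot_cor)),
    n_interactors = length(interactors),
    n_edges = if (!is.null(net)) igraph::ecount(net) else 0L)

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_detection_tables(det, outdir)
    if (!is.null(profiles)) {
      utils::write.table(attr(profiles, "flat"),
                         file.path(outdir, "profiles.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
    }
    if (!is.null(cmat)) {
      utils::write.table(cmat$R, file.path(outdir, "correlation_R.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      utils::write.table(cmat$P, file.path(outdir, "correlation_P.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
    }
    if (!is.null(net)) write_network(net, file.path(outdir, "network"))
    if (!is.null(bench)) {
      jsonlite::write_json(unclass(bench),
                           file.path(outdir, "benchmark.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(norm = norm, detection = det, interactors = interactors,
       profiles = profiles, cmat = cmat, network = net, hc_network = hc,
       benchmark = bench, manifest = manifest)
}

write_detection_tables <- function(det, outdir) {
  long <- data.frame(
    protein = rep(det$proteins, times = length(det$times)),
    time_s = rep(det$times, each = length(det$proteins)),
    r_mean = as.vector(det$r_mean),
    p_mean = as.vector(det$p_mean),
    detect_frac = as.vector(det$detect_frac))
  utils::write.table(long, file.path(outdir, "detection_per_time.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary_tab <- data.frame(protein = det$proteins, r_max = det$r_max,
                            specific = det$specific, is_bait = det$is_bait)
  utils::write.table(summary_tab, file.path(outdir, "detection_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outdir)
}

#' Compare a detection result with simulated ground truth
#'
#' Sensitivity is the fraction of planted specific preys called specific;
#' the false discovery proportion is the fraction of called interactors that
#' were not planted.
#'
#' @param det a `detection_result`
#' @param truth `truth` element of [simulate_experiment()]
#' @return list (sensitivity, fdp, n_called, true_positives)
#' @export
detection_recovery <- function(det, truth) {
  called <- specific_interactors(det)
  tp <- sum(called %in% truth$specific_ids)
  list(sensitivity = if (length(truth$specific_ids)) {
         tp / length(truth$specific_ids)
       } else NA_real_,
       fdp = if (length(called)) 1 - tp / length(called) else 0,
       n_called = length(called), true_positives = tp)
}

#' Recall of planted within-module edges by a network
#'
#' @param net igraph network
#' @param truth `truth` element of [simulate_experiment()]
#' @return fraction of planted true edges recovered as network edges (NA
#'   when no true edges exist)
#' @export
edge_recall <- function(net, truth) {
  edges <- truth$true_edges
  if (nrow(edges) == 0) return(NA_real_)
  ref <- normalize_reference(as.data.frame(edges, stringsAsFactors = FALSE))
  edge_hits(net, ref) / nrow(ref)
}
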