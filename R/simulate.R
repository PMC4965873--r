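#' Kinetic profile presets
#'
#' Named relative-recruitment profiles over the stimulation time course,
#' scaled so the maximum over time is 1. They emulate the kinetic classes
#' observed for signalosome preys: a sharp early peak shortly after receptor
#' engagement, an intermediate peak, a late accumulation, a fast rise that is
#' sustained, and a constitutive (time-invariant) association.
#'
#' @param n_timepoints number of time points the profile must span
#' @return named list of numeric vectors, each of length `n_timepoints`,
#'   values in (0, 1] with max 1
#' @export
profile_presets <- function(n_timepoints = 5) {
  presets <- list(
    "early-peak"   = c(0.30, 1.00, 0.45, 0.20, 0.10),
    "mid-peak"     = c(0.10, 0.35, 1.00, 0.50, 0.20),
    "late-peak"    = c(0.05, 0.10, 0.30, 0.70, 1.00),
    "sustained"    = c(0.15, 0.80, 0.95, 1.00, 0.90),
    "constitutive" = c(1.00, 1.00, 1.00, 1.00, 1.00)
  )
  if (n_timepoints != 5L) {
    # interpolate onto the requested grid, preserving max = 1
    presets <- lapply(presets, function(p) {
      v <- stats::approx(seq_along(p), p, n = n_timepoints)$y
      v / max(v)
    })
  }
  presets
}

#' Simulation configuration for a synthetic AP-MS time course
#'
#' Defines one bait-tagged experiment plus its matched wild-type control:
#' sample sizes, planted specific interactors organised into co-recruitment
#' modules, contaminant background, log-normal intensity noise and
#' intensity-dependent missingness.
#'
#' Defaults mirror the design of the study conditions this generator
#' emulates: 5 stimulation conditions (unstimulated plus 30, 120, 300 and
#' 600 s), 3 biological x 3 technical replicates per condition and
#' background, 200 non-specific contaminants, 40 planted specific preys in 4
#' kinetic modules of 10, 8-fold mean enrichment at the profile peak, and a
#' per-measurement log10 intensity noise SD of 0.15.
#'
#' @param times stimulation time points in seconds
#' @param n_bio,n_tech biological / technical replicates per condition
#' @param n_background_proteins number of non-specific contaminant proteins
#' @param n_specific number of planted specific preys
#' @param modules list of `list(module_id, member_count, profile_shape)`;
#'   member counts must not exceed `n_specific`, leftover preys are assigned
#'   to no module (they carry the "sustained" shape but share no module edges)
#' @param enrichment_fold mean bait/control fold for specific preys at their
#'   profile peak (> 1)
#' @param noise_sd_log SD of the per-measurement log10 intensity noise
#' @param mean_log,sd_log mean and SD of the per-protein baseline log10
#'   intensity (the contaminant background distribution)
#' @param missing_rate_control probability that any cell is censored at
#'   random, on top of the detection-floor censoring
#' @param detection_floor intensities below this value are reported missing
#' @param bait_log10 constant log10 intensity of the bait protein in bait runs
#' @param seed integer seed; the whole experiment is reproducible from it
#' @return a list of class `sim_config`
#' @export
sim_config <- function(times = c(0, 30, 120, 300, 600),
                       n_bio = 3L,
                       n_tech = 3L,
                       n_background_proteins = 200L,
                       n_specific = 40L,
                       modules = NULL,
                       enrichment_fold = 8,
                       noise_sd_log = 0.15,
                       mean_log = 6,
                       sd_log = 0.8,
                       missing_rate_control = 0.05,
                       detection_floor = 1e4,
                       bait_log10 = 9,
                       seed = 1L) {
  if (is.null(modules)) {
    shapes <- c("early-peak", "mid-peak", "late-peak", "sustained")
    per <- n_specific %/% 4L
    modules <- lapply(seq_along(shapes), function(i) {
      list(module_id = paste0("M", i), member_count = per,
           profile_shape = shapes[i])
    })
  }
  stopifnot(length(times) >= 2, n_bio >= 1, n_tech >= 1,
            n_background_proteins >= 1, n_specific >= 0,
            enrichment_fold > 1, noise_sd_log >= 0,
            missing_rate_control >= 0, missing_rate_control <= 1,
            detection_floor >= 0)
  total <- sum(vapply(modules, function(m) m$member_count, numeric(1)))
  if (total > n_specific) {
    stop("module member counts (", total, ") exceed n_specific (",
         n_specific, ")")
  }
  structure(list(
    times = times, n_bio = as.integer(n_bio), n_tech = as.integer(n_tech),
    n_background_proteins = as.integer(n_background_proteins),
    n_specific = as.integer(n_specific), modules = modules,
    enrichment_fold = enrichment_fold, noise_sd_log = noise_sd_log,
    mean_log = mean_log, sd_log = sd_log,
    missing_rate_control = missing_rate_control,
    detection_floor = detection_floor, bait_log10 = bait_log10,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Simulate one bait-vs-control AP-MS time course
#'
#' Generates one run per (background in bait/control) x time x biological x
#' technical replicate. Contaminant proteins share the same expected
#' intensity in both backgrounds; planted specific preys have expected bait
#' intensity `background level x enrichment_fold x profile(t)` while sitting
#' at background level in control runs; the bait protein itself is present at
#' a high constant intensity in bait runs only. Intensities are simulated on
#' the log10 scale and exponentiated. Cells falling below the detection floor
#' and a Bernoulli fraction of all cells are reported missing (`NA`).
#'
#' @param config a [sim_config()]
#' @param bait_name identifier used for the bait protein row
#' @return list with elements `intensities` (protein x run matrix, `NA` =
#'   missing), `design` (data.frame: run_id, background, bait_name, time_s,
#'   bio_rep, tech_rep) and `truth` (list: specific_ids, profile_of,
#'   module_of, true_edges, baseline_log)
#' @export
simulate_experiment <- function(config, bait_name = "BAIT") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  nt <- length(config$times)
  presets <- profile_presets(nt)

  specific_ids <- if (config$n_specific > 0) {
    sprintf("PREY%03d", seq_len(config$n_specific))
  } else character(0)
  background_ids <- sprintf("CONT%03d", seq_len(config$n_background_proteins))
  proteins <- c(bait_name, specific_ids, background_ids)

  # module membership and kinetic profile per specific prey
  module_of <- stats::setNames(rep(NA_character_, length(specific_ids)),
                               specific_ids)
  profile_of <- matrix(NA_real_, nrow = length(specific_ids), ncol = nt,
                       dimnames = list(specific_ids, NULL))
  cursor <- 0L
  for (m in config$modules) {
    if (m$member_count == 0) next
    idx <- cursor + seq_len(m$member_count)
    module_of[idx] <- m$module_id
    profile_of[idx, ] <- matrix(presets[[m$profile_shape]], nrow = length(idx),
                                ncol = nt, byrow = TRUE)
    cursor <- cursor + m$member_count
  }
  if (cursor < length(specific_ids)) {
    rest <- (cursor + 1L):length(specific_ids)
    profile_of[rest, ] <- matrix(presets[["sustained"]], nrow = length(rest),
                                 ncol = nt, byrow = TRUE)
  }

  # within-module undirected edges
  true_edges <- do.call(rbind, lapply(unique(stats::na.omit(module_of)),
    function(mid) {
      members <- names(module_of)[!is.na(module_of) & module_of == mid]
      if (length(members) < 2) return(NULL)
      t(utils::combn(members, 2))
    }))
  if (is.null(true_edges)) {
    true_edges <- matrix(character(0), ncol = 2)
  }
  colnames(true_edges) <- c("a", "b")

  # run grid
  grid <- expand.grid(tech_rep = seq_len(config$n_tech),
                      bio_rep = seq_len(config$n_bio),
                      time_s = config$times,
                      background = c("bait", "control"),
                      stringsAsFactors = FALSE)
  run_id <- sprintf("%s_t%03d_b%d_r%d",
                    ifelse(grid$background == "bait", "bait", "ctrl"),
                    match(grid$time_s, config$times) - 1L,
                    grid$bio_rep, grid$tech_rep)
  design <- data.frame(run_id = run_id, background = grid$background,
                       bait_name = bait_name, time_s = grid$time_s,
                       bio_rep = grid$bio_rep, tech_rep = grid$tech_rep,
                       stringsAsFactors = FALSE)

  # per-protein baseline (non-specific background level), shared between
  # backgrounds so contaminants must be rejected by the enrichment test
  baseline_log <- stats::setNames(
    stats::rnorm(length(proteins), config$mean_log, config$sd_log), proteins)

  nrun <- nrow(design)
  expected_log <- matrix(rep(baseline_log, nrun), nrow = length(proteins),
                         ncol = nrun,
                         dimnames = list(proteins, design$run_id))
  bait_runs <- design$background == "bait"
  t_index <- match(design$time_s, config$times)
  if (length(specific_ids) > 0) {
    fold_log <- log10(config$enrichment_fold * profile_of) # prey x time
    expected_log[specific_ids, bait_runs] <-
      expected_log[specific_ids, bait_runs] + fold_log[, t_index[bait_runs]]
  }
  # bait protein: high constant intensity in bait runs only, essentially
  # absent from control pulldowns
  expected_log[bait_name, ] <- ifelse(bait_runs, config$bait_log10, -Inf)

  noise <- matrix(stats::rnorm(length(expected_log), 0, config$noise_sd_log),
                  nrow = nrow(expected_log))
  intensities <- 10^(expected_log + noise)
  intensities[expected_log == -Inf] <- 0

  # missingness: the detection floor censors low intensities everywhere;
  # on top of that, control (background) purifications lose a random
  # fraction of cells, emulating the sparser sampling of non-specific
  # background. High bait-side signals are only lost through the floor.
  below <- intensities < config$detection_floor | intensities == 0
  random_miss <- matrix(
    stats::runif(length(intensities)) < config$missing_rate_control,
    nrow = nrow(intensities))
  random_miss[, bait_runs] <- FALSE
  intensities[below | random_miss] <- NA_real_

  truth <- list(specific_ids = specific_ids,
                profile_of = profile_of,
                module_of = module_of,
                true_edges = true_edges,
                baseline_log = baseline_log,
                bait = bait_name)
  list(intensities = intensities, design = design, truth = truth)
}

#' Down-sample the ground-truth edge list into a reference interaction list
#'
#' Emulates an external curated interaction database that covers only part of
#' the truly existing interactions: each planted within-module edge is kept
#' independently with probability `recall`.
#'
#' @param truth `truth` element returned by [simulate_experiment()]
#' @param recall probability in \[0, 1\] that a true edge is present in the
#'   reference
#' @param seed integer seed
#' @return data.frame with columns `a`, `b` (undirected, upper-cased symbols)
#' @export
truth_reference_list <- function(truth, recall, seed = 1L) {
  stopifnot(recall >= 0, recall <= 1)
  edges <- truth$true_edges
  set.seed(as.integer(seed))
  keep <- stats::runif(nrow(edges)) < recall
  out <- as.data.frame(edges[keep, , drop = FALSE], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  normalize_reference(out)
}

#' Write the synthetic experiment as the pipeline's external file formats
#'
#' Produces a protein-groups style intensity table, a design table, a
#' two-column reference edge list and a ground-truth table, so the synthetic
#' data can be consumed through the same readers as real data.
#'
#' @param sim result of [simulate_experiment()]
#' @param dir output directory (created if needed)
#' @param reference optional reference edge data.frame to write alongside
#' @return invisibly, the named vector of file paths written
#' @export
write_fixture_files <- function(sim, dir, reference = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(intensities = file.path(dir, "proteinGroups.txt"),
             design = file.path(dir, "design.tsv"),
             truth = file.path(dir, "ground_truth.tsv"))
  write_protein_groups(sim$intensities, paths[["intensities"]])
  utils::write.table(sim$design, paths[["design"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_tab <- data.frame(
    protein = rownames(sim$truth$profile_of),
    module = unname(sim$truth$module_of),
    t(apply(sim$truth$profile_of, 1, identity)),
    check.names = FALSE)
  colnames(truth_tab) <- c("protein", "module",
                           paste0("profile_t", seq_len(ncol(sim$truth$profile_of))))
  utils::write.table(truth_tab, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(reference)) {
    paths <- c(paths, reference = file.path(dir, "reference.tsv"))
    utils::write.table(reference, paths[["reference"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(paths)
}
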