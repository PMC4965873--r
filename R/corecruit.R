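#' Bait normalization
#'
#' Rescales every run so that the bait protein has the same intensity in all
#' of them (on the log scale: a per-run additive offset bringing the bait to
#' the mean bait level). This removes run-to-run differences in purification
#' yield before recruitment kinetics are compared.
#'
#' @param norm a [norm_table()] without missing cells
#' @param design sample design
#' @param bait bait protein identifier (must be observed, not imputed, in
#'   every bait run)
#' @return a [norm_table()] restricted to the bait runs
#' @export
bait_normalize <- function(norm, design, bait) {
  stopifnot(inherits(norm, "norm_table"))
  if (!bait %in% rownames(norm$log_intensity)) {
    stop("bait '", bait, "' not found in the table")
  }
  bait_runs <- design$run_id[design$background == "bait"]
  miss <- bait_runs[norm$imputed[bait, bait_runs]]
  if (length(miss)) {
    stop("bait '", bait, "' not observed in run(s): ",
         paste(miss, collapse = ", "))
  }
  logm <- norm$log_intensity[, bait_runs, drop = FALSE]
  bait_log <- logm[bait, ]
  offsets <- mean(bait_log) - bait_log
  out <- sweep(logm, 2, offsets, "+")
  norm_table(out, imputed = norm$imputed[, bait_runs, drop = FALSE],
             audit = c(norm$audit, list(bait_offsets = offsets)))
}

#' Build normalized recruitment profiles
#'
#' For every interactor, biological replicate and time point the
#' technical-replicate mean of the (bait-normalized, linear-scale) intensity
#' is computed; each biological replicate's time series is then divided by
#' its maximum over time, so profiles live in \[0, 1\] with max 1. An
#' all-zero series yields a zero profile and is flagged.
#'
#' @param norm a bait-normalized [norm_table()] covering the bait runs
#' @param design sample design (only bait runs are used)
#' @param interactors protein identifiers to profile
#' @return 3-d array `[protein, time, bio_rep]` of class
#'   `recruitment_profiles`, with attributes `times` and `flat` (the
#'   protein x (time x bio) matrix used for correlations)
#' @export
build_profiles <- function(norm, design, interactors) {
  stopifnot(inherits(norm, "norm_table"))
  missing_ids <- setdiff(interactors, rownames(norm$log_intensity))
  if (length(missing_ids)) {
    stop("interactors not in table: ", paste(missing_ids, collapse = ", "))
  }
  bd <- design[design$background == "bait" &
               design$run_id %in% colnames(norm$log_intensity), ]
  times <- sort(unique(bd$time_s))
  bios <- sort(unique(bd$bio_rep))
  lin <- 10^norm$log_intensity[interactors, , drop = FALSE]

  prof <- array(NA_real_, dim = c(length(interactors), length(times),
                                  length(bios)),
                dimnames = list(interactors, times, bios))
  for (bi in seq_along(bios)) {
    for (ti in seq_along(times)) {
      runs <- bd$run_id[bd$bio_rep == bios[bi] & bd$time_s == times[ti]]
      prof[, ti, bi] <- rowMeans(lin[, runs, drop = FALSE])
    }
    mx <- apply(prof[, , bi, drop = FALSE], 1, max)
    scale <- ifelse(mx > 0, mx, 1)       # all-zero series stay zero
    prof[, , bi] <- prof[, , bi] / scale
  }
  flat <- matrix(prof, nrow = length(interactors),
                 dimnames = list(interactors, NULL))
  zero <- apply(flat, 1, function(v) all(v == 0))
  structure(prof, class = "recruitment_profiles", times = times,
            flat = flat, all_zero = zero)
}

# Paired profile vectors for two proteins (concatenation over bio reps of
# the per-time normalized values)
profile_points <- function(profiles, i, j) {
  flat <- attr(profiles, "flat")
  list(x = flat[i, ], y = flat[j, ])
}

# Pearson r and two-sided p (t distribution, n - 2 df) for paired vectors
pearson_rp <- function(x, y) {
  n <- length(x)
  r <- suppressWarnings(stats::cor(x, y))
  if (is.na(r)) return(c(r = NA_real_, p = NA_real_))
  r2 <- min(abs(r), 1 - 1e-15)
  tt <- r2 * sqrt((n - 2) / (1 - r2^2))
  p <- max(2 * stats::pt(-tt, n - 2), .Machine$double.xmin)
  c(r = r, p = p)
}

# Core bootstrap for one pair of paired vectors: resample the paired points
# with replacement, compute Pearson r and p per sample, return the means
# over non-degenerate samples.
bootstrap_pearson_xy <- function(x, y, n_boot) {
  n <- length(x)
  idx <- matrix(sample.int(n, n_boot * n, replace = TRUE), nrow = n_boot)
  xs <- matrix(x[idx], nrow = n_boot)
  ys <- matrix(y[idx], nrow = n_boot)
  xm <- rowMeans(xs); ym <- rowMeans(ys)
  xc <- xs - xm; yc <- ys - ym
  sx <- sqrt(rowSums(xc^2)); sy <- sqrt(rowSums(yc^2))
  ok <- sx > 0 & sy > 0
  r <- rowSums(xc * yc) / (sx * sy)
  r2 <- pmin(abs(r), 1 - 1e-15)
  tt <- r2 * sqrt((n - 2) / (1 - r2^2))
  p <- pmax(2 * stats::pt(-tt, n - 2), .Machine$double.xmin)
  c(R = mean(r[ok]), P = mean(p[ok]), n_skipped = sum(!ok))
}

#' Bootstrap Pearson correlation between two recruitment profiles
#'
#' Pairs the two proteins' normalized recruitment values across all
#' (time point, biological replicate) observations, resamples the paired
#' points with replacement and computes the Pearson coefficient and its
#' two-sided p-value (t distribution on n - 2 df) in every bootstrap sample.
#' The reported R and P are means over samples; zero-variance samples are
#' skipped and counted.
#'
#' @param profiles a `recruitment_profiles` object
#' @param i,j protein identifiers (or indices)
#' @param n_boot bootstrap samples (default 1000)
#' @param seed integer seed
#' @return named vector `c(R, P, n_skipped)`
#' @export
bootstrap_pearson <- function(profiles, i, j, n_boot = 1000L, seed = 1L) {
  pts <- profile_points(profiles, i, j)
  if (length(pts$x) < 3) stop("need at least 3 paired observations")
  set.seed(as.integer(seed))
  bootstrap_pearson_xy(pts$x, pts$y, as.integer(n_boot))
}

#' Bootstrap Pearson correlation matrix over all interactor pairs
#'
#' Applies the paired bootstrap Pearson estimate to every unordered pair of
#' profiled proteins (each pair computed once; the matrix is symmetric by
#' construction, with unit diagonal). Proteins whose profile is degenerate
#' (all zero) are excluded with a warning.
#'
#' @param profiles a `recruitment_profiles` object
#' @param n_boot bootstrap samples per pair (default 1000)
#' @param seed integer seed (pairs are visited in a fixed order)
#' @return list of class `correlation_matrix` with matrices `R` and `P`
#' @export
correlation_matrix <- function(profiles, n_boot = 1000L, seed = 1L) {
  flat <- attr(profiles, "flat")
  zero <- attr(profiles, "all_zero")
  if (any(zero)) {
    warning("excluding degenerate all-zero profiles: ",
            paste(names(zero)[zero], collapse = ", "))
    flat <- flat[!zero, , drop = FALSE]
  }
  ids <- rownames(flat)
  n <- length(ids)
  if (n < 2) stop("need at least 2 non-degenerate profiles")
  R <- diag(1, n); P <- matrix(.Machine$double.xmin, n, n)
  dimnames(R) <- dimnames(P) <- list(ids, ids)
  set.seed(as.integer(seed))
  for (a in seq_len(n - 1)) {
    xa <- flat[a, ]
    for (b in (a + 1):n) {
      est <- bootstrap_pearson_xy(xa, flat[b, ], as.integer(n_boot))
      R[a, b] <- R[b, a] <- est[["R"]]
      P[a, b] <- P[b, a] <- est[["P"]]
    }
  }
  structure(list(R = R, P = P, proteins = ids, n_boot = as.integer(n_boot),
                 seed = as.integer(seed)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat("correlation_matrix:", length(x$proteins), "proteins,",
      x$n_boot, "bootstrap samples per pair\n")
  invisible(x)
}

#' K-means partition of the correlation matrix
#'
#' Clusters interactors using the rows of the correlation matrix as feature
#' vectors (squared-Euclidean K-means, best of `n_init` starts).
#'
#' @param cmat a `correlation_matrix`
#' @param k number of clusters (2 <= k <= number of proteins)
#' @param n_init random restarts (default 25)
#' @param seed integer seed
#' @return named integer vector of cluster labels
#' @export
kmeans_partition <- function(cmat, k, n_init = 25L, seed = 1L) {
  stopifnot(inherits(cmat, "correlation_matrix"))
  n <- nrow(cmat$R)
  if (k < 2 || k > n) stop("k must be in [2, ", n, "]")
  if (k == n) return(stats::setNames(seq_len(n), cmat$proteins))  # singletons
  set.seed(as.integer(seed))
  fit <- stats::kmeans(cmat$R, centers = k, nstart = as.integer(n_init))
  stats::setNames(fit$cluster, cmat$proteins)
}

#' Mean silhouette width across candidate k
#'
#' Helper for choosing the number of K-means clusters: average silhouette
#' width (squared-Euclidean distance on the correlation-matrix rows) for
#' each candidate k.
#'
#' @param cmat a `correlation_matrix`
#' @param k_range candidate cluster counts
#' @inheritParams kmeans_partition
#' @return data.frame (k, mean_silhouette)
#' @export
silhouette_scan <- function(cmat, k_range = 2:8, n_init = 25L, seed = 1L) {
  d <- stats::dist(cmat$R)
  res <- vapply(k_range, function(k) {
    labels <- kmeans_partition(cmat, k, n_init = n_init, seed = seed)
    mean(cluster::silhouette(labels, d)[, "sil_width"])
  }, numeric(1))
  data.frame(k = k_range, mean_silhouette = res)
}

#' Bonferroni edge threshold
#'
#' For N interactors there are N(N-1)/2 candidate correlations; the
#' family-wise threshold at significance level alpha is
#' `alpha / (N(N-1)/2)`.
#'
#' @param alpha significance level (0 < alpha < 1)
#' @param n_nodes number of interactors N (>= 2)
#' @return threshold p-value P*
#' @export
bonferroni_threshold <- function(alpha, n_nodes) {
  stopifnot(alpha > 0, alpha < 1, n_nodes >= 2)
  alpha / (n_nodes * (n_nodes - 1) / 2)
}

#' Build the co-recruitment network
#'
#' Draws an edge between two interactors when their bootstrap-mean Pearson
#' p-value falls below the Bonferroni threshold for the chosen alpha; edges
#' with R above `hc_r` carry the high-confidence flag.
#'
#' @param cmat a `correlation_matrix`
#' @param alpha network significance level (default 5e-5)
#' @param hc_r high-confidence correlation threshold (default 0.8)
#' @return igraph object with edge attributes `R`, `P`, `high_confidence`
#'   and graph attributes `alpha`, `p_threshold`, `hc_r`
#' @export
build_network <- function(cmat, alpha = 5e-5, hc_r = 0.8) {
  stopifnot(inherits(cmat, "correlation_matrix"))
  n <- length(cmat$proteins)
  p_star <- bonferroni_threshold(alpha, n)
  pairs <- which(upper.tri(cmat$P) & cmat$P < p_star, arr.ind = TRUE)
  edges <- data.frame(
    from = cmat$proteins[pairs[, 1]],
    to = cmat$proteins[pairs[, 2]],
    R = cmat$R[pairs],
    P = cmat$P[pairs],
    stringsAsFactors = FALSE)
  edges$high_confidence <- edges$R > hc_r
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = cmat$proteins)
  g <- igraph::set_graph_attr(g, "alpha", alpha)
  g <- igraph::set_graph_attr(g, "p_threshold", p_star)
  g <- igraph::set_graph_attr(g, "hc_r", hc_r)
  g
}

#' High-confidence subnetwork
#'
#' Keeps only edges whose bootstrap-mean Pearson R exceeds the
#' high-confidence threshold stored in the network.
#'
#' @param net network built by [build_network()]
#' @return igraph object (same vertex set)
#' @export
high_confidence_network <- function(net) {
  igraph::subgraph_from_edges(net, igraph::E(net)[igraph::E(net)$high_confidence],
                              delete.vertices = FALSE)
}
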