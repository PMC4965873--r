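prep_clean <- function(seed = 61) {
  sim <- clean_sim(seed = seed)
  norm <- preprocess_table(sim$intensities, sim$design, seed = 1)
  list(sim = sim, norm = norm)
}

test_that("bait normalization makes the bait row constant across runs", {
  x <- prep_clean(61)
  bn <- bait_normalize(x$norm, x$sim$design, "BAIT")
  bait_row <- bn$log_intensity["BAIT", ]
  expect_lt(max(bait_row) - min(bait_row), 1e-12)
  bait_runs <- x$sim$design$run_id[x$sim$design$background == "bait"]
  expect_setequal(colnames(bn$log_intensity), bait_runs)

  # already-constant bait: identity on the bait runs
  again <- bait_normalize(bn, x$sim$design, "BAIT")
  expect_equal(again$log_intensity, bn$log_intensity)

  # a run where everything (bait included) is doubled is scaled back, up to
  # the constant absorbed by the bait's mean level
  shifted <- bn
  shifted$log_intensity[, 1] <- shifted$log_intensity[, 1] + log10(2)
  undone <- bait_normalize(shifted, x$sim$design, "BAIT")
  delta <- undone$log_intensity - bn$log_intensity
  expect_lt(diff(range(delta)), 1e-12)
})

test_that("bait missing from a bait run is an error naming the run", {
  x <- prep_clean(62)
  norm <- x$norm
  bait_runs <- x$sim$design$run_id[x$sim$design$background == "bait"]
  norm$imputed["BAIT", bait_runs[3]] <- TRUE
  expect_error(bait_normalize(norm, x$sim$design, "BAIT"), bait_runs[3],
               fixed = TRUE)
  expect_error(bait_normalize(x$norm, x$sim$design, "NOPE"), "not found")
})

test_that("profiles are tech-replicate means max-normalized per bio rep", {
  # hand-built: 1 protein, 3 times, 1 bio rep, 2 tech reps, monotone series
  design <- data.frame(
    run_id = paste0("r", 1:6),
    background = "bait", bait_name = "B", time_s = rep(c(0, 30, 120), each = 2),
    bio_rep = 1, tech_rep = rep(1:2, 3), stringsAsFactors = FALSE)
  lin <- rbind(A = log10(c(1, 1, 2, 2, 4, 4)), B = rep(5, 6))
  colnames(lin) <- design$run_id
  prof <- build_profiles(norm_table(lin), design, c("A", "B"))
  expect_equal(unname(prof["A", , 1]), c(0.25, 0.5, 1))
  # constant series normalizes to all ones
  expect_equal(unname(prof["B", , 1]), c(1, 1, 1))
})

test_that("noiseless planted profiles are recovered exactly", {
  x <- prep_clean(63)
  bn <- bait_normalize(x$norm, x$sim$design, "BAIT")
  prof <- build_profiles(bn, x$sim$design, x$sim$truth$specific_ids)
  for (p in x$sim$truth$specific_ids) {
    planted <- x$sim$truth$profile_of[p, ]
    for (b in 1:3) {
      expect_equal(unname(prof[p, , b]), unname(planted / max(planted)),
                   tolerance = 1e-9)
    }
  }
})

test_that("profiles absorb a constant rescaling of one bio replicate", {
  x <- prep_clean(64)
  bn <- bait_normalize(x$norm, x$sim$design, "BAIT")
  ids <- x$sim$truth$specific_ids
  prof1 <- build_profiles(bn, x$sim$design, ids)
  bn2 <- bn
  b2 <- x$sim$design$run_id[x$sim$design$background == "bait" &
                            x$sim$design$bio_rep == 2]
  keep <- rownames(bn2$log_intensity) != "BAIT"
  bn2$log_intensity[keep, b2] <- bn2$log_intensity[keep, b2] + 0.7
  prof2 <- build_profiles(bn2, x$sim$design, ids)
  expect_equal(prof2, prof1, ignore_attr = TRUE, tolerance = 1e-9)
})

test_that("plain Pearson matches the closed-form oracle to 12 decimals", {
  set.seed(65)
  for (i in 1:10) {
    xv <- rnorm(15); yv <- 0.6 * xv + rnorm(15, 0, 0.5)
    est <- recruitnet:::pearson_rp(xv, yv)
    ct <- stats::cor.test(xv, yv)
    expect_equal(unname(est["r"]), unname(ct$estimate), tolerance = 1e-12)
    expect_equal(unname(est["p"]), ct$p.value, tolerance = 1e-12)
  }
})

test_that("self- and anti-correlated profiles hit the boundaries", {
  flat <- rbind(a = c(0.1, 0.4, 1, 0.6, 0.2, 0.15, 0.45, 0.95, 0.55, 0.25,
                      0.12, 0.42, 1, 0.58, 0.22),
                b = NA)
  flat["b", ] <- 1 - flat["a", ]
  prof <- structure(array(flat, dim = c(2, 15, 1),
                          dimnames = list(c("a", "b"), NULL, NULL)),
                    class = "recruitment_profiles", flat = flat,
                    all_zero = c(a = FALSE, b = FALSE))
  self <- bootstrap_pearson(prof, "a", "a", n_boot = 100, seed = 1)
  expect_equal(unname(self["R"]), 1, tolerance = 1e-12)
  expect_lt(unname(self["P"]), 1e-12)
  anti <- bootstrap_pearson(prof, "a", "b", n_boot = 100, seed = 1)
  expect_equal(unname(anti["R"]), -1, tolerance = 1e-12)
})

test_that("bootstrap mean agrees with an independent large-sample oracle", {
  set.seed(66)
  xv <- runif(15); yv <- 0.8 * xv + rnorm(15, 0, 0.15)
  flat <- rbind(a = xv, b = yv)
  prof <- structure(array(flat, dim = c(2, 15, 1),
                          dimnames = list(c("a", "b"), NULL, NULL)),
                    class = "recruitment_profiles", flat = flat,
                    all_zero = c(a = FALSE, b = FALSE))
  est <- bootstrap_pearson(prof, "a", "b", n_boot = 1000, seed = 2)

  # oracle: naive re-implementation with its own RNG stream, 1e5 samples
  set.seed(1234)
  n <- 15
  rs <- ps <- numeric(1e5)
  for (b in seq_len(1e5)) {
    idx <- sample.int(n, n, replace = TRUE)
    r <- suppressWarnings(stats::cor(xv[idx], yv[idx]))
    rs[b] <- r
    tt <- abs(r) * sqrt((n - 2) / (1 - min(abs(r), 1 - 1e-15)^2))
    ps[b] <- 2 * stats::pt(-tt, n - 2)
  }
  se_r <- stats::sd(rs) / sqrt(1000)
  se_p <- stats::sd(ps) / sqrt(1000)
  expect_lt(abs(est[["R"]] - mean(rs)), 3 * se_r)
  expect_lt(abs(est[["P"]] - mean(ps)), 3 * se_p)
})

test_that("correlation matrix is symmetric with unit diagonal", {
  x <- prep_clean(67)
  bn <- bait_normalize(x$norm, x$sim$design, "BAIT")
  prof <- build_profiles(bn, x$sim$design, x$sim$truth$specific_ids)
  cmat <- correlation_matrix(prof, n_boot = 50, seed = 3)
  expect_identical(cmat$R, t(cmat$R))
  expect_identical(cmat$P, t(cmat$P))
  expect_equal(unname(diag(cmat$R)), rep(1, nrow(cmat$R)))
  expect_true(all(abs(cmat$R) <= 1 + 1e-12))
  expect_true(all(cmat$P > 0 & cmat$P <= 1))

  # two-protein matrix equals the single-pair estimate
  prof2 <- build_profiles(bn, x$sim$design, x$sim$truth$specific_ids[1:2])
  cm2 <- correlation_matrix(prof2, n_boot = 50, seed = 3)
  set.seed(3)
  pair <- recruitnet:::bootstrap_pearson_xy(attr(prof2, "flat")[1, ],
                                            attr(prof2, "flat")[2, ], 50L)
  expect_equal(cm2$R[1, 2], pair[["R"]])
  expect_equal(cm2$P[1, 2], pair[["P"]])
})

test_that("within-module correlations exceed between-module correlations", {
  sim <- small_sim(seed = 68, noise_sd_log = 0.05)
  norm <- preprocess_table(sim$intensities, sim$design, seed = 1)
  bn <- bait_normalize(norm, sim$design, "BAIT")
  prof <- build_profiles(bn, sim$design, sim$truth$specific_ids)
  cmat <- correlation_matrix(prof, n_boot = 100, seed = 4)
  mod <- sim$truth$module_of[cmat$proteins]
  same <- outer(mod, mod, "==") & upper.tri(cmat$R)
  diff <- outer(mod, mod, "!=") & upper.tri(cmat$R)
  expect_gt(mean(cmat$R[same]), mean(cmat$R[diff]))
})

test_that("k-means recovers well separated modules", {
  sim <- small_sim(seed = 69, noise_sd_log = 0.05)
  norm <- preprocess_table(sim$intensities, sim$design, seed = 1)
  bn <- bait_normalize(norm, sim$design, "BAIT")
  prof <- build_profiles(bn, sim$design, sim$truth$specific_ids)
  cmat <- correlation_matrix(prof, n_boot = 50, seed = 5)
  labels <- kmeans_partition(cmat, 2, seed = 6)
  truthmod <- sim$truth$module_of[names(labels)]
  expect_equal(ari_oracle(labels, truthmod), 1)

  # k = N gives singleton clusters
  n <- length(cmat$proteins)
  singletons <- kmeans_partition(cmat, n, seed = 6)
  expect_equal(length(unique(singletons)), n)
  expect_error(kmeans_partition(cmat, n + 1), "k must be")
})

test_that("Bonferroni threshold follows alpha / (N(N-1)/2)", {
  expect_equal(bonferroni_threshold(5e-5, 98), 5e-5 / (98 * 97 / 2))
  expect_equal(signif(bonferroni_threshold(5e-5, 98), 3), 1.05e-8)
  expect_equal(bonferroni_threshold(0.01, 2), 0.01)
  expect_equal(signif(bonferroni_threshold(5e-5, 44), 3), 5.29e-8)
  expect_error(bonferroni_threshold(0, 10))
})

test_that("network edges obey the threshold and the high-confidence flag", {
  proteins <- paste0("P", 1:6)
  R <- diag(1, 6); P <- matrix(1, 6, 6)
  dimnames(R) <- dimnames(P) <- list(proteins, proteins)
  set_pair <- function(i, j, r, p) {
    R[i, j] <<- R[j, i] <<- r
    P[i, j] <<- P[j, i] <<- p
  }
  set_pair(1, 2, 0.99, 1e-12)
  set_pair(2, 3, 0.5, 1e-10)
  set_pair(4, 5, 0.9, 1e-5)   # above the Bonferroni threshold: no edge
  cmat <- structure(list(R = R, P = P, proteins = proteins, n_boot = 1L,
                         seed = 1L), class = "correlation_matrix")
  net <- build_network(cmat, alpha = 5e-5)
  p_star <- bonferroni_threshold(5e-5, 6)
  expect_equal(igraph::ecount(net), 2)
  expect_true(all(igraph::E(net)$P < p_star))
  hc <- high_confidence_network(net)
  expect_equal(igraph::ecount(hc), 1)
  expect_true(all(igraph::E(hc)$R > 0.8))

  # all p-values at 1: empty network
  empty <- build_network(structure(list(R = diag(1, 6), P = matrix(1, 6, 6),
                                        proteins = proteins, n_boot = 1L,
                                        seed = 1L),
                                   class = "correlation_matrix"))
  expect_equal(igraph::ecount(empty), 0)
})

test_that("raising alpha only adds edges; HC stays nested; order-invariant", {
  sim <- small_sim(seed = 70, noise_sd_log = 0.02)
  norm <- preprocess_table(sim$intensities, sim$design, seed = 1)
  bn <- bait_normalize(norm, sim$design, "BAIT")
  prof <- build_profiles(bn, sim$design, sim$truth$specific_ids)
  cmat <- correlation_matrix(prof, n_boot = 100, seed = 7)
  edge_keys <- function(net) {
    el <- igraph::as_edgelist(net)
    sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2])))
  }
  tight <- build_network(cmat, alpha = 1e-6)
  loose <- build_network(cmat, alpha = 1e-3)
  expect_true(all(edge_keys(tight) %in% edge_keys(loose)))
  net <- build_network(cmat, alpha = 5e-5)
  expect_true(all(edge_keys(high_confidence_network(net)) %in% edge_keys(net)))

  perm <- sample(length(cmat$proteins))
  cmat_p <- cmat
  cmat_p$R <- cmat$R[perm, perm]
  cmat_p$P <- cmat$P[perm, perm]
  cmat_p$proteins <- cmat$proteins[perm]
  expect_equal(edge_keys(build_network(cmat_p, alpha = 5e-5)),
               edge_keys(net))
})

test_that("noiseless co-recruited pairs form edges with R = 1", {
  x <- prep_clean(71)
  bn <- bait_normalize(x$norm, x$sim$design, "BAIT")
  prof <- build_profiles(bn, x$sim$design, x$sim$truth$specific_ids)
  cmat <- correlation_matrix(prof, n_boot = 200, seed = 8)
  net <- build_network(cmat, alpha = 5e-5)
  expect_equal(edge_recall(net, x$sim$truth), 1)
  mod <- x$sim$truth$module_of[x$sim$truth$specific_ids]
  pair <- names(mod)[mod == "M1"][1:2]
  expect_equal(cmat$R[pair[1], pair[2]], 1, tolerance = 1e-9)
})

test_that("silhouette scan prefers the planted number of modules", {
  sim <- small_sim(seed = 72, noise_sd_log = 0.05)
  norm <- preprocess_table(sim$intensities, sim$design, seed = 1)
  bn <- bait_normalize(norm, sim$design, "BAIT")
  prof <- build_profiles(bn, sim$design, sim$truth$specific_ids)
  cmat <- correlation_matrix(prof, n_boot = 50, seed = 9)
  scan <- silhouette_scan(cmat, k_range = 2:5, seed = 10)
  expect_equal(scan$k[which.max(scan$mean_silhouette)], 2)
})
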