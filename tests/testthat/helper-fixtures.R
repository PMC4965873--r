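# Shared fixtures: small synthetic experiments and independent oracles.

# compact experiment for fast unit tests
small_config <- function(seed = 1L, ...) {
  sim_config(n_background_proteins = 40L, n_specific = 8L,
             modules = list(
               list(module_id = "M1", member_count = 4,
                    profile_shape = "early-peak"),
               list(module_id = "M2", member_count = 4,
                    profile_shape = "late-peak")),
             seed = seed, ...)
}

small_sim <- function(seed = 1L, ...) simulate_experiment(small_config(seed, ...))

# noise-free, fully observed experiment (exact arithmetic downstream)
clean_sim <- function(seed = 1L) {
  simulate_experiment(sim_config(
    n_background_proteins = 20L, n_specific = 8L,
    modules = list(
      list(module_id = "M1", member_count = 4, profile_shape = "early-peak"),
      list(module_id = "M2", member_count = 4, profile_shape = "late-peak")),
    noise_sd_log = 0, missing_rate_control = 0, detection_floor = 0,
    seed = seed))
}

# textbook one-way ANOVA oracle via stats::lm / stats::anova
anova_oracle <- function(bait_vals, ctrl_vals) {
  df <- data.frame(y = c(bait_vals, ctrl_vals),
                   g = factor(rep(c("bait", "ctrl"),
                                  c(length(bait_vals), length(ctrl_vals)))))
  p <- stats::anova(stats::lm(y ~ g, data = df))[["Pr(>F)"]][1]
  r <- 10^(mean(bait_vals) - mean(ctrl_vals))
  c(r = r, p = p)
}

# brute-force breadth-first shortest paths from one source
bfs_oracle <- function(adj, source) {
  n <- nrow(adj)
  dist <- rep(Inf, n)
  dist[source] <- 0
  frontier <- source
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) {
      nbr <- which(adj[v, ] == 1 & is.infinite(dist))
      dist[nbr] <- dist[v] + 1
      nxt <- c(nxt, nbr)
    }
    frontier <- unique(nxt)
  }
  dist
}

# adjusted Rand index between two labelings (independent of mclust)
ari_oracle <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}
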