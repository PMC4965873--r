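#' Precision of predicted interactions
#'
#' Fraction of predicted edges that are present in the reference interaction
#' list. Undefined (NA) when nothing was predicted.
#'
#' @param n_validated predicted edges found in the reference
#' @param n_predicted total predicted edges
#' @return raw quotient (report with [round2()] for the 2-decimal convention)
#' @export
precision <- function(n_validated, n_predicted) {
  stopifnot(n_validated >= 0, n_predicted >= 0, n_validated <= n_predicted)
  if (n_predicted == 0) return(NA_real_)
  n_validated / n_predicted
}

#' Random-network baseline probability
#'
#' Probability that a uniformly random edge among N nodes hits one of the K
#' reference interactions present among those nodes: `2K / (N(N-1))`.
#'
#' @param k_reference_edges reference edges among the network's nodes
#' @param n_nodes node count (>= 2)
#' @return probability
#' @export
random_baseline <- function(k_reference_edges, n_nodes) {
  stopifnot(k_reference_edges >= 0, n_nodes >= 2)
  2 * k_reference_edges / (n_nodes * (n_nodes - 1))
}

#' First neighbors of a node
#'
#' @param net igraph network
#' @param node vertex name
#' @return character vector of nodes at unweighted graph distance 1
#' @export
first_neighbors <- function(net, node) {
  if (!node %in% igraph::V(net)$name) stop("node '", node, "' not in network")
  names(igraph::neighbors(net, node))
}

#' Validation of a node's first neighbors against a target set
#'
#' @param net igraph network
#' @param node anchor vertex name
#' @param target_set character vector of protein identifiers
#' @return list (hits, n_neighbors, fraction, percent); fraction is NA for an
#'   isolated node
#' @export
neighbor_validation <- function(net, node, target_set) {
  nb <- first_neighbors(net, node)
  hits <- sum(nb %in% toupper(target_set))
  frac <- if (length(nb) == 0) NA_real_ else hits / length(nb)
  list(hits = hits, n_neighbors = length(nb), fraction = frac,
       percent = if (is.na(frac)) NA_real_ else round1(100 * frac))
}

#' Expected neighbor hit rate for randomly drawn edges
#'
#' Chance that a random network neighbor belongs to the target set, with all
#' network nodes as candidates: `100 x n_targets / n_candidates` percent.
#'
#' @param n_targets size of the target set among the candidates
#' @param n_candidates candidate node count (>= 1)
#' @return percentage (raw; round with [round1()] for reporting)
#' @export
expected_random_neighbor_rate <- function(n_targets, n_candidates) {
  stopifnot(n_candidates >= 1, n_targets >= 0)
  100 * n_targets / n_candidates
}

#' Distance-stratified validation
#'
#' Groups all other network nodes by unweighted shortest-path distance from
#' an anchor node and reports, per distance, how many belong to the target
#' set. Unreachable nodes are binned as `Inf`.
#'
#' @param net igraph network
#' @param anchor_node anchor vertex name
#' @param target_set character vector of protein identifiers
#' @return data.frame (distance, n_nodes, hits, fraction)
#' @export
distance_stratified_validation <- function(net, anchor_node, target_set) {
  if (!anchor_node %in% igraph::V(net)$name) {
    stop("anchor '", anchor_node, "' not in network")
  }
  d <- igraph::distances(net, v = anchor_node)[1, ]
  d <- d[names(d) != anchor_node]
  target_set <- toupper(target_set)
  lv <- sort(unique(d))
  rows <- lapply(lv, function(dd) {
    nodes <- names(d)[d == dd]
    hits <- sum(nodes %in% target_set)
    data.frame(distance = dd, n_nodes = length(nodes), hits = hits,
               fraction = hits / length(nodes))
  })
  do.call(rbind, rows)
}

#' Enrichment ratio between two maximum mean enrichments
#'
#' @param r_max_a,r_max_b maximum mean enrichments (positive)
#' @return quotient (raw; round with [round1()] for reporting)
#' @export
enrichment_ratio <- function(r_max_a, r_max_b) {
  stopifnot(r_max_a > 0, r_max_b > 0)
  r_max_a / r_max_b
}

#' Reporting rounders
#'
#' The study conventions: probabilities to 2 decimals, percentages and folds
#' to 1 decimal. Raw values are always retained in machine output; these
#' helpers only format reports.
#'
#' @param x numeric
#' @return rounded numeric
#' @export
round2 <- function(x) round(x, 2)

#' @rdname round2
#' @export
round1 <- function(x) round(x, 1)

# count predicted edges present in the reference (unordered symbol pairs)
edge_hits <- function(net, reference) {
  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0) return(0L)
  lo <- pmin(toupper(el[, 1]), toupper(el[, 2]))
  hi <- pmax(toupper(el[, 1]), toupper(el[, 2]))
  keys <- paste(lo, hi, sep = "\r")
  ref_keys <- paste(reference$a, reference$b, sep = "\r")
  sum(keys %in% ref_keys)
}

# reference edges whose both endpoints are network nodes
reference_edges_among <- function(reference, nodes) {
  nodes <- toupper(nodes)
  sum(reference$a %in% nodes & reference$b %in% nodes)
}

#' Benchmark a co-recruitment network against a reference interaction list
#'
#' Computes, for both the complete network and its high-confidence
#' subnetwork: the number of predicted edges, the number validated by the
#' reference, the precision, the number of reference edges among the
#' network's nodes and the corresponding random-network baseline.
#'
#' @param net network built by [build_network()]
#' @param reference a `reference_interactions` data.frame
#' @return list of class `benchmark_report`
#' @export
benchmark_network <- function(net, reference) {
  hc <- high_confidence_network(net)
  report_one <- function(g) {
    n_nodes <- igraph::vcount(g)
    n_pred <- igraph::ecount(g)
    n_val <- edge_hits(g, reference)
    k <- reference_edges_among(reference, igraph::V(g)$name)
    list(n_nodes = n_nodes, n_predicted_edges = n_pred,
         n_validated = n_val,
         precision = precision(n_val, n_pred),
         n_reference_edges_among_nodes = k,
         random_baseline = if (n_nodes >= 2) random_baseline(k, n_nodes)
                           else NA_real_)
  }
  structure(list(full = report_one(net), high_confidence = report_one(hc)),
            class = "benchmark_report")
}

#' @export
print.benchmark_report <- function(x, ...) {
  fmt <- function(lbl, r) {
    cat(sprintf("%s: %d nodes, %d predicted edges, %d validated (precision %s; random baseline %s over %d reference edges)\n",
                lbl, r$n_nodes, r$n_predicted_edges, r$n_validated,
                ifelse(is.na(r$precision), "NA", round2(r$precision)),
                ifelse(is.na(r$random_baseline), "NA",
                       round2(r$random_baseline)),
                r$n_reference_edges_among_nodes))
  }
  fmt("complete network", x$full)
  fmt("high-confidence network", x$high_confidence)
  invisible(x)
}
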