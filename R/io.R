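#' Default ubiquitin alias map
#'
#' Ubiquitin is encoded by four genes (two of them as fusions with ribosomal
#' proteins); label-free AP-MS evidence for any of them is conventionally
#' indexed under a single ubiquitin symbol. The default map collapses
#' UBA52, RPS27A, UBB and UBC onto "UB".
#'
#' @return named character vector: names are gene symbols, values the alias
#' @export
ub_alias_map <- function() {
  c(UBA52 = "UB", RPS27A = "UB", UBB = "UB", UBC = "UB")
}

#' Read a MaxQuant-style protein groups table
#'
#' Reads a tab-separated protein groups file with one `Intensity <run>`
#' column per LC-MS run. Rows flagged as reverse decoys or potential
#' contaminants (marker columns containing `+`) are dropped, zero intensities
#' become missing values, and each protein group is mapped to one display
#' identifier: the first gene name if present, else the first majority
#' protein accession. Groups resolving to the same symbol (including through
#' `alias_map`) are merged by summing intensities per run.
#'
#' @param path tab-separated file
#' @param id_policy `"gene_first"` (first gene symbol, accession fallback) or
#'   `"accession"` (always first accession)
#' @param alias_map named character vector applied to the display identifier
#'   after upper-casing (default [ub_alias_map()]); `NULL` disables aliasing
#' @return numeric matrix (protein x run) with `NA` for missing cells;
#'   attribute `id_map` records the group-to-identifier mapping
#' @export
read_protein_groups <- function(path, id_policy = c("gene_first", "accession"),
                                alias_map = ub_alias_map()) {
  id_policy <- match.arg(id_policy)
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (nrow(tab) == 0) stop("empty protein groups file: ", path)
  int_cols <- grep("^Intensity .+", colnames(tab), value = TRUE)
  if (length(int_cols) == 0) stop("no 'Intensity <run>' columns in ", path)
  run_ids <- sub("^Intensity ", "", int_cols)
  if (anyDuplicated(run_ids)) stop("duplicate run ids in ", path)

  drop <- rep(FALSE, nrow(tab))
  for (col in c("Reverse", "Potential contaminant", "Contaminant")) {
    if (col %in% colnames(tab)) drop <- drop | tab[[col]] %in% "+"
  }
  tab <- tab[!drop, , drop = FALSE]

  first_field <- function(x) vapply(strsplit(x, ";", fixed = TRUE),
                                    function(v) if (length(v)) v[[1]] else "",
                                    character(1))
  genes <- if ("Gene names" %in% colnames(tab)) {
    first_field(as.character(tab[["Gene names"]]))
  } else rep("", nrow(tab))
  accs <- if ("Majority protein IDs" %in% colnames(tab)) {
    first_field(as.character(tab[["Majority protein IDs"]]))
  } else rep("", nrow(tab))
  ids <- if (id_policy == "gene_first") ifelse(genes != "", genes, accs) else accs
  if (any(ids == "")) stop("rows without identifier in ", path)
  ids <- toupper(ids)
  if (!is.null(alias_map)) {
    hit <- ids %in% names(alias_map)
    ids[hit] <- unname(alias_map[ids[hit]])
  }

  mat <- as.matrix(tab[, int_cols, drop = FALSE])
  mode(mat) <- "numeric"
  colnames(mat) <- run_ids
  mat[!is.finite(mat)] <- NA_real_
  mat[mat == 0] <- NA_real_

  # merge protein groups sharing one display symbol by summing per run
  merged <- rowsum(ifelse(is.na(mat), 0, mat), group = ids)
  seen <- rowsum((!is.na(mat)) * 1L, group = ids)
  merged[seen == 0] <- NA_real_
  attr(merged, "id_map") <- data.frame(row = seq_along(ids), id = ids,
                                       stringsAsFactors = FALSE)
  merged
}

#' Write an intensity matrix as a MaxQuant-style protein groups file
#'
#' Missing cells are written as 0, following the zero-as-missing convention
#' of label-free protein groups output.
#'
#' @param intensities protein x run matrix with `NA` missing cells
#' @param path output file
#' @export
write_protein_groups <- function(intensities, path) {
  out <- data.frame(
    `Majority protein IDs` = rownames(intensities),
    `Gene names` = rownames(intensities),
    Reverse = "", `Potential contaminant` = "",
    check.names = FALSE, stringsAsFactors = FALSE)
  vals <- ifelse(is.na(intensities), 0, intensities)
  colnames(vals) <- paste("Intensity", colnames(intensities))
  out <- cbind(out, as.data.frame(vals, check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample design table
#'
#' @param path tab-separated table with columns `run_id`, `background`
#'   (`bait`/`control`), `time_s`, `bio_rep`, `tech_rep` and optionally
#'   `bait_name`
#' @param intensities optional intensity matrix to validate run ids against
#' @return data.frame of run annotations
#' @export
read_design <- function(path, intensities = NULL) {
  design <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("run_id", "background", "time_s", "bio_rep", "tech_rep")
  missing_cols <- setdiff(required, colnames(design))
  if (length(missing_cols)) {
    stop("design table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (!all(design$background %in% c("bait", "control"))) {
    stop("design 'background' must be 'bait' or 'control'")
  }
  if (!is.null(intensities)) check_design(intensities, design)
  design
}

check_design <- function(intensities, design) {
  runs <- colnames(intensities)
  if (!setequal(runs, design$run_id) || anyDuplicated(design$run_id)) {
    stop("run ids in design and intensity table do not match one-to-one")
  }
  invisible(TRUE)
}

normalize_reference <- function(edges) {
  if (nrow(edges) == 0) {
    out <- data.frame(a = character(0), b = character(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("reference_interactions", class(out))
    return(out)
  }
  a <- toupper(trimws(as.character(edges[[1]])))
  b <- toupper(trimws(as.character(edges[[2]])))
  keep <- a != b & a != "" & b != ""
  a <- a[keep]; b <- b[keep]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  dedup <- !duplicated(key)
  out <- data.frame(a = lo[dedup], b = hi[dedup], stringsAsFactors = FALSE)
  class(out) <- c("reference_interactions", class(out))
  out
}

#' Read a reference physical-interaction edge list
#'
#' Accepts either a BioGRID tab-delimited export (columns
#' `Official Symbol Interactor A`/`B`) or a plain two-column symbol-pair
#' table. Symbols are upper-cased (human/mouse symbol case differs between
#' databases), self-loops are removed and (A,B)/(B,A) duplicates collapsed.
#'
#' @param path tab-separated file; an empty file yields an empty edge set
#' @param alias_map named character vector applied to symbols (default
#'   [ub_alias_map()]); `NULL` disables aliasing
#' @return data.frame of class `reference_interactions` with columns `a`, `b`
#' @export
read_reference <- function(path, alias_map = ub_alias_map()) {
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character(0))
  if (length(first) == 0 || !nzchar(first)) {
    return(normalize_reference(data.frame(a = character(0), b = character(0))))
  }
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  bio_a <- "Official Symbol Interactor A"
  bio_b <- "Official Symbol Interactor B"
  if (all(c(bio_a, bio_b) %in% colnames(tab))) {
    edges <- tab[, c(bio_a, bio_b)]
  } else if (ncol(tab) >= 2) {
    edges <- tab[, 1:2]
  } else {
    stop("reference file must have two symbol columns or BioGRID headers")
  }
  if (!is.null(alias_map) && nrow(edges) > 0) {
    for (j in 1:2) {
      v <- toupper(trimws(as.character(edges[[j]])))
      hit <- v %in% names(alias_map)
      v[hit] <- unname(alias_map[v[hit]])
      edges[[j]] <- v
    }
  }
  normalize_reference(edges)
}

#' Write / read a correlation network
#'
#' `write_network()` stores a network as GraphML plus a flat edge table
#' (`node_a`, `node_b`, `R`, `P`, `high_confidence`); `read_edge_table()`
#' reconstructs the igraph object from the edge table.
#'
#' @param net igraph object with edge attributes `R`, `P`, `high_confidence`
#' @param path output path without extension; `<path>.graphml` and
#'   `<path>_edges.tsv` are written
#' @return invisibly, the paths written
#' @export
write_network <- function(net, path) {
  graphml <- paste0(path, ".graphml")
  edges_path <- paste0(path, "_edges.tsv")
  igraph::write_graph(net, graphml, format = "graphml")
  write_edge_table(net, edges_path)
  invisible(c(graphml = graphml, edges = edges_path))
}

#' @rdname write_network
#' @export
write_edge_table <- function(net, path) {
  el <- igraph::as_edgelist(net)
  tab <- data.frame(
    node_a = if (nrow(el)) el[, 1] else character(0),
    node_b = if (nrow(el)) el[, 2] else character(0),
    R = if (igraph::ecount(net)) igraph::E(net)$R else numeric(0),
    P = if (igraph::ecount(net)) igraph::E(net)$P else numeric(0),
    high_confidence = if (igraph::ecount(net)) igraph::E(net)$high_confidence
                      else logical(0),
    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @param nodes optional character vector of node names (isolated nodes are
#'   not recoverable from an edge table alone)
#' @export
read_edge_table <- function(path, nodes = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  vertices <- unique(c(nodes, tab$node_a, tab$node_b))
  g <- igraph::graph_from_data_frame(
    tab[, c("node_a", "node_b", "R", "P", "high_confidence")],
    directed = FALSE, vertices = vertices)
  g
}
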