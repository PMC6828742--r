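#' Construct a protein-protein interaction graph
#'
#' A `ppi_graph` holds an ordered gene universe and a symmetric,
#' non-negative adjacency matrix of interaction-confidence weights, the
#' substrate for [propagate_weights()]. Isolated nodes (zero row sum) are
#' allowed; they are recorded in the `isolated` attribute and receive only
#' the restart term during propagation.
#'
#' @param adjacency symmetric non-negative numeric matrix of edge
#'   confidences; self-loops are permitted but not required.
#' @param nodes character vector of unique gene identifiers, one per
#'   row/column of `adjacency`. Defaults to the matrix dimnames.
#' @return An object of class `ppi_graph` with elements `nodes`,
#'   `adjacency` and `degree` (row sums).
#' @seealso [read_string_graph()], [normalize_adjacency()]
#' @export
#' @examples
#' A <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
#' g <- ppi_graph(A)
ppi_graph <- function(adjacency, nodes = rownames(adjacency)) {
  if (!is.matrix(adjacency) || !is.numeric(adjacency))
    stop_user("adjacency must be a numeric matrix")
  if (nrow(adjacency) != ncol(adjacency))
    stop_user("adjacency must be square")
  if (is.null(nodes)) stop_user("node identifiers are required")
  nodes <- as.character(nodes)
  if (length(nodes) != nrow(adjacency))
    stop_user("length(nodes) must match the adjacency dimension")
  if (anyDuplicated(nodes))
    stop_user("duplicate node identifiers: ",
              paste(unique(nodes[duplicated(nodes)]), collapse = ", "))
  if (anyNA(adjacency)) stop_user("adjacency contains missing values")
  if (any(adjacency < 0)) stop_user("negative edge weights are not allowed")
  if (max(abs(adjacency - t(adjacency))) > 1e-12)
    stop_user("adjacency must be symmetric")
  dimnames(adjacency) <- list(nodes, nodes)
  deg <- rowSums(adjacency)
  structure(
    list(nodes = nodes, adjacency = adjacency, degree = deg),
    isolated = nodes[deg == 0],
    class = "ppi_graph"
  )
}

#' @export
print.ppi_graph <- function(x, ...) {
  n_edge <- sum(x$adjacency[upper.tri(x$adjacency)] > 0)
  cat("ppi_graph:", length(x$nodes), "nodes,", n_edge, "edges\n")
  iso <- attr(x, "isolated")
  if (length(iso) > 0) cat("  isolated nodes:", length(iso), "\n")
  invisible(x)
}

#' Build a ppi_graph from an edge list
#'
#' @param edges data frame with columns `protein1`, `protein2`,
#'   `combined_score`. Scores on the STRING 0-1000 scale (detected by
#'   `max > 1`) are divided by 1000; scores already in `[0, 1]` pass
#'   through.
#' @param nodes optional gene universe; defaults to the genes seen in the
#'   edge list (sorted). Extra nodes become isolated vertices.
#' @return A [ppi_graph()].
#' @export
ppi_graph_from_edges <- function(edges, nodes = NULL) {
  need <- c("protein1", "protein2", "combined_score")
  if (!all(need %in% names(edges)))
    stop_user("edge list must have columns ", paste(need, collapse = ", "))
  score <- as.numeric(edges$combined_score)
  if (anyNA(score)) stop_user("non-numeric combined_score values")
  if (any(score < 0)) stop_user("negative edge weights are not allowed")
  if (length(score) > 0 && max(score) > 1) score <- score / 1000
  p1 <- as.character(edges$protein1)
  p2 <- as.character(edges$protein2)
  if (is.null(nodes)) nodes <- sort(unique(c(p1, p2)))
  missing <- setdiff(c(p1, p2), nodes)
  if (length(missing) > 0)
    stop_user("edge endpoints absent from the node universe: ",
              paste(head(missing, 5), collapse = ", "))
  A <- matrix(0, length(nodes), length(nodes), dimnames = list(nodes, nodes))
  i <- match(p1, nodes); j <- match(p2, nodes)
  # symmetrize; on duplicate pairs the last score wins
  A[cbind(i, j)] <- score
  A[cbind(j, i)] <- score
  ppi_graph(A, nodes)
}

#' Read a STRING-style interaction file
#'
#' Parses the STRING "detail" format: whitespace- or tab-delimited columns
#' `protein1 protein2 combined_score`, with or without a header line.
#' Combined scores on the published 0-1000 integer scale are rescaled to
#' `[0, 1]`.
#'
#' @param path path to the edge-list file.
#' @param mapping optional path to a two-column identifier-mapping TSV
#'   (protein id, gene symbol); endpoints are translated before the graph
#'   is built and unmapped proteins kept under their original id.
#' @param nodes optional gene universe passed to [ppi_graph_from_edges()].
#' @return A [ppi_graph()].
#' @export
read_string_graph <- function(path, mapping = NULL, nodes = NULL) {
  if (!file.exists(path)) stop_user("file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- grepl("protein1", first, fixed = TRUE) ||
    is.na(suppressWarnings(as.numeric(strsplit(trimws(first), "[ \t]+")[[1]][3])))
  tab <- read.table(path, header = has_header, stringsAsFactors = FALSE)
  if (ncol(tab) < 3)
    stop_user("expected at least 3 columns (protein1 protein2 combined_score) in ", path)
  names(tab)[1:3] <- c("protein1", "protein2", "combined_score")
  if (!is.null(mapping)) {
    if (!file.exists(mapping)) stop_user("file not found: ", mapping)
    map <- read.table(mapping, header = FALSE, stringsAsFactors = FALSE)
    lut <- stats::setNames(as.character(map[[2]]), as.character(map[[1]]))
    tr <- function(x) ifelse(x %in% names(lut), unname(lut[x]), x)
    tab$protein1 <- tr(as.character(tab$protein1))
    tab$protein2 <- tr(as.character(tab$protein2))
  }
  ppi_graph_from_edges(tab[, 1:3], nodes = nodes)
}

#' Symmetric degree normalization of a PPI adjacency matrix
#'
#' Computes `A' = D^{-1/2} A D^{-1/2}` where `D` is the diagonal matrix of
#' row sums of `A`, i.e. each edge weight is normalized by the degrees of
#' its endpoints. Rows and columns of zero-degree (isolated) nodes are set
#' to zero, so such nodes receive only the restart term during
#' propagation. All eigenvalues of the result lie in `[-1, 1]`, which
#' makes the propagation iteration a contraction for any alpha < 1.
#'
#' @param graph a [ppi_graph()].
#' @return The normalized adjacency matrix (symmetric, dimnames kept).
#' @export
normalize_adjacency <- function(graph) {
  stopifnot(inherits(graph, "ppi_graph"))
  d <- graph$degree
  inv_sqrt <- ifelse(d > 0, 1 / sqrt(d), 0)
  Ap <- graph$adjacency * tcrossprod(inv_sqrt)
  dimnames(Ap) <- dimnames(graph$adjacency)
  Ap
}
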