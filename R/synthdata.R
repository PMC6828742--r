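# Synthetic benchmark: expression matrices with i.i.d. standard-normal
# entries stand in for standardized RMA profiles; the drug response is a
# deterministic 5th-degree polynomial of two planted target genes, and a
# planted-neighborhood PPI fixture stands in for STRING.

#' Generate a standardized expression matrix
#'
#' Entries are i.i.d. standard normal, emulating standardized (per-gene
#' z-scored) RMA basal expression profiles. Rows are samples (cell
#' lines), columns genes.
#'
#' @param n_samples,n_genes matrix dimensions (each >= 2).
#' @param seed RNG seed; the same seed reproduces the matrix exactly.
#' @return Numeric matrix with sample ids `S001, ...` and gene ids
#'   `g001, ...`.
#' @export
make_expression <- function(n_samples = 200L, n_genes = 200L, seed = 1L) {
  if (n_samples < 2 || n_genes < 2) stop_user("need n_samples, n_genes >= 2")
  set.seed(seed)
  X <- matrix(rnorm(n_samples * n_genes), n_samples, n_genes)
  wid <- function(prefix, n) sprintf("%s%0*d", prefix, max(3L, nchar(n)), seq_len(n))
  dimnames(X) <- list(wid("S", n_samples), wid("g", n_genes))
  X
}

#' Synthetic IC50 response from two target genes
#'
#' Evaluates the deterministic 5th-degree drug-sensitivity surface
#' `a*Xi^5 + b*Xj^5 + c*Xi^3*Xj^2 + d*Xi^2*Xj^3` on two distinct columns
#' of the expression matrix. No noise term is added: the response is an
#' exact function of the two planted targets.
#'
#' @param X expression matrix.
#' @param i,j distinct column indices or gene names of the two targets.
#' @param coeffs numeric coefficients `(a, b, c, d)`; default all 1.
#' @return Numeric response vector, one value per sample.
#' @export
synthetic_ic50 <- function(X, i, j, coeffs = c(a = 1, b = 1, c = 1, d = 1)) {
  if (is.character(i)) i <- match(i, colnames(X))
  if (is.character(j)) j <- match(j, colnames(X))
  if (anyNA(c(i, j))) stop_user("unknown target gene")
  if (i == j) stop_user("the two target genes must be distinct")
  if (length(coeffs) != 4) stop_user("coeffs must have 4 entries (a, b, c, d)")
  xi <- X[, i]; xj <- X[, j]
  coeffs[1] * xi^5 + coeffs[2] * xj^5 +
    coeffs[3] * xi^3 * xj^2 + coeffs[4] * xi^2 * xj^3
}

#' Generate the full synthetic drug-sensitivity benchmark
#'
#' Draws a standardized expression matrix, picks (or accepts) two target
#' genes, computes the polynomial IC50 response and its min-max scaled
#' version. This is the dataset on which biased ensembles with all prior
#' weight on the two targets can be compared against unbiased random
#' forests.
#'
#' @inheritParams make_expression
#' @param targets two gene ids (or indices) to plant the signal on;
#'   `NULL` picks two at random (seeded).
#' @param coeffs polynomial coefficients, see [synthetic_ic50()].
#' @return A `synthetic_benchmark` list: `expression`, `targets` (gene
#'   ids), `target_idx`, `coeffs`, `ic50` (raw), `ic50_scaled`
#'   ([scale_ic50()] output).
#' @export
make_benchmark <- function(n_samples = 200L, n_genes = 200L, targets = NULL,
                           coeffs = c(a = 1, b = 1, c = 1, d = 1), seed = 1L) {
  X <- make_expression(n_samples, n_genes, seed)
  if (is.null(targets)) {
    set.seed(seed + 104729L)
    targets <- sample(colnames(X), 2L)
  }
  if (is.numeric(targets)) targets <- colnames(X)[targets]
  if (length(targets) != 2 || anyNA(match(targets, colnames(X))))
    stop_user("targets must name two genes of the expression matrix")
  y <- synthetic_ic50(X, targets[1], targets[2], coeffs)
  structure(list(expression = X, targets = targets,
                 target_idx = match(targets, colnames(X)),
                 coeffs = coeffs, ic50 = y, ic50_scaled = scale_ic50(y)),
            class = "synthetic_benchmark")
}

#' @export
print.synthetic_benchmark <- function(x, ...) {
  cat("synthetic_benchmark:", nrow(x$expression), "samples x",
      ncol(x$expression), "genes; targets:",
      paste(x$targets, collapse = ", "), "\n")
  invisible(x)
}

#' Generate a planted-neighborhood PPI fixture
#'
#' Builds a synthetic interaction network over a gene universe: each
#' target is wired to its own set of effector genes with high confidence
#' (0.9), and sparse background edges among all genes are added at low
#' confidence (0.15). Propagating target weights over the fixture must
#' rank the effectors above background genes, which makes the planted
#' structure a ground truth for diffusion tests.
#'
#' @param universe character vector of gene ids.
#' @param targets genes to wire effectors to (subset of `universe`).
#' @param effectors_per_target effectors planted per target (default 3).
#' @param background_density probability of a background edge between any
#'   unplanted gene pair, in `[0, 1]` (0 leaves non-planted genes
#'   isolated).
#' @param seed RNG seed.
#' @return A `ppi_fixture` list: `graph` ([ppi_graph()]), `targets`,
#'   `effectors` (named list per target), `edges` (data frame with
#'   `protein1`, `protein2`, `combined_score` in `(0, 1]`).
#' @export
make_ppi_fixture <- function(universe, targets, effectors_per_target = 3L,
                             background_density = 0.02, seed = 1L) {
  universe <- as.character(universe)
  targets <- as.character(targets)
  if (!all(targets %in% universe)) stop_user("targets must lie in the universe")
  if (!(background_density >= 0 && background_density <= 1))
    stop_user("background_density must lie in [0, 1]")
  pool <- setdiff(universe, targets)
  if (length(pool) < effectors_per_target * length(targets))
    stop_user("not enough non-target genes for the requested effectors")
  set.seed(seed)
  effectors <- list()
  for (tg in targets) {
    eff <- sample(pool, effectors_per_target)
    pool <- setdiff(pool, eff)
    effectors[[tg]] <- eff
  }
  p1 <- character(0); p2 <- character(0); sc <- numeric(0)
  for (tg in targets) {
    p1 <- c(p1, rep(tg, length(effectors[[tg]])))
    p2 <- c(p2, effectors[[tg]])
    sc <- c(sc, rep(0.9, length(effectors[[tg]])))
  }
  if (background_density > 0) {
    pairs <- utils::combn(universe, 2)
    planted <- paste(p1, p2) # planted pairs, either orientation
    planted <- c(planted, paste(p2, p1))
    keep <- runif(ncol(pairs)) < background_density
    keep <- keep & !(paste(pairs[1, ], pairs[2, ]) %in% planted)
    p1 <- c(p1, pairs[1, keep]); p2 <- c(p2, pairs[2, keep])
    sc <- c(sc, rep(0.15, sum(keep)))
  }
  edges <- data.frame(protein1 = p1, protein2 = p2, combined_score = sc,
                      stringsAsFactors = FALSE)
  structure(list(graph = ppi_graph_from_edges(edges, nodes = universe),
                 targets = targets, effectors = effectors, edges = edges),
            class = "ppi_fixture")
}

#' Write an edge list in STRING detail format
#'
#' Writes `protein1 protein2 combined_score` (space-delimited, header
#' line, scores on the STRING 0-1000 integer scale) so the file can be
#' read back with [read_string_graph()]. Output is byte-identical for
#' identical input.
#'
#' @param x a `ppi_fixture` or an edge data frame with confidences in
#'   `(0, 1]`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_string_edges <- function(x, path) {
  edges <- if (inherits(x, "ppi_fixture")) x$edges else x
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("protein1 protein2 combined_score", con)
  writeLines(sprintf("%s %s %d", edges$protein1, edges$protein2,
                     as.integer(round(edges$combined_score * 1000))), con)
  invisible(path)
}
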