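# Shared oracles and fixture builders. Oracles are deliberately naive
# (dense enumeration, direct linear solves) and independent of the code
# paths they check.

# exhaustive enumeration over all (gene, midpoint-threshold) pairs;
# ties broken towards lower gene index, then lower threshold, and a
# split must strictly reduce the node SSE
brute_best_split <- function(X, y, candidates, tps) {
  parent <- sum((y - mean(y))^2)
  eps <- 1e-10 * parent
  best <- NULL
  for (f in sort(candidates)) {
    v <- sort(unique(X[, f]))
    if (length(v) < 2) next
    for (thr in (v[-length(v)] + v[-1]) / 2) {
      left <- X[, f] <= thr
      if (sum(left) < tps || sum(!left) < tps) next
      loss <- sum((y[left] - mean(y[left]))^2) +
        sum((y[!left] - mean(y[!left]))^2)
      if (is.null(best) || loss < best$loss - eps)
        best <- list(gene = f, threshold = thr, loss = loss)
    }
  }
  if (!is.null(best) && !(best$loss < parent * (1 - 1e-12))) return(NULL)
  best
}

# direct linear solve of the diffusion fixed point
closed_form_ws <- function(w0, graph, alpha) {
  Ap <- normalize_adjacency(graph)
  drop(solve(diag(nrow(Ap)) - alpha * Ap, (1 - alpha) * as.numeric(w0)))
}

# Erdos-Renyi-style random weighted PPI graph
random_ppi <- function(n, p_edge = 0.1, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  on <- up[runif(length(up)) < p_edge]
  A[on] <- runif(length(on), 0.1, 1)
  A <- A + t(A)
  nodes <- sprintf("g%03d", seq_len(n))
  dimnames(A) <- list(nodes, nodes)
  ppi_graph(A)
}

path_graph <- function(ids) {
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) A[i, i + 1] <- A[i + 1, i] <- 1
  ppi_graph(A)
}

star_graph <- function(hub, leaves) {
  ids <- c(hub, leaves)
  A <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  A[1, -1] <- A[-1, 1] <- 1
  ppi_graph(A)
}

# small benchmark reused by harness tests
small_bench <- function(n_samples = 60, n_genes = 20, seed = 1) {
  make_benchmark(n_samples, n_genes, seed = seed)
}
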