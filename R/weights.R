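#' Initial bias weights from drug targets
#'
#' Builds the initial split-sampling weight vector W0: every reported drug
#' target receives `high_weight` and every other gene the small positive
#' floor `epsilon`, so that no feature is ever strictly unselectable.
#' Targets missing from the gene universe are skipped with a warning; the
#' skip count is recorded in the `skipped` attribute.
#'
#' @param targets character vector of target gene identifiers.
#' @param universe ordered character vector of all gene identifiers
#'   (typically the expression-matrix columns).
#' @param high_weight weight given to targets, in `(epsilon, 1]`. The
#'   convention is that a weight of 0 would mean "never select" and 1
#'   "always select"; intermediate values bias the per-node feature draw
#'   proportionally.
#' @param epsilon floor weight for non-target genes (default `1e-5`).
#' @return A `bias_weights` object: a named numeric vector over `universe`
#'   with attributes `stage = "initial"` and `targets`.
#' @export
#' @examples
#' w0 <- initial_weights("g2", paste0("g", 1:5))
initial_weights <- function(targets, universe, high_weight = 1, epsilon = 1e-5) {
  universe <- as.character(universe)
  if (anyDuplicated(universe)) stop_user("gene universe has duplicate ids")
  if (!(epsilon > 0 && epsilon < high_weight && high_weight <= 1))
    stop_user("need 0 < epsilon < high_weight <= 1")
  targets <- unique(as.character(targets))
  missing <- setdiff(targets, universe)
  if (length(missing) > 0)
    warning(length(missing), " target(s) absent from the universe, skipped: ",
            paste(head(missing, 5), collapse = ", "))
  kept <- intersect(targets, universe)
  if (length(kept) == 0) stop_user("no target gene is present in the universe")
  w <- stats::setNames(rep(epsilon, length(universe)), universe)
  w[kept] <- high_weight
  structure(w, class = "bias_weights", stage = "initial", targets = kept,
            skipped = length(missing), high_weight = high_weight,
            epsilon = epsilon)
}

#' @export
print.bias_weights <- function(x, ...) {
  cat("bias_weights (", attr(x, "stage"), ") over ", length(x), " genes\n",
      sep = "")
  cat("  range [", format(min(x)), ", ", format(max(x)), "]\n", sep = "")
  it <- attr(x, "iterations")
  if (!is.null(it))
    cat("  propagation: alpha=", attr(x, "alpha"), ", ", it, " iterations, ",
        "residual=", format(attr(x, "residual")), "\n", sep = "")
  invisible(x)
}

#' Propagation settings
#'
#' @param alpha diffusion strength in `(0, 1)`; larger values let target
#'   weight travel farther through the network. 0.7 is the value reported
#'   as optimal for STRING-scale PPI networks.
#' @param tol convergence tolerance on the iterate difference.
#' @param max_iter iteration cap; exceeding it is an error.
#' @param norm norm for the convergence test: `"max"` (elementwise,
#'   default) or `"l2"`.
#' @return A `propagation_config` list.
#' @export
propagation_config <- function(alpha = 0.7, tol = 1e-6, max_iter = 10000L,
                               norm = c("max", "l2")) {
  norm <- match.arg(norm)
  if (!(is.numeric(alpha) && length(alpha) == 1 && alpha > 0 && alpha < 1))
    stop_user("alpha must lie strictly in (0, 1)")
  if (!(tol > 0)) stop_user("tol must be positive")
  if (!(max_iter >= 1)) stop_user("max_iter must be >= 1")
  structure(list(alpha = alpha, tol = tol, max_iter = as.integer(max_iter),
                 norm = norm),
            class = "propagation_config")
}

#' Propagate bias weights over a PPI network
#'
#' Runs the random-walk-with-restart diffusion
#' `W_{t+1} = alpha * A' W_t + (1 - alpha) * W0` with the symmetric
#' degree-normalized adjacency `A'` until the change between iterates
#' falls below `config$tol`, and returns the smoothed weights Ws. Because
#' the spectral radius of `alpha * A'` is at most `alpha < 1` the
#' iteration is a contraction and always converges; the fixed point is
#' `(1 - alpha) (I - alpha A')^{-1} W0`.
#'
#' Genes present in `w0` but absent from the graph keep their initial
#' weight unchanged (absence of interaction evidence should not erase a
#' known target); their count is reported via a message. Isolated graph
#' nodes keep only the restart term `(1 - alpha) * w0`.
#'
#' @param w0 initial [initial_weights()] vector (any `bias_weights` or
#'   named numeric vector works).
#' @param graph a [ppi_graph()].
#' @param config a [propagation_config()].
#' @return A `bias_weights` vector over the same gene universe as `w0`,
#'   with `stage = "propagated"` and attributes `alpha`, `iterations`,
#'   `residual`.
#' @export
propagate_weights <- function(w0, graph, config = propagation_config()) {
  stopifnot(inherits(graph, "ppi_graph"))
  if (!inherits(config, "propagation_config"))
    config <- do.call(propagation_config, as.list(config))
  if (is.null(names(w0))) stop_user("w0 must be named by gene id")
  universe <- names(w0)
  in_graph <- universe %in% graph$nodes
  if (!all(in_graph))
    message(sum(!in_graph), " gene(s) not in the PPI graph keep their initial weight")
  Ap <- normalize_adjacency(graph)
  idx <- match(universe[in_graph], graph$nodes)
  # run the iteration on the full graph; genes outside w0's universe (if
  # any) start from and restart to 0 and therefore only relay weight
  v0 <- stats::setNames(numeric(length(graph$nodes)), graph$nodes)
  v0[idx] <- w0[in_graph]
  alpha <- config$alpha
  nrm <- if (config$norm == "max") function(x) max(abs(x)) else
    function(x) sqrt(sum(x^2))
  v <- v0
  resid <- Inf
  res_trace <- numeric(0)
  iter <- 0L
  while (iter < config$max_iter) {
    v_new <- drop(alpha * (Ap %*% v)) + (1 - alpha) * v0
    resid <- nrm(v_new - v)
    res_trace <- c(res_trace, resid)
    v <- v_new
    iter <- iter + 1L
    if (resid < config$tol) break
  }
  if (resid >= config$tol)
    stop("propagation did not converge in ", config$max_iter,
         " iterations (last residual ", format(resid), ")")
  ws <- as.numeric(w0)
  names(ws) <- universe
  ws[in_graph] <- v[idx]
  structure(ws, class = "bias_weights", stage = "propagated",
            targets = attr(w0, "targets"), alpha = alpha, tol = config$tol,
            iterations = iter, residual = resid,
            residual_trace = res_trace,
            outside_graph = sum(!in_graph))
}

#' Top-k neighborhood of influence
#'
#' Ranks genes by propagated weight, descending, and returns the top `k`.
#' This is the reporting view of the diffusion result: the genes most
#' influenced by the drug targets through the network. Ties are broken by
#' lexicographic gene id for determinism.
#'
#' @param ws a propagated `bias_weights` vector.
#' @param k number of genes to return, `1 <= k <= length(ws)`.
#' @return data frame with columns `gene`, `weight`, ordered by rank.
#' @export
neighborhood_of_influence <- function(ws, k) {
  if (!identical(attr(ws, "stage"), "propagated"))
    stop_user("neighborhood_of_influence expects propagated weights")
  if (!(k >= 1 && k <= length(ws))) stop_user("k out of range")
  ord <- order(-as.numeric(ws), names(ws))[seq_len(k)]
  data.frame(gene = names(ws)[ord], weight = as.numeric(ws)[ord],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write / read a bias-weight vector as two-column TSV
#'
#' The file carries `gene_id` and `weight` columns; propagation metadata
#' (stage, alpha, tolerance, iteration count) is recorded in `#` header
#' comments and restored on read.
#'
#' @param w a `bias_weights` vector.
#' @param path output file.
#' @return `path`, invisibly (write); a `bias_weights` vector (read).
#' @export
write_weights_tsv <- function(w, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(stage = attr(w, "stage") %||% "initial",
            alpha = attr(w, "alpha"), tol = attr(w, "tol"),
            iterations = attr(w, "iterations"))
  for (k in names(meta))
    writeLines(sprintf("# %s=%s", k, format(meta[[k]], digits = 17)), con)
  writeLines("gene_id\tweight", con)
  writeLines(sprintf("%s\t%.17g", names(w), as.numeric(w)), con)
  invisible(path)
}

#' @rdname write_weights_tsv
#' @export
read_weights_tsv <- function(path) {
  if (!file.exists(path)) stop_user("file not found: ", path)
  lines <- readLines(path)
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- strsplit(sub("^#\\s*", "", ml), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- kv[2]
  }
  tab <- read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                    sep = "\t", stringsAsFactors = FALSE)
  w <- stats::setNames(as.numeric(tab$weight), tab$gene_id)
  structure(w, class = "bias_weights",
            stage = meta$stage %||% "initial",
            alpha = if (!is.null(meta$alpha)) as.numeric(meta$alpha),
            iterations = if (!is.null(meta$iterations)) as.integer(meta$iterations))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
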