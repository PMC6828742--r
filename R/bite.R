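#' Ensemble configuration
#'
#' Tuning parameters for a biased tree ensemble. With a uniform (or
#' `NULL`) bias the sampler reduces to the standard random-forests
#' feature draw, so the same code path fits both the RF baseline and
#' BiTE/NetBiTE.
#'
#' @param n_tree number of trees (default 500).
#' @param mtry number of candidate features drawn at each node. `NULL`
#'   resolves to `floor(sqrt(n_genes))` at fit time; the drug-sensitivity
#'   protocol sets it to the number of reported targets.
#' @param tps target partition size: minimum number of training samples a
#'   leaf may hold (default 1). Tree depth is controlled solely by `tps`.
#' @param bias a [initial_weights()] / [propagate_weights()] vector, a
#'   named numeric vector over the training genes, or `NULL` for uniform
#'   sampling (plain RF).
#' @param bootstrap draw an n-out-of-n bootstrap per tree (default TRUE).
#' @param seed master RNG seed; each tree derives its own stream from it,
#'   so changing `n_tree` does not perturb earlier trees.
#' @return A `bite_config` list.
#' @export
bite_config <- function(n_tree = 500L, mtry = NULL, tps = 1L, bias = NULL,
                        bootstrap = TRUE, seed = 1L) {
  if (!(n_tree >= 1)) stop_user("n_tree must be >= 1")
  if (!is.null(mtry) && !(mtry >= 1)) stop_user("mtry must be >= 1")
  if (!(tps >= 1)) stop_user("tps must be >= 1")
  if (!is.null(bias) && !is.numeric(bias)) stop_user("bias must be numeric or NULL")
  structure(list(n_tree = as.integer(n_tree),
                 mtry = if (!is.null(mtry)) as.integer(mtry),
                 tps = as.integer(tps), bias = bias,
                 bootstrap = isTRUE(bootstrap), seed = as.integer(seed)),
            class = "bite_config")
}

# per-tree RNG stream: a fixed affine jump from the master seed, so tree t
# is reproducible independently of n_tree
tree_seed <- function(seed, t) {
  as.integer((as.numeric(seed) %% 20000) * 100003 + t)
}

# align a bias vector to the training genes; NULL means uniform
resolve_bias <- function(bias, gene_ids) {
  m <- length(gene_ids)
  if (is.null(bias)) return(rep(1, m))
  if (!is.null(names(bias))) {
    missing <- setdiff(gene_ids, names(bias))
    if (length(missing) > 0)
      stop_user("bias weights missing for ", length(missing), " gene(s): ",
                paste(head(missing, 10), collapse = ", "))
    bias <- as.numeric(bias[gene_ids])
  } else if (length(bias) != m) {
    stop_user("unnamed bias vector must have one weight per gene")
  }
  if (any(bias < 0) || anyNA(bias)) stop_user("bias weights must be >= 0")
  as.numeric(bias)
}

# 0-based row order per feature column (stable for ties)
sort_order0 <- function(X) {
  so <- apply(X, 2, order) - 1L
  storage.mode(so) <- "integer"
  so
}

check_matrix <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop_user("expression matrix must be numeric")
  if (anyNA(X)) stop_user("expression matrix contains missing values")
  if (is.null(colnames(X))) colnames(X) <- paste0("g", seq_len(ncol(X)))
  if (anyDuplicated(colnames(X))) stop_user("duplicate gene ids")
  X
}

#' Draw a weighted feature subset
#'
#' Samples `mtry` distinct feature indices without replacement, each draw
#' proportional to the remaining weights. Uniform weights reproduce the
#' random-forests scheme exactly; concentrated weights bias the candidate
#' set towards the highly weighted genes. Uses and advances R's RNG.
#'
#' @param bias non-negative weight vector (zero-weight features are never
#'   drawn).
#' @param mtry number of features to draw; must not exceed the number of
#'   positive-weight features.
#' @return Integer vector of `mtry` distinct 1-based indices, in draw
#'   order.
#' @export
draw_feature_subset <- function(bias, mtry) {
  bias <- as.numeric(bias)
  if (any(bias < 0) || anyNA(bias)) stop_user("bias weights must be >= 0")
  if (mtry > sum(bias > 0))
    stop_user("mtry (", mtry, ") exceeds the ", sum(bias > 0),
              " positive-weight features")
  cpp_draw_features(bias, as.integer(mtry)) + 1L
}

#' Best variance-reducing split
#'
#' Scans the candidate genes and all midpoint thresholds between
#' consecutive distinct sorted values, and returns the split minimizing
#' the child-size-weighted sum of response variances (equivalently the
#' summed child SSE reported in `loss`), subject to both children holding
#' at least `tps` samples. Ties are broken towards the lower gene index,
#' then the lower threshold.
#'
#' @param X numeric sample-by-gene matrix.
#' @param y numeric response.
#' @param candidates 1-based column indices (or gene names) to consider.
#' @param tps minimum child size.
#' @param rows optional 1-based row subset defining the node (default all).
#' @return `NULL` when no legal split strictly reduces the node SSE
#'   (constant response, constant candidates, or `tps` infeasible);
#'   otherwise a list with `gene` (index), `gene_id`, `threshold`, `loss`.
#' @export
best_split <- function(X, y, candidates, tps = 1L, rows = NULL) {
  X <- check_matrix(X)
  if (is.character(candidates)) candidates <- match(candidates, colnames(X))
  if (anyNA(candidates)) stop_user("unknown candidate gene")
  if (is.null(rows)) rows <- seq_len(nrow(X))
  res <- cpp_best_split(X, as.numeric(y), as.integer(rows) - 1L,
                        as.integer(candidates) - 1L, as.integer(tps))
  if (res$var < 0) return(NULL)
  list(gene = res$var + 1L, gene_id = colnames(X)[res$var + 1L],
       threshold = res$threshold, loss = res$loss)
}

#' Fit a single biased CART regression tree
#'
#' Recursive variance-reduction CART: at every node a fresh feature
#' subset of size `mtry` is drawn according to `bias`, the best split
#' among those candidates is applied, and recursion stops when no legal
#' split strictly reduces the node SSE or a child would fall below `tps`
#' samples. Leaves predict the mean response of their samples.
#'
#' @inheritParams best_split
#' @param mtry candidate features per node.
#' @param bias weight vector (`NULL` = uniform).
#' @param rows training rows (with multiplicity, e.g. a bootstrap draw).
#' @param seed optional seed applied before growing.
#' @return A `bite_tree`: parallel node arrays `var`, `threshold`,
#'   `left`, `right` (0-based, -1 for leaves), `value`, `nsamp`.
#' @export
fit_tree <- function(X, y, mtry, tps = 1L, bias = NULL, rows = NULL,
                     seed = NULL) {
  X <- check_matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop_user("length(y) must equal nrow(X)")
  bias <- resolve_bias(bias, colnames(X))
  if (mtry > sum(bias > 0)) stop_user("mtry exceeds positive-weight features")
  if (is.null(rows)) rows <- seq_len(nrow(X))
  if (!is.null(seed)) set.seed(seed)
  tr <- cpp_fit_tree(X, y, as.integer(rows) - 1L, sort_order0(X), bias,
                     as.integer(mtry), as.integer(tps))
  class(tr) <- "bite_tree"
  tr
}

predict_tree <- function(tree, X) {
  cpp_predict_tree(tree$var, tree$threshold, tree$left, tree$right,
                   tree$value, X)
}

#' Fit a biased tree ensemble
#'
#' Fits `n_tree` independent CART regression trees, each on its own
#' bootstrap draw (if enabled), with per-node candidate features sampled
#' according to the bias weights. The ensemble prediction is the mean
#' over trees. Per-tree RNG streams are derived from the master seed, so
#' the fit is fully reproducible and growing more trees leaves earlier
#' ones unchanged.
#'
#' @param X numeric sample-by-gene matrix (genes as named columns).
#' @param y numeric response, one value per row of `X`.
#' @param config a [bite_config()].
#' @return A `bite_ensemble` with elements `trees`, `config` (mtry
#'   resolved), `gene_ids`, `n_train`, `bias`, and `bootstrap_indices`.
#' @export
#' @examples
#' bm <- make_benchmark(n_samples = 60, n_genes = 20, seed = 1)
#' w0 <- initial_weights(bm$targets, colnames(bm$expression), 0.6)
#' fit <- fit_bite(bm$expression, bm$ic50_scaled,
#'                 bite_config(n_tree = 10, mtry = 2, bias = w0, seed = 1))
#' head(predict(fit, bm$expression))
fit_bite <- function(X, y, config = bite_config()) {
  stopifnot(inherits(config, "bite_config"))
  X <- check_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop_user("length(y) must equal nrow(X)")
  if (n < 2) stop_user("need at least 2 samples")
  bias <- resolve_bias(config$bias, colnames(X))
  mtry <- config$mtry %||% max(1L, floor(sqrt(ncol(X))))
  if (mtry > ncol(X)) stop_user("mtry exceeds the number of genes")
  if (mtry > sum(bias > 0)) stop_user("mtry exceeds positive-weight features")
  config$mtry <- as.integer(mtry)
  so <- sort_order0(X) # per-feature row order, shared by all trees
  trees <- vector("list", config$n_tree)
  boots <- if (config$bootstrap) vector("list", config$n_tree)
  for (t in seq_len(config$n_tree)) {
    set.seed(tree_seed(config$seed, t))
    rows <- if (config$bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    tr <- cpp_fit_tree(X, y, rows - 1L, so, bias, config$mtry, config$tps)
    class(tr) <- "bite_tree"
    trees[[t]] <- tr
    if (config$bootstrap) boots[[t]] <- rows
  }
  structure(list(trees = trees, config = config, gene_ids = colnames(X),
                 n_train = n, bias = bias, bootstrap_indices = boots),
            class = "bite_ensemble")
}

#' Predict from a biased tree ensemble
#'
#' @param object a fitted [fit_bite()] ensemble.
#' @param newdata numeric sample-by-gene matrix; when it carries column
#'   names, columns are aligned to the training genes and every training
#'   gene must be present.
#' @param ... unused.
#' @return Numeric vector: per-sample mean of the tree predictions.
#' @export
predict.bite_ensemble <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X))) {
    missing <- setdiff(object$gene_ids, colnames(X))
    if (length(missing) > 0)
      stop_user("newdata lacks ", length(missing), " training gene(s): ",
                paste(head(missing, 10), collapse = ", "))
    X <- X[, object$gene_ids, drop = FALSE]
  } else if (ncol(X) != length(object$gene_ids)) {
    stop_user("newdata has ", ncol(X), " columns; the model was trained on ",
              length(object$gene_ids), " genes")
  }
  preds <- numeric(nrow(X))
  for (tr in object$trees) preds <- preds + predict_tree(tr, X)
  preds / length(object$trees)
}

#' @export
print.bite_ensemble <- function(x, ...) {
  cfg <- x$config
  uniform <- length(unique(x$bias)) == 1
  cat("bite_ensemble:", cfg$n_tree, "trees, mtry =", cfg$mtry,
      ", tps =", cfg$tps, if (uniform) "(uniform bias: plain RF)" else
        "(biased feature sampling)", "\n")
  cat("  trained on", x$n_train, "samples x", length(x$gene_ids), "genes\n")
  invisible(x)
}
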