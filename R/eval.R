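# Evaluation protocol: min-max response scaling, repeated k-fold CV with
# pooled out-of-fold rho (Pearson correlation, clamped to [0, 1]), paired
# NetBiTE-vs-RF comparisons, the dummy-target control and the alpha
# sweep.

#' Min-max scale an IC50 response to [0, 1]
#'
#' `(y - min) / (max - min)`; the extremes map to 0 and 1 exactly and the
#' recorded range allows exact inversion.
#'
#' @param ic50 numeric vector with at least 2 distinct values.
#' @return A `scaled_ic50` numeric vector with attributes `ic50_min`,
#'   `ic50_max`.
#' @export
scale_ic50 <- function(ic50) {
  if (!is.numeric(ic50)) stop_user("ic50 must be numeric")
  if (anyNA(ic50)) stop_user("ic50 contains missing values")
  lo <- min(ic50); hi <- max(ic50)
  if (hi == lo) stop_user("constant IC50 vector cannot be scaled")
  structure((as.vector(ic50) - lo) / (hi - lo), names = names(ic50),
            class = "scaled_ic50", ic50_min = lo, ic50_max = hi)
}

#' @rdname scale_ic50
#' @param scaled a `scaled_ic50` vector.
#' @return `unscale_ic50`: the original-scale values.
#' @export
unscale_ic50 <- function(scaled) {
  lo <- attr(scaled, "ic50_min"); hi <- attr(scaled, "ic50_max")
  if (is.null(lo) || is.null(hi)) stop_user("not a scaled_ic50 vector")
  stats::setNames(as.numeric(scaled) * (hi - lo) + lo, names(scaled))
}

#' Cross-validation fold count
#'
#' The protocol uses thirty- to forty-fold cross-validation chosen by
#' dataset size; the auto rule is `clamp(round(n / 25), 30, 40)`. Small
#' datasets (n < 60) cannot sustain 30 folds and fall back to 10 with a
#' warning.
#'
#' @param n number of samples.
#' @param k explicit fold count, or `"auto"`.
#' @return Integer fold count.
#' @export
choose_k <- function(n, k = "auto") {
  if (!identical(k, "auto")) {
    k <- as.integer(k)
    if (k < 2 || k > n) stop_user("k must lie in [2, n]")
    return(k)
  }
  if (n < 60) {
    warning("n = ", n, " < 60: falling back to 10-fold cross-validation")
    return(10L)
  }
  max(30L, min(40L, as.integer(round(n / 25))))
}

# near-equal fold assignment: the first n %% k folds get one extra sample
fold_assignments <- function(n, k, seed) {
  set.seed(seed)
  perm <- sample.int(n)
  sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
  folds <- integer(n)
  folds[perm] <- rep(seq_len(k), times = sizes)
  folds
}

# pooled out-of-fold accuracy: rho is the Pearson correlation between
# predictions and truth (equivalently sqrt(R^2) with R^2 the squared
# correlation coefficient), clamped into [0, 1]; undefined correlations
# (constant predictions, e.g. a mean-only model) map to 0
pooled_rho <- function(y, pred) {
  r <- suppressWarnings(stats::cor(pred, y))
  if (is.na(r)) 0 else max(r, 0)
}

fit_seed_for <- function(seed, repeat_i, fold_i) {
  as.integer((as.numeric(seed) %% 9973) * 100003 +
               repeat_i * 211 + fold_i) # < 2^31
}

#' Model adapters for the evaluation harness
#'
#' The harness is model-agnostic: anything exposing `fit(X, y, seed)` and
#' `predict(fit, X)` can be cross-validated, so external regressors plug
#' in through [regressor_model()]. `bite_model()` adapts [fit_bite()]
#' (pass `bias = NULL` for the plain-RF arm) and `lm_model()` is the
#' linear-regression-on-targets baseline.
#'
#' @param n_tree,mtry,tps,bias,bootstrap see [bite_config()].
#' @param label model label used in reports.
#' @return A `netbite_model` list with `label`, `fit`, `predict`.
#' @export
bite_model <- function(n_tree = 500L, mtry = NULL, tps = 1L, bias = NULL,
                       bootstrap = TRUE,
                       label = if (is.null(bias)) "RF" else "BiTE") {
  structure(list(
    label = label,
    fit = function(X, y, seed) {
      fit_bite(X, y, bite_config(n_tree = n_tree, mtry = mtry, tps = tps,
                                 bias = bias, bootstrap = bootstrap,
                                 seed = seed))
    },
    predict = function(fit, X) predict(fit, X)
  ), class = "netbite_model")
}

#' @rdname bite_model
#' @param features gene ids (or indices) the linear model regresses on.
#' @export
lm_model <- function(features, label = "LR") {
  structure(list(
    label = label,
    fit = function(X, y, seed) {
      d <- as.data.frame(X[, features, drop = FALSE])
      names(d) <- paste0("f", seq_along(d))
      lm(y ~ ., data = cbind(d, y = y))
    },
    predict = function(fit, X) {
      d <- as.data.frame(X[, features, drop = FALSE])
      names(d) <- paste0("f", seq_along(d))
      unname(predict(fit, newdata = d))
    }
  ), class = "netbite_model")
}

#' @rdname bite_model
#' @param fit function `(X, y, seed) -> fitted object`.
#' @param predict function `(fitted, X) -> numeric predictions`.
#' @export
regressor_model <- function(label, fit, predict) {
  structure(list(label = label, fit = fit, predict = predict),
            class = "netbite_model")
}

#' Repeated k-fold cross-validated rho
#'
#' For each repeat the samples are shuffled into k near-equal folds; the
#' model is fitted on k-1 folds and predicts the held-out fold; all
#' out-of-fold predictions are pooled and scored once per repeat as the
#' Pearson correlation rho between predictions and truth (the square
#' root of the coefficient of determination, taking R^2 as the squared
#' correlation), clamped into `[0, 1]`: negative or undefined
#' correlations -- a model no better than the mean -- report 0. The mean
#' over repeats is the headline accuracy. Fold assignments depend only
#' on `(seed, repeat)`, so two models evaluated with the same seed see
#' identical folds (paired design).
#'
#' @param X sample-by-gene matrix.
#' @param y numeric response (scale with [scale_ic50()] first to mirror
#'   the IC50 protocol).
#' @param model a `netbite_model` adapter, e.g. [bite_model()].
#' @param k fold count or `"auto"` (see [choose_k()]).
#' @param repeats number of repeats averaged (default 10).
#' @param seed master seed for shuffles and model fits.
#' @return An `evaluation_report`: list with `label`, `rho` (per repeat),
#'   `mean_rho`, `folds` (list of assignments), `fold_hash`, `config`.
#' @export
crossval_rho <- function(X, y, model, k = "auto", repeats = 10L, seed = 1L) {
  stopifnot(inherits(model, "netbite_model"))
  X <- check_matrix(X)
  y <- as.numeric(y)
  n <- nrow(X)
  if (length(y) != n) stop_user("length(y) must equal nrow(X)")
  k <- choose_k(n, k)
  rho <- numeric(repeats)
  folds_all <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    folds <- fold_assignments(n, k, seed + r)
    preds <- numeric(n)
    for (f in seq_len(k)) {
      test <- which(folds == f)
      fit <- model$fit(X[-test, , drop = FALSE], y[-test],
                       fit_seed_for(seed, r, f))
      preds[test] <- model$predict(fit, X[test, , drop = FALSE])
    }
    rho[r] <- pooled_rho(y, preds)
    folds_all[[r]] <- folds
  }
  structure(list(label = model$label, rho = rho, mean_rho = mean(rho),
                 folds = folds_all,
                 fold_hash = vapply(folds_all, fold_hash, numeric(1)),
                 config = list(k = k, repeats = repeats, seed = seed)),
            class = "evaluation_report")
}

fold_hash <- function(folds) {
  sum(as.numeric(folds) * seq_along(folds)) %% 2147483647
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation_report [", x$label, "]: mean rho = ",
      format(x$mean_rho, digits = 4), " over ", x$config$repeats,
      " repeats of ", x$config$k, "-fold CV (sd ",
      format(sd(x$rho), digits = 3), ")\n", sep = "")
  invisible(x)
}

#' Paired NetBiTE-versus-RF comparison over an n_tree grid
#'
#' Evaluates the biased ensemble and the uniform-weight RF baseline with
#' identical fold assignments per repeat (paired design) for each tree
#' count, and reports mean accuracies, their difference
#' `delta_rho = rho_biased - rho_rf`, and a paired two-sided t-test over
#' the per-repeat rho values.
#'
#' @inheritParams crossval_rho
#' @param bias bias weights for the biased arm.
#' @param n_tree_grid integer vector of tree counts.
#' @param mtry,tps,bootstrap shared tuning parameters of both arms.
#' @return Data frame with one row per `n_tree`: `n_tree`, `rho_biased`,
#'   `rho_rf`, `delta_rho`, `p_value`; per-repeat rho matrices and fold
#'   hashes are kept in the `reports` attribute.
#' @export
compare_models <- function(X, y, bias, n_tree_grid = c(10L, 100L),
                           mtry = NULL, tps = 1L, bootstrap = TRUE,
                           k = "auto", repeats = 10L, seed = 1L) {
  rows <- vector("list", length(n_tree_grid))
  reports <- vector("list", length(n_tree_grid))
  for (i in seq_along(n_tree_grid)) {
    nt <- n_tree_grid[i]
    rep_b <- crossval_rho(X, y, bite_model(n_tree = nt, mtry = mtry,
                                           tps = tps, bias = bias,
                                           bootstrap = bootstrap,
                                           label = "biased"),
                          k = k, repeats = repeats, seed = seed)
    rep_r <- crossval_rho(X, y, bite_model(n_tree = nt, mtry = mtry,
                                           tps = tps, bias = NULL,
                                           bootstrap = bootstrap,
                                           label = "RF"),
                          k = k, repeats = repeats, seed = seed)
    stopifnot(identical(rep_b$fold_hash, rep_r$fold_hash)) # paired folds
    pv <- if (repeats >= 2 && sd(rep_b$rho - rep_r$rho) > 0)
      t.test(rep_b$rho, rep_r$rho, paired = TRUE)$p.value else NA_real_
    rows[[i]] <- data.frame(n_tree = nt, rho_biased = rep_b$mean_rho,
                            rho_rf = rep_r$mean_rho,
                            delta_rho = rep_b$mean_rho - rep_r$mean_rho,
                            p_value = pv)
    reports[[i]] <- list(biased = rep_b, rf = rep_r)
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}

#' Replace drug targets by random dummy genes
#'
#' Control experiment: draws a gene set of the same size as the true
#' target set, uniformly from the non-target genes (so the dummy set is
#' disjoint from the truth). A biased ensemble built on dummy targets
#' should lose the accuracy gain of the informed model.
#'
#' @param targets true target gene ids.
#' @param universe all gene ids.
#' @param seed RNG seed.
#' @return Character vector of dummy targets, `length(targets)` genes.
#' @export
randomize_targets <- function(targets, universe, seed = 1L) {
  targets <- as.character(targets); universe <- as.character(universe)
  pool <- setdiff(universe, targets)
  if (length(targets) > length(pool))
    stop_user("not enough non-target genes to draw dummies from")
  set.seed(seed)
  sample(pool, length(targets))
}

#' Sweep the diffusion parameter alpha
#'
#' Runs the full pipeline — initial target weights, network propagation
#' at each alpha, biased ensemble, repeated cross-validation — and
#' tabulates mean rho per alpha. Useful to check whether network
#' smoothing (large alpha) beats near-zero propagation when the
#' predictive genes are network neighbors of the nominal targets.
#'
#' @inheritParams crossval_rho
#' @param targets drug-target gene ids.
#' @param graph a [ppi_graph()].
#' @param alphas numeric vector of diffusion strengths in (0, 1).
#' @param n_tree,mtry,tps ensemble tuning parameters.
#' @param high_weight,epsilon initial-weight parameters.
#' @return Data frame `(alpha, mean_rho)`; full reports in the `reports`
#'   attribute.
#' @export
alpha_sweep <- function(X, y, targets, graph, alphas, n_tree = 100L,
                        mtry = NULL, tps = 1L, high_weight = 1,
                        epsilon = 1e-5, k = "auto", repeats = 10L,
                        seed = 1L) {
  X <- check_matrix(X)
  if (length(alphas) == 0)
    return(data.frame(alpha = numeric(0), mean_rho = numeric(0)))
  w0 <- initial_weights(targets, colnames(X), high_weight, epsilon)
  rows <- vector("list", length(alphas))
  reports <- vector("list", length(alphas))
  for (i in seq_along(alphas)) {
    ws <- propagate_weights(w0, graph, propagation_config(alpha = alphas[i]))
    rep_i <- crossval_rho(X, y,
                          bite_model(n_tree = n_tree, mtry = mtry, tps = tps,
                                     bias = ws,
                                     label = sprintf("NetBiTE(alpha=%g)",
                                                     alphas[i])),
                          k = k, repeats = repeats, seed = seed)
    rows[[i]] <- data.frame(alpha = alphas[i], mean_rho = rep_i$mean_rho)
    reports[[i]] <- rep_i
  }
  out <- do.call(rbind, rows)
  attr(out, "reports") <- reports
  out
}
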