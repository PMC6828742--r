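test_that("weighted feature draws follow the remaining-weight law", {
  # exhaustive draw: mtry = m returns every feature
  set.seed(1)
  expect_setequal(draw_feature_subset(rep(1, 6), 6), 1:6)

  # a unit-weight gene among epsilon-weighted ones is drawn first almost
  # always: first-draw probability w_1 / sum(w) = 1 / (1 + 3e-5)
  set.seed(42)
  first <- replicate(2e4, draw_feature_subset(c(1, 1e-5, 1e-5, 1e-5), 1))
  expect_gt(mean(first == 1), 0.999)

  # uniform weights, mtry = 1: every index equally likely (chi-square)
  set.seed(43)
  draws <- replicate(2e4, draw_feature_subset(rep(1, 5), 1))
  p <- chisq.test(tabulate(draws, 5))$p.value
  expect_gt(p, 0.001)

  # zero-weight features are never drawn; too few positives is an error
  set.seed(44)
  got <- replicate(200, draw_feature_subset(c(0, 1, 1, 0), 2))
  expect_false(any(got %in% c(1, 4)))
  expect_error(draw_feature_subset(c(0, 1, 1, 0), 3), "positive-weight")
})

test_that("best_split matches exhaustive enumeration and handles degenerate blocks", {
  # perfectly separated response: threshold at the midpoint, zero loss
  X <- matrix(c(1, 2, 8, 9), 4, 1, dimnames = list(NULL, "g"))
  y <- c(0, 0, 10, 10)
  s <- best_split(X, y, 1, tps = 1)
  expect_equal(s$threshold, 5)
  expect_equal(s$loss, 0)
  expect_identical(s$gene_id, "g")

  # constant response or constant candidates: no split
  expect_null(best_split(X, rep(3, 4), 1))
  Xc <- matrix(1, 4, 2, dimnames = list(NULL, c("a", "b")))
  expect_null(best_split(Xc, y, 1:2))

  # brute-force enumeration oracle on random small blocks (ties included
  # via discretized values and responses)
  set.seed(7)
  for (rep in 1:150) {
    n <- sample(4:12, 1)
    Xb <- matrix(sample(0:5, n * 4, TRUE) + rnorm(n * 4, 0, 1e-8), n, 4,
                 dimnames = list(NULL, paste0("g", 1:4)))
    yb <- sample(0:3, n, TRUE)
    tps <- sample(1:2, 1)
    got <- best_split(Xb, yb, 1:4, tps)
    want <- brute_best_split(Xb, yb, 1:4, tps)
    expect_identical(is.null(got), is.null(want))
    if (!is.null(got)) {
      expect_identical(got$gene, want$gene)
      expect_equal(got$threshold, want$threshold)
      expect_equal(got$loss, want$loss, tolerance = 1e-9)
    }
  }
})

test_that("single trees respect TPS, interpolate, and beat the best stump", {
  set.seed(11)
  X <- matrix(rnorm(16), 8, 2, dimnames = list(NULL, c("g1", "g2")))
  y <- synthetic_ic50(X, 1, 2)

  # TPS = n: a single-leaf tree predicting the mean response
  t1 <- fit_tree(X, y, mtry = 2, tps = 8, seed = 1)
  expect_identical(length(t1$value), 1L)
  expect_equal(t1$value, mean(y))

  # full-depth CART with all features interpolates the training data
  t2 <- fit_tree(X, y, mtry = 2, tps = 1, seed = 1)
  expect_equal(netbite:::predict_tree(t2, X), y)
  expect_true(all(t2$nsamp[t2$var < 0] >= 1))

  # the full tree's training SSE is no worse than the best single split
  stump <- best_split(X, y, 1:2, tps = 1)
  sse_tree <- sum((netbite:::predict_tree(t2, X) - y)^2)
  expect_lte(sse_tree, stump$loss + 1e-12)
})

test_that("ensembles are reproducible, extendable and respect the leaf bound", {
  bm <- small_bench(seed = 3)
  X <- bm$expression
  y <- as.numeric(bm$ic50_scaled)

  # a one-tree ensemble predicts exactly as its tree
  f1 <- fit_bite(X, y, bite_config(n_tree = 1, mtry = 4, seed = 5))
  expect_equal(predict(f1, X), netbite:::predict_tree(f1$trees[[1]], X))

  # determinism: identical seed, bit-identical predictions
  f2a <- fit_bite(X, y, bite_config(n_tree = 8, mtry = 4, seed = 9))
  f2b <- fit_bite(X, y, bite_config(n_tree = 8, mtry = 4, seed = 9))
  expect_identical(predict(f2a, X), predict(f2b, X))

  # per-tree streams derive from the master seed: growing the ensemble
  # leaves earlier trees unchanged
  f3 <- fit_bite(X, y, bite_config(n_tree = 12, mtry = 4, seed = 9))
  expect_identical(f3$trees[1:8], f2a$trees[1:8])
  expect_identical(f3$bootstrap_indices[1:8], f2a$bootstrap_indices[1:8])

  # every leaf of every tree holds at least TPS training samples
  f4 <- fit_bite(X, y, bite_config(n_tree = 15, mtry = 6, tps = 4, seed = 2))
  min_leaf <- min(unlist(lapply(f4$trees, function(tr) tr$nsamp[tr$var < 0])))
  expect_gte(min_leaf, 4)

  # no-bootstrap fit records no indices and interpolates at mtry = m
  f5 <- fit_bite(X, y, bite_config(n_tree = 2, mtry = ncol(X), tps = 1,
                                   bootstrap = FALSE, seed = 1))
  expect_null(f5$bootstrap_indices)
  expect_equal(predict(f5, X), y)
})

test_that("prediction aligns genes by name and rejects mismatches", {
  bm <- small_bench(seed = 4)
  X <- bm$expression
  fit <- fit_bite(X, bm$ic50, bite_config(n_tree = 3, mtry = 4, seed = 1))
  shuffled <- X[, rev(colnames(X))]
  expect_equal(predict(fit, shuffled), predict(fit, X))
  expect_error(predict(fit, X[, -(1:3)]), "lacks 3 training gene")
  expect_error(predict(fit, unname(X)[, 1:5]), "columns")
})

test_that("serialized ensembles reproduce predictions bit-exactly", {
  bm <- small_bench(seed = 6)
  X <- bm$expression
  y <- as.numeric(bm$ic50_scaled)
  w0 <- initial_weights(bm$targets, colnames(X), 0.6)
  fit <- fit_bite(X, y, bite_config(n_tree = 5, mtry = 2, bias = w0, seed = 7))
  path <- tempfile(fileext = ".json")
  write_bite_json(fit, path)
  back <- read_bite_json(path)
  expect_identical(predict(back, X), predict(fit, X))
  expect_identical(back$config[c("n_tree", "mtry", "tps", "bootstrap", "seed")],
                   fit$config[c("n_tree", "mtry", "tps", "bootstrap", "seed")])
  expect_identical(back$gene_ids, fit$gene_ids)
  expect_equal(back$bias, unname(fit$bias))
  expect_error(read_bite_json(tempfile()), "not found")
})
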