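test_that("initial weights assign the high weight to targets and epsilon elsewhere", {
  u <- paste0("g", 1:5)
  w <- initial_weights("g2", u, high_weight = 1, epsilon = 1e-5)
  expect_equal(as.numeric(w), c(1e-5, 1, 1e-5, 1e-5, 1e-5))
  expect_identical(names(w), u)
  expect_identical(attr(w, "stage"), "initial")
  expect_setequal(unique(as.numeric(w)), c(1, 1e-5))

  # saturation: every gene is a target
  w_all <- initial_weights(u, u, high_weight = 0.6)
  expect_equal(as.numeric(w_all), rep(0.6, 5))

  # unknown targets are skipped with a warning; none left is an error
  expect_warning(w_skip <- initial_weights(c("g2", "gX"), u), "skipped")
  expect_identical(attr(w_skip, "skipped"), 1L)
  expect_equal(as.numeric(w_skip)[2], 1)
  expect_error(suppressWarnings(initial_weights("g9", c("g1", "g2"))),
               "no target")
  expect_error(initial_weights("g1", u, high_weight = 2), "high_weight")
  expect_error(initial_weights("g1", u, epsilon = 0), "epsilon")
})

test_that("adjacency normalization divides by the endpoint degrees", {
  # single unit edge: degrees 1, normalization is the identity
  g2 <- ppi_graph(matrix(c(0, 1, 1, 0), 2, 2,
                         dimnames = list(c("a", "b"), c("a", "b"))))
  expect_equal(normalize_adjacency(g2),
               matrix(c(0, 1, 1, 0), 2, 2,
                      dimnames = list(c("a", "b"), c("a", "b"))))

  # path a-b-c: d = (1, 2, 1), off-diagonal entries 1/sqrt(2)
  gp <- path_graph(c("a", "b", "c"))
  Ap <- normalize_adjacency(gp)
  expect_equal(Ap["a", "b"], 1 / sqrt(2))
  expect_equal(Ap["b", "c"], 1 / sqrt(2))
  expect_equal(Ap, t(Ap))

  # star K_{1,3}: hub degree 3, leaves 1 -> hub entries 1/sqrt(3)
  gs <- star_graph("hub", c("l1", "l2", "l3"))
  As <- normalize_adjacency(gs)
  expect_equal(unname(As["hub", c("l1", "l2", "l3")]), rep(1 / sqrt(3), 3))

  # spectral radius of the normalized matrix is at most 1
  g <- random_ppi(40, 0.15, seed = 3)
  expect_lte(max(abs(eigen(normalize_adjacency(g))$values)), 1 + 1e-12)

  # isolated nodes get zero rows instead of dividing by zero
  A <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  A[1, 2] <- A[2, 1] <- 1
  gi <- ppi_graph(A)
  expect_identical(attr(gi, "isolated"), "c")
  expect_equal(normalize_adjacency(gi)[3, ], c(a = 0, b = 0, c = 0))

  expect_error(ppi_graph(matrix(c(0, -1, -1, 0), 2, 2,
                                dimnames = list(1:2, 1:2))), "negative")
})

test_that("iterative propagation converges to the closed-form fixed point", {
  # two nodes, one unit edge: (I - aA')^{-1} = [[1, a], [a, 1]] / (1 - a^2)
  g2 <- ppi_graph(matrix(c(0, 1, 1, 0), 2, 2,
                         dimnames = list(c("t", "o"), c("t", "o"))))
  w0 <- initial_weights("t", c("t", "o"), 1, 1e-5)
  a <- 0.7
  ws <- propagate_weights(w0, g2, propagation_config(alpha = a, tol = 1e-10))
  expect_equal(as.numeric(ws),
               (1 - a) / (1 - a^2) * c(1 + a * 1e-5, a + 1e-5),
               tolerance = 1e-8)
  expect_identical(attr(ws, "stage"), "propagated")
  expect_gt(attr(ws, "iterations"), 1)
  expect_lt(attr(ws, "residual"), 1e-10)

  # random graphs match the direct linear solve within 10x tolerance
  for (s in 1:8) {
    g <- random_ppi(sample(10:120, 1), 0.1, seed = 100 + s)
    tg <- sample(g$nodes, 3)
    w0 <- initial_weights(tg, g$nodes, 1, 1e-5)
    for (a in c(0.02, 0.7)) {
      ws <- propagate_weights(w0, g, propagation_config(alpha = a))
      expect_lt(max(abs(as.numeric(ws) - closed_form_ws(w0, g, a))), 1e-5)
    }
  }

  # alpha -> 0 limit recovers W0
  g <- random_ppi(30, 0.2, seed = 9)
  w0 <- initial_weights(g$nodes[1], g$nodes, 1, 1e-5)
  ws0 <- propagate_weights(w0, g, propagation_config(alpha = 1e-12))
  expect_lt(max(abs(as.numeric(ws0) - as.numeric(w0))), 1e-9)

  # iteration cap produces an error carrying the last residual
  err <- tryCatch(
    propagate_weights(w0, g, propagation_config(alpha = 0.9, max_iter = 1)),
    error = function(e) conditionMessage(e))
  expect_match(err, "did not converge")
  expect_match(err, "residual")
})

test_that("propagated weights keep out-of-graph genes and log them", {
  g <- path_graph(c("g1", "g2", "g3"))
  u <- c("g1", "g2", "g3", "g4", "g9") # g4, g9 not in the network
  w0 <- initial_weights(c("g1", "g9"), u, 1, 1e-5)
  expect_message(ws <- propagate_weights(w0, g, propagation_config()),
                 "not in the PPI graph")
  expect_identical(attr(ws, "outside_graph"), 2L)
  # a target outside the graph keeps its full initial weight
  expect_equal(unname(ws["g9"]), 1)
  expect_equal(unname(ws["g4"]), 1e-5)
  # in-graph genes were diffused
  expect_lt(unname(ws["g1"]), 1)
  expect_gt(unname(ws["g2"]), 1e-5)
})

test_that("propagation contracts, stays positive and decays with distance", {
  g0 <- random_ppi(60, 0.15, seed = 21)
  A <- g0$adjacency
  for (i in 1:59) A[i, i + 1] <- A[i + 1, i] <- pmax(A[i, i + 1], 0.2)
  g <- ppi_graph(A) # ring overlay guarantees connectivity
  w0 <- initial_weights(g$nodes[5], g$nodes, 1, 1e-5)
  ws <- suppressMessages(propagate_weights(w0, g, propagation_config()))
  expect_true(all(as.numeric(ws) > 0))
  tr <- attr(ws, "residual_trace")
  expect_true(all(diff(tr) < 0)) # monotone contraction after iteration 1

  # unweighted path with the target at one end: strict decay with distance
  ids <- paste0("n", 1:6)
  gp <- path_graph(ids)
  wp <- propagate_weights(initial_weights("n1", ids, 1, 1e-5), gp,
                          propagation_config(tol = 1e-12))
  expect_true(all(diff(as.numeric(wp)) < 0))
})

test_that("neighborhood ranking is ordered, complete and deterministic", {
  gs <- star_graph("hub", c("l1", "l2", "l3"))
  ids <- c("hub", "l1", "l2", "l3", "far1", "far2") # far nodes isolated
  A <- matrix(0, 6, 6, dimnames = list(ids, ids))
  A[1, 2:4] <- A[2:4, 1] <- 1
  g <- ppi_graph(A)
  w0 <- initial_weights("hub", ids, 1, 1e-5)
  ws <- propagate_weights(w0, g, propagation_config())
  top <- neighborhood_of_influence(ws, 4)
  expect_identical(top$gene[1], "hub")
  expect_setequal(top$gene[2:4], c("l1", "l2", "l3"))
  # equal-weight leaves appear in lexicographic order
  expect_identical(top$gene[2:4], c("l1", "l2", "l3"))
  # k = |universe| returns a permutation of all genes
  expect_setequal(neighborhood_of_influence(ws, 6)$gene, ids)

  # path a-b-c-d from a: monotone ranking by distance
  gp <- path_graph(letters[1:4])
  wp <- propagate_weights(initial_weights("a", letters[1:4], 1, 1e-5), gp,
                          propagation_config())
  expect_identical(neighborhood_of_influence(wp, 4)$gene, letters[1:4])

  expect_error(neighborhood_of_influence(wp, 9), "out of range")
  expect_error(neighborhood_of_influence(w0, 2), "propagated")
})

test_that("STRING edge lists and weight tables round-trip through disk", {
  fx <- make_ppi_fixture(sprintf("g%03d", 1:30), c("g001", "g002"),
                         effectors_per_target = 3, background_density = 0.1,
                         seed = 5)
  path <- tempfile(fileext = ".tsv")
  write_string_edges(fx, path)
  g <- read_string_graph(path) # header present, 0-1000 integer scores
  expect_equal(g$adjacency["g001", fx$effectors[["g001"]][1]], 0.9)

  # headerless variant parses identically
  lines <- readLines(path)
  path2 <- tempfile()
  writeLines(lines[-1], path2)
  g2 <- read_string_graph(path2)
  expect_equal(g2$adjacency, g$adjacency[g2$nodes, g2$nodes])

  # identifier mapping translates endpoints
  map <- tempfile()
  writeLines(c("g001\tTP53", "g002\tEGFR"), map)
  gm <- read_string_graph(path, mapping = map)
  expect_true(all(c("TP53", "EGFR") %in% gm$nodes))
  expect_false("g001" %in% gm$nodes)

  expect_error(read_string_graph(tempfile()), "not found")

  # weight vector TSV round-trip, metadata included
  w0 <- initial_weights("g001", g$nodes, 1, 1e-5)
  ws <- propagate_weights(w0, g, propagation_config(alpha = 0.7))
  wt <- tempfile(fileext = ".tsv")
  write_weights_tsv(ws, wt)
  back <- read_weights_tsv(wt)
  expect_equal(as.numeric(back), as.numeric(ws))
  expect_identical(names(back), names(ws))
  expect_identical(attr(back, "stage"), "propagated")
  expect_equal(attr(back, "alpha"), 0.7)
})
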