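test_that("transition matrix distributes 1/d(x) per column", {
  W <- transition_matrix(path_net())
  expect_equal(W["a", "b"], 0.5)
  expect_equal(W["c", "b"], 0.5)
  expect_equal(W["b", "a"], 1)
  expect_equal(unname(colSums(W)), rep(1, 3))
  # isolated nodes self-loop
  iso <- mon(data.frame(id = c("a", "b", "x")),
             data.frame(from = "a", to = "b"))
  Wi <- transition_matrix(iso)
  expect_equal(Wi["x", "x"], 1)
  expect_error(transition_matrix(mon(data.frame(id = character()))),
               "empty")
})

test_that("columns are stochastic on random graphs, weighted or not", {
  for (s in 1:5) {
    net <- random_net(30, p = 0.1, seed = s)
    expect_equal(unname(colSums(transition_matrix(net))), rep(1, 30),
                 tolerance = 1e-12)
    net$edges$weight <- runif(nrow(net$edges), 0.1, 2)
    net <- mon(net$nodes, net$edges)
    expect_equal(unname(colSums(transition_matrix(net, weighted = TRUE))),
                 rep(1, 30), tolerance = 1e-12)
  }
})

test_that("parallel provenance edges collapse to one adjacency entry", {
  net <- mon(data.frame(id = c("a", "b")),
             data.frame(from = c("a", "a"), to = c("b", "b"),
                        provenance = c("knowledge_ppi", "coding"),
                        weight = c(0.4, 0.9)))
  W <- transition_matrix(net)
  expect_equal(W["b", "a"], 1)
  Ww <- transition_matrix(net, weighted = TRUE)
  expect_equal(Ww["b", "a"], 1)  # single neighbour, max weight normalized
})

test_that("restart-only walk returns the seed distribution exactly", {
  net <- star_net()
  r <- rwr(net, c("l1", "l2"), walk_config(restart = 1))
  expect_equal(unname(r$scores[c("l1", "l2")]), c(0.5, 0.5))
  expect_equal(sum(r$scores), 1)
  expect_false(any(r$seeds %in% r$ranking$node))
})

test_that("the 3-leaf star closed form is reproduced", {
  r <- rwr(star_net(), "c", walk_config(restart = 0.5, tol = 1e-14))
  expect_equal(unname(r$scores["c"]), 2 / 3, tolerance = 1e-10)
  expect_equal(unname(r$scores[c("l1", "l2", "l3")]), rep(1 / 9, 3),
               tolerance = 1e-10)
})

test_that("iteration matches the direct linear solve on random graphs", {
  for (s in 1:20) {
    n <- sample(20:120, 1)
    net <- random_net(n, p = 0.05, seed = s)
    W <- transition_matrix(net)
    seeds <- sample(net$nodes$id, sample(1:3, 1))
    r <- sample(c(0.3, 0.5, 0.7), 1)
    got <- rwr(net, seeds, walk_config(restart = r, tol = 1e-12))
    want <- rwr_solve_oracle(W, seeds, r)
    expect_lt(sum(abs(got$scores[names(want)] - want)), 1e-8)
    expect_equal(sum(got$scores), 1, tolerance = 1e-8)
  }
})

test_that("scores decrease with hop distance on a path", {
  ids <- paste0("n", 1:7)
  net <- path_net(ids)
  for (r in c(0.1, 0.5, 0.9)) {
    res <- rwr(net, "n1", walk_config(restart = r, tol = 1e-13))
    # non-seed scores strictly decrease with hop distance from the seed
    expect_true(all(diff(unname(res$scores[ids[-1]])) < 0))
  }
})

test_that("relabelling nodes permutes scores identically", {
  net <- random_net(25, p = 0.15, seed = 9)
  res <- rwr(net, "n001", walk_config(restart = 0.6, tol = 1e-12))
  relab <- setNames(sprintf("z%03d", 25:1), net$nodes$id)
  nodes2 <- net$nodes; nodes2$id <- unname(relab[nodes2$id])
  edges2 <- net$edges
  edges2$from <- unname(relab[edges2$from])
  edges2$to <- unname(relab[edges2$to])
  net2 <- mon(nodes2, edges2)
  res2 <- rwr(net2, unname(relab["n001"]),
              walk_config(restart = 0.6, tol = 1e-12))
  expect_equal(unname(res2$scores[unname(relab[names(res$scores)])]),
               unname(res$scores), tolerance = 1e-9)
})

test_that("mechanism sub-networks report layer reach screens", {
  nodes <- data.frame(
    id = c("go:T", "rna:g", "prot:p", "met:m"),
    layer = c("go_term", "gene", "protein", "metabolite"))
  edges <- data.frame(from = c("go:T", "rna:g", "prot:p"),
                      to = c("rna:g", "prot:p", "met:m"),
                      provenance = c("annotation", "coding",
                                     "knowledge_reaction"))
  net <- mon(nodes, edges)
  scr <- mechanism_subnetworks(net, k = 25)
  expect_equal(scr$seed, "go:T")
  expect_true(scr$reaches_gene_and_protein)
  expect_true(scr$reaches_gene_protein_metabolite)
  # seed adjacent to a single gene in a 2-node net: sub-network is both
  net2 <- mon(nodes[1:2, ], edges[1, , drop = FALSE])
  scr2 <- mechanism_subnetworks(net2, k = 5)
  sub <- attr(scr2, "subnetworks")[["go:T"]]
  expect_setequal(sub$nodes$id, c("go:T", "rna:g"))
  expect_false(scr2$reaches_gene_and_protein)
})

test_that("function prediction assigns the nearest term node", {
  nodes <- data.frame(id = c("go:T", "prot:u", "prot:far"),
                      layer = c("go_term", "protein", "protein"))
  edges <- data.frame(from = "prot:u", to = "go:T",
                      provenance = "knowledge_ppi")
  net <- mon(nodes, edges)
  pred <- predict_function(net, unannotated = c("prot:u", "prot:far"))
  pu <- pred[pred$node == "prot:u", ]
  expect_true(pu$assigned)
  expect_equal(pu$term, "go:T")
  pf <- pred[pred$node == "prot:far", ]
  expect_false(pf$assigned)
  expect_true(is.na(pf$term))
})

test_that("planted term memberships are recovered by propagation", {
  recov <- vapply(1:20, function(s) {
    fix <- make_prediction_fixture(s)
    pred <- predict_function(fix$net, unannotated = names(fix$truth))
    mean(pred$term == unname(fix$truth[pred$node]))
  }, 0)
  expect_gte(mean(recov), 0.95)
})

test_that("cluster intersection retains only cross-cluster seeds with terms", {
  # homogeneous clusters: nothing retained
  nodes <- data.frame(id = c("a", "b", "go:T"),
                      layer = c("gene", "gene", "go_term"),
                      cluster = c("1", "1", NA))
  edges <- data.frame(from = c("a", "b"), to = c("b", "go:T"),
                      provenance = c("inferred_mi", "annotation"))
  net <- mon(nodes, edges)
  res <- cluster_intersection(net, k = 5)
  expect_equal(sum(res$retained), 0L)
  # a seed tied to an opposite-cluster node and a term node is retained
  nodes$cluster <- c("1", "2", NA)
  net2 <- mon(nodes, edges)
  res2 <- cluster_intersection(net2, k = 5)
  expect_true(res2$retained[res2$seed == "a"])
})

test_that("planted cross-cluster regulators are retained by the screen", {
  # regulator r (cluster 1) wired into cluster-2 targets and a term node
  nodes <- data.frame(
    id = c("reg", paste0("t", 1:3), paste0("o", 1:3), "go:T"),
    layer = c(rep("gene", 7), "go_term"),
    cluster = c("1", "2", "2", "2", "1", "1", "1", NA))
  edges <- rbind(
    data.frame(from = "reg", to = paste0("t", 1:3),
               provenance = "inferred_mi"),
    data.frame(from = "o1", to = c("o2", "o3"), provenance = "inferred_mi"),
    data.frame(from = "reg", to = "go:T", provenance = "annotation"))
  net <- mon(nodes, edges)
  res <- cluster_intersection(net, k = 4)
  expect_true(res$retained[res$seed == "reg"])
  expect_true("reg" %in% names(attr(res, "subnetworks")))
})
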