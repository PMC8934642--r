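test_that("constructor enforces the node and edge invariants", {
  expect_error(mon(data.frame(id = c("a", "a"))), "duplicate")
  expect_error(mon(data.frame(id = "a", layer = "weird")), "unknown layer")
  expect_error(mon(data.frame(id = c("a", "b")),
                   data.frame(from = "a", to = "a")), "self-edges")
  expect_error(mon(data.frame(id = "a"),
                   data.frame(from = "a", to = "zzz")), "zzz")
  # term nodes are never measured and carry no cluster
  net <- mon(data.frame(id = "g1", layer = "go_term", measured = TRUE,
                        cluster = 3))
  expect_false(net$nodes$measured)
  expect_true(is.na(net$nodes$cluster))
  # duplicate (pair, provenance) collapses, keeping the larger weight
  net <- mon(data.frame(id = c("a", "b")),
             data.frame(from = c("a", "b"), to = c("b", "a"),
                        provenance = "knowledge_ppi", weight = c(0.2, 0.9)))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 0.9)
})

test_that("merge_networks unions nodes and edges with the resolution rules", {
  g <- mon(data.frame(id = c("a", "b"), measured = c(TRUE, FALSE)),
           data.frame(from = "a", to = "b"))
  empty <- mon(data.frame(id = character()))
  m <- merge_networks(list(g, empty))
  expect_equal(m$nodes[order(m$nodes$id), ], g$nodes[order(g$nodes$id), ],
               ignore_attr = TRUE)
  expect_equal(m$edges, g$edges, ignore_attr = TRUE)
  # idempotence
  m2 <- merge_networks(list(g, g))
  expect_equal(nrow(m2$nodes), 2L)
  expect_equal(nrow(m2$edges), 1L)
  # measured = TRUE wins; cluster labels union
  h <- mon(data.frame(id = "b", measured = TRUE, cluster = "2"))
  g2 <- mon(data.frame(id = "b", measured = FALSE, cluster = "1"))
  mm <- merge_networks(list(g2, h))
  expect_true(mm$nodes$measured)
  expect_equal(mm$nodes$cluster, "1;2")
  # conflicting layers error and name the id
  bad <- mon(data.frame(id = "a", layer = "protein"))
  expect_error(merge_networks(list(g, bad)), "a")
})

test_that("merge is commutative and associative on random fixtures", {
  nets <- lapply(1:3, function(s) random_net(12, p = 0.2, seed = s))
  canon <- function(n) {
    list(nodes = n$nodes[order(n$nodes$id), ],
         edges = n$edges[order(n$edges$from, n$edges$to,
                               n$edges$provenance), ])
  }
  ab <- merge_networks(nets[1:2])
  ba <- merge_networks(nets[2:1])
  expect_equal(canon(ab), canon(ba), ignore_attr = TRUE)
  left <- merge_networks(list(merge_networks(nets[1:2]), nets[[3]]))
  right <- merge_networks(list(nets[[1]], merge_networks(nets[2:3])))
  expect_equal(canon(left), canon(right), ignore_attr = TRUE)
})

test_that("induced_subnetwork keeps exactly the requested structure", {
  p <- path_net()
  sub <- induced_subnetwork(p, c("a", "c"))
  expect_equal(sort(sub$nodes$id), c("a", "c"))
  expect_equal(nrow(sub$edges), 0L)
  expect_equal(induced_subnetwork(p, c("a", "b", "c"))$edges, p$edges)
  tri <- triangle_net()
  expect_equal(nrow(induced_subnetwork(tri, c("a", "b"))$edges), 1L)
  expect_error(induced_subnetwork(p, "nope"), "nope")
})

test_that("summarize_network counts layers, components and isolated nodes", {
  s0 <- summarize_network(mon(data.frame(id = character())))
  expect_equal(s0$n_nodes, 0L)
  expect_equal(s0$n_components, 0L)
  sp <- summarize_network(path_net())
  expect_equal(sp$n_components, 1L)
  expect_equal(sp$n_isolated, 0L)
  two <- mon(data.frame(id = letters[1:4]),
             data.frame(from = c("a", "c"), to = c("b", "d")))
  expect_equal(summarize_network(two)$n_components, 2L)
  iso <- mon(data.frame(id = c("a", "b", "x")),
             data.frame(from = "a", to = "b"))
  expect_equal(summarize_network(iso)$n_isolated, 1L)
})

test_that("edge tables read with validation and round-trip through disk", {
  tmp <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("source\ttarget", "a\tb", "b\tc"), tmp)
  net <- read_edge_table(tmp)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(nrow(net$edges), 2L)
  writeLines(c("source\ttarget\tweight", "a\tb\t0.5", "b\tc"), tmp)
  expect_error(read_edge_table(tmp), "line 3")
  writeLines(c("source\ttarget\tweight", "a\tb\tnotanumber"), tmp)
  expect_error(read_edge_table(tmp), "non-numeric weight")
  # round trip
  net <- random_net(15, p = 0.25, seed = 7,
                    layers = c("gene", "protein"))
  out <- withr::local_tempfile(fileext = ".tsv")
  write_edge_table(net, out)
  back <- read_edge_table(out)
  expect_setequal(paste(back$edges$from, back$edges$to),
                  paste(net$edges$from, net$edges$to))
})

test_that("GraphML round trip preserves nodes, edges and attributes", {
  net <- mon(data.frame(id = c("rna:a", "prot:b", "go:T1"),
                        layer = c("gene", "protein", "go_term"),
                        measured = c(TRUE, FALSE, FALSE),
                        cluster = c("2", NA, NA),
                        label = c(NA, "beta", "term one")),
             data.frame(from = c("rna:a", "go:T1"),
                        to = c("prot:b", "prot:b"),
                        provenance = c("coding", "annotation"),
                        weight = c(0.123456789012, 1),
                        source_role = c("rna:a", NA)))
  tmp <- withr::local_tempfile(fileext = ".graphml")
  write_graphml(net, tmp)
  back <- read_graphml(tmp)
  o <- order(back$nodes$id)
  expect_equal(back$nodes[o, ], net$nodes[order(net$nodes$id), ],
               ignore_attr = TRUE)
  oe <- order(back$edges$from, back$edges$to)
  on <- order(net$edges$from, net$edges$to)
  expect_equal(back$edges[oe, c("from", "to", "provenance", "source_role")],
               net$edges[on, c("from", "to", "provenance", "source_role")],
               ignore_attr = TRUE)
  expect_equal(back$edges$weight[oe], net$edges$weight[on],
               tolerance = 1e-12)
})

test_that("GMT files parse, validate and round-trip", {
  tmp <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("T1\tdesc\tA\tB", "T2\tother\tC\tD\tE"), tmp)
  ann <- read_gmt(tmp)
  expect_equal(ann$members$T1, c("A", "B"))
  expect_equal(lengths(ann$members), c(T1 = 2L, T2 = 3L))
  writeLines(c("T1\tdesc\tA", "T1\tdesc\tB"), tmp)
  expect_error(read_gmt(tmp), "duplicate term")
  writeLines(c("T1\tdesc"), tmp)
  expect_error(read_gmt(tmp), "fewer than 3")
  ann <- annotation_set(list(X = c("a", "b"), Y = c("c")),
                        source = "GO:MF", description = c("dx", "dy"))
  out <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(ann, out)
  back <- read_gmt(out, source = "GO:MF")
  expect_equal(back$members, ann$members)
  expect_equal(back$meta, ann$meta)
})
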