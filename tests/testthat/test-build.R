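test_that("MI of a variable with itself equals the marginal entropy", {
  x <- as.numeric(1:100)  # n divisible by 4: exact equal-frequency bins
  mim <- estimate_mi(rbind(a = x, b = x), bins = 4)
  expect_equal(mim$mi["a", "b"], 2)  # log2(4) bits
})

test_that("MI estimator matches the brute-force contingency oracle", {
  set.seed(41)
  for (i in 1:10) {
    n <- sample(20:60, 1)
    bins <- sample(2:5, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    mim <- estimate_mi(rbind(a = x, b = y), bins = bins)
    expect_equal(mim$mi["a", "b"],
                 mi_oracle_binned(bin_equal_freq(x, bins),
                                  bin_equal_freq(y, bins)),
                 tolerance = 1e-12)
  }
})

test_that("independent variables give near-zero MI at large n", {
  small <- vapply(1:20, function(s) {
    set.seed(s)
    x <- runif(1000); y <- runif(1000)
    estimate_mi(rbind(a = x, b = y), bins = 4)$mi["a", "b"] <= 0.05
  }, TRUE)
  expect_gte(mean(small), 0.95)
})

test_that("constant features get MI 0 with a warning", {
  expect_warning(mim <- estimate_mi(rbind(a = rep(1, 10), b = rnorm(10))),
                 "constant")
  expect_equal(mim$mi["a", "b"], 0)
})

test_that("DPI pruning removes each triangle's weakest edge", {
  mi <- matrix(0, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  mi["a", "b"] <- mi["b", "a"] <- 0.5
  mi["b", "c"] <- mi["c", "b"] <- 0.4
  mi["a", "c"] <- mi["c", "a"] <- 0.1
  diag(mi) <- NA
  mim <- structure(list(mi = mi, bins = 3, unit = "bits"),
                   class = "mi_matrix")
  ed0 <- dpi_prune(mim, mi_floor = 0, epsilon = 0)
  key <- paste(ed0$from, ed0$to)
  expect_setequal(key, c("a b", "b c"))
  # with a tolerant epsilon the weak edge survives: 0.1 >= 0.2 * 0.4
  ed8 <- dpi_prune(mim, mi_floor = 0, epsilon = 0.8)
  expect_equal(nrow(ed8), 3L)
  # output is always a subset of the thresholded MI graph
  ed_thr <- dpi_prune(mim, mi_floor = 0.3, epsilon = 0)
  expect_true(all(ed_thr$weight >= 0.3))
})

test_that("chain fixtures lose the indirect edge and keep direct ones", {
  hits <- vapply(1:20, function(s) {
    reg <- gen_regulatory(n_nodes = 3, n_samples = 200, seed = s)
    ed <- dpi_prune(estimate_mi(reg$expr), mi_floor = 0, epsilon = 0.15)
    key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
    truth <- paste(pmin(reg$edges$from, reg$edges$to),
                   pmax(reg$edges$from, reg$edges$to))
    setequal(key, truth)
  }, TRUE)
  expect_gte(mean(hits), 0.9)
})

test_that("planted 50-node regulatory structure is recovered with F1 >= 0.7", {
  reg <- gen_regulatory(n_nodes = 50, n_samples = 200, seed = 1)
  floor_ <- mi_permutation_floor(reg$expr, seed = 1)
  ed <- dpi_prune(estimate_mi(reg$expr), mi_floor = floor_, epsilon = 0.15)
  key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to))
  truth <- paste(pmin(reg$edges$from, reg$edges$to),
                 pmax(reg$edges$from, reg$edges$to))
  tp <- length(intersect(key, truth))
  f1 <- 2 * tp / (length(key) + length(truth))
  expect_gte(f1, 0.7)
})

test_that("knowledge layer extends to first-degree neighbours only", {
  tab <- data.frame(id_a = c("A", "C", "B"), id_b = c("C", "D", "A"))
  net <- knowledge_layer(c("A", "B"), tab, extend = TRUE)
  expect_setequal(net$nodes$id, c("A", "B", "C"))
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("A B", "A C"))
  expect_false(net$nodes$measured[net$nodes$id == "C"])
  net0 <- knowledge_layer(c("A", "B"), tab, extend = FALSE)
  expect_setequal(net0$nodes$id, c("A", "B"))
  expect_equal(nrow(net0$edges), 1L)
})

test_that("confidence scores filter knowledge rows", {
  tab <- data.frame(id_a = c("A", "A"), id_b = c("B", "C"),
                    score = c(0.9, 0.1))
  net <- knowledge_layer(c("A", "B", "C"), tab,
                         score_min = median(tab$score))
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$weight, 0.9)
})

test_that("no unmeasured node sits farther than one hop from a measured one", {
  set.seed(51)
  for (i in 1:10) {
    meas <- sprintf("m%02d", 1:8)
    unmeas <- sprintf("u%02d", 1:8)
    all_ids <- c(meas, unmeas)
    tab <- data.frame(id_a = sample(all_ids, 40, replace = TRUE),
                      id_b = sample(all_ids, 40, replace = TRUE))
    tab <- tab[tab$id_a != tab$id_b, ]
    net <- knowledge_layer(meas, tab, extend = TRUE)
    g <- mon_igraph(net)
    dm <- igraph::distances(g, v = net$nodes$id[!net$nodes$measured],
                            to = net$nodes$id[net$nodes$measured])
    if (nrow(dm)) expect_true(all(apply(dm, 1, min) == 1))
  }
})

test_that("reaction layer builds compound cliques and enzyme links", {
  rx <- data.frame(reaction_id = "R1", compounds = "C1;C2", enzymes = "E1")
  net <- reaction_layer("C1", rx)
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("C1 C2", "C1 E1", "C2 E1"))
  expect_false(net$nodes$measured[net$nodes$id == "C2"])
  # disjoint reactions produce no cross edges
  rx2 <- data.frame(reaction_id = c("R1", "R2"),
                    compounds = c("C1;C2", "C3;C4"), enzymes = c("", ""))
  net2 <- reaction_layer(c("C1", "C3"), rx2)
  keys <- paste(net2$edges$from, net2$edges$to)
  expect_setequal(keys, c("C1 C2", "C3 C4"))
  # reactions with no measured compound are skipped entirely
  net3 <- reaction_layer("C1", rx2)
  expect_false(any(c("C3", "C4") %in% net3$nodes$id))
})

test_that("cross-link rows become provenance-typed deduplicated edges", {
  tab <- data.frame(id_a = c("prot:TP53", "prot:TP53", "prot:TF1"),
                    id_b = c("rna:TP53", "rna:TP53", "rna:G1"),
                    relation = c("coding", "coding", "tf_target"))
  ed <- cross_link_ids(tab)
  expect_equal(nrow(ed), 2L)
  expect_setequal(ed$provenance, c("coding", "tf_target"))
  expect_equal(ed$source_role, ed$from)
  expect_equal(nrow(cross_link_ids(tab[0, ])), 0L)
  expect_error(cross_link_ids(data.frame(id_a = "a", id_b = "b",
                                         relation = "banana")), "banana")
})

test_that("rank-correlation links obey the threshold", {
  x <- matrix(c(1, 2, 3, 4, 5), 1, dimnames = list("a", NULL))
  y <- rbind(mono = c(2, 4, 6, 9, 20), anti = c(5, 4, 3, 2, 1))
  ed <- correlation_link(x, y, rho_min = 0.99)
  expect_setequal(ed$to, c("mono", "anti"))
  expect_equal(ed$weight, c(1, 1))
  set.seed(61)
  z <- rbind(noisy = rank(c(1, 2, 4, 3, 5)))  # spearman 0.9 < 0.99
  expect_equal(nrow(correlation_link(x, z, rho_min = 0.99)), 0L)
})

test_that("identical compositional trajectories give basis correlation 1", {
  set.seed(71)
  base <- matrix(rpois(4 * 50, 40) + 1, ncol = 4)
  counts <- cbind(base, twin = base[, 1])
  colnames(counts) <- c("t1", "t2", "t3", "t4", "twin")
  sp <- sparcc_correlation(counts)
  expect_equal(sp$rho["t1", "twin"], 1, tolerance = 0.05)
  expect_error(sparcc_correlation(counts[, 1:3]), "at least 4")
})

test_that("SparCC estimates are calibrated on planted fixtures", {
  ind <- gen_compositional(n_taxa = 20, n_samples = 500, seed = 1)
  sp <- sparcc_correlation(ind$counts)
  expect_lte(mean(abs(sp$rho[upper.tri(sp$rho)])), 0.1)
  pl <- gen_compositional(n_taxa = 20, n_samples = 500,
                          planted = data.frame(i = 1, j = 2, rho = 0.8),
                          seed = 2)
  sp2 <- sparcc_correlation(pl$counts)
  expect_lt(abs(sp2$rho[1, 2] - 0.8), 0.15)
})

test_that("assemble partitions measured nodes and shares knowledge hubs", {
  # hub protein H linked to measured proteins in different clusters
  tab <- data.frame(id_a = c("p1", "p2", "p1", "p3"),
                    id_b = c("H", "H", "p2", "p4"))
  labels <- c(p1 = 1, p2 = 2, p3 = 1, p4 = 2)
  build_fun <- function(ids) knowledge_layer(ids, tab, extend = TRUE)
  res <- assemble(build_fun, labels)
  meas_entire <- res$entire$nodes$id[res$entire$nodes$measured]
  meas_per <- lapply(res$per_cluster, function(n)
    n$nodes$id[n$nodes$measured])
  expect_setequal(unlist(meas_per), meas_entire)
  expect_equal(sum(duplicated(unlist(meas_per))), 0L)
  in_clusters <- vapply(res$per_cluster, function(n) "H" %in% n$nodes$id,
                        TRUE)
  expect_gte(sum(in_clusters), 2L)
  # cluster labels are stamped onto measured nodes
  stamped <- res$entire$nodes$cluster[match(names(labels),
                                            res$entire$nodes$id)]
  expect_equal(stamped, as.character(labels), ignore_attr = TRUE)
  # single-cluster case: the per-cluster network equals the entire one
  res1 <- assemble(build_fun, setNames(rep(1, 4), names(labels)))
  expect_equal(sort(res1$per_cluster[[1]]$nodes$id),
               sort(res1$entire$nodes$id))
  expect_warning(assemble(build_fun, labels[1:3],
                          all_features = names(labels)), "cluster label")
})
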