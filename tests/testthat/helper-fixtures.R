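# Small graph builders and independent brute-force oracles used across the
# suite. Oracles are deliberately naive re-derivations of the definitions,
# kept separate from the implementation paths they check.

path_net <- function(ids = c("a", "b", "c")) {
  mon(data.frame(id = ids),
      data.frame(from = ids[-length(ids)], to = ids[-1]))
}

star_net <- function(center = "c", leaves = c("l1", "l2", "l3")) {
  mon(data.frame(id = c(center, leaves)),
      data.frame(from = center, to = leaves))
}

triangle_net <- function(ids = c("a", "b", "c")) {
  mon(data.frame(id = ids),
      data.frame(from = ids[c(1, 2, 3)], to = ids[c(2, 3, 1)]))
}

random_net <- function(n, p = 0.1, seed = 1, layers = "gene") {
  set.seed(seed)
  ids <- sprintf("n%03d", seq_len(n))
  pairs <- t(combn(ids, 2))
  take <- runif(nrow(pairs)) < p
  mon(data.frame(id = ids, layer = sample(layers, n, replace = TRUE)),
      if (any(take)) data.frame(from = pairs[take, 1], to = pairs[take, 2])
      else NULL)
}

# dense linear-solve oracle for the restart walk: (I - (1-r)W) p = r p0
rwr_solve_oracle <- function(W, seeds, r) {
  ids <- rownames(W)
  p0 <- setNames(rep(0, length(ids)), ids)
  p0[seeds] <- 1 / length(seeds)
  p <- solve(diag(length(ids)) - (1 - r) * W, r * p0)
  setNames(as.numeric(p), ids)
}

# brute-force silhouette under correlation distance, straight from the
# definition; singletons contribute 0
silhouette_oracle <- function(profiles, labels) {
  d <- 1 - cor(t(profiles))
  n <- nrow(profiles)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(d[i, labels == cl]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# brute-force MI (bits) from already-binned integer vectors via table()
mi_oracle_binned <- function(xi, yi) {
  tab <- table(xi, yi)
  n <- sum(tab)
  pj <- tab / n
  px <- rowSums(pj); py <- colSums(pj)
  tot <- 0
  for (i in seq_len(nrow(pj))) for (j in seq_len(ncol(pj))) {
    if (pj[i, j] > 0)
      tot <- tot + pj[i, j] * log2(pj[i, j] / (px[i] * py[j]))
  }
  as.numeric(tot)
}

# equal-frequency binning mirroring the estimator's rule
bin_equal_freq <- function(x, bins) {
  as.integer(cut(rank(x, ties.method = "first"), breaks = bins,
                 labels = FALSE, include.lowest = TRUE))
}

# hypergeometric upper tail by direct summation of the pmf
hyper_tail_oracle <- function(k, N, m, q) {
  if (k == 0) return(1)
  js <- k:min(m, q)
  sum(choose(m, js) * choose(N - m, q - js)) / choose(N, q)
}

# annotation + knowledge fixture for guilt-by-association recovery: each
# unlabeled node touches members of exactly one planted term
make_prediction_fixture <- function(seed, n_terms = 4, members_per_term = 5,
                                    n_unlabeled = 10) {
  set.seed(seed)
  term_ids <- sprintf("go:T%02d", seq_len(n_terms))
  mem <- lapply(seq_len(n_terms), function(i)
    sprintf("prot:m%02d_%02d", i, seq_len(members_per_term)))
  truth <- sample(seq_len(n_terms), n_unlabeled, replace = TRUE)
  unl <- sprintf("prot:u%02d", seq_len(n_unlabeled))
  nodes <- rbind(
    data.frame(id = term_ids, layer = "go_term", measured = FALSE),
    data.frame(id = unlist(mem), layer = "protein", measured = TRUE),
    data.frame(id = unl, layer = "protein", measured = TRUE))
  ann_edges <- do.call(rbind, lapply(seq_len(n_terms), function(i)
    data.frame(from = term_ids[i], to = mem[[i]], provenance = "annotation")))
  ppi_edges <- do.call(rbind, lapply(seq_len(n_unlabeled), function(u) {
    tgt <- sample(mem[[truth[u]]], 2)
    data.frame(from = unl[u], to = tgt, provenance = "knowledge_ppi")
  }))
  # intra-term cliques tie members together
  clique <- do.call(rbind, lapply(mem, function(m) {
    pr <- t(combn(m, 2))
    data.frame(from = pr[, 1], to = pr[, 2], provenance = "knowledge_ppi")
  }))
  list(net = mon(nodes, rbind(ann_edges, ppi_edges, clique)),
       truth = setNames(term_ids[truth], unl))
}

rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  pairs <- combn(n, 2)
  same_a <- a[pairs[1, ]] == a[pairs[2, ]]
  same_b <- b[pairs[1, ]] == b[pairs[2, ]]
  mean(same_a == same_b)
}

# run the standard modelling front end of the fixture blocks
scaled_fixture_blocks <- function(gb, fc = 2) {
  lapply(gb$blocks, function(bb) {
    ff <- fold_change_filter(bb, fc)$block
    scale_profiles(noise_filter(model_profiles(ff)))
  })
}
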