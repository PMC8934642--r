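#' Random-walk configuration
#'
#' @param restart restart probability r in [0, 1] (probability of jumping
#'   back to the seed distribution at each step; avoids dead ends in
#'   multi-layer graphs). The 0.7 default follows common practice for
#'   restart walks on molecular networks.
#' @param tol L1 convergence tolerance of the iteration.
#' @param max_iter maximum iterations.
#' @param weighted use edge weights (column-normalized) instead of the
#'   degree-based walk.
#' @return list of class `walk_config`.
#' @export
walk_config <- function(restart = 0.7, tol = 1e-10, max_iter = 5000,
                        weighted = FALSE) {
  stopifnot(restart >= 0, restart <= 1, tol > 0, max_iter >= 1)
  structure(list(restart = restart, tol = tol, max_iter = max_iter,
                 weighted = weighted), class = "walk_config")
}

#' Column-stochastic transition matrix of a network
#'
#' Parallel (multi-provenance) edges are collapsed first. In the unweighted
#' walk the column of node x distributes `1/d(x)` to each neighbour, where
#' `d(x)` is its degree; the weighted variant normalizes edge weights per
#' column. Isolated nodes get a self-loop of 1 so every column is
#' stochastic.
#'
#' @param net a `mon`.
#' @param weighted use edge weights.
#' @return dense column-stochastic matrix with node ids as dimnames.
#' @export
transition_matrix <- function(net, weighted = FALSE) {
  stopifnot(inherits(net, "mon"))
  if (nrow(net$nodes) == 0L) stop("empty graph")
  g <- mon_igraph(net, collapse = TRUE)
  A <- as.matrix(igraph::as_adjacency_matrix(
    g, attr = if (weighted) "weight" else NULL, sparse = TRUE))
  A <- A[net$nodes$id, net$nodes$id, drop = FALSE]
  colsum <- colSums(A)
  iso <- colsum == 0
  W <- A
  W[, !iso] <- sweep(A[, !iso, drop = FALSE], 2, colsum[!iso], `/`)
  if (any(iso)) W[cbind(which(iso), which(iso))] <- 1
  W
}

#' Random walk with restart
#'
#' Iterates `p <- (1 - r) W p + r p0` from the uniform seed distribution
#' `p0` until the L1 change drops below the tolerance; the fixed point
#' solves `(I - (1 - r) W) p = r p0`. Scores are non-negative, sum to 1,
#' and measure each node's proximity to the seed set.
#'
#' @param net a `mon`.
#' @param seeds node ids (non-empty subset of the network's nodes).
#' @param config a [walk_config()].
#' @return object of class `propagation_result`: list with `seeds`,
#'   `scores` (named numeric), `ranking` (data.frame of non-seed nodes by
#'   descending score, ties broken by node id), `iterations`, `config`.
#' @export
rwr <- function(net, seeds, config = walk_config()) {
  stopifnot(inherits(net, "mon"), inherits(config, "walk_config"))
  seeds <- unique(as.character(seeds))
  miss <- setdiff(seeds, net$nodes$id)
  if (length(miss)) stop("seed(s) not in network: ",
                         paste(miss, collapse = ", "))
  if (!length(seeds)) stop("empty seed set")
  W <- transition_matrix(net, weighted = config$weighted)
  ids <- rownames(W)
  p0 <- setNames(rep(0, length(ids)), ids)
  p0[seeds] <- 1 / length(seeds)
  r <- config$restart
  p <- p0
  used <- 0L
  if (r == 1) {
    p <- p0
  } else {
    for (it in seq_len(config$max_iter)) {
      pn <- (1 - r) * as.numeric(W %*% p) + r * p0
      delta <- sum(abs(pn - p))
      p <- setNames(pn, ids)
      used <- it
      if (delta < config$tol) break
    }
    if (used == config$max_iter && delta >= config$tol)
      stop(sprintf("RWR did not converge in %d iterations (L1 residual %.3g)",
                   config$max_iter, delta))
  }
  nonseed <- setdiff(ids, seeds)
  ord <- order(-p[nonseed], nonseed)
  ranking <- data.frame(node = nonseed[ord], score = unname(p[nonseed][ord]),
                        rank = seq_along(nonseed), stringsAsFactors = FALSE)
  structure(list(seeds = seeds, scores = p, ranking = ranking,
                 iterations = used, config = config),
            class = "propagation_result")
}

#' @export
print.propagation_result <- function(x, ...) {
  cat(sprintf("<propagation_result> %d seed(s), %d nodes, %d iterations, r=%.2f\n",
              length(x$seeds), length(x$scores), x$iterations,
              x$config$restart))
  invisible(x)
}

top_k_subnetwork <- function(net, res, k) {
  top <- head(res$ranking$node, k)
  induced_subnetwork(net, c(res$seeds, top))
}

#' Mechanism sub-networks from annotation-term seeds
#'
#' Each term seed (GO/disease node) is propagated from in turn; the induced
#' sub-network of the seed plus its `k` highest-scoring nodes is extracted
#' and profiled by layer. Two multi-omics screens are reported: whether the
#' sub-network reaches both genes and proteins, and whether it additionally
#' reaches metabolites.
#'
#' @param net a `mon` containing term nodes.
#' @param term_seeds term node ids to seed from (default: every term node).
#' @param k number of closest nodes per seed.
#' @param config a [walk_config()].
#' @return data.frame (seed, layer counts, reaches_gene_and_protein,
#'   reaches_gene_protein_metabolite) with the sub-networks in the
#'   `subnetworks` attribute (named list of `mon`).
#' @export
mechanism_subnetworks <- function(net, term_seeds = NULL, k = 25,
                                  config = walk_config()) {
  stopifnot(inherits(net, "mon"))
  if (is.null(term_seeds))
    term_seeds <- net$nodes$id[net$nodes$layer %in% TERM_LAYERS]
  if (!length(term_seeds)) stop("no term seeds in the network")
  subs <- list()
  rows <- lapply(term_seeds, function(s) {
    res <- rwr(net, s, config)
    sub <- top_k_subnetwork(net, res, k)
    subs[[s]] <<- sub
    others <- sub$nodes[sub$nodes$id != s, , drop = FALSE]
    lc <- table(factor(others$layer, levels = NODE_LAYERS))
    has_gene <- lc[["gene"]] + lc[["tf"]] > 0
    data.frame(seed = s, n_gene = lc[["gene"]] + lc[["tf"]],
               n_protein = lc[["protein"]], n_metabolite = lc[["metabolite"]],
               n_otu = lc[["otu"]], n_clinical = lc[["clinical"]],
               n_term = lc[["go_term"]] + lc[["disease"]],
               reaches_gene_and_protein = has_gene && lc[["protein"]] > 0,
               reaches_gene_protein_metabolite =
                 has_gene && lc[["protein"]] > 0 && lc[["metabolite"]] > 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "subnetworks") <- subs
  out
}

#' Guilt-by-association function prediction for unannotated nodes
#'
#' Molecule nodes with no annotation edge are treated as unannotated. Each
#' is turned into a seed; per ontology/source of the term layer, the
#' highest-scoring term node of that ontology is assigned (ties broken by
#' node id). Nodes that cannot reach any term node are flagged unassigned.
#'
#' @param net a `mon` with a term layer.
#' @param unannotated node ids to predict for; default: molecule nodes with
#'   no annotation-provenance edge.
#' @param sources optional mapping of term node id to ontology (named
#'   character). When NULL all term nodes form one pool tagged by layer.
#' @param config a [walk_config()].
#' @return data.frame (node, ontology, term, score, assigned).
#' @export
predict_function <- function(net, unannotated = NULL, sources = NULL,
                             config = walk_config()) {
  stopifnot(inherits(net, "mon"))
  is_term <- net$nodes$layer %in% TERM_LAYERS
  term_ids <- net$nodes$id[is_term]
  if (!length(term_ids)) stop("network has no term layer")
  if (is.null(unannotated)) {
    ann_edges <- net$edges[net$edges$provenance == "annotation", ,
                           drop = FALSE]
    annotated <- unique(c(ann_edges$from, ann_edges$to))
    unannotated <- setdiff(net$nodes$id[!is_term], annotated)
  }
  if (is.null(sources))
    sources <- setNames(net$nodes$layer[is_term], term_ids)
  onts <- unique(sources)
  rows <- lapply(unannotated, function(s) {
    res <- rwr(net, s, config)
    do.call(rbind, lapply(onts, function(o) {
      pool <- names(sources)[sources == o]
      sc <- res$scores[pool]
      sc <- sc[sc > 0]
      if (!length(sc))
        return(data.frame(node = s, ontology = o, term = NA_character_,
                          score = NA_real_, assigned = FALSE,
                          stringsAsFactors = FALSE))
      best <- names(sc)[order(-sc, names(sc))][1L]
      data.frame(node = s, ontology = o, term = best,
                 score = unname(sc[best]), assigned = TRUE,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

#' Cross-cluster regulator screen
#'
#' Each measured seed is propagated from; the sub-network of its `k`
#' closest nodes is retained when it contains at least one node with a
#' kinetic-cluster label different from the seed's AND at least one
#' annotation-term node — the configuration suggestive of a regulatory
#' relationship between expression programs.
#'
#' @param net a `mon` with cluster labels and a term layer.
#' @param measured_seeds seed ids (default: all measured nodes with a
#'   cluster label).
#' @param k number of closest nodes per seed.
#' @param config a [walk_config()].
#' @return data.frame (seed, seed_cluster, other_clusters, n_terms,
#'   retained) with sub-networks of retained seeds in attribute
#'   `subnetworks`.
#' @export
cluster_intersection <- function(net, measured_seeds = NULL, k = 10,
                                 config = walk_config()) {
  stopifnot(inherits(net, "mon"))
  if (is.null(measured_seeds))
    measured_seeds <- net$nodes$id[net$nodes$measured &
                                     !is.na(net$nodes$cluster)]
  if (!length(measured_seeds)) stop("no measured, cluster-labelled seeds")
  clmap <- setNames(net$nodes$cluster, net$nodes$id)
  is_term <- setNames(net$nodes$layer %in% TERM_LAYERS, net$nodes$id)
  subs <- list()
  rows <- lapply(measured_seeds, function(s) {
    res <- rwr(net, s, config)
    sub <- top_k_subnetwork(net, res, k)
    others <- setdiff(sub$nodes$id, s)
    seed_cl <- cluster_labels(clmap[[s]])[[1]]
    other_cl <- setdiff(unique(unlist(cluster_labels(clmap[others]))),
                        seed_cl)
    n_terms <- sum(is_term[others])
    retained <- length(other_cl) > 0 && n_terms > 0
    if (retained) subs[[s]] <<- sub
    data.frame(seed = s, seed_cluster = clmap[[s]],
               other_clusters = paste(sort(other_cl), collapse = ";"),
               n_terms = n_terms, retained = retained,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "subnetworks") <- subs
  out
}

#' Write a propagation ranking as TSV
#'
#' @param net the network the result came from (for layer/cluster columns).
#' @param res a `propagation_result`.
#' @param path output TSV (seed, node, layer, cluster, score, rank).
#' @export
write_propagation <- function(net, res, path) {
  idx <- match(res$ranking$node, net$nodes$id)
  d <- data.frame(seed = paste(res$seeds, collapse = ";"),
                  node = res$ranking$node,
                  layer = net$nodes$layer[idx],
                  cluster = net$nodes$cluster[idx],
                  score = res$ranking$score,
                  rank = res$ranking$rank, stringsAsFactors = FALSE)
  write.table(format_num_df(d), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
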