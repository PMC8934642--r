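#' Default id prefixes per omics layer
#'
#' The node id namespace of a merged multi-omics network is flat, so the
#' assembler disambiguates features of different omics types with these
#' prefixes.
#' @export
LAYER_PREFIXES <- c(gene = "rna:", tf = "tf:", protein = "prot:",
                    metabolite = "met:", otu = "otu:", clinical = "clin:",
                    go_term = "go:", disease = "dis:")

#' Prefix feature ids by their block/layer
#' @param ids character feature ids.
#' @param block block name or layer name (`rna`/`gene`, `prot`/`protein`,
#'   `met`/`metabolite`, `otu`, `clin`/`clinical`, `tf`).
#' @return prefixed ids.
#' @export
prefix_ids <- function(ids, block) {
  key <- c(rna = "rna:", gene = "rna:", tf = "tf:", prot = "prot:",
           protein = "prot:", met = "met:", metabolite = "met:",
           otu = "otu:", clin = "clin:", clinical = "clin:")
  pre <- key[as.character(block)]
  pre[is.na(pre)] <- paste0(as.character(block)[is.na(pre)], ":")
  paste0(pre, ids)
}

#' Estimate pairwise mutual information by equal-frequency binning
#'
#' Each feature is discretized into `bins` equal-frequency bins (rank
#' based); the mutual information of every pair is computed from the joint
#' contingency table, `MI = sum p(x,y) log2[p(x,y)/(p(x)p(y))]`, in bits.
#' Constant features get MI 0 against everything, with a warning.
#'
#' @param expr numeric matrix, features x samples.
#' @param bins number of bins. The default scales as the cube root of the
#'   sample count, `max(3, min(10, floor(n^(1/3))))`, so the expected
#'   occupancy of each joint cell grows with n and the finite-sample MI
#'   bias stays small relative to the MI differences the DPI step compares.
#' @return object of class `mi_matrix`: list with `mi` (symmetric feature x
#'   feature matrix, diagonal NA), `bins`, `unit = "bits"`.
#' @export
estimate_mi <- function(expr, bins = NULL) {
  expr <- as.matrix(expr)
  n <- ncol(expr); p <- nrow(expr)
  if (is.null(bins)) bins <- max(3L, min(10L, floor(n^(1/3))))
  if (bins < 2) stop("bins must be >= 2")
  if (is.null(rownames(expr))) rownames(expr) <- paste0("f", seq_len(p))
  const <- apply(expr, 1, function(x) length(unique(x)) == 1L)
  if (any(const))
    warning("constant feature(s), MI set to 0: ",
            paste(head(rownames(expr)[const]), collapse = ", "))
  # equal-frequency bin index per feature
  disc <- t(apply(expr, 1, function(x) {
    if (length(unique(x)) == 1L) return(rep(1L, n))
    as.integer(cut(rank(x, ties.method = "first"),
                   breaks = bins, labels = FALSE, include.lowest = TRUE))
  }))
  mi <- matrix(0, p, p, dimnames = list(rownames(expr), rownames(expr)))
  for (i in seq_len(p - 1L)) {
    if (const[i]) next
    for (j in (i + 1L):p) {
      if (const[j]) next
      mi[i, j] <- mi[j, i] <- mi_from_counts(disc[i, ], disc[j, ], bins)
    }
  }
  diag(mi) <- NA_real_
  structure(list(mi = mi, bins = bins, unit = "bits"), class = "mi_matrix")
}

mi_from_counts <- function(xi, yi, bins) {
  joint <- tabulate((xi - 1L) * bins + yi, nbins = bins * bins)
  n <- length(xi)
  pj <- joint / n
  px <- tabulate(xi, nbins = bins) / n
  py <- tabulate(yi, nbins = bins) / n
  pxy <- outer(px, py)
  pjm <- matrix(pj, bins, bins, byrow = TRUE)  # row = x bin, col = y bin
  nz <- pjm > 0
  sum(pjm[nz] * log2(pjm[nz] / pxy[nz]))
}

#' @export
print.mi_matrix <- function(x, ...) {
  cat(sprintf("<mi_matrix> %d features, %d bins, %s\n",
              nrow(x$mi), x$bins, x$unit))
  invisible(x)
}

#' Permutation-null mutual information floor
#'
#' Estimates the MI threshold below which pairs are indistinguishable from
#' independence: each feature's samples are permuted independently and the
#' requested quantile of the resulting null MI distribution is returned.
#'
#' @param expr features x samples matrix.
#' @param bins bins passed to [estimate_mi()].
#' @param n_perm number of permutations.
#' @param probs quantile of the null distribution.
#' @param seed integer seed.
#' @return MI floor (bits).
#' @export
mi_permutation_floor <- function(expr, bins = NULL, n_perm = 20,
                                 probs = 0.95, seed = 1) {
  expr <- as.matrix(expr)
  with_seed(split_seed(seed, "mi_floor"), {
    null_mi <- unlist(lapply(seq_len(n_perm), function(i) {
      perm <- t(apply(expr, 1, sample))
      m <- suppressWarnings(estimate_mi(perm, bins = bins))$mi
      m[upper.tri(m)]
    }))
    as.numeric(quantile(null_mi, probs))
  })
}

#' Prune indirect edges by the data-processing inequality
#'
#' Starting from pairs with `MI >= mi_floor`, every triangle (i, j, k) is
#' inspected and edge (i, j) is marked for removal when
#' `MI(i,j) < (1 - epsilon) * min(MI(i,k), MI(j,k))`; marked edges are
#' removed simultaneously. With `epsilon = 0` this removes each triangle's
#' strictly weakest edge, discarding likely indirect interactions.
#'
#' @param mim an `mi_matrix` from [estimate_mi()].
#' @param mi_floor minimum MI to consider an edge at all.
#' @param epsilon DPI tolerance in [0, 1).
#' @return data.frame (from, to, weight) of surviving edges.
#' @export
dpi_prune <- function(mim, mi_floor = 0, epsilon = 0.15) {
  stopifnot(inherits(mim, "mi_matrix"), epsilon >= 0, epsilon < 1)
  mi <- mim$mi
  p <- nrow(mi)
  adj <- !is.na(mi) & mi >= mi_floor
  remove <- matrix(FALSE, p, p)
  for (i in seq_len(p - 1L)) for (j in (i + 1L):p) {
    if (!adj[i, j]) next
    ks <- which(adj[i, ] & adj[j, ])
    ks <- ks[ks != i & ks != j]
    for (k in ks) {
      if (mi[i, j] < (1 - epsilon) * min(mi[i, k], mi[j, k])) {
        remove[i, j] <- TRUE
        break
      }
    }
  }
  keep <- which(adj & upper.tri(adj) & !remove, arr.ind = TRUE)
  ids <- rownames(mi)
  data.frame(from = ids[keep[, 1]], to = ids[keep[, 2]],
             weight = mi[keep], stringsAsFactors = FALSE)
}

#' Infer a co-expression layer (MI estimation plus DPI pruning)
#'
#' Convenience wrapper chaining [estimate_mi()], [mi_permutation_floor()]
#' and [dpi_prune()] into a `mon` layer with provenance `inferred_mi`.
#'
#' @param expr features x samples matrix (ids already prefixed if needed).
#' @param layer node layer for the features.
#' @param bins,epsilon,mi_floor estimator settings; `mi_floor = NULL` uses
#'   the 95th percentile of a 20-permutation null.
#' @param seed seed for the permutation null.
#' @return a `mon`.
#' @export
inference_layer <- function(expr, layer = "gene", bins = NULL,
                            epsilon = 0.15, mi_floor = NULL, seed = 1) {
  mim <- suppressWarnings(estimate_mi(expr, bins = bins))
  if (is.null(mi_floor))
    mi_floor <- mi_permutation_floor(expr, bins = bins, seed = seed)
  ed <- dpi_prune(mim, mi_floor = mi_floor, epsilon = epsilon)
  nodes <- data.frame(id = rownames(expr), layer = layer, measured = TRUE,
                      stringsAsFactors = FALSE)
  if (nrow(ed)) ed$provenance <- "inferred_mi"
  mon(nodes, ed, name = paste0("inferred_", layer))
}

#' Build a knowledge interaction layer with first-degree extension
#'
#' Keeps interaction rows with `score >= score_min` (all rows when the table
#' is unscored), then forms the node set from the measured molecules present
#' in the table plus, when `extend = TRUE`, their direct interactors flagged
#' `measured = FALSE`. Edges are the surviving table rows with both
#' endpoints in that node set, so no unmeasured node ever sits at graph
#' distance greater than one from a measured molecule.
#'
#' @param measured_ids measured molecule ids.
#' @param table data.frame (id_a, id_b, optional type, optional score).
#' @param layer node layer.
#' @param score_min minimum confidence score (ignored if no score column).
#' @param extend include first-degree unmeasured interactors.
#' @param provenance edge provenance tag.
#' @return a `mon`.
#' @export
knowledge_layer <- function(measured_ids, table, layer = "protein",
                            score_min = NULL, extend = TRUE,
                            provenance = "knowledge_ppi") {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  stopifnot(all(c("id_a", "id_b") %in% names(table)))
  if (!is.null(table$score) && !is.null(score_min))
    table <- table[as.numeric(table$score) >= score_min, , drop = FALSE]
  measured_ids <- unique(as.character(measured_ids))
  touches <- table$id_a %in% measured_ids | table$id_b %in% measured_ids
  table <- table[touches, , drop = FALSE]
  nodes_meas <- intersect(measured_ids, c(table$id_a, table$id_b))
  if (extend) {
    ext <- setdiff(unique(c(table$id_a, table$id_b)), measured_ids)
    keep_edge <- rep(TRUE, nrow(table))
  } else {
    ext <- character()
    keep_edge <- table$id_a %in% measured_ids & table$id_b %in% measured_ids
  }
  table <- table[keep_edge, , drop = FALSE]
  nodes <- data.frame(id = c(nodes_meas, ext), layer = layer,
                      measured = c(rep(TRUE, length(nodes_meas)),
                                   rep(FALSE, length(ext))),
                      stringsAsFactors = FALSE)
  edges <- if (nrow(table))
    data.frame(from = table$id_a, to = table$id_b, provenance = provenance,
               weight = if (!is.null(table$score))
                 as.numeric(table$score) else 1,
               stringsAsFactors = FALSE)
  else NULL
  mon(nodes, edges, name = paste0("knowledge_", layer))
}

#' Build a metabolic reaction layer
#'
#' Compounds sharing a reaction are linked as a clique (provenance
#' `knowledge_reaction`) and every (enzyme, compound) pair co-occurring in a
#' reaction is linked, connecting the metabolite layer to genes/proteins.
#' Non-measured compounds are included only when they share a reaction with
#' a measured one (first degree).
#'
#' @param metabolite_ids measured compound ids.
#' @param reactions data.frame (reaction_id, compounds, enzymes) with
#'   `;`-separated id lists.
#' @param enzyme_layer layer of the enzyme nodes.
#' @return a `mon`.
#' @export
reaction_layer <- function(metabolite_ids, reactions,
                           enzyme_layer = "protein") {
  reactions <- as.data.frame(reactions, stringsAsFactors = FALSE)
  stopifnot(all(c("reaction_id", "compounds") %in% names(reactions)))
  metabolite_ids <- unique(as.character(metabolite_ids))
  comp_nodes <- character(); enz_nodes <- character()
  edges <- list()
  for (r in seq_len(nrow(reactions))) {
    comps <- strsplit(reactions$compounds[r], ";", fixed = TRUE)[[1]]
    comps <- comps[nzchar(comps)]
    enzymes <- if (!is.null(reactions$enzymes))
      strsplit(reactions$enzymes[r], ";", fixed = TRUE)[[1]] else character()
    enzymes <- enzymes[nzchar(enzymes)]
    if (!any(comps %in% metabolite_ids)) next  # reaction unseen in the data
    comp_nodes <- c(comp_nodes, comps)
    enz_nodes <- c(enz_nodes, enzymes)
    if (length(comps) >= 2) {
      pr <- t(combn(comps, 2))
      edges[[length(edges) + 1L]] <-
        data.frame(from = pr[, 1], to = pr[, 2],
                   provenance = "knowledge_reaction",
                   stringsAsFactors = FALSE)
    }
    if (length(enzymes) && length(comps))
      edges[[length(edges) + 1L]] <-
        data.frame(from = rep(enzymes, each = length(comps)),
                   to = rep(comps, times = length(enzymes)),
                   provenance = "knowledge_reaction",
                   stringsAsFactors = FALSE)
  }
  comp_nodes <- unique(comp_nodes); enz_nodes <- unique(enz_nodes)
  nodes <- rbind(
    data.frame(id = comp_nodes,
               layer = rep("metabolite", length(comp_nodes)),
               measured = comp_nodes %in% metabolite_ids,
               stringsAsFactors = FALSE),
    data.frame(id = enz_nodes,
               layer = rep(enzyme_layer, length(enz_nodes)),
               measured = rep(FALSE, length(enz_nodes)),
               stringsAsFactors = FALSE))
  mon(nodes, if (length(edges)) do.call(rbind, edges) else NULL,
      name = "reactions")
}

#' Cross-layer identifier links (protein-coding, TF-target)
#'
#' One undirected edge per mapping row with provenance `coding` or
#' `tf_target`; the regulatory role of the first id is retained in the
#' `source_role` edge attribute. Duplicate rows are deduplicated.
#'
#' @param map_table data.frame (id_a, id_b, relation) with relation in
#'   `coding`, `tf_target`.
#' @return data.frame of edges suitable for [mon()] /
#'   [merge_networks()] via [edges_as_network()].
#' @export
cross_link_ids <- function(map_table) {
  map_table <- as.data.frame(map_table, stringsAsFactors = FALSE)
  if (nrow(map_table) == 0L)
    return(data.frame(from = character(), to = character(),
                      provenance = character(), weight = numeric(),
                      source_role = character(), stringsAsFactors = FALSE))
  stopifnot(all(c("id_a", "id_b", "relation") %in% names(map_table)))
  bad <- setdiff(unique(map_table$relation), c("coding", "tf_target"))
  if (length(bad)) stop("unknown relation(s): ", paste(bad, collapse = ", "))
  d <- data.frame(from = map_table$id_a, to = map_table$id_b,
                  provenance = map_table$relation, weight = 1,
                  source_role = map_table$id_a, stringsAsFactors = FALSE)
  d[!duplicated(d[, c("from", "to", "provenance")]), , drop = FALSE]
}

#' Wrap an edge table and endpoint metadata into a network
#'
#' Endpoints not described in `known_nodes` are added as unmeasured nodes of
#' `default_layer`.
#'
#' @param edges data.frame (from, to, provenance, ...).
#' @param known_nodes data.frame of node records for known endpoints.
#' @param default_layer layer for endpoints absent from `known_nodes`.
#' @param name network name.
#' @return a `mon`.
#' @export
edges_as_network <- function(edges, known_nodes = NULL,
                             default_layer = "gene", name = "links") {
  ids <- unique(c(edges$from, edges$to))
  if (is.null(known_nodes)) {
    nodes <- data.frame(id = ids, layer = default_layer, measured = FALSE,
                        stringsAsFactors = FALSE)
  } else {
    extra <- setdiff(ids, known_nodes$id)
    nodes <- rbind(known_nodes[known_nodes$id %in% ids,
                               intersect(names(known_nodes),
                                         c("id", "layer", "measured",
                                           "cluster", "label")),
                               drop = FALSE],
                   if (length(extra))
                     data.frame(id = extra, layer = default_layer,
                                measured = FALSE, stringsAsFactors = FALSE))
  }
  mon(nodes, edges, name = name)
}

#' Rank-correlation cross-layer links
#'
#' Links every cross-block feature pair whose Spearman correlation across
#' the shared samples/grid reaches `rho_min` in absolute value, with the
#' absolute correlation as edge weight.
#'
#' @param blockA,blockB features x observations matrices sharing columns.
#' @param rho_min minimum `|rho|` (the stringent 0.99 default follows usage
#'   with densely sampled modelled profiles).
#' @param method correlation method.
#' @return data.frame (from, to, provenance = "correlation", weight).
#' @export
correlation_link <- function(blockA, blockB, rho_min = 0.99,
                             method = "spearman") {
  stopifnot(ncol(blockA) == ncol(blockB))
  r <- cor(t(blockA), t(blockB), method = method)
  hit <- which(abs(r) >= rho_min, arr.ind = TRUE)
  d <- data.frame(from = rownames(blockA)[hit[, 1]],
                  to = rownames(blockB)[hit[, 2]],
                  provenance = rep("correlation", nrow(hit)),
                  weight = abs(r[hit]), stringsAsFactors = FALSE)
  d[d$from != d$to, , drop = FALSE]
}

#' Compositionally aware correlation of count data (SparCC-style)
#'
#' Estimates correlations between the latent basis abundances underlying a
#' compositional count table from the log-ratio variances
#' `t_ij = var(log(x_i / x_j))`: under sparsity of true correlations, the
#' component variances solve the linear system `T_i = (D - 2) w_i^2 +
#' sum_j w_j^2`, and the correlation is
#' `rho_ij = (w_i^2 + w_j^2 - t_ij) / (2 w_i w_j)`, clipped to [-1, 1].
#' This is the single-pass basis estimate, without iterative exclusion of
#' strongly correlated pairs.
#'
#' @param counts samples x taxa count matrix (a pseudocount of 1 is added
#'   before forming relative abundances).
#' @param rho_min minimum `|rho|` for an edge.
#' @return list with `rho` (taxa x taxa correlation matrix) and `edges`
#'   (data.frame from, to, provenance = "correlation", weight).
#' @export
sparcc_correlation <- function(counts, rho_min = 0.3) {
  counts <- as.matrix(counts)
  D <- ncol(counts)
  if (D < 4) stop("need at least 4 taxa (variance system underdetermined)")
  if (is.null(colnames(counts))) colnames(counts) <- paste0("t", seq_len(D))
  frac <- (counts + 1) / rowSums(counts + 1)
  lf <- log(frac)
  # t_ij = var(log x_i - log x_j)
  v <- apply(lf, 2, var)
  cv <- cov(lf)
  tmat <- outer(v, v, `+`) - 2 * cv
  diag(tmat) <- 0
  Ti <- rowSums(tmat)
  total <- sum(Ti) / (2 * (D - 1))
  w2 <- (Ti - total) / (D - 2)
  w2 <- pmax(w2, 1e-8)
  w <- sqrt(w2)
  rho <- (outer(w2, w2, `+`) - tmat) / (2 * outer(w, w))
  rho <- pmin(pmax(rho, -1), 1)
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(counts), colnames(counts))
  hit <- which(abs(rho) >= rho_min & upper.tri(rho), arr.ind = TRUE)
  edges <- data.frame(from = colnames(counts)[hit[, 1]],
                      to = colnames(counts)[hit[, 2]],
                      provenance = rep("correlation", nrow(hit)),
                      weight = abs(rho[hit]), stringsAsFactors = FALSE)
  list(rho = rho, edges = edges)
}

#' Assemble the entire and per-cluster multi-omics networks
#'
#' The entire network merges all layers and cross-links and stamps measured
#' nodes with their kinetic-cluster label. Per-cluster networks are rebuilt
#' from scratch on each cluster's measured features by calling
#' `build_fun` again on that subset (so inference is re-run and knowledge
#' extension re-applied per cluster, and shared knowledge nodes may appear
#' in several cluster networks). Features without a cluster label are placed
#' in the entire network only, with a warning.
#'
#' @param build_fun function(measured_ids) returning a merged `mon` for
#'   that subset of measured features.
#' @param clustering named cluster labels for measured features (a
#'   `kinetic_clustering` or a named vector).
#' @param all_features measured feature ids for the entire network (default:
#'   the names of the labels).
#' @return list with `entire` (a `mon`) and `per_cluster` (named list of
#'   `mon`).
#' @export
assemble <- function(build_fun, clustering, all_features = NULL) {
  labels <- if (inherits(clustering, "kinetic_clustering"))
    clustering$labels else clustering
  stopifnot(!is.null(names(labels)))
  if (is.null(all_features)) all_features <- names(labels)
  unlabeled <- setdiff(all_features, names(labels))
  if (length(unlabeled))
    warning(length(unlabeled),
            " feature(s) without a cluster label are in the entire network only")
  entire <- build_fun(all_features)
  idx <- match(entire$nodes$id, names(labels))
  stamped <- !is.na(idx) & entire$nodes$measured
  entire$nodes$cluster[stamped] <- as.character(labels[idx[stamped]])
  per <- lapply(split(names(labels), labels), function(ids) {
    net <- build_fun(ids)
    idx <- match(net$nodes$id, names(labels))
    st <- !is.na(idx) & net$nodes$measured
    net$nodes$cluster[st] <- as.character(labels[idx[st]])
    net
  })
  list(entire = entire, per_cluster = per)
}
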