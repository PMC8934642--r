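#' Cluster profiles by their pattern of consecutive differences
#'
#' Each feature is mapped to the sign pattern of the consecutive differences
#' of its fitted profile, one symbol per grid interval in {-, 0, +}; each
#' distinct pattern forms a cluster. Differences smaller in magnitude than
#' `eps_frac` of the profile's range count as 0, so the labelling is
#' invariant under positive affine transforms of a profile.
#'
#' @param mset a [model_profiles()] result (kept features are clustered).
#' @param eps_frac zero-band width as a fraction of each profile's range.
#' @return object of class `kinetic_clustering`: list with `labels` (named
#'   integer vector), `k`, `silhouette` (NA unless >= 2 clusters and >= 3
#'   features), `method = "pattern"`, `patterns` (the symbol strings).
#' @export
pattern_cluster <- function(mset, eps_frac = 0.01) {
  stopifnot(inherits(mset, "modeled_profiles"))
  m <- mset$fitted[mset$kept, , drop = FALSE]
  if (ncol(m) < 2L) stop("need at least 2 grid points")
  pats <- apply(m, 1, function(y) {
    d <- diff(y)
    eps <- eps_frac * diff(range(y))
    paste(ifelse(abs(d) <= eps, "0", ifelse(d > 0, "+", "-")),
          collapse = "")
  })
  ulev <- sort(unique(pats))
  labels <- setNames(match(pats, ulev), rownames(m))
  sil <- NA_real_
  if (length(ulev) >= 2L && nrow(m) >= 3L) {
    sm <- t(scale(t(m)))
    ok <- apply(m, 1, sd) > 0
    if (sum(ok) >= 3L && length(unique(labels[ok])) >= 2L)
      sil <- silhouette_score(sm[ok, , drop = FALSE], labels[ok])
  }
  structure(list(labels = labels, k = length(ulev), silhouette = sil,
                 method = "pattern",
                 patterns = setNames(pats, rownames(m))),
            class = "kinetic_clustering")
}

#' @export
print.kinetic_clustering <- function(x, ...) {
  cat(sprintf("<kinetic_clustering> method=%s k=%d silhouette=%s, %d features\n",
              x$method, x$k,
              ifelse(is.na(x$silhouette), "NA", sprintf("%.3f", x$silhouette)),
              length(x$labels)))
  invisible(x)
}

# consensus-score alternating least squares for one multi-block PLS
# component. blocks: list of grid x features matrices (observations = grid).
mbpls_component <- function(blocks, tol = 1e-9, max_iter = 5000) {
  # deterministic init: leading left singular vector of the concatenated
  # blocks, sign fixed so the largest-magnitude entry is positive
  conc <- do.call(cbind, blocks)
  if (all(abs(conc) < 1e-12)) stop("all blocks fully deflated")
  tcons <- svd(conc, nu = 1, nv = 0)$u[, 1]
  if (tcons[which.max(abs(tcons))] < 0) tcons <- -tcons
  tcons <- tcons / sqrt(sum(tcons^2))
  for (it in seq_len(max_iter)) {
    w <- lapply(blocks, function(X) {
      wb <- crossprod(X, tcons)
      nb <- sqrt(sum(wb^2))
      if (nb == 0) wb else wb / nb
    })
    tb <- mapply(function(X, wb) X %*% wb, blocks, w, SIMPLIFY = FALSE)
    tnew <- Reduce(`+`, tb) / length(tb)
    nn <- sqrt(sum(tnew^2))
    if (nn == 0) stop("degenerate component: zero consensus score")
    tnew <- tnew / nn
    if (sum(abs(tnew - tcons)) < tol || sum(abs(tnew + tcons)) < tol) {
      tcons <- tnew
      if (tcons[which.max(abs(tcons))] < 0) {
        tcons <- -tcons
        w <- lapply(w, function(wb) -wb)
      }
      return(list(score = as.numeric(tcons), weights = w, iter = it))
    }
    tcons <- tnew
  }
  stop("block-PLS component did not converge after ", max_iter, " iterations")
}

#' Cluster features by multi-block PLS latent components
#'
#' Computes `ncomp` successive latent components that maximize the summed
#' covariance between each block's score and a consensus score (alternating
#' least squares with deflation), with the shared time grid as the
#' observation dimension. Each feature is assigned to the component on which
#' it loads most strongly, split by loading sign, giving at most `2 * ncomp`
#' clusters: cluster `2c-1` is component `c` positive, `2c` negative.
#'
#' @param blocks list of standardized profile matrices (features x grid, as
#'   from [scale_profiles()]), sharing the grid.
#' @param ncomp number of latent components.
#' @return `kinetic_clustering` with additional fields `loadings` (feature x
#'   component matrix per block), `scores` (grid x component consensus
#'   scores), `ncomp`.
#' @export
block_pls_cluster <- function(blocks, ncomp = 2) {
  if (inherits(blocks, "matrix")) blocks <- list(blocks)
  stopifnot(length(blocks) >= 1, ncomp >= 1)
  glen <- unique(vapply(blocks, ncol, 0L))
  if (length(glen) != 1L) stop("blocks must share the time grid")
  if (is.null(names(blocks))) names(blocks) <- paste0("block", seq_along(blocks))
  # observations = grid points, variables = features
  X <- lapply(blocks, function(m) t(m))
  loadings <- lapply(X, function(x)
    matrix(0, ncol(x), ncomp, dimnames = list(colnames(x), NULL)))
  scores <- matrix(0, glen, ncomp)
  for (h in seq_len(ncomp)) {
    cmp <- tryCatch(mbpls_component(X),
                    error = function(e)
                      stop("component ", h, ": ", conditionMessage(e)))
    for (b in seq_along(X)) {
      loadings[[b]][, h] <- cmp$weights[[b]]
      # deflate each block on the consensus score
      proj <- cmp$score %*% crossprod(cmp$score, X[[b]])
      X[[b]] <- X[[b]] - proj
    }
    scores[, h] <- cmp$score
  }
  all_load <- do.call(rbind, loadings)
  labels <- assign_from_loadings(all_load)
  feat <- unlist(lapply(blocks, rownames), use.names = FALSE)
  labels <- setNames(labels, feat)
  prof <- do.call(rbind, blocks)
  sil <- if (length(unique(labels)) >= 2L)
    silhouette_score(prof, labels) else NA_real_
  structure(list(labels = labels, k = length(unique(labels)),
                 silhouette = sil, method = "block_pls",
                 loadings = loadings, scores = scores, ncomp = ncomp),
            class = "kinetic_clustering")
}

assign_from_loadings <- function(load_mat) {
  comp <- apply(abs(load_mat), 1, which.max)
  sgn <- vapply(seq_len(nrow(load_mat)),
                function(i) sign(load_mat[i, comp[i]]), 0)
  as.integer(2L * (comp - 1L) + ifelse(sgn >= 0, 1L, 2L))
}

#' Average silhouette coefficient under correlation distance
#'
#' Standard silhouette `s(i) = (b - a) / max(a, b)` averaged over features,
#' with the distance between two profiles defined as one minus their Pearson
#' correlation (profiles cluster by shape, not magnitude). Features in
#' singleton clusters contribute 0.
#'
#' @param profiles features x grid matrix of (standardized) profiles.
#' @param labels integer cluster labels, one per row of `profiles`.
#' @return average silhouette in [-1, 1].
#' @export
silhouette_score <- function(profiles, labels) {
  stopifnot(nrow(profiles) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("silhouette requires at least 2 clusters")
  d <- 1 - cor(t(profiles))
  d[!is.finite(d)] <- 2  # degenerate constant rows: maximal distance
  diag(d) <- 0
  sil <- cluster::silhouette(as.integer(factor(labels)), dmatrix = d)
  mean(sil[, "sil_width"])
}

#' Select the number of clusters by maximizing the silhouette
#'
#' Runs [block_pls_cluster()] over a grid of component counts and returns
#' the clustering with the highest average silhouette coefficient, breaking
#' ties toward fewer clusters.
#'
#' @param blocks list of standardized profile matrices (features x grid).
#' @param ncomp_grid candidate numbers of latent components.
#' @return the winning `kinetic_clustering`, with a `candidates` data.frame
#'   (ncomp, k, silhouette) attached.
#' @export
choose_k <- function(blocks, ncomp_grid = 1:3) {
  stopifnot(length(ncomp_grid) >= 1)
  fits <- lapply(ncomp_grid, function(nc) block_pls_cluster(blocks, nc))
  cand <- data.frame(ncomp = ncomp_grid,
                     k = vapply(fits, `[[`, 0L, "k"),
                     silhouette = vapply(fits, `[[`, 0, "silhouette"))
  if (length(fits) == 1L) {
    best <- 1L
  } else {
    ord <- order(-cand$silhouette, cand$k, cand$ncomp)
    best <- ord[1L]
  }
  out <- fits[[best]]
  out$candidates <- cand
  out
}

#' Sparse per-cluster signatures by loading thresholding
#'
#' Within each latent component, retains per block the `keepX` features of
#' largest absolute loading, soft-thresholds the remaining loadings to zero,
#' recomputes cluster assignment, and reports the retained features per
#' cluster.
#'
#' @param clustering a `kinetic_clustering` from [block_pls_cluster()].
#' @param keepX number of features retained per block and component (a
#'   single value or one per component).
#' @return the clustering with `signature` (list cluster -> feature ids) and
#'   `sparse_labels` added.
#' @export
sparse_signature <- function(clustering, keepX) {
  stopifnot(inherits(clustering, "kinetic_clustering"),
            clustering$method == "block_pls")
  ncomp <- clustering$ncomp
  keepX <- rep_len(keepX, ncomp)
  sload <- clustering$loadings
  for (b in seq_along(sload)) {
    L <- sload[[b]]
    for (h in seq_len(ncomp)) {
      a <- abs(L[, h])
      nkeep <- min(keepX[h], sum(a > 0))
      thr <- if (nkeep > 0) sort(a, decreasing = TRUE)[nkeep] else Inf
      soft <- sign(L[, h]) * pmax(a - max(a[a < thr], 0), 0)
      soft[a < thr] <- 0
      L[, h] <- soft
    }
    sload[[b]] <- L
  }
  all_load <- do.call(rbind, sload)
  retained <- rowSums(abs(all_load)) > 0
  lab <- assign_from_loadings(all_load)
  lab <- setNames(lab, rownames(all_load))
  sig <- split(names(lab)[retained], lab[retained])
  clustering$signature <- sig
  clustering$sparse_labels <- lab
  clustering$sparse_loadings <- sload
  clustering
}

#' Write a cluster-assignment table
#'
#' @param clustering a `kinetic_clustering`.
#' @param path output CSV (feature, cluster, in_signature).
#' @param blocks optional named list of profile matrices to record the block
#'   of each feature.
#' @export
write_clusters <- function(clustering, path, blocks = NULL) {
  feat <- names(clustering$labels)
  blk <- NA_character_
  if (!is.null(blocks)) {
    map <- rep(names(blocks), vapply(blocks, nrow, 0L))
    names(map) <- unlist(lapply(blocks, rownames), use.names = FALSE)
    blk <- unname(map[feat])
  }
  insig <- if (!is.null(clustering$signature))
    feat %in% unlist(clustering$signature) else NA
  d <- data.frame(feature = feat, block = blk,
                  cluster = unname(clustering$labels),
                  in_signature = insig, stringsAsFactors = FALSE)
  write.table(d, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
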