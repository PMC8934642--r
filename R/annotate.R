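#' Over-representation analysis of a query set against annotation terms
#'
#' For each term, computes the upper-tail hypergeometric probability of
#' observing at least the seen overlap between the query and the term's
#' members, given the universe. Term member lists are intersected with the
#' universe first. P-values are adjusted per ontology/source by
#' Benjamini-Hochberg; a term is significant when its adjusted p-value is
#' below `alpha`.
#'
#' @param query character vector of feature ids, a subset of `universe`.
#' @param ann an [annotation_set()].
#' @param universe character vector of background feature ids.
#' @param alpha significance cutoff on the adjusted p-value.
#' @return object of class `enrichment_result`: data.frame with columns
#'   term, source, description, overlap, query_size, term_size,
#'   universe_size, p, adj_p, significant; attributes `alpha`,
#'   `adjust_method = "BH"`, `universe`.
#' @export
ora <- function(query, ann, universe, alpha = 0.05) {
  stopifnot(inherits(ann, "annotation_set"))
  query <- unique(as.character(query))
  universe <- unique(as.character(universe))
  if (!length(query)) stop("empty query")
  if (!length(universe)) stop("empty universe")
  extra <- setdiff(query, universe)
  if (length(extra))
    stop("query ids outside the universe: ",
         paste(head(extra), collapse = ", "))
  N <- length(universe); q <- length(query)
  rows <- lapply(seq_along(ann$members), function(i) {
    members <- intersect(ann$members[[i]], universe)
    m <- length(members)
    k <- length(intersect(members, query))
    # P(X >= k) with X ~ Hypergeom(N, m, q)
    p <- if (k == 0) 1 else phyper(k - 1, m, N - m, q, lower.tail = FALSE)
    data.frame(term = ann$meta$term[i], source = ann$meta$source[i],
               description = ann$meta$description[i],
               overlap = k, query_size = q, term_size = m,
               universe_size = N, p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$adj_p <- NA_real_
  for (s in unique(res$source)) {
    sel <- res$source == s
    res$adj_p[sel] <- p.adjust(res$p[sel], method = "BH")
  }
  res$significant <- res$adj_p < alpha
  structure(res, class = c("enrichment_result", "data.frame"),
            alpha = alpha, adjust_method = "BH", universe = universe)
}

#' Fisher's combined probability test
#'
#' Combines independent p-values via `X2 = -2 * sum(log(p))`, referred to a
#' chi-square distribution with `2k` degrees of freedom.
#'
#' @param pvals numeric p-values in (0, 1]; zeros are an error (the caller
#'   should clamp).
#' @return combined upper-tail probability.
#' @export
fisher_combine <- function(pvals) {
  pvals <- as.numeric(pvals)
  if (!length(pvals)) stop("no p-values to combine")
  if (any(pvals <= 0)) stop("p-values must be > 0 (log undefined at 0)")
  if (any(pvals > 1)) stop("p-values must be <= 1")
  x2 <- -2 * sum(log(pvals))
  pchisq(x2, df = 2 * length(pvals), lower.tail = FALSE)
}

#' Inject significant terms as an annotation-term layer
#'
#' Adds one node per significant term of the requested layer and connects
#' it, with annotation-provenance edges, to every network node among the
#' term's members (measured or extended). Absent members are skipped.
#'
#' @param net a `mon`.
#' @param result an [ora()] result.
#' @param ann the [annotation_set()] the result came from.
#' @param layer `"go_term"` or `"disease"`.
#' @return the augmented `mon`.
#' @export
add_term_layer <- function(net, result, ann, layer = c("go_term", "disease")) {
  layer <- match.arg(layer)
  stopifnot(inherits(net, "mon"), inherits(result, "enrichment_result"),
            inherits(ann, "annotation_set"))
  sig <- result$term[result$significant]
  if (!length(sig)) return(net)
  desc <- setNames(result$description, result$term)
  nodes <- data.frame(id = sig, layer = layer, measured = FALSE,
                      label = unname(desc[sig]), stringsAsFactors = FALSE)
  edges <- do.call(rbind, lapply(sig, function(tid) {
    present <- intersect(ann$members[[tid]], net$nodes$id)
    if (!length(present)) return(NULL)
    data.frame(from = tid, to = present, provenance = "annotation",
               stringsAsFactors = FALSE)
  }))
  term_net <- mon(nodes, edges = NULL, name = "terms")
  merged <- merge_networks(list(net, term_net), name = net$name)
  if (!is.null(edges)) {
    all_edges <- rbind(merged$edges,
                       data.frame(from = edges$from, to = edges$to,
                                  provenance = edges$provenance, weight = 1,
                                  source_role = NA_character_,
                                  stringsAsFactors = FALSE))
    merged <- mon(merged$nodes, all_edges, name = merged$name)
  }
  merged
}

#' Compare per-cluster and entire-set enrichment
#'
#' Summarizes, per ontology/source: the number of significant terms in each
#' cluster and in the entire-set analysis, all pairwise intersections of
#' cluster term sets, terms unique to single clusters, and p-value
#' distribution summaries.
#'
#' @param cluster_results named list of [ora()] results, one per cluster.
#' @param entire_result [ora()] result on the full molecule set.
#' @return list with `counts` (data.frame source x analysis), `pairwise`
#'   (data.frame cluster_a, cluster_b, source, n_shared), `unique_terms`
#'   (list), `pvalue_summary` (data.frame of quartiles per analysis).
#' @export
compare_cluster_vs_entire <- function(cluster_results, entire_result) {
  stopifnot(length(cluster_results) >= 1)
  if (is.null(names(cluster_results)))
    names(cluster_results) <- paste0("cluster", seq_along(cluster_results))
  all_res <- c(cluster_results, list(entire = entire_result))
  sig_terms <- lapply(all_res, function(r)
    split(r$term[r$significant], r$source[r$significant]))
  sources <- unique(unlist(lapply(all_res, function(r) unique(r$source))))
  counts <- do.call(rbind, lapply(names(all_res), function(nm) {
    data.frame(analysis = nm, source = sources,
               n_significant = vapply(sources, function(s)
                 length(sig_terms[[nm]][[s]]), 0L),
               stringsAsFactors = FALSE)
  }))
  cl <- names(cluster_results)
  pairwise <- NULL
  if (length(cl) >= 2) {
    pr <- t(combn(cl, 2))
    pairwise <- do.call(rbind, lapply(sources, function(s) {
      data.frame(cluster_a = pr[, 1], cluster_b = pr[, 2], source = s,
                 n_shared = vapply(seq_len(nrow(pr)), function(i)
                   length(intersect(sig_terms[[pr[i, 1]]][[s]],
                                    sig_terms[[pr[i, 2]]][[s]])), 0L),
                 stringsAsFactors = FALSE)
    }))
  }
  unique_terms <- lapply(cl, function(a) {
    others <- unlist(sig_terms[setdiff(cl, a)], use.names = FALSE)
    setdiff(unlist(sig_terms[[a]], use.names = FALSE), others)
  })
  names(unique_terms) <- cl
  pvalue_summary <- do.call(rbind, lapply(names(all_res), function(nm) {
    p <- all_res[[nm]]$p
    data.frame(analysis = nm, q25 = quantile(p, .25), median = median(p),
               q75 = quantile(p, .75), stringsAsFactors = FALSE)
  }))
  rownames(pvalue_summary) <- NULL
  list(counts = counts, pairwise = pairwise, unique_terms = unique_terms,
       pvalue_summary = pvalue_summary)
}
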