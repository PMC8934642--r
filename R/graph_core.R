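#' @importFrom stats var sd cor cov na.omit quantile setNames median coef lm
#' @importFrom utils read.delim write.table count.fields head tail combn
#'   packageVersion
NULL

NODE_LAYERS <- c("gene", "tf", "protein", "metabolite", "otu", "clinical",
                 "go_term", "disease")
EDGE_PROVENANCES <- c("inferred_mi", "knowledge_ppi", "knowledge_reaction",
                      "coding", "tf_target", "correlation", "annotation")
TERM_LAYERS <- c("go_term", "disease")

#' Construct a typed multi-layer omics network
#'
#' A `mon` object is an undirected multi-layer graph. Nodes represent
#' molecules (genes, TFs, proteins, metabolites, OTUs, clinical variables) or
#' annotation terms (GO, disease); edges carry a provenance tag recording how
#' the interaction was obtained (inference, curated database, reaction,
#' cross-link, correlation, annotation) and a non-negative weight.
#'
#' Term-layer nodes (`go_term`, `disease`) are never measured and carry no
#' kinetic-cluster label. Edges are undirected and unique per (node pair,
#' provenance); the regulatory direction of TF-target rows, when known, is
#' retained in the `source_role` edge attribute rather than as an arrow.
#'
#' @param nodes data.frame with columns `id` (unique character), and
#'   optionally `layer` (one of the supported layers), `measured` (logical),
#'   `cluster` (kinetic-cluster label, character or integer; may encode
#'   multiple labels separated by `;`), `label` (display string).
#' @param edges data.frame with columns `from`, `to`, and optionally
#'   `provenance`, `weight`, `source_role`. May be `NULL` for an edgeless
#'   graph.
#' @param name network name.
#' @return An object of class `mon`: a list with `nodes`, `edges`, `name`.
#' @export
mon <- function(nodes, edges = NULL, name = "network") {
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  if (!"id" %in% names(nodes)) stop("nodes must have an 'id' column")
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id))
    stop("duplicate node ids: ",
         paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", "))
  nn <- nrow(nodes)
  if (is.null(nodes$layer)) nodes$layer <- rep("gene", nn)
  nodes$layer <- as.character(nodes$layer)
  bad <- setdiff(unique(nodes$layer), NODE_LAYERS)
  if (length(bad)) stop("unknown layer(s): ", paste(bad, collapse = ", "))
  if (is.null(nodes$measured)) nodes$measured <- rep(TRUE, nn)
  nodes$measured <- as.logical(nodes$measured)
  if (is.null(nodes$cluster)) nodes$cluster <- rep(NA_character_, nn)
  nodes$cluster <- as.character(nodes$cluster)
  if (is.null(nodes$label)) nodes$label <- rep(NA_character_, nn)
  nodes$label <- as.character(nodes$label)
  term <- nodes$layer %in% TERM_LAYERS
  nodes$measured[term] <- FALSE
  nodes$cluster[term] <- NA_character_
  nodes <- nodes[, c("id", "layer", "measured", "cluster", "label")]

  if (is.null(edges) || nrow(as.data.frame(edges)) == 0L) {
    edges <- data.frame(from = character(), to = character(),
                        provenance = character(), weight = numeric(),
                        source_role = character(), stringsAsFactors = FALSE)
  } else {
    edges <- as.data.frame(edges, stringsAsFactors = FALSE)
    if (!all(c("from", "to") %in% names(edges)))
      stop("edges must have 'from' and 'to' columns")
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (is.null(edges$provenance)) edges$provenance <- "knowledge_ppi"
    edges$provenance <- as.character(edges$provenance)
    bad <- setdiff(unique(edges$provenance), EDGE_PROVENANCES)
    if (length(bad)) stop("unknown provenance(s): ", paste(bad, collapse = ", "))
    if (is.null(edges$weight)) edges$weight <- 1
    edges$weight <- as.numeric(edges$weight)
    if (any(!is.finite(edges$weight)) || any(edges$weight < 0))
      stop("edge weights must be finite and non-negative")
    if (is.null(edges$source_role)) edges$source_role <- NA_character_
    edges$source_role <- as.character(edges$source_role)
    if (any(edges$from == edges$to)) stop("self-edges are not allowed")
    miss <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
    if (length(miss))
      stop("edge endpoints not in node set: ", paste(miss, collapse = ", "))
    # canonical unordered pair, then one record per (pair, provenance)
    swap <- edges$from > edges$to
    tmp <- edges$from[swap]; edges$from[swap] <- edges$to[swap]
    edges$to[swap] <- tmp
    key <- paste(edges$from, edges$to, edges$provenance, sep = "\r")
    if (anyDuplicated(key)) {
      ord <- order(key, -edges$weight)
      edges <- edges[ord, , drop = FALSE]
      edges <- edges[!duplicated(key[ord]), , drop = FALSE]
    }
    edges <- edges[, c("from", "to", "provenance", "weight", "source_role")]
  }
  rownames(nodes) <- NULL
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges, name = as.character(name)),
            class = "mon")
}

#' @export
print.mon <- function(x, ...) {
  cat(sprintf("<mon> %s: %d nodes, %d edges\n",
              x$name, nrow(x$nodes), nrow(x$edges)))
  if (nrow(x$nodes)) {
    tab <- table(x$nodes$layer)
    cat("  layers:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
        "\n")
  }
  invisible(x)
}

node_ids <- function(net) net$nodes$id

#' Split a (possibly multi-valued) cluster field into labels
#' @param x character vector of cluster fields (labels joined by `;`).
#' @return list of character label vectors (empty for NA).
#' @export
cluster_labels <- function(x) {
  lapply(x, function(v) if (is.na(v)) character() else strsplit(v, ";",
                                                               fixed = TRUE)[[1]])
}

join_clusters <- function(a, b) {
  labs <- sort(unique(c(cluster_labels(a)[[1]], cluster_labels(b)[[1]])))
  if (!length(labs)) NA_character_ else paste(labs, collapse = ";")
}

#' Merge multi-layer networks into one
#'
#' Node sets are unioned by id. Attribute conflicts resolve by rule:
#' `measured = TRUE` wins; differing kinetic-cluster labels are kept as the
#' union (joined by `;`); the first non-missing display label wins. The same
#' id appearing with two different layers is an error. Edges are unioned
#' keyed by (unordered pair, provenance), keeping the maximum weight.
#'
#' @param networks list of `mon` objects.
#' @param name name for the merged network.
#' @return merged `mon`.
#' @export
merge_networks <- function(networks, name = "merged") {
  stopifnot(length(networks) >= 1L)
  for (n in networks) stopifnot(inherits(n, "mon"))
  nodes <- do.call(rbind, lapply(networks, `[[`, "nodes"))
  edges <- do.call(rbind, lapply(networks, `[[`, "edges"))
  if (nrow(nodes)) {
    lay <- tapply(nodes$layer, nodes$id, function(v) length(unique(v)))
    bad <- names(lay)[lay > 1L]
    if (length(bad))
      stop("node id(s) with conflicting layers: ", paste(bad, collapse = ", "))
    parts <- split(nodes, nodes$id)
    nodes <- do.call(rbind, lapply(parts, function(d) {
      cl <- Reduce(join_clusters, d$cluster)
      lab <- d$label[!is.na(d$label)]
      data.frame(id = d$id[1L], layer = d$layer[1L],
                 measured = any(d$measured),
                 cluster = cl,
                 label = if (length(lab)) lab[1L] else NA_character_,
                 stringsAsFactors = FALSE)
    }))
    nodes <- nodes[order(nodes$id), , drop = FALSE]
  }
  mon(nodes, edges, name = name)
}

#' Induced sub-network on a node subset
#'
#' Keeps exactly the requested nodes and every edge with both endpoints in
#' the subset.
#'
#' @param net a `mon`.
#' @param ids character vector of node ids, all present in `net`.
#' @return `mon` restricted to `ids`.
#' @export
induced_subnetwork <- function(net, ids) {
  stopifnot(inherits(net, "mon"))
  ids <- unique(as.character(ids))
  miss <- setdiff(ids, net$nodes$id)
  if (length(miss)) stop("unknown node id(s): ", paste(miss, collapse = ", "))
  nodes <- net$nodes[net$nodes$id %in% ids, , drop = FALSE]
  keep <- net$edges$from %in% ids & net$edges$to %in% ids
  mon(nodes, net$edges[keep, , drop = FALSE], name = net$name)
}

#' Convert to an igraph object
#'
#' @param net a `mon`.
#' @param collapse collapse parallel (multi-provenance) edges to a single
#'   edge keeping the maximum weight. Required before propagation.
#' @return undirected `igraph` graph with node/edge attributes.
#' @export
mon_igraph <- function(net, collapse = FALSE) {
  stopifnot(inherits(net, "mon"))
  edges <- net$edges
  if (collapse && nrow(edges)) {
    key <- paste(edges$from, edges$to, sep = "\r")
    ord <- order(key, -edges$weight)
    edges <- edges[ord, , drop = FALSE]
    edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  }
  igraph::graph_from_data_frame(edges, directed = FALSE,
                                vertices = net$nodes)
}

#' Summary counts for a network
#'
#' @param net a `mon`.
#' @return list with node/edge totals, per-layer and per-provenance counts,
#'   number of connected components and number of isolated (degree-0) nodes.
#' @export
summarize_network <- function(net) {
  stopifnot(inherits(net, "mon"))
  n <- nrow(net$nodes)
  if (n == 0L) {
    return(list(n_nodes = 0L, n_edges = 0L,
                by_layer = integer(), by_provenance = integer(),
                n_components = 0L, n_isolated = 0L))
  }
  g <- mon_igraph(net)
  deg <- igraph::degree(g)
  list(n_nodes = n,
       n_edges = nrow(net$edges),
       by_layer = table(net$nodes$layer),
       by_provenance = table(net$edges$provenance),
       n_components = igraph::components(g)$no,
       n_isolated = sum(deg == 0L))
}

# ---- file I/O --------------------------------------------------------------

#' Read a network from a tab-separated edge table
#'
#' The table must have a header including `source` and `target` columns;
#' optional columns `provenance`, `weight` (or `score`, used as weight) and
#' `source_role` are honoured. Malformed rows (wrong field count,
#' non-numeric weight) raise an error naming the offending line.
#'
#' @param path TSV file path.
#' @param layer default layer for nodes created from the table.
#' @param measured default measured flag.
#' @param name network name.
#' @return a `mon`.
#' @export
read_edge_table <- function(path, layer = "gene", measured = TRUE,
                            name = basename(path)) {
  nf <- count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) < 1L) stop("empty edge table: ", path)
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("malformed row in %s at line %d: expected %d fields, found %d",
                 path, bad, nf[1L], nf[bad]))
  }
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("source", "target") %in% names(d)))
    stop("edge table must have 'source' and 'target' columns: ", path)
  w <- if (!is.null(d$weight)) d$weight else d$score
  if (!is.null(w)) {
    wn <- suppressWarnings(as.numeric(w))
    if (anyNA(wn) && !all(is.na(w))) {
      bad <- which(is.na(wn) & !is.na(w))[1L]
      stop(sprintf("malformed row in %s at line %d: non-numeric weight '%s'",
                   path, bad + 1L, w[bad]))
    }
  }
  ids <- unique(c(d$source, d$target))
  nodes <- data.frame(id = ids, layer = layer, measured = measured,
                      stringsAsFactors = FALSE)
  edges <- data.frame(from = d$source, to = d$target,
                      provenance = if (!is.null(d$provenance)) d$provenance
                      else "knowledge_ppi",
                      weight = if (!is.null(w)) as.numeric(w) else 1,
                      source_role = if (!is.null(d$source_role)) d$source_role
                      else NA_character_,
                      stringsAsFactors = FALSE)
  mon(nodes, edges, name = name)
}

#' Write a network as a SIF-like tab-separated edge list
#'
#' Isolated nodes are appended as single-column rows after the edge block is
#' not standard SIF; instead a companion node table is written when
#' `node_path` is given.
#'
#' @param net a `mon`.
#' @param path output TSV path (columns source, target, provenance, weight,
#'   source_role).
#' @param node_path optional path for the node attribute table.
#' @export
write_edge_table <- function(net, path, node_path = NULL) {
  stopifnot(inherits(net, "mon"))
  d <- net$edges
  names(d)[1:2] <- c("source", "target")
  write.table(format_num_df(d), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(node_path))
    write.table(format_num_df(net$nodes), node_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(path)
}

# fixed-format numeric columns so outputs are byte-stable across platforms
format_num_df <- function(d) {
  for (j in seq_along(d)) {
    if (is.numeric(d[[j]]) && !is.integer(d[[j]]))
      d[[j]] <- sprintf("%.12g", d[[j]])
  }
  d
}

#' Write a network to GraphML
#'
#' All node attributes (layer, measured, cluster, label) and edge attributes
#' (provenance, weight, source_role) are preserved; `read_graphml()` is the
#' inverse.
#'
#' @param net a `mon`.
#' @param path output file.
#' @export
write_graphml <- function(net, path) {
  stopifnot(inherits(net, "mon"))
  g <- mon_igraph(net)
  # igraph writes logical as numeric and NA strings literally; encode
  # explicitly so the round trip is lossless
  igraph::V(g)$measured <- as.integer(igraph::V(g)$measured)
  igraph::V(g)$cluster <- ifelse(is.na(igraph::V(g)$cluster), "",
                                 igraph::V(g)$cluster)
  igraph::V(g)$label <- ifelse(is.na(igraph::V(g)$label), "",
                               igraph::V(g)$label)
  if (igraph::ecount(g) > 0)
    igraph::E(g)$source_role <- ifelse(is.na(igraph::E(g)$source_role), "",
                                       igraph::E(g)$source_role)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a network written by [write_graphml()]
#' @param path GraphML file.
#' @param name network name.
#' @return a `mon`.
#' @export
read_graphml <- function(path, name = basename(path)) {
  g <- igraph::read_graph(path, format = "graphml")
  vd <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  nodes <- data.frame(id = vd$name, layer = vd$layer,
                      measured = as.logical(vd$measured),
                      cluster = ifelse(vd$cluster == "", NA_character_,
                                       vd$cluster),
                      label = ifelse(vd$label == "", NA_character_, vd$label),
                      stringsAsFactors = FALSE)
  if (nrow(ed)) {
    ed$source_role[ed$source_role == ""] <- NA_character_
    edges <- ed[, c("from", "to", "provenance", "weight", "source_role")]
  } else edges <- NULL
  mon(nodes, edges, name = name)
}

#' Construct an annotation set
#'
#' @param members named list mapping term id to a character vector of member
#'   feature ids (non-empty).
#' @param source ontology/source tag, recycled per term (e.g. "GO:BP",
#'   "disease").
#' @param description per-term description strings.
#' @return object of class `annotation_set`: list with `members` (named
#'   list) and `meta` (data.frame term, description, source).
#' @export
annotation_set <- function(members, source = "GO:BP",
                           description = names(members)) {
  stopifnot(is.list(members), length(members) > 0L)
  if (is.null(names(members)) || any(names(members) == ""))
    stop("terms must be named")
  if (anyDuplicated(names(members)))
    stop("duplicate term id(s): ",
         paste(unique(names(members)[duplicated(names(members))]),
               collapse = ", "))
  if (any(lengths(members) == 0L)) stop("term member lists must be non-empty")
  members <- lapply(members, function(m) unique(as.character(m)))
  meta <- data.frame(term = names(members),
                     description = rep_len(as.character(description),
                                           length(members)),
                     source = rep_len(as.character(source), length(members)),
                     stringsAsFactors = FALSE)
  structure(list(members = members, meta = meta), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d terms (%s), %d..%d members\n",
              length(x$members),
              paste(unique(x$meta$source), collapse = ","),
              min(lengths(x$members)), max(lengths(x$members))))
  invisible(x)
}

#' Read annotation sets from a GMT file
#'
#' One term per line: term id, description, then member ids, tab-separated.
#' Duplicate term ids are an error.
#'
#' @param path GMT file.
#' @param source ontology/source tag attached to every term.
#' @return an `annotation_set`.
#' @export
read_gmt <- function(path, source = "GO:BP") {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3L)
  if (length(short))
    stop(sprintf("malformed GMT line %d in %s: fewer than 3 fields",
                 short[1L], path))
  terms <- vapply(parts, `[[`, "", 1L)
  if (anyDuplicated(terms))
    stop("duplicate term in GMT: ",
         paste(unique(terms[duplicated(terms)]), collapse = ", "))
  members <- lapply(parts, function(p) p[-(1:2)])
  names(members) <- terms
  annotation_set(members, source = source,
                 description = vapply(parts, `[[`, "", 2L))
}

#' Write an annotation set to a GMT file
#' @param ann an `annotation_set`.
#' @param path output file.
#' @export
write_gmt <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  lines <- vapply(seq_along(ann$members), function(i) {
    paste(c(ann$meta$term[i], ann$meta$description[i], ann$members[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
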