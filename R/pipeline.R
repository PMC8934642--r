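PIPELINE_STAGES <- c("simulate", "filter", "model", "cluster", "build",
                     "annotate", "propagate")

#' Default pipeline configuration
#'
#' A single declarative configuration drives the whole pipeline; every
#' resolved value is echoed into each stage's provenance record, and each
#' stage is cached under a hash of its own parameters plus everything
#' upstream, so changing one stage's settings re-executes from that stage
#' onward only.
#'
#' The defaults run on the built-in synthetic fixture: 3 omics blocks
#' (transcript-like, protein-like, metabolite-like), 4 planted kinetic
#' clusters, 5 timepoints, 3 subjects, noise sd 0.2 on a log2 scale.
#' Fold-change thresholds mirror a transcript/protein split (2-fold for the
#' transcript block, 3-fold elsewhere).
#'
#' @param seed master seed for every stochastic step.
#' @return nested named list of class `run_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = as.integer(seed),
    simulate = list(n_clusters = 4, features_per_block = 20, n_blocks = 3,
                    timepoints = 5, subjects = 3, sigma = 0.2,
                    noise_features = 5),
    filter = list(fold_change = list(rna = 2, prot = 3, met = 3),
                  default_fold_change = 2),
    model = list(r2_floor = 0.1),
    cluster = list(ncomp_grid = c(1, 2, 3), keepX = 3),
    build = list(bins = NULL, epsilon = 0.15, score_min = NULL,
                 rho_min_cross = 0.99),
    annotate = list(alpha = 0.05, universe = "measured"),
    propagate = list(restart = 0.7, tol = 1e-10, k_mechanism = 25,
                     k_intersection = 10)
  ), class = "run_config")
}

config_hash <- function(x) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(as.character(jsonlite::toJSON(x, auto_unbox = TRUE,
                                           digits = NA)), tmp)
  unname(tools::md5sum(tmp))
}

stage_cached <- function(outdir, stage, hash) {
  f <- file.path(outdir, "cache", paste0(stage, ".rds"))
  h <- file.path(outdir, "cache", paste0(stage, ".hash"))
  if (file.exists(f) && file.exists(h) && readLines(h)[1] == hash)
    readRDS(f) else NULL
}

stage_store <- function(outdir, stage, hash, value, params) {
  dir.create(file.path(outdir, "cache"), recursive = TRUE,
             showWarnings = FALSE)
  saveRDS(value, file.path(outdir, "cache", paste0(stage, ".rds")))
  writeLines(hash, file.path(outdir, "cache", paste0(stage, ".hash")))
  prov <- list(stage = stage, hash = hash, params = params,
               package_version = as.character(utils::packageVersion("kinetnet")))
  jsonlite::write_json(prov,
                       file.path(outdir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  value
}

run_stage <- function(outdir, stage, hash, params, fn, verbose) {
  cached <- stage_cached(outdir, stage, hash)
  if (!is.null(cached)) {
    if (verbose) message(sprintf("[%s] cached", stage))
    return(cached)
  }
  t0 <- proc.time()[["elapsed"]]
  val <- fn()
  if (verbose)
    message(sprintf("[%s] done in %.1fs", stage,
                    proc.time()[["elapsed"]] - t0))
  stage_store(outdir, stage, hash, val, params)
}

fc_threshold_for <- function(cfg, block_name) {
  fc <- cfg$filter$fold_change
  if (!is.null(fc[[block_name]])) fc[[block_name]]
  else cfg$filter$default_fold_change
}

# prefix knowledge-table identifiers into the network namespace
prefix_knowledge <- function(kn) {
  if (!is.null(kn$ppi)) {
    kn$ppi$id_a <- prefix_ids(kn$ppi$id_a, "prot")
    kn$ppi$id_b <- prefix_ids(kn$ppi$id_b, "prot")
  }
  if (!is.null(kn$reactions)) {
    kn$reactions$compounds <- vapply(strsplit(kn$reactions$compounds, ";"),
                                     function(v) paste(prefix_ids(v, "met"),
                                                       collapse = ";"), "")
    kn$reactions$enzymes <- vapply(strsplit(kn$reactions$enzymes, ";"),
                                   function(v) paste(prefix_ids(v, "prot"),
                                                     collapse = ";"), "")
  }
  if (!is.null(kn$cross_links) && nrow(kn$cross_links)) {
    cl <- kn$cross_links
    coding <- cl$relation == "coding"
    cl$id_a[coding] <- prefix_ids(cl$id_a[coding], "rna")
    cl$id_b[coding] <- prefix_ids(cl$id_b[coding], "prot")
    cl$id_a[!coding] <- prefix_ids(cl$id_a[!coding], "prot")
    cl$id_b[!coding] <- prefix_ids(cl$id_b[!coding], "rna")
    kn$cross_links <- cl
  }
  kn
}

#' Run the full integration pipeline on the synthetic fixture
#'
#' Executes simulate, fold-change filter, time-course modelling plus noise
#' filter, multi-block clustering with silhouette-based component
#' selection, entire and per-cluster network assembly (mutual-information
#' inference with DPI pruning on the transcript block, knowledge PPI layer
#' with first-degree extension, reaction layer, cross-links),
#' over-representation analysis with term-layer injection, and the three
#' random-walk interpretation analyses. Every stage writes plain-text
#' artifacts plus a JSON provenance record into `outdir` and is cached, so
#' a rerun with an unchanged configuration reuses upstream results and a
#' rerun with the same configuration and seed reproduces the numeric
#' outputs byte for byte.
#'
#' @param config a [default_config()] list (possibly modified).
#' @param outdir output directory.
#' @param verbose log stage timings to stderr.
#' @param until last stage to execute (one of `simulate`, `filter`,
#'   `model`, `cluster`, `build`, `annotate`, `propagate`); later stages
#'   are skipped, which combined with caching gives stage-wise runs.
#' @return invisibly, a list with the per-stage results (`simulate`,
#'   `filter`, `model`, `cluster`, `build`, `annotate`, `propagate`, some
#'   `NULL` when `until` stops earlier) and `outdir`.
#' @export
run_pipeline <- function(config = default_config(), outdir = tempfile("run"),
                         verbose = TRUE, until = "propagate") {
  until <- match.arg(until, PIPELINE_STAGES)
  done <- function(stage)
    match(stage, PIPELINE_STAGES) >= match(until, PIPELINE_STAGES)
  result <- function(...) {
    out <- list(...)
    miss <- setdiff(c(PIPELINE_STAGES, "outdir"), names(out))
    out[miss] <- list(NULL)
    invisible(out)
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  config <- unclass(config)
  jsonlite::write_json(config, file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  seed <- config$seed
  hash <- config_hash(list(seed = seed, simulate = config$simulate))

  sim <- run_stage(outdir, "simulate", hash, config$simulate, function() {
    gb <- do.call(gen_blocks, c(config$simulate, list(seed = seed)))
    tr <- gb$truth$features
    kn <- gen_knowledge(gene_ids = tr$feature[tr$block == "rna"],
                        protein_ids = tr$feature[tr$block == "prot"],
                        metabolite_ids = tr$feature[tr$block == "met"],
                        seed = seed)
    fc <- setNames(tr$cluster, prefix_ids(tr$feature, tr$block))
    ann <- gen_annotations(fc, seed = seed)
    write_gmt(ann$annotation, file.path(outdir, "annotations.gmt"))
    list(blocks = gb$blocks, truth = gb$truth, knowledge = kn,
         annotation = ann$annotation, planted_terms = ann$truth)
  }, verbose)

  if (done("simulate")) return(result(simulate = sim, outdir = outdir))

  hash <- config_hash(list(hash, filter = config$filter))
  filt <- run_stage(outdir, "filter", hash, config$filter, function() {
    out <- lapply(names(sim$blocks), function(bn) {
      fold_change_filter(sim$blocks[[bn]], fc_threshold_for(config, bn))
    })
    names(out) <- names(sim$blocks)
    rep <- lapply(out, function(o)
      o$report[c("threshold", "n_in", "n_kept", "n_dropped")])
    jsonlite::write_json(rep, file.path(outdir, "filter_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out
  }, verbose)

  if (done("filter"))
    return(result(simulate = sim, filter = filt, outdir = outdir))

  hash <- config_hash(list(hash, model = config$model))
  mods <- run_stage(outdir, "model", hash, config$model, function() {
    out <- lapply(names(filt), function(bn) {
      m <- model_profiles(filt[[bn]]$block)
      noise_filter(m, r2_floor = config$model$r2_floor)
    })
    names(out) <- names(filt)
    for (bn in names(out)) {
      m <- out[[bn]]
      d <- cbind(feature = rownames(m$fitted),
                 model = m$model_class, r2 = sprintf("%.6f", m$fit_quality),
                 kept = m$kept,
                 as.data.frame(matrix(sprintf("%.8f", m$fitted),
                                      nrow(m$fitted),
                                      dimnames = dimnames(m$fitted))))
      write.table(d, file.path(outdir, paste0("profiles_", bn, ".csv")),
                  sep = ",", quote = FALSE, row.names = FALSE)
    }
    out
  }, verbose)

  if (done("model"))
    return(result(simulate = sim, filter = filt, model = mods,
                  outdir = outdir))

  hash <- config_hash(list(hash, cluster = config$cluster))
  clus <- run_stage(outdir, "cluster", hash, config$cluster, function() {
    scaled <- lapply(mods, scale_profiles)
    ck <- choose_k(scaled, ncomp_grid = config$cluster$ncomp_grid)
    if (!is.null(config$cluster$keepX))
      ck <- sparse_signature(ck, config$cluster$keepX)
    # relabel into the flat network namespace
    blocks <- names(scaled)
    map <- unlist(lapply(blocks, function(bn)
      setNames(prefix_ids(rownames(scaled[[bn]]), bn),
               rownames(scaled[[bn]]))))
    ck$labels_prefixed <- setNames(ck$labels, unname(map[names(ck$labels)]))
    write_clusters(ck, file.path(outdir, "clusters.csv"), blocks = scaled)
    ck
  }, verbose)

  if (done("cluster"))
    return(result(simulate = sim, filter = filt, model = mods,
                  cluster = clus, outdir = outdir))

  hash <- config_hash(list(hash, build = config$build))
  nets <- run_stage(outdir, "build", hash, config$build, function() {
    kn <- prefix_knowledge(sim$knowledge)
    expr_rna <- t(filt$rna$block$values)  # features x samples, raw values
    rownames(expr_rna) <- prefix_ids(rownames(expr_rna), "rna")
    prot_meas_all <- prefix_ids(colnames(filt$prot$block$values), "prot")
    met_meas_all <- prefix_ids(colnames(filt$met$block$values), "met")
    build_fun <- function(ids) {
      layers <- list()
      rna_ids <- intersect(ids, rownames(expr_rna))
      if (length(rna_ids) >= 2)
        layers$rna <- inference_layer(expr_rna[rna_ids, , drop = FALSE],
                                      layer = "gene",
                                      bins = config$build$bins,
                                      epsilon = config$build$epsilon,
                                      seed = seed)
      prot_ids <- intersect(ids, prot_meas_all)
      if (length(prot_ids))
        layers$prot <- knowledge_layer(prot_ids, kn$ppi, layer = "protein",
                                       score_min = config$build$score_min,
                                       extend = TRUE)
      met_ids <- intersect(ids, met_meas_all)
      if (length(met_ids) && !is.null(kn$reactions))
        layers$met <- reaction_layer(met_ids, kn$reactions)
      if (!length(layers))
        layers$empty <- mon(data.frame(id = ids, stringsAsFactors = FALSE))
      net <- merge_networks(layers, name = "assembled")
      cl_edges <- cross_link_ids(kn$cross_links)
      cl_edges <- cl_edges[cl_edges$from %in% net$nodes$id &
                             cl_edges$to %in% net$nodes$id, , drop = FALSE]
      if (nrow(cl_edges))
        net <- mon(net$nodes, rbind(net$edges, cl_edges), name = net$name)
      net
    }
    res <- assemble(build_fun, clus$labels_prefixed)
    write_graphml(res$entire, file.path(outdir, "network_entire.graphml"))
    write_edge_table(res$entire, file.path(outdir, "network_entire.tsv"))
    for (cn in names(res$per_cluster))
      write_graphml(res$per_cluster[[cn]],
                    file.path(outdir,
                              sprintf("network_cluster%s.graphml", cn)))
    res
  }, verbose)

  if (done("build"))
    return(result(simulate = sim, filter = filt, model = mods,
                  cluster = clus, build = nets, outdir = outdir))

  hash <- config_hash(list(hash, annotate = config$annotate))
  enr <- run_stage(outdir, "annotate", hash, config$annotate, function() {
    labels <- clus$labels_prefixed
    measured <- names(labels)
    universe <- if (identical(config$annotate$universe, "extended"))
      union(measured, nets$entire$nodes$id[!nets$entire$nodes$measured &
                                             !nets$entire$nodes$layer %in%
                                             TERM_LAYERS])
    else measured
    alpha <- config$annotate$alpha
    entire_res <- ora(measured, sim$annotation, universe, alpha)
    cl_res <- lapply(split(names(labels), labels), function(ids)
      ora(ids, sim$annotation, universe, alpha))
    comp <- compare_cluster_vs_entire(cl_res, entire_res)
    # union of significant terms across analyses feeds the term layer
    combined <- entire_res
    sig_any <- Reduce(union, c(lapply(cl_res, function(r)
      r$term[r$significant]), list(entire_res$term[entire_res$significant])))
    combined$significant <- combined$term %in% sig_any
    entire_annotated <- add_term_layer(nets$entire, combined,
                                       sim$annotation, "go_term")
    per_annotated <- lapply(names(cl_res), function(cn) {
      add_term_layer(nets$per_cluster[[cn]], cl_res[[cn]],
                     sim$annotation, "go_term")
    })
    names(per_annotated) <- names(cl_res)
    tab <- as.data.frame(entire_res)
    tab$p <- sprintf("%.8g", tab$p); tab$adj_p <- sprintf("%.8g", tab$adj_p)
    write.table(tab, file.path(outdir, "enrichment_entire.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    list(entire = entire_res, clusters = cl_res, comparison = comp,
         network = entire_annotated, per_cluster = per_annotated)
  }, verbose)

  if (done("annotate"))
    return(result(simulate = sim, filter = filt, model = mods,
                  cluster = clus, build = nets, annotate = enr,
                  outdir = outdir))

  hash <- config_hash(list(hash, propagate = config$propagate))
  prop <- run_stage(outdir, "propagate", hash, config$propagate, function() {
    cfg <- walk_config(restart = config$propagate$restart,
                       tol = config$propagate$tol)
    net <- enr$network
    mech <- mechanism_subnetworks(net, k = config$propagate$k_mechanism,
                                  config = cfg)
    pred <- predict_function(net, config = cfg)
    inter <- cluster_intersection(net, k = config$propagate$k_intersection,
                                  config = cfg)
    write.table(format_num_df(as.data.frame(mech)),
                file.path(outdir, "mechanism_screen.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(format_num_df(pred),
                file.path(outdir, "function_prediction.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(format_num_df(as.data.frame(inter)),
                file.path(outdir, "cluster_intersection.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(mechanism = mech, prediction = pred, intersection = inter)
  }, verbose)

  result(simulate = sim, filter = filt, model = mods, cluster = clus,
         build = nets, annotate = enr, propagate = prop, outdir = outdir)
}
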