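#' @importFrom stats rnorm runif rmultinom smooth.spline predict lm splinefun
#'   phyper pchisq p.adjust
NULL

# All generator randomness flows from one integer seed through a splitting
# scheme keyed by operation tag, so each generator is reproducible on its own
# and in any call order. Global RNG state is saved and restored.
split_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 69069 + h * 2654435) %% 2147483647)
}

with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# mutually orthogonal smooth archetype curves over the grid (centered,
# unit-sd): smooth basis curves orthogonalized by QR
make_archetypes <- function(grid, n_arch) {
  tt <- (grid - min(grid)) / diff(range(grid))
  basis <- cbind(sin(2 * pi * tt), tt - 0.5, cos(2 * pi * tt),
                 (tt - 0.5)^2)
  if (n_arch > ncol(basis))
    stop("at most ", ncol(basis), " archetypes supported")
  b <- scale(basis, center = TRUE, scale = FALSE)
  q <- qr.Q(qr(b))[, seq_len(n_arch), drop = FALSE]
  # unit sd over the grid for a consistent amplitude scale
  q <- apply(q, 2, function(v) (v - mean(v)) / sd(v))
  q <- matrix(q, nrow = length(grid))
  colnames(q) <- paste0("archetype", seq_len(n_arch))
  rownames(q) <- as.character(grid)
  q
}

#' Generate replicated time-course omics blocks with planted kinetics
#'
#' Emulates a longitudinal multi-omics design: each measured feature follows
#' one of a small number of archetype time curves (mutually orthogonal over
#' the grid), with a planted sign, a per-subject random intercept, and i.i.d.
#' Gaussian measurement noise, on a log2 abundance scale. Kinetic cluster
#' `2a-1` is archetype `a` with sign `+1`, cluster `2a` the same archetype
#' with sign `-1`. A configurable number of pure-noise features (no time
#' trend) is appended per block.
#'
#' @param n_clusters number of planted kinetic clusters (one archetype per
#'   pair of clusters).
#' @param features_per_block signal features in each block.
#' @param n_blocks number of omics blocks (default mirrors a 3-block
#'   transcriptome / translatome / proteome design).
#' @param timepoints number of equally spaced timepoints.
#' @param subjects number of subjects (biological replicates).
#' @param sigma measurement noise standard deviation (log2 units).
#' @param subject_sd standard deviation of subject random intercepts.
#' @param amplitude archetype amplitude in log2 units (2 = 4-fold swing).
#' @param noise_features pure-noise features appended per block.
#' @param seed integer master seed.
#' @return list with `blocks` (list of [omics_block()]) and `truth` (list:
#'   `archetypes` grid x archetype matrix, `features` data.frame (feature,
#'   block, cluster, sign), `grid`, `sigma`, `seed`).
#' @export
gen_blocks <- function(n_clusters = 4, features_per_block = 20, n_blocks = 3,
                       timepoints = 5, subjects = 3, sigma = 0.2,
                       subject_sd = 0.3, amplitude = 2, noise_features = 5,
                       seed = 1) {
  stopifnot(n_clusters >= 2, timepoints >= 3, subjects >= 1)
  with_seed(split_seed(seed, "gen_blocks"), {
    grid <- seq(0, 1, length.out = timepoints)
    n_arch <- ceiling(n_clusters / 2)
    arch <- make_archetypes(grid, n_arch)
    block_names <- c("rna", "prot", "met", paste0("blk", seq_len(max(0, n_blocks - 3))))[seq_len(n_blocks)]
    meta <- data.frame(
      subject = rep(paste0("S", seq_len(subjects)), each = timepoints),
      replicate = rep(paste0("S", seq_len(subjects)), each = timepoints),
      time = rep(grid, times = subjects),
      stringsAsFactors = FALSE)
    blocks <- list(); truth_rows <- list()
    for (b in seq_len(n_blocks)) {
      n_feat <- features_per_block + noise_features
      fid <- sprintf("%s_f%03d", block_names[b], seq_len(n_feat))
      # cluster sizes are skewed (proportional to n_clusters:1), as in real
      # kinetic clusterings where one programme dominates; this also keeps
      # the latent components identifiable (no two archetypes carry the
      # same number of features)
      prop <- (n_clusters:1) / sum(n_clusters:1)
      sizes <- pmax(2L, floor(prop * features_per_block))
      while (sum(sizes) > features_per_block)
        sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
      while (sum(sizes) < features_per_block)
        sizes[which.min(sizes)] <- sizes[which.min(sizes)] + 1L
      cl <- rep(seq_len(n_clusters), times = sizes)
      cl <- c(cl, rep(NA_integer_, noise_features))
      sgn <- ifelse(is.na(cl), NA_real_, ifelse(cl %% 2 == 1, 1, -1))
      a_idx <- ifelse(is.na(cl), NA_integer_, (cl + 1) %/% 2)
      vals <- matrix(0, nrow = nrow(meta), ncol = n_feat,
                     dimnames = list(paste0(meta$subject, "_t",
                                            rep(seq_len(timepoints), subjects)),
                                     fid))
      base <- runif(n_feat, 6, 10)
      offs <- matrix(rnorm(n_feat * subjects, 0, subject_sd),
                     nrow = subjects)
      for (f in seq_len(n_feat)) {
        # archetype amplitudes are staggered (each programme 25% weaker
        # than the previous) so no two kinetic programmes carry identical
        # energy, as in real designs where dominant responses differ
        curve <- if (is.na(cl[f])) rep(0, timepoints)
        else amplitude * 0.75^(a_idx[f] - 1) * sgn[f] * arch[, a_idx[f]]
        mu <- base[f] + rep(curve, times = subjects) +
          rep(offs[, f], each = timepoints)
        vals[, f] <- mu + rnorm(nrow(meta), 0, sigma)
      }
      blocks[[block_names[b]]] <- omics_block(vals, meta, scale = "log",
                                              log_base = 2)
      truth_rows[[b]] <- data.frame(feature = fid, block = block_names[b],
                                    cluster = cl, sign = sgn,
                                    stringsAsFactors = FALSE)
    }
    list(blocks = blocks,
         truth = list(archetypes = arch,
                      features = do.call(rbind, truth_rows),
                      grid = grid, sigma = sigma, seed = seed,
                      n_clusters = n_clusters, amplitude = amplitude))
  })
}

#' Generate a planted regulatory network with induced co-expression
#'
#' Samples a random tree over `n_nodes` regulators/targets and draws
#' expression by propagating a standard-normal root signal down the tree
#' with attenuation, so that directly linked pairs share the strongest
#' dependence and indirect pairs satisfy the data-processing inequality.
#'
#' @param n_nodes number of genes.
#' @param n_samples independent samples (columns).
#' @param coupling parent-child correlation of the planted edges.
#' @param seed integer seed.
#' @return list with `expr` (features x samples matrix) and `edges`
#'   (data.frame from, to of planted regulatory edges).
#' @export
gen_regulatory <- function(n_nodes = 50, n_samples = 200, coupling = 0.85,
                           seed = 1) {
  stopifnot(n_nodes >= 3)
  with_seed(split_seed(seed, "gen_regulatory"), {
    parent <- c(NA, vapply(2:n_nodes, function(i) sample.int(i - 1L, 1L), 1L))
    x <- matrix(0, n_nodes, n_samples)
    x[1, ] <- rnorm(n_samples)
    for (i in 2:n_nodes)
      x[i, ] <- coupling * x[parent[i], ] +
        sqrt(1 - coupling^2) * rnorm(n_samples)
    ids <- sprintf("g%03d", seq_len(n_nodes))
    rownames(x) <- ids
    list(expr = x,
         edges = data.frame(from = ids[parent[-1]], to = ids[-1],
                            stringsAsFactors = FALSE))
  })
}

#' Generate knowledge interaction, reaction and cross-link tables
#'
#' Emulates curated database exports: a scored protein-protein interaction
#' table over the measured proteins plus unmeasured first-degree interactors,
#' a reaction table linking metabolite compounds and protein enzymes (with
#' unmeasured compounds sharing reactions with measured ones), and a
#' cross-link table with protein-coding (gene to protein) and TF-target
#' rows. Every unmeasured id is, by construction, directly connected to at
#' least one measured molecule.
#'
#' @param gene_ids,protein_ids,metabolite_ids measured identifiers per layer.
#' @param extra_unmeasured unmeasured interactors added per measured protein
#'   (and unmeasured compounds per reaction).
#' @param p_edge density of the measured-measured PPI part.
#' @param n_reactions number of enzymatic reactions.
#' @param seed integer seed.
#' @return list of data.frames `ppi` (id_a, id_b, type, score), `reactions`
#'   (reaction_id, compounds `;`-separated, enzymes `;`-separated),
#'   `cross_links` (id_a, id_b, relation).
#' @export
gen_knowledge <- function(gene_ids, protein_ids, metabolite_ids = character(),
                          extra_unmeasured = 1, p_edge = 0.1,
                          n_reactions = 5, seed = 1) {
  with_seed(split_seed(seed, "gen_knowledge"), {
    np <- length(protein_ids)
    rows <- list()
    if (np >= 2) {
      pairs <- which(upper.tri(matrix(0, np, np)), arr.ind = TRUE)
      take <- runif(nrow(pairs)) < p_edge
      # keep the PPI part connected-ish: chain backbone
      chain <- cbind(seq_len(np - 1L), 2:np)
      idx <- unique(rbind(pairs[take, , drop = FALSE], chain))
      rows$meas <- data.frame(id_a = protein_ids[idx[, 1]],
                              id_b = protein_ids[idx[, 2]],
                              type = "physical",
                              score = round(runif(nrow(idx), 0.5, 1), 4),
                              stringsAsFactors = FALSE)
    }
    if (extra_unmeasured > 0 && np >= 1) {
      u <- sprintf("uprot%03d", seq_len(np * extra_unmeasured))
      anchor <- rep(protein_ids, each = extra_unmeasured)
      rows$ext <- data.frame(id_a = anchor, id_b = u, type = "physical",
                             score = round(runif(length(u), 0.5, 1), 4),
                             stringsAsFactors = FALSE)
    }
    ppi <- do.call(rbind, rows)
    reactions <- NULL
    if (n_reactions > 0 && length(metabolite_ids) >= 1 && np >= 1) {
      rid <- sprintf("R%03d", seq_len(n_reactions))
      comp <- character(n_reactions); enz <- character(n_reactions)
      for (r in seq_len(n_reactions)) {
        meas <- sample(metabolite_ids, min(2, length(metabolite_ids)))
        un <- if (extra_unmeasured > 0) sprintf("umet%03d", r) else character()
        comp[r] <- paste(c(meas, un), collapse = ";")
        enz[r] <- paste(sample(protein_ids, 1), collapse = ";")
      }
      reactions <- data.frame(reaction_id = rid, compounds = comp,
                              enzymes = enz, stringsAsFactors = FALSE)
    }
    ncl <- min(length(gene_ids), np)
    cross <- data.frame(id_a = character(), id_b = character(),
                        relation = character(), stringsAsFactors = FALSE)
    if (ncl >= 1) {
      cross <- data.frame(id_a = gene_ids[seq_len(ncl)],
                          id_b = protein_ids[seq_len(ncl)],
                          relation = "coding", stringsAsFactors = FALSE)
      ntf <- max(1L, np %/% 5L)
      tf <- sample(protein_ids, ntf)
      tgt <- sample(gene_ids, min(ntf * 2L, length(gene_ids)), replace = FALSE)
      cross <- rbind(cross,
                     data.frame(id_a = rep_len(tf, length(tgt)), id_b = tgt,
                                relation = "tf_target",
                                stringsAsFactors = FALSE))
    }
    list(ppi = ppi, reactions = reactions, cross_links = cross)
  })
}

#' Generate annotation sets with one planted enriched term per cluster
#'
#' The planted term for cluster `c` draws its members exclusively from
#' cluster `c` features, so a query consisting of that cluster is strongly
#' over-represented in it. Background terms sample members uniformly from
#' the whole universe.
#'
#' @param feature_clusters named integer vector, feature id to cluster label
#'   (NA features are background-only).
#' @param member_frac fraction of a cluster included in its planted term.
#' @param n_background number of background terms.
#' @param bg_size_range size range of background terms.
#' @param source ontology tag.
#' @param seed integer seed.
#' @return list with `annotation` (an [annotation_set()]) and `truth`
#'   (named character vector: cluster label to planted term id).
#' @export
gen_annotations <- function(feature_clusters, member_frac = 0.7,
                            n_background = 10, bg_size_range = c(5, 15),
                            source = "GO:BP", seed = 1) {
  stopifnot(!is.null(names(feature_clusters)))
  with_seed(split_seed(seed, "gen_annotations"), {
    universe <- names(feature_clusters)
    cls <- sort(unique(feature_clusters[!is.na(feature_clusters)]))
    members <- list(); planted <- character()
    for (c in cls) {
      feats <- universe[!is.na(feature_clusters) & feature_clusters == c]
      n <- max(2L, round(member_frac * length(feats)))
      tid <- sprintf("TERM:planted_c%s", c)
      members[[tid]] <- sample(feats, min(n, length(feats)))
      planted[as.character(c)] <- tid
    }
    for (i in seq_len(n_background)) {
      sz <- sample(seq(bg_size_range[1], bg_size_range[2]), 1)
      members[[sprintf("TERM:bg%03d", i)]] <-
        sample(universe, min(sz, length(universe)))
    }
    list(annotation = annotation_set(members, source = source),
         truth = planted)
  })
}

#' Generate a compositional count table with planted basis correlations
#'
#' Basis (absolute) abundances are log-normal; planted pairs share a common
#' Gaussian factor so their log-basis correlation equals the target. Counts
#' are multinomial draws of the per-sample compositions at a fixed depth,
#' emulating an OTU table.
#'
#' @param n_taxa number of taxa (>= 4).
#' @param n_samples number of samples.
#' @param planted data.frame (i, j, rho) of planted basis correlations
#'   between taxon indices, or NULL for fully independent taxa.
#' @param depth sequencing depth per sample.
#' @param seed integer seed.
#' @return list with `counts` (samples x taxa matrix), `log_basis`
#'   (samples x taxa), `truth` (planted table).
#' @export
gen_compositional <- function(n_taxa = 20, n_samples = 500, planted = NULL,
                              depth = 1e5, seed = 1) {
  stopifnot(n_taxa >= 4)
  with_seed(split_seed(seed, "gen_compositional"), {
    z <- matrix(rnorm(n_samples * n_taxa), n_samples, n_taxa)
    if (!is.null(planted)) {
      for (r in seq_len(nrow(planted))) {
        i <- planted$i[r]; j <- planted$j[r]; rho <- planted$rho[r]
        z[, j] <- rho * z[, i] + sqrt(1 - rho^2) * rnorm(n_samples)
      }
    }
    mu <- runif(n_taxa, 0, 2)
    logb <- sweep(z, 2, mu, `+`)
    frac <- exp(logb)
    frac <- frac / rowSums(frac)
    counts <- t(apply(frac, 1, function(p) rmultinom(1, size = depth,
                                                     prob = p)[, 1]))
    colnames(counts) <- sprintf("otu%03d", seq_len(n_taxa))
    colnames(logb) <- colnames(counts)
    list(counts = counts, log_basis = logb,
         truth = list(planted = planted, depth = depth, seed = seed))
  })
}

#' Write the default synthetic input bundle to disk
#'
#' Emits everything the pipeline consumes: per-block abundance CSVs with a
#' sample-metadata CSV, knowledge TSVs (PPI, reactions, cross-links), an
#' annotation GMT, a compositional count CSV, and a `truth.json` record of
#' the planted structure.
#'
#' @param dir output directory (created).
#' @param seed master seed.
#' @param ... passed to [gen_blocks()].
#' @return invisibly, the list of written paths.
#' @export
simulate_bundle <- function(dir, seed = 1, ...) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gb <- gen_blocks(seed = seed, ...)
  paths <- list()
  for (bn in names(gb$blocks)) {
    b <- gb$blocks[[bn]]
    p <- file.path(dir, paste0(bn, ".csv"))
    write.table(cbind(sample = rownames(b$values),
                      as.data.frame(round(b$values, 6))),
                p, sep = ",", quote = FALSE, row.names = FALSE)
    paths[[paste0("block_", bn)]] <- p
  }
  meta <- gb$blocks[[1]]$sample_meta
  pmeta <- file.path(dir, "sample_meta.csv")
  write.table(cbind(sample = rownames(gb$blocks[[1]]$values), meta), pmeta,
              sep = ",", quote = FALSE, row.names = FALSE)
  paths$sample_meta <- pmeta

  tr <- gb$truth$features
  kn <- gen_knowledge(
    gene_ids = tr$feature[tr$block == "rna"],
    protein_ids = tr$feature[tr$block == "prot"],
    metabolite_ids = tr$feature[tr$block == "met"],
    seed = seed)
  for (nm in c("ppi", "reactions", "cross_links")) {
    if (is.null(kn[[nm]])) next
    p <- file.path(dir, paste0(nm, ".tsv"))
    write.table(kn[[nm]], p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths[[nm]] <- p
  }

  fc <- setNames(tr$cluster, prefix_ids(tr$feature, tr$block))
  ann <- gen_annotations(fc, seed = seed)
  pgmt <- file.path(dir, "annotations.gmt")
  write_gmt(ann$annotation, pgmt)
  paths$annotations <- pgmt

  truth <- gb$truth
  truth$archetypes <- as.data.frame(truth$archetypes)
  truth$planted_terms <- as.list(ann$truth)
  ptruth <- file.path(dir, "truth.json")
  jsonlite::write_json(truth, ptruth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths$truth <- ptruth
  invisible(paths)
}
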