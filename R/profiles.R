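#' Construct an omics block
#'
#' One omics layer's measured abundance matrix together with its sample
#' metadata (subject, replicate, time). Values may be on a linear or a log
#' scale; the scale drives how the fold-change filter is computed.
#'
#' @param values numeric matrix, samples in rows, features in columns
#'   (column names are the feature ids).
#' @param sample_meta data.frame with one row per sample and columns
#'   `subject`, `replicate`, `time`.
#' @param scale `"linear"` or `"log"`.
#' @param log_base base of the logarithm when `scale = "log"`.
#' @return object of class `omics_block`.
#' @export
omics_block <- function(values, sample_meta, scale = c("linear", "log"),
                        log_base = 2) {
  scale <- match.arg(scale)
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("values must have feature column names")
  sample_meta <- as.data.frame(sample_meta, stringsAsFactors = FALSE)
  if (!all(c("subject", "replicate", "time") %in% names(sample_meta)))
    stop("sample_meta needs columns subject, replicate, time")
  if (nrow(values) != nrow(sample_meta))
    stop("values rows (", nrow(values), ") do not align with sample_meta (",
         nrow(sample_meta), ")")
  if (!all(is.finite(sample_meta$time))) stop("times must be finite")
  if (length(unique(sample_meta$time)) < 2L)
    stop("need at least 2 distinct timepoints")
  structure(list(values = values, sample_meta = sample_meta, scale = scale,
                 log_base = log_base, feature_ids = colnames(values)),
            class = "omics_block")
}

#' @export
print.omics_block <- function(x, ...) {
  cat(sprintf("<omics_block> %d samples x %d features (%s scale), %d timepoints, %d subjects\n",
              nrow(x$values), ncol(x$values), x$scale,
              length(unique(x$sample_meta$time)),
              length(unique(x$sample_meta$subject))))
  invisible(x)
}

per_time_summary <- function(block) {
  tt <- block$sample_meta$time
  ut <- sort(unique(tt))
  out <- vapply(ut, function(u)
    colMeans(block$values[tt == u, , drop = FALSE], na.rm = TRUE),
    numeric(ncol(block$values)))
  # features x times
  matrix(out, ncol = length(ut),
         dimnames = list(colnames(block$values), as.character(ut)))
}

#' Filter features by time-course fold change
#'
#' Keeps only molecules whose expression swing between the lowest and
#' highest per-time mean over the whole time course reaches `threshold`.
#' On a linear scale the criterion is `max/min >= threshold`; on a log
#' scale it is `max - min >= log(threshold)` in the block's log base.
#' Non-positive per-time minima on the linear scale are offset by a
#' pseudocount (half the smallest positive value in the block unless
#' supplied) and the pseudocount is recorded in the report.
#'
#' @param block an [omics_block()].
#' @param threshold fold-change threshold (>= 1).
#' @param pseudocount optional pseudocount for non-positive linear minima.
#' @return list with `block` (filtered) and `report` (kept/dropped counts,
#'   per-feature fold change, drop reasons, pseudocount used).
#' @export
fold_change_filter <- function(block, threshold, pseudocount = NULL) {
  stopifnot(inherits(block, "omics_block"), threshold >= 1)
  s <- per_time_summary(block)
  all_nan <- apply(s, 1, function(r) all(!is.finite(r)))
  fc <- rep(NA_real_, nrow(s))
  used_pseudo <- NULL
  if (block$scale == "linear") {
    mn <- apply(s, 1, min); mx <- apply(s, 1, max)
    if (any(mn <= 0, na.rm = TRUE)) {
      if (is.null(pseudocount)) {
        pos <- block$values[block$values > 0]
        pseudocount <- if (length(pos)) min(pos) / 2 else 0.5
      }
      used_pseudo <- pseudocount
      mn <- mn + pseudocount; mx <- mx + pseudocount
    }
    fc <- mx / mn
    keep <- !all_nan & fc >= threshold
  } else {
    delta <- apply(s, 1, max) - apply(s, 1, min)
    fc <- block$log_base^delta
    keep <- !all_nan & delta >= log(threshold, base = block$log_base)
  }
  keep[is.na(keep)] <- FALSE
  reasons <- ifelse(all_nan, "all_nan", ifelse(keep, NA, "low_fc"))
  out <- block
  out$values <- block$values[, keep, drop = FALSE]
  out$feature_ids <- colnames(out$values)
  list(block = out,
       report = list(threshold = threshold, n_in = ncol(block$values),
                     n_kept = sum(keep), n_dropped = sum(!keep),
                     fold_change = setNames(fc, rownames(s)),
                     dropped = setNames(reasons[!keep],
                                        rownames(s)[!keep]),
                     pseudocount = used_pseudo))
}

# single-feature model hierarchy fit; returns list(class, pred_obs, pred_fun,
# k) or NULL when a candidate is unavailable
fit_candidates <- function(y, t, subject) {
  dt <- sort(unique(t))
  ndt <- length(dt)
  n_subj <- length(unique(subject))
  cands <- list()
  cands$constant <- list(pred = rep(mean(y), length(y)),
                         f = local({ m <- mean(y); function(g) rep(m, length(g)) }),
                         k = 1)
  cf <- stats::coef(lm(y ~ t))
  cands$linear <- list(pred = cf[1] + cf[2] * t,
                       f = local({ cf <- cf; function(g) cf[1] + cf[2] * g }),
                       k = 2)
  if (ndt >= 4) {
    if (ndt <= 5) {
      means <- vapply(dt, function(u) mean(y[t == u]), 0)
      f <- splinefun(dt, means, method = "natural")
      cands$spline_mean <- list(pred = f(t), f = f, k = ndt)
    } else {
      ss <- try(smooth.spline(t, y), silent = TRUE)
      if (!inherits(ss, "try-error")) {
        f <- local({ ss <- ss; function(g) predict(ss, g)$y })
        cands$spline_mean <- list(pred = f(t), f = f, k = ss$df)
      }
    }
    if (!is.null(cands$spline_mean) && n_subj >= 2) {
      sm <- cands$spline_mean
      res <- y - sm$pred
      ms <- tapply(res, subject, mean)
      ns <- tapply(res, subject, length)
      sig2 <- max(mean(tapply(res, subject, function(r)
        if (length(r) > 1) var(r) else 0)), 1e-12)
      vb <- max(0, var(as.numeric(ms)) - mean(sig2 / ns))
      shrink <- vb / (vb + sig2 / ns)
      b <- shrink * ms
      cands$spline_subject <- list(
        pred = sm$pred + as.numeric(b[as.character(subject)]),
        f = sm$f,  # population curve: subject offsets average out
        k = sm$k + sum(shrink))
    }
  }
  cands
}

#' Model every feature's time course and interpolate on a grid
#'
#' Fits, per feature, a small hierarchy of time-course models — constant
#' mean, straight line, cubic smoothing spline of the group mean (natural
#' interpolating spline through per-time means when there are at most 5
#' distinct timepoints), and the spline plus shrunken per-subject intercept
#' offsets — and selects among them by BIC. The winning population curve is
#' evaluated on `grid` (which must lie inside the observed time range; no
#' extrapolation). With fewer than 4 distinct timepoints the spline
#' candidates are excluded and a warning is recorded.
#'
#' @param block an [omics_block()].
#' @param grid increasing time vector inside the observed range; defaults to
#'   the sorted distinct observed timepoints.
#' @return object of class `modeled_profiles`: list with `grid`, `fitted`
#'   (features x grid matrix), `model_class`, `fit_quality` (R-squared of
#'   the winning model against the observations), `kept` (all TRUE here),
#'   `kept_reason`, `warnings`, `scale`, `log_base`.
#' @export
model_profiles <- function(block, grid = NULL) {
  stopifnot(inherits(block, "omics_block"))
  t <- block$sample_meta$time
  if (is.null(grid)) grid <- sort(unique(t))
  if (min(grid) < min(t) || max(grid) > max(t))
    stop("grid extends outside the observed time range (no extrapolation)")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be increasing")
  subject <- as.character(block$sample_meta$subject)
  ndt <- length(unique(t))
  warn <- character()
  if (ndt < 4)
    warn <- c(warn, sprintf(
      "only %d distinct timepoints: spline candidates excluded", ndt))
  p <- ncol(block$values)
  fitted <- matrix(NA_real_, p, length(grid),
                   dimnames = list(colnames(block$values),
                                   as.character(grid)))
  model_class <- character(p); quality <- numeric(p); gof <- numeric(p)
  order_pref <- c("constant", "linear", "spline_mean", "spline_subject")
  n <- length(t)
  for (i in seq_len(p)) {
    y <- block$values[, i]
    cands <- fit_candidates(y, t, subject)
    bic <- vapply(cands, function(cd) {
      rss <- sum((y - cd$pred)^2)
      n * log(max(rss, 1e-12) / n) + cd$k * log(n)
    }, 0)
    # prefer the simplest model among near-ties of the minimum
    ord <- order_pref[order_pref %in% names(cands)]
    bic <- bic[ord]
    best <- ord[which(bic <= min(bic) + 1e-9)[1L]]
    cd <- cands[[best]]
    model_class[i] <- best
    rss <- sum((y - cd$pred)^2)
    tss <- sum((y - mean(y))^2)
    quality[i] <- if (tss > 0) 1 - rss / tss else 0
    # goodness of fit of the winning model over the constant mean (F test)
    gof[i] <- if (best == "constant" || tss <= 0) 1 else {
      df1 <- max(cd$k - 1, 1)
      df2 <- n - cd$k
      if (df2 <= 0 || rss <= 1e-12) 0
      else stats::pf(((tss - rss) / df1) / (rss / df2), df1, df2,
                     lower.tail = FALSE)
    }
    fitted[i, ] <- cd$f(grid)
  }
  structure(list(grid = grid, fitted = fitted,
                 model_class = setNames(model_class, rownames(fitted)),
                 fit_quality = setNames(quality, rownames(fitted)),
                 gof_p = setNames(gof, rownames(fitted)),
                 kept = setNames(rep(TRUE, p), rownames(fitted)),
                 kept_reason = setNames(rep(NA_character_, p),
                                        rownames(fitted)),
                 warnings = warn, scale = block$scale,
                 log_base = block$log_base),
            class = "modeled_profiles")
}

#' @export
print.modeled_profiles <- function(x, ...) {
  cat(sprintf("<modeled_profiles> %d features on %d grid points; %d kept\n",
              nrow(x$fitted), length(x$grid), sum(x$kept)))
  print(table(x$model_class))
  invisible(x)
}

#' Flag noisy modelled profiles
#'
#' A profile is noisy when its selected model is the constant mean (no time
#' structure), when the winning model explains less than `r2_floor` of the
#' observed variance, or when the winning model's improvement over the
#' constant mean is not significant by F test at `gof_alpha` (the
#' goodness-of-fit screen; conservative by default so that trendless
#' profiles are almost always removed). Noisy features get `kept = FALSE`
#' with reason `"noisy"`.
#'
#' @param mset a [model_profiles()] result.
#' @param r2_floor minimum R-squared of the winning model.
#' @param gof_alpha significance level of the model-vs-constant F test;
#'   `NULL` disables the screen.
#' @return the updated `modeled_profiles`.
#' @export
noise_filter <- function(mset, r2_floor = 0.1, gof_alpha = 0.01) {
  stopifnot(inherits(mset, "modeled_profiles"))
  noisy <- mset$model_class == "constant" | mset$fit_quality < r2_floor
  if (!is.null(gof_alpha) && !is.null(mset$gof_p))
    noisy <- noisy | mset$gof_p > gof_alpha
  mset$kept <- mset$kept & !noisy
  mset$kept_reason[noisy] <- "noisy"
  mset
}

#' Row-standardize kept modelled profiles
#'
#' Centers each kept feature's fitted profile to mean 0 and scales to unit
#' variance, the form expected by correlation-distance clustering. Constant
#' fitted rows are an error (they should have been removed upstream).
#'
#' @param mset a [model_profiles()] result (after [noise_filter()]).
#' @return features x grid matrix of standardized profiles.
#' @export
scale_profiles <- function(mset) {
  stopifnot(inherits(mset, "modeled_profiles"))
  m <- mset$fitted[mset$kept, , drop = FALSE]
  if (nrow(m) == 0L) stop("no kept features to scale")
  sds <- apply(m, 1, sd)
  if (any(sds == 0))
    stop("constant fitted profile(s): ",
         paste(head(rownames(m)[sds == 0]), collapse = ", "))
  t(scale(t(m)))[, , drop = FALSE]
}
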