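#' Feature vectors for profile clustering
#'
#' Turns surviving probes' fitted temporal profiles into the matrix that is
#' clustered.  The default feature is the treated-minus-control fitted
#' difference at the grid days, z-scored per probe (mean 0, sd 1), so that
#' probes are grouped by the shape of their response and not by its
#' amplitude or baseline.  Zero-variance vectors (identical treated and
#' control curves) map to all-zeros.
#'
#' @param fit a `"tc_fit"`.
#' @param probes probe ids to include (default: all probes in `fit`).
#' @param feature_mode `"fitted_difference"` (default), `"fitted_both"`
#'   (both arm curves concatenated), or `"coefficients"` (group-term
#'   coefficients).
#' @param model fitted curves of the `"full"` polynomial model (default)
#'   or of the stepwise-`"selected"` one.  The full model keeps every
#'   probe in the same feature space; reduced models differ in basis
#'   between probes, which distorts between-probe distances.
#' @return numeric matrix, probes x features, z-scored per row.
#' @export
profile_vectors <- function(fit, probes = fit$probe_id,
                            feature_mode = c("fitted_difference",
                                             "fitted_both", "coefficients"),
                            model = c("full", "selected")) {
  feature_mode <- match.arg(feature_mode)
  model <- match.arg(model)
  missing <- setdiff(probes, fit$probe_id)
  if (length(missing))
    stop_input("unknown probe id(s): %s", paste(utils::head(missing, 3),
                                                collapse = ", "))
  pc <- if (model == "full") fit$profile_control_full else fit$profile_control
  pt <- if (model == "full") fit$profile_treated_full else fit$profile_treated
  V <- switch(feature_mode,
    fitted_difference = (pt - pc)[probes, , drop = FALSE],
    fitted_both = cbind(pc, pt)[probes, , drop = FALSE],
    coefficients = {
      B <- if (model == "full") fit$coefficients else fit$coefficients_selected
      gcols <- grep("^grp", colnames(B))
      B[probes, gcols, drop = FALSE]
    })
  t(apply(V, 1, function(v) {
    s <- sd(v)
    if (!is.finite(s) || s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }))
}

#' Seeded best-of-restarts k-means
#'
#' Lloyd iteration via [stats::kmeans()] started from greedy farthest-point
#' spread seeds: the first centre is a random point, each further centre
#' the point maximising its distance to the centres chosen so far.  The
#' best of `restarts` such runs (lowest total within-cluster sum of
#' squares) is returned.  Deterministic for a fixed seed.
#'
#' @param vectors numeric matrix, points x features.
#' @param k number of clusters; must not exceed the number of distinct
#'   points.
#' @param restarts number of seeded restarts.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return list with `labels`, `centers`, `withinss`, `tot_withinss`.
#' @export
kmeans_cluster <- function(vectors, k, restarts = 25L, seed = NULL) {
  vectors <- as.matrix(vectors)
  ndist <- nrow(unique(vectors))
  if (!is_count(k) || k < 1) stop_input("k must be a positive integer")
  if (k > ndist)
    stop_input("k = %d exceeds the %d distinct vectors", k, ndist)
  run <- function() {
    best <- NULL
    for (r in seq_len(restarts)) {
      ctr <- farthest_point_seeds(vectors, k)
      km <- suppressWarnings(kmeans(vectors, centers = ctr, iter.max = 100L,
                                    algorithm = "Lloyd"))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  }
  km <- with_seed(seed, run())
  list(labels = setNames(km$cluster, rownames(vectors)),
       centers = km$centers, withinss = km$withinss,
       tot_withinss = km$tot.withinss)
}

farthest_point_seeds <- function(vectors, k) {
  n <- nrow(vectors)
  first <- sample.int(n, 1L)
  idx <- integer(k); idx[1] <- first
  dmin <- colSums((t(vectors) - vectors[first, ])^2)
  if (k > 1) for (j in 2:k) {
    # avoid re-picking coincident points so centres stay distinct
    dmin_pick <- dmin; dmin_pick[idx[seq_len(j - 1)]] <- -Inf
    idx[j] <- which.max(dmin_pick)
    dmin <- pmin(dmin, colSums((t(vectors) - vectors[idx[j], ])^2))
  }
  ctr <- vectors[idx, , drop = FALSE]
  # jitter exact duplicates among seeds (possible with duplicated points)
  dup <- duplicated(ctr)
  if (any(dup)) ctr[dup, ] <- ctr[dup, ] + 1e-8 * seq_len(sum(dup))
  ctr
}

#' Choose the number of clusters
#'
#' Sweeps k over `[k_min, k_max]`, scoring each partition by the mean
#' silhouette width; the winner (ties towards smaller k) is then compared
#' against the single-cluster hypothesis with a gap statistic computed
#' against uniform reference data in the feature bounding box.  If the gap
#' at the silhouette winner does not exceed the gap at k = 1 by more than
#' one reference standard error, k = 1 is returned.  With fewer than
#' `min_probes` vectors no clustering is attempted and k = 0 is returned,
#' the degenerate "zero clusters" outcome.
#'
#' @param vectors numeric matrix from [profile_vectors()] (may have zero
#'   rows).
#' @param k_min,k_max candidate range (k_max is clamped to one less than
#'   the number of distinct vectors).
#' @param restarts k-means restarts per candidate.
#' @param min_probes minimum surviving probes to attempt clustering.
#' @param min_cluster_size smallest admissible cluster (default 1:
#'   singleton clusters are permitted).
#' @param n_ref number of uniform reference datasets for the gap statistic.
#' @param seed integer seed.
#' @return list with `k_star` (0 if not attempted), `labels` (named, or
#'   `NULL`), and `scores` (data frame: k, silhouette, and the gap columns
#'   where evaluated).
#' @export
select_optimal_k <- function(vectors, k_min = 1L, k_max = 15L,
                             restarts = 25L, min_probes = 5L,
                             min_cluster_size = 1L, n_ref = 20L, seed = 1L) {
  vectors <- as.matrix(vectors)
  n <- nrow(vectors)
  empty <- data.frame(k = integer(), silhouette = numeric(),
                      gap = numeric(), gap_se = numeric())
  if (n < min_probes)
    return(list(k_star = 0L, labels = NULL, scores = empty))
  if (k_min < 1 || k_min > k_max) stop_input("need 1 <= k_min <= k_max")
  ndist <- nrow(unique(vectors))
  k_hi <- min(k_max, ndist, n - 1L)
  ks <- seq.int(max(2L, k_min), k_hi)
  ks <- ks[ks >= 2L]
  sil <- rep(NA_real_, length(ks))
  labs <- vector("list", length(ks))
  d <- dist(vectors)
  for (i in seq_along(ks)) {
    km <- kmeans_cluster(vectors, ks[i], restarts = restarts,
                         seed = seed + ks[i])
    if (min(tabulate(km$labels, ks[i])) < min_cluster_size) next
    sil[i] <- mean(cluster::silhouette(as.integer(km$labels), d)[, 3])
    labs[[i]] <- km
  }
  scores <- data.frame(k = ks, silhouette = sil,
                       gap = NA_real_, gap_se = NA_real_)
  if (all(is.na(sil))) {
    # nothing admissible beyond a single cluster
    return(list(k_star = 1L,
                labels = setNames(rep(1L, n), rownames(vectors)),
                scores = rbind(data.frame(k = 1L, silhouette = NA_real_,
                                          gap = NA_real_, gap_se = NA_real_),
                               scores)))
  }
  best <- ks[which.max(sil)]          # which.max takes the first: ties to smaller k
  km_best <- labs[[match(best, ks)]]
  out_labels <- km_best$labels
  k_star <- best
  if (k_min <= 1L) {
    g <- gap_statistic(vectors, km_best, best,
                       n_ref = n_ref, restarts = restarts, seed = seed)
    scores <- rbind(data.frame(k = 1L, silhouette = NA_real_,
                               gap = g$gap[1], gap_se = g$se[1]), scores)
    scores$gap[scores$k == best] <- g$gap[2]
    scores$gap_se[scores$k == best] <- g$se[2]
    if (g$gap[2] <= g$gap[1] + g$se[2]) {
      k_star <- 1L
      out_labels <- setNames(rep(1L, n), rownames(vectors))
    }
  }
  list(k_star = as.integer(k_star), labels = out_labels, scores = scores)
}

# gap statistic at k = 1 and k = k_best against uniform bounding-box refs
gap_statistic <- function(vectors, km_best, k_best, n_ref, restarts, seed) {
  n <- nrow(vectors)
  w_obs <- c(sum(scale(vectors, scale = FALSE)^2),
             km_best$tot_withinss)
  lo <- apply(vectors, 2, min); hi <- apply(vectors, 2, max)
  logw_ref <- with_seed(seed, {
    sapply(seq_len(n_ref), function(b) {
      ref <- sapply(seq_along(lo), function(j) runif(n, lo[j], hi[j]))
      w1 <- sum(scale(ref, scale = FALSE)^2)
      wk <- kmeans_cluster(ref, min(k_best, n - 1L),
                           restarts = max(5L, restarts %/% 5L))$tot_withinss
      log(c(w1, wk))
    })
  })  # 2 x n_ref
  gap <- rowMeans(logw_ref) - log(w_obs)
  se <- apply(logw_ref, 1, sd) * sqrt(1 + 1 / n_ref)
  list(gap = gap, se = se)
}

#' Cluster surviving probes' temporal profiles
#'
#' Applies the significance and R-squared stringency filters to a
#' `"tc_fit"`, builds the profile feature matrix, selects the number of
#' clusters, and summarises per-cluster mean treated and control fitted
#' curves.
#'
#' @inheritParams profile_vectors
#' @inheritParams select_optimal_k
#' @param alpha global significance level for the stage-1 filter.
#' @param r2_threshold R-squared stringency tier (0.5 stringent, 0.2
#'   relaxed).
#' @param adjust p-value adjustment for the significance filter.
#' @return object of class `"tc_clusters"`: `contrast`, `k`, `labels`
#'   (named by probe, empty when k = 0), `scores`, `cluster_profiles` (per
#'   cluster mean treated/control curves), `survivors`, and the filter
#'   settings.
#' @examples
#' sim <- simulate_study(preset_ba_mimic(seed = 1, probes_per_template = 8,
#'                                       n_null_probes = 50))
#' fit <- tc_fit(sim$expr, sim$design, contrast = "ba")
#' cl <- tc_cluster(fit, k_max = 12, seed = 1)
#' print(cl)
#' @export
tc_cluster <- function(fit, alpha = 0.05, r2_threshold = 0.5,
                       adjust = c("none", "BH"),
                       feature_mode = c("fitted_difference", "fitted_both",
                                        "coefficients"),
                       k_min = 1L, k_max = 15L, restarts = 25L,
                       min_probes = 5L, min_cluster_size = 1L, seed = 1L) {
  adjust <- match.arg(adjust); feature_mode <- match.arg(feature_mode)
  survivors <- surviving_probes(fit, alpha, r2_threshold, adjust)
  V <- profile_vectors(fit, survivors, feature_mode)
  selk <- select_optimal_k(V, k_min = k_min, k_max = k_max,
                           restarts = restarts, min_probes = min_probes,
                           min_cluster_size = min_cluster_size, seed = seed)
  labels <- selk$labels %||% setNames(integer(0), character(0))
  profiles <- if (selk$k_star >= 1L && length(labels)) {
    do.call(rbind, lapply(seq_len(selk$k_star), function(cl) {
      ids <- names(labels)[labels == cl]
      data.frame(cluster = cl, day = fit$day_grid,
                 n_probes = length(ids),
                 mean_treated = colMeans(fit$profile_treated_full[ids, , drop = FALSE]),
                 mean_control = colMeans(fit$profile_control_full[ids, , drop = FALSE]),
                 row.names = NULL)
    }))
  } else data.frame(cluster = integer(), day = numeric(),
                    n_probes = integer(), mean_treated = numeric(),
                    mean_control = numeric())
  structure(list(contrast = fit$contrast, k = selk$k_star,
                 labels = labels, scores = selk$scores,
                 cluster_profiles = profiles,
                 survivors = survivors,
                 annotation = fit$annotation, day_grid = fit$day_grid,
                 settings = list(alpha = alpha, r2_threshold = r2_threshold,
                                 adjust = adjust, feature_mode = feature_mode,
                                 k_min = k_min, k_max = k_max,
                                 restarts = restarts, min_probes = min_probes,
                                 min_cluster_size = min_cluster_size,
                                 seed = seed)),
            class = "tc_clusters")
}

#' @export
print.tc_clusters <- function(x, ...) {
  cat(sprintf("profile clustering, %s vs control (alpha %.3g, R2 >= %.2f):\n",
              toupper(x$contrast), x$settings$alpha, x$settings$r2_threshold))
  if (x$k == 0L) {
    cat(sprintf("  %d surviving probe(s): below min_probes, zero clusters\n",
                length(x$survivors)))
  } else {
    cat(sprintf("  %d surviving probes in %d cluster(s); sizes: %s\n",
                length(x$labels), x$k,
                paste(tabulate(x$labels, x$k), collapse = ", ")))
  }
  invisible(x)
}

#' Plot per-cluster mean profiles
#'
#' One panel per cluster: mean treated (dashed) and control (solid) fitted
#' curves over the day grid, days on a log axis.
#'
#' @param x a `"tc_clusters"` with k >= 1.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.tc_clusters <- function(x, ...) {
  if (x$k < 1L) {
    graphics::plot.new()
    graphics::title(main = "zero clusters")
    return(invisible(x))
  }
  old <- graphics::par(mfrow = grDevices::n2mfrow(x$k),
                       mar = c(3, 3, 2, 0.5))
  on.exit(graphics::par(old))
  for (cl in seq_len(x$k)) {
    p <- x$cluster_profiles[x$cluster_profiles$cluster == cl, ]
    graphics::matplot(p$day, cbind(p$mean_control, p$mean_treated),
                      type = "b", pch = c(1, 2), lty = c(1, 2), log = "x",
                      xlab = "day", ylab = "Av. fitted expression",
                      main = sprintf("cluster %d (n = %d)", cl, p$n_probes[1]),
                      ...)
  }
  invisible(x)
}

#' Cross-contrast cluster report
#'
#' The tabular output of the clustering stage: per contrast, one row per
#' clustered probe with its gene symbol, cluster id, and a shared flag set
#' when the probe was also clustered in the other contrast (the "grey
#' square" annotation), plus per-cluster mean treated/control profile
#' summaries.
#'
#' @param ba,gh `"tc_clusters"` for the two contrasts (either may have
#'   k = 0).
#' @param annotation optional probe-to-gene map overriding the fits'.
#' @return list with `tables` (named list of data frames: `probe_id`,
#'   `gene`, `cluster`, `shared_flag`) and `profiles` (named list of
#'   per-cluster profile data frames).
#' @export
cluster_report <- function(ba, gh, annotation = NULL) {
  stopifnot(inherits(ba, "tc_clusters"), inherits(gh, "tc_clusters"))
  one <- function(x, other) {
    if (x$k == 0L || !length(x$labels))
      return(data.frame(probe_id = character(), gene = character(),
                        cluster = integer(), shared_flag = logical()))
    ids <- names(x$labels)
    ann <- annotation %||% x$annotation
    gene <- unname(ann[ids]); gene[is.na(gene)] <- ""
    d <- data.frame(probe_id = ids, gene = gene,
                    cluster = as.integer(x$labels),
                    shared_flag = ids %in% names(other$labels),
                    stringsAsFactors = FALSE)
    d[order(d$cluster, d$probe_id), , drop = FALSE]
  }
  list(tables = list(ba = one(ba, gh), gh = one(gh, ba)),
       profiles = list(ba = ba$cluster_profiles, gh = gh$cluster_profiles))
}
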