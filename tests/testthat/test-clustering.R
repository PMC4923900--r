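test_that("profile vectors are z-scored shapes, blind to scale and offset", {
  prof <- matrix(rnorm(40), 8, 5,
                 dimnames = list(paste0("p", 1:8), paste0("day_", c(1, 3, 7, 13, 27))))
  fake <- list(probe_id = rownames(prof),
               profile_control_full = prof * 0,
               profile_treated_full = prof,
               profile_control = prof * 0, profile_treated = prof,
               coefficients = NULL, coefficients_selected = NULL)
  V <- profile_vectors(fake)
  expect_equal(unname(rowMeans(V)), rep(0, 8), tolerance = 1e-12)
  expect_equal(unname(apply(V, 1, sd)), rep(1, 8), tolerance = 1e-12)

  # scale invariance: 10x the raw difference gives the identical vector
  fake10 <- fake; fake10$profile_treated_full <- prof * 10
  expect_equal(profile_vectors(fake10), V, tolerance = 1e-12)

  # identical treated and control curves map to the zero vector
  fake0 <- fake; fake0$profile_treated_full <- fake0$profile_control_full
  expect_true(all(profile_vectors(fake0) == 0))
})

test_that("seeded k-means recovers planted blobs and is deterministic", {
  bl <- make_blobs(k = 2, per = 25, sep = 8, seed = 3)
  km <- kmeans_cluster(bl$x, 2, seed = 10)
  expect_equal(adjusted_rand_index(km$labels, bl$truth), 1)
  km2 <- kmeans_cluster(bl$x, 2, seed = 10)
  expect_identical(km$labels, km2$labels)

  # k = 1: one cluster holding everything, within-SS = total SS
  km1 <- kmeans_cluster(bl$x, 1, seed = 1)
  expect_true(all(km1$labels == 1))
  expect_equal(km1$tot_withinss, sum(scale(bl$x, scale = FALSE)^2),
               tolerance = 1e-8)

  # duplicated points always co-cluster
  x <- rbind(bl$x, bl$x[1, , drop = FALSE])
  rownames(x)[nrow(x)] <- "dup"
  kmd <- kmeans_cluster(x, 2, seed = 5)
  expect_equal(unname(kmd$labels["dup"]), unname(kmd$labels[1]))

  expect_error(kmeans_cluster(bl$x[c(1, 1, 1), ], 2, seed = 1), "distinct")
})

test_that("optimal-k selection finds planted structure, one blob, and none", {
  bl <- make_blobs(k = 3, per = 20, sep = 8, seed = 6)
  sel <- select_optimal_k(bl$x, k_max = 8, seed = 2)
  expect_equal(sel$k_star, 3L)
  expect_equal(adjusted_rand_index(sel$labels, bl$truth), 1)
  expect_true(all(diff(sel$scores$k) > 0))

  # a single Gaussian blob: the gap comparison returns k = 1
  set.seed(8)
  one <- matrix(rnorm(60 * 4), 60)
  rownames(one) <- paste0("p", 1:60)
  sel1 <- select_optimal_k(one, k_max = 6, seed = 3)
  expect_equal(sel1$k_star, 1L)
  expect_true(all(sel1$labels == 1))

  # fewer than min_probes: the degenerate zero-cluster outcome
  sel0 <- select_optimal_k(one[1:3, ], min_probes = 5, seed = 1)
  expect_equal(sel0$k_star, 0L)
  expect_null(sel0$labels)
  sel00 <- select_optimal_k(one[0, ], seed = 1)
  expect_equal(sel00$k_star, 0L)
})

test_that("an extreme outlier is isolated as a singleton cluster", {
  set.seed(4)
  blob <- matrix(rnorm(40 * 5, 0, 0.5), 40)
  x <- rbind(blob, rep(25, 5))
  rownames(x) <- c(paste0("p", 1:40), "fgf21_like")
  sel <- select_optimal_k(x, k_max = 6, seed = 7)
  expect_equal(sel$k_star, 2L)
  expect_equal(sum(sel$labels == sel$labels[["fgf21_like"]]), 1L)
})

test_that("tc_cluster ties filters, selection and profiles together", {
  sim <- simulate_study(preset_ba_mimic(seed = 5, probes_per_template = 12,
                                        n_null_probes = 60))
  fit <- tc_fit(sim$expr, sim$design, contrast = "ba")
  cl <- tc_cluster(fit, r2_threshold = 0.5, k_max = 12, seed = 5)
  expect_s3_class(cl, "tc_clusters")
  expect_equal(cl$k, 9L)
  # every labelled probe passed both filters
  expect_true(all(names(cl$labels) %in%
                    surviving_probes(fit, 0.05, 0.5)))
  # cluster ids contiguous 1..k and all non-empty
  expect_identical(sort(unique(as.integer(cl$labels))), 1:cl$k)
  # per-cluster profile table covers the day grid for each cluster
  expect_equal(nrow(cl$cluster_profiles), cl$k * 5)
  sc <- recovery_score(cl, sim$truth)
  expect_gte(sc$ari, 0.9)
  # determinism of the full clustering stage
  cl2 <- tc_cluster(fit, r2_threshold = 0.5, k_max = 12, seed = 5)
  expect_identical(cl$labels, cl2$labels)
})

test_that("cluster report flags probes shared between the two contrasts", {
  mk <- function(labels, contrast) {
    structure(list(contrast = contrast, k = max(c(0L, labels)),
                   labels = labels,
                   cluster_profiles = data.frame(),
                   survivors = names(labels),
                   annotation = c(p1 = "Psat1", p2 = "", p3 = "Fgf21"),
                   settings = list(alpha = 0.05, r2_threshold = 0.5)),
              class = "tc_clusters")
  }
  ba <- mk(c(p1 = 1L, p2 = 1L, p3 = 2L), "ba")
  gh <- mk(c(p1 = 1L), "gh")
  rep_ <- cluster_report(ba, gh)
  tab <- rep_$tables$ba
  expect_identical(tab$shared_flag[match(c("p1", "p2", "p3"), tab$probe_id)],
                   c(TRUE, FALSE, FALSE))
  expect_identical(rep_$tables$gh$shared_flag, TRUE)
  expect_identical(tab$gene[match("p1", tab$probe_id)], "Psat1")

  gh0 <- mk(setNames(integer(0), character(0)), "gh")
  rep0 <- cluster_report(ba, gh0)
  expect_equal(nrow(rep0$tables$gh), 0L)
  expect_true(all(!rep0$tables$ba$shared_flag))
})

test_that("adjusted Rand index matches its definition on known cases", {
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1)), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 1), c(1, 1, 1)), 1)
  expect_lt(abs(adjusted_rand_index(rep(1:2, 50),
                                    rep(c(1, 2), each = 50))), 0.2)
  # independent cross-check against mclust where available
  if (requireNamespace("mclust", quietly = TRUE)) {
    set.seed(12)
    for (i in 1:10) {
      a <- sample(1:4, 30, TRUE); b <- sample(1:3, 30, TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
  }
})
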