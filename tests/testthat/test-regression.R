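test_that("the contrast model matrix has the maSigPro structure", {
  des <- tiny_design(r = 3)
  X <- build_design_matrix(des, degree = 2, contrast = "ba")
  expect_identical(colnames(X),
                   c("(Intercept)", "T", "T2", "grp", "grp.T", "grp.T2"))
  ctrl <- as.character(des$treatment) == "control"
  expect_true(all(X[ctrl, c("grp", "grp.T", "grp.T2")] == 0))
  expect_equal(X[, "T"], des$transformed_time)

  # full rank at the maximal degree, against an independent SVD rank oracle
  X4 <- build_design_matrix(des, degree = 4, contrast = "ba")
  sv <- svd(X4)$d
  expect_equal(sum(sv > max(dim(X4)) * .Machine$double.eps * sv[1]), ncol(X4))

  expect_error(build_design_matrix(des, degree = 5), "exceeds")
  des3 <- tiny_design(r = 2, arms = c("control", "ba", "gh"))
  expect_error(build_design_matrix(des3, contrast = "ba"), "only control")
})

test_that("fit_probe matches an independent least-squares + F-test oracle", {
  des <- tiny_design(r = 3)
  X <- build_design_matrix(des, degree = 2, contrast = "ba")
  set.seed(42)
  for (i in 1:50) {
    y <- drop(X %*% rnorm(ncol(X))) + rnorm(nrow(X), 0, runif(1, 0.1, 2))
    fit <- fit_probe(y, X)
    orc <- lm_oracle(y, X)
    expect_equal(unname(fit$coefficients), orc$coef, tolerance = 1e-8)
    expect_equal(fit$r_squared, orc$r2, tolerance = 1e-8)
    expect_equal(fit$global_p, orc$p, tolerance = 1e-8)
  }
})

test_that("fit_probe handles degenerate and exact inputs", {
  des <- tiny_design(r = 3)
  X <- build_design_matrix(des, degree = 2, contrast = "ba")
  f0 <- fit_probe(rep(4.2, nrow(X)), X)
  expect_equal(f0$r_squared, 0)
  expect_equal(f0$global_p, 1)
  beta <- c(1, 0.5, -0.2, 2, 0.3, -0.1)
  fx <- fit_probe(drop(X %*% beta), X)
  expect_equal(fx$r_squared, 1, tolerance = 1e-12)
  expect_lt(max(abs(fx$residuals)), 1e-10)
  expect_equal(unname(fx$coefficients), beta, tolerance = 1e-8)
  expect_error(fit_probe(c(NA, rnorm(nrow(X) - 1)), X), "non-finite")
  expect_error(fit_probe(rnorm(3), X), "match")
})

test_that("fitted profiles evaluate the model on the day grid per arm", {
  des <- tiny_design(r = 3)
  X <- build_design_matrix(des, degree = 2, contrast = "ba")
  beta <- c(1, 0.5, -0.2, 2, 0.3, -0.1)
  fx <- fit_probe(drop(X %*% beta), X)
  tt <- transform_times(c(1, 3, 7, 13, 27))
  expect_equal(unname(fx$fitted_profiles["control", ]),
               beta[1] + beta[2] * tt + beta[3] * tt^2, tolerance = 1e-10)
  expect_equal(unname(fx$fitted_profiles["treated", ]),
               (beta[1] + beta[4]) + (beta[2] + beta[5]) * tt +
                 (beta[3] + beta[6]) * tt^2, tolerance = 1e-10)
})

test_that("backward elimination obeys its boundary behaviours", {
  des <- tiny_design(r = 3)
  X <- build_design_matrix(des, degree = 2, contrast = "ba")
  set.seed(9)
  y <- rnorm(nrow(X))
  full <- fit_probe(y, X)
  kept_all <- stepwise_select(full, y, X, alpha_step = 1)
  expect_identical(kept_all$selected_terms, colnames(X))
  kept_none <- stepwise_select(full, y, X, alpha_step = 1e-12)
  expect_identical(kept_none$selected_terms, "(Intercept)")
  expect_equal(kept_none$r_squared, 0, tolerance = 1e-12)
})

test_that("a strong group-by-time interaction survives stepwise selection", {
  des <- tiny_design(r = 10)
  X <- build_design_matrix(des, degree = 2, contrast = "ba")
  set.seed(31)
  kept <- replicate(100, {
    y <- 5 + 10 * X[, "grp.T"] + rnorm(nrow(X))   # effect 10x noise sd
    f <- stepwise_select(fit_probe(y, X), y, X, alpha_step = 0.05)
    "grp.T" %in% f$selected_terms
  })
  expect_gte(mean(kept), 0.99)
})

test_that("vectorised tc_fit agrees with the single-probe path", {
  sim <- simulate_study(preset_ba_mimic(seed = 4, probes_per_template = 2,
                                        n_null_probes = 10))
  fit <- tc_fit(sim$expr, sim$design, contrast = "ba")
  des <- fit$design
  X <- build_design_matrix(des, degree = 2, contrast = "ba")
  for (p in sample(fit$probe_id, 8)) {
    y <- fit$y[p, ]
    single <- stepwise_select(fit_probe(y, X, p), y, X, alpha_step = 0.05)
    expect_equal(unname(fit$global_p[p]), fit_probe(y, X)$global_p,
                 tolerance = 1e-10)
    expect_equal(unname(fit$r_squared[p]), single$r_squared,
                 tolerance = 1e-10)
    expect_identical(colnames(fit$selected)[fit$selected[
      match(p, fit$probe_id), ]], single$selected_terms)
    expect_equal(fit$profile_treated[p, ],
                 single$fitted_profiles["treated", ], tolerance = 1e-10)
  }
})

test_that("significance filter uses a strict boundary and optional BH", {
  fake <- list(global_p = c(a = 0.049, b = 0.050, c = 0.051, d = 0.20))
  expect_identical(significant_probes(fake, 0.05), "a")
  expect_identical(significant_probes(list(global_p = setNames(
    numeric(0), character(0))), 0.05), character(0))
  # BH adjustment is monotone: never admits more probes than raw p
  set.seed(2)
  fake2 <- list(global_p = setNames(runif(100), paste0("p", 1:100)))
  expect_true(all(significant_probes(fake2, 0.05, adjust = "BH") %in%
                    significant_probes(fake2, 0.05)))
})

test_that("R2 stringency boundary is inclusive and antitone in the tier", {
  fake <- list(r_squared = c(a = 0.50, b = 0.49, c = 0.95, d = 0.20))
  expect_identical(r2_filter(fake, 0.5), c("a", "c"))
  expect_true(all(r2_filter(fake, 0.5) %in% r2_filter(fake, 0.2)))
  expect_identical(r2_filter(fake, 0), names(fake$r_squared))
  expect_error(r2_filter(fake, 1.5), "\\[0, 1\\]")
})

test_that("noisier data yield weakly fewer survivors at fixed thresholds", {
  wheel <- profclust:::template_wheel(4)
  mk <- function(noise) {
    tpl <- lapply(1:4, function(j) list(multipliers = wheel[, j],
                                        n_probes = 20, affected = "ba",
                                        amplitude = 0.8))
    names(tpl) <- colnames(wheel)
    sim <- simulate_study(study_config(templates = tpl, n_null_probes = 50,
                                       noise_sd = noise, seed = 13))
    fit <- tc_fit(sim$expr, sim$design, contrast = "ba")
    length(surviving_probes(fit, 0.05, 0.5))
  }
  counts <- vapply(c(0.15, 0.35, 0.8), mk, 0)
  expect_true(all(diff(counts) <= 0))
  expect_gt(counts[1], counts[3])
})

test_that("cluster features are invariant to the log base of time", {
  sim <- simulate_study(preset_ba_mimic(seed = 6, probes_per_template = 3,
                                        n_null_probes = 10))
  des10 <- study_design(sim$design$sample_id,
                        as.character(sim$design$treatment),
                        sim$design$day, sim$design$batch, log_base = 10)
  fit_e <- tc_fit(sim$expr, sim$design, contrast = "ba", step = FALSE)
  fit_10 <- tc_fit(sim$expr, des10, contrast = "ba", step = FALSE)
  expect_equal(profile_vectors(fit_e), profile_vectors(fit_10),
               tolerance = 1e-8)
  expect_equal(fit_e$global_p, fit_10$global_p, tolerance = 1e-10)
})
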