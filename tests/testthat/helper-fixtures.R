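# shared fixture builders and independent oracles, all generated in code

# minimal balanced two-arm design over the default grid, r replicates/day
tiny_design <- function(r = 3, arms = c("control", "ba"),
                        days = c(1, 3, 7, 13, 27)) {
  grid <- expand.grid(rep = seq_len(r), day = days, arm = arms,
                      stringsAsFactors = FALSE)
  study_design(sample_id = sprintf("s_%s_d%02d_r%d", grid$arm, grid$day,
                                   grid$rep),
               treatment = grid$arm, day = grid$day,
               batch = ((grid$rep - 1) %% 2) + 1,
               day_grid = days)
}

# brute-force OLS + F-test oracle via stats::lm, independent of fit_probe
lm_oracle <- function(y, X) {
  d <- as.data.frame(X[, -1, drop = FALSE])
  names(d) <- paste0("x", seq_len(ncol(d)))
  d$y <- y
  f <- lm(y ~ ., data = d)
  f0 <- lm(y ~ 1, data = d)
  a <- anova(f0, f)
  list(coef = unname(coef(f)), r2 = summary(f)$r.squared,
       p = a$`Pr(>F)`[2], fstat = a$F[2])
}

# well-separated Gaussian blobs for clustering tests
make_blobs <- function(k, per, dim = 5, sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- matrix(rnorm(k * dim), k) * sep
  x <- centers[rep(seq_len(k), each = per), ] +
    matrix(rnorm(k * per * dim, 0, sd), k * per)
  rownames(x) <- sprintf("pt%03d", seq_len(nrow(x)))
  list(x = x, truth = rep(seq_len(k), each = per))
}

# exhaustive permutation p-value of the Welch statistic for two small groups
perm_welch_p <- function(a, b) {
  nab <- c(a, b)
  n1 <- length(a)
  idx <- utils::combn(length(nab), n1)
  tobs <- abs(welch_stat(a, b))
  tall <- apply(idx, 2, function(ii) abs(welch_stat(nab[ii], nab[-ii])))
  mean(tall >= tobs - 1e-12)
}

welch_stat <- function(a, b) {
  (mean(a) - mean(b)) / sqrt(var(a) / length(a) + var(b) / length(b))
}

# projection-based sequential sums of squares, independent of stats::anova
seq_ss_oracle <- function(y, terms) {
  # terms: named list of model matrices added in order (after intercept)
  n <- length(y)
  X <- matrix(1, n, 1)
  rss_prev <- sum(lm.fit(X, y)$residuals^2)
  out <- numeric(length(terms))
  for (i in seq_along(terms)) {
    X <- cbind(X, terms[[i]])
    rss <- sum(lm.fit(X, y)$residuals^2)
    out[i] <- rss_prev - rss
    rss_prev <- rss
  }
  names(out) <- names(terms)
  c(out, residual = rss_prev)
}
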