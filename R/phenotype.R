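#' Two-way ANOVA with batch blocking
#'
#' The phenotype-layer model: an additive block term for batch, then
#' treatment, time, and their interaction, fitted by least squares with
#' sequential (type I) sums of squares and F-tests against the residual
#' mean square.  Batch enters first, so a constant shift of any one batch
#' is absorbed by the block term and leaves treatment and interaction
#' F-statistics unchanged.
#'
#' @param values numeric response vector (one observation per animal).
#' @param treatment,time,batch factors (or coercible) of the same length.
#' @return object of class `"anova_result"`: `table` (term, df, sum_sq,
#'   mean_sq, statistic, p), `mse`, `df_residual`, `group_means`
#'   (treatment), `cell_means` (treatment x time), `sed` (per treatment
#'   pair, from the pooled residual mean square).
#' @export
two_way_anova_blocked <- function(values, treatment, time, batch) {
  treatment <- factor(treatment); time <- factor(time); batch <- factor(batch)
  if (length(unique(treatment)) < 2L || length(unique(time)) < 2L)
    stop_input("need >= 2 treatment and >= 2 time levels")
  cell <- table(treatment, time)
  if (any(cell < 2L)) {
    i <- which(cell < 2L, arr.ind = TRUE)[1, ]
    stop_input("treatment x time cell '%s' x '%s' has %d observation(s); need >= 2",
               rownames(cell)[i[1]], colnames(cell)[i[2]], cell[i[1], i[2]])
  }
  fit <- lm(values ~ batch + treatment * time)
  anova_result(fit, values, treatment, time)
}

#' One-way ANOVA
#'
#' Standard between/within decomposition for a single grouping factor.
#'
#' @param values numeric response vector.
#' @param group grouping factor with >= 2 levels, >= 2 observations each.
#' @return an `"anova_result"`; see [two_way_anova_blocked()].
#' @export
one_way_anova <- function(values, group) {
  group <- factor(group)
  if (nlevels(droplevels(group)) < 2L)
    stop_input("one-way ANOVA needs at least 2 groups")
  if (any(table(group) < 2L))
    stop_input("every group needs >= 2 observations")
  fit <- lm(values ~ group)
  anova_result(fit, values, group, NULL)
}

anova_result <- function(fit, values, treatment, time) {
  a <- anova(fit)
  tab <- data.frame(term = rownames(a), df = a$Df, sum_sq = a$`Sum Sq`,
                    mean_sq = a$`Mean Sq`, statistic = a$`F value`,
                    p = a$`Pr(>F)`, row.names = NULL,
                    stringsAsFactors = FALSE)
  mse <- tab$mean_sq[tab$term == "Residuals"]
  dfres <- tab$df[tab$term == "Residuals"]
  gm <- tapply(values, treatment, mean)
  ns <- table(treatment)
  lev <- names(gm)
  prs <- if (length(lev) > 1) t(utils::combn(lev, 2)) else
    matrix(character(), 0, 2)
  seds <- apply(prs, 1, function(pr)
    sed(mse, ns[[pr[1]]], ns[[pr[2]]]))
  sed_tab <- data.frame(group1 = prs[, 1], group2 = prs[, 2],
                        sed = as.numeric(seds), stringsAsFactors = FALSE)
  cm <- if (!is.null(time)) tapply(values, list(treatment, time), mean) else NULL
  structure(list(table = tab, mse = mse, df_residual = dfres,
                 group_means = gm, cell_means = cm, sed = sed_tab,
                 fit = fit),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  tab <- x$table
  tab$p <- format.pval(tab$p, digits = 3)
  print(tab, row.names = FALSE)
  cat(sprintf("residual MSE: %.4g on %d df\n", x$mse, x$df_residual))
  if (nrow(x$sed))
    cat("SED:", paste(sprintf("%s-%s %.3g", x$sed$group1, x$sed$group2,
                              x$sed$sed), collapse = ", "), "\n")
  invisible(x)
}

#' Standard error of a difference between two group means
#'
#' `sqrt(mse * (1/n1 + 1/n2))` under a pooled residual variance; the
#' precision attached to pairwise treatment-mean comparisons.
#'
#' @param mse pooled residual mean square (>= 0).
#' @param n1,n2 group sizes (>= 1).
#' @return the SED, in the units of the response.
#' @examples
#' sed(2, 10, 10)   # 0.6325
#' @export
sed <- function(mse, n1, n2) {
  if (mse < 0) stop_input("mse must be >= 0")
  if (n1 < 1 || n2 < 1) stop_input("group sizes must be >= 1")
  sqrt(mse * (1 / n1 + 1 / n2))
}

#' Dunnett many-to-one comparisons by Monte-Carlo max-|t|
#'
#' Compares every treatment group mean against the control using the joint
#' null distribution of the correlated t statistics: for each comparison
#' `t_i = (mean_i - mean_0) / sqrt(mse (1/n_i + 1/n_0))`, the adjusted p
#' is `P(max_j |T_j| >= |t_i|)` under the null, estimated by seeded
#' Monte-Carlo simulation of the max-|t| distribution (group means drawn
#' normal, residual variance drawn scaled chi-squared).  Simulation covers
#' balanced and unbalanced designs alike, which matters here because the
#' emulated study has a larger day-27 cohort.
#'
#' @param values numeric response vector.
#' @param group grouping factor; must contain `control_label`.
#' @param control_label level treated as control (default `"control"`).
#' @param alpha family-wise level for the `significant` column.
#' @param n_sim Monte-Carlo draws of the max-|t| null.
#' @param seed integer seed for the draws.
#' @return data frame of class `"dunnett_result"`: `comparison`,
#'   `estimate`, `se`, `statistic`, `p_unadjusted` (two-sided two-sample t
#'   with pooled variance), `p_adjusted`, `significant`; attributes `mse`,
#'   `df`, `n_sim`.
#' @export
dunnett_test <- function(values, group, control_label = "control",
                         alpha = 0.05, n_sim = 1e5, seed = 1L) {
  group <- factor(group)
  if (!control_label %in% levels(group))
    stop_input("control label '%s' not found among groups (%s)",
               control_label, paste(levels(group), collapse = ", "))
  if (nlevels(group) < 2L)
    stop_input("need the control plus at least one treatment group")
  ns <- table(group)
  if (any(ns < 2L)) stop_input("every group needs >= 2 observations")
  means <- tapply(values, group, mean)
  n <- length(values); kg <- nlevels(group)
  dfres <- n - kg
  mse <- sum(tapply(values, group, function(v) sum((v - mean(v))^2))) / dfres
  trt <- setdiff(levels(group), control_label)
  n0 <- ns[[control_label]]
  se_i <- sqrt(mse * (1 / ns[trt] + 1 / n0))
  est <- means[trt] - means[[control_label]]
  tstat <- est / se_i
  p_un <- 2 * pt(abs(tstat), dfres, lower.tail = FALSE)

  # null draws of max-|t| with the same correlation structure
  maxt <- with_seed(seed, {
    z0 <- rnorm(n_sim, 0, sqrt(1 / n0))
    s2 <- rchisq(n_sim, dfres) / dfres
    mt <- rep(0, n_sim)
    for (g in trt) {
      zg <- rnorm(n_sim, 0, sqrt(1 / ns[[g]]))
      tg <- abs(zg - z0) / sqrt(s2 * (1 / ns[[g]] + 1 / n0))
      mt <- pmax(mt, tg)
    }
    mt
  })
  p_adj <- vapply(abs(tstat), function(tt) mean(maxt >= tt), 0)
  p_adj <- pmax(p_adj, p_un)   # adjustment can never be anti-conservative
  out <- data.frame(comparison = paste(trt, "-", control_label),
                    estimate = as.numeric(est), se = as.numeric(se_i),
                    statistic = as.numeric(tstat),
                    p_unadjusted = as.numeric(p_un),
                    p_adjusted = as.numeric(p_adj),
                    significant = as.numeric(p_adj) < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "mse") <- mse; attr(out, "df") <- dfres
  attr(out, "n_sim") <- n_sim
  class(out) <- c("dunnett_result", "data.frame")
  out
}

#' Phenotype statistics for one response column
#'
#' The study's analysis recipe for a growth/phenotype trait: batch-blocked
#' two-way ANOVA (treatment, time, interaction), and Dunnett many-to-one
#' comparisons of treatment means against control, gated on the
#' interaction being non-significant ("auto"), always run, or skipped.
#'
#' @param data data frame with columns `batch`, `treatment`, `day` and the
#'   response.
#' @param response name of the response column.
#' @param dunnett `"auto"` (run unless the treatment:time interaction has
#'   p < alpha), `"always"`, or `"never"`.
#' @param alpha significance level used for the gate and the comparisons.
#' @param seed passed to [dunnett_test()].
#' @return list with `anova` (an `"anova_result"`), `dunnett` (a
#'   `"dunnett_result"` or `NULL`), and `dunnett_run` (logical).
#' @export
phenotype_stats <- function(data, response, dunnett = c("auto", "always",
                                                        "never"),
                            alpha = 0.05, seed = 1L) {
  dunnett <- match.arg(dunnett)
  need <- c("batch", "treatment", "day", response)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop_input("missing column(s): %s",
                               paste(miss, collapse = ", "))
  y <- data[[response]]
  an <- two_way_anova_blocked(y, data$treatment, data$day, data$batch)
  inter_p <- an$table$p[grepl(":", an$table$term)][1]
  run <- switch(dunnett, always = TRUE, never = FALSE,
                auto = !is.na(inter_p) && inter_p >= alpha)
  dn <- if (run) dunnett_test(y, normalise_label(data$treatment),
                              control_label = "control", alpha = alpha,
                              seed = seed) else NULL
  list(anova = an, dunnett = dn, dunnett_run = run)
}
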