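#' Model matrix for a single treatment-versus-control contrast
#'
#' maSigPro-style single-series parameterisation: a polynomial of the given
#' degree in transformed time shared by both arms, a treated-group
#' indicator, and group-by-time interaction terms up to the same degree.
#' Control samples carry zeros in all group columns, so the group terms
#' parameterise the treated-minus-control difference curve directly.
#'
#' @param design a `"study_design"` containing only control samples and the
#'   contrast arm.
#' @param degree polynomial degree in transformed time (>= 1 and at most
#'   number of distinct days - 1).
#' @param contrast `"ba"` or `"gh"`; which arm the group terms encode.
#' @return numeric matrix with named columns `(Intercept)`, `T`, ...,
#'   `T<degree>`, `grp`, `grp.T`, ..., `grp.T<degree>`, with attributes
#'   `day_grid`, `tt_grid`, `degree`, `contrast`.  Errors if the matrix is
#'   column rank deficient, naming the collinear terms.
#' @export
build_design_matrix <- function(design, degree = 2L,
                                contrast = c("ba", "gh")) {
  contrast <- normalise_label(match.arg(contrast))
  arms <- unique(as.character(design$treatment))
  extra <- setdiff(arms, c("control", contrast))
  if (length(extra))
    stop_input("design must contain only control and '%s' samples (found: %s)",
               contrast, paste(extra, collapse = ", "))
  days <- sort(unique(design$day))
  if (!is_count(degree) || degree < 1L)
    stop_input("degree must be a positive integer")
  if (degree > length(days) - 1L)
    stop_input("degree %d exceeds distinct time points - 1 (= %d)",
               degree, length(days) - 1L)
  tt <- design$transformed_time
  grp <- as.numeric(as.character(design$treatment) == contrast)
  Xt <- sapply(seq_len(degree), function(m) tt^m)
  X <- cbind(1, Xt, grp, grp * Xt)
  tnames <- c("T", if (degree > 1) paste0("T", 2:degree))
  colnames(X) <- c("(Intercept)", tnames, "grp", paste0("grp.", tnames))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_input("model matrix is rank deficient; collinear term(s): %s",
               paste(dropped, collapse = ", "))
  }
  structure(X, day_grid = days,
            tt_grid = tt[match(days, design$day)],
            degree = degree, contrast = contrast)
}

# rows of the model matrix evaluated at the grid days for one arm, on the
# same transformed-time scale the matrix was built with
grid_rows <- function(X, treated) {
  degree <- attr(X, "degree")
  tt <- attr(X, "tt_grid")
  Xt <- sapply(seq_len(degree), function(m) tt^m)
  G <- cbind(1, Xt, treated, treated * Xt)
  colnames(G) <- colnames(X)
  G
}

#' Fit the full polynomial model to one probe
#'
#' Ordinary least squares of a single probe's values on a model matrix from
#' [build_design_matrix()], with the global F-test of the full model
#' against intercept-only and the fitted per-arm profiles at the grid days.
#'
#' @param y numeric vector of per-sample log-intensities.
#' @param X model matrix from [build_design_matrix()].
#' @param probe_id optional id carried into the result.
#' @return object of class `"probe_fit"`: coefficients, `global_p`,
#'   `r_squared`, `selected_terms` (all terms at this stage),
#'   `fitted_profiles` (2 x days matrix, rows control/treated), `df_residual`.
#' @export
fit_probe <- function(y, X, probe_id = NA_character_) {
  if (length(y) != nrow(X))
    stop_input("length of y (%d) does not match rows of X (%d)",
               length(y), nrow(X))
  if (any(!is.finite(y)))
    stop_input("non-finite values in y; filter probes upstream")
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  beta <- qr.coef(qrX, y)
  res <- y - drop(X %*% beta)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  if (tss <= .Machine$double.eps * n) {
    r2 <- 0; pval <- 1
  } else {
    r2 <- 1 - rss / tss
    f <- ((tss - rss) / (p - 1)) / (rss / (n - p))
    pval <- pf(f, p - 1, n - p, lower.tail = FALSE)
  }
  prof <- rbind(control = drop(grid_rows(X, 0) %*% beta),
                treated = drop(grid_rows(X, 1) %*% beta))
  colnames(prof) <- paste0("day_", attr(X, "day_grid"))
  structure(list(probe_id = probe_id, coefficients = beta,
                 global_p = pval, r_squared = r2,
                 selected_terms = colnames(X),
                 fitted_profiles = prof,
                 df_residual = n - p, residuals = res),
            class = "probe_fit")
}

#' @export
print.probe_fit <- function(x, ...) {
  cat(sprintf("probe fit%s: global p = %.3g, R2 = %.3f, terms: %s\n",
              if (is.na(x$probe_id)) "" else paste0(" ", x$probe_id),
              x$global_p, x$r_squared,
              paste(x$selected_terms, collapse = " ")))
  invisible(x)
}

#' Backward stepwise reduction of a probe fit
#'
#' Iteratively refits after dropping the non-intercept term with the
#' largest p-value above `alpha_step`, until every remaining term is
#' individually significant at `alpha_step` (or only the intercept is
#' left).  The reported R-squared is that of the final reduced model.
#'
#' @param fit a `"probe_fit"` from [fit_probe()] on `X` (its `residuals`
#'   element is not needed, only the data via `y`).
#' @param y the probe's values used for `fit`.
#' @param X the model matrix used for `fit`.
#' @param alpha_step per-term inclusion level.
#' @return the `"probe_fit"` with `selected_terms`, `coefficients` (reduced
#'   model, dropped terms absent), `r_squared` and `fitted_profiles`
#'   updated; `global_p` is unchanged (it belongs to the stage-1 filter).
#' @export
stepwise_select <- function(fit, y, X, alpha_step = 0.05) {
  sel <- stepwise_engine(matrix(y, nrow = 1), X, alpha_step)
  keep <- sel$active[1, ]
  Xs <- X[, keep, drop = FALSE]
  beta <- qr.coef(qr(Xs), y)
  fit$selected_terms <- colnames(X)[keep]
  fit$coefficients <- beta
  fit$r_squared <- sel$r2[1]
  prof <- rbind(control = drop(grid_rows(X, 0)[, keep, drop = FALSE] %*% beta),
                treated = drop(grid_rows(X, 1)[, keep, drop = FALSE] %*% beta))
  colnames(prof) <- paste0("day_", attr(X, "day_grid"))
  fit$fitted_profiles <- prof
  fit
}

# vectorised backward elimination for all probes sharing one model matrix.
# Probes are processed in groups sharing the same active term set, so each
# iteration costs a handful of QR decompositions regardless of probe count.
stepwise_engine <- function(Y, X, alpha_step) {
  np <- nrow(Y); n <- nrow(X); p <- ncol(X)
  active <- matrix(TRUE, np, p, dimnames = list(NULL, colnames(X)))
  done <- rep(FALSE, np)
  tss <- rowSums((Y - rowMeans(Y))^2)
  r2 <- rep(0, np)
  while (!all(done)) {
    undone <- which(!done)
    patterns <- apply(active[undone, , drop = FALSE], 1, paste, collapse = "")
    for (pat in unique(patterns)) {
      rows <- undone[patterns == pat]
      keep <- active[rows[1], ]
      Xs <- X[, keep, drop = FALSE]
      k <- ncol(Xs)
      qrX <- qr(Xs)
      B <- qr.coef(qrX, t(Y[rows, , drop = FALSE]))      # k x length(rows)
      B <- matrix(B, nrow = k)
      R <- t(Y[rows, , drop = FALSE]) - Xs %*% B
      rss <- colSums(R^2)
      if (k >= n) stop_input("saturated model in stepwise (k >= n)")
      sigma2 <- rss / (n - k)
      XtXi <- chol2inv(chol(crossprod(Xs)))
      se <- sqrt(outer(diag(XtXi), sigma2))               # k x length(rows)
      tval <- B / se
      pv <- 2 * pt(abs(tval), df = n - k, lower.tail = FALSE)
      nonint <- which(colnames(Xs) != "(Intercept)")
      r2[rows] <- ifelse(tss[rows] > 0, 1 - rss / tss[rows], 0)
      if (!length(nonint)) { done[rows] <- TRUE; next }
      pn <- pv[nonint, , drop = FALSE]
      worst <- apply(pn, 2, which.max)
      worst_p <- pn[cbind(worst, seq_along(rows))]
      finished <- worst_p <= alpha_step | !is.finite(worst_p)
      done[rows[finished]] <- TRUE
      if (any(!finished)) {
        drop_term <- colnames(Xs)[nonint[worst[!finished]]]
        active[cbind(rows[!finished], match(drop_term, colnames(X)))] <- FALSE
      }
    }
  }
  list(active = active, r2 = r2)
}

#' Two-stage regression over all probes of one contrast
#'
#' Stage 1 fits the full polynomial model to every probe by shared-QR least
#' squares and records the global F-test p-value.  Stage 2 applies backward
#' stepwise term selection per probe and recomputes R-squared and fitted
#' profiles under the reduced model.  Control samples are reused across
#' contrasts; each contrast is fitted on its own two-arm subset.
#'
#' @param expr an `"expr_set"` (or probes x samples matrix).
#' @param design a `"study_design"` covering the expression samples; arms
#'   other than control and `contrast` are dropped.
#' @param contrast `"ba"` or `"gh"`.
#' @param degree polynomial degree in transformed time (default 2).
#' @param alpha_step stepwise per-term inclusion level.
#' @param step run stage-2 stepwise selection (default TRUE).
#' @return object of class `"tc_fit"` with per-probe vectors `global_p`,
#'   `r_squared` (selected model), `r_squared_full`, logical term matrix
#'   `selected`, full- and selected-model coefficients, fitted per-arm
#'   profile matrices at the grid days, and the inputs needed by the
#'   clustering stage.
#' @examples
#' sim <- simulate_study(preset_ba_mimic(seed = 1, probes_per_template = 5,
#'                                       n_null_probes = 20))
#' fit <- tc_fit(sim$expr, sim$design, contrast = "ba")
#' summary(fit)
#' @export
tc_fit <- function(expr, design, contrast = c("ba", "gh"), degree = 2L,
                   alpha_step = 0.05, step = TRUE) {
  contrast <- normalise_label(match.arg(normalise_label(contrast[1]),
                                        c("ba", "gh")))
  if (inherits(expr, "expr_set")) {
    annotation <- expr$annotation
    Y <- expr$values
  } else {
    Y <- as.matrix(expr)
    annotation <- setNames(rep("", nrow(Y)), rownames(Y))
  }
  design <- match_design(list(values = Y), design)
  keep <- as.character(design$treatment) %in% c("control", contrast)
  design <- design[keep, , drop = FALSE]
  Y <- Y[, design$sample_id, drop = FALSE]
  X <- build_design_matrix(design, degree = degree, contrast = contrast)
  n <- nrow(X); p <- ncol(X)
  qrX <- qr(X)
  B <- qr.coef(qrX, t(Y))                       # p x np
  Fit <- X %*% B
  rss <- colSums((t(Y) - Fit)^2)
  tss <- rowSums((Y - rowMeans(Y))^2)
  ok <- tss > .Machine$double.eps * n
  r2_full <- ifelse(ok, 1 - rss / tss, 0)
  fstat <- ((tss - rss) / (p - 1)) / (rss / (n - p))
  global_p <- ifelse(ok, pf(fstat, p - 1, n - p, lower.tail = FALSE), 1)

  if (step) {
    sel <- stepwise_engine(Y, X, alpha_step)
    active <- sel$active
    r2_sel <- ifelse(ok, sel$r2, 0)
  } else {
    active <- matrix(TRUE, nrow(Y), p, dimnames = list(NULL, colnames(X)))
    r2_sel <- r2_full
  }
  # selected-model coefficients and fitted grid profiles, grouped by pattern
  Bsel <- matrix(0, p, nrow(Y), dimnames = list(colnames(X), rownames(Y)))
  G0 <- grid_rows(X, 0); G1 <- grid_rows(X, 1)
  prof_c_full <- t(G0 %*% B); prof_t_full <- t(G1 %*% B)
  dimnames(prof_c_full) <- dimnames(prof_t_full) <-
    list(rownames(Y), paste0("day_", attr(X, "day_grid")))
  prof_c <- prof_t <- matrix(NA_real_, nrow(Y), nrow(G0),
                             dimnames = list(rownames(Y),
                                             paste0("day_", attr(X, "day_grid"))))
  pats <- apply(active, 1, paste, collapse = "")
  for (pat in unique(pats)) {
    rows <- which(pats == pat)
    kp <- active[rows[1], ]
    Xs <- X[, kp, drop = FALSE]
    Bs <- matrix(qr.coef(qr(Xs), t(Y[rows, , drop = FALSE])), ncol = length(rows))
    Bsel[kp, rows] <- Bs
    prof_c[rows, ] <- t(G0[, kp, drop = FALSE] %*% Bs)
    prof_t[rows, ] <- t(G1[, kp, drop = FALSE] %*% Bs)
  }
  structure(list(probe_id = rownames(Y), contrast = contrast,
                 degree = degree, alpha_step = alpha_step, step = step,
                 global_p = setNames(global_p, rownames(Y)),
                 r_squared = setNames(r2_sel, rownames(Y)),
                 r_squared_full = setNames(r2_full, rownames(Y)),
                 selected = active,
                 coefficients = t(B),
                 coefficients_selected = t(Bsel),
                 profile_control = prof_c, profile_treated = prof_t,
                 profile_control_full = prof_c_full,
                 profile_treated_full = prof_t_full,
                 day_grid = attr(X, "day_grid"),
                 annotation = annotation,
                 design = design, y = Y, model_matrix = X),
            class = "tc_fit")
}

#' @export
print.tc_fit <- function(x, ...) {
  cat(sprintf("time-course fit: %d probes, contrast %s vs control, degree %d\n",
              length(x$probe_id), toupper(x$contrast), x$degree))
  cat(sprintf("  global p < 0.05: %d probes; selected-model R2 >= 0.5: %d; >= 0.2: %d\n",
              sum(x$global_p < 0.05), sum(x$r_squared >= 0.5),
              sum(x$r_squared >= 0.2)))
  invisible(x)
}

#' @export
summary.tc_fit <- function(object, ...) {
  d <- data.frame(probe_id = object$probe_id,
                  gene = object$annotation[object$probe_id],
                  global_p = object$global_p,
                  r_squared = object$r_squared,
                  n_terms = rowSums(object$selected),
                  row.names = NULL, stringsAsFactors = FALSE)
  d$gene[is.na(d$gene)] <- ""
  d[order(d$global_p, d$probe_id), ]
}

#' @export
coef.tc_fit <- function(object, model = c("full", "selected"), ...) {
  switch(match.arg(model), full = object$coefficients,
         selected = object$coefficients_selected)
}

#' @export
fitted.tc_fit <- function(object, ...) {
  t(object$model_matrix %*% t(object$coefficients))
}

#' @export
residuals.tc_fit <- function(object, ...) {
  object$y - fitted(object)
}

#' Predict fitted arm profiles at chosen days
#'
#' @param object a `"tc_fit"`.
#' @param days days to evaluate at (default: the study grid).
#' @param model use the stepwise-selected or the full model.
#' @param ... unused.
#' @return list with `control` and `treated` probes-x-days matrices.
#' @export
predict.tc_fit <- function(object, days = object$day_grid,
                           model = c("selected", "full"), ...) {
  model <- match.arg(model)
  tt <- transform_times(days)
  Xt <- sapply(seq_len(object$degree), function(m) tt^m)
  G0 <- cbind(1, Xt, 0, 0 * Xt)
  G1 <- cbind(1, Xt, 1, Xt)
  B <- t(switch(model, selected = object$coefficients_selected,
                full = object$coefficients))
  nm <- paste0("day_", days)
  list(control = structure(t(G0 %*% B), dimnames = list(object$probe_id, nm)),
       treated = structure(t(G1 %*% B), dimnames = list(object$probe_id, nm)))
}

#' Probes passing the global significance filter
#'
#' Strict inequality `p < alpha`, optionally after Benjamini-Hochberg
#' adjustment (the original maSigPro default; raw p is this package's
#' default, matching a plain `p < 0.05` ANOVA filter).
#'
#' @param fit a `"tc_fit"`.
#' @param alpha significance level.
#' @param adjust `"none"` (raw p) or `"BH"`.
#' @return character vector of probe ids.
#' @export
significant_probes <- function(fit, alpha = 0.05, adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  p <- fit$global_p
  if (adjust == "BH") p <- stats::p.adjust(p, "BH")
  names(p)[p < alpha]
}

#' Probes meeting the R-squared stringency tier
#'
#' Inclusive boundary: a probe with R-squared exactly at the threshold is
#' retained.
#'
#' @param fit a `"tc_fit"` (stage-2 R-squared is used).
#' @param r2_threshold stringency tier in `[0, 1]` (study tiers: 0.5, 0.2).
#' @return character vector of probe ids.
#' @export
r2_filter <- function(fit, r2_threshold = 0.5) {
  if (r2_threshold < 0 || r2_threshold > 1)
    stop_input("r2_threshold must lie in [0, 1]")
  names(fit$r_squared)[fit$r_squared >= r2_threshold]
}

#' Probes surviving both filters
#'
#' @inheritParams significant_probes
#' @inheritParams r2_filter
#' @return character vector of probe ids passing `global_p < alpha` and
#'   `r_squared >= r2_threshold`.
#' @export
surviving_probes <- function(fit, alpha = 0.05, r2_threshold = 0.5,
                             adjust = c("none", "BH")) {
  intersect(significant_probes(fit, alpha, match.arg(adjust)),
            r2_filter(fit, r2_threshold))
}

#' Per-probe fit table
#'
#' The stage-1/stage-2 results in exportable form: one row per probe with
#' the global p, selected terms, selected-model R-squared and the fitted
#' per-arm values at each grid day.
#'
#' @param fit a `"tc_fit"`.
#' @return data frame.
#' @export
fit_table <- function(fit) {
  terms <- apply(fit$selected, 1, function(s)
    paste(colnames(fit$selected)[s], collapse = "+"))
  d <- data.frame(probe_id = fit$probe_id,
                  gene = unname(fit$annotation[fit$probe_id]),
                  global_p = unname(fit$global_p),
                  selected_terms = terms,
                  r_squared = unname(fit$r_squared),
                  stringsAsFactors = FALSE)
  d$gene[is.na(d$gene)] <- ""
  fc <- fit$profile_control; ft <- fit$profile_treated
  colnames(fc) <- paste0("control_", colnames(fc))
  colnames(ft) <- paste0("treated_", colnames(ft))
  cbind(d, fc, ft, row.names = NULL)
}
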