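#' Per-time-point differential expression (Welch t-test)
#'
#' Compares one treatment arm against control at a single sampling day,
#' probe by probe, with a two-sided Welch (unequal-variance) t-test.
#' Probes for which the test is undefined (zero variance in both groups)
#' get p = 1 (never significant) and a warning is issued once.
#'
#' @param expr an `"expr_set"` or probes x samples matrix.
#' @param design a `"study_design"`.
#' @param day the sampling day to test at.
#' @param contrast `"ba"` or `"gh"`.
#' @param alpha significance level for the `significant` column.
#' @return data frame of class `"de_table"`: `probe_id`, `effect` (treated
#'   minus control mean, log-intensity units), `p`, `rank` (ascending p,
#'   ties broken by probe id), `significant` (`p < alpha`).  Attributes
#'   `day`, `contrast`, `alpha`.
#' @export
per_time_de <- function(expr, design, day, contrast = c("ba", "gh"),
                        alpha = 0.05) {
  contrast <- normalise_label(match.arg(normalise_label(contrast[1]),
                                        c("ba", "gh")))
  Y <- if (inherits(expr, "expr_set")) expr$values else as.matrix(expr)
  design <- match_design(list(values = Y), design)
  trt <- as.character(design$treatment)
  i1 <- which(design$day == day & trt == contrast)
  i0 <- which(design$day == day & trt == "control")
  if (length(i1) < 2L || length(i0) < 2L)
    stop_input("need >= 2 samples per group at day %s (have %d treated, %d control)",
               format(day), length(i1), length(i0))
  w <- welch_rows(Y[, i1, drop = FALSE], Y[, i0, drop = FALSE])
  if (any(w$undefined))
    warning(sprintf("%d probe(s) with zero variance in both groups at day %s: returned non-significant",
                    sum(w$undefined), format(day)), call. = FALSE)
  ord <- order(w$p, rownames(Y))
  rank <- integer(nrow(Y)); rank[ord] <- seq_len(nrow(Y))
  out <- data.frame(probe_id = rownames(Y), effect = w$effect, p = w$p,
                    rank = rank, significant = w$p < alpha,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "day") <- day; attr(out, "contrast") <- contrast
  attr(out, "alpha") <- alpha
  class(out) <- c("de_table", "data.frame")
  out
}

# vectorised two-sided Welch t-test across matrix rows
welch_rows <- function(A, B) {
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n1 - 1)
  v2 <- rowSums((B - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  undefined <- se2 == 0
  tstat <- ifelse(undefined, 0, (m1 - m2) / sqrt(se2))
  df <- ifelse(undefined, 1,
               se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1))))
  p <- ifelse(undefined, 1, 2 * pt(abs(tstat), df, lower.tail = FALSE))
  list(effect = m1 - m2, p = p, t = tstat, df = df, undefined = undefined)
}

#' Venn partition counts of two significant sets
#'
#' @param de_a,de_b character vectors of significant probe ids (or
#'   `"de_table"`s, whose significant probes are taken).
#' @return named integer vector `c(only_a, only_b, shared)`; satisfies
#'   `only_a + shared == length(A)` and `only_b + shared == length(B)`.
#' @export
venn_counts <- function(de_a, de_b) {
  ids <- function(x) if (inherits(x, "de_table"))
    x$probe_id[x$significant] else as.character(x)
  a <- unique(ids(de_a)); b <- unique(ids(de_b))
  shared <- length(intersect(a, b))
  c(only_a = length(a) - shared, only_b = length(b) - shared,
    shared = shared)
}

#' Overlap of clustered probes with the day's most significant probes
#'
#' The statistic the study uses to tie cluster membership to per-day
#' significance rankings: the percentage of clustered probes appearing in
#' the top-n probes of a per-day DE ranking.
#'
#' @param de a `"de_table"` from [per_time_de()].
#' @param clustered_probes character vector of clustered probe ids
#'   (non-empty).
#' @param n size of the top list (default 50).
#' @return percentage in `[0, 100]`.
#' @export
top_n_cluster_overlap <- function(de, clustered_probes, n = 50L) {
  if (!length(clustered_probes))
    stop_input("clustered probe set is empty: overlap percentage undefined")
  if (n > nrow(de))
    stop_input("n = %d exceeds the %d ranked probes", n, nrow(de))
  top <- de$probe_id[de$rank <= n]
  100 * length(intersect(unique(clustered_probes), top)) /
    length(unique(clustered_probes))
}
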