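#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between an inferred clustering and ground
#' truth labels (1 = identical partitions, ~0 = chance).  Used to score
#' recovery of planted templates in simulation benchmarks.
#'
#' @param a,b label vectors of equal length (any types coercible to
#'   factor); names are ignored, positions must correspond.
#' @return the adjusted Rand index, a number <= 1.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop_input("label vectors differ in length (%d vs %d)",
               length(a), length(b))
  if (!length(a)) return(NaN)
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  maximum <- (sum_a + sum_b) / 2
  if (maximum == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (maximum - expected)
}

#' Score recovery of planted templates
#'
#' Compares a clustering result with the simulation ground truth on the
#' clustered probes: the adjusted Rand index between cluster labels and
#' planted template ids, plus bookkeeping on how many planted and null
#' probes survived the filters.
#'
#' @param clusters a `"tc_clusters"`.
#' @param truth truth data frame from [simulate_study()].
#' @return list: `ari`, `k`, `n_clustered`, `n_planted_clustered`,
#'   `n_null_clustered`.
#' @export
recovery_score <- function(clusters, truth) {
  ids <- names(clusters$labels)
  tpl <- truth$template_id[match(ids, truth$probe_id)]
  list(ari = if (length(ids)) adjusted_rand_index(clusters$labels, tpl)
       else NaN,
       k = clusters$k,
       n_clustered = length(ids),
       n_planted_clustered = sum(tpl != "null", na.rm = TRUE),
       n_null_clustered = sum(tpl == "null", na.rm = TRUE))
}
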