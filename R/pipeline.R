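## end-to-end orchestration: simulate/load -> regress -> filter -> cluster
## -> per-day DE -> report

pipeline_defaults <- function() {
  list(
    simulate = NULL,          # list(preset=..., ...) or NULL
    paths = NULL,             # list(expression=, design=, annotation=)
    regression = list(degree = 2L, alpha = 0.05, alpha_step = 0.05,
                      adjust = "none"),
    stringency = list(ba = 0.5, gh = 0.2),
    cluster = list(k_min = 1L, k_max = 15L, restarts = 25L,
                   min_probes = 5L, min_cluster_size = 1L,
                   feature_mode = "fitted_difference"),
    de = list(alpha = 0.05, top_n = 50L),
    seed = 1L
  )
}

#' Validate and normalise a pipeline configuration
#'
#' Accepts a named list or the path of a JSON file.  Unknown keys are
#' rejected by full key path; defaults are filled in; value ranges are
#' checked before any computation starts.  Exactly one of `simulate` (a
#' synthetic-study block) or `paths` (expression/design/annotation TSVs)
#' must be present.
#'
#' @param config named list or path to a JSON config file.
#' @return the normalised configuration, class `"pipeline_config"`.
#' @examples
#' cfg <- validate_config(list(simulate = list(preset = "ba_mimic"), seed = 7))
#' cfg$regression$alpha
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop_input("config file '%s' not found", config)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop_input("config must be a named list or JSON path")
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop_input("unknown config key(s): %s", paste(unknown, collapse = ", "))
  for (blk in c("regression", "stringency", "cluster", "de")) {
    extra <- setdiff(names(config[[blk]]), names(defaults[[blk]]))
    if (length(extra))
      stop_input("unknown config key(s): %s",
                 paste(paste0(blk, ".", extra), collapse = ", "))
    defaults[[blk]] <- modifyList(defaults[[blk]], config[[blk]] %||% list())
  }
  defaults$seed <- config$seed %||% defaults$seed
  defaults$simulate <- config$simulate
  defaults$paths <- config$paths
  cfg <- defaults
  if (is.null(cfg$simulate) == is.null(cfg$paths))
    stop_input("config needs exactly one of 'simulate' or 'paths'")
  if (!is.null(cfg$paths)) {
    need <- c("expression", "design")
    miss <- setdiff(need, names(cfg$paths))
    if (length(miss))
      stop_input("paths block missing: %s",
                 paste(paste0("paths.", miss), collapse = ", "))
  } else {
    known <- c("preset", "seed", "probes_per_template", "n_null_probes")
    extra <- setdiff(names(cfg$simulate), known)
    if (length(extra))
      stop_input("unknown config key(s): %s",
                 paste(paste0("simulate.", extra), collapse = ", "))
    if (is.null(cfg$simulate$preset) ||
        !cfg$simulate$preset %in% c("ba_mimic", "gh_mimic"))
      stop_input("simulate.preset must be 'ba_mimic' or 'gh_mimic'")
  }
  num_in <- function(x, lo, hi, key) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi)
      stop_input("config key '%s' must be a number in [%s, %s] (got %s)",
                 key, lo, hi, paste(x, collapse = ","))
  }
  num_in(cfg$regression$alpha, 0, 1, "regression.alpha")
  num_in(cfg$regression$alpha_step, 0, 1, "regression.alpha_step")
  num_in(cfg$regression$degree, 1, 4, "regression.degree")
  num_in(cfg$stringency$ba, 0, 1, "stringency.ba")
  num_in(cfg$stringency$gh, 0, 1, "stringency.gh")
  num_in(cfg$de$alpha, 0, 1, "de.alpha")
  if (!cfg$regression$adjust %in% c("none", "BH"))
    stop_input("config key 'regression.adjust' must be 'none' or 'BH'")
  if (!cfg$cluster$feature_mode %in% c("fitted_difference", "fitted_both",
                                       "coefficients"))
    stop_input("config key 'cluster.feature_mode' is invalid")
  if (cfg$cluster$k_min < 1 || cfg$cluster$k_min > cfg$cluster$k_max)
    stop_input("config needs 1 <= cluster.k_min <= cluster.k_max")
  if (!is_count(cfg$seed) || cfg$seed < 0)
    stop_input("config key 'seed' must be a non-negative integer")
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full analysis pipeline
#'
#' Simulate (or load) a study, fit both treatment contrasts, write fit
#' tables and survivor sets at both stringency tiers (0.5 and 0.2),
#' cluster each contrast at its configured tier, run per-day Welch DE with
#' Venn overlaps and top-n cluster overlap statistics, and write a
#' machine-readable run summary.  All outputs are deterministic functions
#' of the configuration (including its seed); an existing non-empty output
#' directory is refused unless `overwrite = TRUE`.
#'
#' @param config a `"pipeline_config"`, raw list, or JSON path (passed
#'   through [validate_config()]).
#' @param outdir output directory.
#' @param overwrite allow writing into a non-empty `outdir`.
#' @return (invisibly) a list with the run summary, the two `"tc_fit"`s,
#'   the two `"tc_clusters"`, and the cluster report.
#' @export
run_pipeline <- function(config, outdir, overwrite = FALSE) {
  cfg <- validate_config(config)
  if (dir.exists(outdir) && length(dir(outdir)) && !overwrite)
    stop_input("output directory '%s' is not empty (use overwrite = TRUE)",
               outdir)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(outdir, "run.log")
  logline <- function(...) cat(sprintf(...), "\n", sep = "", file = logf,
                               append = TRUE)
  cat("", file = logf)

  if (!is.null(cfg$simulate)) {
    sim_seed <- as.integer(cfg$simulate$seed %||% cfg$seed)
    maker <- switch(cfg$simulate$preset, ba_mimic = preset_ba_mimic,
                    gh_mimic = preset_gh_mimic)
    args <- list(seed = sim_seed)
    for (k in c("probes_per_template", "n_null_probes"))
      if (!is.null(cfg$simulate[[k]])) args[[k]] <- as.integer(cfg$simulate[[k]])
    scfg <- do.call(maker, args)
    sim <- simulate_study(scfg)
    expr <- sim$expr; design <- sim$design
    write_truth(sim$truth, file.path(outdir, "truth.tsv"), config = scfg)
    logline("simulated preset %s (seed %d): %d probes x %d samples",
            cfg$simulate$preset, sim_seed, nrow(expr$values),
            ncol(expr$values))
  } else {
    expr <- read_expression(cfg$paths$expression, cfg$paths$annotation)
    design <- read_design(cfg$paths$design)
    logline("loaded %d probes x %d samples from %s", nrow(expr$values),
            ncol(expr$values), cfg$paths$expression)
  }
  jsonlite::write_json(unclass(cfg), file.path(outdir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  tiers <- c(0.5, 0.2)
  contrasts <- c("ba", "gh")
  fits <- clusters <- list()
  survivors <- list()
  for (ct in contrasts) {
    fit <- tc_fit(expr, design, contrast = ct,
                  degree = cfg$regression$degree,
                  alpha_step = cfg$regression$alpha_step)
    fits[[ct]] <- fit
    write.table(fit_table(fit),
                file.path(outdir, sprintf("fit_%s.tsv", ct)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (tier in tiers) {
      ids <- surviving_probes(fit, cfg$regression$alpha, tier,
                              cfg$regression$adjust)
      survivors[[sprintf("%s_r2_%s", ct, format(tier))]] <- ids
      writeLines(ids, file.path(outdir, sprintf("survivors_%s_r2_%s.tsv",
                                                ct, format(tier))))
      logline("filter %s: alpha %.3g (%s), R2 >= %.2f -> %d survivors",
              toupper(ct), cfg$regression$alpha, cfg$regression$adjust,
              tier, length(ids))
    }
    cl <- tc_cluster(fit, alpha = cfg$regression$alpha,
                     r2_threshold = cfg$stringency[[ct]],
                     adjust = cfg$regression$adjust,
                     feature_mode = cfg$cluster$feature_mode,
                     k_min = cfg$cluster$k_min, k_max = cfg$cluster$k_max,
                     restarts = cfg$cluster$restarts,
                     min_probes = cfg$cluster$min_probes,
                     min_cluster_size = cfg$cluster$min_cluster_size,
                     seed = cfg$seed)
    clusters[[ct]] <- cl
    write.table(cl$scores, file.path(outdir, sprintf("kselect_%s.tsv", ct)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    logline("cluster %s at R2 >= %.2f: k = %d (%d survivors)", toupper(ct),
            cfg$stringency[[ct]], cl$k, length(cl$survivors))
  }
  report <- cluster_report(clusters$ba, clusters$gh)
  for (ct in contrasts) {
    write.table(report$tables[[ct]],
                file.path(outdir, sprintf("clusters_%s.tsv", ct)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(report$profiles[[ct]],
                file.path(outdir, sprintf("cluster_profiles_%s.tsv", ct)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  days <- sort(unique(design$day))
  venn <- data.frame(); topn <- data.frame()
  de_sets <- list()
  for (d in days) {
    for (ct in contrasts) {
      de <- per_time_de(expr, design, d, ct, alpha = cfg$de$alpha)
      de_sets[[paste(ct, d)]] <- de
      write.table(de, file.path(outdir, sprintf("de_%s_day%s.tsv", ct,
                                                format(d))),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      clustered <- names(clusters[[ct]]$labels)
      if (length(clustered)) {
        nn <- min(cfg$de$top_n, nrow(de))
        topn <- rbind(topn, data.frame(
          contrast = ct, day = d, n = nn,
          overlap_pct = top_n_cluster_overlap(de, clustered, nn)))
      }
    }
    vc <- venn_counts(de_sets[[paste("ba", d)]], de_sets[[paste("gh", d)]])
    venn <- rbind(venn, data.frame(day = d, only_ba = vc[["only_a"]],
                                   only_gh = vc[["only_b"]],
                                   shared = vc[["shared"]]))
  }
  write.table(venn, file.path(outdir, "venn_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  if (nrow(topn))
    write.table(topn, file.path(outdir, "top_n_overlap.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)

  summary <- list(
    seed = cfg$seed,
    n_probes = nrow(expr$values), n_samples = ncol(expr$values),
    k_star = lapply(clusters, function(cl) cl$k),
    survivor_counts = lapply(survivors, length),
    stringency = cfg$stringency,
    venn = venn,
    top_n_overlap = if (nrow(topn)) topn else NULL)
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", dataframe = "rows")
  logline("run complete: k_star BA = %d, GH = %d", clusters$ba$k,
          clusters$gh$k)
  invisible(list(summary = summary, fits = fits, clusters = clusters,
                 report = report, outdir = outdir))
}
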