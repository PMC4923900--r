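#' Assemble a probes-by-samples expression set
#'
#' Light container pairing a numeric log-intensity matrix (probes in rows,
#' samples in columns) with an optional probe-to-gene annotation.  Values
#' must be finite; probes containing non-finite values are dropped with a
#' message by default, or rejected when `strict = TRUE`.
#'
#' @param values numeric matrix, probes x samples, with unique non-empty
#'   rownames (probe ids) and colnames (sample ids).
#' @param annotation named character vector mapping probe id to gene symbol;
#'   probes absent from it get the empty string.
#' @param strict if `TRUE`, any non-finite value is an error instead of a
#'   probe drop.
#' @return an object of class `"expr_set"`: a list with elements `values`
#'   and `annotation`.
#' @export
expression_set <- function(values, annotation = NULL, strict = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop_input("'values' must be a numeric matrix (probes x samples)")
  pid <- rownames(values); sid <- colnames(values)
  if (is.null(pid) || is.null(sid))
    stop_input("expression matrix needs probe ids as rownames and sample ids as colnames")
  if (anyDuplicated(pid))
    stop_input("duplicated probe id(s): %s",
               paste(unique(pid[duplicated(pid)]), collapse = ", "))
  if (anyDuplicated(sid))
    stop_input("duplicated sample id(s): %s",
               paste(unique(sid[duplicated(sid)]), collapse = ", "))
  bad <- !is.finite(values)
  if (any(bad)) {
    if (strict) {
      idx <- which(bad, arr.ind = TRUE)[1, ]
      stop_input("non-finite expression value at probe '%s', sample '%s'",
                 pid[idx[1]], sid[idx[2]])
    }
    drop <- rowSums(bad) > 0
    message(sprintf("dropping %d probe(s) with non-finite values", sum(drop)))
    values <- values[!drop, , drop = FALSE]
    pid <- rownames(values)
  }
  ann <- setNames(rep("", length(pid)), pid)
  if (!is.null(annotation)) {
    annotation <- annotation[!is.na(annotation)]
    hit <- intersect(names(annotation), pid)
    ann[hit] <- as.character(annotation[hit])
  }
  structure(list(values = values, annotation = ann), class = "expr_set")
}

#' @export
print.expr_set <- function(x, ...) {
  cat(sprintf("expression set: %d probes x %d samples (%d annotated)\n",
              nrow(x$values), ncol(x$values), sum(nzchar(x$annotation))))
  invisible(x)
}

#' @export
dim.expr_set <- function(x) dim(x$values)

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample ids and a first column of probe ids; all
#' remaining cells numeric log-intensities.
#'
#' @param path expression TSV.
#' @param annotation_path optional two-column TSV (`probe_id`, `gene_symbol`).
#' @param strict passed to [expression_set()].
#' @return an `"expr_set"`.
#' @export
read_expression <- function(path, annotation_path = NULL, strict = FALSE) {
  raw <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character")
  if (ncol(raw) < 2L)
    stop_input("'%s': expected probe id column plus at least one sample column", path)
  pid <- raw[[1]]
  if (anyDuplicated(pid))
    stop_input("'%s': duplicated probe id '%s' (row %d)", path,
               pid[anyDuplicated(pid)], anyDuplicated(pid))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim(vals)))
  bad <- is.na(num) & !is.na(vals) & nzchar(trimws(vals))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop_input("'%s': non-numeric cell at row %d ('%s'), column '%s'",
               path, idx[1], pid[idx[1]], colnames(vals)[idx[2]])
  }
  dimnames(num) <- list(pid, colnames(vals))
  ann <- if (!is.null(annotation_path)) read_annotation(annotation_path) else NULL
  expression_set(num, annotation = ann, strict = strict)
}

#' Write an expression set as TSV
#'
#' Values are serialised with 17 significant digits so that a write/read
#' round trip reproduces the doubles bit-exactly.
#'
#' @param x an `"expr_set"` or a probes-x-samples numeric matrix.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  m <- if (inherits(x, "expr_set")) x$values else x
  body <- apply(m, 1:2, function(v) sprintf("%.17g", v))
  out <- cbind(probe_id = rownames(m), body)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation table
#'
#' @param path two-column TSV `probe_id`, `gene_symbol` (header required).
#' @return named character vector, probe id -> gene symbol.
#' @export
read_annotation <- function(path) {
  a <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  if (ncol(a) < 2L) stop_input("'%s': expected columns probe_id, gene_symbol", path)
  if (anyDuplicated(a[[1]]))
    stop_input("'%s': duplicated probe id '%s' in annotation", path,
               a[[1]][anyDuplicated(a[[1]])])
  setNames(a[[2]], a[[1]])
}

#' Build a study design table
#'
#' @param sample_id character vector of unique sample ids.
#' @param treatment treatment labels; matched case- and
#'   whitespace-insensitively against `control`, `BA`, `GH`.
#' @param day sampling day of each sample (> 0).
#' @param batch batch label of each sample (small integers).
#' @param day_grid finite grid the days must come from, or `NULL` to accept
#'   any positive day.
#' @param log_base base for the transformed time scale.
#' @return a `data.frame` of class `"study_design"` with columns
#'   `sample_id`, `treatment` (factor control/ba/gh), `day`, `batch` and
#'   `transformed_time`.
#' @export
study_design <- function(sample_id, treatment, day, batch,
                         day_grid = DEFAULT_DAY_GRID, log_base = exp(1)) {
  n <- length(sample_id)
  if (length(treatment) != n || length(day) != n || length(batch) != n)
    stop_input("design columns have unequal lengths")
  if (anyDuplicated(sample_id))
    stop_input("duplicated sample id '%s' in design",
               sample_id[anyDuplicated(sample_id)])
  tr <- normalise_label(treatment)
  unknown <- setdiff(unique(tr), TREATMENT_LEVELS)
  if (length(unknown))
    stop_input("unknown treatment label(s): %s (expected control/BA/GH)",
               paste(unknown, collapse = ", "))
  day <- as.numeric(day)
  if (any(!is.finite(day) | day <= 0))
    stop_input("sampling days must be finite and > 0 (sample '%s')",
               sample_id[which(!is.finite(day) | day <= 0)[1]])
  if (!is.null(day_grid)) {
    off <- !day %in% day_grid
    if (any(off))
      stop_input("day %s of sample '%s' is not on the configured grid {%s}",
                 format(day[which(off)[1]]), sample_id[which(off)[1]],
                 paste(day_grid, collapse = ", "))
  }
  d <- data.frame(sample_id = as.character(sample_id),
                  treatment = factor(tr, levels = TREATMENT_LEVELS),
                  day = day,
                  batch = as.integer(batch),
                  transformed_time = transform_times(day, base = log_base),
                  stringsAsFactors = FALSE)
  class(d) <- c("study_design", "data.frame")
  d
}

#' Read a study design TSV
#'
#' Columns `sample_id`, `treatment`, `day`, `batch` (header required; extra
#' columns are carried along but ignored).
#'
#' @inheritParams study_design
#' @param path design TSV.
#' @return a `"study_design"` data frame; see [study_design()].
#' @export
read_design <- function(path, day_grid = DEFAULT_DAY_GRID, log_base = exp(1)) {
  d <- read.delim(path, header = TRUE, sep = "\t", colClasses = "character")
  need <- c("sample_id", "treatment", "day", "batch")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop_input("'%s': missing design column(s): %s", path,
               paste(miss, collapse = ", "))
  day <- suppressWarnings(as.numeric(d$day))
  if (any(is.na(day)))
    stop_input("'%s': non-numeric day '%s' (sample '%s')", path,
               d$day[which(is.na(day))[1]], d$sample_id[which(is.na(day))[1]])
  study_design(d$sample_id, d$treatment, day, d$batch,
               day_grid = day_grid, log_base = log_base)
}

#' Write a study design TSV
#' @param design a `"study_design"`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  out <- design[, c("sample_id", "treatment", "day", "batch")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# check an expr_set and a design describe the same samples, in order
match_design <- function(expr, design) {
  sid <- colnames(expr$values)
  if (!setequal(sid, design$sample_id))
    stop_input("expression samples and design samples differ (e.g. %s)",
               paste(utils::head(c(setdiff(sid, design$sample_id),
                                   setdiff(design$sample_id, sid)), 3),
                     collapse = ", "))
  design[match(sid, design$sample_id), , drop = FALSE]
}
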