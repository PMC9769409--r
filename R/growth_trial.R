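# Pot-trial statistics: treatment summaries, log2 fold change vs control,
# per-parameter one-way ANOVA, and PCA of the vegetative-parameter matrix.

#' Vegetative parameters recorded per plant replicate
#' @export
GROWTH_PARAMETERS <- c("leaf_count", "shoot_length", "root_length",
                       "shoot_fresh_wt", "root_fresh_wt",
                       "shoot_dry_wt", "root_dry_wt", "chl_a", "chl_b")

check_growth_records <- function(records) {
  require_columns(records, c("treatment", "timepoint", "replicate",
                             GROWTH_PARAMETERS), "growth records")
  dup <- duplicated(records[, c("treatment", "timepoint", "replicate")])
  if (any(dup)) {
    stop("validation error: duplicate replicate index within a ",
         "(treatment, timepoint) cell", call. = FALSE)
  }
  invisible(records)
}

#' Per-treatment summaries of a pot trial
#'
#' Mean and standard error (SE = sample sd / sqrt(n)) per (treatment,
#' timepoint, parameter) cell.
#'
#' @param records long-format data.frame of growth records: `treatment`,
#'   `timepoint`, `replicate`, and one column per vegetative parameter.
#' @return data.frame with `treatment`, `timepoint`, `parameter`, `mean`,
#'   `se`, `n`.
#' @export
summarize_treatments <- function(records) {
  check_growth_records(records)
  cells <- unique(records[, c("treatment", "timepoint")])
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- records$treatment == cells$treatment[i] &
      records$timepoint == cells$timepoint[i]
    for (p in GROWTH_PARAMETERS) {
      m <- measurement_with_error(records[[p]][sel])
      rows[[length(rows) + 1L]] <- data.frame(
        treatment = cells$treatment[i], timepoint = cells$timepoint[i],
        parameter = p, mean = m$mean, se = m$se, n = m$n,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Log2 fold change of a treatment mean over the control mean
#'
#' @param treatment_mean,control_mean positive means.
#' @return `log2(treatment_mean / control_mean)`; 0 means no change, equal
#'   distances above/below 0 are equal relative changes.
#' @export
log2_fold_change <- function(treatment_mean, control_mean) {
  if (any(treatment_mean <= 0) || any(control_mean <= 0)) {
    stop("domain error: means must be positive for a log fold change",
         call. = FALSE)
  }
  log2(treatment_mean / control_mean)
}

#' Fold-change table for a whole trial
#'
#' Fold changes use the means of replicates (not per-replicate ratios),
#' computed per treatment, timepoint and parameter against the control arm
#' at the same timepoint.
#'
#' @param records long-format growth records (see [summarize_treatments()]).
#' @param control label of the control arm.
#' @return data.frame with `treatment`, `timepoint`, `parameter`,
#'   `fold_change`, `log2_fc`.
#' @export
fold_change_table <- function(records, control = "control") {
  summ <- summarize_treatments(records)
  if (!control %in% summ$treatment) {
    stop("domain error: control arm '", control, "' not present",
         call. = FALSE)
  }
  out <- list()
  for (tp in unique(summ$timepoint)) {
    ctrl <- summ[summ$treatment == control & summ$timepoint == tp, ]
    trt <- summ[summ$treatment != control & summ$timepoint == tp, ]
    cm <- stats::setNames(ctrl$mean, ctrl$parameter)
    out[[length(out) + 1L]] <- data.frame(
      treatment = trt$treatment, timepoint = tp, parameter = trt$parameter,
      fold_change = trt$mean / cm[trt$parameter],
      log2_fc = log2_fold_change(trt$mean, cm[trt$parameter]),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, out)
}

#' One-way ANOVA across treatment groups
#'
#' Classic equal-variance Fisher decomposition: F = MSB / MSW with
#' df = (k - 1, N - k), p from the upper tail of the F distribution.
#' Degenerate inputs are handled explicitly: zero within-group variance
#' with unequal means gives `F = Inf, p = 0`; all values identical gives
#' `F = 0, p = 1`.
#'
#' @param groups list of numeric replicate vectors (>= 2 groups, each
#'   >= 2 values).
#' @return list of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2) stop("domain error: need >= 2 groups", call. = FALSE)
  if (any(vapply(groups, length, 1L) < 2)) {
    stop("domain error: each group needs >= 2 values", call. = FALSE)
  }
  k <- length(groups)
  n <- sum(lengths(groups))
  df_b <- k - 1L
  df_w <- n - k
  grand <- mean(unlist(groups))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  if (ssw == 0) {
    if (ssb == 0) {
      res <- list(F = 0, df_between = df_b, df_within = df_w, p = 1)
    } else {
      res <- list(F = Inf, df_between = df_b, df_within = df_w, p = 0)
    }
    class(res) <- "anova_result"
    return(res)
  }
  values <- unlist(groups)
  grp <- factor(rep(seq_along(groups), lengths(groups)))
  fit <- stats::oneway.test(values ~ grp, var.equal = TRUE)
  structure(list(F = unname(fit$statistic),
                 df_between = as.integer(fit$parameter[["num df"]]),
                 df_within = as.integer(fit$parameter[["denom df"]]),
                 p = unname(fit$p.value)),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  invisible(x)
}

#' Per-parameter ANOVA table for a trial
#'
#' Treatments are compared within each timepoint separately, one ANOVA per
#' vegetative parameter. No multiple-testing correction is applied across
#' the parameters (raw p-values; interpret accordingly).
#'
#' @param records long-format growth records.
#' @param alpha significance threshold recorded alongside (default 0.05).
#' @return data.frame with `timepoint`, `parameter`, `F`, `df_between`,
#'   `df_within`, `p`, `significant`.
#' @export
anova_by_parameter <- function(records, alpha = 0.05) {
  check_growth_records(records)
  out <- list()
  for (tp in unique(records$timepoint)) {
    sub <- records[records$timepoint == tp, ]
    for (p in GROWTH_PARAMETERS) {
      groups <- split(sub[[p]], sub$treatment)
      a <- one_way_anova(groups)
      out[[length(out) + 1L]] <- data.frame(
        timepoint = tp, parameter = p, F = a$F,
        df_between = a$df_between, df_within = a$df_within, p = a$p,
        significant = a$p < alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' PCA of an observations-by-parameters matrix
#'
#' Columns are standardized to zero mean and unit variance (the parameters
#' mix counts, centimetres, grams and mg/g, so the correlation matrix is
#' the right basis), then eigen-decomposed via [stats::prcomp()]. Explained
#' variance percentages are non-increasing and sum to 100.
#'
#' @param x numeric matrix or data.frame, >= 2 rows and >= 2 columns.
#' @return list of class `pca_result`: `loadings` (parameters x
#'   components), `scores`, `explained_variance_pct`.
#' @export
pca_params <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2 || ncol(x) < 2) {
    stop("domain error: PCA needs >= 2 observations and >= 2 parameters",
         call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("degenerate column (constant, cannot standardize): ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  fit <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  ev <- fit$sdev^2
  structure(list(loadings = fit$rotation, scores = fit$x,
                 explained_variance_pct = 100 * ev / sum(ev)),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  pct <- x$explained_variance_pct
  cat("PCA:", paste(sprintf("PC%d %.2f%%", seq_along(pct), pct),
                    collapse = ", "), "\n")
  invisible(x)
}

#' Full pot-trial analysis
#'
#' Runs the summary, fold-change, ANOVA and (per timepoint) PCA stages on a
#' set of growth records.
#'
#' @param records long-format growth records.
#' @param control label of the control arm.
#' @return list with `summary`, `fold_changes`, `anova`, and `pca` (one
#'   [pca_params()] result per timepoint, computed on the replicate-by-
#'   parameter matrix).
#' @export
analyze_trial <- function(records, control = "control") {
  check_growth_records(records)
  pca <- lapply(split(records, records$timepoint), function(sub) {
    pca_params(as.matrix(sub[, GROWTH_PARAMETERS]))
  })
  list(summary = summarize_treatments(records),
       fold_changes = fold_change_table(records, control = control),
       anova = anova_by_parameter(records),
       pca = pca)
}
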