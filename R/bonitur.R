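# The bonitur scale: an additive multi-trait scoring system used to pick
# elite isolates from a screening campaign. Quantitative PGP traits are
# binned into 0-3 points, selected binary traits score 1 point each, and
# every pathogen in the dual-culture panel contributes 0-3 points from the
# percent-inhibition bins; the maximum with the default rules is 41.

PGP_POINT_TRAITS <- c("iaa", "p_solub", "ammonia", "n2_fixation",
                      "acc_deaminase", "siderophore", "chitinase")

#' Bonitur scoring rules
#'
#' Builds the rule set for [score_isolate()]. Defaults reproduce the
#' published 41-point scale: IAA points 1/2/3 for (0,15], (15,30], >30
#' ug/ml; phosphate solubilization points 1/2/3 for (0,100], (100,200],
#' >200 ug/ml; ammonia, nitrogen fixation, ACC deaminase, siderophore and
#' chitinase 1 point each when positive/detected; growth inhibition points
#' 0/1/2/3 for <=10, (10,30], (30,60], (60,100] percent per pathogen. All
#' bins are upper-inclusive. A not-detected trait or a no-activity pathogen
#' cell scores 0.
#'
#' The rule set is configuration: other campaigns can redefine thresholds,
#' the binary trait list, or point values per binary trait.
#'
#' @param iaa_bins two increasing thresholds splitting points 1/2/3.
#' @param ps_bins likewise for phosphate solubilization.
#' @param gi_bins three increasing thresholds splitting inhibition points
#'   0/1/2/3.
#' @param binary_traits names of traits scoring `binary_points` when
#'   positive; quantitative trait names here count as positive when detected.
#' @param binary_points points per positive binary trait.
#' @param n_pathogens size of the pathogen panel (caps the antifungal
#'   subtotal).
#' @return list of class `bonitur_rules`; `max_total` is derived from the
#'   components.
#' @export
bonitur_rules <- function(iaa_bins = c(15, 30), ps_bins = c(100, 200),
                          gi_bins = c(10, 30, 60),
                          binary_traits = c("ammonia", "n2_fixation",
                                            "acc_deaminase", "siderophore",
                                            "chitinase"),
                          binary_points = 1L, n_pathogens = 10L) {
  stopifnot(length(iaa_bins) == 2, length(ps_bins) == 2, length(gi_bins) == 3)
  if (is.unsorted(iaa_bins, strictly = TRUE) ||
      is.unsorted(ps_bins, strictly = TRUE) ||
      is.unsorted(gi_bins, strictly = TRUE)) {
    stop("configuration error: bin thresholds must be strictly increasing",
         call. = FALSE)
  }
  known <- c(QUANT_TRAITS, BINARY_TRAITS, OPTIONAL_BINARY_TRAITS)
  unknown <- setdiff(binary_traits, known)
  if (length(unknown)) {
    stop("configuration error: unknown trait name(s) in rules: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(iaa_bins = iaa_bins, ps_bins = ps_bins, gi_bins = gi_bins,
                 binary_traits = binary_traits,
                 binary_points = as.integer(binary_points),
                 n_pathogens = as.integer(n_pathogens),
                 max_total = 3L + 3L +
                   length(binary_traits) * as.integer(binary_points) +
                   3L * as.integer(n_pathogens)),
            class = "bonitur_rules")
}

#' Read / write bonitur rules as YAML configuration
#'
#' @param path YAML file.
#' @return for the reader, a `bonitur_rules` object.
#' @export
read_bonitur_rules <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(bonitur_rules, cfg)
}

#' @rdname read_bonitur_rules
#' @param rules a `bonitur_rules` object.
#' @export
write_bonitur_rules <- function(rules, path) {
  yaml::write_yaml(unclass(rules)[c("iaa_bins", "ps_bins", "gi_bins",
                                    "binary_traits", "binary_points",
                                    "n_pathogens")], path)
  invisible(path)
}

#' Bin a quantitative trait value into 0-3 points
#'
#' Upper-inclusive bins: not detected (`NA`) or 0 scores 0; (0, t1] scores
#' 1; (t1, t2] scores 2; above t2 scores 3.
#'
#' @param value concentration (or `NA` for not detected); vectorized.
#' @param bins two increasing thresholds.
#' @return integer points 0-3.
#' @export
score_quant_trait <- function(value, bins) {
  stopifnot(length(bins) == 2, bins[1] < bins[2])
  if (any(value < 0, na.rm = TRUE)) {
    stop("domain error: negative trait value", call. = FALSE)
  }
  pts <- ifelse(is.na(value) | value == 0, 0L,
                ifelse(value <= bins[1], 1L,
                       ifelse(value <= bins[2], 2L, 3L)))
  as.integer(pts)
}

#' Bin a percent growth inhibition into 0-3 points
#'
#' Upper-inclusive bins: absent (`NA`) or <= t1 scores 0; (t1, t2] scores 1;
#' (t2, t3] scores 2; (t3, 100] scores 3.
#'
#' @param gi percent inhibition in `[0, 100]` or `NA` for no activity;
#'   vectorized.
#' @param bins three increasing thresholds (default 10/30/60).
#' @return integer points 0-3.
#' @export
score_inhibition <- function(gi, bins = c(10, 30, 60)) {
  stopifnot(length(bins) == 3)
  if (any(gi < 0 | gi > 100, na.rm = TRUE)) {
    stop("domain error: inhibition percent outside [0, 100]", call. = FALSE)
  }
  pts <- ifelse(is.na(gi) | gi <= bins[1], 0L,
                ifelse(gi <= bins[2], 1L,
                       ifelse(gi <= bins[3], 2L, 3L)))
  as.integer(pts)
}

score_binary <- function(profile, trait, rules) {
  if (trait %in% QUANT_TRAITS) {
    positive <- !is.na(profile[[trait]]) && profile[[trait]] > 0
  } else {
    positive <- isTRUE(profile[[trait]])
  }
  if (positive) rules$binary_points else 0L
}

#' Score one isolate on the bonitur scale
#'
#' @param profile one-row data.frame (or list) with the isolate's trait
#'   values as produced by [read_trait_table()].
#' @param inhibition_row named numeric vector of percent inhibitions per
#'   pathogen (`NA` = no activity); at most `rules$n_pathogens` entries.
#' @param rules a [bonitur_rules()] object.
#' @return one-row data.frame score card: per-trait points (named like the
#'   input columns), `pgp_subtotal`, `antifungal_subtotal`, `total`.
#' @export
score_isolate <- function(profile, inhibition_row = NULL,
                          rules = bonitur_rules()) {
  stopifnot(inherits(rules, "bonitur_rules"))
  if (is.null(inhibition_row)) inhibition_row <- numeric(0)
  if (length(inhibition_row) > rules$n_pathogens) {
    stop("configuration error: more pathogens than the rule set allows",
         call. = FALSE)
  }
  card <- data.frame(isolate_id = profile$isolate_id %||% NA_character_,
                     stringsAsFactors = FALSE)
  card$iaa <- score_quant_trait(profile$iaa, rules$iaa_bins)
  card$p_solub <- score_quant_trait(profile$p_solub, rules$ps_bins)
  for (tr in rules$binary_traits) {
    card[[tr]] <- as.integer(score_binary(profile, tr, rules))
  }
  gi_pts <- score_inhibition(inhibition_row, rules$gi_bins)
  for (j in seq_along(gi_pts)) {
    card[[names(inhibition_row)[j] %||% paste0("pathogen_", j)]] <- gi_pts[j]
  }
  card$pgp_subtotal <- card$iaa + card$p_solub +
    sum(vapply(rules$binary_traits, function(tr) card[[tr]], 1L))
  card$antifungal_subtotal <- as.integer(sum(gi_pts))
  card$total <- card$pgp_subtotal + card$antifungal_subtotal
  card
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score a whole campaign
#'
#' Applies [score_isolate()] to every row of a trait table, pairing it with
#' its inhibition-matrix row (an isolate absent from the matrix contributes
#' no antifungal points), then attaches dense ranks.
#'
#' @param traits a `trait_table`.
#' @param inhibition an `inhibition_matrix` (or NULL for PGP-only scoring).
#' @param rules a [bonitur_rules()] object.
#' @return data.frame of score cards, one per isolate, with a `rank` column,
#'   ordered by rank.
#' @export
score_campaign <- function(traits, inhibition = NULL,
                           rules = bonitur_rules()) {
  cards <- lapply(seq_len(nrow(traits)), function(i) {
    profile <- traits[i, , drop = FALSE]
    row <- NULL
    if (!is.null(inhibition) && profile$isolate_id %in% rownames(inhibition)) {
      row <- inhibition[profile$isolate_id, ]
    } else if (!is.null(inhibition)) {
      row <- stats::setNames(rep(NA_real_, ncol(inhibition)),
                             colnames(inhibition))
    }
    score_isolate(profile, row, rules)
  })
  cards <- do.call(rbind, cards)
  rank_isolates(cards)
}

#' Dense-rank score cards by total
#'
#' Equal totals share a rank; the next distinct total takes the next
#' integer (1, 2, 3, 3, 4, ...). Ranking depends only on the ordering of
#' totals, so it is invariant under any order-preserving transformation.
#'
#' @param cards data.frame with a `total` column.
#' @return the cards ordered by descending total with a `rank` column.
#' @export
rank_isolates <- function(cards) {
  if (!nrow(cards)) stop("domain error: no score cards to rank", call. = FALSE)
  ord <- order(-cards$total)
  cards <- cards[ord, , drop = FALSE]
  distinct <- sort(unique(cards$total), decreasing = TRUE)
  cards$rank <- match(cards$total, distinct)
  rownames(cards) <- NULL
  cards
}

#' Reconcile recomputed score cards with a published score table
#'
#' For every shared isolate, lists the point cells where the recomputed card
#' differs from the published row, and checks whether the published row's
#' own points sum to its printed total. Mismatches are reported, never
#' auto-corrected: reproducibility tooling must surface source
#' inconsistencies, not hide them.
#'
#' @param recomputed score cards from [score_campaign()].
#' @param published data.frame of the published table: per-trait point
#'   columns named like the score-card columns, plus `total` (see
#'   [read_published_scores()]).
#' @return list of class `score_audit`: `cell_mismatches` (data.frame with
#'   isolate_id, cell, recomputed, published), `internal_sums` (data.frame
#'   with isolate_id, points_sum, printed_total, consistent), and
#'   `flagged_isolates` (ids with any discrepancy).
#' @export
audit_scores <- function(recomputed, published) {
  shared <- intersect(recomputed$isolate_id, published$isolate_id)
  point_cols <- intersect(setdiff(names(published),
                                  c("isolate_id", "total", "rank",
                                    "pgp_subtotal", "antifungal_subtotal")),
                          names(recomputed))
  mism <- list()
  sums <- list()
  for (id in shared) {
    rec <- recomputed[recomputed$isolate_id == id, , drop = FALSE]
    pub <- published[published$isolate_id == id, , drop = FALSE]
    for (cl in point_cols) {
      if (rec[[cl]] != pub[[cl]]) {
        mism[[length(mism) + 1L]] <- data.frame(
          isolate_id = id, cell = cl,
          recomputed = as.integer(rec[[cl]]),
          published = as.integer(pub[[cl]]), stringsAsFactors = FALSE)
      }
    }
    if (rec$total != pub$total) {
      mism[[length(mism) + 1L]] <- data.frame(
        isolate_id = id, cell = "total",
        recomputed = as.integer(rec$total),
        published = as.integer(pub$total), stringsAsFactors = FALSE)
    }
    psum <- sum(vapply(point_cols, function(cl) as.integer(pub[[cl]]), 1L))
    sums[[length(sums) + 1L]] <- data.frame(
      isolate_id = id, points_sum = psum,
      printed_total = as.integer(pub$total),
      consistent = psum == pub$total, stringsAsFactors = FALSE)
  }
  cell_mismatches <- if (length(mism)) do.call(rbind, mism) else
    data.frame(isolate_id = character(), cell = character(),
               recomputed = integer(), published = integer())
  internal_sums <- do.call(rbind, sums)
  flagged <- sort(unique(c(cell_mismatches$isolate_id,
                           internal_sums$isolate_id[!internal_sums$consistent])))
  structure(list(cell_mismatches = cell_mismatches,
                 internal_sums = internal_sums,
                 flagged_isolates = flagged),
            class = "score_audit")
}

#' @export
print.score_audit <- function(x, ...) {
  if (!length(x$flagged_isolates)) {
    cat("score audit: no discrepancies\n")
    return(invisible(x))
  }
  cat("score audit: discrepancies for",
      paste(x$flagged_isolates, collapse = ", "), "\n")
  if (nrow(x$cell_mismatches)) print(x$cell_mismatches)
  bad <- x$internal_sums[!x$internal_sums$consistent, , drop = FALSE]
  if (nrow(bad)) {
    cat("published rows whose points do not sum to the printed total:\n")
    print(bad)
  }
  invisible(x)
}

#' Read a published bonitur score table
#'
#' @param path CSV with `isolate_id`, one integer column per scored trait
#'   and pathogen, `total`, and optionally `rank`.
#' @return data.frame.
#' @export
read_published_scores <- function(path) {
  df <- read_csv_strict(path)
  require_columns(df, c("isolate_id", "total"), "published score table")
  for (cl in setdiff(names(df), "isolate_id")) df[[cl]] <- as.integer(df[[cl]])
  df
}
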