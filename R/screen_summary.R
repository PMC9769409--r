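# Community-level descriptive statistics over a screening campaign.

# The published tables print percentages truncated to 2 decimals
# (e.g. 25/51 -> 49.01); both that convention and half-up rounding are
# supported.
round_pct <- function(x, digits = 2, mode = c("trunc", "half_up")) {
  mode <- match.arg(mode)
  f <- 10^digits
  switch(mode,
         trunc = trunc(x * f) / f,
         half_up = floor(x * f + 0.5) / f)
}

#' Trait prevalence across a campaign
#'
#' A quantitative trait counts as positive iff detected (non-ND), with no
#' magnitude threshold; a binary trait iff its flag is set. Percentages are
#' over all profiles.
#'
#' @param traits a `trait_table`.
#' @param digits decimal places for percentages.
#' @param rounding `"trunc"` (default; matches the published tables'
#'   formatting) or `"half_up"`.
#' @return data.frame of class `prevalence_report`: `trait`, `positive`,
#'   `n`, `percentage`, `rule` (the positivity rule applied).
#' @export
trait_prevalence <- function(traits, digits = 2,
                             rounding = c("trunc", "half_up")) {
  rounding <- match.arg(rounding)
  n <- nrow(traits)
  if (!n) stop("domain error: empty trait table", call. = FALSE)
  rows <- lapply(c(QUANT_TRAITS, intersect(c(BINARY_TRAITS,
                                             OPTIONAL_BINARY_TRAITS),
                                           names(traits))), function(tr) {
    if (tr %in% QUANT_TRAITS) {
      pos <- sum(!is.na(traits[[tr]]))
      rule <- "detected (non-ND)"
    } else {
      pos <- sum(traits[[tr]], na.rm = TRUE)
      rule <- "flag positive"
    }
    data.frame(trait = tr, positive = pos, n = n,
               percentage = round_pct(100 * pos / n, digits, rounding),
               rule = rule, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("prevalence_report", "data.frame")
  out
}

#' Antagonism spectrum of an inhibition matrix
#'
#' An isolate counts against a pathogen iff a value is present (any
#' activity); broad-spectrum isolates inhibit every pathogen in the panel.
#'
#' @param inhibition an `inhibition_matrix`.
#' @param digits,rounding as in [trait_prevalence()].
#' @return list: `per_pathogen` (data.frame pathogen/inhibitors/percentage),
#'   `n_any` (isolates active against >= 1 pathogen), `any_isolates` (their
#'   ids), `broad_spectrum` (ids active against all pathogens).
#' @export
antagonism_spectrum <- function(inhibition, digits = 2,
                                rounding = c("trunc", "half_up")) {
  rounding <- match.arg(rounding)
  if (!nrow(inhibition)) stop("domain error: empty inhibition matrix",
                              call. = FALSE)
  present <- !is.na(inhibition)
  n <- nrow(inhibition)
  per_pathogen <- data.frame(
    pathogen = colnames(inhibition),
    inhibitors = colSums(present),
    percentage = round_pct(100 * colSums(present) / n, digits, rounding),
    row.names = NULL, stringsAsFactors = FALSE)
  hits <- rowSums(present)
  list(per_pathogen = per_pathogen,
       n_any = sum(hits > 0),
       any_isolates = rownames(inhibition)[hits > 0],
       broad_spectrum = rownames(inhibition)[hits == ncol(inhibition)])
}

#' Genus and tissue composition of a roster
#'
#' @param roster an `isolate_roster`.
#' @param digits,rounding as in [trait_prevalence()].
#' @return list of data.frames `by_genus` and `by_tissue` with counts and
#'   percentages over the roster size (unknown genus grouped as
#'   `"unknown"`).
#' @export
composition_summary <- function(roster, digits = 2,
                                rounding = c("trunc", "half_up")) {
  rounding <- match.arg(rounding)
  n <- nrow(roster)
  tab_of <- function(v) {
    v[is.na(v) | v == ""] <- "unknown"
    tb <- sort(table(v), decreasing = TRUE)
    data.frame(level = names(tb), count = as.integer(tb),
               percentage = round_pct(100 * as.integer(tb) / n, digits,
                                      rounding),
               stringsAsFactors = FALSE)
  }
  genus <- if ("genus" %in% names(roster)) roster$genus else
    rep(NA_character_, n)
  list(by_genus = tab_of(genus), by_tissue = tab_of(roster$tissue))
}

#' Per-trait value extremes with isolate attribution
#'
#' Maximum and minimum detected value per quantitative trait, and the global
#' inhibition extremes with isolate and pathogen attribution. Ties return
#' every attaining isolate (deterministic regardless of row order).
#'
#' @param traits a `trait_table` (or NULL).
#' @param inhibition an `inhibition_matrix` (or NULL).
#' @return list with one element per trait: `max`/`min` sublists carrying
#'   `value` and `isolates` (and `pathogen` pairs for inhibition); a trait
#'   with no detected value is reported as `empty`.
#' @export
value_extremes <- function(traits = NULL, inhibition = NULL) {
  out <- list()
  if (!is.null(traits)) {
    for (tr in QUANT_TRAITS) {
      v <- traits[[tr]]
      if (all(is.na(v))) {
        out[[tr]] <- list(empty = TRUE)
        next
      }
      out[[tr]] <- list(
        empty = FALSE,
        max = list(value = max(v, na.rm = TRUE),
                   isolates = traits$isolate_id[which(v == max(v, na.rm = TRUE))]),
        min = list(value = min(v, na.rm = TRUE),
                   isolates = traits$isolate_id[which(v == min(v, na.rm = TRUE))]))
    }
  }
  if (!is.null(inhibition) && any(!is.na(inhibition))) {
    attain <- function(val) {
      idx <- which(inhibition == val, arr.ind = TRUE)
      list(value = val,
           pairs = data.frame(isolate_id = rownames(inhibition)[idx[, 1]],
                              pathogen = colnames(inhibition)[idx[, 2]],
                              stringsAsFactors = FALSE))
    }
    out$inhibition <- list(empty = FALSE,
                           max = attain(max(inhibition, na.rm = TRUE)),
                           min = attain(min(inhibition, na.rm = TRUE)))
  } else if (!is.null(inhibition)) {
    out$inhibition <- list(empty = TRUE)
  }
  out
}

#' Bundle a full campaign report
#'
#' Prevalence, composition, antagonism spectrum and value extremes in one
#' structure, serializable to JSON.
#'
#' @param roster,traits,inhibition the three campaign tables.
#' @param rounding percentage rounding convention.
#' @return list of class `campaign_report`.
#' @export
campaign_report <- function(roster, traits, inhibition,
                            rounding = c("trunc", "half_up")) {
  rounding <- match.arg(rounding)
  structure(list(
    n_isolates = nrow(traits),
    prevalence = trait_prevalence(traits, rounding = rounding),
    composition = composition_summary(roster, rounding = rounding),
    antagonism = antagonism_spectrum(inhibition, rounding = rounding),
    extremes = value_extremes(traits, inhibition),
    validation = validate_roster(roster, traits, inhibition)),
    class = "campaign_report")
}

#' Write any report object to JSON
#'
#' @param x a report (list/data.frame structure).
#' @param path output path.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(unclass_deep(x), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.data.frame(x)) return(as.data.frame(unclass(x)))
  if (is.list(x)) return(lapply(unclass(x), unclass_deep))
  if (is.matrix(x)) return(apply(x, 1, identity, simplify = FALSE))
  x
}
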