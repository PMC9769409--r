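#' @keywords internal
"_PACKAGE"

# Column layout shared by readers, writers and the scoring stage.
QUANT_TRAITS <- c("iaa", "p_solub", "ammonia", "siderophore")
BINARY_TRAITS <- c("n2_fixation", "acc_deaminase", "chitinase",
                   "protease", "cellulase", "pectinase")
OPTIONAL_BINARY_TRAITS <- "chitinase_gene"
TISSUE_LEVELS <- c("Root", "Leaf")

# Tokens accepted as a negative flag or a "no activity" cell. The printed
# tables use an en dash; ASCII hyphen and minus are accepted too.
DASH_TOKENS <- c("-", "–", "−", "")

#' Parse "value ± error" assay cells
#'
#' Assay tables print replicate summaries as `"v ± e"` (mean and standard
#' error, n = 3 by default). This parses such cells, as well as bare numbers,
#' a configurable not-detected token, and dash/empty cells.
#'
#' @param x character vector of cells.
#' @param nd_token token meaning "not detected" (default `"ND"`). Not-detected
#'   is a first-class absent state, distinct from a measured zero; it comes
#'   back as `NA`.
#' @param context label used in parse-error messages (e.g. a column name).
#' @return list with numeric vectors `mean` and `se` (`se` is `NA` where no
#'   error term is printed; both are `NA` for ND/dash cells).
#' @export
parse_measurement <- function(x, nd_token = "ND", context = "cell") {
  x <- trimws(as.character(x))
  n <- length(x)
  mean <- se <- rep(NA_real_, n)
  absent <- is.na(x) | x %in% c(nd_token, DASH_TOKENS)
  todo <- which(!absent)
  for (i in todo) {
    parts <- trimws(strsplit(x[i], "±", fixed = TRUE)[[1]])
    v <- suppressWarnings(as.numeric(parts[1]))
    if (is.na(v)) {
      stop(sprintf("cannot parse %s value '%s' (row %d): not numeric and not '%s'",
                   context, x[i], i, nd_token), call. = FALSE)
    }
    mean[i] <- v
    if (length(parts) > 1) {
      e <- suppressWarnings(as.numeric(parts[2]))
      if (is.na(e) || e < 0) {
        stop(sprintf("cannot parse %s error term '%s' (row %d)", context, x[i], i),
             call. = FALSE)
      }
      se[i] <- e
    }
  }
  list(mean = mean, se = se)
}

#' Format numeric values back into "value ± error" cells
#'
#' Inverse of [parse_measurement()]: `NA` means become the ND token, an `NA`
#' error term is omitted. Numbers are written with [format()] at full
#' precision so a write/read round trip preserves every value exactly.
#'
#' @param mean,se numeric vectors.
#' @inheritParams parse_measurement
#' @return character vector of cells.
#' @export
format_measurement <- function(mean, se, nd_token = "ND") {
  out <- ifelse(is.na(mean), nd_token,
                ifelse(is.na(se),
                       vapply(mean, format, "", digits = 15),
                       paste(vapply(mean, format, "", digits = 15), "±",
                             vapply(se, format, "", digits = 15))))
  out
}

parse_flag <- function(x, column = "flag") {
  x <- trimws(as.character(x))
  out <- rep(NA, length(x))
  out[x == "+"] <- TRUE
  out[x %in% DASH_TOKENS] <- FALSE
  bad <- which(is.na(out) & !is.na(x))
  if (length(bad)) {
    stop(sprintf("cannot parse %s cell '%s' (row %d): expected '+' or '-'",
                 column, x[bad[1]], bad[1]), call. = FALSE)
  }
  out
}

format_flag <- function(x) ifelse(x, "+", "-")

read_csv_strict <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character",
                        fileEncoding = "UTF-8")
  if (nrow(df) == 0 || ncol(df) == 0) {
    stop("format error: '", path, "' has no data rows", call. = FALSE)
  }
  df
}

require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sprintf("format error: %s is missing required column(s): %s",
                 what, paste(missing, collapse = ", ")), call. = FALSE)
  }
}

#' Read an isolate roster table
#'
#' The roster lists one row per isolate with its code, optional morphology
#' descriptors, tissue of origin (Root/Leaf) and genus where known.
#'
#' @param path CSV file; must contain `isolate_id` and `tissue` columns.
#' @return data.frame of class `isolate_roster`.
#' @export
read_roster <- function(path) {
  df <- read_csv_strict(path)
  require_columns(df, c("isolate_id", "tissue"), "roster")
  df$isolate_id <- trimws(df$isolate_id)
  if (any(df$isolate_id == "")) stop("format error: empty isolate_id in roster",
                                     call. = FALSE)
  if ("genus" %in% names(df)) {
    df$genus[trimws(df$genus) == ""] <- NA_character_
  }
  bad <- setdiff(unique(df$tissue), TISSUE_LEVELS)
  if (length(bad)) {
    stop("validation error: tissue must be one of ",
         paste(TISSUE_LEVELS, collapse = "/"), "; found: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  class(df) <- c("isolate_roster", "data.frame")
  df
}

#' Read a per-isolate PGP trait table
#'
#' Quantitative traits (IAA and phosphate solubilization in ug/ml, ammonia in
#' umol/ml, siderophore in percent) are parsed from `"v ± e"` cells into
#' `<trait>` (mean) and `<trait>_se` columns; the ND token becomes `NA`
#' (not detected -- never coerced to zero). Binary traits (`+`/`-`) become
#' logicals.
#'
#' @param path CSV file with one row per isolate.
#' @param nd_token not-detected token, default `"ND"`.
#' @return data.frame of class `trait_table`.
#' @export
read_trait_table <- function(path, nd_token = "ND") {
  df <- read_csv_strict(path)
  require_columns(df, c("isolate_id", QUANT_TRAITS, BINARY_TRAITS), "trait table")
  out <- data.frame(isolate_id = trimws(df$isolate_id), stringsAsFactors = FALSE)
  for (tr in QUANT_TRAITS) {
    parsed <- parse_measurement(df[[tr]], nd_token = nd_token, context = tr)
    if (any(parsed$mean < 0, na.rm = TRUE)) {
      stop("validation error: negative ", tr, " value", call. = FALSE)
    }
    out[[tr]] <- parsed$mean
    out[[paste0(tr, "_se")]] <- parsed$se
  }
  if (any(out$siderophore > 100, na.rm = TRUE)) {
    stop("validation error: siderophore percent above 100", call. = FALSE)
  }
  for (tr in c(BINARY_TRAITS, intersect(OPTIONAL_BINARY_TRAITS, names(df)))) {
    out[[tr]] <- parse_flag(df[[tr]], column = tr)
  }
  class(out) <- c("trait_table", "data.frame")
  out
}

#' Write a trait table back to CSV
#'
#' Inverse of [read_trait_table()]; a write/read round trip preserves all
#' values, ND states and flags exactly.
#'
#' @param traits a `trait_table`.
#' @param path output CSV path.
#' @inheritParams read_trait_table
#' @export
write_trait_table <- function(traits, path, nd_token = "ND") {
  df <- data.frame(isolate_id = traits$isolate_id, stringsAsFactors = FALSE)
  for (tr in QUANT_TRAITS) {
    df[[tr]] <- format_measurement(traits[[tr]], traits[[paste0(tr, "_se")]],
                                   nd_token = nd_token)
  }
  for (tr in c(BINARY_TRAITS, intersect(OPTIONAL_BINARY_TRAITS, names(traits)))) {
    df[[tr]] <- format_flag(traits[[tr]])
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read an isolate-by-pathogen percent-inhibition matrix
#'
#' Dual-culture antagonism results: each cell is the percent of mycelial
#' growth inhibited, printed as `"v ± e"`. A dash or empty cell means no
#' activity and is stored as `NA` (absent), not zero.
#'
#' @param path CSV file; first column `isolate_id`, remaining columns one per
#'   pathogen.
#' @return numeric matrix (isolates x pathogens) of class
#'   `inhibition_matrix`, rownames = isolate ids; attribute `se` carries the
#'   error terms.
#' @export
read_inhibition_matrix <- function(path) {
  df <- read_csv_strict(path)
  require_columns(df, "isolate_id", "inhibition matrix")
  pathogens <- setdiff(names(df), "isolate_id")
  if (!length(pathogens)) stop("format error: no pathogen columns", call. = FALSE)
  n <- nrow(df)
  vals <- ses <- matrix(NA_real_, n, length(pathogens),
                        dimnames = list(trimws(df$isolate_id), pathogens))
  for (p in pathogens) {
    parsed <- parse_measurement(df[[p]], context = p)
    vals[, p] <- parsed$mean
    ses[, p] <- parsed$se
  }
  if (any(vals < 0 | vals > 100, na.rm = TRUE)) {
    stop("validation error: inhibition percent outside [0, 100]", call. = FALSE)
  }
  structure(vals, se = ses, class = c("inhibition_matrix", class(vals)))
}

#' Write an inhibition matrix back to CSV
#'
#' @param mat an `inhibition_matrix`.
#' @param path output CSV path.
#' @export
write_inhibition_matrix <- function(mat, path) {
  ses <- attr(mat, "se")
  if (is.null(ses)) ses <- matrix(NA_real_, nrow(mat), ncol(mat))
  df <- data.frame(isolate_id = rownames(mat), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(mat))) {
    df[[colnames(mat)[j]]] <- format_measurement(mat[, j], ses[, j], nd_token = "-")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Cross-validate the three campaign tables
#'
#' Reports (never raises) inconsistencies across the roster, trait table and
#' inhibition matrix: isolate ids present in one table but not another,
#' duplicated ids, and out-of-range values. Published campaigns are not
#' always internally consistent; the report surfaces that rather than hiding
#' or "fixing" it.
#'
#' @param roster an `isolate_roster` (or NULL to skip).
#' @param traits a `trait_table` (or NULL).
#' @param inhibition an `inhibition_matrix` (or NULL).
#' @return list of class `validation_report` with elements `duplicates`,
#'   `id_mismatches`, `out_of_range`, and logical `clean`.
#' @export
validate_roster <- function(roster = NULL, traits = NULL, inhibition = NULL) {
  ids <- list()
  if (!is.null(roster)) ids$roster <- roster$isolate_id
  if (!is.null(traits)) ids$traits <- traits$isolate_id
  if (!is.null(inhibition)) ids$inhibition <- rownames(inhibition)

  duplicates <- lapply(ids, function(v) sort(unique(v[duplicated(v)])))
  duplicates <- duplicates[vapply(duplicates, length, 1L) > 0]

  id_mismatches <- list()
  tables <- names(ids)
  if (length(tables) > 1) {
    for (a in tables) for (b in setdiff(tables, a)) {
      only <- sort(setdiff(ids[[a]], ids[[b]]))
      if (length(only)) {
        id_mismatches[[paste0("in_", a, "_not_", b)]] <- only
      }
    }
  }

  out_of_range <- character()
  if (!is.null(traits)) {
    for (tr in QUANT_TRAITS) {
      neg <- which(traits[[tr]] < 0)
      if (length(neg)) {
        out_of_range <- c(out_of_range,
                          sprintf("%s: negative value for %s", tr,
                                  paste(traits$isolate_id[neg], collapse = ", ")))
      }
    }
    high <- which(traits$siderophore > 100)
    if (length(high)) {
      out_of_range <- c(out_of_range,
                        sprintf("siderophore: >100%% for %s",
                                paste(traits$isolate_id[high], collapse = ", ")))
    }
  }
  if (!is.null(inhibition)) {
    bad <- which(inhibition < 0 | inhibition > 100, arr.ind = TRUE)
    if (nrow(bad)) {
      out_of_range <- c(out_of_range,
                        sprintf("inhibition: out of [0,100] at %s/%s",
                                rownames(inhibition)[bad[, 1]],
                                colnames(inhibition)[bad[, 2]]))
    }
  }

  structure(list(duplicates = duplicates,
                 id_mismatches = id_mismatches,
                 out_of_range = out_of_range,
                 clean = !length(duplicates) && !length(id_mismatches) &&
                   !length(out_of_range)),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  if (x$clean) {
    cat("validation report: clean\n")
    return(invisible(x))
  }
  cat("validation report:\n")
  for (tab in names(x$duplicates)) {
    cat("  duplicated ids in", tab, ":",
        paste(x$duplicates[[tab]], collapse = ", "), "\n")
  }
  for (k in names(x$id_mismatches)) {
    cat(" ", gsub("_", " ", k), ":",
        paste(x$id_mismatches[[k]], collapse = ", "), "\n")
  }
  for (msg in x$out_of_range) cat("  out of range:", msg, "\n")
  invisible(x)
}

#' Path to a packaged screening-campaign fixture
#'
#' @param name one of `"roster"`, `"traits"`, `"inhibition"`,
#'   `"bonitur_published"`.
#' @return file path inside the installed package.
#' @export
pgp_fixture <- function(name = c("roster", "traits", "inhibition",
                                 "bonitur_published")) {
  name <- match.arg(name)
  fn <- c(roster = "orchid_roster.csv", traits = "orchid_traits.csv",
          inhibition = "orchid_inhibition.csv",
          bonitur_published = "orchid_bonitur_published.csv")[[name]]
  path <- system.file("extdata", fn, package = "pgpscreen")
  if (path == "") stop("fixture not found: ", fn, call. = FALSE)
  path
}
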