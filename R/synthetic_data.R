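# Seeded generators for whole screening campaigns and pot trials. They
# emulate the statistical structure the analysis stages assume -- per-trait
# detection prevalences, printed value ranges, a sparse inhibition matrix,
# multiplicative replicate noise around configurable treatment fold changes
# -- so every stage is testable without laboratory data.

# Independent substream per component: adding a generator never perturbs
# the draws of an existing one under the same master seed.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + k * 9973) %% 2147483647)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Campaign-scale defaults: prevalences are the published counts out of 51
# isolates; value ranges are the published min-max per trait.
DEFAULT_DETECTION <- c(iaa = 27 / 51, p_solub = 25 / 51, ammonia = 35 / 51,
                       siderophore = 13 / 51, n2_fixation = 17 / 51,
                       acc_deaminase = 14 / 51, chitinase = 19 / 51,
                       protease = 22 / 51, cellulase = 12 / 51,
                       pectinase = 11 / 51)
DEFAULT_RANGES <- list(iaa = c(4.0, 43.8), p_solub = c(61.1, 289.7),
                       ammonia = c(0.9, 5.9), siderophore = c(10, 61.2))
DEFAULT_GENUS_PROBS <- c(Streptomyces = 29, Actinomadura = 6, Nocardia = 4,
                         Nocardiopsis = 4, Pseudonocardia = 3,
                         Nocardioides = 3, Microbacterium = 1,
                         Mycolicibacterium = 1) / 51
DEFAULT_PATHOGENS <- c("P_hypobrunnea", "F_solani", "R_solani",
                       "F_oxysporum", "C_capsici", "P_lamaensis", "P_theae",
                       "C_eragrostidis", "N_sphaerica", "G_cingulata")

#' Configuration for a synthetic screening campaign
#'
#' Defaults emulate the published campaign: 51 isolates, per-trait detection
#' probabilities equal to the printed prevalences, detected values uniform
#' within the printed ranges (IAA 4.0-43.8 ug/ml, phosphate solubilization
#' 61.1-289.7 ug/ml, ammonia 0.9-5.9 umol/ml, siderophore 10-61.2%), a
#' 10-pathogen inhibition panel with the printed cell-presence rate
#' (131/510) and value range 26.1-92.2%, and the printed genus and tissue
#' (root 33/51) composition.
#'
#' @param n_isolates number of isolates.
#' @param detection named per-trait detection/positivity probabilities.
#' @param ranges named list of `c(min, max)` per quantitative trait.
#' @param distribution `"uniform"` or `"log_uniform"` for detected values.
#' @param genus_probs named probability vector (must sum to 1).
#' @param tissue_prob probability of root origin.
#' @param pathogens pathogen column labels.
#' @param inhibition_sparsity probability a given isolate-pathogen cell
#'   shows activity (independent per cell).
#' @param inhibition_range `c(min, max)` percent inhibition for active
#'   cells.
#' @param seed master integer seed.
#' @return list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_isolates = 51,
                              detection = DEFAULT_DETECTION,
                              ranges = DEFAULT_RANGES,
                              distribution = c("uniform", "log_uniform"),
                              genus_probs = DEFAULT_GENUS_PROBS,
                              tissue_prob = 33 / 51,
                              pathogens = DEFAULT_PATHOGENS,
                              inhibition_sparsity = 131 / 510,
                              inhibition_range = c(26.1, 92.2),
                              seed = 1L) {
  distribution <- match.arg(distribution)
  probs <- c(detection, tissue_prob, inhibition_sparsity, genus_probs)
  if (any(probs < 0 | probs > 1)) {
    stop("configuration error: probabilities must lie in [0, 1]",
         call. = FALSE)
  }
  if (abs(sum(genus_probs) - 1) > 1e-8) {
    stop("configuration error: genus probabilities must sum to 1",
         call. = FALSE)
  }
  for (r in c(ranges, list(inhibition_range))) {
    if (length(r) != 2 || r[1] > r[2]) {
      stop("configuration error: ranges must be ordered c(min, max)",
           call. = FALSE)
    }
  }
  structure(list(n_isolates = as.integer(n_isolates), detection = detection,
                 ranges = ranges, distribution = distribution,
                 genus_probs = genus_probs, tissue_prob = tissue_prob,
                 pathogens = pathogens,
                 inhibition_sparsity = inhibition_sparsity,
                 inhibition_range = inhibition_range,
                 seed = as.integer(seed)),
            class = "screen_sim_config")
}

draw_values <- function(n, range, distribution) {
  if (distribution == "log_uniform") {
    exp(stats::runif(n, log(range[1]), log(range[2])))
  } else {
    stats::runif(n, range[1], range[2])
  }
}

#' Simulate a screening campaign
#'
#' Deterministic given the config's seed: the same config yields the same
#' roster, trait table and inhibition matrix (and hence byte-identical CSV
#' files through the writers).
#'
#' @param config a [screen_sim_config()].
#' @return list with `roster` (`isolate_roster`), `traits` (`trait_table`)
#'   and `inhibition` (`inhibition_matrix`).
#' @export
simulate_screen <- function(config = screen_sim_config()) {
  stopifnot(inherits(config, "screen_sim_config"))
  n <- config$n_isolates
  ids <- sprintf("SYN%03d", seq_len(n))

  roster <- with_seed(derive_seed(config$seed, 1L), {
    data.frame(
      isolate_id = ids,
      tissue = ifelse(stats::runif(n) < config$tissue_prob, "Root", "Leaf"),
      genus = sample(names(config$genus_probs), n, replace = TRUE,
                     prob = config$genus_probs),
      stringsAsFactors = FALSE)
  })
  class(roster) <- c("isolate_roster", "data.frame")

  traits <- with_seed(derive_seed(config$seed, 2L), {
    df <- data.frame(isolate_id = ids, stringsAsFactors = FALSE)
    for (tr in QUANT_TRAITS) {
      detected <- stats::runif(n) < config$detection[[tr]]
      vals <- rep(NA_real_, n)
      vals[detected] <- draw_values(sum(detected), config$ranges[[tr]],
                                    config$distribution)
      # replicate scatter of a 3-replicate assay, printed as "v ± e"
      ses <- rep(NA_real_, n)
      ses[detected] <- signif(vals[detected] *
                                stats::runif(sum(detected), 0.005, 0.04), 2)
      df[[tr]] <- vals
      df[[paste0(tr, "_se")]] <- ses
    }
    for (tr in BINARY_TRAITS) {
      df[[tr]] <- stats::runif(n) < config$detection[[tr]]
    }
    df
  })
  class(traits) <- c("trait_table", "data.frame")

  inhibition <- with_seed(derive_seed(config$seed, 3L), {
    m <- matrix(NA_real_, n, length(config$pathogens),
                dimnames = list(ids, config$pathogens))
    active <- matrix(stats::runif(length(m)) < config$inhibition_sparsity,
                     nrow = n)
    m[active] <- round(draw_values(sum(active), config$inhibition_range,
                                   config$distribution), 1)
    s <- matrix(NA_real_, n, length(config$pathogens),
                dimnames = dimnames(m))
    s[active] <- round(stats::runif(sum(active), 0.1, 1.5), 1)
    structure(m, se = s, class = c("inhibition_matrix", class(m)))
  })

  list(roster = roster, traits = traits, inhibition = inhibition)
}

#' Configuration for a synthetic pot trial
#'
#' Defaults emulate the published design: a control arm plus three
#' treatments (two single-strain inoculations and their consortium), two
#' harvests (35 and 70 days), five replicates per cell, and per-treatment
#' fold changes within the published 1.3-5.3 range. Replicate noise is
#' multiplicative lognormal with a configurable coefficient of variation
#' (mean 1, so configured fold changes are recovered in expectation).
#'
#' @param treatments treatment labels (excluding control).
#' @param control control arm label.
#' @param timepoints harvest days.
#' @param replicates replicates per (treatment, timepoint) cell.
#' @param control_means named per-parameter control means (all
#'   [GROWTH_PARAMETERS]).
#' @param fold_changes either a named per-treatment scalar applied to every
#'   parameter, or a treatments x parameters matrix.
#' @param noise_cv coefficient of variation of replicate noise (>= 0).
#' @param seed master integer seed.
#' @return list of class `trial_sim_config`.
#' @export
trial_sim_config <- function(treatments = c("T1", "T2", "consortium"),
                             control = "control",
                             timepoints = c(35, 70),
                             replicates = 5L,
                             control_means = c(leaf_count = 8,
                                               shoot_length = 12,
                                               root_length = 7,
                                               shoot_fresh_wt = 2.5,
                                               root_fresh_wt = 0.8,
                                               shoot_dry_wt = 0.35,
                                               root_dry_wt = 0.12,
                                               chl_a = 1.2, chl_b = 0.5),
                             fold_changes = c(T1 = 1.8, T2 = 1.6,
                                              consortium = 2.6),
                             noise_cv = 0.08,
                             seed = 1L) {
  if (any(control_means <= 0)) {
    stop("configuration error: control means must be positive",
         call. = FALSE)
  }
  missing_p <- setdiff(GROWTH_PARAMETERS, names(control_means))
  if (length(missing_p)) {
    stop("configuration error: control means missing for: ",
         paste(missing_p, collapse = ", "), call. = FALSE)
  }
  if (is.matrix(fold_changes)) {
    fc <- fold_changes[treatments, GROWTH_PARAMETERS, drop = FALSE]
  } else {
    if (!all(treatments %in% names(fold_changes))) {
      stop("configuration error: fold change missing for some treatment",
           call. = FALSE)
    }
    fc <- matrix(fold_changes[treatments], nrow = length(treatments),
                 ncol = length(GROWTH_PARAMETERS),
                 dimnames = list(treatments, GROWTH_PARAMETERS))
  }
  if (any(fc <= 0)) {
    stop("configuration error: fold changes must be positive", call. = FALSE)
  }
  if (noise_cv < 0) stop("configuration error: noise CV must be >= 0",
                         call. = FALSE)
  structure(list(treatments = treatments, control = control,
                 timepoints = timepoints, replicates = as.integer(replicates),
                 control_means = control_means[GROWTH_PARAMETERS],
                 fold_changes = fc, noise_cv = noise_cv,
                 seed = as.integer(seed)),
            class = "trial_sim_config")
}

#' Simulate a pot trial
#'
#' Each replicate value is `control_mean * fold_change * noise` where noise
#' is lognormal with mean 1 and the configured CV (exactly 1 when CV = 0).
#' The control arm has fold change 1. Deterministic given the seed.
#'
#' @param config a [trial_sim_config()].
#' @return long-format data.frame of growth records (`treatment`,
#'   `timepoint`, `replicate`, one column per parameter).
#' @export
simulate_trial <- function(config = trial_sim_config()) {
  stopifnot(inherits(config, "trial_sim_config"))
  sigma <- sqrt(log(1 + config$noise_cv^2))
  arms <- c(config$control, config$treatments)
  with_seed(derive_seed(config$seed, 4L), {
    rows <- list()
    for (tp in config$timepoints) {
      for (arm in arms) {
        for (r in seq_len(config$replicates)) {
          fc <- if (arm == config$control) {
            rep(1, length(GROWTH_PARAMETERS))
          } else {
            config$fold_changes[arm, ]
          }
          noise <- if (sigma == 0) rep(1, length(GROWTH_PARAMETERS)) else
            exp(stats::rnorm(length(GROWTH_PARAMETERS), -sigma^2 / 2, sigma))
          vals <- config$control_means * fc * noise
          rows[[length(rows) + 1L]] <- c(
            list(treatment = arm, timepoint = tp, replicate = r),
            as.list(stats::setNames(vals, GROWTH_PARAMETERS)))
        }
      }
    }
    do.call(rbind, lapply(rows, as.data.frame))
  })
}

#' Generate a synthetic calibration standard series
#'
#' Stands in for the unstated IAA / KH2PO4 / ammonium-sulfate standard
#' series: equally spaced concentrations with absorbance
#' `slope * conc + intercept + noise`.
#'
#' @param assay preset choosing the concentration span: `"iaa"` (0-50
#'   ug/ml), `"phosphate"` (0-300 ug/ml), `"ammonia"` (0-6 umol/ml).
#' @param slope,intercept true line coefficients.
#' @param n_points number of standards (>= 3).
#' @param noise_sd absorbance noise sd (0 = noiseless).
#' @param seed integer seed.
#' @return data.frame with `concentration` and `absorbance`.
#' @export
synthetic_standards <- function(assay = c("iaa", "phosphate", "ammonia"),
                                slope = 0.05, intercept = 0.02,
                                n_points = 8, noise_sd = 0, seed = 1L) {
  assay <- match.arg(assay)
  if (n_points < 3) {
    stop("configuration error: need at least 3 standard points",
         call. = FALSE)
  }
  span <- c(iaa = 50, phosphate = 300, ammonia = 6)[[assay]]
  conc <- seq(0, span, length.out = n_points)
  noise <- if (noise_sd == 0) rep(0, n_points) else
    with_seed(derive_seed(seed, 5L), stats::rnorm(n_points, 0, noise_sd))
  data.frame(concentration = conc,
             absorbance = slope * conc + intercept + noise)
}
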