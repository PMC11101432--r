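#' Default generator calibration
#'
#' Reads the versioned calibration file shipped under `inst/extdata/`:
#' the published 5x4 cross-tabulation (317 cases) from which the molecular
#' subtype priors and the truth-conditional classified-column probabilities
#' are derived, the per-column AR/TIL sampling profiles, the per-endpoint
#' hazard-ratio map (LP reference), and the default alteration frequencies
#' and HRD-score parameters.
#'
#' @return nested list mirroring the JSON file, with `counts` converted to a
#'   5x4 integer matrix.
#' @export
default_calibration <- function() {
  path <- system.file("extdata", "table1_calibration.json",
                      package = "tnbcsubtyper", mustWork = TRUE)
  cal <- jsonlite::read_json(path, simplifyVector = TRUE)
  cal$counts <- matrix(
    as.integer(t(do.call(rbind, cal$counts[MOLECULAR_LEVELS]))),
    nrow = length(MOLECULAR_LEVELS), byrow = TRUE,
    dimnames = list(truth = MOLECULAR_LEVELS, classified = SUBTYPE_LEVELS))
  cal
}

## canonical deterministic AR/TIL values per classified column (fixture)
CANONICAL_COLUMN_VALUES <- list(
  LAR = list(ar_percent = 80, ar_intensity = "strong", til_percent = 10),
  LP  = list(ar_percent = 0, ar_intensity = "negative", til_percent = 70),
  LI  = list(ar_percent = 0, ar_intensity = "negative", til_percent = 40),
  LD  = list(ar_percent = 0, ar_intensity = "negative", til_percent = 10)
)

#' Deterministic fixture reproducing the published cross-tabulation
#'
#' Builds a 317-case table whose (molecular truth x classified subtype)
#' cross-tabulation exactly reproduces the published 5x4 cell counts
#' (column totals 71/73/59/114 for LAR/LP/LI/LD). AR and TIL values are
#' fixed canonical values per intended column -- e.g. every LAR-column case
#' has `ar_percent = 80` with strong intensity (Allred 8), every LP-column
#' case has `ar_percent = 0` and `til_percent = 70` -- so [classify_table()]
#' assigns each case its intended column and repeated calls are
#' byte-identical. Survival fields and the (classifier-unused) p16 pattern
#' are filled with deterministic index-derived values.
#'
#' @return data.frame of 317 case records (see [generate_cohort()] for the
#'   column dictionary).
#' @export
build_table1_fixture <- function() {
  counts <- default_calibration()$counts
  rows <- list()
  k <- 0L
  for (col in SUBTYPE_LEVELS) {
    for (tr in MOLECULAR_LEVELS) {
      n <- counts[tr, col]
      if (n == 0L) next
      v <- CANONICAL_COLUMN_VALUES[[col]]
      idx <- k + seq_len(n)
      rows[[paste(col, tr)]] <- data.frame(
        case_id = sprintf("T1-%03d", idx),
        ar_percent = v$ar_percent,
        ar_intensity = v$ar_intensity,
        til_percent = v$til_percent,
        p16_pattern = P16_LEVELS[(idx %% 3L) + 1L],
        molecular_truth = tr,
        time_os = 24 + (idx %% 60L),
        event_os = idx %% 2L,
        time_rfs = 12 + (idx %% 48L),
        event_rfs = (idx + 1L) %% 2L,
        time_dfs = 18 + (idx %% 54L),
        event_dfs = idx %% 2L,
        stringsAsFactors = FALSE
      )
      k <- k + n
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Cohort generator configuration
#'
#' Assembles and validates the configuration for [generate_cohort()].
#' Defaults are calibrated to the published cross-tabulation: molecular
#' subtype priors are the truth-row totals over 317, and the probability
#' that a case of a given truth lands in each classified column is the
#' corresponding cell fraction. AR/TIL values are then drawn from
#' per-column profiles, which composes to the truth-conditional AR/TIL
#' distributions the generator needs.
#'
#' @param n_cases number of cases to draw.
#' @param seed integer RNG seed.
#' @param subtype_priors named probability vector over LAR/IM/BL1/M/UNC
#'   (must sum to 1 within 1e-9).
#' @param conditionals 5x4 row-stochastic matrix: P(classified column |
#'   molecular truth).
#' @param column_profiles per-column lists of candidate `ar_percent`,
#'   `ar_intensity`, `til_percent` values to sample uniformly.
#' @param hr_map per-endpoint named hazard-ratio vectors (LP = 1 reference)
#'   keyed by classified subtype.
#' @param baseline_hazard event hazard per month in the LP group (> 0).
#' @param censor_rate independent exponential censoring hazard per month
#'   (> 0).
#' @param til_increment snap TIL values to multiples of 10 (default TRUE,
#'   matching 10% scoring increments).
#' @return validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_cases, seed = 1L,
                          subtype_priors = NULL, conditionals = NULL,
                          column_profiles = NULL, hr_map = NULL,
                          baseline_hazard = NULL, censor_rate = NULL,
                          til_increment = TRUE) {
  cal <- default_calibration()
  if (is.null(subtype_priors)) {
    subtype_priors <- rowSums(cal$counts) / sum(cal$counts)
  }
  if (is.null(conditionals)) {
    conditionals <- cal$counts / rowSums(cal$counts)
  }
  column_profiles <- column_profiles %||% cal$column_profiles
  hr_map <- hr_map %||% cal$hr_map
  baseline_hazard <- baseline_hazard %||% cal$baseline_hazard
  censor_rate <- censor_rate %||% cal$censor_rate

  if (length(n_cases) != 1L || is.na(n_cases) || n_cases < 0) {
    stop("n_cases must be a nonnegative count", call. = FALSE)
  }
  if (abs(sum(subtype_priors) - 1) > 1e-9) {
    stop("subtype_priors must sum to 1 (tolerance 1e-9)", call. = FALSE)
  }
  stopifnot(setequal(names(subtype_priors), MOLECULAR_LEVELS),
            all(subtype_priors >= 0))
  conditionals <- as.matrix(conditionals)[MOLECULAR_LEVELS, SUBTYPE_LEVELS]
  if (any(abs(rowSums(conditionals) - 1) > 1e-9) || any(conditionals < 0)) {
    stop("conditionals must be row-stochastic", call. = FALSE)
  }
  for (ep in names(hr_map)) {
    if (any(unlist(hr_map[[ep]]) <= 0)) {
      stop("hazard ratios must be > 0", call. = FALSE)
    }
  }
  if (baseline_hazard <= 0 || censor_rate <= 0) {
    stop("rates must be > 0", call. = FALSE)
  }
  structure(list(
    n_cases = as.integer(n_cases), seed = as.integer(seed),
    subtype_priors = subtype_priors[MOLECULAR_LEVELS],
    conditionals = conditionals, column_profiles = column_profiles,
    hr_map = hr_map, baseline_hazard = baseline_hazard,
    censor_rate = censor_rate, til_increment = isTRUE(til_increment)
  ), class = "cohort_config")
}

sample_from <- function(values, n) {
  values <- unlist(values)
  values[sample.int(length(values), n, replace = TRUE)]
}

#' Generate a synthetic TNBC cohort
#'
#' Draws the molecular truth from the configured priors, the classified
#' column from the truth-conditional probabilities, AR/TIL readings from
#' the per-column profiles (TIL snapped to 10% increments by default), and
#' survival times for OS/RFS/DFS from an exponential proportional-hazards
#' model: the event hazard is `baseline_hazard` times the classified
#' subtype's hazard ratio, with independent exponential censoring at
#' `censor_rate`. Reproducible under the config seed.
#'
#' Column dictionary of the output: `case_id`, `ar_percent` (0--100),
#' `ar_intensity` (negative/weak/intermediate/strong), `til_percent`
#' (0--100), `p16_pattern` (carried, unused by the classifier),
#' `molecular_truth` (LAR/IM/BL1/M/UNC), and per endpoint `time_<ep>`
#' (months) and `event_<ep>` (1 = event, 0 = censored).
#'
#' @param config a [cohort_config()].
#' @return data.frame of case records.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_cases
  if (n == 0L) {
    return(data.frame(
      case_id = character(0), ar_percent = numeric(0),
      ar_intensity = character(0), til_percent = numeric(0),
      p16_pattern = character(0), molecular_truth = character(0),
      time_os = numeric(0), event_os = integer(0),
      time_rfs = numeric(0), event_rfs = integer(0),
      time_dfs = numeric(0), event_dfs = integer(0),
      stringsAsFactors = FALSE))
  }
  set.seed(config$seed)
  truth <- sample(MOLECULAR_LEVELS, n, replace = TRUE,
                  prob = config$subtype_priors)
  column <- vapply(truth, function(tr) {
    sample(SUBTYPE_LEVELS, 1L, prob = config$conditionals[tr, ])
  }, character(1))
  ar_percent <- numeric(n)
  ar_intensity <- character(n)
  til_percent <- numeric(n)
  for (col in SUBTYPE_LEVELS) {
    idx <- which(column == col)
    if (!length(idx)) next
    prof <- config$column_profiles[[col]]
    ar_percent[idx] <- sample_from(prof$ar_percent, length(idx))
    ar_intensity[idx] <- sample_from(prof$ar_intensity, length(idx))
    til <- sample_from(prof$til_percent, length(idx))
    if (!config$til_increment) {
      # jitter within the 10-point bin while keeping the classified column
      til <- pmin(pmax(til + stats::runif(length(idx), 0, 9.99), 0), 100)
    }
    til_percent[idx] <- til
  }
  out <- data.frame(
    case_id = sprintf("SIM-%05d", seq_len(n)),
    ar_percent = ar_percent,
    ar_intensity = ar_intensity,
    til_percent = til_percent,
    p16_pattern = sample(P16_LEVELS, n, replace = TRUE),
    molecular_truth = truth,
    stringsAsFactors = FALSE
  )
  for (ep in c("os", "rfs", "dfs")) {
    hr <- unlist(config$hr_map[[ep]])[column]
    hazard <- config$baseline_hazard * hr
    t_event <- stats::rexp(n, rate = hazard)
    t_cens <- stats::rexp(n, rate = config$censor_rate)
    out[[paste0("time_", ep)]] <- pmin(t_event, t_cens)
    out[[paste0("event_", ep)]] <- as.integer(t_event <= t_cens)
  }
  out
}

#' Generate expression profiles with subtype centroids
#'
#' Builds four near-orthogonal centroid vectors -- each molecular subtype
#' gets an exclusive block of genes elevated by `centroid_sep` -- and emits
#' per-sample profiles equal to the truth centroid plus i.i.d. Gaussian
#' noise (`noise_sd`). UNC-truth samples are pure noise with no centroid
#' signal (noise sd `max(noise_sd, 1)` so their profiles are never
#' constant).
#'
#' @param cases case table with `case_id` and `molecular_truth`.
#' @param n_genes number of genes (>= 10, to distinguish 4 centroids).
#' @param centroid_sep centroid block elevation (log2-scale units).
#' @param noise_sd per-gene Gaussian noise sd (>= 0).
#' @param seed RNG seed.
#' @return list with `expr` (genes x samples matrix) and `centroids`
#'   (genes x 4 matrix, columns LAR/IM/BL1/M).
#' @export
generate_expression <- function(cases, n_genes = 100, centroid_sep = 1,
                                noise_sd = 0.5, seed = 1L) {
  stopifnot(is.data.frame(cases), "molecular_truth" %in% names(cases),
            noise_sd >= 0)
  if (n_genes < 10L) {
    stop("need n_genes >= 10 to distinguish 4 centroids", call. = FALSE)
  }
  set.seed(seed)
  genes <- sprintf("g%04d", seq_len(n_genes))
  block <- floor(n_genes / 4)
  centroids <- matrix(0, n_genes, 4,
                      dimnames = list(genes, MOLECULAR_CORE))
  for (i in seq_along(MOLECULAR_CORE)) {
    centroids[((i - 1) * block + 1):(i * block), i] <- centroid_sep
  }
  n <- nrow(cases)
  expr <- matrix(0, n_genes, n,
                 dimnames = list(genes, cases$case_id %||%
                                   as.character(seq_len(n))))
  for (j in seq_len(n)) {
    tr <- cases$molecular_truth[j]
    if (tr %in% MOLECULAR_CORE) {
      expr[, j] <- centroids[, tr] + stats::rnorm(n_genes, sd = noise_sd)
    } else {
      expr[, j] <- stats::rnorm(n_genes, sd = max(noise_sd, 1))
    }
  }
  list(expr = expr, centroids = centroids)
}

#' Generate binary alteration calls and HRD-like scores
#'
#' Per-event Bernoulli draws with classified-subtype-specific frequencies
#' and a per-case HRD-like score from subtype-specific normal distributions
#' (defaults: low mean in LAR, high in LD; negative draws truncated at 0).
#'
#' @param cases classified case table (needs `classified`; run
#'   [classify_table()] first).
#' @param freq_table data.frame with columns `gene`, `event_type` and one
#'   frequency column per subtype (LAR/LP/LI/LD), all in \[0, 1\]. Defaults
#'   to the shipped calibration.
#' @param hrd_params list with `mean` (named per subtype) and `sd`.
#' @param seed RNG seed.
#' @return list with `alterations` (events x samples binary matrix,
#'   rownames `"GENE:event_type"`) and `hrd_scores` (named numeric vector).
#' @export
generate_alterations <- function(cases, freq_table = NULL, hrd_params = NULL,
                                 seed = 1L) {
  stopifnot(is.data.frame(cases))
  if (!"classified" %in% names(cases)) {
    stop("cases must carry a 'classified' column", call. = FALSE)
  }
  cal <- default_calibration()
  freq_table <- freq_table %||% cal$alteration_frequencies
  hrd_params <- hrd_params %||% cal$hrd_params
  stopifnot(all(SUBTYPE_LEVELS %in% names(freq_table)))
  freqs <- as.matrix(freq_table[, SUBTYPE_LEVELS])
  if (any(freqs < 0 | freqs > 1)) {
    stop("alteration frequencies must be in [0, 1]", call. = FALSE)
  }
  bad <- setdiff(unique(cases$classified), SUBTYPE_LEVELS)
  if (length(bad)) {
    stop("unknown subtype key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  set.seed(seed)
  n <- nrow(cases)
  ids <- cases$case_id %||% as.character(seq_len(n))
  events <- paste0(freq_table$gene, ":", freq_table$event_type)
  alts <- matrix(0L, nrow = length(events), ncol = n,
                 dimnames = list(events, ids))
  for (e in seq_along(events)) {
    p <- freqs[e, cases$classified]
    alts[e, ] <- stats::rbinom(n, 1L, p)
  }
  mu <- unlist(hrd_params$mean)[cases$classified]
  hrd <- pmax(stats::rnorm(n, mean = mu, sd = hrd_params$sd), 0)
  names(hrd) <- ids
  list(alterations = alts, hrd_scores = hrd)
}
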