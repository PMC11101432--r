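#' Read and write case tables
#'
#' Case tables are plain TSV/CSV with the column dictionary documented in
#' [generate_cohort()]. The delimiter is inferred from the file extension
#' (`.csv` -> comma, otherwise tab).
#'
#' @param path file path.
#' @return data.frame of case records.
#' @export
read_cases <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_cases
#' @param x data.frame to write.
#' @export
write_cases <- function(x, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::write.table(x, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix as genes x samples TSV
#' @param expr matrix with gene rownames; @param path output path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an alteration matrix in long format
#'
#' One row per altered (case, gene, event_type) triple.
#'
#' @param alts events x samples binary matrix (rownames `"GENE:type"`).
#' @param path output path.
#' @export
write_alterations <- function(alts, path) {
  idx <- which(alts == 1L, arr.ind = TRUE)
  ev <- strsplit(rownames(alts)[idx[, 1L]], ":", fixed = TRUE)
  df <- data.frame(
    case_id = colnames(alts)[idx[, 2L]],
    gene = vapply(ev, `[[`, character(1), 1L),
    event_type = vapply(ev, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$case_id, df$gene, df$event_type), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

RUN_CONFIG_KEYS <- c(
  "input", "n_cases", "seed", "stages", "allred_cutoff", "til_cutoffs",
  "alpha", "fdr_q", "n_genes", "centroid_sep", "noise_sd", "endpoints"
)

#' Validate a pipeline run configuration
#'
#' A run config is a named list (or a YAML/JSON file path) with keys:
#' `input` (path to an existing case table; if absent a cohort is
#' simulated), `n_cases`, `seed`, `stages` (subset of `simulate`,
#' `classify`, `molecular`, `concordance`, `survival`, `downstream`),
#' `allred_cutoff` (default 6), `til_cutoffs` (default 20, 60), `alpha`
#' (default 0.05), `fdr_q` (default 0.05), `n_genes`, `centroid_sep`,
#' `noise_sd`, `endpoints`. Unknown keys are rejected by name.
#'
#' @param config named list or path to a YAML (`.yml`/`.yaml`) or JSON file.
#' @return validated config list with defaults filled in.
#' @export
run_config <- function(config = list()) {
  if (is.character(config)) {
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("the 'yaml' package is needed for YAML configs", call. = FALSE)
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), RUN_CONFIG_KEYS)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(
    input = NULL, n_cases = 500L, seed = 1L,
    stages = c("simulate", "classify", "molecular", "concordance",
               "survival", "downstream"),
    allred_cutoff = 6, til_cutoffs = c(20, 60), alpha = 0.05, fdr_q = 0.05,
    n_genes = 100L, centroid_sep = 1, noise_sd = 0.5,
    endpoints = c("os", "rfs", "dfs")
  )
  out <- utils::modifyList(defaults, config)
  stopifnot(out$allred_cutoff %in% 0:8, length(out$til_cutoffs) == 2L)
  out
}

#' Run the full desk-scale analysis pipeline
#'
#' Executes simulate (or ingest) -> score -> classify -> molecular call ->
#' concordance -> survival -> downstream statistics, writing every artifact
#' under `out_dir` together with a manifest (package version, seed, config,
#' config hash, file checksums). Reruns with the same config are
#' bit-identical for the deterministic stages.
#'
#' @param config a [run_config()] list or config file path.
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_all <- function(config = list(), out_dir) {
  cfg <- run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  artifacts <- character(0)
  save_tsv <- function(x, name) {
    p <- file.path(out_dir, name)
    write_cases(x, p)
    artifacts <<- c(artifacts, p)
    p
  }
  report <- list(config = cfg)

  ## ingest or simulate
  cases <- if (!is.null(cfg$input)) {
    read_cases(cfg$input)
  } else {
    generate_cohort(cohort_config(cfg$n_cases, seed = cfg$seed))
  }
  if ("simulate" %in% cfg$stages && is.null(cfg$input)) {
    save_tsv(cases, "cohort.tsv")
  }

  ## score + classify
  cases <- classify_table(cases, cfg$allred_cutoff, cfg$til_cutoffs)
  save_tsv(cases, "classified.tsv")
  excl <- attr(cases, "exclusions")
  report$n_cases <- nrow(cases)
  report$exclusions <- excl

  ## molecular call on simulated expression
  if ("molecular" %in% cfg$stages) {
    ge <- generate_expression(cases, n_genes = cfg$n_genes,
                              centroid_sep = cfg$centroid_sep,
                              noise_sd = cfg$noise_sd, seed = cfg$seed)
    norm <- normalize_expression(ge$expr, pre_logged = TRUE)
    calls <- suppressMessages(
      call_cohort(norm, ge$centroids, alpha = cfg$alpha))
    save_tsv(calls, "molecular_calls.tsv")
    report$unc_fraction <- mean(calls$label == "UNC")
  }

  ## concordance against molecular truth
  if ("concordance" %in% cfg$stages && "molecular_truth" %in% names(cases)) {
    ct <- crosstab(cases$classified, cases$molecular_truth)
    acc <- overall_accuracy(ct)
    report$concordance <- list(
      counts = unclass(ct),
      column_percentages = column_percentages(ct),
      accuracy = acc$accuracy, accuracy_ci = c(acc$lower, acc$upper),
      kappa = cohen_kappa(ct),
      per_class = per_class_metrics(ct)
    )
  }

  ## survival per endpoint
  if ("survival" %in% cfg$stages) {
    report$survival <- lapply(stats::setNames(cfg$endpoints, cfg$endpoints),
      function(ep) {
        fit <- survival_by_subtype(cases, ep)
        save_tsv(fit$km, paste0("km_", ep, ".tsv"))
        list(logrank = fit$logrank,
             cox = as.data.frame(fit$cox),
             cox_reference = attr(fit$cox, "reference"))
      })
  }

  ## downstream alteration / HRD statistics on simulated genomics
  if ("downstream" %in% cfg$stages && nrow(cases) >= 8L) {
    ga <- generate_alterations(cases, seed = cfg$seed)
    save_tsv(data.frame(case_id = names(ga$hrd_scores),
                        hrd_score = unname(ga$hrd_scores)), "hrd_scores.tsv")
    p <- file.path(out_dir, "alterations.tsv")
    write_alterations(ga$alterations, p)
    artifacts <- c(artifacts, p)
    report$alterations <- alteration_tests(ga$alterations, cases$classified)
    report$hrd <- hrd_compare(ga$hrd_scores, cases$classified)
  }

  ## report + manifest
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = 10,
                       force = TRUE, pretty = TRUE)
  artifacts <- c(artifacts, report_path)
  manifest <- list(
    package = "tnbcsubtyper",
    version = as.character(utils::packageVersion("tnbcsubtyper")),
    seed = cfg$seed,
    config = cfg,
    config_hash = local({
      tf <- tempfile(fileext = ".json")
      on.exit(unlink(tf))
      jsonlite::write_json(cfg, tf, auto_unbox = TRUE, force = TRUE)
      unname(tools::md5sum(tf))
    }),
    files = data.frame(
      file = basename(artifacts),
      md5 = unname(tools::md5sum(artifacts)),
      stringsAsFactors = FALSE
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, force = TRUE, pretty = TRUE)
  invisible(manifest)
}
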