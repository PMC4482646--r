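#' @title End-to-end orchestration
#' @name pipeline
#' @description
#' One call simulates or loads a cohort, validates inclusion, fits every
#' requested method's bias surface in both covariate parameterizations
#' (their slopes differ in sign and magnitude, so both are always reported
#' side by side), runs the preterm classification report, optionally refits
#' the malaria-unexposed / non-oversampled sub-group, and emits report
#' tables plus a manifest of seeds and file hashes. Outputs are a pure
#' function of (input, seed): re-runs are byte-identical.
NULL

#' Pipeline run configuration
#'
#' @param input Either a cohort CSV path or a [sim_config()].
#' @param methods Methods to analyse; defaults to the methods measurable in
#'   the input cohort.
#' @param covariate_sources Parameterizations to fit (default both).
#' @param subgroup If `TRUE`, also refit the newborn-exam surface on the
#'   malaria-unexposed, non-oversampled sub-group.
#' @param out_dir Output directory, or `NULL` for in-memory results only.
#' @param seed Integer seed driving a simulated input.
#' @return Object of class `run_config`.
#' @export
run_config <- function(input, methods = NULL,
                       covariate_sources = c("crl", "method"),
                       subgroup = FALSE, out_dir = NULL, seed = 1L) {
  stopifnot(all(covariate_sources %in% c("crl", "method")),
            length(covariate_sources) >= 1)
  if (inherits(input, "sim_config")) {
    input$seed <- input$seed %||% seed
    methods <- methods %||%
      switch(input$cohort, dubowitz = "dubowitz", c("hc", "bpd", "sfh"))
  } else if (!is.character(input)) {
    stop("input must be a cohort CSV path or a sim_config")
  }
  if (is.null(methods) || length(methods) == 0) {
    stop("at least one method must be analysed")
  }
  structure(list(input = input, methods = methods,
                 covariate_sources = covariate_sources,
                 subgroup = subgroup, out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Descriptive summary of a cohort
#'
#' @param records Cohort `data.frame`.
#' @param standard Growth standard for Z-scores.
#' @return One-row `data.frame` of counts and summaries (maturity
#'   categories by CRL dating, SGA, malaria, missing Z-scores).
#' @export
cohort_descriptives <- function(records, standard = synthetic_growth_standard()) {
  ga <- records$newborn_ga_crl
  mat <- classify_maturity(ga)
  z <- zscore_birthweight(records$birthweight_g, ga, records$sex, standard)
  data.frame(
    n = nrow(records),
    ga_median = stats::median(ga, na.rm = TRUE),
    ga_min = min(ga, na.rm = TRUE), ga_max = max(ga, na.rm = TRUE),
    very_preterm = sum(mat == "very_preterm", na.rm = TRUE),
    preterm = sum(mat == "preterm", na.rm = TRUE),
    term = sum(mat == "term", na.rm = TRUE),
    post_term = sum(mat == "post_term", na.rm = TRUE),
    birthweight_mean = mean(records$birthweight_g, na.rm = TRUE),
    sga = sum(classify_sga(z), na.rm = TRUE),
    missing_z = sum(is.na(z)),
    malaria = sum(records$malaria_exposed)
  )
}

#' Sub-group refit of the newborn-exam bias surface
#'
#' Filters to malaria-unexposed pregnancies sampled outside the
#' pre-/post-term oversampling stratum (the prospective-inclusion
#' conditions of the biometry cohort), then refits the single-measurement
#' surface.
#'
#' @param records Cohort `data.frame` with `malaria_exposed` and
#'   `sampling_stratum` columns.
#' @param method Method to refit (default `"dubowitz"`).
#' @param covariate_source Covariate parameterization.
#' @param standard Growth standard.
#' @return A [bias_fit()] with an `n_subgroup` attribute.
#' @export
subgroup_refit <- function(records, method = "dubowitz",
                           covariate_source = "crl",
                           standard = synthetic_growth_standard()) {
  keep <- !records$malaria_exposed &
    (is.na(records$sampling_stratum) | records$sampling_stratum != "extreme")
  sub <- records[keep, , drop = FALSE]
  if (nrow(sub) == 0) stop("sub-group filter removed every record")
  tab <- build_differences(sub, method, covariate_source, standard)
  fit <- fit_bias_surface_single(tab)
  attr(fit, "n_subgroup") <- nrow(sub)
  fit
}

.records_with_sfh <- function(records) {
  k <- vapply(seq_len(nrow(records)), function(i) nrow(sfh_series(records[i, ])),
              integer(1))
  records[k >= 3, , drop = FALSE]
}

#' Run the full agreement pipeline
#'
#' @param config A [run_config()].
#' @param standard Growth standard for Z-scores.
#' @return List of class `gestagree_run` with elements `records`,
#'   `validation`, `descriptives`, `fits` (named
#'   `<method>_<covariate_source>`), `classification`, `subgroup_fit`
#'   (when requested), `exclusions` and `manifest`. When
#'   `config$out_dir` is set, fits are written as JSON, tables as CSV and
#'   the manifest (seed, package version, md5 per file) as JSON.
#' @export
run_pipeline <- function(config, standard = synthetic_growth_standard()) {
  stopifnot(inherits(config, "run_config"))
  if (inherits(config$input, "sim_config")) {
    records <- simulate_cohort(config$input)
    cohort_kind <- config$input$cohort
  } else {
    records <- read_cohort(config$input)
    cohort_kind <- if (all(records$cohort == "dubowitz")) "dubowitz" else "biometry"
  }
  validation <- validate_inclusion(records, cohort_kind)
  included <- validation$records[validation$records$included, , drop = FALSE]

  exclusions <- list(validation = validation$reasons)
  fits <- list()
  for (m in config$methods) {
    use <- if (m == "sfh") .records_with_sfh(included) else included
    for (src in config$covariate_sources) {
      tab <- build_differences(use, m, src, standard)
      exclusions[[paste0(m, "_", src, "_dropped")]] <- attr(tab, "n_dropped")
      fit <- if (m %in% c("hc", "bpd")) {
        fit_bias_surface_replicated(tab)
      } else {
        fit_bias_surface_single(tab)
      }
      fits[[paste0(m, "_", src)]] <- fit
    }
  }
  cls_methods <- config$methods
  cls_records <- included
  classification <- classification_report(
    if ("sfh" %in% cls_methods) included else cls_records,
    setdiff(cls_methods, "sfh"))
  if ("sfh" %in% cls_methods) {
    sfh_rep <- classification_report(.records_with_sfh(included), "sfh")
    classification <- rbind(classification, sfh_rep[sfh_rep$method == "sfh", ])
  }
  descriptives <- cohort_descriptives(included, standard)

  result <- list(records = records, validation = validation,
                 descriptives = descriptives, fits = fits,
                 classification = classification, exclusions = exclusions)
  if (isTRUE(config$subgroup)) {
    result$subgroup_fit <- subgroup_refit(included, standard = standard)
  }

  manifest <- list(
    seed = if (inherits(config$input, "sim_config")) config$input$seed else NULL,
    input = if (is.character(config$input)) config$input else "simulation",
    n_records = nrow(records), n_included = nrow(included),
    methods = config$methods, covariate_sources = config$covariate_sources,
    package_version = as.character(utils::packageVersion("gestagree"))
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (nm in names(fits)) {
      p <- file.path(config$out_dir, paste0("fit_", nm, ".json"))
      write_bias_fit(fits[[nm]], p, provenance = list(seed = manifest$seed))
      files <- c(files, p)
    }
    p <- file.path(config$out_dir, "classification.csv")
    utils::write.csv(classification, p, row.names = FALSE)
    files <- c(files, p)
    p <- file.path(config$out_dir, "descriptives.csv")
    utils::write.csv(descriptives, p, row.names = FALSE)
    files <- c(files, p)
    manifest$files <- as.list(tools::md5sum(files))
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result$manifest <- manifest
  class(result) <- "gestagree_run"
  result
}

#' @export
print.gestagree_run <- function(x, ...) {
  cat("<gestagree_run> ", x$manifest$n_included, "/", x$manifest$n_records,
      " records included; fits: ", paste(names(x$fits), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}
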