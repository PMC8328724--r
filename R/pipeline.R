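#' Run the full secretome DEP pipeline on a synthetic or supplied dataset
#'
#' Orchestrates the stages end to end: simulate (or take a supplied
#' dataset), spike-normalize, collapse technical replicates, apply the
#' quantifiability / missingness / coverage filter funnel per endpoint,
#' compute paired log2 fold changes, call deregulated proteins, exclude
#' control-group DEP, partition the identification sets by endpoint,
#' summarize, and (when an annotation is supplied) run over-representation
#' analysis of the up- and down-regulated sets separately against the
#' endpoint's retained proteins as universe.
#'
#' The filter funnel is applied independently within each endpoint's four
#' six-animal cells (CT and LPS at baseline and endpoint), mirroring the
#' fact that the two endpoints are separate acquisition batches: a protein
#' can be retained at one endpoint and withdrawn at the other, which is
#' what makes the common/specific partition non-trivial.
#'
#' @param config A [simulation_config()] used when `data` is `NULL`.
#' @param data Optional list with `quant` and `design` (e.g. from
#'   [generate_dataset()] or read from disk) to run instead of simulating.
#' @param annotation Optional annotation tibble for enrichment.
#' @param spike_id Spike-in accession (default `P00924`).
#' @param min_peptides,min_score,max_na_per_group,min_coverage_pct
#'   Filter-funnel thresholds.
#' @param fc_threshold,min_qualifying DEP-rule thresholds.
#' @param out_dir Optional directory; when given, all stage outputs and the
#'   manifest are written there.
#' @return A list: `calls` (combined LPS call tibble after control
#'   exclusion), `partition`, `tables` (summary tables per analysis level),
#'   `enrichment` (or `NULL`), `filter_reports` (per endpoint),
#'   `retained_ids` (per endpoint), `truth` (when simulated) and
#'   `manifest`.
#' @export
run_pipeline <- function(config = simulation_config(),
                         data = NULL,
                         annotation = NULL,
                         spike_id = NULL,
                         min_peptides = 2, min_score = 6,
                         max_na_per_group = 2, min_coverage_pct = 15,
                         fc_threshold = 1, min_qualifying = 4,
                         out_dir = NULL) {
  if (is.null(data)) {
    if (min_qualifying > config$n_animals_per_group) {
      abort_dep("min_qualifying exceeds the group size", "config")
    }
    data <- generate_dataset(config)
    if (is.null(spike_id)) spike_id <- config$spike_protein_id
  }
  if (is.null(spike_id)) spike_id <- "P00924"
  quant <- validate_quant_matrix(data$quant)
  design <- validate_design(data$design)
  check_quant_design(quant, design)

  normalized <- normalize_to_spike(quant, spike_id)
  collapsed <- collapse_tech_reps(normalized, design)

  endpoints <- sort(setdiff(unique(collapsed$design$timepoint), "T0"))
  per_endpoint <- list()
  for (ep in endpoints) {
    d_ep <- collapsed$design[
      .endpoint_of_group(collapsed$design$group) == ep, ]
    q_ep <- collapsed$quant[, c(.quant_meta_cols, d_ep$sample_id)]

    f1 <- filter_quantifiable(q_ep, min_peptides, min_score)
    f2 <- filter_missingness(f1$quant, d_ep, max_na_per_group)
    f3 <- filter_coverage(f2$quant, min_coverage_pct)
    reports <- dplyr::bind_rows(f1$report, f2$report, f3$report)
    check_filter_chain(reports)

    q_f <- f3$quant
    # the spike is an instrument standard, not a candidate biomarker
    retained <- setdiff(q_f$protein_id, spike_id)
    fc <- paired_log2fc(q_f[q_f$protein_id != spike_id, ], d_ep)
    calls <- call_dep(fc, fc_threshold, min_qualifying)
    lps_group <- paste0("LPS", sub("^T", "", ep))
    ct_group <- paste0("CT", sub("^T", "", ep))
    excl <- exclude_control_dep(calls[calls$group == lps_group, ],
                                calls[calls$group == ct_group, ])
    per_endpoint[[ep]] <- list(
      reports = reports, retained_ids = retained,
      fold_changes = fc, calls = excl$retained,
      excluded_ids = excl$excluded_ids
    )
  }

  all_calls <- dplyr::bind_rows(lapply(per_endpoint, `[[`, "calls"))
  control_excluded <- sort(unique(unlist(
    lapply(per_endpoint, `[[`, "excluded_ids")
  )))
  partition <- partition_sets(
    ids_t50 = if ("T50" %in% endpoints) per_endpoint$T50$retained_ids
              else character(0),
    ids_t90 = if ("T90" %in% endpoints) per_endpoint$T90$retained_ids
              else character(0),
    calls = all_calls,
    control_excluded_ids = control_excluded
  )
  tables <- summarize_dep(all_calls, partition, meta = quant)

  enr <- NULL
  if (!is.null(annotation)) {
    enr <- list()
    for (ep in endpoints) {
      universe <- per_endpoint[[ep]]$retained_ids
      calls_ep <- per_endpoint[[ep]]$calls
      for (dirn in c("up", "down")) {
        ids <- calls_ep$protein_id[calls_ep$direction == dirn]
        enr[[paste(ep, dirn, sep = "_")]] <-
          enrich(ids, universe, annotation)
      }
    }
  }

  settings <- list(
    spike_id = spike_id, min_peptides = min_peptides,
    min_score = min_score, max_na_per_group = max_na_per_group,
    min_coverage_pct = min_coverage_pct, fc_threshold = fc_threshold,
    min_qualifying = min_qualifying
  )
  manifest <- list(
    package = "pairedDEP",
    version = as.character(utils::packageVersion("pairedDEP")),
    seed = if (!is.null(config$seed)) config$seed else NA_integer_,
    config_hash = rlang::hash(list(config = unclass(config),
                                   settings = settings)),
    settings = settings,
    filter_reports = lapply(per_endpoint, function(x) {
      r <- x$reports
      r$removed_ids <- NULL
      r
    }),
    n_retained = lapply(per_endpoint, function(x) length(x$retained_ids)),
    n_control_excluded = length(control_excluded),
    n_dep = lapply(per_endpoint, function(x)
      sum(x$calls$direction != "none"))
  )

  result <- list(
    calls = all_calls, partition = partition, tables = tables,
    enrichment = enr,
    filter_reports = lapply(per_endpoint, `[[`, "reports"),
    fold_changes = lapply(per_endpoint, `[[`, "fold_changes"),
    retained_ids = lapply(per_endpoint, `[[`, "retained_ids"),
    truth = data$truth, manifest = manifest
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_results(tables, out_dir)
    readr::write_tsv(all_calls, file.path(out_dir, "dep_calls.tsv"),
                     na = "NA")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    if (!is.null(enr)) {
      write_results(enr, file.path(out_dir, "enrichment"))
    }
  }
  result
}
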