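.geomean <- function(x) exp(mean(log(x)))

filter_report <- function(stage, before_ids, after_ids) {
  removed <- setdiff(before_ids, after_ids)
  tibble::tibble(
    stage = stage,
    n_before = length(before_ids),
    n_after = length(after_ids),
    removed_ids = list(removed)
  )
}

#' Check that a chain of filter reports is gap-free
#'
#' Each stage's `n_before` must equal the previous stage's `n_after`, and
#' within every stage `n_after = n_before - length(removed_ids)`.
#'
#' @param reports A filter-report tibble (rows in stage order).
#' @return Invisibly `TRUE`; errors on any inconsistency.
#' @export
check_filter_chain <- function(reports) {
  for (i in seq_len(nrow(reports))) {
    if (reports$n_after[i] !=
          reports$n_before[i] - length(reports$removed_ids[[i]])) {
      abort_dep(paste0("filter stage '", reports$stage[i],
                       "' has inconsistent counts"), "filter_chain")
    }
    if (i > 1 && reports$n_before[i] != reports$n_after[i - 1]) {
      abort_dep(paste0("filter chain broken between '", reports$stage[i - 1],
                       "' and '", reports$stage[i], "'"), "filter_chain")
    }
  }
  invisible(TRUE)
}

#' Normalize intensities to the spiked internal standard
#'
#' Every sample column is divided by that sample's spike intensity relative
#' to the geometric mean of the spike across all samples. The geometric-mean
#' reference (rather than an arbitrary anchor sample) makes the output
#' invariant to sample order, and the operation idempotent: after one pass
#' the spike is constant across samples, so a second pass divides by 1.
#'
#' @param quant A quantification matrix.
#' @param spike_id Accession of the spike-in row (default yeast enolase,
#'   `P00924`).
#' @return The normalized quantification matrix (spike row retained).
#' @export
normalize_to_spike <- function(quant, spike_id = "P00924") {
  validate_quant_matrix(quant)
  sc <- sample_columns(quant)
  row <- which(quant$protein_id == spike_id)
  if (length(row) != 1) {
    abort_dep(paste0("spike-in '", spike_id,
                     "' not found in quantification matrix"), "normalize")
  }
  spike <- unlist(quant[row, sc], use.names = FALSE)
  if (anyNA(spike)) {
    abort_dep("spike-in intensity is missing in at least one sample",
              "normalize")
  }
  if (any(spike <= 0)) {
    abort_dep("spike-in intensity must be positive in every sample",
              "normalize")
  }
  factors <- spike / .geomean(spike)
  for (i in seq_along(sc)) {
    quant[[sc[i]]] <- quant[[sc[i]]] / factors[i]
  }
  quant
}

#' Collapse technical replicates to one column per (animal, time point)
#'
#' Replicate intensities are averaged arithmetically on the raw scale over
#' the observed values; a collapsed cell is missing only if every replicate
#' is missing. Returns the collapsed matrix together with a matching
#' animal-level design (one row per animal and time point, `tech_rep = 1`).
#'
#' @param quant A quantification matrix.
#' @param design Its sample design.
#' @return A list with elements `quant` and `design`.
#' @export
collapse_tech_reps <- function(quant, design) {
  validate_quant_matrix(quant)
  design <- as.data.frame(validate_design(design))
  check_quant_design(quant, design)

  key <- paste(design$animal_id, design$timepoint, sep = "_")
  groups <- split(design$sample_id, key)
  meta <- quant[, .quant_meta_cols]
  collapsed <- lapply(groups, function(cols) {
    m <- as.matrix(quant[, cols, drop = FALSE])
    v <- rowMeans(m, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  })
  out <- dplyr::bind_cols(meta, tibble::as_tibble(collapsed))

  first <- design[!duplicated(key), ]
  new_design <- tibble::tibble(
    sample_id = paste(first$animal_id, first$timepoint, sep = "_"),
    animal_id = first$animal_id,
    condition = first$condition,
    timepoint = first$timepoint,
    tech_rep = 1L,
    group = first$group
  )
  new_design <- new_design[order(new_design$group, new_design$animal_id,
                                 new_design$timepoint), ]
  out <- out[, c(.quant_meta_cols, new_design$sample_id)]
  list(quant = out, design = new_design)
}

#' Filter to quantifiable proteins
#'
#' Retains proteins identified with at least `min_peptides` unique peptides
#' and a quality score of at least `min_score` (both bounds inclusive).
#'
#' @param quant A quantification matrix.
#' @param min_peptides Minimum unique-peptide count (default 2).
#' @param min_score Minimum quality score (default 6).
#' @return A list with the filtered `quant` and a one-row `report`.
#' @export
filter_quantifiable <- function(quant, min_peptides = 2, min_score = 6) {
  validate_quant_matrix(quant)
  if (anyNA(quant$n_unique_peptides) || anyNA(quant$quality_score)) {
    abort_dep("peptide-count or score metadata is missing", "format")
  }
  keep <- quant$n_unique_peptides >= min_peptides &
    quant$quality_score >= min_score
  out <- quant[keep, ]
  list(quant = out,
       report = filter_report("quantifiable", quant$protein_id,
                              out$protein_id))
}

#' Filter proteins by per-group missingness
#'
#' A protein is withdrawn if, in any (group, time point) cell of the design,
#' it is missing in more than `max_na_per_group` of that cell's samples
#' (i.e. missing in at least `max_na_per_group + 1`). Intended to run after
#' technical replicates have been collapsed, so each cell holds one column
#' per animal.
#'
#' @param quant A quantification matrix.
#' @param design Its (collapsed) sample design.
#' @param max_na_per_group Maximum tolerated missing values per cell
#'   (default 2, i.e. withdrawn at 3 or more).
#' @return A list with the filtered `quant` and a one-row `report`.
#' @export
filter_missingness <- function(quant, design, max_na_per_group = 2) {
  validate_quant_matrix(quant)
  design <- validate_design(design)
  check_quant_design(quant, design)
  cells <- split(design$sample_id,
                 paste(design$group, design$timepoint, sep = "."))
  if (any(lengths(cells) == 0)) {
    abort_dep("a (group, timepoint) cell has no samples", "design")
  }
  na_counts <- vapply(cells, function(cols) {
    rowSums(is.na(as.matrix(quant[, cols, drop = FALSE])))
  }, numeric(nrow(quant)))
  if (nrow(quant) == 1) na_counts <- matrix(na_counts, nrow = 1)
  keep <- apply(na_counts, 1, max) <= max_na_per_group
  out <- quant[keep, ]
  list(quant = out,
       report = filter_report("missingness", quant$protein_id,
                              out$protein_id))
}

#' Filter proteins by sequence coverage
#'
#' Retains proteins whose sequence coverage is at least `min_coverage_pct`
#' (inclusive bound, following the rule that proteins with *less than* the
#' cutoff are withdrawn).
#'
#' @param quant A quantification matrix.
#' @param min_coverage_pct Coverage cutoff in percent (default 15).
#' @return A list with the filtered `quant` and a one-row `report`.
#' @export
filter_coverage <- function(quant, min_coverage_pct = 15) {
  validate_quant_matrix(quant)
  cov <- quant$coverage_pct
  if (anyNA(cov) || any(cov < 0 | cov > 100)) {
    abort_dep("coverage_pct must be within [0, 100] and non-missing",
              "format")
  }
  keep <- cov >= min_coverage_pct
  out <- quant[keep, ]
  list(quant = out,
       report = filter_report("coverage", quant$protein_id, out$protein_id))
}
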