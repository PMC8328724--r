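#' Per-animal paired log2 fold changes (endpoint vs baseline)
#'
#' For every protein, group and animal, computes
#' `log2(intensity_Tend / intensity_T0)` from the animal's own pair of
#' columns. The matrix is expected to be spike-normalized and
#' replicate-collapsed. Missingness propagates: the fold change is missing
#' exactly when either member of the pair is missing. An observed zero in a
#' pair is an error — the ratio is undefined and silently dropping it would
#' hide a data problem.
#'
#' @param quant A normalized, replicate-collapsed quantification matrix.
#' @param design Its animal-level sample design.
#' @return A fold-change tibble with columns `protein_id`, `group`,
#'   `animal_id`, `log2fc`.
#' @export
paired_log2fc <- function(quant, design) {
  validate_quant_matrix(quant)
  design <- validate_design(design)
  check_quant_design(quant, design)

  t0 <- design[design$timepoint == "T0", ]
  tend <- design[design$timepoint != "T0", ]
  if (!setequal(t0$animal_id, tend$animal_id)) {
    abort_dep("an animal lacks its baseline or endpoint sample", "design")
  }
  tend <- tend[match(t0$animal_id, tend$animal_id), ]

  m0 <- as.matrix(quant[, t0$sample_id, drop = FALSE])
  m1 <- as.matrix(quant[, tend$sample_id, drop = FALSE])
  pair_zero <- (m0 == 0 & !is.na(m1)) | (m1 == 0 & !is.na(m0))
  if (any(pair_zero, na.rm = TRUE)) {
    abort_dep(
      "zero intensity within a baseline/endpoint pair: log ratio undefined",
      "zero_intensity"
    )
  }
  fc <- log2(m1 / m0)

  n_prot <- nrow(quant)
  n_anim <- nrow(t0)
  tibble::tibble(
    protein_id = rep(quant$protein_id, times = n_anim),
    group = rep(t0$group, each = n_prot),
    animal_id = rep(t0$animal_id, each = n_prot),
    log2fc = as.vector(fc)
  ) %>%
    dplyr::arrange(.data$protein_id, .data$group, .data$animal_id)
}

#' Call deregulated proteins by the k-of-n fold-change rule
#'
#' A protein is called upregulated in a group when its per-animal log2 fold
#' change is at or above `+threshold` in at least `min_qualifying` animals,
#' and downregulated when at or below `-threshold` in at least
#' `min_qualifying` animals (defaults: |log2FC| >= 1 in at least 4 of 6).
#' The two tallies are counted independently; with the default 4-of-6 they
#' can never both reach the cutoff. Animals with a missing fold change count
#' toward neither tally, and the denominator stays the group size — the rule
#' is an absolute count, not a proportion of observed animals.
#'
#' Summary statistics (median, and the range endpoints) are computed over
#' the qualifying animals only. The range is reported in magnitude
#' orientation: `log2fc_min` is the qualifying value closest to the
#' threshold and `log2fc_max` the most extreme, both carrying the call's
#' sign (so a down call may read `-1.96 (-1.19; -5.20)`).
#'
#' @param fc A fold-change tibble from [paired_log2fc()].
#' @param threshold Absolute log2 fold-change cutoff (default 1).
#' @param min_qualifying Minimum number of qualifying animals (default 4).
#' @return A call tibble: `protein_id`, `group`, `direction` (`up`, `down`
#'   or `none`), `n_up`, `n_down`, `n_qualifying`, `n_animals`,
#'   `log2fc_median`, `log2fc_min`, `log2fc_max`.
#' @export
call_dep <- function(fc, threshold = 1, min_qualifying = 4) {
  needed <- c("protein_id", "group", "animal_id", "log2fc")
  if (!all(needed %in% names(fc))) {
    abort_dep("fold-change table needs protein_id, group, animal_id, log2fc",
              "format")
  }
  group_sizes <- tapply(fc$animal_id, fc$group,
                        function(a) length(unique(a)))
  if (any(min_qualifying > group_sizes)) {
    abort_dep("min_qualifying exceeds the number of animals in a group",
              "config")
  }

  call_one <- function(values, n_animals) {
    n_up <- sum(values >= threshold, na.rm = TRUE)
    n_down <- sum(values <= -threshold, na.rm = TRUE)
    direction <- if (n_up >= min_qualifying) "up"
      else if (n_down >= min_qualifying) "down"
      else "none"
    if (direction == "none") {
      return(tibble::tibble(
        direction = direction, n_up = n_up, n_down = n_down,
        n_qualifying = max(n_up, n_down), n_animals = n_animals,
        log2fc_median = NA_real_, log2fc_min = NA_real_,
        log2fc_max = NA_real_
      ))
    }
    qual <- if (direction == "up") {
      values[!is.na(values) & values >= threshold]
    } else {
      values[!is.na(values) & values <= -threshold]
    }
    sgn <- if (direction == "up") 1 else -1
    tibble::tibble(
      direction = direction, n_up = n_up, n_down = n_down,
      n_qualifying = length(qual), n_animals = n_animals,
      log2fc_median = stats::median(qual),
      log2fc_min = sgn * min(abs(qual)),
      log2fc_max = sgn * max(abs(qual))
    )
  }

  fc %>%
    dplyr::group_by(.data$protein_id, .data$group) %>%
    dplyr::reframe(call_one(.data$log2fc, length(unique(.data$animal_id)))) %>%
    dplyr::arrange(.data$protein_id, .data$group)
}

.endpoint_of_group <- function(group) {
  paste0("T", sub("^(CT|LPS)", "", group))
}

#' Exclude proteins deregulated in the matched control group
#'
#' Any protein called deregulated (either direction) in the control group of
#' an endpoint is removed from that endpoint's LPS candidate list — such a
#' change is attributable to the procedure itself (anesthesia, cannulation,
#' fluid administration, repeated sampling), not the insult under study.
#'
#' @param lps_calls Call tibble for the LPS group of one endpoint.
#' @param ct_calls Call tibble for the control (CT) group of the same
#'   endpoint.
#' @return A list: `retained` (LPS calls with excluded proteins dropped and
#'   a `control_excluded = FALSE` column) and `excluded_ids`.
#' @export
exclude_control_dep <- function(lps_calls, ct_calls) {
  lps_groups <- unique(lps_calls$group)
  ct_groups <- unique(ct_calls$group)
  if (length(lps_groups) != 1 || length(ct_groups) != 1 ||
        !startsWith(lps_groups, "LPS") || !startsWith(ct_groups, "CT") ||
        .endpoint_of_group(lps_groups) != .endpoint_of_group(ct_groups)) {
    abort_dep(
      "calls must cover one LPS group and its matched CT group (same endpoint)",
      "group_mismatch"
    )
  }
  excluded_ids <- sort(ct_calls$protein_id[ct_calls$direction != "none"])
  retained <- lps_calls[!lps_calls$protein_id %in% excluded_ids, ]
  retained$control_excluded <- FALSE
  list(retained = retained, excluded_ids = excluded_ids)
}

#' Partition identification sets by endpoint
#'
#' Splits the retained proteins into those identified at both endpoints
#' (common), only at the first, and only at the second — the three analysis
#' levels downstream summaries are reported in.
#'
#' @param ids_t50 Protein accessions retained at the 50-minute endpoint.
#' @param ids_t90 Protein accessions retained at the 90-minute endpoint.
#' @param calls Optional combined call tibble to attach.
#' @param control_excluded_ids Optional accessions removed by control
#'   exclusion.
#' @return A `dep_partition` list: `common_ids`, `t50_specific_ids`,
#'   `t90_specific_ids`, `calls`, `control_excluded_ids`.
#' @export
partition_sets <- function(ids_t50, ids_t90, calls = NULL,
                           control_excluded_ids = character(0)) {
  common <- sort(intersect(ids_t50, ids_t90))
  structure(
    list(
      common_ids = common,
      t50_specific_ids = sort(setdiff(ids_t50, ids_t90)),
      t90_specific_ids = sort(setdiff(ids_t90, ids_t50)),
      calls = calls,
      control_excluded_ids = sort(control_excluded_ids)
    ),
    class = "dep_partition"
  )
}

.format_summary <- function(med, mn, mx) {
  sprintf("%.2f (%.2f; %.2f)", med, mn, mx)
}

#' Summary tables of deregulated proteins
#'
#' Produces publication-style result tables: accession, gene name,
#' direction, `median (min; max)` of the qualifying log2 fold changes, and
#' `n/N` qualifying animals. Rows are ordered upregulated first, then by
#' descending qualifying count, then by descending |median|. Proteins in
#' the partition's control-excluded list never appear.
#'
#' @param calls A call tibble (any mix of groups).
#' @param partition Optional [partition_sets()] result; when given, one
#'   table per analysis level is returned (`common_T50`, `common_T90`,
#'   `t50_specific`, `t90_specific`), otherwise a single table.
#' @param meta Optional tibble with `protein_id` and `gene_name` used to
#'   decorate rows.
#' @return A tibble, or a named list of tibbles when `partition` is given.
#' @export
summarize_dep <- function(calls, partition = NULL, meta = NULL) {
  one_table <- function(sub) {
    sub <- sub[sub$direction != "none", , drop = FALSE]
    if (!is.null(partition)) {
      sub <- sub[!sub$protein_id %in% partition$control_excluded_ids, ,
                 drop = FALSE]
    }
    out <- tibble::tibble(
      protein_id = sub$protein_id,
      gene_name = if (!is.null(meta)) {
        meta$gene_name[match(sub$protein_id, meta$protein_id)]
      } else NA_character_,
      group = sub$group,
      direction = sub$direction,
      log2fc_median = sub$log2fc_median,
      log2fc_min = sub$log2fc_min,
      log2fc_max = sub$log2fc_max,
      summary = .format_summary(sub$log2fc_median, sub$log2fc_min,
                                sub$log2fc_max),
      n_of_n = paste0(sub$n_qualifying, "/", sub$n_animals)
    )
    out[order(out$direction != "up",
              -as.integer(sub$n_qualifying),
              -abs(out$log2fc_median)), ]
  }

  if (is.null(partition)) {
    return(one_table(calls))
  }
  ep <- .endpoint_of_group(calls$group)
  list(
    common_T50 = one_table(calls[calls$protein_id %in% partition$common_ids &
                                   ep == "T50", ]),
    common_T90 = one_table(calls[calls$protein_id %in% partition$common_ids &
                                   ep == "T90", ]),
    t50_specific = one_table(
      calls[calls$protein_id %in% partition$t50_specific_ids & ep == "T50", ]
    ),
    t90_specific = one_table(
      calls[calls$protein_id %in% partition$t90_specific_ids & ep == "T90", ]
    )
  )
}
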