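#' Simulation configuration for paired-design secretome data
#'
#' Assembles and validates the parameters of the synthetic-data generator.
#' The defaults emulate the paired endotoxemia study design: four groups
#' (CT50, LPS50, CT90, LPS90) of six animals, each animal sampled at
#' baseline `T0` and at its group's endpoint, each sample measured in
#' technical duplicate, with a yeast enolase spike-in (accession `P00924`)
#' added in fixed amount to every sample as the normalization standard.
#'
#' Planted truth: `floor(n_proteins * frac)` proteins are assigned to each
#' planted class (up, down, control drift). Up/down proteins change by
#' `± effect_log2fc` between `T0` and the endpoint in the LPS groups only;
#' control-drift proteins change (random sign) in every group, so a correct
#' control-exclusion step must remove them. The spike-in is never planted
#' and never made missing.
#'
#' @param n_animals_per_group Animals per (condition, endpoint) group.
#' @param groups Character vector of group labels, condition pasted to
#'   endpoint minutes (e.g. `"LPS90"`).
#' @param n_proteins Number of simulated rat proteins (the spike-in is added
#'   on top of these).
#' @param n_technical_replicates Instrumental replicates per sample.
#' @param spike_protein_id Accession of the spiked internal standard.
#' @param spike_amount True spike intensity, arbitrary units.
#' @param effect_log2fc Planted deregulation magnitude (log2 ratio).
#' @param frac_deregulated_up,frac_deregulated_down Fractions of proteins
#'   planted up-/downregulated in the LPS groups.
#' @param frac_control_drift Fraction planted deregulated in the control
#'   groups too.
#' @param missing_rate Overall fraction of (non-spike) cells made missing.
#' @param mnar_strength Intensity-dependence of missingness: dropout
#'   probability is proportional to `plogis(-mnar_strength * z)` with `z`
#'   the standardized log10 intensity; 0 gives missing-completely-at-random.
#' @param coverage_range Range (low, high) of simulated sequence coverage, %.
#' @param baseline_log10_range Range of per-protein mean log10 intensity.
#' @param baseline_sd_log10 Between-animal sd of baseline log10 intensity.
#' @param tech_rep_sd_log10 Technical-replicate noise sd, log10 scale.
#' @param scale_factor_range Per-sample global scale factors are drawn
#'   log-uniformly in this range; they hit every protein including the
#'   spike, which is what makes the normalization stage necessary.
#' @param frac_low_evidence Fraction of null proteins emitted with
#'   sub-threshold identification metadata (single peptide or score < 6),
#'   so that the quantifiability filter has work to do.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_animals_per_group = 6L,
                              groups = c("CT50", "LPS50", "CT90", "LPS90"),
                              n_proteins = 300L,
                              n_technical_replicates = 2L,
                              spike_protein_id = "P00924",
                              spike_amount = 7e5,
                              effect_log2fc = 2,
                              frac_deregulated_up = 0.05,
                              frac_deregulated_down = 0.05,
                              frac_control_drift = 0.02,
                              missing_rate = 0.1,
                              mnar_strength = 1,
                              coverage_range = c(5, 95),
                              baseline_log10_range = c(4, 8),
                              baseline_sd_log10 = 0.2,
                              tech_rep_sd_log10 = 0.05,
                              scale_factor_range = c(0.5, 2),
                              frac_low_evidence = 0.1,
                              seed = 1L) {
  cfg <- list(
    n_animals_per_group = as.integer(n_animals_per_group),
    groups = groups,
    n_proteins = as.integer(n_proteins),
    n_technical_replicates = as.integer(n_technical_replicates),
    spike_protein_id = spike_protein_id,
    spike_amount = spike_amount,
    effect_log2fc = effect_log2fc,
    frac_deregulated_up = frac_deregulated_up,
    frac_deregulated_down = frac_deregulated_down,
    frac_control_drift = frac_control_drift,
    missing_rate = missing_rate,
    mnar_strength = mnar_strength,
    coverage_range = coverage_range,
    baseline_log10_range = baseline_log10_range,
    baseline_sd_log10 = baseline_sd_log10,
    tech_rep_sd_log10 = tech_rep_sd_log10,
    scale_factor_range = scale_factor_range,
    frac_low_evidence = frac_low_evidence,
    seed = as.integer(seed)
  )
  props <- c("frac_deregulated_up", "frac_deregulated_down",
             "frac_control_drift", "missing_rate", "frac_low_evidence")
  for (p in props) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) {
      abort_dep(paste0(p, " must be in [0, 1]"), "config")
    }
  }
  if (cfg$frac_deregulated_up + cfg$frac_deregulated_down +
        cfg$frac_control_drift > 1) {
    abort_dep("planted fractions (up + down + control drift) exceed 1",
              "config")
  }
  if (cfg$n_animals_per_group < 1) {
    abort_dep("n_animals_per_group must be >= 1", "config")
  }
  if (cfg$n_technical_replicates < 1) {
    abort_dep("n_technical_replicates must be >= 1", "config")
  }
  if (cfg$mnar_strength < 0) abort_dep("mnar_strength must be >= 0", "config")
  if (cfg$spike_amount <= 0) abort_dep("spike_amount must be > 0", "config")
  if (length(cfg$coverage_range) != 2 ||
        cfg$coverage_range[1] > cfg$coverage_range[2] ||
        cfg$coverage_range[1] < 0 || cfg$coverage_range[2] > 100) {
    abort_dep("coverage_range must be (low, high) within [0, 100]", "config")
  }
  bad_groups <- !grepl("^(CT|LPS)(50|90)$", cfg$groups)
  if (length(cfg$groups) == 0 || any(bad_groups)) {
    abort_dep("groups must be condition+endpoint labels like 'LPS90'",
              "config")
  }
  structure(cfg, class = "simulation_config")
}

.group_condition <- function(group) sub("(50|90)$", "", group)
.group_endpoint <- function(group) paste0("T", sub("^(CT|LPS)", "", group))

#' Generate a synthetic paired-design quantification dataset
#'
#' Draws a full dataset with known ground truth: per-protein log-normal
#' baselines, exact planted fold changes between `T0` and the endpoint,
#' per-sample global scale factors (log-uniform), multiplicative
#' technical-replicate noise, intensity-dependent (MNAR) missingness, and
#' per-protein identification metadata. Planted fold changes are noiseless
#' by design: a planted protein's true endpoint intensity is exactly
#' `2^(±effect_log2fc)` times that animal's baseline, and a null protein's
#' ratio is exactly 1, so after spike normalization (and with replicate
#' noise disabled) the recovered per-animal log2 fold change equals the
#' planted value to floating-point tolerance.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `quant` (quantification matrix tibble),
#'   `design` (sample-design tibble) and `truth` (one row per protein:
#'   `protein_id`, `planted_class`, and the true log2 fold change per group
#'   in columns named by group label).
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "simulation_config")) {
    abort_dep("config must be created by simulation_config()", "config")
  }
  set.seed(config$seed)
  n <- config$n_proteins
  protein_ids <- sprintf("PSIM%04d", seq_len(n))

  # planted classes, floor() counts so truth is deterministic in n
  n_up <- floor(n * config$frac_deregulated_up)
  n_down <- floor(n * config$frac_deregulated_down)
  n_drift <- floor(n * config$frac_control_drift)
  shuffled <- sample(protein_ids)
  up_ids <- shuffled[seq_len(n_up)]
  down_ids <- shuffled[n_up + seq_len(n_down)]
  drift_ids <- shuffled[n_up + n_down + seq_len(n_drift)]
  planted_class <- rep("null", n)
  names(planted_class) <- protein_ids
  planted_class[up_ids] <- "up"
  planted_class[down_ids] <- "down"
  planted_class[drift_ids] <- "control_drift"
  drift_sign <- sample(c(-1, 1), length(drift_ids), replace = TRUE)
  names(drift_sign) <- drift_ids

  # true per-(protein, group) log2 fold change Tend vs T0
  truth_fc <- matrix(0, nrow = n, ncol = length(config$groups),
                     dimnames = list(protein_ids, config$groups))
  for (g in config$groups) {
    if (.group_condition(g) == "LPS") {
      truth_fc[up_ids, g] <- config$effect_log2fc
      truth_fc[down_ids, g] <- -config$effect_log2fc
    }
    truth_fc[drift_ids, g] <- drift_sign * config$effect_log2fc
  }

  # design: one column per (animal, timepoint, replicate)
  design <- tidyr::expand_grid(
    group = config$groups,
    animal = seq_len(config$n_animals_per_group),
    rep = seq_len(config$n_technical_replicates)
  )
  design <- tidyr::expand_grid(design,
                               timepoint_slot = c("T0", "Tend"))
  design$condition <- .group_condition(design$group)
  design$timepoint <- ifelse(design$timepoint_slot == "T0", "T0",
                             .group_endpoint(design$group))
  design$animal_id <- paste0(design$group, "_A", design$animal)
  design$sample_id <- paste0(design$animal_id, "_", design$timepoint,
                             "_R", design$rep)
  design <- tibble::tibble(
    sample_id = design$sample_id,
    animal_id = design$animal_id,
    condition = design$condition,
    timepoint = design$timepoint,
    tech_rep = as.integer(design$rep),
    group = design$group
  )
  design <- design[order(design$group, design$animal_id, design$timepoint,
                         design$tech_rep), ]
  validate_design(design)

  # baseline abundance: per-protein mean, per-animal deviation (log10)
  mu <- stats::runif(n, config$baseline_log10_range[1],
                     config$baseline_log10_range[2])
  names(mu) <- protein_ids
  animals <- unique(design$animal_id)
  baseline <- matrix(
    10^(rep(mu, times = length(animals)) +
          stats::rnorm(n * length(animals), 0, config$baseline_sd_log10)),
    nrow = n, dimnames = list(protein_ids, animals)
  )

  # true sample-level intensity: baseline, times 2^fc at the endpoint
  n_samples <- nrow(design)
  true_int <- matrix(NA_real_, nrow = n + 1, ncol = n_samples,
                     dimnames = list(c(protein_ids, config$spike_protein_id),
                                     design$sample_id))
  for (j in seq_len(n_samples)) {
    a <- design$animal_id[j]
    g <- design$group[j]
    fc <- if (design$timepoint[j] == "T0") 0 else truth_fc[, g]
    true_int[protein_ids, j] <- baseline[, a] * 2^fc
    true_int[config$spike_protein_id, j] <- config$spike_amount
  }

  # per-sample global scale factor (log-uniform), then replicate noise
  scale_fac <- exp(stats::runif(n_samples,
                                log(config$scale_factor_range[1]),
                                log(config$scale_factor_range[2])))
  noise <- matrix(10^stats::rnorm((n + 1) * n_samples, 0,
                                  config$tech_rep_sd_log10),
                  nrow = n + 1)
  observed <- sweep(true_int, 2, scale_fac, `*`) * noise

  # MNAR dropout on non-spike cells, never on the spike row
  if (config$missing_rate > 0) {
    rat <- observed[protein_ids, , drop = FALSE]
    z <- as.vector(scale(as.vector(log10(rat))))
    w <- stats::plogis(-config$mnar_strength * z)
    p_miss <- pmin(config$missing_rate * w / mean(w), 0.95)
    drop <- stats::runif(length(p_miss)) < p_miss
    rat[matrix(drop, nrow = nrow(rat))] <- NA_real_
    observed[protein_ids, ] <- rat
  }

  # identification metadata: planted proteins always pass the
  # quantifiability and coverage filters, so recovery tests probe the
  # caller rather than the filters; a slice of nulls gets low evidence
  meta_ids <- c(protein_ids, config$spike_protein_id)
  n_all <- length(meta_ids)
  peptides <- 2L + stats::rpois(n_all, 4)
  score <- stats::runif(n_all, 6, 13)
  coverage <- stats::runif(n_all, config$coverage_range[1],
                           config$coverage_range[2])
  planted_all <- c(planted_class, "null")
  names(planted_all) <- meta_ids
  is_planted <- planted_all != "null" | meta_ids == config$spike_protein_id
  coverage[is_planted] <- stats::runif(sum(is_planted),
                                       max(15, config$coverage_range[1]),
                                       max(15, config$coverage_range[2]))
  null_idx <- which(!is_planted & meta_ids != config$spike_protein_id)
  n_low <- floor(length(null_idx) * config$frac_low_evidence)
  if (n_low > 0) {
    low <- sample(null_idx, n_low)
    defect <- sample(c("peptides", "score"), n_low, replace = TRUE)
    peptides[low[defect == "peptides"]] <- 1L
    score[low[defect == "score"]] <- stats::runif(sum(defect == "score"), 0, 6)
  }

  quant <- tibble::tibble(
    protein_id = meta_ids,
    gene_name = paste0("Gene_", meta_ids),
    n_unique_peptides = peptides,
    quality_score = round(score, 2),
    coverage_pct = round(coverage, 1)
  )
  intens <- tibble::as_tibble(observed[meta_ids, , drop = FALSE])
  quant <- dplyr::bind_cols(quant, intens)
  validate_quant_matrix(quant)
  check_quant_design(quant, design)

  truth <- tibble::tibble(
    protein_id = meta_ids,
    planted_class = unname(planted_all[meta_ids])
  )
  fc_cols <- rbind(truth_fc, rep(0, length(config$groups)))
  rownames(fc_cols) <- meta_ids
  truth <- dplyr::bind_cols(truth, tibble::as_tibble(fc_cols))

  list(quant = quant, design = design, truth = truth)
}

#' Generate a synthetic gene-set annotation for enrichment testing
#'
#' Builds a GMT-style annotation over the simulated proteins: one term,
#' `planted_up`, contains exactly the planted upregulated proteins (a known
#' enrichment positive), and the remaining terms are random draws without
#' replacement.
#'
#' @param truth Truth tibble from [generate_dataset()].
#' @param n_terms Total number of terms (>= 1).
#' @param seed Integer seed.
#' @param term_size_range Size range of the random terms.
#' @return An annotation tibble (`term_id`, `term_name`, `members`).
#' @export
generate_annotation <- function(truth, n_terms = 20L, seed = 1L,
                                term_size_range = c(5L, 30L)) {
  if (n_terms < 1) abort_dep("n_terms must be >= 1", "config")
  set.seed(seed)
  ids <- truth$protein_id
  up_ids <- truth$protein_id[truth$planted_class == "up"]
  terms <- list()
  if (length(up_ids) > 0) {
    terms[["planted_up"]] <- up_ids
  }
  n_random <- n_terms - length(terms)
  if (n_random > 0) {
    sizes <- sample(seq(term_size_range[1],
                        min(term_size_range[2], length(ids))),
                    n_random, replace = TRUE)
    for (i in seq_len(n_random)) {
      terms[[sprintf("TERM%03d", i)]] <- sample(ids, sizes[i])
    }
  }
  tibble::tibble(
    term_id = names(terms),
    term_name = ifelse(names(terms) == "planted_up",
                       "planted upregulated proteins",
                       paste0("random set ", names(terms))),
    members = unname(terms)
  )
}
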