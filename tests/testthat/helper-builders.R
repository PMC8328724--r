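# Builders for small in-code fixtures.

# A quantification matrix from a plain intensity matrix; metadata defaults
# to comfortably quantifiable values.
toy_quant <- function(intensities, protein_ids = NULL,
                      n_peptides = 5L, score = 10, coverage = 50) {
  m <- as.matrix(intensities)
  if (is.null(colnames(m))) {
    colnames(m) <- sprintf("s%02d", seq_len(ncol(m)))
  }
  if (is.null(protein_ids)) {
    protein_ids <- if (!is.null(rownames(m))) rownames(m)
                   else sprintf("P%03d", seq_len(nrow(m)))
  }
  n <- nrow(m)
  meta <- tibble::tibble(
    protein_id = protein_ids,
    gene_name = paste0("g_", protein_ids),
    n_unique_peptides = rep_len(as.integer(n_peptides), n),
    quality_score = rep_len(score, n),
    coverage_pct = rep_len(coverage, n)
  )
  dplyr::bind_cols(meta, tibble::as_tibble(m))
}

# A paired design: n_animals per group, groups like c("CT50", "LPS50").
toy_design <- function(groups = c("CT50", "LPS50"), n_animals = 6,
                       n_reps = 1) {
  rows <- list()
  for (g in groups) {
    ep <- paste0("T", sub("^(CT|LPS)", "", g))
    cond <- sub("(50|90)$", "", g)
    for (a in seq_len(n_animals)) {
      for (tp in c("T0", ep)) {
        for (r in seq_len(n_reps)) {
          rows[[length(rows) + 1]] <- tibble::tibble(
            sample_id = paste0(g, "_A", a, "_", tp, "_R", r),
            animal_id = paste0(g, "_A", a),
            condition = cond, timepoint = tp, tech_rep = as.integer(r),
            group = g
          )
        }
      }
    }
  }
  dplyr::bind_rows(rows)
}

# A one-group fold-change tibble from a vector of per-animal log2fc values.
toy_fc <- function(values, protein_id = "P001", group = "LPS50") {
  tibble::tibble(
    protein_id = protein_id,
    group = group,
    animal_id = paste0("A", seq_along(values)),
    log2fc = values
  )
}
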