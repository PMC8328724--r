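# Published per-protein DEP summaries, transcribed row by row from the
# study's three result tables. The n/6 column of those tables is printed
# only when it changes; blank cells inherit the value above, which is how
# the n values below were filled in. Two rows print internally
# inconsistent signs (a positive median with a negative range, or the
# reverse); they are transcribed as printed with sign_consistent = FALSE
# and their fixture vectors are built from the magnitudes with the sign of
# the table section they sit in.
.dep_fixture_rows <- function() {
  tribble_row <- function(acc, protein, gene, set, endpoint, direction,
                          med, mn, mx, n, sign_ok = TRUE) {
    tibble::tibble(protein_id = acc, protein_name = protein,
                   gene_name = gene, set = set, endpoint = endpoint,
                   direction = direction, log2fc_median = med,
                   log2fc_min = mn, log2fc_max = mx, n_of_6 = as.integer(n),
                   sign_consistent = sign_ok)
  }
  dplyr::bind_rows(
    # common set, 50-minute endpoint
    tribble_row("P06765", "Platelet factor 4", "Pf4", "common", "T50", "up", 3.31, 1.02, 5.20, 5),
    tribble_row("D3ZFH5", "Inter-alpha-trypsin inhibitor heavy chain 2", "Itih2", "common", "T50", "up", 1.25, 1.08, 2.34, 4),
    tribble_row("P26644", "Beta-2-glycoprotein 1", "Apoh", "common", "T50", "up", 1.45, 1.03, 1.55, 4),
    tribble_row("O55004", "Ribonuclease 4", "Rnase4", "common", "T50", "up", 1.78, 1.70, 2.90, 4),
    tribble_row("P00697", "Lysozyme C-1", "Lyz1", "common", "T50", "up", 1.77, 1.70, 2.63, 4),
    tribble_row("P23764", "Glutathione peroxidase 3", "Gpx3", "common", "T50", "down", -2.58, -1.45, -4.75, 4),
    # common set, 90-minute endpoint
    tribble_row("P17475", "Alpha-1-antiproteinase", "Serpina1", "common", "T90", "up", 3.73, 2.97, 5.65, 5),
    tribble_row("Q99PS8", "Histidine-rich glycoprotein", "Hrg", "common", "T90", "up", 2.39, 1.37, 3.89, 5),
    tribble_row("D3ZFH5", "Inter-alpha-trypsin inhibitor heavy chain 2", "Itih2", "common", "T90", "up", 1.92, 1.58, 3.82, 4),
    tribble_row("Q9QUH3", "Apolipoprotein A-V", "Apoa5", "common", "T90", "up", 1.44, 1.00, 2.24, 4),
    tribble_row("P24594", "Insulin-like growth factor-binding protein 5", "Igfbp5", "common", "T90", "up", 2.14, 1.02, 3.79, 4),
    tribble_row("P08650", "Complement C5", "C5", "common", "T90", "up", 5.27, 3.28, 6.21, 4),
    tribble_row("O55004", "Ribonuclease 4", "Rnase4", "common", "T90", "up", 1.68, 1.28, 2.32, 4),
    tribble_row("D3ZTE0", "Coagulation factor XII", "F12", "common", "T90", "up", 1.42, 1.32, 1.73, 4),
    tribble_row("P00697", "Lysozyme C-1", "Lyz1", "common", "T90", "up", 2.86, 1.25, 3.81, 4),
    tribble_row("Q6IRK9", "Carboxypeptidase Q", "Cpq", "common", "T90", "up", 1.94, 1.05, 3.34, 4),
    tribble_row("P04638", "Apolipoprotein A-II", "Apoa2", "common", "T90", "down", -1.96, -1.19, -5.20, 5),
    tribble_row("P55797", "Apolipoprotein C-IV", "Apoc4", "common", "T90", "down", -1.88, -1.37, -2.91, 5),
    tribble_row("P20767", "Ig lambda-2 chain C region", NA, "common", "T90", "down", 2.39, -1.50, -3.30, 5, sign_ok = FALSE),
    tribble_row("Q8R2H5", "Phosphatidylinositol-glycan-specific phospholipase D", "Gpld1", "common", "T90", "down", -1.48, -1.02, -2.72, 5),
    tribble_row("P14630", "Apolipoprotein M", "Apom", "common", "T90", "down", -2.94, -1.46, -4.82, 5),
    tribble_row("P23764", "Glutathione peroxidase 3", "Gpx3", "common", "T90", "down", -2.05, -1.48, -3.44, 5),
    tribble_row("Q68FP1", "Gelsolin", "Gsn", "common", "T90", "down", -2.05, -1.67, -4.47, 4),
    tribble_row("P06759", "Apolipoprotein C-III", "Apoc3", "common", "T90", "down", -2.60, -1.08, -3.66, 4),
    tribble_row("P55159", "Serum paraoxonase/arylesterase 1", "Pon1", "common", "T90", "down", -2.15, -1.17, -2.49, 4),
    tribble_row("P02651", "Apolipoprotein A-IV", "Apoa4", "common", "T90", "down", -1.54, -1.04, -2.61, 4),
    tribble_row("P35859", "Insulin-like growth factor-binding protein complex acid labile subunit", "Igfals", "common", "T90", "down", -2.49, -2.20, -2.90, 4),
    tribble_row("P10960", "Prosaposin", "Psap", "common", "T90", "down", -2.57, -1.53, -3.90, 4),
    # 50-minute-specific set
    tribble_row("Q5FVN3", "Ccl9-like protein", "Ccl9", "t50_specific", "T50", "up", 3.69, 1.38, 4.98, 4),
    tribble_row("Q05820", "Putative lysozyme C-2", "Lyz2", "t50_specific", "T50", "up", 1.67, 1.30, 2.64, 4),
    tribble_row("Q63556", "Serine protease inhibitor A3M", "Serpina3m", "t50_specific", "T50", "up", 1.10, 1.30, 2.63, 4),
    tribble_row("Q5BK77", "Chemerin", "Rarres2", "t50_specific", "T50", "down", -2.24, -1.36, -2.98, 5),
    # 90-minute-specific set
    tribble_row("Q5GAM5", "Angiogenin ribonuclease 2", "Ang2", "t90_specific", "T90", "up", 1.79, 1.32, 3.47, 4),
    tribble_row("Q6MG90", "C4a anaphylatoxin", "C4a", "t90_specific", "T90", "down", -3.22, -1.42, -6.85, 6),
    tribble_row("D3ZQ25", "Fibulin-1", "Fbln1", "t90_specific", "T90", "down", -2.37, 1.24, 5.70, 6, sign_ok = FALSE),
    tribble_row("Q5M890", "Apolipoprotein N", "Apon", "t90_specific", "T90", "down", -4.55, -1.46, -5.61, 6),
    tribble_row("Q5M8C3", "Serine proteinase inhibitor clade A member 4", "Serpina4", "t90_specific", "T90", "down", -1.59, -1.11, -2.75, 6),
    tribble_row("Q64240", "Protein AMBP", "Ambp", "t90_specific", "T90", "down", -3.25, -1.09, -5.11, 6),
    tribble_row("B1H260", "Coagulation factor XIII B chain", "F13b", "t90_specific", "T90", "down", -3.86, -1.07, -5.12, 5),
    tribble_row("F1LZ11", "Ig-like domain-containing protein", NA, "t90_specific", "T90", "down", -1.72, -1.00, -3.56, 5),
    tribble_row("A0A0G2JXI1", "Coagulation factor V", "F5", "t90_specific", "T90", "down", -2.23, -1.76, -4.25, 4),
    tribble_row("P08649", "Complement C4", "C4", "t90_specific", "T90", "down", -3.14, -1.16, -4.59, 4),
    tribble_row("P07151", "Beta-2-microglobulin", "B2m", "t90_specific", "T90", "down", -1.51, -1.32, -2.36, 4)
  )
}

#' Packaged fixture tables of published DEP summaries
#'
#' Builds the transcribed per-protein DEP summary rows (accession, gene,
#' median, range, qualifying count, direction, analysis level) together
#' with deterministic six-animal fold-change vectors consistent with each
#' row. For a row with `n` qualifying animals the vector places the printed
#' range endpoints, fills the remaining `n - 2` qualifying entries with the
#' printed median (which makes the qualifying median exact for odd `n` and
#' a symmetric pair for even `n`), and sets the `6 - n` non-qualifying
#' entries to 0. For the two sign-inconsistent rows the vector is built
#' from the magnitudes with the direction sign of their table section.
#'
#' @param dir Optional directory; when given, `dep_fixture_rows.tsv` and
#'   `dep_fixture_fold_changes.tsv` are written there.
#' @return A list: `rows` (one tibble row per published table row) and
#'   `fold_changes` (a fold-change tibble with `protein_id`, `group`,
#'   `animal_id`, `log2fc`, plus `set` and `endpoint` carried along).
#' @export
make_fixtures <- function(dir = NULL) {
  rows <- .dep_fixture_rows()

  fc_rows <- lapply(seq_len(nrow(rows)), function(i) {
    r <- rows[i, ]
    sgn <- if (r$direction == "up") 1 else -1
    qual <- sgn * c(abs(r$log2fc_min),
                    rep(abs(r$log2fc_median), r$n_of_6 - 2),
                    abs(r$log2fc_max))
    values <- c(qual, rep(0, 6 - r$n_of_6))
    tibble::tibble(
      protein_id = r$protein_id,
      group = paste0("LPS", sub("^T", "", r$endpoint)),
      animal_id = paste0("A", 1:6),
      log2fc = values,
      set = r$set,
      endpoint = r$endpoint
    )
  })
  fold_changes <- dplyr::bind_rows(fc_rows)

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_tsv(rows, file.path(dir, "dep_fixture_rows.tsv"), na = "NA")
    readr::write_tsv(fold_changes,
                     file.path(dir, "dep_fixture_fold_changes.tsv"),
                     na = "NA")
  }
  list(rows = rows, fold_changes = fold_changes)
}
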