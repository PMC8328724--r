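#' @importFrom rlang abort .data
#' @importFrom dplyr %>%
NULL

# Metadata columns every quantification table carries, in canonical order.
# Everything after these is a sample intensity column.
.quant_meta_cols <- c(
  "protein_id", "gene_name", "n_unique_peptides", "quality_score",
  "coverage_pct"
)

abort_dep <- function(message, class) {
  abort(message, class = c(paste0("pairedDEP_", class), "pairedDEP_error"))
}

#' Sample (intensity) columns of a quantification matrix
#'
#' A quantification matrix is a tibble whose first five columns are protein
#' metadata (`protein_id`, `gene_name`, `n_unique_peptides`, `quality_score`,
#' `coverage_pct`); every remaining column is one sample's intensities.
#'
#' @param quant A quantification matrix tibble.
#' @return Character vector of sample column names.
#' @export
sample_columns <- function(quant) {
  setdiff(names(quant), .quant_meta_cols)
}

#' Validate a quantification matrix
#'
#' Checks the container contract: unique non-missing protein accessions, all
#' metadata columns present, and non-negative (or missing) intensities.
#' Missing values are carried as `NA`, never as zero; an observed zero is a
#' legitimate measurement and is kept distinct so that downstream log-ratio
#' steps can fail loudly instead of silently dropping it.
#'
#' @param quant A quantification matrix tibble.
#' @return `quant`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_quant_matrix <- function(quant) {
  missing_meta <- setdiff(.quant_meta_cols, names(quant))
  if (length(missing_meta) > 0) {
    abort_dep(
      paste0("quantification matrix lacks metadata column(s): ",
             paste(missing_meta, collapse = ", ")),
      "format"
    )
  }
  if (anyNA(quant$protein_id)) {
    abort_dep("protein_id contains missing values", "format")
  }
  dup <- unique(quant$protein_id[duplicated(quant$protein_id)])
  if (length(dup) > 0) {
    abort_dep(
      paste0("duplicated protein accession(s): ", paste(dup, collapse = ", ")),
      "format"
    )
  }
  for (col in sample_columns(quant)) {
    v <- quant[[col]]
    if (!is.numeric(v)) {
      abort_dep(paste0("sample column '", col, "' is not numeric"), "format")
    }
    if (any(v < 0, na.rm = TRUE)) {
      abort_dep(paste0("negative intensity in sample column '", col, "'"),
                "format")
    }
  }
  invisible(quant)
}

#' Validate a sample-design table
#'
#' The design maps each sample column to (animal, condition, time point,
#' technical replicate). Each animal must appear at exactly two time points:
#' the baseline `T0` and one endpoint (`T50` or `T90`); its group label is
#' the condition pasted to the endpoint (e.g. `LPS90`).
#'
#' @param design A design tibble with columns `sample_id`, `animal_id`,
#'   `condition`, `timepoint`, `tech_rep` (and optionally `group`, which is
#'   recomputed and checked).
#' @return The design with a `group` column, invisibly validated.
#' @export
validate_design <- function(design) {
  needed <- c("sample_id", "animal_id", "condition", "timepoint", "tech_rep")
  missing_cols <- setdiff(needed, names(design))
  if (length(missing_cols) > 0) {
    abort_dep(paste0("design lacks column(s): ",
                     paste(missing_cols, collapse = ", ")), "design")
  }
  if (anyDuplicated(design$sample_id) > 0) {
    abort_dep("duplicated sample_id in design", "design")
  }
  bad_cond <- setdiff(unique(design$condition), c("CT", "LPS"))
  if (length(bad_cond) > 0) {
    abort_dep(paste0("unknown condition(s): ", paste(bad_cond, collapse = ", ")),
              "design")
  }
  bad_tp <- setdiff(unique(design$timepoint), c("T0", "T50", "T90"))
  if (length(bad_tp) > 0) {
    abort_dep(paste0("unknown timepoint(s): ", paste(bad_tp, collapse = ", ")),
              "design")
  }
  if (any(design$tech_rep < 1)) {
    abort_dep("tech_rep must be >= 1", "design")
  }
  key <- paste(design$animal_id, design$timepoint, design$tech_rep)
  if (anyDuplicated(key) > 0) {
    abort_dep("(animal_id, timepoint, tech_rep) not unique in design",
              "design")
  }
  # every animal: exactly T0 plus one endpoint
  by_animal <- split(design$timepoint, design$animal_id)
  for (animal in names(by_animal)) {
    tps <- sort(unique(by_animal[[animal]]))
    if (length(tps) != 2 || tps[1] != "T0") {
      abort_dep(
        paste0("animal '", animal,
               "' must appear at exactly two time points (T0 and one endpoint), got: ",
               paste(tps, collapse = ", ")),
        "design"
      )
    }
  }
  cond_per_animal <- tapply(design$condition, design$animal_id,
                            function(x) length(unique(x)))
  if (any(cond_per_animal > 1)) {
    abort_dep("an animal is assigned more than one condition", "design")
  }
  endpoints <- vapply(by_animal, function(tps) setdiff(unique(tps), "T0"),
                      character(1))
  exp_group <- paste0(design$condition,
                      sub("^T", "", endpoints[design$animal_id]))
  if ("group" %in% names(design)) {
    if (!identical(as.character(design$group), exp_group)) {
      abort_dep("group column inconsistent with condition and endpoint",
                "design")
    }
  } else {
    design$group <- exp_group
  }
  invisible(design)
}

#' Cross-check a quantification matrix against its design
#'
#' @param quant A quantification matrix.
#' @param design A validated design table.
#' @return Invisibly `TRUE`; errors on any sample column absent from the
#'   design (or vice versa).
#' @export
check_quant_design <- function(quant, design) {
  sc <- sample_columns(quant)
  not_in_design <- setdiff(sc, design$sample_id)
  if (length(not_in_design) > 0) {
    abort_dep(
      paste0("sample column(s) absent from design: ",
             paste(not_in_design, collapse = ", ")),
      "design_mismatch"
    )
  }
  not_in_quant <- setdiff(design$sample_id, sc)
  if (length(not_in_quant) > 0) {
    abort_dep(
      paste0("design sample(s) absent from quantification matrix: ",
             paste(not_in_quant, collapse = ", ")),
      "design_mismatch"
    )
  }
  invisible(TRUE)
}

.sniff_delim <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

.na_strings <- c("NA", "", "nan", "NaN")

#' Read a quantification matrix from delimited text
#'
#' Tab-separated is the canonical dialect; comma-separated files are accepted
#' via delimiter sniffing on the header line. The cells `NA`, `nan` and the
#' empty string are parsed as missing. Parsing is locale-independent
#' (decimal point).
#'
#' @param path Path to a delimited text file whose header names the five
#'   metadata columns followed by one column per sample.
#' @return A validated quantification matrix tibble.
#' @export
read_quant_matrix <- function(path) {
  if (!file.exists(path)) {
    abort_dep(paste0("file not found: ", path), "io")
  }
  delim <- .sniff_delim(path)
  quant <- readr::read_delim(
    path, delim = delim, na = .na_strings, show_col_types = FALSE,
    col_types = readr::cols(
      protein_id = readr::col_character(),
      gene_name = readr::col_character(),
      n_unique_peptides = readr::col_integer(),
      quality_score = readr::col_double(),
      coverage_pct = readr::col_double(),
      .default = readr::col_double()
    ),
    locale = readr::locale(decimal_mark = ".")
  )
  validate_quant_matrix(quant)
  quant
}

#' Write a quantification matrix as tab-separated text
#'
#' @param quant A quantification matrix.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_quant_matrix <- function(quant, path) {
  validate_quant_matrix(quant)
  readr::write_tsv(quant, path, na = "NA")
  invisible(path)
}

#' Read a sample-design table
#'
#' @param path Path to a tab- or comma-separated design table with columns
#'   `sample_id`, `animal_id`, `condition`, `timepoint`, `tech_rep`.
#' @return A validated design tibble with a `group` column.
#' @export
read_design <- function(path) {
  if (!file.exists(path)) {
    abort_dep(paste0("file not found: ", path), "io")
  }
  delim <- .sniff_delim(path)
  design <- readr::read_delim(
    path, delim = delim, na = .na_strings, show_col_types = FALSE,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      animal_id = readr::col_character(),
      condition = readr::col_character(),
      timepoint = readr::col_character(),
      tech_rep = readr::col_integer(),
      .default = readr::col_character()
    )
  )
  out <- validate_design(design)
  if (!"group" %in% names(design)) design$group <- out$group
  design
}

#' Write a sample-design table as tab-separated text
#'
#' @param design A design tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  validate_design(design)
  readr::write_tsv(design, path, na = "NA")
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One term per line: term id, description, then member accessions, all
#' tab-separated. Duplicate members within a term are collapsed.
#'
#' @param path Path to a GMT file.
#' @return An annotation tibble with columns `term_id`, `term_name` and the
#'   list-column `members`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) {
    abort_dep(paste0("file not found: ", path), "io")
  }
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    if (length(parts[[i]]) < 3) {
      abort_dep(paste0("GMT line ", i, " has no members (term '",
                       parts[[i]][1], "')"), "format")
    }
  }
  tibble::tibble(
    term_id = vapply(parts, `[`, character(1), 1),
    term_name = vapply(parts, `[`, character(1), 2),
    members = lapply(parts, function(p) unique(p[-(1:2)]))
  )
}

#' Write an annotation table in GMT format
#'
#' @param annotation Annotation tibble (`term_id`, `term_name`, `members`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(annotation, path) {
  if (any(lengths(annotation$members) == 0)) {
    abort_dep("cannot write GMT term with no members", "format")
  }
  lines <- vapply(
    seq_len(nrow(annotation)),
    function(i) paste(c(annotation$term_id[i], annotation$term_name[i],
                        annotation$members[[i]]), collapse = "\t"),
    character(1)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Write result tables to a directory
#'
#' Each element of `tables` is written as `<name>.tsv` under `dir`.
#'
#' @param tables Named list of data frames.
#' @param dir Output directory, created if needed.
#' @return Character vector of files written, invisibly.
#' @export
write_results <- function(tables, dir) {
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    abort_dep("tables must be a named list", "io")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, paste0(names(tables), ".tsv"))
  for (i in seq_along(tables)) {
    readr::write_tsv(tables[[i]], paths[i], na = "NA")
  }
  invisible(paths)
}
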