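#' Over-representation analysis of a protein set
#'
#' Hypergeometric upper-tail test per annotation term: with a universe of
#' `N` proteins of which `K` belong to the term, and a query set of `n`
#' proteins of which `k` belong, the p-value is `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)`, identical to a one-sided Fisher exact test
#' on the 2x2 table. P-values are Benjamini-Hochberg adjusted across the
#' tested terms.
#'
#' The universe should be the proteins that survived the preprocessing
#' filters (detection-conditioned background), not the whole proteome:
#' plasma MS detection is strongly abundance-biased, and testing against an
#' unconditioned background would count that bias as signal.
#'
#' @param dep_ids Query accessions (must be a subset of `universe_ids`).
#' @param universe_ids Background accessions.
#' @param annotations Annotation tibble (`term_id`, `term_name`, `members`),
#'   e.g. from [read_gmt()].
#' @param min_term_size Terms with fewer universe members are skipped
#'   (default 2).
#' @return A tibble with one row per tested term: `term_id`, `term_name`,
#'   `k`, `K`, `n`, `N`, `p_value`, `q_value`, sorted by ascending p-value.
#' @export
enrich <- function(dep_ids, universe_ids, annotations, min_term_size = 2) {
  universe_ids <- unique(universe_ids)
  dep_ids <- unique(dep_ids)
  if (length(universe_ids) == 0) {
    abort_dep("universe is empty", "enrich")
  }
  stray <- setdiff(dep_ids, universe_ids)
  if (length(stray) > 0) {
    abort_dep(paste0("query proteins outside the universe: ",
                     paste(utils::head(stray, 5), collapse = ", ")),
              "enrich")
  }
  N <- length(universe_ids)
  n <- length(dep_ids)

  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    term_univ <- intersect(annotations$members[[i]], universe_ids)
    K <- length(term_univ)
    if (K < min_term_size) return(NULL)
    k <- length(intersect(dep_ids, term_univ))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble::tibble(term_id = annotations$term_id[i],
                   term_name = annotations$term_name[i],
                   k = k, K = K, n = n, N = N, p_value = p)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble::tibble(term_id = character(), term_name = character(),
                          k = integer(), K = integer(), n = integer(),
                          N = integer(), p_value = double(),
                          q_value = double()))
  }
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out[order(out$p_value), ]
}
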