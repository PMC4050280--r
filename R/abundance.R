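# emPAI relative protein abundance.

#' Exponentially modified protein abundance index
#'
#' `empai = 10^(n_observed / n_observable) - 1`, the label-free relative
#' abundance measure computed from the number of observed versus
#' theoretically observable peptides of a protein.
#'
#' @param n_observed number of observed peptides (>= 0); vectorized.
#' @param n_observable number of observable peptides (>= 1); vectorized.
#' @return emPAI values (unitless, >= 0).
#' @export
#' @examples
#' empai(0, 10)   # 0
#' empai(10, 10)  # 9
empai <- function(n_observed, n_observable) {
  if (any(n_observable < 1)) abort("`n_observable` must be >= 1")
  if (any(n_observed < 0)) abort("`n_observed` must be >= 0")
  10^(n_observed / n_observable) - 1
}

#' emPAI table constructor
#'
#' @param x data frame with columns `protein` and `empai` (`NA` =
#'   not detected); an `accession` column is kept when present.
#' @return tibble of class `empai_table`.
#' @export
empai_table <- function(x) {
  x <- as_tibble(x)
  if (!all(c("protein", "empai") %in% names(x)))
    abort("empai table needs columns `protein` and `empai`")
  if (any(!is.na(x$empai) & x$empai < 0)) abort("empai values must be >= 0")
  class(x) <- c("empai_table", class(x))
  x
}

#' Relative abundance from emPAI values
#'
#' Adds the column `relative_abundance_pct`:
#' `100 * empai_i / sum(empai over detected entries)`. Not-detected
#' entries (`NA` emPAI) are excluded from the denominator and receive
#' `NA` percentages. Full precision is retained; round to integers for
#' report-style output.
#'
#' @param table an [empai_table()] (or data frame with `protein`,
#'   `empai`).
#' @return the table with `relative_abundance_pct` added; the unrounded
#'   percentages over detected entries sum to 100.
#' @export
relative_abundance <- function(table) {
  table <- empai_table(table)
  det <- !is.na(table$empai)
  if (!any(det)) abort("all entries are not-detected: no denominator")
  total <- sum(table$empai[det])
  if (total <= 0) abort("detected emPAI values sum to zero")
  table$relative_abundance_pct <- ifelse(det, 100 * table$empai / total,
                                         NA_real_)
  table
}

#' The packaged vesicle-preparation emPAI table
#'
#' Mass-spectrometry emPAI values for the major proteins identified in
#' the EFF-1 and AFF-1 vesicle preparations, together with the published
#' integer relative-abundance percentages (`printed_pct_*`) for
#' cross-checking. `NA` means not detected in that preparation.
#'
#' @return tibble with columns `protein`, `accession`, `mass_da`,
#'   `empai_aff1`, `printed_pct_aff1`, `empai_eff1`, `printed_pct_eff1`.
#' @export
empai_table1 <- function() {
  path <- system.file("extdata", "empai_vesicle_preps.tsv",
                      package = "subtomo", mustWork = TRUE)
  as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                              quote = "", stringsAsFactors = FALSE))
}

#' One preparation's column of the packaged emPAI table
#'
#' @param prep `"aff1"` or `"eff1"`.
#' @return an [empai_table()] with `protein`, `accession`, `empai`,
#'   `printed_pct`.
#' @export
empai_prep <- function(prep = c("aff1", "eff1")) {
  prep <- match.arg(prep)
  t1 <- empai_table1()
  empai_table(tibble(
    protein = t1$protein, accession = t1$accession,
    empai = t1[[paste0("empai_", prep)]],
    printed_pct = t1[[paste0("printed_pct_", prep)]]))
}
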