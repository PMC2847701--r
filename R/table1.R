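#' Observed recurrence risks for common complex diseases
#'
#' Loads the packaged reference table of disease prevalence `K` and
#' recurrence risk ratios (`lambda_mz`, `lambda_sib`, `lambda_op`) for 15
#' common complex genetic diseases, together with the derived columns as
#' printed in the source compilation (suffixed `_printed`). One row's disease
#' label is blank in the source and stays blank (`NA`) here.
#'
#' @param path Optional path to a user-supplied TSV in the same schema
#'   (tab-separated, `#` comments, one header line); defaults to the packaged
#'   fixture.
#' @return A tibble with one row per disease.
#' @examples
#' load_table1()
#' @export
load_table1 <- function(path = NULL) {
  path <- path %||%
    system.file("extdata", "table1.tsv", package = "multirisk", mustWork = TRUE)
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(
                           disease = readr::col_character(),
                           .default = readr::col_double()))
  required <- c("disease", "K", "lambda_mz", "lambda_sib")
  missing <- setdiff(required, names(tbl))
  if (length(missing)) {
    abort(paste0("table is missing required columns: ",
                 paste(missing, collapse = ", ")))
  }
  bad <- !is.na(tbl$lambda_mz) & tbl$lambda_mz > 1 / tbl$K + 1e-9
  if (any(bad)) {
    abort(paste0("lambda_mz exceeds its bound 1/K for: ",
                 paste(tbl$disease[bad], collapse = ", ")))
  }
  tbl
}

#' Recompute the derived epidemiological columns from (K, lambda) inputs
#'
#' Adds to a table of observed `K` and recurrence risks the derived
#' quantities: `h2_01` (broad-sense risk-scale heritability,
#' [h2_01_from_lambda_mz()]), `dominance_ratio`
#' (\eqn{(\lambda_{Sib}-1)/(\lambda_{OP}-1)}), `excess_ratio`
#' (\eqn{(\lambda_{MZ}-1)/(\lambda_{Sib}-1)}) and `mz_over_sib_sq`
#' (\eqn{\lambda_{MZ}/\lambda_{Sib}^2}), all at full precision (round for
#' display). Rows with missing inputs get `NA` in the affected columns.
#'
#' @param records A tibble with columns `K`, `lambda_mz`, `lambda_sib` and
#'   optionally `lambda_op`, e.g. from [load_table1()].
#' @return The input tibble with the four derived columns appended.
#' @examples
#' derive_columns(load_table1())[, c("disease", "h2_01", "excess_ratio")]
#' @export
derive_columns <- function(records) {
  stopifnot(is.data.frame(records))
  need <- c("K", "lambda_mz", "lambda_sib")
  missing <- setdiff(need, names(records))
  if (length(missing)) {
    abort(paste0("missing columns: ", paste(missing, collapse = ", ")))
  }
  lop <- if ("lambda_op" %in% names(records)) records$lambda_op else NA_real_
  diag_ <- ratio_diagnostics(records$lambda_mz, records$lambda_sib, lop)
  records |>
    dplyr::mutate(
      h2_01 = purrr::map2_dbl(.data$lambda_mz, .data$K, function(l, k) {
        if (is.na(l)) NA_real_ else h2_01_from_lambda_mz(l, k)
      }),
      dominance_ratio = diag_$dominance_ratio,
      excess_ratio = diag_$excess_ratio,
      mz_over_sib_sq = diag_$mz_over_sib_sq
    )
}
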