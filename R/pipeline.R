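#' Fit Foley models for a raw retention-data file
#'
#' Reads a long-format CSV of raw micellar retention observations — columns
#' `compound_id`, `conc_mol_per_L` and either `k` (retention factors) or
#' `t_R_min` (retention times, converted with the supplied dead time) —
#' fits the Foley model per compound, and writes a per-compound table of
#' intercept (1/km), slope (KAM/km), fit R^2, number of points, and the
#' lipophilicity descriptor log(km/KAM). Rows at or below the cmc are
#' rejected with a warning; negative-intercept warnings from the fits are
#' collected and reported.
#'
#' @param input Path to the raw CSV.
#' @param output Optional path for the per-compound result CSV.
#' @param t_M Dead time (min), required when the input has `t_R_min`
#'   instead of `k`.
#' @param cmc Critical micellization concentration (mol/L), default 0.
#' @return Invisibly, the per-compound result data frame.
#' @export
run_foley_pipeline <- function(input, output = NULL, t_M = NULL, cmc = 0) {
  raw <- read_normalized_csv(input)
  if (nrow(raw) == 0L) stop("schema error: no data rows in ", input)
  need <- c("compound_id", "conc_mol_per_L")
  missing <- setdiff(need, names(raw))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  conc <- parse_numeric_column(raw$conc_mol_per_L, "conc_mol_per_L")
  if (!is.null(raw$k)) {
    k <- parse_numeric_column(raw$k, "k")
  } else if (!is.null(raw$t_R_min)) {
    if (is.null(t_M))
      stop("schema error: t_M is required with retention-time input")
    k <- retention_factor(parse_numeric_column(raw$t_R_min, "t_R_min"), t_M)
  } else stop("schema error: need a 'k' or 't_R_min' column")
  below <- conc <= cmc
  if (any(below)) {
    warning(sum(below), " observation(s) at or below the cmc rejected")
    raw <- raw[!below, , drop = FALSE]
    conc <- conc[!below]; k <- k[!below]
  }
  ids <- unique(raw$compound_id)
  rows <- lapply(ids, function(id) {
    sel <- raw$compound_id == id
    fit <- fit_foley(retention_series(id, conc[sel], k = k[sel], cmc = cmc))
    data.frame(compound_id = id, inv_km = fit$intercept,
               kam_over_km = fit$slope, r2 = fit$r2,
               n_points = fit$n_points, log_km_kam = fit$log_km_kam,
               negative_intercept = fit$negative_intercept,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (!is.null(output))
    utils::write.csv(res, output, row.names = FALSE, quote = FALSE)
  invisible(res)
}

#' Run the full QSAR model-building report
#'
#' Loads a descriptor table, enumerates the 12 full + 3 reduced candidate
#' models, fits each, computes the full validation battery, applies the
#' screening rules, and writes into `out_dir`: `model_report.csv` (one
#' validation row per model), `screening.csv` (exclusion flags and ranks),
#' `equations.txt` (fitted equations with standard errors in parentheses),
#' and `williams_<label>.csv` applicability-domain tables for the selected
#' (non-excluded, rank-ordered) models.
#'
#' @param table A `descriptor_table`, or a path to a descriptor CSV.
#' @param out_dir Output directory (created if absent).
#' @param rules [screening_rules()] thresholds.
#' @param residual_cutoff Standardized-residual band for the Williams
#'   tables.
#' @return Invisibly, a list with `fits`, `stats`, `screening`, and
#'   `equations`.
#' @export
run_qsar_report <- function(table, out_dir = ".",
                            rules = screening_rules(),
                            residual_cutoff = 3) {
  if (is.character(table)) table <- load_descriptor_table(table)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  specs <- enumerate_models()
  fits <- lapply(specs, fit_mlr, table = table)
  names(fits) <- vapply(specs, `[[`, "", "label")
  stats <- lapply(fits, model_statistics)
  screening <- screen_models(stats, rules)
  equations <- vapply(fits, format_equation, "")
  write_model_report(stats, file.path(out_dir, "model_report.csv"))
  utils::write.csv(screening, file.path(out_dir, "screening.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(equations, file.path(out_dir, "equations.txt"))
  selected <- screening$label[!screening$excluded]
  for (lab in selected) {
    wd <- tryCatch(williams_data(fits[[lab]], residual_cutoff),
                   error = function(e) {
                     warning("Williams table skipped for ", lab, ": ",
                             conditionMessage(e))
                     NULL
                   })
    if (is.null(wd)) next
    wd$compound_id <- table$compound_id
    utils::write.csv(wd, file.path(out_dir, paste0("williams_",
                                                   sub("\\*$", "s", lab),
                                                   ".csv")),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(list(fits = fits, stats = stats, screening = screening,
                 equations = equations))
}
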