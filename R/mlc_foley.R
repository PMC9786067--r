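#' Chromatographic retention factor
#'
#' Computes the dimensionless retention factor k = (tR - tM)/tM from the
#' retention time of the solute and the hold-up (dead) time measured from an
#' unretained marker. A retention time below the dead time yields a negative
#' k, which is permitted but meaningless for retention modeling (such rows
#' are dropped by [fit_foley()]).
#'
#' @param t_R Solute retention time (same units as `t_M`), vectorized.
#' @param t_M Dead time, > 0.
#' @return Retention factor(s) k.
#' @examples
#' retention_factor(5, 1)   # 4
#' retention_factor(3.3, 1.1)
#' @export
retention_factor <- function(t_R, t_M) {
  if (any(!is.finite(t_R)) || any(!is.finite(t_M)))
    stop("domain error: non-finite retention or dead time")
  if (any(t_M <= 0))
    stop("domain error: dead time t_M must be positive")
  (t_R - t_M) / t_M
}

#' Micellized surfactant concentration
#'
#' \[M\] is the total surfactant concentration in the mobile phase minus the
#' critical micellization concentration (cmc). Below the cmc there is no
#' micellar pseudophase and retention modeling is undefined.
#'
#' @param total_conc Total surfactant concentration (mol/L), vectorized.
#' @param cmc Critical micellization concentration (mol/L), >= 0.
#' @return Micellized concentration(s) in mol/L.
#' @export
micelle_concentration <- function(total_conc, cmc = 0) {
  if (any(!is.finite(total_conc)) || !is.finite(cmc) || cmc < 0)
    stop("domain error: concentrations must be finite and cmc >= 0")
  if (any(total_conc <= cmc))
    stop("domain error: total surfactant concentration at or below the cmc ",
         "(no micellar pseudophase)")
  total_conc - cmc
}

#' One compound's micellar retention series
#'
#' Bundles the observations needed to fit the Foley retention model for one
#' compound: retention factors (or retention times plus a dead time) at a
#' set of total surfactant concentrations, and the cmc used to convert total
#' concentration to micellized concentration \[M\].
#'
#' @param compound_id Compound label.
#' @param total_conc Total surfactant concentrations (mol/L).
#' @param k Retention factors; either `k` or both `t_R` and `t_M` must be
#'   supplied.
#' @param t_R,t_M Retention times and dead time, used when `k` is missing.
#' @param cmc Critical micellization concentration (mol/L); default 0, i.e.
#'   \[M\] is taken as the total concentration. The fitted slope (and hence
#'   the lipophilicity descriptor) is invariant to this choice.
#' @return An object of class `retention_series`.
#' @export
retention_series <- function(compound_id, total_conc, k = NULL,
                             t_R = NULL, t_M = NULL, cmc = 0) {
  if (is.null(k)) {
    if (is.null(t_R) || is.null(t_M))
      stop("supply either k or both t_R and t_M")
    k <- retention_factor(t_R, t_M)
  }
  if (length(k) != length(total_conc))
    stop("total_conc and k must have equal length")
  if (length(total_conc) < 2L)
    stop("need at least 2 observations to fit the retention model")
  m <- micelle_concentration(total_conc, cmc)
  structure(list(compound_id = compound_id, total_conc = total_conc,
                 micelle_conc = m, k = k, cmc = cmc),
            class = "retention_series")
}

#' Fit the Foley retention model
#'
#' Fits the linear form of the Foley equation, 1/k = 1/km + (KAM/km)\[M\],
#' by ordinary least squares of 1/k on the micellized surfactant
#' concentration \[M\]. The slope KAM/km yields the micellar lipophilicity
#' descriptor log(km/KAM) = -log10(slope); the intercept estimates 1/km.
#' Strongly retained solutes commonly give a (physically uninterpretable)
#' negative intercept — this is recorded and warned about, but the
#' slope-derived descriptor remains valid because it does not use the
#' intercept. Observations with k <= 0 (retention at or below the dead
#' time) are dropped with a warning before fitting.
#'
#' @param series A [retention_series()] object.
#' @return An object of class `foley_fit` with elements `compound_id`,
#'   `intercept` (1/km), `slope` (KAM/km, L/mol), `r2`, `log_km_kam`
#'   (= -log10(slope)), `n_points`, and `negative_intercept` flag.
#' @examples
#' m <- c(0.10, 0.105, 0.11, 0.12)
#' s <- retention_series("1", m, k = 1 / (-0.765 + 9.066 * m))
#' fit_foley(s)
#' @export
fit_foley <- function(series) {
  stopifnot(inherits(series, "retention_series"))
  keep <- series$k > 0
  if (!all(keep)) {
    warning(sum(!keep), " observation(s) with k <= 0 dropped for compound ",
            series$compound_id)
  }
  x <- series$micelle_conc[keep]
  y <- 1 / series$k[keep]
  if (length(x) < 2L)
    stop("need at least 2 usable observations for compound ",
         series$compound_id)
  if (stats::var(x) == 0)
    stop("singular fit: zero variance in micelle concentration for compound ",
         series$compound_id)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope <= 0)
    stop("descriptor undefined: non-positive Foley slope (", signif(slope, 4),
         ") for compound ", series$compound_id)
  r2 <- if (length(x) == 2L) 1 else summary(fit)$r.squared
  if (intercept < 0)
    warning("negative Foley intercept (", signif(intercept, 4),
            ") for compound ", series$compound_id,
            "; 1/km not physically interpretable, slope-based descriptor ",
            "unaffected")
  structure(list(compound_id = series$compound_id,
                 intercept = intercept, slope = slope, r2 = r2,
                 log_km_kam = -log10(slope), n_points = length(x),
                 negative_intercept = intercept < 0),
            class = "foley_fit")
}

#' Micellar lipophilicity descriptor log(km/KAM)
#'
#' The slope of the Foley model is KAM/km, so -log10(slope) = log10(km/KAM):
#' a lipophilicity descriptor combining the solute's affinity for the
#' surfactant-modified stationary phase (km) and its binding to the micelles
#' (KAM). It is computed from the slope only and is therefore insensitive to
#' the (often negative) fitted intercept and to the assumed cmc.
#'
#' @param x A `foley_fit` object, or a numeric vector of positive Foley
#'   slopes KAM/km.
#' @return log10(km/KAM), dimensionless.
#' @examples
#' micellar_lipophilicity(9.066)  # -0.957
#' @export
micellar_lipophilicity <- function(x) {
  slope <- if (inherits(x, "foley_fit")) x$slope else x
  if (!is.numeric(slope) || any(!is.finite(slope)) || any(slope <= 0))
    stop("domain error: Foley slope must be positive and finite")
  -log10(slope)
}

#' @export
print.foley_fit <- function(x, ...) {
  cat(sprintf("Foley fit, compound %s (n = %d)\n", x$compound_id, x$n_points))
  cat(sprintf("  1/km (intercept): %8.3f%s\n", x$intercept,
              if (x$negative_intercept) "  [negative]" else ""))
  cat(sprintf("  KAM/km (slope):   %8.3f L/mol\n", x$slope))
  cat(sprintf("  R2:               %8.4f\n", x$r2))
  cat(sprintf("  log(km/KAM):      %8.3f\n", x$log_km_kam))
  invisible(x)
}
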