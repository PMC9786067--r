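#' Canonical descriptor-group template for model enumeration
#'
#' The model template pairs the micellar lipophilicity descriptor with one
#' polar descriptor (group I: TPSA or HBA), one molecular-size descriptor
#' (group II: polarizability, parachor, or MW) and optionally the
#' flexibility descriptor (group III: NRB). The member order here fixes the
#' labels produced by [enumerate_models()].
#'
#' @return A named list with elements `I`, `II`, `III` (character vectors
#'   of descriptor names) and `lipophilicity` (the always-included
#'   descriptor).
#' @export
model_template <- function() {
  list(lipophilicity = "log_km_kam",
       I = c("tpsa", "hba"),
       II = c("alpha", "parachor_P", "mw"),
       III = "nrb")
}

as_group_list <- function(grouping) {
  if (inherits(grouping, "descriptor_grouping")) {
    out <- list(lipophilicity = "log_km_kam",
                I = group_members(grouping, "I"),
                II = group_members(grouping, "II"),
                III = group_members(grouping, "III"))
  } else out <- grouping
  if (is.null(out$I) || is.null(out$II) || is.null(out$III) ||
      length(out$I) < 1L || length(out$II) < 1L)
    stop("parameter error: grouping must define groups I, II and III")
  if (is.null(out$lipophilicity)) out$lipophilicity <- "log_km_kam"
  out
}

#' A candidate QSAR model specification
#'
#' @param label Model label, e.g. `"M5"`.
#' @param response Response column name (`"log_bb"` or `"log_bb_star"`).
#' @param predictors Ordered predictor column names.
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(label, response, predictors) {
  if (anyDuplicated(predictors))
    stop("predictors must be unique")
  if (response %in% predictors)
    stop("response cannot be among the predictors")
  structure(list(label = label, response = response,
                 predictors = predictors),
            class = "model_spec")
}

#' Enumerate candidate QSAR models over descriptor groups
#'
#' Builds the model family log SP = a0 + a1*lipophilicity + a2*dI + a3*dIII
#' + a4*dII, one model per combination of a group-I and a group-II member,
#' for each response. With the flexibility descriptor (NRB) included this
#' gives 2 responses x 2 x 3 = 12 models labeled M1-M12 (first response
#' first; within a response the first group-I member first; group-II members
#' in template order). Without NRB, the "starred" reduced variants of the
#' models named in `starred_base` are produced (e.g. M5 -> M5*).
#'
#' @param grouping A [cluster_variables()] result or a plain list like
#'   [model_template()]. Group member order determines labeling.
#' @param responses Response column names, in label order.
#' @param include_flexibility `"both"` (default: the 12 full models plus the
#'   starred reductions), `"with"` (full models only) or `"without"`
#'   (starred reductions only).
#' @param starred_base Labels of the full models whose NRB-free reductions
#'   are enumerated.
#' @return A list of [model_spec()] objects.
#' @export
enumerate_models <- function(grouping = model_template(),
                             responses = c("log_bb", "log_bb_star"),
                             include_flexibility = c("both", "with", "without"),
                             starred_base = c("M5", "M11", "M12")) {
  include_flexibility <- match.arg(include_flexibility)
  g <- as_group_list(grouping)
  full <- list()
  i <- 0L
  for (resp in responses)
    for (dI in g$I)
      for (dII in g$II) {
        i <- i + 1L
        full[[i]] <- model_spec(paste0("M", i), resp,
                                c(g$lipophilicity, dI, g$III, dII))
      }
  starred <- lapply(Filter(function(s) s$label %in% starred_base, full),
                    function(s) model_spec(paste0(s$label, "*"), s$response,
                                           setdiff(s$predictors, g$III)))
  switch(include_flexibility,
         both = c(full, starred),
         with = full,
         without = starred)
}

#' Fit a QSAR model by ordinary least squares
#'
#' Multiple linear regression with intercept of the response on the spec's
#' predictors; coefficient standard errors use the unbiased residual
#' variance estimate.
#'
#' @param spec A [model_spec()].
#' @param table A `descriptor_table` (or data frame) containing the
#'   response and all predictors.
#' @return An object of class `qsar_fit`: the spec, the underlying `lm`
#'   fit, coefficient table, fitted values, residuals, hat diagonals, and
#'   design dimensions `n` (rows) and `p` (predictors).
#' @export
fit_mlr <- function(spec, table) {
  stopifnot(inherits(spec, "model_spec"))
  df <- as.data.frame(table)
  missing <- setdiff(c(spec$response, spec$predictors), names(df))
  if (length(missing))
    stop("column(s) not in table: ", paste(missing, collapse = ", "))
  n <- nrow(df)
  p <- length(spec$predictors)
  if (n <= p + 1L)
    stop("degrees-of-freedom error: n = ", n, " rows for p = ", p,
         " predictors")
  fm <- stats::reformulate(spec$predictors, response = spec$response)
  fit <- stats::lm(fm, data = df)
  if (fit$rank < p + 1L)
    stop("singular matrix: design is rank deficient (rank ", fit$rank,
         " < ", p + 1L, ")")
  structure(list(spec = spec, lm = fit,
                 coefficients = stats::coef(fit),
                 se = summary(fit)$coefficients[, "Std. Error"],
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit),
                 hat = stats::hatvalues(fit),
                 response = df[[spec$response]],
                 n = n, p = p),
            class = "qsar_fit")
}

#' Leave-one-out PRESS and predicted R-squared
#'
#' PRESS is computed by the exact hat-matrix identity for linear least
#' squares: the leave-one-out residual for observation i equals
#' e_i / (1 - h_i), so PRESS = sum (e_i / (1 - h_i))^2 without refitting.
#' The predicted R^2 (identically Q^2 of leave-one-out cross-validation) is
#' 1 - PRESS/SS with SS the total sum of squares of the response.
#'
#' @param fit A [fit_mlr()] result.
#' @return A list with `press`, `r2_pred`, and `q2_loo` (== `r2_pred`).
#' @export
loo_press <- function(fit) {
  stopifnot(inherits(fit, "qsar_fit"))
  h <- fit$hat
  if (any(h >= 1 - 1e-12))
    stop("degenerate leverage: observation with h = 1 ",
         "(exactly interpolated point)")
  press <- sum((fit$residuals / (1 - h))^2)
  ss <- sum((fit$response - mean(fit$response))^2)
  r2_pred <- 1 - press / ss
  list(press = press, r2_pred = r2_pred, q2_loo = r2_pred)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R2_j), where R2_j comes from regressing predictor j on
#' the remaining predictors (with intercept). Values above 5 indicate
#' problematic collinearity under the screening rules of
#' [screen_models()]. Perfectly collinear predictors are reported as `Inf`.
#'
#' @param x A `qsar_fit`, or a data frame / matrix of predictor columns
#'   (>= 2 columns).
#' @return A list with `vif` (named per-predictor vector) and `max_vif`.
#' @export
vif_values <- function(x) {
  X <- if (inherits(x, "qsar_fit"))
    stats::model.matrix(x$lm)[, -1, drop = FALSE]
  else as.matrix(as.data.frame(x))
  storage.mode(X) <- "double"
  if (ncol(X) < 2L)
    stop("need at least 2 predictors for VIF")
  v <- vapply(seq_len(ncol(X)), function(j) {
    r2j <- summary(stats::lm(X[, j] ~ X[, -j, drop = FALSE]))$r.squared
    if (r2j >= 1 - 1e-12) Inf else 1 / (1 - r2j)
  }, numeric(1))
  names(v) <- colnames(X)
  list(vif = v, max_vif = max(v))
}

#' Full validation battery for a fitted QSAR model
#'
#' Computes the statistics used to evaluate and compare candidate models:
#' total sum of squares SS, R^2 = 1 - RSS/SS, adjusted R^2, MSE =
#' RSS/(n-p-1), the F statistic (R^2/p) / ((1-R^2)/(n-p-1)) with its
#' p-value, leave-one-out PRESS / predicted R^2 / Q^2 via [loo_press()],
#' and per-predictor VIFs via [vif_values()]. A perfect fit reports
#' F = `Inf` with the `perfect_fit` flag set.
#'
#' @param fit A [fit_mlr()] result.
#' @return An object of class `model_stats` (a named list; see fields in
#'   [write_model_report()]).
#' @export
model_statistics <- function(fit) {
  stopifnot(inherits(fit, "qsar_fit"))
  y <- fit$response
  n <- fit$n; p <- fit$p
  ss <- sum((y - mean(y))^2)
  if (ss == 0) stop("zero response variance: SS = 0")
  rss <- sum(fit$residuals^2)
  r2 <- 1 - rss / ss
  r2_adj <- 1 - (1 - r2) * (n - 1) / (n - p - 1)
  mse <- rss / (n - p - 1)
  perfect <- rss <= 1e-12 * ss
  f <- if (perfect) Inf else (r2 / p) / ((1 - r2) / (n - p - 1))
  p_value <- stats::pf(f, p, n - p - 1, lower.tail = FALSE)
  loo <- loo_press(fit)
  vifs <- vif_values(fit)
  structure(list(label = fit$spec$label, response = fit$spec$response,
                 n = n, p = p,
                 r2 = r2, r2_adj = r2_adj, r2_pred = loo$r2_pred,
                 press = loo$press, press_loo = loo$press,
                 q2_loo = loo$q2_loo,
                 ss = ss, rss = rss, mse = mse,
                 f = f, p_value = p_value,
                 vif = vifs$vif, max_vif = vifs$max_vif,
                 press_ss_ratio = loo$press / ss,
                 perfect_fit = perfect),
            class = "model_stats")
}

#' Screening rule thresholds
#'
#' @param vif_max Models whose maximum VIF, at the 1-decimal reporting
#'   precision, is at or above this value are excluded (default 5.0).
#' @param q2_min Minimum acceptable Q^2 of leave-one-out cross-validation
#'   (default 0.6).
#' @param press_ss_max Maximum acceptable PRESS/SS ratio (default 0.4).
#' @return A named list of thresholds.
#' @export
screening_rules <- function(vif_max = 5.0, q2_min = 0.6, press_ss_max = 0.4) {
  stopifnot(vif_max > 0, press_ss_max > 0)
  list(vif_max = vif_max, q2_min = q2_min, press_ss_max = press_ss_max)
}

#' Screen and rank candidate models
#'
#' Applies the collinearity and predictivity screening rules: models whose
#' maximum VIF (rounded to the 1-decimal reporting precision) reaches
#' `vif_max` are excluded; remaining models are flagged if Q^2(LOO) is not
#' above `q2_min` or PRESS/SS is not below `press_ss_max`, and ranked by
#' higher predicted R^2, ties broken by lower PRESS.
#'
#' @param stats A list of [model_statistics()] results.
#' @param rules A [screening_rules()] list.
#' @return A data frame, one row per model: label, response, r2, r2_pred,
#'   press, press_ss_ratio, max_vif, excluded (VIF rule), pass_q2,
#'   pass_press_ss, rank (NA for excluded models). Rows are ordered
#'   survivors-by-rank first, then excluded models.
#' @export
screen_models <- function(stats, rules = screening_rules()) {
  if (inherits(stats, "model_stats")) stats <- list(stats)
  if (!length(stats)) stop("parameter error: empty model statistics")
  tab <- do.call(rbind, lapply(stats, function(s) data.frame(
    label = s$label, response = s$response,
    r2 = s$r2, r2_pred = s$r2_pred, press = s$press,
    press_ss_ratio = s$press_ss_ratio, max_vif = s$max_vif,
    stringsAsFactors = FALSE)))
  tab$excluded <- round(tab$max_vif, 1) >= rules$vif_max
  tab$pass_q2 <- tab$r2_pred > rules$q2_min
  tab$pass_press_ss <- tab$press_ss_ratio < rules$press_ss_max
  tab$rank <- NA_integer_
  keep <- which(!tab$excluded)
  ord <- keep[order(-tab$r2_pred[keep], tab$press[keep])]
  tab$rank[ord] <- seq_along(ord)
  tab[order(tab$excluded, tab$rank), , drop = FALSE]
}

#' Standardized regression coefficients
#'
#' b_j = a_j * sd(x_j) / sd(y) with sample (n-1) standard deviations:
#' the coefficients the model would have if every variable were scaled to
#' unit variance, used to compare the direction and strength of each
#' descriptor's contribution.
#'
#' @param fit A [fit_mlr()] result.
#' @return Named numeric vector of standardized coefficients (no
#'   intercept).
#' @export
standardized_coefficients <- function(fit) {
  stopifnot(inherits(fit, "qsar_fit"))
  X <- stats::model.matrix(fit$lm)[, -1, drop = FALSE]
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("domain error: constant predictor(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  fit$coefficients[-1] * sds / stats::sd(fit$response)
}

#' Predict response for new compounds, with applicability-domain check
#'
#' Applies the fitted equation to new descriptor records and computes each
#' new point's leverage against the training design,
#' h0 = x0' (X'X)^{-1} x0 (intercept-augmented). Points with leverage above
#' the warning leverage h* = 3(p+1)/n fall outside the model's
#' applicability domain.
#'
#' @param object A [fit_mlr()] result.
#' @param newdata Data frame with all predictor columns.
#' @param ... Unused.
#' @return A data frame with columns `prediction`, `leverage`, `in_domain`.
#' @export
predict.qsar_fit <- function(object, newdata, ...) {
  missing <- setdiff(object$spec$predictors, names(newdata))
  if (length(missing))
    stop("missing predictor value(s): ", paste(missing, collapse = ", "))
  X <- stats::model.matrix(object$lm)
  X0 <- cbind(1, as.matrix(as.data.frame(newdata)[object$spec$predictors]))
  storage.mode(X0) <- "double"
  pred <- drop(X0 %*% object$coefficients)
  xtxi <- chol2inv(chol(crossprod(X)))
  lev <- rowSums((X0 %*% xtxi) * X0)
  hstar <- warning_leverage(object$n, object$p)
  data.frame(prediction = pred, leverage = lev,
             in_domain = lev <= hstar, row.names = NULL)
}

#' Format a fitted model as an equation string
#'
#' Renders the fitted equation with coefficients to 3 decimals and standard
#' errors in parentheses, e.g.
#' `log BB = 0.253(0.232) + 0.198(0.091) log(km/KAM) - 0.160(0.023) HBA ...`.
#'
#' @param fit A [fit_mlr()] result.
#' @param digits Decimals for coefficients and standard errors.
#' @return A single character string.
#' @export
format_equation <- function(fit, digits = 3) {
  stopifnot(inherits(fit, "qsar_fit"))
  pretty <- c(log_bb = "log BB", log_bb_star = "log BB*",
              log_km_kam = "log(km/KAM)", tpsa = "TPSA", hba = "HBA",
              nrb = "NRB", mw = "MW", alpha = "alpha",
              parachor_P = "parachor")
  nm <- function(x) ifelse(is.na(pretty[x]), x, pretty[x])
  co <- fit$coefficients; se <- fit$se
  fmt <- function(v) formatC(abs(v), digits = digits, format = "f")
  terms <- sprintf("%s(%s) %s", fmt(co[-1]), fmt(se[-1]),
                   nm(fit$spec$predictors))
  signs <- ifelse(co[-1] < 0, "- ", "+ ")
  sprintf("%s: %s = %s%s(%s) %s", fit$spec$label, nm(fit$spec$response),
          if (co[1] < 0) "-" else "", fmt(co[1]), fmt(se[1]),
          paste(paste0(signs, terms), collapse = " "))
}

#' @export
print.qsar_fit <- function(x, ...) {
  cat(format_equation(x), "\n")
  cat(sprintf("  n = %d, p = %d\n", x$n, x$p))
  invisible(x)
}

#' @export
print.model_stats <- function(x, ...) {
  cat(sprintf("%s (%s): R2 %.4f  R2adj %.4f  R2pred %.4f  PRESS %.4f\n",
              x$label, x$response, x$r2, x$r2_adj, x$r2_pred, x$press))
  cat(sprintf("  SS %.4f  MSE %.4f  F %.1f  p %.5f  max VIF %.1f\n",
              x$ss, x$mse, x$f, x$p_value, x$max_vif))
  invisible(x)
}
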