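#' Leverages (hat-matrix diagonal) of a fitted model
#'
#' The leverage h_i of observation i is the i-th diagonal element of the
#' hat matrix H = X (X'X)^{-1} X' of the intercept-augmented design. For a
#' full-rank intercept model 1/n <= h_i <= 1 and sum(h_i) = p + 1.
#'
#' @param fit A [fit_mlr()] result.
#' @return Numeric vector of leverages, one per training compound.
#' @export
leverages <- function(fit) {
  stopifnot(inherits(fit, "qsar_fit"))
  unname(fit$hat)
}

#' Warning leverage h*
#'
#' The conventional applicability-domain threshold h* = 3(p+1)/n, where p
#' is the number of predictors and n the number of training compounds.
#' Compounds with leverage above h* are structurally distant from the
#' training set and model predictions for them are extrapolations.
#'
#' @param n Number of training samples (> 0).
#' @param p Number of predictors (>= 1).
#' @return h*, dimensionless.
#' @examples
#' warning_leverage(65, 4)  # 0.23077
#' @export
warning_leverage <- function(n, p) {
  if (!is.numeric(n) || n <= 0) stop("domain error: n must be positive")
  if (!is.numeric(p) || p < 1) stop("domain error: p must be >= 1")
  3 * (p + 1) / n
}

#' Standardized residuals
#'
#' By default the simple standardization r_i = e_i / s with
#' s = sqrt(RSS/(n-p-1)); `type = "internal"` gives the internally
#' studentized variant r_i = e_i / (s * sqrt(1 - h_i)), which accounts for
#' the smaller variance of residuals at high-leverage points.
#'
#' @param fit A [fit_mlr()] result.
#' @param type `"simple"` (default) or `"internal"`.
#' @return Numeric vector of standardized residuals.
#' @export
standardized_residuals <- function(fit, type = c("simple", "internal")) {
  type <- match.arg(type)
  stopifnot(inherits(fit, "qsar_fit"))
  dfree <- fit$n - fit$p - 1
  if (dfree <= 0) stop("no residual degrees of freedom")
  rss <- sum(fit$residuals^2)
  ss <- sum((fit$response - mean(fit$response))^2)
  if (rss <= 1e-20 * max(ss, .Machine$double.eps))
    stop("degenerate: perfect fit, residual scale is zero")
  s <- sqrt(rss / dfree)
  r <- fit$residuals / s
  if (type == "internal") r <- r / sqrt(1 - fit$hat)
  unname(r)
}

#' Williams-plot records: the applicability domain of a model
#'
#' Joins per-compound leverages and standardized residuals with the warning
#' leverage h* = 3(p+1)/n and flags compounds that are structural outliers
#' (h_i > h*) or response outliers (|r_i| > `residual_cutoff`). The
#' returned table is the data behind a Williams plot (standardized residual
#' vs leverage).
#'
#' @param fit A [fit_mlr()] result.
#' @param residual_cutoff Standardized-residual band (default 3).
#' @param type Residual standardization passed to
#'   [standardized_residuals()].
#' @return A data frame of class `ad_table` with columns `compound_id`,
#'   `leverage`, `std_residual`, `h_star`, `high_leverage`, `outlier`, and
#'   attribute `h_star`.
#' @export
williams_data <- function(fit, residual_cutoff = 3,
                          type = c("simple", "internal")) {
  stopifnot(inherits(fit, "qsar_fit"))
  h <- leverages(fit)
  r <- standardized_residuals(fit, type)
  hstar <- warning_leverage(fit$n, fit$p)
  ids <- fit$lm$model$compound_id
  if (is.null(ids)) {
    df <- tryCatch(stats::model.frame(fit$lm), error = function(e) NULL)
    ids <- rownames(df)
    if (is.null(ids)) ids <- as.character(seq_len(fit$n))
  }
  out <- data.frame(compound_id = ids, leverage = h, std_residual = r,
                    h_star = hstar, high_leverage = h > hstar,
                    outlier = abs(r) > residual_cutoff,
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(out, h_star = hstar, class = c("ad_table", "data.frame"))
}
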