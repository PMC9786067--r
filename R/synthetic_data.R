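#' Configuration for the synthetic-data generator
#'
#' Defines the study conditions emulated by the generator: 65 compounds,
#' retention measured at four SDS concentrations (0.10, 0.105, 0.11,
#' 0.12 mol/L), a descriptor table whose correlation structure mirrors the
#' reference dataset (a near-collinear polar pair TPSA/HBA, a strongly
#' correlated size trio MW/alpha/parachor, a weakly coupled flexibility
#' count NRB, and a lipophilicity descriptor moderately anti-correlated
#' with polarity and correlated with size), and a response generated from a
#' known linear model plus Gaussian noise. Descriptor means and standard
#' deviations default to the reference-dataset values; the default true
#' coefficients are those of the four-descriptor log BB model.
#'
#' @param n_compounds Number of compounds (default 65).
#' @param concentrations Total surfactant concentrations, mol/L.
#' @param cmc Critical micellization concentration, mol/L.
#' @param intercept_range Range of true Foley intercepts 1/km.
#' @param descriptor_means,descriptor_sds Named vectors over
#'   `log_km_kam`, `tpsa`, `hba`, `mw`, `alpha`, `parachor_P`, `nrb`.
#' @param rho_polar Target TPSA-HBA correlation.
#' @param rho_size Target pairwise correlation within MW/alpha/parachor.
#' @param rho_between Target correlation across groups and with NRB.
#' @param rho_lip_polar,rho_lip_size Target correlation of the
#'   lipophilicity descriptor with the polar and size groups.
#' @param true_coef Named numeric of true regression coefficients; the
#'   first element must be named `"(Intercept)"`.
#' @param sigma_y Response noise standard deviation.
#' @param sigma_k Additive noise standard deviation on the 1/k scale.
#' @param seed Integer seed; every generator call is deterministic given
#'   the seed in its config.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_compounds = 65,
                             concentrations = c(0.10, 0.105, 0.11, 0.12),
                             cmc = 0,
                             intercept_range = c(-1.2, -0.13),
                             descriptor_means = c(log_km_kam = -0.64,
                                                  tpsa = 56.8, hba = 5.7,
                                                  mw = 326.6, alpha = 35.7,
                                                  parachor_P = 645.3,
                                                  nrb = 3.2),
                             descriptor_sds = c(log_km_kam = 0.24,
                                                tpsa = 11.1, hba = 0.9,
                                                mw = 31.3, alpha = 3.6,
                                                parachor_P = 63.5,
                                                nrb = 1.2),
                             rho_polar = 0.99, rho_size = 0.93,
                             rho_between = 0.15,
                             rho_lip_polar = -0.5, rho_lip_size = 0.6,
                             true_coef = c("(Intercept)" = 0.253,
                                           log_km_kam = 0.198,
                                           hba = -0.160, nrb = -0.019,
                                           parachor_P = 0.002),
                             sigma_y = 0.08, sigma_k = 0.01,
                             seed = 1L) {
  stopifnot(n_compounds >= 2, length(concentrations) >= 2,
            sigma_y >= 0, sigma_k >= 0,
            abs(rho_polar) < 1, abs(rho_size) < 1, abs(rho_between) < 1,
            names(true_coef)[1] == "(Intercept)")
  cfg <- list(n_compounds = n_compounds, concentrations = concentrations,
              cmc = cmc, intercept_range = intercept_range,
              descriptor_means = descriptor_means,
              descriptor_sds = descriptor_sds,
              rho_polar = rho_polar, rho_size = rho_size,
              rho_between = rho_between,
              rho_lip_polar = rho_lip_polar, rho_lip_size = rho_lip_size,
              true_coef = true_coef, sigma_y = sigma_y, sigma_k = sigma_k,
              seed = as.integer(seed))
  R <- generator_correlation(cfg)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("config error: target correlation matrix is not positive definite")
  cfg$correlation <- R
  structure(cfg, class = "generator_config")
}

# Target correlation matrix over the 7 generated descriptors.
generator_correlation <- function(cfg) {
  v <- c("log_km_kam", "tpsa", "hba", "mw", "alpha", "parachor_P", "nrb")
  R <- diag(length(v)); dimnames(R) <- list(v, v)
  set <- function(a, b, val) { R[a, b] <<- val; R[b, a] <<- val }
  polar <- c("tpsa", "hba"); size <- c("mw", "alpha", "parachor_P")
  set("tpsa", "hba", cfg$rho_polar)
  for (a in size) for (b in setdiff(size, a)) set(a, b, cfg$rho_size)
  for (a in polar) for (b in size) set(a, b, cfg$rho_between)
  for (a in c(polar, size)) set(a, "nrb", cfg$rho_between)
  for (a in polar) set("log_km_kam", a, cfg$rho_lip_polar)
  for (b in size) set("log_km_kam", b, cfg$rho_lip_size)
  R
}

#' Generate a synthetic descriptor table
#'
#' Draws `n_compounds` rows from a multivariate normal with the configured
#' means, standard deviations and correlation structure, then rounds the
#' count descriptors to integers and clips them to the plausible ranges of
#' the reference dataset (HBA 5-8, NRB 2-6). The pre-rounding latent values
#' are kept in the `"latent"` attribute, since rounding attenuates sample
#' correlations slightly.
#'
#' @param config A [generator_config()].
#' @return A `descriptor_table` with `n_compounds` rows and a `"latent"`
#'   attribute holding the unrounded draw.
#' @export
generate_descriptor_table <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  v <- colnames(config$correlation)
  Sigma <- diag(config$descriptor_sds[v]) %*% config$correlation %*%
    diag(config$descriptor_sds[v])
  Z <- MASS::mvrnorm(config$n_compounds, mu = config$descriptor_means[v],
                     Sigma = Sigma)
  colnames(Z) <- v
  out <- as.data.frame(Z)
  out$hba <- pmin(pmax(round(out$hba), 5), 8)
  out$nrb <- pmin(pmax(round(out$nrb), 2), 6)
  out <- cbind(compound_id = as.character(seq_len(config$n_compounds)), out,
               stringsAsFactors = FALSE)
  structure(out, latent = Z,
            class = c("descriptor_table", "data.frame"))
}

#' True Foley parameters consistent with a descriptor table
#'
#' Inverts the lipophilicity descriptor to per-compound Foley truth:
#' slope = 10^(-log(km/KAM)) and an intercept drawn uniformly from the
#' configured range (negative, as observed for strongly retained solutes),
#' adjusted upward where needed so that 1/k stays positive at every
#' configured concentration.
#'
#' @param config A [generator_config()].
#' @param table A descriptor table containing `log_km_kam`.
#' @return A data frame with columns `compound_id`, `intercept`, `slope`.
#' @export
foley_truth <- function(config, table) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed + 1L)
  slope <- 10^(-table$log_km_kam)
  m_min <- min(micelle_concentration(config$concentrations, config$cmc))
  intercept <- stats::runif(nrow(table), config$intercept_range[1],
                            config$intercept_range[2])
  # keep 1/k comfortably positive at the lowest micelle concentration,
  # with headroom for the configured 1/k noise
  floor_int <- -slope * m_min * 0.8
  intercept <- pmax(intercept, floor_int)
  data.frame(compound_id = table$compound_id, intercept = intercept,
             slope = slope, stringsAsFactors = FALSE)
}

#' Generate synthetic micellar retention series
#'
#' For each compound, inverts the Foley model to retention factors
#' k = 1 / (intercept + slope * \[M\]) at the configured concentrations and
#' adds Gaussian noise of standard deviation `sigma_k` on the 1/k scale
#' (the scale on which the model is fitted, so ordinary least squares
#' recovery is unbiased).
#'
#' @param config A [generator_config()].
#' @param truth Data frame with columns `compound_id`, `intercept`,
#'   `slope` (e.g. from [foley_truth()]).
#' @return A list of [retention_series()] objects.
#' @export
generate_retention_series <- function(config, truth) {
  stopifnot(inherits(config, "generator_config"),
            all(c("compound_id", "intercept", "slope") %in% names(truth)))
  set.seed(config$seed + 2L)
  m <- micelle_concentration(config$concentrations, config$cmc)
  lapply(seq_len(nrow(truth)), function(i) {
    inv_k <- truth$intercept[i] + truth$slope[i] * m
    if (any(inv_k <= 0))
      stop("truth-range error: non-positive 1/k for compound ",
           truth$compound_id[i])
    inv_k <- inv_k + stats::rnorm(length(m), 0, config$sigma_k)
    if (any(inv_k <= 0))
      stop("truth-range error: noise drove 1/k non-positive for compound ",
           truth$compound_id[i], "; reduce sigma_k")
    retention_series(truth$compound_id[i], config$concentrations,
                     k = 1 / inv_k, cmc = config$cmc)
  })
}

#' Generate a response from a known linear model
#'
#' y = a0 + sum_j a_j x_j + eps with eps ~ Normal(0, sigma_y^2), using the
#' configured true coefficients. Deterministic given the config seed.
#'
#' @param config A [generator_config()].
#' @param table A descriptor table containing every predictor named in
#'   `config$true_coef`.
#' @return Numeric response vector of length `nrow(table)`.
#' @export
generate_response <- function(config, table) {
  stopifnot(inherits(config, "generator_config"))
  coefs <- config$true_coef
  preds <- names(coefs)[-1]
  missing <- setdiff(preds, names(table))
  if (length(missing))
    stop("config error: predictor(s) not in table: ",
         paste(missing, collapse = ", "))
  set.seed(config$seed + 3L)
  X <- as.matrix(as.data.frame(table)[preds])
  storage.mode(X) <- "double"
  drop(coefs[1] + X %*% coefs[-1]) +
    stats::rnorm(nrow(table), 0, config$sigma_y)
}
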