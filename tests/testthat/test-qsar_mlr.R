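test_that("model enumeration follows the group template and labeling order", {
  full <- enumerate_models(include_flexibility = "with")
  expect_length(full, 12)
  expect_equal(vapply(full, `[[`, "", "label"), paste0("M", 1:12))
  expect_equal(full[[5]]$response, "log_bb")
  expect_equal(full[[5]]$predictors, c("log_km_kam", "hba", "nrb", "parachor_P"))
  expect_equal(full[[1]]$predictors, c("log_km_kam", "tpsa", "nrb", "alpha"))
  expect_equal(full[[12]]$predictors, c("log_km_kam", "hba", "nrb", "mw"))
  expect_true(all(vapply(full[1:6], `[[`, "", "response") == "log_bb"))
  expect_true(all(vapply(full[7:12], `[[`, "", "response") == "log_bb_star"))

  starred <- enumerate_models(include_flexibility = "without")
  expect_equal(vapply(starred, `[[`, "", "label"), c("M5*", "M11*", "M12*"))
  expect_false(any(vapply(starred, function(s) "nrb" %in% s$predictors, TRUE)))

  expect_length(enumerate_models(), 15)

  small <- enumerate_models(
    grouping = list(lipophilicity = "log_km_kam", I = c("tpsa", "hba"),
                    II = "mw", III = "nrb"),
    responses = "log_bb", include_flexibility = "with")
  expect_length(small, 2)
})

test_that("model_spec rejects malformed specifications", {
  expect_error(model_spec("X", "y", c("a", "a")), "unique")
  expect_error(model_spec("X", "y", c("a", "y")), "response")
  expect_error(enumerate_models(grouping = list(I = "a")), "grouping")
})

test_that("fitted coefficients reproduce the published equations", {
  fits <- fit_all_models()
  expect_equal(unname(round(fits[["M5"]]$coefficients, 3)),
               c(0.253, 0.198, -0.160, -0.019, 0.002))
  expect_equal(unname(round(fits[["M5"]]$se[1:3], 3)),
               c(0.232, 0.091, 0.023))
  expect_equal(unname(round(fits[["M12*"]]$coefficients["hba"], 3)), -0.156)
  expect_equal(unname(round(fits[["M5*"]]$coefficients, 3)),
               c(0.406, 0.181, -0.180, 0.002))
  expect_equal(unname(round(fits[["M12"]]$coefficients[1:3], 3)),
               c(0.911, 0.103, -0.158))
})

test_that("an exact linear response is fitted with zero residuals", {
  tab <- ref_table
  tab$log_bb <- 1 - 0.3 * tab$log_km_kam + 0.05 * tab$hba
  fit <- fit_mlr(model_spec("X", "log_bb", c("log_km_kam", "hba")), tab)
  expect_lt(max(abs(fit$residuals)), 1e-10)
  expect_equal(summary(fit$lm)$r.squared, 1, tolerance = 1e-12)
})

test_that("ill-posed designs are rejected", {
  tab <- ref_table
  tab$dup <- tab$hba
  expect_error(fit_mlr(model_spec("X", "log_bb", c("hba", "dup")), tab),
               "rank deficient")
  expect_error(fit_mlr(model_spec("X", "log_bb",
                                  c("log_km_kam", "hba", "nrb", "mw")),
                       tab[1:5, ]),
               "degrees-of-freedom")
  expect_error(fit_mlr(model_spec("X", "log_bb", "nope"), tab), "nope")
})

test_that("the validation battery matches the published statistics", {
  fits <- fit_all_models()
  stats <- lapply(fits, model_statistics)
  for (i in seq_len(nrow(ref_stats))) {
    s <- stats[[ref_stats$label[i]]]
    expect_lt(abs(s$r2 - ref_stats$r2[i]), 1.5e-4,
              label = paste(s$label, "R2 deviation"))
    expect_lt(abs(s$r2_adj - ref_stats$r2_adj[i]), 1.5e-4,
              label = paste(s$label, "R2adj deviation"))
    expect_lt(abs(s$r2_pred - ref_stats$r2_pred[i]), 1.5e-4,
              label = paste(s$label, "R2pred deviation"))
    expect_lt(abs(s$press - ref_stats$press[i]), 1.5e-4,
              label = paste(s$label, "PRESS deviation"))
    expect_lt(abs(s$ss - ref_stats$ss[i]), 1.5e-4,
              label = paste(s$label, "SS deviation"))
    if (!is.na(ref_stats$f[i]))
      expect_lt(abs(s$f - ref_stats$f[i]), 0.11,
                label = paste(s$label, "F deviation"))
    expect_lt(s$p_value, 5e-6)
    # internal identities
    expect_equal(s$r2_pred, 1 - s$press / s$ss, tolerance = 1e-12)
    expect_equal(s$q2_loo, s$r2_pred)
    expect_equal(s$press_loo, s$press)
    expect_equal(s$r2_adj,
                 1 - (1 - s$r2) * (s$n - 1) / (s$n - s$p - 1),
                 tolerance = 1e-12)
  }
})

test_that("adding a predictor never decreases R2 (nested models)", {
  fits <- fit_all_models()
  for (pair in list(c("M5*", "M5"), c("M11*", "M11"), c("M12*", "M12"))) {
    expect_lte(model_statistics(fits[[pair[1]]])$r2,
               model_statistics(fits[[pair[2]]])$r2)
  }
})

test_that("hat-matrix LOO shortcut equals the explicit refit loop", {
  set.seed(101)
  for (trial in 1:100) {
    n <- sample(8:25, 1)
    p <- sample(2:4, 1)
    X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
    y <- rnorm(n)
    tab <- data.frame(y = y, X)
    fit <- fit_mlr(model_spec("T", "y", colnames(X)), tab)
    expect_equal(loo_press(fit)$press, press_by_refit(y, X),
                 tolerance = 1e-10)
  }
})

test_that("duplicating every row halves leverages and keeps PRESS finite", {
  tab <- ref_table[, c("log_bb", "log_km_kam", "hba")]
  tab2 <- rbind(tab, tab)
  fit2 <- fit_mlr(model_spec("D", "log_bb", c("log_km_kam", "hba")), tab2)
  fit1 <- fit_mlr(model_spec("S", "log_bb", c("log_km_kam", "hba")), tab)
  expect_equal(fit2$hat, rep(fit1$hat / 2, 2), ignore_attr = TRUE,
               tolerance = 1e-12)
  expect_true(is.finite(loo_press(fit2)$press))
})

test_that("interpolated points make the LOO shortcut fail loudly", {
  tab <- data.frame(y = c(1, 2, 3, 10), x = c(0, 0.01, 0.02, 5))
  fit <- fit_mlr(model_spec("L", "y", "x"), tab)
  # the far point nearly determines its own fit; force exact h = 1
  fit$hat[4] <- 1
  expect_error(loo_press(fit), "degenerate leverage")
})

test_that("VIFs match the regress-on-the-rest definition and car's values", {
  fits <- fit_all_models()
  v5 <- vif_values(fits[["M5"]])
  expect_equal(round(v5$max_vif, 1), 4.8)
  expect_equal(round(max(vif_values(fits[["M12*"]])$vif), 1), 4.1)
  # independent cross-check against car's implementation
  expect_equal(v5$vif, car::vif(fits[["M5"]]$lm), tolerance = 1e-10)

  # orthogonal-polynomial columns are mutually orthogonal after centering
  ortho <- unclass(poly(1:10, 4))
  colnames(ortho) <- paste0("q", 1:4)
  vo <- vif_values(ortho)
  expect_equal(unname(vo$vif), rep(1, 4), tolerance = 1e-10)

  dup <- data.frame(a = rnorm(10))
  dup$b <- 2 * dup$a
  expect_true(is.infinite(vif_values(dup)$max_vif))
})

test_that("screening reproduces the exclusion set and ranks survivors", {
  stats <- lapply(fit_all_models(), model_statistics)
  scr <- screen_models(stats)
  expect_setequal(scr$label[scr$excluded], c("M1", "M3", "M4", "M7", "M9", "M10"))
  survivors <- scr[!scr$excluded, ]
  expect_equal(survivors$rank, seq_len(nrow(survivors)))
  expect_true(all(diff(survivors$r2_pred) <= 1e-12))
  expect_true(all(survivors$pass_q2))
  expect_true(all(survivors$pass_press_ss))
  # the selected log BB and log BB* models survive
  expect_true(all(c("M5", "M11", "M12", "M5*", "M11*", "M12*") %in%
                    survivors$label))
  expect_error(screen_models(list()), "empty")
})

test_that("screening thresholds act on the stated boundaries", {
  fake <- function(label, r2_pred, press, ss, vif) {
    structure(list(label = label, response = "y", r2 = r2_pred,
                   r2_pred = r2_pred, press = press, press_ss_ratio = press / ss,
                   max_vif = vif), class = "model_stats")
  }
  scr <- screen_models(list(fake("A", 0.9, 0.5, 1.0, 2),   # ratio 0.5 -> flag
                            fake("B", 0.5, 0.2, 1.0, 2),   # q2 <= 0.6 -> flag
                            fake("C", 0.8, 0.3, 1.0, 4.94),
                            fake("D", 0.95, 0.1, 1.0, 4.96))) # rounds to 5.0
  expect_equal(scr$label[scr$excluded], "D")
  expect_false(scr$pass_press_ss[scr$label == "A"])
  expect_false(scr$pass_q2[scr$label == "B"])
  expect_equal(scr$rank[scr$label == "A"], 1)  # highest surviving r2_pred
})

test_that("standardized coefficients identify HBA as dominant and are scale-free", {
  fits <- fit_all_models()
  b <- standardized_coefficients(fits[["M5"]])
  expect_equal(names(which.max(abs(b))), "hba")
  expect_equal(sign(b), sign(fits[["M5"]]$coefficients[-1]),
               ignore_attr = TRUE)

  tab <- ref_table
  tab$parachor_P <- tab$parachor_P * 10
  b_scaled <- standardized_coefficients(
    fit_mlr(model_spec("M5s", "log_bb",
                       c("log_km_kam", "hba", "nrb", "parachor_P")), tab))
  expect_equal(b_scaled, b, ignore_attr = TRUE, tolerance = 1e-10)

  ident <- data.frame(y = rnorm(20))
  ident$x <- ident$y
  ident$z <- rnorm(20)
  b1 <- standardized_coefficients(fit_mlr(model_spec("I", "y", "x"), ident))
  expect_equal(unname(b1), 1, tolerance = 1e-12)
})

test_that("prediction returns leverage and applicability-domain flags", {
  fits <- fit_all_models()
  m5 <- fits[["M5"]]
  row1 <- ref_table[1, ]
  pred <- predict(m5, row1)
  expect_equal(pred$prediction, ref_table$log_bb[1] - m5$residuals[1],
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_true(pred$in_domain)
  expect_equal(pred$leverage, unname(m5$hat[1]), tolerance = 1e-10)

  centroid <- as.data.frame(t(colMeans(ref_table[m5$spec$predictors])))
  expect_equal(predict(m5, centroid)$leverage, 1 / 65, tolerance = 1e-10)

  far <- row1
  far$parachor_P <- 5000
  expect_false(predict(m5, far)$in_domain)

  expect_error(predict(m5, row1[, c("log_km_kam", "hba")]), "nrb")
})

test_that("coefficient recovery on noisy synthetic tables covers truth", {
  cfg <- generator_config(seed = 2024)
  truth <- cfg$true_coef
  within <- integer(0)
  for (rep in 1:500) {
    cfg_r <- generator_config(seed = 2024 + rep)
    tab <- generate_descriptor_table(cfg_r)
    tab$log_bb <- generate_response(cfg_r, tab)
    fit <- fit_mlr(model_spec("T", "log_bb", names(truth)[-1]), tab)
    within <- c(within, abs(fit$coefficients - truth) <= 3 * fit$se)
  }
  expect_gte(mean(within), 0.99)
})
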