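test_that("the identity-family intercept-only fit recovers the sample mean", {
  set.seed(8)
  n <- 400
  d <- data.frame(score = runif(n, -0.8, 0.8),
                  aggressor = sample(letters[1:6], n, TRUE),
                  recipient = sample(LETTERS[1:6], n, TRUE),
                  group = "G")
  d$dyad <- paste(d$aggressor, d$recipient, sep = ":")
  fit <- suppressWarnings(direction_model(d, family = "linear", fixed = ~ 1))
  expect_lt(abs(coef(fit)[["(Intercept)"]] - mean(d$score)), 1e-4)
})

test_that("the fitted model is deterministic given data and family, and its
           summary reports symmetric Wald intervals", {
  f1 <- small_fit("linear")
  d <- f1$data
  f2 <- suppressWarnings(direction_model(d, family = "linear"))
  expect_equal(coef(f1), coef(f2))
  sm <- summary(f1)
  expect_equal(sm$coefficients$ci_upper - sm$coefficients$estimate,
               sm$coefficients$estimate - sm$coefficients$ci_lower)
  expect_equal(sm$coefficients$ci_upper - sm$coefficients$ci_lower,
               2 * 1.96 * sm$coefficients$std_error, tolerance = 1e-6)
})

test_that("a single-level categorical term is dropped with a warning and
           the rest of the fit proceeds", {
  fit <- small_fit("linear")
  d <- fit$data
  d$species <- "mountain"
  w <- capture_warnings(m <- direction_model(d, family = "linear"))
  expect_true(any(grepl("fewer than 2 observed levels", w)))
  expect_false("specieswestern" %in% names(coef(m)))
})

test_that("the beta-logit family squeezes the response off the boundaries
           and predicts on the score scale", {
  fit_b <- small_fit("beta_logit")
  expect_true(all(fit_b$data$.resp > 0 & fit_b$data$.resp < 1))
  pr <- predict(fit_b)
  expect_true(all(pr >= -1 & pr <= 1))
  sims <- simulate(fit_b, nsim = 2, seed = 1)
  expect_true(all(as.matrix(sims) >= -1 & as.matrix(sims) <= 1))
  # same seed, same draws
  expect_equal(simulate(fit_b, nsim = 2, seed = 1), sims)
})

test_that("Type-II Wald tests reduce to (estimate/SE)^2 for single
           coefficients, use df = levels - 1 for factors, and match an
           independent implementation", {
  fit <- small_fit("linear")
  w <- type2_wald_tests(fit)
  b <- coef(fit); V <- as.matrix(vcov(fit))
  expect_equal(w$chisq[w$term == "n_males"],
               unname((b["n_males"] / sqrt(V["n_males", "n_males"]))^2))
  expect_identical(w$df[w$term == "state"], 4L)
  expect_identical(w$df[w$term == "intensity"], 2L)
  expect_true(all(w$chisq >= 0) && all(w$p_value >= 0 & w$p_value <= 1))
  # independent oracle: car's Type-II Anova on the underlying fit
  a <- car::Anova(fit$model, type = "II")
  expect_equal(w$chisq, unname(a[w$term, "Chisq"]), tolerance = 1e-8)
  expect_equal(w$p_value, unname(a[w$term, "Pr(>Chisq)"]), tolerance = 1e-8)
})

test_that("p-values are invariant to reordering of the input rows", {
  fit <- small_fit("linear")
  d <- fit$data
  set.seed(3)
  d2 <- d[sample.int(nrow(d)), ]
  fit2 <- suppressWarnings(direction_model(d2, family = "linear"))
  expect_equal(type2_wald_tests(fit)$p_value, type2_wald_tests(fit2)$p_value,
               tolerance = 1e-6)
  expect_equal(tukey_contrasts(fit, mc_draws = 2e4, seed = 5)$p_adjusted,
               tukey_contrasts(fit2, mc_draws = 2e4, seed = 5)$p_adjusted,
               tolerance = 1e-4)
})

test_that("tukey_contrasts yields all C(5,2)=10 state comparisons with
           adjusted p in the raw-p/Bonferroni sandwich, reproducibly", {
  fit <- small_fit("linear")
  ct <- tukey_contrasts(fit, "state", mc_draws = 5e4, seed = 11)
  expect_identical(nrow(ct), 10L)
  expect_identical(anyDuplicated(ct$comparison), 0L)
  expect_true(all(ct$p_adjusted >= ct$p_value - 1e-12))
  expect_true(all(ct$p_adjusted <= pmin(1, 10 * ct$p_value) + 1e-12))
  # bit-for-bit reproducibility at fixed (seed, mc_draws)
  ct2 <- tukey_contrasts(fit, "state", mc_draws = 5e4, seed = 11)
  expect_identical(ct$p_adjusted, ct2$p_adjusted)
  # z = estimate / SE and two-sided normal raw p
  expect_equal(ct$z_value, ct$estimate / ct$std_error)
  expect_equal(ct$p_value, 2 * pnorm(-abs(ct$z_value)))
})

test_that("single-step adjustment matches the closed form for independent
           contrasts and the multcomp oracle on a fitted covariance", {
  # independent contrasts: P(max of 3 independent |Z| >= z) has a closed form
  z <- c(0.8, 1.7, 2.6)
  p_mc <- aggdir:::single_step_maxT(z, se = rep(1, 3), K = diag(3),
                                    Vs = diag(3), mc_draws = 4e5, seed = 9)
  p_closed <- 1 - (2 * pnorm(z) - 1)^3
  expect_equal(p_mc, p_closed, tolerance = 3e-3)
  # fitted covariance: multcomp's single-step adjustment as oracle
  fit <- small_fit("linear")
  ct <- tukey_contrasts(fit, "state", mc_draws = 2e5, seed = 4)
  lv <- levels(fit$data$state)
  cn <- paste0("state", lv[-1])
  K <- matrix(0, 10, length(coef(fit)),
              dimnames = list(NULL, names(coef(fit))))
  pairs <- utils::combn(5, 2)
  for (j in 1:10) {
    if (pairs[2, j] > 1) K[j, cn[pairs[2, j] - 1]] <- 1
    if (pairs[1, j] > 1) K[j, cn[pairs[1, j] - 1]] <- -1
  }
  g <- summary(multcomp::glht(multcomp::parm(coef(fit), as.matrix(vcov(fit))),
                              linfct = K))
  expect_equal(ct$estimate, unname(as.numeric(g$test$coefficients)))
  expect_equal(ct$p_adjusted, unname(as.numeric(g$test$pvalues)),
               tolerance = 0.01)
})

test_that("a two-level factor collapses the adjustment to the unadjusted
           p-value within Monte Carlo error", {
  fit <- small_fit("linear")
  d <- fit$data
  d$state <- factor(ifelse(as.character(d$state) == "cycling",
                           "cycling", "lactating"),
                    levels = c("cycling", "lactating"))
  m <- suppressWarnings(direction_model(
    d, family = "linear", fixed = ~ intensity + n_males + n_females + state))
  ct <- tukey_contrasts(m, "state", mc_draws = 2e5, seed = 2)
  expect_identical(nrow(ct), 1L)
  expect_equal(ct$p_adjusted, ct$p_value, tolerance = 1e-3)
})

test_that("generalized VIFs are 1 for orthogonal predictors, hit the
           1/(1-R^2) closed form under known correlation, and flag exact
           collinearity", {
  set.seed(21)
  n <- 10000
  x1 <- rnorm(n)
  x2 <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(n)
  d <- data.frame(x1 = x1, x2 = x2, x3 = rnorm(n))
  v <- vif_terms(d, ~ x1 + x2 + x3)
  expect_equal(v$gvif[v$term %in% c("x1", "x2")], rep(1 / (1 - 0.36), 2),
               tolerance = 0.05)
  expect_equal(v$gvif[v$term == "x3"], 1, tolerance = 0.01)
  ortho <- vif_terms(data.frame(a = rep(c(-1, 1), 50),
                                b = rep(c(-1, 1), each = 50)), ~ a + b)
  expect_equal(ortho$gvif, c(1, 1))
  d$x4 <- d$x1
  expect_warning(vdup <- vif_terms(d, ~ x1 + x2 + x3 + x4), "collinear")
  expect_true(any(!is.finite(vdup$gvif)))
  # model-based VIFs stay below the published multicollinearity bar
  fit <- small_fit("linear")
  expect_true(all(vif_terms(fit)$gvif_scaled < 1.5))
})

test_that("residual diagnostics refuse tiny simulation counts, are calm on
           well-specified data, and flag doubled noise as overdispersion", {
  fit <- small_fit("linear")
  expect_error(residual_diagnostics(fit, n_sim = 10), "at least 50")
  rc <- residual_diagnostics(fit, n_sim = 120, seed = 2)
  expect_gt(rc$uniformity$p_value, 0.001)
  expect_true(abs(rc$dispersion$ratio - 1) < 0.15)
  expect_identical(residual_diagnostics(fit, n_sim = 120, seed = 2)$dispersion,
                   rc$dispersion)
  noisy <- fit$data
  noisy$score <- pmin(1, pmax(-1, noisy$score +
                                rnorm(nrow(noisy), 0, sd(residuals(fit)))))
  rc2 <- residual_diagnostics(fit, data = noisy, n_sim = 120, seed = 2)
  expect_gt(rc2$dispersion$ratio, 1.2)
  expect_lt(rc2$dispersion$p_value, 0.05)
})

test_that("under the fitted model's own simulations the scaled residuals
           are marginally uniform and the dispersion test is calibrated", {
  fit <- small_fit("linear")
  sims <- simulate(fit, nsim = 40, seed = 77)
  stats <- vapply(seq_len(40), function(i) {
    d <- fit$data
    d$score <- sims[[i]]
    rc <- residual_diagnostics(fit, data = d, n_sim = 80, seed = i)
    c(ks_rej = rc$uniformity$p_value < 0.05,
      disp_rej = rc$dispersion$p_value < 0.05,
      mean_u = mean(rc$scaled_residuals))
  }, numeric(3))
  # dispersion: calibrated at the nominal rate
  expect_lte(mean(stats["disp_rej", ]), 0.15)
  # residuals marginally uniform: rep means centred at 0.5
  expect_lt(abs(mean(stats["mean_u", ]) - 0.5), 0.02)
  # the KS uniformity test is anti-conservative under crossed random
  # effects because the simulations redraw them, correlating the scaled
  # residuals within identity clusters (a known property of
  # simulation-based residuals); it must still not reject wholesale
  expect_lte(mean(stats["ks_rej", ]), 0.6)
})

test_that("predict_effects is linear in a numeric covariate for the
           identity family and monotone through the logit link", {
  fit <- small_fit("linear")
  g <- range(fit$data$n_males)
  eff <- predict_effects(fit, "n_males", grid = g)
  expect_equal(eff$score[2] - eff$score[1], diff(g) * coef(fit)[["n_males"]],
               tolerance = 1e-8)
  expect_true(all(eff$lower <= eff$score & eff$score <= eff$upper))
  fit_b <- small_fit("beta_logit")
  b_males <- coef(fit_b)[["n_males"]]
  eff_b <- predict_effects(fit_b, "n_males",
                           grid = seq(g[1], g[2], length.out = 6))
  expect_true(all(diff(eff_b$score) * sign(b_males) > 0))
  expect_warning(predict_effects(fit, "n_males", grid = c(0, 50)),
                 "outside the observed range")
  eff_s <- predict_effects(fit, "state")
  expect_identical(nrow(eff_s), 5L)
})
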