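# Model fitting, AIC comparison, backward simplification, random-effect
# LRT and post hoc marginal means.

sim_data <- function(beta, sd_u, sd_e, seed, design = "infection") {
  em <- effect_model("L", beta = beta, sd_individual = sd_u, sd_resid = sd_e)
  generate_shift_dataset(experiment_design(design), em, seed = seed)
}

fake_fit <- function(AIC, k, n_ia = 0, random_id = FALSE, n = 100) {
  spec <- structure(list(response = "L", fixed = "treatment",
                         interactions = rep("a:b", n_ia),
                         random_id = random_id),
                    class = "cs_model_spec")
  structure(list(AIC = AIC, k = k, logLik = (2 * k - AIC) / 2, n = n,
                 method = "ML", spec = spec),
            class = "cs_model_fit")
}

test_that("near-noiseless data recovers the generating coefficients", {
  beta <- c("(Intercept)" = 2, "lineR" = -0.5, "treatmentinfected" = 1.5,
            "time_h" = 0.08)
  d <- sim_data(beta, 0, 0, seed = 1)
  set.seed(2)
  d$delta <- d$delta + rnorm(nrow(d), 0, 1e-8)
  fit <- fit_model(d, model_spec("L", c("line", "treatment", "time_h")), "ML")
  expect_equal(fit$coef_table[names(beta), "estimate"], unname(beta),
               tolerance = 1e-4)
})

test_that("a zero variance-component estimate is flagged as a boundary fit", {
  d <- sim_data(c("(Intercept)" = 1), sd_u = 0, sd_e = 1, seed = 24)
  fit <- suppressMessages(
    fit_model(d, model_spec("L", c("line", "treatment", "time_h")), "ML"))
  expect_true(fit$singular)
  expect_equal(fit$sigma_id, 0, tolerance = 1e-8)
})

test_that("an intercept-only model estimates the sample mean", {
  d <- sim_data(c("(Intercept)" = 3), 1, 1, seed = 5)
  fit <- fit_model(d, model_spec("L", fixed = character(), random_id = FALSE))
  expect_equal(fit$coef_table["(Intercept)", "estimate"], mean(d$delta),
               tolerance = 1e-10)
})

test_that("the OLS special case reproduces closed-form coefficients", {
  d <- data.frame(individual_id = paste0("i", 1:5), attribute = "L",
                  time_h = c(1, 2, 4, 7, 11),
                  delta = c(2.0, 2.9, 5.2, 8.8, 12.1))
  fit <- fit_model(d, model_spec("L", fixed = "time_h", random_id = FALSE))
  sxx <- sum((d$time_h - mean(d$time_h))^2)
  slope <- sum((d$time_h - mean(d$time_h)) * (d$delta - mean(d$delta))) / sxx
  intercept <- mean(d$delta) - slope * mean(d$time_h)
  expect_equal(fit$coef_table["time_h", "estimate"], slope, tolerance = 1e-12)
  expect_equal(fit$coef_table["(Intercept)", "estimate"], intercept,
               tolerance = 1e-12)
  expect_equal(fit$coef_table$df, c(3, 3))
})

test_that("AIC equals 2k - 2 logLik, verified by hand on a small fixture", {
  d <- data.frame(individual_id = paste0("i", 1:10), attribute = "L",
                  time_h = rep(c(24, 48), 5),
                  delta = c(3.1, 5.2, 2.8, 6.1, 3.5, 5.8, 2.9, 5.5, 3.3, 6.0))
  fit <- fit_model(d, model_spec("L", fixed = "time_h", random_id = FALSE))
  # independent hand computation: Gaussian ML log-likelihood of OLS
  res <- d$delta - cbind(1, d$time_h) %*%
    solve(crossprod(cbind(1, d$time_h)), crossprod(cbind(1, d$time_h), d$delta))
  n <- 10
  ll <- -n / 2 * (log(2 * pi) + log(sum(res^2) / n) + 1)
  k <- 3                                        # intercept, slope, sigma
  expect_equal(fit$logLik, ll, tolerance = 1e-9)
  expect_equal(fit$k, k)
  expect_equal(fit$AIC, 2 * k - 2 * ll, tolerance = 1e-9)
})

test_that("within-2 AIC equivalence prefers the simpler model", {
  # 1.9 units apart: equivalent, fewer parameters wins despite higher AIC
  cmp <- compare_models(list(fake_fit(100.0, k = 6), fake_fit(101.9, k = 4)))
  expect_identical(cmp$chosen, 2L)
  # 3 units apart: lower AIC wins regardless of complexity
  cmp <- compare_models(list(fake_fit(100.0, k = 6), fake_fit(103.0, k = 4)))
  expect_identical(cmp$chosen, 1L)
  # identical models: delta AIC 0, simpler (here: first by tie-break) chosen
  cmp <- compare_models(list(fake_fit(100, k = 4), fake_fit(100, k = 4)))
  expect_identical(cmp$chosen, 1L)
  expect_equal(cmp$table$dAIC, c(0, 0))
  # equal k: fewer interactions, then fixed-only before mixed
  cmp <- compare_models(list(fake_fit(100, 4, n_ia = 1),
                             fake_fit(101, 4, n_ia = 0)))
  expect_identical(cmp$chosen, 2L)
  cmp <- compare_models(list(fake_fit(100, 4, random_id = TRUE),
                             fake_fit(101, 4, random_id = FALSE)))
  expect_identical(cmp$chosen, 2L)
})

test_that("model comparison rejects mixed ML/REML input", {
  f1 <- fake_fit(100, 4); f2 <- fake_fit(101, 4)
  f2$method <- "REML"
  expect_error(compare_models(list(f1, f2)), "ML")
})

test_that("comparison is invariant to response row order", {
  d <- sim_data(c("(Intercept)" = 1, "treatmentinfected" = 2), 1, 1, seed = 9)
  ladder <- candidate_ladder("L")
  aic1 <- vapply(ladder, function(s) fit_model(d, s, "ML")$AIC, 0)
  set.seed(1)
  d2 <- d[sample(nrow(d)), ]
  aic2 <- vapply(ladder, function(s) fit_model(d2, s, "ML")$AIC, 0)
  expect_equal(aic1, aic2, tolerance = 1e-8)
})

test_that("backward simplification keeps the real effect and drops the rest", {
  d <- sim_data(c("(Intercept)" = 0.5, "treatmentinfected" = 3), 1, 0.8,
                seed = 13)
  full <- fit_model(d, model_spec("L", c("line", "treatment", "time_h")), "ML")
  simp <- simplify_model(full, d)
  expect_true("treatment" %in% simp$final$spec$fixed)
  expect_false("line" %in% simp$final$spec$fixed)
  expect_false("time_h" %in% simp$final$spec$fixed)
  expect_true(all(simp$path$AIC_after < simp$path$AIC_before))
  expect_identical(simp$final_reml$method, "REML")
})

test_that("simplification respects marginality for retained interactions", {
  d <- sim_data(c("(Intercept)" = 0.5, "treatmentinfected" = 1, "lineR" = 0.3,
                  "lineR:treatmentinfected" = 3), 0.5, 0.7, seed = 17)
  spec <- model_spec("L", c("line", "treatment", "time_h"),
                     interactions = "line:treatment")
  simp <- simplify_model(fit_model(d, spec, "ML"), d)
  expect_true("line:treatment" %in% simp$final$spec$interactions)
  expect_true(all(c("line", "treatment") %in% simp$final$spec$fixed))
  # while the interaction is in the model, its mains are never on the path
  expect_false(any(simp$path$dropped %in% c("line", "treatment")))
})

test_that("the random-effect LRT behaves at both variance extremes", {
  spec_w <- model_spec("L", c("line", "treatment", "time_h"), random_id = TRUE)
  spec_o <- model_spec("L", c("line", "treatment", "time_h"), random_id = FALSE)
  # no individual variance, boundary estimate: chi-square is exactly zero
  d0 <- sim_data(c("(Intercept)" = 1), 0, 1, seed = 24)
  rt0 <- suppressMessages(test_random_effect(d0, spec_w, spec_o))
  expect_identical(rt0$chisq, 0)
  expect_identical(rt0$df, 1L)
  expect_identical(rt0$p.value, 1)
  # and across null replicates the test stays non-significant almost always
  nonsig <- vapply(101:130, function(s) {
    d <- sim_data(c("(Intercept)" = 1), 0, 1, seed = s)
    suppressMessages(test_random_effect(d, spec_w, spec_o))$p.value > 0.05
  }, TRUE)
  expect_gte(mean(nonsig), 0.9)
  # strong individual variance (ICC 0.5): decisive rejection
  d1 <- sim_data(c("(Intercept)" = 1), 1, 1, seed = 23)
  rt1 <- test_random_effect(d1, spec_w, spec_o)
  expect_gt(rt1$chisq, 10)
  expect_lt(rt1$p.value, 0.001)
  # guard: specs must differ only in the random intercept
  expect_error(test_random_effect(d1, spec_w, model_spec("L", "line", random_id = FALSE)),
               "identical")
})

test_that("post hoc marginal means equal cell means in balanced designs", {
  d <- sim_data(c("(Intercept)" = 1, "treatmentinfected" = 2), 0, 1, seed = 29)
  fit <- fit_model(d, model_spec("L", "treatment", random_id = FALSE))
  ph <- posthoc_means(fit, "treatment")
  cell <- tapply(d$delta, d$treatment, mean)
  expect_equal(ph$means$emmean,
               as.vector(cell[as.character(ph$means$treatment)]),
               tolerance = 1e-9)
  # two-level factor: a single comparison, so adjusted p equals the raw p
  expect_identical(nrow(ph$pairs), 1L)
  raw <- summary(fit$fit)$coefficients["treatmentinfected", "Pr(>|t|)"]
  expect_equal(ph$pairs$p.value, raw, tolerance = 1e-9)
  expect_error(posthoc_means(fit, "line"), "not a term")
})

test_that("three-level post hocs recover an ordered effect pattern", {
  beta <- c("(Intercept)" = 0, "treatmentsingle" = 2, "treatmentgroup" = 4)
  em <- effect_model("L", beta = beta, sd_individual = 0.5, sd_resid = 0.5)
  d <- generate_shift_dataset(experiment_design("social"), em, seed = 31)
  fit <- fit_model(d, model_spec("L", c("line", "treatment"), random_id = TRUE),
                   "REML")
  ph <- posthoc_means(fit, "treatment")
  expect_identical(nrow(ph$pairs), 3L)
  mns <- ph$means$emmean[match(c("control", "single", "group"),
                               ph$means$treatment)]
  expect_true(all(diff(mns) > 0))
  expect_true(all(ph$pairs$p.value < 0.01))
})
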