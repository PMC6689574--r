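# Mixed-model inference over colour-shift tables: candidate-model ladder,
# maximum-likelihood AIC comparison with the 2-unit equivalence rule,
# marginality-respecting backward elimination, random-intercept
# likelihood-ratio test and estimated-marginal-mean post hocs.
#
# Mixed fits go through lmerTest (Satterthwaite denominator df for the
# fixed-effect t tests); fixed-only fits through stats::lm with residual df.
# All selection is done on ML fits; the final reported model is refit by
# REML for unbiased variance components.

#' Specify a candidate model
#'
#' @param response Attribute modelled (`"L"`, `"h"` or `"C"`; matched against
#'   the `attribute` column when present).
#' @param fixed Character vector of fixed main effects, a subset of
#'   `c("line", "treatment", "time_h", "interval")`.
#' @param interactions Character vector of interaction terms written with
#'   `:` (e.g. `"line:treatment"`); every component must appear in `fixed`.
#' @param random_id Include a per-individual random intercept?
#' @return Object of class `cs_model_spec`.
#' @export
model_spec <- function(response = "L",
                       fixed = c("line", "treatment", "time_h"),
                       interactions = character(),
                       random_id = TRUE) {
  for (ia in interactions) {
    parts <- strsplit(ia, ":", fixed = TRUE)[[1]]
    if (!all(parts %in% fixed)) {
      stop("interaction ", ia, " includes terms absent from the main effects")
    }
  }
  structure(list(response = response, fixed = fixed,
                 interactions = interactions, random_id = random_id),
            class = "cs_model_spec")
}

.spec_formula <- function(spec) {
  rhs <- c(spec$fixed, spec$interactions)
  if (!length(rhs)) rhs <- "1"
  if (spec$random_id) rhs <- c(rhs, "(1 | individual_id)")
  stats::as.formula(paste("delta ~", paste(rhs, collapse = " + ")))
}

.spec_label <- function(spec) {
  rhs <- c(spec$fixed, spec$interactions)
  if (!length(rhs)) rhs <- "1"
  paste0(paste(rhs, collapse = " + "), if (spec$random_id) " + (1|ID)" else "")
}

#' Fit one candidate model to a shift table
#'
#' Specs with a random intercept are fitted as linear mixed models; specs
#' without as ordinary least squares. The coefficient table mirrors the
#' conventional mixed-model report: estimate, standard error, denominator
#' degrees of freedom, t value and p value per fixed term. Singular
#' random-effect fits are flagged, not silently accepted.
#'
#' @param data Shift table with columns `delta`, `individual_id` and the
#'   covariates named in the spec; rows are filtered to `spec$response` when
#'   an `attribute` column is present.
#' @param spec A [model_spec()].
#' @param method `"ML"` (used for all AIC comparison) or `"REML"`.
#' @return Object of class `cs_model_fit`: list with the underlying `fit`,
#'   `spec`, `method`, `coef_table`, `logLik`, `AIC`, `k` (parameter count
#'   including variances), `n`, `sigma_id`, `sigma_resid`, `singular`.
#' @export
fit_model <- function(data, spec, method = c("ML", "REML")) {
  method <- match.arg(method)
  stopifnot(inherits(spec, "cs_model_spec"))
  if ("attribute" %in% names(data)) {
    data <- data[data$attribute == spec$response, , drop = FALSE]
  }
  if (!nrow(data)) stop("no rows for response attribute ", spec$response)
  if (any(!is.finite(data$delta))) stop("response contains non-finite values")
  form <- .spec_formula(spec)

  if (spec$random_id) {
    # singularity is reported via the fit's own `singular` flag; muffle
    # lme4's console message so simulation loops stay readable
    fit <- withCallingHandlers(
      lmerTest::lmer(form, data = data, REML = (method == "REML")),
      message = function(m) {
        if (grepl("boundary \\(singular\\)", conditionMessage(m))) {
          invokeRestart("muffleMessage")
        }
      })
    sm <- suppressWarnings(summary(fit))
    ct <- as.data.frame(sm$coefficients)
    names(ct) <- c("estimate", "std.error", "df", "t.value", "p.value")
    singular <- lme4::isSingular(fit, tol = 1e-10)
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_id <- vc$sdcor[vc$grp == "individual_id"]
    sigma_resid <- vc$sdcor[vc$grp == "Residual"]
  } else {
    fit <- stats::lm(form, data = data)
    sm <- summary(fit)
    ct <- as.data.frame(sm$coefficients)
    names(ct) <- c("estimate", "std.error", "t.value", "p.value")
    ct <- ct[, c("estimate", "std.error", "t.value", "p.value")]
    ct$df <- fit$df.residual
    ct <- ct[, c("estimate", "std.error", "df", "t.value", "p.value")]
    singular <- FALSE
    sigma_id <- NA_real_
    sigma_resid <- sm$sigma
  }
  ll <- stats::logLik(fit)
  structure(list(fit = fit, spec = spec, method = method,
                 coef_table = ct,
                 logLik = as.numeric(ll), k = attr(ll, "df"),
                 AIC = 2 * attr(ll, "df") - 2 * as.numeric(ll),
                 n = stats::nobs(fit),
                 sigma_id = sigma_id, sigma_resid = sigma_resid,
                 singular = singular,
                 df_method = if (spec$random_id) "Satterthwaite" else "residual"),
            class = "cs_model_fit")
}

#' @export
print.cs_model_fit <- function(x, digits = 4, ...) {
  cat("model: delta ~", .spec_label(x$spec), " [", x$method, "]\n")
  cat("n =", x$n, " k =", x$k, " logLik =", round(x$logLik, 3),
      " AIC =", round(x$AIC, 3), "\n")
  if (x$singular) cat("NOTE: boundary (singular) random-effect fit\n")
  print(round(x$coef_table, digits))
  invisible(x)
}

.n_interactions <- function(spec) length(spec$interactions)

#' Compare candidate models by maximum-likelihood AIC
#'
#' Computes delta-AIC against the best candidate and applies the 2-unit
#' equivalence rule: all models within 2 AIC units of the minimum are
#' treated as equivalent and the simplest of them is chosen. Ties break
#' deterministically: fewest parameters, then fewest interaction terms,
#' then the model without a random term before the one with.
#'
#' @param fits List of `cs_model_fit` objects, all fitted by ML on the same
#'   observations.
#' @return Object of class `cs_model_comparison`: list with `table`
#'   (candidate, k, logLik, AIC, dAIC, equivalent, chosen), `chosen` (index)
#'   and `fits`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1, all(vapply(fits, inherits, TRUE, "cs_model_fit")))
  if (any(vapply(fits, function(f) f$method, "") != "ML")) {
    stop("model comparison requires ML fits (mixed ML/REML input)")
  }
  if (length(unique(vapply(fits, function(f) f$n, 0))) != 1) {
    stop("candidates are not fitted to the same number of observations")
  }
  aic <- vapply(fits, function(f) f$AIC, 0)
  k <- vapply(fits, function(f) f$k, 0)
  dAIC <- aic - min(aic)
  equivalent <- dAIC < 2
  nia <- vapply(fits, function(f) .n_interactions(f$spec), 0)
  rand <- vapply(fits, function(f) f$spec$random_id, TRUE)
  cand <- which(equivalent)
  ord <- order(k[cand], nia[cand], rand[cand], cand)
  chosen <- cand[ord[1]]
  tab <- data.frame(
    candidate = vapply(fits, function(f) .spec_label(f$spec), ""),
    k = k,
    logLik = vapply(fits, function(f) f$logLik, 0),
    AIC = aic, dAIC = dAIC, equivalent = equivalent,
    chosen = seq_along(fits) == chosen)
  structure(list(table = tab, chosen = chosen, fits = fits),
            class = "cs_model_comparison")
}

#' @export
print.cs_model_comparison <- function(x, digits = 3, ...) {
  tab <- x$table
  tab$logLik <- round(tab$logLik, digits)
  tab$AIC <- round(tab$AIC, digits)
  tab$dAIC <- round(tab$dAIC, digits)
  print(tab)
  cat("chosen:", x$table$candidate[x$chosen],
      "(within-2 equivalence, simplest preferred)\n")
  invisible(x)
}

# fixed terms currently removable under marginality: main effects not
# contained in any retained interaction; interactions not contained in a
# higher-order retained interaction
.removable_terms <- function(spec) {
  terms <- c(spec$fixed, spec$interactions)
  contained <- function(t1, t2) {
    p1 <- strsplit(t1, ":", fixed = TRUE)[[1]]
    p2 <- strsplit(t2, ":", fixed = TRUE)[[1]]
    length(p2) > length(p1) && all(p1 %in% p2)
  }
  keep <- vapply(terms, function(t) !any(vapply(terms, function(o) contained(t, o), TRUE)), TRUE)
  terms[keep]
}

.drop_term <- function(spec, term) {
  model_spec(spec$response,
             fixed = setdiff(spec$fixed, term),
             interactions = setdiff(spec$interactions, term),
             random_id = spec$random_id)
}

#' Backward model simplification by AIC
#'
#' Repeatedly drops the removable fixed term whose removal lowers the ML
#' AIC the most, respecting marginality (a main effect is never dropped
#' while an interaction containing it remains), and stops when no removal
#' lowers the AIC. The final model is refit by REML for reporting; both
#' fits and the full elimination path are returned.
#'
#' @param fit A `cs_model_fit` fitted by ML (a REML fit is refit by ML
#'   first).
#' @param data The shift table the fit was estimated on.
#' @return Object of class `cs_simplification`: list with `final` (ML fit),
#'   `final_reml` (REML refit), and `path` (data frame of steps: dropped
#'   term and AIC before/after).
#' @export
simplify_model <- function(fit, data) {
  stopifnot(inherits(fit, "cs_model_fit"))
  cur <- if (fit$method != "ML") fit_model(data, fit$spec, "ML") else fit
  path <- data.frame(step = integer(), dropped = character(),
                     AIC_before = numeric(), AIC_after = numeric())
  step <- 0L
  repeat {
    cand_terms <- .removable_terms(cur$spec)
    if (!length(cand_terms)) break
    trials <- lapply(cand_terms, function(tm) {
      fit_model(data, .drop_term(cur$spec, tm), "ML")
    })
    aics <- vapply(trials, function(f) f$AIC, 0)
    best <- which.min(aics)
    if (aics[best] >= cur$AIC) break
    step <- step + 1L
    path <- rbind(path, data.frame(step = step, dropped = cand_terms[best],
                                   AIC_before = cur$AIC, AIC_after = aics[best]))
    cur <- trials[[best]]
  }
  structure(list(final = cur,
                 final_reml = if (cur$spec$random_id) fit_model(data, cur$spec, "REML") else cur,
                 path = path),
            class = "cs_simplification")
}

#' @export
print.cs_simplification <- function(x, ...) {
  if (nrow(x$path)) {
    cat("elimination path:\n"); print(x$path)
  } else cat("no term removal lowered the AIC\n")
  cat("final model: delta ~", .spec_label(x$final$spec), "\n")
  invisible(x)
}

#' Likelihood-ratio test for the individual random intercept
#'
#' Compares ML fits of two specs that are identical except for the random
#' intercept. The statistic is `2 * (logLik_full - logLik_reduced)`; the
#' degrees of freedom are reported as the difference in parameter counts.
#' The boundary nature of a variance test makes the resulting p-value
#' conservative.
#'
#' @param data Shift table.
#' @param spec_with Spec including the random intercept.
#' @param spec_without Same spec without it.
#' @return Object of class `cs_ranef_test`: list with `chisq`, `df`,
#'   `p.value` and the two fits.
#' @export
test_random_effect <- function(data, spec_with, spec_without) {
  stopifnot(inherits(spec_with, "cs_model_spec"),
            inherits(spec_without, "cs_model_spec"))
  same_fixed <- identical(spec_with$fixed, spec_without$fixed) &&
    identical(spec_with$interactions, spec_without$interactions) &&
    identical(spec_with$response, spec_without$response)
  if (!same_fixed || !spec_with$random_id || spec_without$random_id) {
    stop("specs must be identical apart from the random intercept")
  }
  full <- fit_model(data, spec_with, "ML")
  reduced <- fit_model(data, spec_without, "ML")
  chisq <- 2 * (full$logLik - reduced$logLik)
  if (chisq < -1e-6) {
    stop("full model log-likelihood below reduced model: convergence failure")
  }
  chisq <- max(chisq, 0)
  df <- as.integer(full$k - reduced$k)
  structure(list(chisq = chisq, df = df,
                 p.value = stats::pchisq(chisq, df, lower.tail = FALSE),
                 full = full, reduced = reduced),
            class = "cs_ranef_test")
}

#' @export
print.cs_ranef_test <- function(x, ...) {
  cat(sprintf("random-intercept LRT: chisq = %.3f, d.f. = %d, p = %.4g\n",
              x$chisq, x$df, x$p.value))
  invisible(x)
}

#' Estimated marginal means and pairwise post hoc comparisons
#'
#' Marginal means of the factor's levels averaged over the other model
#' terms, with all pairwise differences and Tukey-adjusted p-values (the
#' classic least-squares-means workflow).
#'
#' @param fit A `cs_model_fit`.
#' @param factor Name of a factor in the fitted model (e.g. `"treatment"`).
#' @param adjust Multiplicity adjustment, default `"tukey"`.
#' @return Object of class `cs_posthoc`: list with `means` (level, emmean,
#'   SE, df) and `pairs` (contrast, estimate, SE, df, t.ratio, p.value).
#' @export
posthoc_means <- function(fit, factor, adjust = "tukey") {
  stopifnot(inherits(fit, "cs_model_fit"))
  if (!factor %in% fit$spec$fixed) {
    stop("factor ", factor, " is not a term of the fitted model")
  }
  # pass the model frame explicitly: fits are created inside fit_model, so
  # emmeans cannot recover the data from the calling environment
  frame <- if (fit$spec$random_id) fit$fit@frame else fit$fit$model
  emm <- emmeans::emmeans(fit$fit, stats::as.formula(paste("~", factor)),
                          data = frame)
  prs <- emmeans::contrast(emm, method = "pairwise", adjust = adjust)
  structure(list(means = as.data.frame(emm),
                 pairs = as.data.frame(prs),
                 factor = factor, adjust = adjust),
            class = "cs_posthoc")
}

#' @export
print.cs_posthoc <- function(x, digits = 4, ...) {
  cat("estimated marginal means of", x$factor, "\n")
  print(x$means, digits = digits)
  cat("pairwise comparisons (", x$adjust, "-adjusted):\n", sep = "")
  print(x$pairs, digits = digits)
  invisible(x)
}

#' The default candidate-model ladder
#'
#' Four candidates per response: additive fixed effects and the full
#' interaction structure, each with and without the individual random
#' intercept.
#'
#' @param response Attribute to model.
#' @param fixed Main effects (default line, treatment and interval-end
#'   hour).
#' @return List of four [model_spec()] objects.
#' @export
candidate_ladder <- function(response = "L",
                             fixed = c("line", "treatment", "time_h")) {
  full_ia <- c(utils::combn(fixed, 2, paste, collapse = ":"),
               if (length(fixed) >= 3) utils::combn(fixed, 3, paste, collapse = ":"))
  list(
    model_spec(response, fixed, character(), random_id = TRUE),
    model_spec(response, fixed, full_ia, random_id = TRUE),
    model_spec(response, fixed, character(), random_id = FALSE),
    model_spec(response, fixed, full_ia, random_id = FALSE)
  )
}
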