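#' @importFrom lme4 lmer glmer fixef VarCorr isSingular glmerControl lmerControl
NULL

# Normalize a condition column to the 0/1 coding (narrow = 0, wide = 1).
condition_code <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  as.numeric(x == "wide")
}

# Assemble a model_result from a fitted (g)lmer model.
# For lmerTest fits, Satterthwaite df drive the p-values and CIs; otherwise
# a Wald normal approximation is used and flagged in `df_method`.
model_result <- function(fit, singular_terms = character(0), note = NULL,
                         extra = list()) {
  sm <- summary(fit)
  co <- as.data.frame(sm$coefficients)
  est <- co[, "Estimate"]; se <- co[, "Std. Error"]
  if ("df" %in% names(co)) {          # lmerTest / Satterthwaite
    df <- co[, "df"]; p <- co[, "Pr(>|t|)"]
    crit <- stats::qt(0.975, df)
    df_method <- "satterthwaite"
  } else {
    df <- rep(Inf, nrow(co))
    z <- est / se
    p <- stats::pchisq(z^2, 1, lower.tail = FALSE)   # Wald chi-square
    crit <- rep(stats::qnorm(0.975), nrow(co))
    df_method <- "wald"
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  nm <- ifelse(is.na(vc$var1) | vc$var1 == "(Intercept)", vc$grp,
               paste(vc$grp, vc$var1, sep = "."))
  nm[!is.na(vc$var2)] <- paste(vc$grp, "cov", sep = ".")[!is.na(vc$var2)]
  vcomp <- stats::setNames(vc$vcov, nm)
  conv <- length(fit@optinfo$conv$lme4$messages %||% character(0)) == 0
  structure(c(list(
    coefficients = data.frame(term = rownames(co), estimate = est, se = se,
                              df = df, ci_lo = est - crit * se,
                              ci_hi = est + crit * se, p = p,
                              row.names = NULL, stringsAsFactors = FALSE),
    variance_components = vcomp,
    converged = conv,
    singular = lme4::isSingular(fit),
    singular_terms = singular_terms,
    df_method = df_method,
    n_obs = stats::nobs(fit),
    note = note,
    fit = fit), extra),
    class = "model_result")
}

#' @export
print.model_result <- function(x, ...) {
  cat(sprintf("<model_result> n = %d, df method: %s%s%s\n", x$n_obs,
              x$df_method,
              if (!x$converged) " [NOT CONVERGED]" else "",
              if (length(x$singular_terms))
                paste0(" [singular: ", paste(x$singular_terms, collapse = ","), "]")
              else ""))
  print(x$coefficients, digits = 4)
  if (length(x$variance_components)) {
    cat("variance components:\n")
    print(round(x$variance_components, 5))
  }
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Trial-level ERP amplitude mixed model
#'
#' Fits `amplitude ~ condition + (condition | participant) + (1 | channel)`
#' by REML with the condition coded narrow = 0, wide = 1, Satterthwaite
#' degrees of freedom for the two-tailed condition p-value. When the
#' channel variance estimates to zero (a singular fit), the channel term is
#' dropped, the refit is returned and `"channel"` is recorded in
#' `singular_terms`.
#'
#' @param trial_amplitudes long table with columns `amplitude_uv`,
#'   `condition`, `participant`, `channel`.
#' @return a `model_result`.
#' @export
fit_lmm_amplitude <- function(trial_amplitudes) {
  d <- trial_amplitudes
  if (length(unique(d$participant)) < 2) stop_fmt("need >= 2 participants")
  if (length(unique(d$channel)) < 2) stop_fmt("need >= 2 channels")
  if (length(unique(d$condition)) < 2) stop_fmt("both conditions required")
  d$cond <- condition_code(d$condition)
  full <- suppressMessages(suppressWarnings(
    lmerTest::lmer(amplitude_uv ~ cond + (cond | participant) + (1 | channel),
                   data = d, REML = TRUE)))
  vc <- as.data.frame(lme4::VarCorr(full))
  ch_var <- vc$vcov[vc$grp == "channel"][1]
  tot <- stats::var(d$amplitude_uv)
  if (is.na(ch_var) || ch_var <= 1e-6 * tot) {
    refit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(amplitude_uv ~ cond + (cond | participant),
                     data = d, REML = TRUE)))
    return(model_result(refit, singular_terms = "channel",
                        note = "channel variance estimated at 0; term dropped"))
  }
  model_result(full)
}

#' Participant-level GFP mixed model
#'
#' Fits `GFP ~ condition + (1 | participant)` by REML (condition coded
#' narrow = 0, wide = 1), Satterthwaite p-values.
#'
#' @param gfp_table data.frame with `gfp`, `condition`, `participant`.
#' @return a `model_result`.
#' @export
fit_lmm_gfp <- function(gfp_table) {
  d <- gfp_table
  if (length(unique(d$participant)) < 2)
    stop_fmt("need >= 2 participants to identify the grouping variance")
  d$cond <- condition_code(d$condition)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(gfp ~ cond + (1 | participant), data = d, REML = TRUE)))
  model_result(fit)
}

#' Intraclass correlations from an intercept-only mixed model
#'
#' Fits `response ~ 1 + (1|g)` for every grouping factor simultaneously and
#' returns each factor's share of the total variance (grouping variances
#' plus residual); the proportions sum to one.
#'
#' @param table data.frame.
#' @param response response column name.
#' @param groupings character vector of grouping column names.
#' @return list of class `icc_result`: per-grouping proportions and
#'   `residual`.
#' @export
icc <- function(table, response, groupings) {
  miss <- setdiff(c(response, groupings), names(table))
  if (length(miss)) stop_fmt("columns not in table: %s", paste(miss, collapse = ", "))
  fml <- stats::as.formula(paste(
    response, "~ 1 +", paste(sprintf("(1 | %s)", groupings), collapse = " + ")))
  fit <- suppressMessages(suppressWarnings(lme4::lmer(fml, data = table)))
  vc <- as.data.frame(lme4::VarCorr(fit))
  tot <- sum(vc$vcov)
  out <- stats::setNames(as.list(vc$vcov / tot),
                         ifelse(vc$grp == "Residual", "residual", vc$grp))
  structure(out, class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat("<icc_result>\n")
  for (nm in names(x)) cat(sprintf("  %s: %.3f\n", nm, x[[nm]]))
  invisible(x)
}

#' Hit-rate GLMM (binomial, logit link)
#'
#' Fits `hit ~ condition + (condition | participant)` with a binomial
#' family and logit link (Laplace approximation); the condition contrast is
#' evaluated with a Wald chi-square test. Complete separation (all hits or
#' all misses in a condition) falls back to an adjusted empirical-logit
#' estimate with a warning, reported as not converged.
#'
#' @param trial_hits data.frame with `is_hit` (logical or 0/1),
#'   `condition`, `participant`.
#' @return a `model_result` with an additional `wald` element
#'   (`chisq`, `p`) for the condition effect.
#' @export
fit_glmm_hit <- function(trial_hits) {
  d <- trial_hits
  d$hit <- as.numeric(d$is_hit)
  d$cond <- condition_code(d$condition)
  by_cond <- tapply(d$hit, d$cond, mean)
  if (any(by_cond %in% c(0, 1))) {
    warning("complete separation in hit rates; reporting adjusted empirical-logit estimates",
            call. = FALSE)
    n <- tapply(d$hit, d$cond, length); k <- tapply(d$hit, d$cond, sum)
    el <- stats::qlogis((k + 0.5) / (n + 1))
    se <- sqrt(1 / (k + 0.5) + 1 / (n - k + 0.5))
    est <- c(el[["0"]], el[["1"]] - el[["0"]])
    se2 <- c(se[["0"]], sqrt(sum(se^2)))
    z <- est / se2
    res <- list(coefficients = data.frame(
      term = c("(Intercept)", "cond"), estimate = est, se = se2,
      df = Inf, ci_lo = est - 1.96 * se2, ci_hi = est + 1.96 * se2,
      p = stats::pchisq(z^2, 1, lower.tail = FALSE), row.names = NULL),
      variance_components = numeric(0), converged = FALSE, singular = FALSE,
      singular_terms = character(0), df_method = "wald", n_obs = nrow(d),
      note = "separation fallback",
      wald = list(chisq = z[2]^2,
                  p = stats::pchisq(z[2]^2, 1, lower.tail = FALSE)))
    return(structure(res, class = "model_result"))
  }
  fit <- suppressMessages(suppressWarnings(
    lme4::glmer(hit ~ cond + (cond | participant), data = d,
                family = stats::binomial("logit"),
                control = lme4::glmerControl(calc.derivs = FALSE))))
  res <- model_result(fit)
  b <- res$coefficients
  i <- match("cond", b$term)
  chisq <- (b$estimate[i] / b$se[i])^2
  res$wald <- list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
  res
}

#' Reaction-time GLMM (inverse Gaussian)
#'
#' Fits `RT ~ condition + (condition | participant)` with an
#' inverse-Gaussian family and the inverse link (Laplace approximation),
#' matching the positive skew of reaction times; the condition contrast is
#' evaluated by Wald chi-square. Estimated condition means on the response
#' scale (`1 / eta`) are returned in `response_means`.
#'
#' @param hit_rts data.frame with `rt_s` (> 0, hits only), `condition`,
#'   `participant`.
#' @return a `model_result` with `wald` and `response_means`.
#' @export
fit_glmm_rt <- function(hit_rts) {
  d <- hit_rts
  if (any(!is.finite(d$rt_s)) || any(d$rt_s <= 0))
    stop_fmt("reaction times must be strictly positive")
  d$cond <- condition_code(d$condition)
  fit <- tryCatch(suppressMessages(suppressWarnings(
    lme4::glmer(rt_s ~ cond + (cond | participant), data = d,
                family = stats::inverse.gaussian("inverse"),
                control = lme4::glmerControl(calc.derivs = FALSE)))),
    error = function(e) NULL)
  simplified <- FALSE
  if (is.null(fit)) {
    fit <- suppressMessages(suppressWarnings(
      lme4::glmer(rt_s ~ cond + (1 | participant), data = d,
                  family = stats::inverse.gaussian("inverse"),
                  control = lme4::glmerControl(calc.derivs = FALSE))))
    simplified <- TRUE
  }
  res <- model_result(fit, note = if (simplified)
    "random slope dropped (did not fit); random intercept only" else NULL)
  b <- res$coefficients
  i <- match("cond", b$term)
  chisq <- (b$estimate[i] / b$se[i])^2
  res$wald <- list(chisq = chisq, p = stats::pchisq(chisq, 1, lower.tail = FALSE))
  eta <- c(narrow = b$estimate[1], wide = b$estimate[1] + b$estimate[i])
  res$response_means <- 1 / eta
  res
}

#' Per-participant score mixed model (paired design)
#'
#' Fits `score ~ condition + (1 | participant)` for a one-score-per-
#' participant-per-condition design; on balanced data the condition
#' estimate equals the mean paired difference. Missing cells are handled by
#' the likelihood and noted.
#'
#' @param scores data.frame with `score`, `condition`, `participant`.
#' @return a `model_result`.
#' @export
fit_score_lmm <- function(scores) {
  d <- scores
  if (length(unique(d$participant)) < 2) stop_fmt("need >= 2 participants")
  d$cond <- condition_code(d$condition)
  unbalanced <- any(table(d$participant) != 2)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(score ~ cond + (1 | participant), data = d, REML = TRUE)))
  model_result(fit, note = if (unbalanced)
    "unbalanced design: some participants miss a condition" else NULL)
}

#' Sensitivity re-analysis of the TRF window contrasts
#'
#' Re-runs the per-window GFP contrast with a stated modification:
#' excluding participants and/or replacing each participant's individual
#' FWHM window by the fixed group (significant) window. With no exclusions
#' and individual windows the result is identical to the base analysis.
#'
#' @param trf_stage output of [trf_group_stage()].
#' @param exclude_participants participant ids to drop.
#' @param fixed_windows use the group significant windows for everyone.
#' @return list with the recomputed `gfp_table` and per-window
#'   `model_result`s (`fits`).
#' @export
sensitivity_rerun <- function(trf_stage, exclude_participants = character(0),
                              fixed_windows = FALSE) {
  gt <- build_gfp_table(trf_stage, fixed_windows = fixed_windows,
                        exclude = exclude_participants)
  fits <- lapply(split(gt, gt$window), function(dw)
    fit_lmm_gfp(dw))
  list(gfp_table = gt, fits = fits,
       fixed_windows = fixed_windows,
       excluded = exclude_participants)
}

#' Tidy coefficient table across fitted models
#'
#' @param results named list of `model_result`s.
#' @return data.frame (model, term, estimate, se, ci_lo, ci_hi, p, n_obs).
#' @export
tidy_results <- function(results) {
  do.call(rbind, lapply(names(results), function(nm) {
    co <- results[[nm]]$coefficients
    data.frame(model = nm, co[, c("term", "estimate", "se", "ci_lo",
                                  "ci_hi", "p")],
               n_obs = results[[nm]]$n_obs, row.names = NULL)
  }))
}
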