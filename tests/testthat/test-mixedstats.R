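# Small simulated designs for the mixed models; all effects known.
sim_amp_table <- function(n_p = 10, n_tr = 12, n_ch = 4, b = 2,
                          sd_u = 1, sd_e = 3, seed = 1) {
  set.seed(seed)
  d <- expand.grid(participant = sprintf("p%02d", seq_len(n_p)),
                   trial = seq_len(n_tr),
                   channel = paste0("ch", seq_len(n_ch)),
                   condition = c("narrow", "wide"),
                   stringsAsFactors = FALSE)
  u0 <- rnorm(n_p, 0, sd_u); u1 <- rnorm(n_p, 0, sd_u / 2)
  i <- as.integer(factor(d$participant))
  d$amplitude_uv <- 1 + b * (d$condition == "wide") + u0[i] +
    u1[i] * (d$condition == "wide") + rnorm(nrow(d), 0, sd_e)
  d
}

test_that("the trial-level amplitude LMM recovers the injected effect and drops a zero-variance channel term", {
  d <- sim_amp_table(b = 2, seed = 4)
  fit <- quiet(fit_lmm_amplitude(d))
  co <- fit$coefficients
  est <- co$estimate[co$term == "cond"]
  se <- co$se[co$term == "cond"]
  expect_lt(abs(est - 2), 3 * se)
  expect_equal(fit$df_method, "satterthwaite")
  # zero channel variance (by construction) is detected and the term dropped
  expect_true("channel" %in% fit$singular_terms)
  # a real channel effect keeps the term
  d2 <- d
  d2$amplitude_uv <- d2$amplitude_uv +
    3 * (as.integer(factor(d2$channel)) - 2.5)
  fit2 <- quiet(fit_lmm_amplitude(d2))
  expect_length(fit2$singular_terms, 0)
  expect_gt(fit2$variance_components[["channel"]], 0.5)
  expect_error(fit_lmm_amplitude(d[d$participant == "p01", ]), "participants")
})

test_that("recoding the condition flips coefficient signs only", {
  d <- sim_amp_table(b = 1.5, seed = 3)
  f1 <- quiet(fit_lmm_amplitude(d))
  d2 <- d
  d2$condition <- ifelse(d$condition == "wide", "narrow", "wide")
  f2 <- quiet(fit_lmm_amplitude(d2))
  c1 <- f1$coefficients$estimate[f1$coefficients$term == "cond"]
  c2 <- f2$coefficients$estimate[f2$coefficients$term == "cond"]
  expect_equal(c2, -c1, tolerance = 1e-6)
  # same for the GFP model
  g <- data.frame(participant = rep(sprintf("p%d", 1:12), 2),
                  condition = rep(c("narrow", "wide"), each = 12),
                  gfp = rnorm(24, 5) + 0.8 * rep(c(0, 1), each = 12))
  g2 <- g; g2$condition <- ifelse(g$condition == "wide", "narrow", "wide")
  e1 <- fit_lmm_gfp(g)$coefficients
  e2 <- fit_lmm_gfp(g2)$coefficients
  expect_equal(e2$estimate[e2$term == "cond"],
               -e1$estimate[e1$term == "cond"], tolerance = 1e-6)
})

test_that("the GFP model needs two participants and recovers a known difference", {
  set.seed(4)
  n_p <- 30
  g <- data.frame(participant = rep(sprintf("p%d", 1:n_p), 2),
                  condition = rep(c("narrow", "wide"), each = n_p))
  u <- rnorm(n_p, 0, 1)
  g$gfp <- 5.5 + 0.8 * (g$condition == "wide") +
    u[as.integer(factor(g$participant))] + rnorm(2 * n_p, 0, 0.5)
  fit <- fit_lmm_gfp(g)
  co <- fit$coefficients
  expect_lt(abs(co$estimate[co$term == "cond"] - 0.8),
            3 * co$se[co$term == "cond"])
  expect_true(co$ci_lo[2] < co$estimate[2] & co$estimate[2] < co$ci_hi[2])
  expect_error(fit_lmm_gfp(g[g$participant == "p1", ]), "participants")
})

test_that("ICC proportions sum to one, vanish without grouping variance, and resist rescaling", {
  set.seed(5)
  n_p <- 50; n_t <- 100
  d <- expand.grid(participant = sprintf("p%02d", 1:n_p), t = 1:n_t)
  # no between-participant variance
  d$y <- rnorm(nrow(d))
  i0 <- icc(d, "y", "participant")
  expect_lt(i0$participant, 0.03)
  expect_equal(i0$participant + i0$residual, 1, tolerance = 1e-9)
  # var_participant = var_residual = 1 -> ICC ~ 0.5
  u <- rnorm(n_p, 0, 1)
  d$y <- u[as.integer(factor(d$participant))] + rnorm(nrow(d), 0, 1)
  i1 <- icc(d, "y", "participant")
  expect_lt(abs(i1$participant - 0.5), 0.05)
  # invariant to rescaling the response
  d$y10 <- d$y * 10
  i10 <- icc(d, "y10", "participant")
  expect_equal(i10$participant, i1$participant, tolerance = 1e-6)
  expect_error(icc(d, "nope", "participant"), "columns")
})

test_that("the binomial hit GLMM recovers the sign of the injected condition effect", {
  set.seed(6)
  sim_hits <- function(p_n, p_w, n_p = 20, n_t = 48, seed = 1) {
    set.seed(seed)
    d <- expand.grid(participant = sprintf("p%02d", 1:n_p), trial = 1:n_t,
                     condition = c("narrow", "wide"), stringsAsFactors = FALSE)
    u <- rnorm(n_p, 0, 0.5)
    eta <- qlogis(ifelse(d$condition == "wide", p_w, p_n)) +
      u[as.integer(factor(d$participant))]
    d$is_hit <- runif(nrow(d)) < plogis(eta)
    d
  }
  signs <- sapply(1:10, function(s) {
    f <- quiet(fit_glmm_hit(sim_hits(0.95, 0.70, seed = s)))
    co <- f$coefficients
    c(co$estimate[co$term == "cond"], f$wald$p)
  })
  expect_true(all(signs[1, ] < 0))
  expect_true(all(signs[2, ] < 0.05))
  # all hits: separation fallback with warning, finite estimates
  dsep <- sim_hits(0.95, 0.70, seed = 1)
  dsep$is_hit <- TRUE
  expect_warning(fsep <- fit_glmm_hit(dsep), "separation")
  expect_true(all(is.finite(fsep$coefficients$estimate)))
  expect_false(fsep$converged)
})

test_that("the inverse-Gaussian RT GLMM recovers response-scale means and rejects bad input", {
  set.seed(7)
  n_p <- 20; n_t <- 40
  d <- expand.grid(participant = sprintf("p%02d", 1:n_p), trial = 1:n_t,
                   condition = c("narrow", "wide"), stringsAsFactors = FALSE)
  u <- rnorm(n_p, 0, 0.05)
  mu <- ifelse(d$condition == "wide", 1.0, 0.8) *
    exp(u[as.integer(factor(d$participant))])
  d$rt_s <- attnscape:::rinvgauss(nrow(d), mu, 4)
  fit <- quiet(fit_glmm_rt(d))
  expect_equal(unname(fit$response_means[["narrow"]]), 0.8, tolerance = 0.04)
  expect_equal(unname(fit$response_means[["wide"]]), 1.0, tolerance = 0.05)
  expect_lt(fit$wald$p, 0.05)
  # identical conditions: effect near zero
  d0 <- d
  d0$rt_s <- attnscape:::rinvgauss(nrow(d0), 0.9, 4)
  f0 <- quiet(fit_glmm_rt(d0))
  co <- f0$coefficients
  expect_lt(abs(co$estimate[co$term == "cond"]),
            3 * co$se[co$term == "cond"])
  d$rt_s[1] <- -0.1
  expect_error(fit_glmm_rt(d), "positive")
})

test_that("the paired score model equals the mean paired difference on balanced data", {
  set.seed(8)
  n_p <- 15
  d <- data.frame(participant = rep(sprintf("p%02d", 1:n_p), 2),
                  condition = rep(c("narrow", "wide"), each = n_p))
  u <- rnorm(n_p, 60, 10)
  d$score <- u[as.integer(factor(d$participant))] +
    ifelse(d$condition == "wide", 10.85, 0) + rnorm(2 * n_p, 0, 7)
  fit <- quiet(fit_score_lmm(d))
  wide <- d$score[d$condition == "wide"]
  narrow <- d$score[d$condition == "narrow"]
  expect_equal(fit$coefficients$estimate[fit$coefficients$term == "cond"],
               mean(wide - narrow), tolerance = 1e-6)
  # paired differences all equal d -> estimate exactly d
  d2 <- d
  d2$score <- u[as.integer(factor(d2$participant))] +
    ifelse(d2$condition == "wide", 3.3, 0)
  f2 <- quiet(fit_score_lmm(d2))
  expect_equal(f2$coefficients$estimate[f2$coefficients$term == "cond"], 3.3,
               tolerance = 1e-6)
  # a missing cell is handled and noted
  d3 <- d[-1, ]
  f3 <- quiet(fit_score_lmm(d3))
  expect_match(f3$note, "unbalanced")
})
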