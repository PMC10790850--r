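#' Simulate key-press behavior for a schedule
#'
#' Each target is detected independently with the condition's hit
#' probability; detected targets receive a reaction time drawn from an
#' inverse-Gaussian distribution, truncated to (0, `hit_window_s`), and a
#' response onset `onset + RT`. Non-targets never receive responses.
#'
#' @param schedule event table with `is_target` flags.
#' @param truth a [ground_truth()].
#' @param seed integer seed.
#' @param hit_window_s truncation bound for reaction times (s).
#' @param participant optional per-participant realization
#'   (`participant_truth`); shifts the hit logit and scales the RT mean.
#' @return the schedule with `is_hit` (targets only; NA elsewhere) and
#'   `response_onset_s` filled in.
#' @export
simulate_behavior <- function(schedule, truth, seed = NULL,
                              hit_window_s = 3, participant = NULL) {
  ev <- schedule
  ev$is_hit <- NA
  ev$response_onset_s <- NA_real_
  tgt <- which(ev$is_target)
  if (!length(tgt)) return(ev)
  cond <- ev$condition[1]
  pt <- participant %||% list(hit_logit_shift = 0, rt_mu_scale = 1)
  p <- truth$hit_prob[[cond]]
  p <- stats::plogis(stats::qlogis(min(max(p, 1e-6), 1 - 1e-6)) +
                       pt$hit_logit_shift)
  if (truth$hit_prob[[cond]] %in% c(0, 1)) p <- truth$hit_prob[[cond]]
  mu <- truth$rt_mu_s[[cond]] * pt$rt_mu_scale
  lam <- truth$rt_lambda_s[[cond]]
  with_seed(seed, {
    hit <- stats::runif(length(tgt)) < p
    ev$is_hit[tgt] <- hit
    nh <- sum(hit)
    if (nh) {
      rt <- rinvgauss(nh, mu, lam)
      bad <- rt <= 0 | rt >= hit_window_s
      while (any(bad)) {             # truncate by rejection
        rt[bad] <- rinvgauss(sum(bad), mu, lam)
        bad <- rt <= 0 | rt >= hit_window_s
      }
      ev$response_onset_s[tgt[hit]] <- ev$onset_s[tgt[hit]] + rt
    }
    ev
  })
}

# Simulate the per-condition questionnaire/behavioral scores of one
# participant (workload, completed layers, followed instructions).
simulate_scores <- function(truth, participant_id, seed = NULL) {
  with_seed(seed, {
    out <- lapply(names(truth$scores), function(sc) {
      p <- truth$scores[[sc]]
      u <- stats::rnorm(1, 0, p[["sd_participant"]])
      data.frame(participant = participant_id,
                 condition = c("narrow", "wide"),
                 score_name = sc,
                 score = c(p[["narrow"]], p[["wide"]]) + u +
                   stats::rnorm(2, 0, p[["sd_resid"]]),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
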