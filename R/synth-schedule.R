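# Run code with a locally-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Default per-category stimulus durations (s) and azimuths (deg).
# Durations/intensities of the source material are design choices of the
# generator (long, loud alarm; short, quiet beep).
stimulus_params <- function() {
  data.frame(
    category = EVENT_CATEGORIES,
    duration_s = c(0.8, 0.15, 0.4, 0.3, 1.2),
    direction_deg = c(45, NA, -90, -90, 0),  # beep varies
    stringsAsFactors = FALSE
  )
}

#' Generate a soundscape stimulus schedule
#'
#' Lays out the five discrete stimulus streams (alarm, beep, two irrelevant
#' sounds, spoken instruction) of one experimental run. Each category is
#' first scheduled `n_per_category` times in a random interleaved order with
#' inter-onset intervals drawn uniformly from `soa_range_s`. The beep can be
#' embedded into (co-onset with) another stimulus, in which case both events
#' are flagged `overlap = TRUE`; every event that became overlapped is then
#' re-added at the end of the run so that each category ends up with exactly
#' `n_per_category` non-overlapping presentations.
#'
#' The target flag follows the condition: the alarm is the target under a
#' narrow attentional focus, the beep under a wide one.
#'
#' @param n_per_category presentations per category that must remain
#'   non-overlapping (0 allowed).
#' @param soa_range_s (min, max) inter-onset interval between consecutive
#'   scheduled events, seconds.
#' @param condition `"narrow"` or `"wide"`.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @param p_embed probability that a beep is embedded into another stimulus.
#' @param t_start_s onset of the first event.
#' @return event data.frame (see [validate_events()]) with an extra
#'   `duration_s` column.
#' @export
make_schedule <- function(n_per_category = 48, soa_range_s = c(3, 6),
                          condition = c("narrow", "wide"), seed = NULL,
                          p_embed = 0.5, t_start_s = 5) {
  condition <- match.arg(condition)
  if (n_per_category < 0) stop_fmt("n_per_category must be >= 0")
  if (length(soa_range_s) != 2 || any(soa_range_s <= 0) ||
      soa_range_s[1] > soa_range_s[2])
    stop_fmt("soa_range_s must be a positive (min, max) pair")
  pars <- stimulus_params()
  if (soa_range_s[1] <= max(pars$duration_s))
    stop_fmt("scheduling infeasible: minimum SOA %.3g s does not clear the longest stimulus (%.3g s)",
             soa_range_s[1], max(pars$duration_s))
  if (n_per_category == 0) return(empty_events())

  with_seed(seed, {
    cats <- sample(rep(EVENT_CATEGORIES, n_per_category))
    embed <- cats == "beep" & stats::runif(length(cats)) < p_embed
    # place the main chain (standalone events) sequentially
    chain <- which(!embed)
    onset <- numeric(length(cats))
    t <- t_start_s
    for (i in chain) {
      onset[i] <- t
      t <- t + stats::runif(1, soa_range_s[1], soa_range_s[2])
    }
    overlap <- logical(length(cats))
    # embed each flagged beep into a random standalone non-beep host
    hosts <- which(!embed & cats != "beep")
    if (any(embed)) {
      pick <- sample(hosts, sum(embed))
      onset[embed] <- onset[pick]
      overlap[embed] <- TRUE
      overlap[pick] <- TRUE
    }
    ev <- data.frame(onset_s = onset, category = cats, overlap = overlap,
                     stringsAsFactors = FALSE)
    # re-add overlapped events until each category has n non-overlapping
    deficit <- vapply(EVENT_CATEGORIES, function(cc)
      n_per_category - sum(ev$category == cc & !ev$overlap), numeric(1))
    extra <- sample(rep(EVENT_CATEGORIES, pmax(0, deficit)))
    for (cc in extra) {
      ev <- rbind(ev, data.frame(onset_s = t, category = cc, overlap = FALSE,
                                 stringsAsFactors = FALSE))
      t <- t + stats::runif(1, soa_range_s[1], soa_range_s[2])
    }
    ev <- ev[order(ev$onset_s), , drop = FALSE]
    rownames(ev) <- NULL
    ev$condition <- condition
    dirs <- pars$direction_deg[match(ev$category, pars$category)]
    # the beep comes from wherever its host (or any) stream is
    is_beep <- ev$category == "beep"
    dirs[is_beep & ev$overlap] <- vapply(which(is_beep & ev$overlap), function(i) {
      host <- which(abs(ev$onset_s - ev$onset_s[i]) < 1e-9 & !is_beep)
      if (length(host)) dirs[host[1]] else 0
    }, numeric(1))
    dirs[is_beep & !ev$overlap] <- sample(c(-135, -90, 0, 45),
                                          sum(is_beep & !ev$overlap),
                                          replace = TRUE)
    ev$direction_deg <- dirs
    ev$duration_s <- pars$duration_s[match(ev$category, pars$category)]
    ev$is_target <- (ev$category == "alarm" & condition == "narrow") |
      (ev$category == "beep" & condition == "wide")
    validate_events(ev)
    ev
  })
}
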