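#' Workflow simulator configuration
#'
#' Parameterises a semi-Markov generator of sacrocolpopexy-like procedures.
#' Default per-phase duration statistics (mean, sd, in seconds) are the
#' clinical values for the five phases: promontory preparation (633, 365),
#' dissection of vault and gutter (3097, 1212), mesh fixation to vault
#' (3888, 879), mesh fixation to promontory (211, 157), peritonealisation
#' (1073, 548). Durations are normal draws floored at
#' `max(30, mean - 2*sd)` seconds (the floor guarantees positive durations
#' without biasing the sample mean appreciably). Phases run in order 1..5, except that
#' peritonealisation may start before mesh fixation to promontory with
#' probability `p_phase5_before_4` (the phase-order variant observed
#' clinically). Transitions between phases are uniform on
#' `transition_range_s`; each phase may pause once (probability `p_pause`)
#' for a uniform `transition_range_s` interval. Non-phase time before the
#' first and after the last phase is uniform on `nonphase_range_s`.
#'
#' @param phase_mean_s,phase_sd_s Numeric length-5 vectors of per-phase
#'   duration means and standard deviations in seconds.
#' @param transition_range_s Length-2 range (seconds) for inter-phase
#'   transitions and pause lengths.
#' @param nonphase_range_s Length-2 range (seconds) for non-phase head and
#'   tail spans.
#' @param p_phase5_before_4 Probability that phase 5 precedes phase 4.
#' @param p_pause Per-phase probability of a single pause.
#' @param fps Downsampled frame rate used downstream (default 2.4).
#' @param seed Integer seed; the simulator is deterministic given the seed.
#' @return A list of class `workflow_sim_config`.
#' @export
workflow_sim_config <- function(phase_mean_s = c(633, 3097, 3888, 211, 1073),
                                phase_sd_s = c(365, 1212, 879, 157, 548),
                                transition_range_s = c(10, 120),
                                nonphase_range_s = c(30, 120),
                                p_phase5_before_4 = 0, p_pause = 0.2,
                                fps = 2.4, seed = 1L) {
  stopifnot(length(phase_mean_s) == 5L, length(phase_sd_s) == 5L)
  if (any(phase_mean_s <= 0)) abort("phase means must be > 0")
  if (any(phase_sd_s < 0)) abort("phase sds must be >= 0")
  for (p in c(p_phase5_before_4, p_pause)) {
    if (p < 0 || p > 1) abort("probabilities must be in [0, 1]")
  }
  stopifnot(length(transition_range_s) == 2L,
            transition_range_s[1L] <= transition_range_s[2L],
            transition_range_s[1L] >= 0)
  structure(list(phase_mean_s = phase_mean_s, phase_sd_s = phase_sd_s,
                 transition_range_s = transition_range_s,
                 nonphase_range_s = nonphase_range_s,
                 p_phase5_before_4 = p_phase5_before_4, p_pause = p_pause,
                 fps = fps, seed = as.integer(seed)),
            class = "workflow_sim_config")
}

#' Simulate one surgical workflow
#'
#' Draws phase durations, transition lengths and optional pauses from the
#' configured distributions and assembles them into a timestamped
#' [phase_annotation()]. Each of the five phases occurs exactly once; a
#' pause freezes the phase (the drawn duration is the *active* duration,
#' and the pause inserts extra wall-clock time).
#'
#' @param cfg A [workflow_sim_config()].
#' @return A [phase_annotation()].
#' @export
simulate_workflow <- function(cfg = workflow_sim_config()) {
  stopifnot(inherits(cfg, "workflow_sim_config"))
  set.seed(cfg$seed)
  order <- if (runif(1) < cfg$p_phase5_before_4) c(1L, 2L, 3L, 5L, 4L) else 1:5
  durations <- vapply(1:5, function(p) {
    floor_s <- max(30, cfg$phase_mean_s[p] - 2 * cfg$phase_sd_s[p])
    rnorm_floored(1L, cfg$phase_mean_s[p], cfg$phase_sd_s[p], floor_s)
  }, numeric(1L))
  transitions <- runif(4L, cfg$transition_range_s[1L], cfg$transition_range_s[2L])
  head_s <- runif(1L, cfg$nonphase_range_s[1L], cfg$nonphase_range_s[2L])
  tail_s <- runif(1L, cfg$nonphase_range_s[1L], cfg$nonphase_range_s[2L])
  rows <- list()
  t <- head_s
  for (k in seq_along(order)) {
    p <- order[k]
    dur <- durations[p]
    add <- function(event, time) {
      rows[[length(rows) + 1L]] <<- tibble::tibble(phase_id = p, event = event,
                                                   time_s = time)
    }
    add("start", t)
    if (runif(1) < cfg$p_pause) {
      frac <- runif(1, 0.1, 0.9)
      pause_len <- runif(1, cfg$transition_range_s[1L], cfg$transition_range_s[2L])
      add("pause", t + frac * dur)
      add("resume", t + frac * dur + pause_len)
      t <- t + dur + pause_len
    } else {
      t <- t + dur
    }
    add("end", t)
    if (k < length(order)) t <- t + transitions[k]
  }
  phase_annotation(dplyr::bind_rows(rows), video_duration_s = t + tail_s,
                   fps_native = 24)
}

#' Active phase durations of an annotation
#'
#' Sums the unpaused spans of each phase, in seconds.
#'
#' @param ann A [phase_annotation()].
#' @return A named numeric vector (one element per phase present).
#' @export
phase_durations <- function(ann) {
  spans <- phase_spans(ann)
  vapply(spans, function(s) sum(s$active[, 2L] - s$active[, 1L]), numeric(1L))
}
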