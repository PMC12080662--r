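#' Experience-sampling design
#'
#' Describes the prompt schedule of an ecological momentary assessment (EMA)
#' protocol: a number of study days, a fixed number of prompts per day placed
#' pseudo-randomly inside a daily time window with a minimum spacing, and an
#' optional one-time postponement of each prompt by a small number of minutes.
#' The defaults reproduce a 7-day protocol with 8 prompts per day between
#' 08:00 and 22:00, at least 25 minutes apart, each postponable once by 5, 10
#' or 15 minutes.
#'
#' @param n_days number of study days.
#' @param prompts_per_day prompts delivered per day.
#' @param window_start,window_end daily prompt window, minutes from midnight.
#' @param min_spacing minimum gap between consecutive prompts, minutes.
#' @param postpone_options admissible postponement delays, minutes.
#' @param postpone_max maximum number of postponements per prompt.
#' @return an object of class `ema_design`.
#' @examples
#' d <- ema_design()
#' s <- build_schedule(d, seed = 1)
#' nrow(s) # 56 prompts
#' @export
ema_design <- function(n_days = 7L, prompts_per_day = 8L,
                       window_start = 480, window_end = 1320,
                       min_spacing = 25, postpone_options = c(5, 10, 15),
                       postpone_max = 1L) {
  stopifnot(n_days >= 1, prompts_per_day >= 1, min_spacing > 0,
            window_start >= 0, window_end <= 1440, postpone_max >= 0,
            all(postpone_options > 0))
  if (window_end <= window_start)
    stop("window_end must be later than window_start", call. = FALSE)
  if (prompts_per_day * min_spacing >= (window_end - window_start))
    stop("infeasible design: cannot place ", prompts_per_day,
         " prompts with spacing ", min_spacing, " min in a ",
         window_end - window_start, " min window", call. = FALSE)
  structure(list(n_days = as.integer(n_days),
                 prompts_per_day = as.integer(prompts_per_day),
                 window_start = window_start, window_end = window_end,
                 min_spacing = min_spacing,
                 postpone_options = postpone_options,
                 postpone_max = as.integer(postpone_max)),
            class = "ema_design")
}

#' Uniform time grid
#'
#' The analysis grid onto which irregular EMA observations are aligned:
#' `slots_per_day` equal intervals per 24-hour day (default one per hour),
#' anchored at midnight of day 0 for every person.  The grid covers the whole
#' day, so overnight slots are structurally missing; gaps are handled by the
#' model through the decay of autoregressive effects across empty slots.
#'
#' @param n_days number of days spanned by the grid.
#' @param slots_per_day intervals per day (default 24, i.e. hourly).
#' @return an object of class `grid_spec` with elements `n_days`,
#'   `slots_per_day`, `n_slots` and `slot_width` (minutes).
#' @export
grid_spec <- function(n_days = 7L, slots_per_day = 24L) {
  stopifnot(n_days >= 1, slots_per_day >= 1, slots_per_day <= 1440)
  structure(list(n_days = as.integer(n_days),
                 slots_per_day = as.integer(slots_per_day),
                 n_slots = as.integer(n_days * slots_per_day),
                 slot_width = 1440 / slots_per_day),
            class = "grid_spec")
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate a prompt schedule
#'
#' Places `prompts_per_day` prompt times per day uniformly at random inside
#' the design window subject to the minimum-spacing constraint, using the gap
#' construction (draw unconstrained points in a shortened window, sort, then
#' re-insert the mandatory gaps), which samples uniformly from the constrained
#' region.  All prompts start out marked as answered.
#'
#' @param design an [ema_design()].
#' @param seed integer seed; the schedule is deterministic given the seed.
#' @return a data.frame with columns `day` (0-based), `time` (minutes from
#'   midnight, fractional), `answered` (logical) and `postponed` (integer).
#' @export
build_schedule <- function(design, seed = NULL) {
  stopifnot(inherits(design, "ema_design"))
  p <- design$prompts_per_day
  L <- design$window_end - design$window_start
  s <- design$min_spacing
  if ((p - 1) * s > L)
    stop("infeasible design: cannot place ", p, " prompts with spacing ", s,
         " min in a ", L, " min window", call. = FALSE)
  with_seed(seed, {
    times <- lapply(seq_len(design$n_days), function(d) {
      u <- sort(stats::runif(p, 0, L - (p - 1) * s))
      design$window_start + u + (seq_len(p) - 1) * s
    })
    data.frame(day = rep(seq_len(design$n_days) - 1L, each = p),
               time = unlist(times),
               answered = TRUE, postponed = 0L)
  })
}

#' Postpone prompts
#'
#' Each prompt still below the design's postponement limit is independently
#' postponed with probability `postpone_prob` by a delay drawn uniformly from
#' the design's postponement options.  Postponed times may exceed the daily
#' window end by at most the largest option; prompt order is preserved.
#'
#' @param schedule a schedule from [build_schedule()].
#' @param design the [ema_design()] the schedule came from.
#' @param postpone_prob probability that a prompt is postponed.
#' @param seed integer seed.
#' @return the schedule with updated `time` and `postponed` columns.
#' @export
apply_postponement <- function(schedule, design = ema_design(),
                               postpone_prob = 0.1, seed = NULL) {
  stopifnot(postpone_prob >= 0, postpone_prob <= 1)
  if (postpone_prob == 0) return(schedule)
  with_seed(seed, {
    eligible <- schedule$postponed < design$postpone_max
    hit <- eligible & stats::runif(nrow(schedule)) < postpone_prob
    delay <- design$postpone_options[sample.int(length(design$postpone_options),
                                                sum(hit), replace = TRUE)]
    schedule$time[hit] <- schedule$time[hit] + delay
    schedule$postponed[hit] <- schedule$postponed[hit] + 1L
    schedule
  })
}

#' Thin a schedule by adherence
#'
#' Marks each prompt as answered independently with probability `adherence`,
#' emulating incomplete compliance.  Zero adherence is rejected: a person
#' without answered prompts carries no dynamic information (the analysis
#' likewise excludes persons with fewer than two observations).
#'
#' @param schedule a prompt schedule.
#' @param adherence probability in (0, 1] that a prompt is answered.
#' @param seed integer seed.
#' @return the schedule with the `answered` column updated.
#' @export
apply_adherence <- function(schedule, adherence, seed = NULL) {
  if (length(adherence) != 1 || is.na(adherence) || adherence <= 0 ||
      adherence > 1)
    stop("adherence must be a single probability in (0, 1]", call. = FALSE)
  if (adherence == 1) {
    schedule$answered <- TRUE
    return(schedule)
  }
  with_seed(seed, {
    schedule$answered <- stats::runif(nrow(schedule)) < adherence
    schedule
  })
}

#' Align timestamped observations to the uniform grid
#'
#' Assigns each observation to the slot `floor(minutes_from_origin /
#' slot_width)` (left-closed hourly bins anchored at midnight of day 0; a time
#' exactly on a boundary belongs to the later slot).  Slots without an
#' observation are filled with `NA`.  When two observations fall into the same
#' slot the earlier one is kept and the later dropped with a warning.
#'
#' @param obs a data.frame with columns `day` (0-based), `time` (minutes from
#'   midnight) and one or more value columns.
#' @param grid a [grid_spec()].
#' @return a data.frame with `slot` running 0 to `n_slots - 1` and the value
#'   columns, `NA` in empty slots.  The number of dropped collisions is
#'   attached as attribute `"n_collisions"`.
#' @export
align_to_grid <- function(obs, grid = grid_spec()) {
  stopifnot(inherits(grid, "grid_spec"),
            all(c("day", "time") %in% names(obs)))
  vals <- setdiff(names(obs), c("day", "time", "answered", "postponed",
                                "person_id"))
  minutes <- obs$day * 1440 + obs$time
  slot <- floor(minutes / grid$slot_width)
  bad <- which(slot < 0 | slot >= grid$n_slots | !is.finite(minutes))
  if (length(bad))
    stop("observations outside the grid span at rows: ",
         paste(utils::head(bad, 10), collapse = ", "), call. = FALSE)
  ord <- order(minutes)
  slot <- slot[ord]
  keep <- !duplicated(slot)
  n_coll <- sum(!keep)
  if (n_coll > 0)
    warning(n_coll, " observation(s) dropped: same grid slot as an earlier ",
            "observation (earliest kept)", call. = FALSE)
  out <- data.frame(slot = seq_len(grid$n_slots) - 1L)
  for (v in vals) {
    col <- rep(NA_real_, grid$n_slots)
    col[slot[keep] + 1L] <- obs[[v]][ord][keep]
    out[[v]] <- col
  }
  attr(out, "n_collisions") <- n_coll
  attr(out, "grid") <- grid
  out
}
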