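#' One step of the deterministic aggregate backlog recursion
#'
#' The weekly aggregate method: at each step the number served is
#' `min(waiting + arrivals, capacity)`, the backlog carries the remainder,
#' and the expected additional wait for the backlog is its size divided by
#' capacity. With zero capacity and a positive queue the wait is the
#' sentinel `Inf` (flagged, never a silent division).
#'
#' @param waiting backlog size entering the step (>= 0).
#' @param arrivals,capacity non-negative counts/rates for the step.
#' @return list with `served`, `waiting` (next backlog) and
#'   `expected_wait_steps`.
#' @examples
#' step_queue_deterministic(20, 10, 10) # served 10, waiting 20, wait 2
#' @export
step_queue_deterministic <- function(waiting, arrivals, capacity) {
  if (waiting < 0 || arrivals < 0 || capacity < 0)
    stop("waiting, arrivals and capacity must be non-negative")
  served <- min(waiting + arrivals, capacity)
  nxt <- waiting + arrivals - served
  wait <- if (capacity > 0) nxt / capacity else if (nxt > 0) Inf else 0
  list(served = served, waiting = nxt, expected_wait_steps = wait)
}

new_delay_distribution <- function(tab, steps, procedure_type,
                                   timestep_weeks) {
  data.table::setattr(tab, "class",
                      c("delay_distribution", class(tab)))
  data.table::setattr(tab, "steps", steps)
  data.table::setattr(tab, "procedure_type", procedure_type)
  data.table::setattr(tab, "timestep_weeks", timestep_weeks)
  tab
}

#' Deterministic aggregate backlog engine
#'
#' Runs the [step_queue_deterministic()] recursion over a whole horizon and
#' attributes to every patient arriving at step `t` the expected additional
#' wait of the backlog at that step, in weeks. This is the desk
#' calculation used for the Australian pathway (weekly backlog size /
#' capacity); it is also the analytic oracle against which the stochastic
#' agent engine is checked.
#'
#' @param arrivals integer arrivals per timestep.
#' @param capacity a `capacity_series` or a numeric capacity-per-step
#'   vector of the same length as `arrivals`.
#' @param timestep_weeks weeks per step when `capacity` is a bare vector.
#' @return a `delay_distribution`: data.table (`patient_id`,
#'   `arrival_step`, `service_step` = NA, `additional_wait_weeks`,
#'   `drained` = FALSE) with a per-step summary in `attr(, "steps")`.
#' @export
simulate_aggregate_queue <- function(arrivals, capacity,
                                     timestep_weeks = 1L) {
  cap <- capacity_vector(capacity, length(arrivals))
  if (inherits(capacity, "capacity_series"))
    timestep_weeks <- capacity$timestep_weeks
  nT <- length(arrivals)
  waiting <- 0
  wait_steps <- numeric(nT)
  served <- numeric(nT)
  backlog <- numeric(nT)
  for (t in seq_len(nT)) {
    st <- step_queue_deterministic(waiting, arrivals[t], cap[t])
    waiting <- st$waiting
    served[t] <- st$served
    backlog[t] <- st$waiting
    wait_steps[t] <- st$expected_wait_steps
  }
  steps <- data.table::data.table(step = seq_len(nT) - 1L,
                                  arrivals = as.numeric(arrivals),
                                  capacity = cap, served = served,
                                  waiting = backlog,
                                  expected_wait_steps = wait_steps)
  arr_step <- rep(seq_len(nT) - 1L, arrivals)
  tab <- data.table::data.table(
    patient_id = seq_along(arr_step),
    arrival_step = arr_step,
    service_step = NA_integer_,
    additional_wait_weeks = wait_steps[arr_step + 1L] * timestep_weeks,
    drained = FALSE)
  pt <- if (inherits(capacity, "capacity_series"))
    capacity$procedure_type else "unspecified"
  new_delay_distribution(tab, steps, pt, timestep_weeks)
}

#' Stochastic agent-based backlog engine
#'
#' The 2-week-timestep agent queue of the Canadian pathway: every patient
#' on the backlog is, at each step, served independently with probability
#' `min(1, capacity_t / waiting_t)` (random service discipline; FIFO is
#' available for sensitivity). Unserved patients carry over; each patient's
#' additional wait is `(service step - arrival step) * timestep_weeks`.
#' Patients still queued at the horizon are served in a drain phase at the
#' final step's capacity and flagged `drained` so they can be excluded in
#' sensitivity analyses.
#'
#' @inheritParams simulate_aggregate_queue
#' @param seed integer RNG seed.
#' @param discipline `"random"` (default) or `"fifo"`.
#' @param max_drain_steps safety bound on the drain phase.
#' @return a `delay_distribution` (see [simulate_aggregate_queue()]), with
#'   `service_step` filled and conservation summary in `attr(, "steps")`.
#' @export
simulate_agent_queue <- function(arrivals, capacity, seed,
                                 timestep_weeks = 2L,
                                 discipline = c("random", "fifo"),
                                 max_drain_steps = 100000L) {
  discipline <- match.arg(discipline)
  cap <- capacity_vector(capacity, length(arrivals))
  if (inherits(capacity, "capacity_series"))
    timestep_weeks <- capacity$timestep_weeks
  nT <- length(arrivals)
  set.seed(as.integer(seed))
  pool_arrival <- integer(0)
  pool_id <- integer(0)
  next_id <- 1L
  n_total <- sum(arrivals)
  res_arrival <- integer(n_total)
  res_service <- integer(n_total)
  served_per_step <- numeric(nT)
  waiting_per_step <- numeric(nT)

  serve_step <- function(t, cap_t) {
    nw <- length(pool_arrival)
    if (nw == 0L) return(integer(0))
    if (discipline == "random") {
      p <- min(1, cap_t / nw)
      which(stats::runif(nw) < p)
    } else {
      k <- floor(cap_t) + stats::rbinom(1L, 1L, cap_t - floor(cap_t))
      if (k >= nw) seq_len(nw) else order(pool_arrival)[seq_len(min(k, nw))]
    }
  }
  record <- function(sel, t) {
    res_arrival[pool_id[sel]] <<- pool_arrival[sel]
    res_service[pool_id[sel]] <<- t
    pool_arrival <<- pool_arrival[-sel]
    pool_id <<- pool_id[-sel]
  }

  for (t in seq_len(nT)) {
    a <- arrivals[t]
    if (a > 0L) {
      pool_arrival <- c(pool_arrival, rep(t - 1L, a))
      pool_id <- c(pool_id, seq.int(next_id, next_id + a - 1L))
      next_id <- next_id + a
    }
    sel <- serve_step(t, cap[t])
    served_per_step[t] <- length(sel)
    if (length(sel) > 0L) record(sel, t - 1L)
    waiting_per_step[t] <- length(pool_arrival)
  }
  horizon_served <- n_total - length(pool_arrival)

  # drain phase: keep serving at the final capacity until the queue clears
  drained_ids <- pool_id
  drain_cap <- cap[nT]
  if (length(pool_arrival) > 0L && drain_cap <= 0)
    stop("cannot drain backlog: final capacity is zero")
  t <- nT
  while (length(pool_arrival) > 0L) {
    t <- t + 1L
    if (t - nT > max_drain_steps) stop("drain phase exceeded safety bound")
    sel <- serve_step(t, drain_cap)
    if (length(sel) > 0L) record(sel, t - 1L)
  }

  tab <- data.table::data.table(
    patient_id = seq_len(n_total),
    arrival_step = res_arrival,
    service_step = res_service,
    additional_wait_weeks =
      (res_service - res_arrival) * timestep_weeks,
    drained = seq_len(n_total) %in% drained_ids)
  steps <- data.table::data.table(step = seq_len(nT) - 1L,
                                  arrivals = as.numeric(arrivals),
                                  capacity = cap,
                                  served = served_per_step,
                                  waiting = waiting_per_step)
  data.table::setattr(tab, "horizon_served", horizon_served)
  pt <- if (inherits(capacity, "capacity_series"))
    capacity$procedure_type else "unspecified"
  new_delay_distribution(tab, steps, pt, timestep_weeks)
}

capacity_vector <- function(capacity, n) {
  cap <- if (inherits(capacity, "capacity_series")) capacity$capacity
  else as.numeric(capacity)
  if (length(cap) != n)
    stop("arrivals and capacity series must have the same length (",
         n, " vs ", length(cap), ")")
  if (any(cap < 0)) stop("negative capacity")
  cap
}

#' Fraction of patients with at least a given additional wait
#'
#' The published summaries report the proportion of patients who waited at
#' least two weeks longer than pre-pandemic expected waits; the threshold
#' is inclusive.
#'
#' @param delays a `delay_distribution`.
#' @param threshold_weeks inclusive threshold, default 2.
#' @return fraction in [0, 1].
#' @export
proportion_with_additional_wait <- function(delays, threshold_weeks = 2) {
  stopifnot(inherits(delays, "delay_distribution"))
  if (nrow(delays) == 0L) stop("empty delay distribution")
  mean(delays$additional_wait_weeks >= threshold_weeks)
}

#' Write a delay distribution to CSV
#'
#' @param delays a `delay_distribution`.
#' @param path output file.
#' @export
write_delay_distribution <- function(delays, path) {
  stopifnot(inherits(delays, "delay_distribution"))
  data.table::fwrite(delays, path)
  invisible(path)
}
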