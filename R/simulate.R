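#' Kinetic scheme for stepwise nucleosome sliding
#'
#' Parameterizes one round of the sliding mechanism: an optional distinct
#' step (rate `extra_rate`), `n_steps` sequential 1-bp DNA translocations
#' from the entry side (each an exponential wait at `rate`), and a
#' concerted, instantaneous ejection of `n_eject` bp of DNA from the exit
#' side.  Rounds repeat `n_rounds` times.  With probability
#' `reversal_prob` a round is followed by a reversal that restores
#' `reversal_bp` bp at the exit side (a phenomenological knob; no mechanism
#' is asserted).
#'
#' @param n_steps integer `>= 1`, translocations per round.
#' @param rate rate of each translocation step (s^-1).
#' @param extra_rate rate of the distinct step (s^-1) or `NULL` to disable.
#' @param extra_position `"before_round"` (default) or `"after_round"`;
#'   the pause-time distribution is invariant to this choice because a sum
#'   of independent exponentials does not depend on their order.
#' @param n_eject base pairs expelled per concerted ejection.
#' @param n_rounds number of rounds to simulate.
#' @param reversal_prob per-round probability of a reversal event.
#' @param reversal_bp base pairs restored per reversal.
#' @return An object of class `kinetic_scheme`.
#' @export
kinetic_scheme <- function(n_steps = 6, rate = 0.1, extra_rate = NULL,
                           extra_position = c("before_round", "after_round"),
                           n_eject = 5, n_rounds = 1,
                           reversal_prob = 0, reversal_bp = n_eject) {
  extra_position <- match.arg(extra_position)
  if (!is.numeric(n_steps) || n_steps < 1 || n_steps != round(n_steps)) {
    stop_remkin("domain_error", "n_steps must be an integer >= 1")
  }
  if (!is.numeric(rate) || rate <= 0) {
    stop_remkin("domain_error", "rate must be positive")
  }
  if (!is.null(extra_rate) && (!is.numeric(extra_rate) || extra_rate <= 0)) {
    stop_remkin("domain_error", "extra_rate must be NULL or positive")
  }
  if (!is.numeric(n_eject) || n_eject < 1 || n_eject != round(n_eject)) {
    stop_remkin("domain_error", "n_eject must be an integer >= 1")
  }
  if (!is.numeric(n_rounds) || n_rounds < 1 || n_rounds != round(n_rounds)) {
    stop_remkin("domain_error", "n_rounds must be an integer >= 1")
  }
  if (!is.numeric(reversal_prob) || reversal_prob < 0 || reversal_prob > 1) {
    stop_remkin("domain_error", "reversal_prob must be in [0, 1]")
  }
  if (!is.numeric(reversal_bp) || reversal_bp < 0) {
    stop_remkin("domain_error", "reversal_bp must be >= 0")
  }
  structure(
    list(n_steps = as.integer(n_steps), rate = rate, extra_rate = extra_rate,
         extra_position = extra_position, n_eject = as.integer(n_eject),
         n_rounds = as.integer(n_rounds), reversal_prob = reversal_prob,
         reversal_bp = as.integer(reversal_bp)),
    class = "kinetic_scheme"
  )
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat(sprintf(
    "<kinetic_scheme> N = %d at k = %.3g s^-1%s; eject %d bp x %d round(s)%s\n",
    x$n_steps, x$rate,
    if (!is.null(x$extra_rate))
      sprintf(" + distinct step at k_X = %.3g s^-1 (%s)", x$extra_rate,
              x$extra_position) else "",
    x$n_eject, x$n_rounds,
    if (x$reversal_prob > 0)
      sprintf("; reversal p = %.2g (%d bp)", x$reversal_prob, x$reversal_bp)
    else ""))
  invisible(x)
}

# instantaneous events (ejection, reversal) are recorded this long after
# the waiting time that triggered them, so event times stay strictly
# increasing; 1 ns is far below the 0.2-s frame time of any trace.
EVENT_EPS <- 1e-9

#' Simulate a single sliding trajectory
#'
#' Event-driven simulation of a [kinetic_scheme]: per round, draw the
#' optional distinct-step wait and the `n_steps` translocation waits, then
#' eject `n_eject` bp instantaneously.  Simulation stops after `n_rounds`
#' rounds or at `max_time`, whichever comes first.
#'
#' @param scheme a [kinetic_scheme].
#' @param max_time time horizon in seconds (events after it are discarded
#'   and the trajectory is flagged truncated).
#' @param seed optional integer seed.
#' @param molecule_id identifier stored on the trajectory.
#' @return An object of class `trajectory`: `events` (data frame with
#'   `time_s`, `kind` in extra_step/translocation/ejection/reversal, and
#'   `exit_bp_after`, the cumulative bp expelled at the exit side),
#'   `end_time`, `truncated`, `molecule_id`, and the generating `scheme`.
#' @export
simulate_trajectory <- function(scheme, max_time = Inf, seed = NULL,
                                molecule_id = "mol_1") {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  if (!is.numeric(max_time) || max_time <= 0) {
    stop_remkin("domain_error", "max_time must be positive")
  }
  R <- scheme$n_rounds
  N <- scheme$n_steps
  ev <- with_seed_(seed, {
    trans <- matrix(stats::rexp(R * N, scheme$rate), nrow = R)
    extra <- if (!is.null(scheme$extra_rate))
      stats::rexp(R, scheme$extra_rate) else NULL
    revs <- if (scheme$reversal_prob > 0)
      stats::runif(R) < scheme$reversal_prob else rep(FALSE, R)
    list(trans = trans, extra = extra, revs = revs)
  })

  round_dur <- rowSums(ev$trans) +
    if (!is.null(ev$extra)) ev$extra else 0
  rev_u <- if (any(ev$revs)) with_seed_(child_seed(seed, 999), {
    stats::runif(R)
  }) else numeric(R)

  times <- numeric(0); kinds <- character(0); dbp <- numeric(0)
  t_now <- 0
  for (r in seq_len(R)) {
    waits <- ev$trans[r, ]
    kinds_r <- rep("translocation", N)
    if (!is.null(ev$extra)) {
      if (scheme$extra_position == "before_round") {
        waits <- c(ev$extra[r], waits)
        kinds_r <- c("extra_step", kinds_r)
      } else {
        waits <- c(waits, ev$extra[r])
        kinds_r <- c(kinds_r, "extra_step")
      }
    }
    tt <- t_now + cumsum(waits)
    t_end <- tt[length(tt)]
    # concerted ejection immediately after the last wait of the round
    tt <- c(tt, t_end + EVENT_EPS)
    kinds_r <- c(kinds_r, "ejection")
    dd <- c(rep(0, length(waits)), scheme$n_eject)
    if (ev$revs[r]) {
      # a reversal lands at a uniform random time within the following
      # round (so it is observable between ejections); after the final
      # round it follows the ejection immediately
      t_rev <- if (r < R) t_end + rev_u[r] * round_dur[r + 1L]
               else t_end + 2 * EVENT_EPS
      tt <- c(tt, t_rev)
      kinds_r <- c(kinds_r, "reversal")
      dd <- c(dd, -scheme$reversal_bp)
    }
    times <- c(times, tt); kinds <- c(kinds, kinds_r); dbp <- c(dbp, dd)
    t_now <- t_end + 2 * EVENT_EPS
    if (t_now > max_time) break
  }

  ord <- order(times)
  times <- times[ord]; kinds <- kinds[ord]; dbp <- dbp[ord]
  exit_bp <- cumsum(dbp)
  # a reversal cannot restore more bp than have been ejected
  if (any(exit_bp < 0)) {
    for (i in seq_along(exit_bp)) {
      prev <- if (i == 1L) 0 else exit_bp[i - 1L]
      if (dbp[i] < 0 && prev + dbp[i] < 0) dbp[i] <- -prev
      exit_bp[i] <- prev + dbp[i]
    }
  }

  keep <- times <= max_time
  events <- data.frame(time_s = times[keep], kind = kinds[keep],
                       exit_bp_after = exit_bp[keep],
                       stringsAsFactors = FALSE)
  truncated <- any(!keep) || t_now > max_time
  end_time <- if (truncated) max_time
              else if (nrow(events)) events$time_s[nrow(events)] else 0
  structure(
    list(molecule_id = molecule_id, events = events,
         end_time = end_time, truncated = truncated, scheme = scheme),
    class = "trajectory"
  )
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf(
    "<trajectory> %s: %d events, %d ejection(s), final exit_bp = %d, end at %.3g s%s\n",
    x$molecule_id, nrow(x$events), sum(x$events$kind == "ejection"),
    if (nrow(x$events)) as.integer(x$events$exit_bp_after[nrow(x$events)]) else 0L,
    x$end_time, if (x$truncated) " (truncated)" else ""))
  invisible(x)
}

#' Cumulative exit-side bp expelled at time t
#'
#' Step function of the trajectory's `exit_bp_after` record.
#'
#' @param traj a [simulate_trajectory] result.
#' @param t times (s) at which to evaluate.
#' @return Integer bp values, same length as `t`.
#' @export
exit_bp_at <- function(traj, t) {
  stopifnot(inherits(traj, "trajectory"))
  changes <- traj$events[traj$events$kind %in% c("ejection", "reversal"), ,
                         drop = FALSE]
  if (!nrow(changes)) return(rep(0L, length(t)))
  idx <- findInterval(t, changes$time_s)
  as.integer(c(0, changes$exit_bp_after)[idx + 1L])
}

#' Extract pause times from a trajectory
#'
#' Pauses are the intervals between consecutive concerted ejections; the
#' first pause runs from the trajectory start (the remodeller is taken to
#' be already bound at t = 0).  If the trajectory was truncated after the
#' last ejection, the trailing incomplete interval is included as a
#' censored value; a trajectory with no ejection yields a single censored
#' interval covering its whole duration.
#'
#' @param traj a [simulate_trajectory] result.
#' @return A [dwell_times] object.
#' @export
pause_times_from_trajectory <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  ej <- traj$events$time_s[traj$events$kind == "ejection"]
  if (!length(ej)) {
    if (traj$end_time <= 0) {
      return(dwell_times(numeric(0), condition = traj$molecule_id))
    }
    return(dwell_times(traj$end_time, censored = TRUE,
                       condition = traj$molecule_id))
  }
  values <- diff(c(0, ej))
  censored <- rep(FALSE, length(values))
  if (traj$truncated && traj$end_time > ej[length(ej)]) {
    values <- c(values, traj$end_time - ej[length(ej)])
    censored <- c(censored, TRUE)
  }
  dwell_times(values, censored = censored, condition = traj$molecule_id)
}

#' Pause times pooled over many simulated trajectories
#'
#' Convenience wrapper: simulates `n` independent trajectories and pools
#' their pause times.
#'
#' @inheritParams simulate_trajectory
#' @param n number of molecules.
#' @param seed top-level seed; per-molecule child streams are derived
#'   deterministically.
#' @return A [dwell_times] object.
#' @export
simulate_pause_times <- function(scheme, n, max_time = Inf, seed = NULL) {
  vals <- numeric(0); cens <- logical(0)
  for (i in seq_len(n)) {
    traj <- simulate_trajectory(scheme, max_time = max_time,
                                seed = child_seed(seed, i),
                                molecule_id = sprintf("mol_%d", i))
    p <- pause_times_from_trajectory(traj)
    vals <- c(vals, p$values); cens <- c(cens, p$censored)
  }
  dwell_times(vals, censored = cens, condition = "simulated")
}

#' Read/write trajectory event logs
#'
#' Tab-delimited text with columns `molecule_id`, `time_s`, `event_kind`,
#' `exit_bp_after`.
#'
#' @param trajs a `trajectory` or list of them.
#' @param path file path.
#' @export
write_trajectory_events <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  rows <- lapply(trajs, function(tr) {
    if (!nrow(tr$events)) return(NULL)
    data.frame(molecule_id = tr$molecule_id, time_s = tr$events$time_s,
               event_kind = tr$events$kind,
               exit_bp_after = tr$events$exit_bp_after,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(molecule_id = character(0), time_s = numeric(0),
                     event_kind = character(0), exit_bp_after = numeric(0))
  }
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_events
#' @return `read_trajectory_events` returns the event log as a data frame.
#' @export
read_trajectory_events <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("molecule_id", "time_s", "event_kind", "exit_bp_after")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_remkin("format_error",
                paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  df
}
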