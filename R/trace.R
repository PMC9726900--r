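#' FRET efficiency from two channels
#'
#' Proximity ratio E = acceptor / (acceptor + donor), uncorrected for
#' crosstalk or detection efficiency.  Frames with nonpositive total
#' intensity are flagged invalid (`NA`).
#'
#' @param donor,acceptor equal-length intensity series, or a [fret_trace]
#'   as the first argument.
#' @return Numeric efficiency series with `NA` at invalid frames.
#' @export
compute_fret <- function(donor, acceptor = NULL) {
  if (inherits(donor, "fret_trace")) {
    acceptor <- donor$acceptor
    donor <- donor$donor
  }
  if (length(donor) != length(acceptor)) {
    stop_remkin("domain_error", "donor and acceptor must have equal length")
  }
  total <- donor + acceptor
  e <- ifelse(total > 0, acceptor / total, NA_real_)
  if (all(is.na(e))) {
    stop_remkin("unusable_trace", "no frame has positive total intensity")
  }
  e
}

# ---- change-point machinery -----------------------------------------------

# best single split of y into two constant segments (squared-error cost);
# returns NULL if y is too short, else list(pos = first index of the right
# segment, gain = cost reduction).  Vectorized over all admissible splits.
best_split <- function(y, min_size) {
  n <- length(y)
  if (n < 2L * min_size) return(NULL)
  cs <- cumsum(y); cs2 <- cumsum(y^2)
  s <- min_size:(n - min_size)             # candidate left-segment lengths
  sse_left <- cs2[s] - cs[s]^2 / s
  nr <- n - s
  sse_right <- (cs2[n] - cs2[s]) - (cs[n] - cs[s])^2 / nr
  gain <- (cs2[n] - cs[n]^2 / n) - (sse_left + sse_right)
  k <- which.max(gain)
  list(pos = s[k] + 1L, gain = gain[k])
}

# recursive binary segmentation: returns sorted change points (first index
# of each new segment, in 1-based coordinates of y)
binseg <- function(y, min_size, penalty) {
  sp <- best_split(y, min_size)
  if (is.null(sp) || sp$gain <= penalty) return(integer(0))
  left <- y[seq_len(sp$pos - 1L)]
  right <- y[sp$pos:length(y)]
  c(binseg(left, min_size, penalty),
    sp$pos,
    binseg(right, min_size, penalty) + sp$pos - 1L)
}

#' Segment a FRET trace into constant levels
#'
#' Piecewise-constant fit of the efficiency series by penalized
#' binary-segmentation minimization of squared error.  The penalty scales
#' with a per-trace noise estimate (median absolute deviation of first
#' differences), so clean and noisy traces are handled with the same
#' default.  The analysis window ends at the acceptor bleach frame when a
#' single bleach step is detected.
#'
#' @param trace a [fret_trace].
#' @param penalty cost-reduction threshold for accepting a split; default
#'   `8 * sigma^2 * log(n)` with sigma estimated by MAD.
#' @param min_size minimum segment length in frames (suppresses shot-noise
#'   segments).
#' @param end_frame last frame of the analysis window; default: frame
#'   before the acceptor bleach if exactly one bleach step is detected,
#'   else the full trace.
#' @param max_changepoints more change points than this triggers a
#'   suspicious-trace warning.
#' @return An object of class `state_segments`: `change_points` (frame
#'   index where each new level starts), `levels` (mean E per segment),
#'   `window_end`, `frame_rate`.
#' @export
segment_trace <- function(trace, penalty = NULL, min_size = 3,
                          end_frame = NULL, max_changepoints = 20) {
  stopifnot(inherits(trace, "fret_trace"))
  if (is.null(end_frame)) {
    bl <- detect_acceptor_bleach(trace)
    end_frame <- if (bl$n_steps == 1L && !is.na(bl$bleach_frame))
      bl$bleach_frame - 1L else length(trace$donor)
  }
  end_frame <- max(end_frame, 1L)
  e <- compute_fret(trace)[seq_len(end_frame)]
  ok <- !is.na(e)
  e_fit <- e[ok]
  if (length(e_fit) < min_size) {
    stop_remkin("unusable_trace", "analysis window shorter than min_size")
  }
  if (is.null(penalty)) {
    sigma <- stats::mad(diff(e_fit)) / sqrt(2)
    penalty <- max(8 * sigma^2 * log(length(e_fit)), 1e-8)
  }
  cp_fit <- binseg(e_fit, min_size = min_size, penalty = penalty)
  # map back to original frame indices (NA frames removed before fitting)
  frames <- which(ok)
  cp <- frames[cp_fit]
  bounds <- c(1L, cp_fit, length(e_fit) + 1L)
  levels <- vapply(seq_len(length(bounds) - 1L), function(i) {
    mean(e_fit[bounds[i]:(bounds[i + 1L] - 1L)])
  }, numeric(1))
  if (length(cp) > max_changepoints) {
    warning(sprintf("suspicious trace %s: %d change points",
                    trace$molecule_id, length(cp)))
  }
  structure(
    list(change_points = cp, levels = levels, window_end = end_frame,
         frame_rate = trace$frame_rate, molecule_id = trace$molecule_id),
    class = "state_segments"
  )
}

#' @export
print.state_segments <- function(x, ...) {
  cat(sprintf("<state_segments> %s: %d change point(s), levels %s\n",
              x$molecule_id, length(x$change_points),
              paste(sprintf("%.2f", x$levels), collapse = " -> ")))
  invisible(x)
}

#' Detect acceptor photobleaching steps
#'
#' Segments the acceptor channel and counts large sustained downward level
#' transitions.  A transition counts as a bleach step when the level drops
#' by at least `min_rel_drop` of its pre-step value: remodelling ejections
#' redistribute intensity between the channels and produce relative
#' acceptor drops well below this (about 0.4-0.6 for single 5-bp
#' ejections and ~0.75 for a compound double ejection), whereas
#' photobleaching sends the acceptor to background (relative drop near
#' 1).
#'
#' @param trace a [fret_trace].
#' @param min_rel_drop minimum relative drop to call a bleach step.
#' @param min_size minimum segment length in frames.
#' @return A list: `n_steps` (count of bleach-like steps) and
#'   `bleach_frame` (frame of the step when `n_steps == 1`, else `NA`).
#' @export
detect_acceptor_bleach <- function(trace, min_rel_drop = 0.8, min_size = 3) {
  stopifnot(inherits(trace, "fret_trace"))
  y <- trace$acceptor
  sigma <- stats::mad(diff(y)) / sqrt(2)
  penalty <- max(8 * sigma^2 * log(length(y)), 1e-8)
  cp <- binseg(y, min_size = min_size, penalty = penalty)
  bounds <- c(1L, cp, length(y) + 1L)
  levels <- vapply(seq_len(length(bounds) - 1L), function(i) {
    mean(y[bounds[i]:(bounds[i + 1L] - 1L)])
  }, numeric(1))
  if (length(levels) < 2L) return(list(n_steps = 0L, bleach_frame = NA_integer_))
  top <- max(levels)
  prev <- utils::head(levels, -1L)
  nxt <- utils::tail(levels, -1L)
  is_bleach <- prev >= 0.1 * top & (prev - nxt) >= min_rel_drop * prev
  n <- sum(is_bleach)
  list(n_steps = as.integer(n),
       bleach_frame = if (n == 1L) cp[which(is_bleach)] else NA_integer_)
}

# initial-dwell FRET estimate: median E over the first `k` pre-bleach
# frames, a proxy for the molecule's starting state that is not dragged
# down by subsequent remodelling
initial_fret <- function(trace, end_frame, k = 25L) {
  e <- compute_fret(trace)[seq_len(max(min(end_frame, k), 1L))]
  stats::median(e, na.rm = TRUE)
}

#' Select analysable molecules
#'
#' Retains traces whose starting FRET efficiency (median over the initial
#' pre-bleach dwell) lies within `e_range` and that show exactly one
#' acceptor photobleaching step.
#'
#' @param traces list of [fret_trace] objects.
#' @param e_range inclusive FRET window for the starting state.
#' @return A list with `retained` (the selected traces) and `report`
#'   (data frame: `molecule_id`, `mean_e`, `n_bleach_steps`, `selected`,
#'   `reason` with `"fret_range"` / `"bleach_steps"` / `NA`).
#' @export
select_molecules <- function(traces, e_range = c(0.55, 0.7)) {
  if (!length(traces)) {
    return(list(retained = list(),
                report = data.frame(molecule_id = character(0),
                                    mean_e = numeric(0),
                                    n_bleach_steps = integer(0),
                                    selected = logical(0),
                                    reason = character(0))))
  }
  rows <- lapply(traces, function(tr) {
    bl <- detect_acceptor_bleach(tr)
    end_frame <- if (bl$n_steps == 1L) bl$bleach_frame - 1L
                 else length(tr$donor)
    me <- initial_fret(tr, end_frame)
    reason <- NA_character_
    if (bl$n_steps != 1L) reason <- "bleach_steps"
    else if (me < e_range[1L] || me > e_range[2L]) reason <- "fret_range"
    data.frame(molecule_id = tr$molecule_id, mean_e = me,
               n_bleach_steps = bl$n_steps, selected = is.na(reason),
               reason = reason, stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  list(retained = traces[report$selected], report = report)
}

#' Extract the pause time from a segmented trace
#'
#' The pause time tau_p is the duration between the first and second
#' downward FRET drops (entry into and exit from the intermediate state).
#' If the second drop is never observed before bleach/trace end the
#' interval is right-censored; a single drop large enough to be a compound
#' (double) ejection is reported as `"no_intermediate"` and carries no
#' pause time.
#'
#' @param segments a [segment_trace] result.
#' @param trace the corresponding [fret_trace].
#' @param min_drop minimum downward level change (E units) to count as an
#'   ejection drop.
#' @param compound_drop single drops at least this large are classified as
#'   compound (no measurable intermediate state).
#' @return A list: `tau_p` (seconds or `NA`), `censored`, `status` in
#'   `"complete"`, `"censored"`, `"no_intermediate"`, `"no_drop"`.
#' @export
extract_pause_time <- function(segments, trace, min_drop = 0.15,
                               compound_drop = 0.4) {
  stopifnot(inherits(segments, "state_segments"))
  d <- diff(segments$levels)
  drops <- which(d <= -min_drop)
  fr <- segments$frame_rate
  if (length(drops) >= 2L) {
    tau <- (segments$change_points[drops[2L]] -
              segments$change_points[drops[1L]]) / fr
    list(tau_p = tau, censored = FALSE, status = "complete")
  } else if (length(drops) == 1L) {
    if (-d[drops] >= compound_drop) {
      list(tau_p = NA_real_, censored = FALSE, status = "no_intermediate")
    } else {
      tau <- (segments$window_end + 1L - segments$change_points[drops]) / fr
      list(tau_p = tau, censored = TRUE, status = "censored")
    }
  } else {
    list(tau_p = NA_real_, censored = TRUE, status = "no_drop")
  }
}

#' Detect FRET reversals
#'
#' Upward level transitions of at least `min_rise` sustained for at least
#' `min_duration` frames, interpreted as transient returns towards the
#' starting nucleosome position.
#'
#' @param segments a [segment_trace] result.
#' @param min_rise minimum upward level change (E units).
#' @param min_duration minimum duration of the raised level (frames).
#' @return Data frame with `frame` and `delta_e` per reversal (0 rows if
#'   none).
#' @export
detect_reversals <- function(segments, min_rise = 0.1, min_duration = 5) {
  stopifnot(inherits(segments, "state_segments"))
  d <- diff(segments$levels)
  starts <- c(1L, segments$change_points)
  ends <- c(segments$change_points - 1L, segments$window_end)
  seg_len <- ends - starts + 1L
  up <- which(d >= min_rise & seg_len[-1L] >= min_duration)
  data.frame(frame = segments$change_points[up], delta_e = d[up])
}

#' Fraction of traces showing at least one reversal
#'
#' @param traces list of [fret_trace] objects (segmented internally) or of
#'   `state_segments`.
#' @param ... passed to [detect_reversals].
#' @return Numeric fraction in `[0, 1]`.
#' @export
reversal_fraction <- function(traces, ...) {
  if (!length(traces)) return(NA_real_)
  hits <- vapply(traces, function(x) {
    seg <- if (inherits(x, "state_segments")) x else segment_trace(x)
    nrow(detect_reversals(seg, ...)) > 0L
  }, logical(1))
  mean(hits)
}

#' Gaussian mixture fit of per-molecule FRET values
#'
#' Expectation-maximization fit (unequal variances) of the distribution of
#' per-molecule mean FRET efficiencies, used to resolve the nucleosome
#' populations.
#'
#' @param values per-molecule mean FRET efficiencies.
#' @param n_components number of Gaussian components.
#' @return A list: `means` (sorted decreasing), `weights`, `sd`, `loglik`.
#' @export
fit_fret_mixture <- function(values, n_components = 3) {
  values <- values[is.finite(values)]
  if (n_components > length(values)) {
    stop_remkin("insufficient_data",
                "more mixture components than data points")
  }
  if (n_components == 1L) {
    return(list(means = mean(values), weights = 1,
                sd = stats::sd(values), loglik = NA_real_))
  }
  fit <- mclust::Mclust(values, G = n_components,
                        modelNames = c("V", "E"), verbose = FALSE)
  if (is.null(fit)) stop_remkin("fit_failure", "mixture fit did not converge")
  mu <- as.numeric(fit$parameters$mean)
  ord <- order(mu, decreasing = TRUE)
  sigmasq <- fit$parameters$variance$sigmasq
  if (length(sigmasq) == 1L) sigmasq <- rep(sigmasq, n_components)
  list(means = mu[ord], weights = fit$parameters$pro[ord],
       sd = sqrt(sigmasq)[ord], loglik = fit$loglik)
}

#' Starting-state FRET per molecule
#'
#' @param traces list of [fret_trace] objects.
#' @return Numeric vector of initial-dwell FRET estimates.
#' @export
molecule_mean_fret <- function(traces) {
  vapply(traces, function(tr) {
    bl <- detect_acceptor_bleach(tr)
    end_frame <- if (bl$n_steps == 1L) bl$bleach_frame - 1L
                 else length(tr$donor)
    initial_fret(tr, end_frame)
  }, numeric(1))
}

#' Run the full per-molecule trace analysis
#'
#' Selection, segmentation, pause-time extraction and reversal detection
#' over a set of traces; the per-molecule results table and a population
#' summary.
#'
#' @param traces list of [fret_trace] objects.
#' @param e_range selection window for the starting FRET state.
#' @param ... passed to [segment_trace].
#' @return A list of class `trace_analysis`: `results` (data frame:
#'   `molecule_id`, `mean_e`, `selected`, `reason`, `tau_p`, `censored`,
#'   `status`, `n_reversals`) and `summary`.
#' @export
analyze_traces <- function(traces, e_range = c(0.55, 0.7), ...) {
  sel <- select_molecules(traces, e_range = e_range)
  rep <- sel$report
  rep$tau_p <- NA_real_
  rep$censored <- NA
  rep$status <- NA_character_
  rep$n_reversals <- NA_integer_
  idx <- which(rep$selected)
  for (i in idx) {
    tr <- traces[[i]]
    seg <- segment_trace(tr, ...)
    pt <- extract_pause_time(seg, tr)
    rep$tau_p[i] <- pt$tau_p
    rep$censored[i] <- pt$censored
    rep$status[i] <- pt$status
    rep$n_reversals[i] <- nrow(detect_reversals(seg))
  }
  complete <- rep$selected & !is.na(rep$status) & rep$status == "complete"
  summary <- list(
    n_traces = nrow(rep),
    n_selected = sum(rep$selected),
    n_complete = sum(complete),
    n_censored = sum(rep$selected & !is.na(rep$status) &
                       rep$status == "censored"),
    n_no_intermediate = sum(rep$selected & !is.na(rep$status) &
                              rep$status == "no_intermediate"),
    reversal_fraction = if (length(idx))
      mean(rep$n_reversals[idx] > 0) else NA_real_
  )
  structure(list(results = rep, summary = summary), class = "trace_analysis")
}

#' @export
print.trace_analysis <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<trace_analysis> %d traces: %d selected, %d complete tau_p, %d censored, %d no-intermediate\n",
    s$n_traces, s$n_selected, s$n_complete, s$n_censored,
    s$n_no_intermediate))
  invisible(x)
}

#' Pause times from an analysis
#'
#' Pools the measured pause times of a [analyze_traces] result into a
#' [dwell_times] object (complete plus censored intervals).
#'
#' @param analysis a `trace_analysis`.
#' @param condition label for the resulting sample.
#' @export
pause_times_from_analysis <- function(analysis, condition = "") {
  stopifnot(inherits(analysis, "trace_analysis"))
  r <- analysis$results
  keep <- r$selected & !is.na(r$tau_p) & r$tau_p > 0
  dwell_times(r$tau_p[keep], censored = r$censored[keep],
              condition = condition)
}

# ---- trace I/O ------------------------------------------------------------

#' Read/write trace tables
#'
#' Long-format tab-delimited text with columns `molecule_id`, `frame`,
#' `time_s`, `donor`, `acceptor`.
#'
#' @param traces list of [fret_trace] objects.
#' @param path file path.
#' @export
write_traces <- function(traces, path) {
  rows <- lapply(traces, function(tr) {
    n <- length(tr$donor)
    data.frame(molecule_id = tr$molecule_id, frame = seq_len(n),
               time_s = seq_len(n) / tr$frame_rate,
               donor = tr$donor, acceptor = tr$acceptor,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @param frame_rate frames per second of the recorded movie.
#' @return `read_traces` returns a list of [fret_trace] objects.
#' @export
read_traces <- function(path, frame_rate = 5) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("molecule_id", "frame", "time_s", "donor", "acceptor")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_remkin("format_error",
                paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  lapply(split(df, df$molecule_id), function(d) {
    d <- d[order(d$frame), ]
    fret_trace(d$donor, d$acceptor, frame_rate = frame_rate,
               molecule_id = d$molecule_id[1L])
  })
}
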