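#' Configuration for synthetic smFRET trace generation
#'
#' Defaults reflect the imaging conditions emulated by the generator:
#' 5 frames per second, a FRET-efficiency change of 0.05 per bp of DNA
#' ejected at the exit side, and three nucleosome populations with mean
#' FRET 0.78 (acceptor on both H2A copies), 0.67 (acceptor proximal: the
#' remodelling-competent mid-FRET class) and 0.42 (acceptor distal).
#'
#' @param frame_rate frames per second.
#' @param fret_per_bp FRET-efficiency decrement per bp ejected.
#' @param e_start initial efficiency of the mid-FRET class.
#' @param class_means mean FRET of the high/mid/low populations.
#' @param noise_sd Gaussian standard deviation added to each intensity
#'   channel (same units as `total_intensity`).
#' @param total_intensity summed donor+acceptor intensity (arbitrary
#'   units).
#' @param acceptor_bleach_rate single-step acceptor photobleaching rate
#'   (s^-1); bleach times are exponential.
#' @param duration movie length in seconds.
#' @param fret_floor lowest attainable efficiency (the dye pair never
#'   reaches zero transfer while both dyes are active).
#' @param background post-bleach acceptor level.
#' @return An object of class `trace_synth_config`.
#' @export
trace_synth_config <- function(frame_rate = 5, fret_per_bp = 0.05,
                               e_start = 0.67,
                               class_means = c(high = 0.78, mid = 0.67,
                                               low = 0.42),
                               noise_sd = 30, total_intensity = 1000,
                               acceptor_bleach_rate = 1 / 150,
                               duration = 300, fret_floor = 0.05,
                               background = 0) {
  if (frame_rate <= 0) stop_remkin("domain_error", "frame_rate must be > 0")
  if (any(class_means < 0) || any(class_means > 1) || e_start < 0 || e_start > 1) {
    stop_remkin("domain_error", "FRET efficiencies must lie in [0, 1]")
  }
  if (noise_sd < 0) stop_remkin("domain_error", "noise_sd must be >= 0")
  if (length(class_means) != 3L) {
    stop_remkin("domain_error", "class_means must have length 3 (high, mid, low)")
  }
  if (duration <= 0 || total_intensity <= 0) {
    stop_remkin("domain_error", "duration and total_intensity must be > 0")
  }
  structure(
    list(frame_rate = frame_rate, fret_per_bp = fret_per_bp,
         e_start = e_start, class_means = class_means, noise_sd = noise_sd,
         total_intensity = total_intensity,
         acceptor_bleach_rate = acceptor_bleach_rate, duration = duration,
         fret_floor = fret_floor, background = background),
    class = "trace_synth_config"
  )
}

#' FRET efficiency as a function of exit-side bp ejected
#'
#' Linear calibration: E = e_start - fret_per_bp * bp, floored at
#' `fret_floor` (efficiency cannot reach zero while both dyes are active).
#'
#' @param bp integer bp ejected, `>= 0`.
#' @param cfg a [trace_synth_config].
#' @return FRET efficiencies.
#' @examples
#' cfg <- trace_synth_config()
#' fret_from_exit_bp(0, cfg)  # 0.67, the mid-FRET class mean
#' fret_from_exit_bp(5, cfg)  # 0.42, coincides with the low-FRET class mean
#' @export
fret_from_exit_bp <- function(bp, cfg = trace_synth_config()) {
  stopifnot(inherits(cfg, "trace_synth_config"))
  pmax(cfg$e_start - cfg$fret_per_bp * bp, cfg$fret_floor)
}

#' Two-channel smFRET trace container
#'
#' @param donor,acceptor equal-length intensity series (arbitrary units).
#' @param frame_rate frames per second.
#' @param molecule_id identifier.
#' @param annotations optional ground-truth list (true change frames, true
#'   pause time, bleach frame, class label) attached by the generator.
#' @return An object of class `fret_trace`.
#' @export
fret_trace <- function(donor, acceptor, frame_rate = 5,
                       molecule_id = "mol_1", annotations = NULL) {
  if (length(donor) != length(acceptor)) {
    stop_remkin("domain_error", "donor and acceptor must have equal length")
  }
  structure(
    list(molecule_id = molecule_id, frame_rate = frame_rate,
         donor = as.numeric(donor), acceptor = as.numeric(acceptor),
         annotations = annotations),
    class = "fret_trace"
  )
}

#' @export
print.fret_trace <- function(x, ...) {
  cat(sprintf("<fret_trace> %s: %d frames at %g fps%s\n", x$molecule_id,
              length(x$donor), x$frame_rate,
              if (!is.null(x$annotations$class))
                paste0(" [", x$annotations$class, "-FRET class]") else ""))
  invisible(x)
}

# frame index of the first frame at or after time t (frame i covers
# ((i-1)/fr, i/fr]); NA if beyond the trace
frame_of_time <- function(t, frame_rate, n_frames) {
  f <- ceiling(t * frame_rate)
  f[f < 1] <- 1
  f[f > n_frames] <- NA_integer_
  as.integer(f)
}

#' Synthesize a two-channel smFRET trace from a trajectory
#'
#' Samples the trajectory's cumulative exit-side bp at the frame rate,
#' converts to FRET efficiency via [fret_from_exit_bp], and emits
#' anti-correlated donor/acceptor channels sharing a constant total
#' intensity, with additive Gaussian noise per channel.  The acceptor
#' bleaches in a single step at an exponential time, after which the
#' acceptor falls to background and the donor is fully dequenched.
#' Ground-truth annotations (ejection frames, true pause time, bleach
#' frame, censoring) are attached.
#'
#' @param traj a [simulate_trajectory] result.
#' @param cfg a [trace_synth_config].
#' @param seed optional integer seed.
#' @param class_mean starting FRET efficiency; defaults to `cfg$e_start`.
#' @return A [fret_trace].
#' @export
synth_trace <- function(traj, cfg = trace_synth_config(), seed = NULL,
                        class_mean = NULL) {
  stopifnot(inherits(traj, "trajectory"), inherits(cfg, "trace_synth_config"))
  n_frames <- floor(cfg$duration * cfg$frame_rate)
  t_frame <- seq_len(n_frames) / cfg$frame_rate
  e0 <- if (is.null(class_mean)) cfg$e_start else class_mean
  bp <- exit_bp_at(traj, t_frame)
  e_true <- pmax(e0 - cfg$fret_per_bp * bp, cfg$fret_floor)

  synth_channels(e_true, cfg, seed = seed, molecule_id = traj$molecule_id,
                 extra_annotations = trace_truth(traj, cfg, n_frames))
}

# ground-truth bookkeeping shared with synth_population
trace_truth <- function(traj, cfg, n_frames) {
  ej <- traj$events$time_s[traj$events$kind == "ejection"]
  rev_t <- traj$events$time_s[traj$events$kind == "reversal"]
  list(class = "mid",
       ejection_times = ej,
       change_frames = frame_of_time(ej, cfg$frame_rate, n_frames),
       reversal_frames = frame_of_time(rev_t, cfg$frame_rate, n_frames),
       true_tau_p = if (length(ej) >= 2) ej[2L] - ej[1L] else NA_real_)
}

# draw noisy channels around a true efficiency series, apply single-step
# acceptor bleaching, and assemble the fret_trace
synth_channels <- function(e_true, cfg, seed = NULL, molecule_id = "mol_1",
                           extra_annotations = list()) {
  n_frames <- length(e_true)
  t_frame <- seq_len(n_frames) / cfg$frame_rate
  out <- with_seed_(seed, {
    bleach_time <- if (cfg$acceptor_bleach_rate > 0)
      stats::rexp(1, cfg$acceptor_bleach_rate) else Inf
    acceptor <- e_true * cfg$total_intensity
    donor <- (1 - e_true) * cfg$total_intensity
    bleached <- t_frame >= bleach_time
    acceptor[bleached] <- cfg$background
    donor[bleached] <- cfg$total_intensity
    if (cfg$noise_sd > 0) {
      acceptor <- acceptor + stats::rnorm(n_frames, 0, cfg$noise_sd)
      donor <- donor + stats::rnorm(n_frames, 0, cfg$noise_sd)
    }
    list(donor = donor, acceptor = acceptor, bleach_time = bleach_time)
  })
  bleach_frame <- if (is.finite(out$bleach_time))
    frame_of_time(out$bleach_time, cfg$frame_rate, n_frames) else NA_integer_
  ann <- c(extra_annotations,
           list(bleach_time = out$bleach_time, bleach_frame = bleach_frame))
  # censored: second ejection (if any is due) not observed before bleach/end
  ej <- ann$ejection_times
  obs_end <- min(out$bleach_time, n_frames / cfg$frame_rate)
  ann$censored <- if (is.null(ej)) NA else !(length(ej) >= 2 && ej[2L] <= obs_end)
  fret_trace(out$donor, out$acceptor, frame_rate = cfg$frame_rate,
             molecule_id = molecule_id, annotations = ann)
}

#' Synthesize a population of smFRET traces
#'
#' Draws molecules from the three FRET classes (high/mid/low) with the
#' given weights.  Only mid-FRET molecules (acceptor proximal to the
#' donor) carry remodelling trajectories; high- and low-FRET molecules
#' hold a constant efficiency until acceptor bleach.
#'
#' @param n number of molecules.
#' @param class_weights probabilities for the high/mid/low classes
#'   (must sum to 1).
#' @param scheme [kinetic_scheme] driving the mid-FRET molecules.
#' @param cfg a [trace_synth_config].
#' @param seed top-level seed; per-molecule streams are derived
#'   deterministically.
#' @return A list of [fret_trace] objects (possibly empty).
#' @export
synth_population <- function(n, class_weights = c(0.3, 0.4, 0.3),
                             scheme = kinetic_scheme(n_rounds = 2),
                             cfg = trace_synth_config(), seed = NULL) {
  if (length(class_weights) != 3L || any(class_weights < 0) ||
      abs(sum(class_weights) - 1) > 1e-8) {
    stop_remkin("domain_error", "class_weights must be 3 probabilities summing to 1")
  }
  if (n < 0) stop_remkin("domain_error", "n must be >= 0")
  if (n == 0) return(list())
  classes <- with_seed_(child_seed(seed, 0), {
    sample(c("high", "mid", "low"), n, replace = TRUE, prob = class_weights)
  })
  lapply(seq_len(n), function(i) {
    id <- sprintf("mol_%04d", i)
    s_i <- child_seed(seed, i)
    if (classes[i] == "mid") {
      traj <- simulate_trajectory(scheme, max_time = cfg$duration,
                                  seed = child_seed(s_i, 1),
                                  molecule_id = id)
      synth_trace(traj, cfg, seed = child_seed(s_i, 2))
    } else {
      e <- cfg$class_means[[if (classes[i] == "high") 1L else 3L]]
      n_frames <- floor(cfg$duration * cfg$frame_rate)
      synth_channels(rep(e, n_frames), cfg, seed = child_seed(s_i, 2),
                     molecule_id = id,
                     extra_annotations = list(class = classes[i]))
    }
  })
}

#' Synthesize a real-time fluorescence assay (RTFA) curve
#'
#' Zero signal during the pre-injection baseline; after ATP injection the
#' normalized fluorescence follows the asymptotic exponential
#' y = F_lim (1 - exp(-k (t - t_inj))), plus Gaussian noise.
#'
#' @param f_lim limiting fluorescence (normalized units).
#' @param k_rtfa pseudo-first-order rate constant (min^-1).
#' @param pre_injection baseline duration before ATP injection (min).
#' @param sample_interval sampling interval (min).
#' @param duration total monitored time (min).
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed optional integer seed.
#' @return An `rtfa_curve`: data frame with `time_min`, `fluorescence`
#'   and attribute `injection_time`.
#' @export
synth_rtfa <- function(f_lim, k_rtfa, pre_injection = 5,
                       sample_interval = 0.5, duration = 30,
                       noise_sd = 0, seed = NULL) {
  if (k_rtfa <= 0) stop_remkin("domain_error", "k_rtfa must be positive")
  time <- seq(0, duration, by = sample_interval)
  y <- ifelse(time <= pre_injection, 0,
              f_lim * (1 - exp(-k_rtfa * (time - pre_injection))))
  if (noise_sd > 0) {
    y <- with_seed_(seed, y + stats::rnorm(length(y), 0, noise_sd))
  }
  rtfa_curve(time, y, injection_time = pre_injection)
}

#' RTFA curve container
#'
#' @param time_min time in minutes, strictly increasing.
#' @param fluorescence normalized fluorescence.
#' @param injection_time ATP injection time (min).
#' @export
rtfa_curve <- function(time_min, fluorescence, injection_time = 5) {
  if (any(diff(time_min) <= 0)) {
    stop_remkin("domain_error", "time must be strictly increasing")
  }
  structure(
    data.frame(time_min = time_min, fluorescence = fluorescence),
    injection_time = injection_time,
    class = c("rtfa_curve", "data.frame")
  )
}

# exact 1:1 equilibrium fraction of probe bound, accounting for probe
# depletion (quadratic solution); all concentrations in the same units
bound_fraction_quadratic <- function(titrant, k_d, probe) {
  s <- probe + titrant + k_d
  complex <- (s - sqrt(s^2 - 4 * probe * titrant)) / 2
  complex / probe
}

bound_fraction_hyperbolic <- function(titrant, k_d) {
  titrant / (titrant + k_d)
}

#' Synthesize a thermophoresis-style binding titration
#'
#' Response = baseline + amplitude x (fraction of labelled probe bound),
#' with the fraction bound computed from the exact 1:1 equilibrium with
#' probe depletion (quadratic solution), plus Gaussian noise.  The default
#' titration is a 16-point 1:2 serial dilution.
#'
#' @param k_d dissociation constant (nM).
#' @param probe labelled probe concentration (nM).
#' @param titrant titrant concentrations (nM); default 1:2 dilution from
#'   5000 nM, 16 points.
#' @param amplitude,baseline response scale (arbitrary units).
#' @param noise_sd Gaussian noise standard deviation.
#' @param n_replicates technical replicates (independent noise draws).
#' @param seed optional integer seed.
#' @return A `binding_curve`: data frame with `titrant_nM`, `response`,
#'   `replicate` and attribute `probe`.
#' @export
synth_mst <- function(k_d, probe = 25, titrant = NULL, amplitude = 1,
                      baseline = 0, noise_sd = 0, n_replicates = 1,
                      seed = NULL) {
  if (k_d <= 0 || probe <= 0) {
    stop_remkin("domain_error", "k_d and probe must be positive")
  }
  if (is.null(titrant)) titrant <- 5000 / 2^(0:15)
  if (any(titrant < 0)) stop_remkin("domain_error", "titrant must be nonnegative")
  fb <- bound_fraction_quadratic(titrant, k_d, probe)
  resp0 <- baseline + amplitude * fb
  df <- with_seed_(seed, {
    do.call(rbind, lapply(seq_len(n_replicates), function(r) {
      y <- resp0
      if (noise_sd > 0) y <- y + stats::rnorm(length(y), 0, noise_sd)
      data.frame(titrant_nM = titrant, response = y, replicate = r)
    }))
  })
  binding_curve(df$titrant_nM, df$response, replicate = df$replicate,
                probe = probe)
}

#' Binding titration container
#'
#' @param titrant_nM titrant concentrations (nM), nonnegative.
#' @param response measured response (arbitrary units).
#' @param replicate replicate index.
#' @param probe labelled probe concentration (nM).
#' @export
binding_curve <- function(titrant_nM, response, replicate = 1, probe = 25) {
  if (any(titrant_nM < 0)) {
    stop_remkin("domain_error", "titrant must be nonnegative")
  }
  structure(
    data.frame(titrant_nM = titrant_nM, response = response,
               replicate = rep_len(replicate, length(titrant_nM))),
    probe = probe,
    class = c("binding_curve", "data.frame")
  )
}

# ---- disordered-region sequence tools -------------------------------------

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

check_aa_sequence <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  bad <- setdiff(unique(chars), AA20)
  if (length(bad)) {
    stop_remkin("domain_error",
                paste("non-amino-acid character(s):", paste(bad, collapse = ", ")))
  }
  chars
}

#' Charge and polarity composition of a protein sequence
#'
#' Counts positively charged (Lys+Arg), negatively charged (Asp+Glu) and
#' polar residues.  The default polar set is \{S, T, N, Q, C, Y, H\}:
#' histidine is counted polar rather than positive, and the small residues
#' G/A/P are excluded.  The convention is configurable.
#'
#' @param seq amino-acid string (one-letter codes).
#' @param region optional 1-based inclusive `c(start, end)` interval.
#' @param positive,negative,polar residue sets as strings.
#' @return Named integer vector `c(positive, negative, polar)`.
#' @examples
#' count_composition("KRDE")  # c(positive = 2, negative = 2, polar = 0)
#' @export
count_composition <- function(seq, region = NULL, positive = "KR",
                              negative = "DE", polar = "STNQCYH") {
  chars <- check_aa_sequence(seq)
  if (!is.null(region)) {
    if (length(region) != 2L || region[1L] < 1 || region[2L] > length(chars) ||
        region[1L] > region[2L]) {
      stop_remkin("domain_error", "region out of sequence bounds")
    }
    chars <- chars[region[1L]:region[2L]]
  }
  in_set <- function(set) sum(chars %in% strsplit(set, "")[[1]])
  c(positive = in_set(positive), negative = in_set(negative),
    polar = in_set(polar))
}

#' Sequence variant of a disordered region
#'
#' @param name variant label.
#' @param sequence amino-acid string.
#' @return An `idr_variant`: name, sequence and its composition counts.
#' @export
idr_variant <- function(name, sequence) {
  counts <- count_composition(sequence)
  structure(
    list(name = name, sequence = toupper(sequence),
         positive_count = unname(counts["positive"]),
         negative_count = unname(counts["negative"]),
         polar_count = unname(counts["polar"])),
    class = "idr_variant"
  )
}

#' @export
print.idr_variant <- function(x, ...) {
  cat(sprintf("<idr_variant> %s: %d aa (+%d / -%d / polar %d)\n", x$name,
              nchar(x$sequence), x$positive_count, x$negative_count,
              x$polar_count))
  invisible(x)
}

#' Scramble a sequence preserving composition
#'
#' Random permutation of the residues: identical composition, different
#' order (emulating a scrambled-IDR control construct).
#'
#' @param seq amino-acid string.
#' @param seed optional integer seed.
#' @param name variant label.
#' @return An [idr_variant].
#' @export
scramble_sequence <- function(seq, seed = NULL, name = "scram") {
  chars <- check_aa_sequence(seq)
  perm <- with_seed_(seed, sample(chars))
  idr_variant(name, paste(perm, collapse = ""))
}

#' Edit a sequence to target charge counts
#'
#' Substitutes residues at random positions until the Lys+Arg and Asp+Glu
#' counts equal the targets, preserving length.  Charge removal replaces a
#' charged residue with alanine (keeping the polar count unchanged);
#' charge addition replaces a small/apolar residue (falling back to a
#' polar one if none remain) with Lys or Glu/Asp respectively.
#'
#' @param seq amino-acid string.
#' @param target_positive,target_negative desired counts.
#' @param seed optional integer seed.
#' @param name variant label.
#' @return An [idr_variant] whose counts equal the targets exactly.
#' @export
make_charge_edited_variant <- function(seq, target_positive, target_negative,
                                       seed = NULL, name = "charge_edit") {
  chars <- check_aa_sequence(seq)
  with_seed_(seed, {
    adjust <- function(chars, set, target, add_with) {
      repeat {
        idx <- which(chars %in% set)
        delta <- length(idx) - target
        if (delta == 0) break
        if (delta > 0) {
          chars[sample(idx, 1L)] <- "A"
        } else {
          pool <- which(!chars %in% c("K", "R", "D", "E", "S", "T", "N",
                                      "Q", "C", "Y", "H"))
          if (!length(pool)) pool <- which(!chars %in% c("K", "R", "D", "E"))
          if (!length(pool)) {
            stop_remkin("domain_error", "cannot reach charge targets: no editable residues")
          }
          chars[sample(pool, 1L)] <- sample(add_with, 1L)
        }
      }
      chars
    }
    chars <- adjust(chars, c("K", "R"), target_positive, c("K", "R"))
    chars <- adjust(chars, c("D", "E"), target_negative, c("D", "E"))
    idr_variant(name, paste(chars, collapse = ""))
  })
}

#' Synthetic IDR sequence with a specified charge composition
#'
#' Generates a random disordered-region-like sequence with exact counts of
#' positive (K/R), negative (D/E) and polar (S/T/N/Q) residues, the
#' remainder drawn from small/apolar residues (A/G/P/V).  The defaults
#' emulate the composition of a 136-residue charged remodeller IDR with 32
#' basic residues.  This is a synthetic stand-in, not a native sequence.
#'
#' @param length sequence length.
#' @param n_positive,n_negative,n_polar residue counts.
#' @param seed optional integer seed.
#' @param name variant label.
#' @return An [idr_variant].
#' @export
synth_idr_sequence <- function(length = 136, n_positive = 32,
                               n_negative = 30, n_polar = 40, seed = NULL,
                               name = "synthetic_idr") {
  n_rest <- length - n_positive - n_negative - n_polar
  if (n_rest < 0) stop_remkin("domain_error", "counts exceed sequence length")
  with_seed_(seed, {
    chars <- c(sample(c("K", "R"), n_positive, replace = TRUE),
               sample(c("D", "E"), n_negative, replace = TRUE),
               sample(c("S", "T", "N", "Q"), n_polar, replace = TRUE),
               sample(c("A", "G", "P", "V"), n_rest, replace = TRUE))
    idr_variant(name, paste(sample(chars), collapse = ""))
  })
}

#' Synthetic non-redundant crosslink table
#'
#' Generates a table of unique unordered intra-protein residue pairs, a
#' specified number of which touch a given region, emulating the structure
#' and scale of a deposited BS3 crosslink list.  This is a synthetic
#' stand-in for real crosslinking mass-spectrometry output.
#'
#' @param n_total total number of unique crosslinks.
#' @param region 1-based inclusive interval `c(start, end)`.
#' @param n_region number of crosslinks with at least one endpoint inside
#'   `region`.
#' @param protein protein identifier for both endpoints.
#' @param n_residues sequence length over which positions are drawn.
#' @param min_separation minimum |i - j| sequence separation.
#' @param seed optional integer seed.
#' @return A data frame with columns `protein_i`, `pos_i`, `protein_j`,
#'   `pos_j`, `score`.
#' @export
synth_xl_table <- function(n_total = 579, region = c(1201, 1340),
                           n_region = 127, protein = "CHD4",
                           n_residues = 1912, min_separation = 5,
                           seed = NULL) {
  if (n_region > n_total) {
    stop_remkin("domain_error", "n_region cannot exceed n_total")
  }
  in_region <- function(p) p >= region[1L] & p <= region[2L]
  with_seed_(seed, {
    draw_pairs <- function(n_needed, want_region) {
      keys <- character(0)
      out_i <- integer(0); out_j <- integer(0)
      while (length(out_i) < n_needed) {
        m <- 2L * (n_needed - length(out_i)) + 10L
        if (want_region) {
          i <- sample(region[1L]:region[2L], m, replace = TRUE)
          j <- sample(n_residues, m, replace = TRUE)
        } else {
          outside <- setdiff(seq_len(n_residues), region[1L]:region[2L])
          i <- sample(outside, m, replace = TRUE)
          j <- sample(outside, m, replace = TRUE)
        }
        ok <- abs(i - j) >= min_separation
        if (want_region) ok <- ok & (in_region(i) | in_region(j))
        else ok <- ok & !in_region(i) & !in_region(j)
        i <- i[ok]; j <- j[ok]
        key <- paste(pmin(i, j), pmax(i, j))
        new <- !duplicated(key) & !(key %in% keys)
        keys <- c(keys, key[new])
        out_i <- c(out_i, i[new]); out_j <- c(out_j, j[new])
      }
      list(i = out_i[seq_len(n_needed)], j = out_j[seq_len(n_needed)])
    }
    a <- draw_pairs(n_region, TRUE)
    b <- draw_pairs(n_total - n_region, FALSE)
    df <- data.frame(protein_i = protein, pos_i = c(a$i, b$i),
                     protein_j = protein, pos_j = c(a$j, b$j),
                     score = round(stats::runif(n_total, 10, 100), 2),
                     stringsAsFactors = FALSE)
    df[sample(nrow(df)), , drop = FALSE]
  })
}

#' Synthetic C-alpha chain
#'
#' Random-walk backbone with 3.8 A steps, as a toy structural model for
#' distance-satisfaction tests; a synthetic stand-in, not a real fold.
#'
#' @param n_residues chain length.
#' @param seed optional integer seed.
#' @param missing residue positions to leave unresolved.
#' @return A [structure_model].
#' @export
synth_structure <- function(n_residues, seed = NULL, missing = integer(0)) {
  coords <- with_seed_(seed, {
    d <- matrix(stats::rnorm(3 * n_residues), ncol = 3)
    d <- d / sqrt(rowSums(d^2)) * 3.8
    apply(d, 2, cumsum)
  })
  keep <- setdiff(seq_len(n_residues), missing)
  structure_model(coords[keep, , drop = FALSE], positions = keep)
}

# ---- FASTA I/O ------------------------------------------------------------

#' Read/write protein sequences as FASTA
#'
#' @param path file path.
#' @return `read_fasta_seq` returns a named character vector of sequences.
#' @export
read_fasta_seq <- function(path) {
  seqs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             forceDNAtolower = FALSE)
  stats::setNames(toupper(unlist(lapply(seqs, as.character))), names(seqs))
}

#' @rdname read_fasta_seq
#' @param seqs named character vector of sequences, or a list of
#'   [idr_variant] objects.
#' @export
write_fasta_seq <- function(seqs, path) {
  if (is.list(seqs) && all(vapply(seqs, inherits, TRUE, "idr_variant"))) {
    seqs <- stats::setNames(vapply(seqs, `[[`, "", "sequence"),
                            vapply(seqs, `[[`, "", "name"))
  }
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path)
  invisible(path)
}
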