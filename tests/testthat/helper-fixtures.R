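# fixtures built in code; no data files

# raw two-channel trace with piecewise-constant acceptor levels given as
# fractions of `total`, each level lasting `len` frames; donor holds the
# complement of the first level unless donor_levels is given
make_step_trace <- function(acceptor_levels, len = 60, total = 1000,
                            donor_levels = NULL, noise_sd = 0, seed = 1,
                            frame_rate = 5, molecule_id = "fix") {
  acc <- rep(acceptor_levels * total, each = len)
  don <- if (is.null(donor_levels)) {
    rep((1 - acceptor_levels[1]) * total, length(acc))
  } else {
    rep(donor_levels * total, each = len)
  }
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      acc <- acc + rnorm(length(acc), 0, noise_sd)
      don <- don + rnorm(length(don), 0, noise_sd)
    })
  }
  fret_trace(don, acc, frame_rate = frame_rate, molecule_id = molecule_id)
}

# noiseless two-drop mid-FRET trace with known change frames
make_two_drop_trace <- function(cp1 = 50, cp2 = 140, n = 400, e0 = 0.67,
                                step = 0.25, total = 1000, noise_sd = 0,
                                seed = 1, frame_rate = 5) {
  e <- rep(e0, n)
  e[cp1:n] <- e0 - step
  e[cp2:n] <- e0 - 2 * step
  acc <- e * total
  don <- (1 - e) * total
  if (noise_sd > 0) {
    withr::with_seed(seed, {
      acc <- acc + rnorm(n, 0, noise_sd)
      don <- don + rnorm(n, 0, noise_sd)
    })
  }
  fret_trace(don, acc, frame_rate = frame_rate, molecule_id = "two_drop")
}

# toy structure with residue i at (i * spacing, 0, 0): distances are exact
# by construction
make_line_structure <- function(n = 100, spacing = 10) {
  structure_model(cbind(seq_len(n) * spacing, 0, 0), positions = seq_len(n))
}
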