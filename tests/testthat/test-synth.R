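test_that("FRET-per-bp calibration maps exit-side bp to efficiencies", {
  cfg <- trace_synth_config()
  expect_equal(fret_from_exit_bp(0, cfg), 0.67)
  expect_equal(fret_from_exit_bp(1, cfg), 0.62)
  # 5 bp ejected from the mid state lands on the low-FRET class mean
  expect_equal(fret_from_exit_bp(5, cfg), 0.42)
  # floored: efficiency never reaches zero
  expect_equal(fret_from_exit_bp(100, cfg), 0.05)
})

test_that("noiseless traces are piecewise constant with steps at ejections", {
  sch <- kinetic_scheme(n_steps = 6, rate = 0.1, n_rounds = 2)
  tr <- simulate_trajectory(sch, max_time = 1e4, seed = 1)
  cfg <- trace_synth_config(noise_sd = 0, acceptor_bleach_rate = 0,
                            duration = 400)
  trace <- synth_trace(tr, cfg, seed = 2)
  e <- compute_fret(trace)
  steps <- which(diff(e) != 0) + 1L
  expect_equal(steps, trace$annotations$change_frames)
  expect_equal(length(steps), 2L)
  # levels are exactly the calibrated values
  expect_equal(unique(e), c(0.67, 0.42, 0.17))
})

test_that("bleach before the second ejection marks the trace censored", {
  sch <- kinetic_scheme(n_steps = 6, rate = 0.1, n_rounds = 2)
  tr <- simulate_trajectory(sch, max_time = 1e4, seed = 3)
  ej2 <- tr$events$time_s[tr$events$kind == "ejection"][2]
  # force a bleach between the ejections by making bleaching very fast
  cfg_fast <- trace_synth_config(noise_sd = 0, acceptor_bleach_rate = 50,
                                 duration = 400)
  trace <- synth_trace(tr, cfg_fast, seed = 4)
  expect_true(trace$annotations$bleach_time < ej2)
  expect_true(trace$annotations$censored)
  # and with no bleaching the same trajectory is complete
  cfg_none <- trace_synth_config(noise_sd = 0, acceptor_bleach_rate = 0,
                                 duration = 400)
  expect_false(synth_trace(tr, cfg_none, seed = 4)$annotations$censored)
})

test_that("population generator respects class weights and edge cases", {
  cfg <- trace_synth_config(noise_sd = 0, acceptor_bleach_rate = 0,
                            duration = 60)
  all_mid <- synth_population(20, class_weights = c(0, 1, 0), cfg = cfg,
                              seed = 5)
  expect_true(all(vapply(all_mid, function(t) t$annotations$class, "") ==
                    "mid"))
  expect_identical(synth_population(0, cfg = cfg, seed = 5), list())
  expect_error(synth_population(5, class_weights = c(0.5, 0.2, 0.2)),
               class = "remkin_domain_error")
})

test_that("synthetic RTFA follows the asymptotic exponential exactly", {
  cu <- synth_rtfa(f_lim = 0.8, k_rtfa = 0.3, noise_sd = 0)
  expect_true(all(cu$fluorescence[cu$time_min <= 5] == 0))
  post <- cu$time_min > 5
  expect_equal(cu$fluorescence[post],
               0.8 * (1 - exp(-0.3 * (cu$time_min[post] - 5))))
  # the sample at the injection instant reads zero
  expect_equal(cu$fluorescence[cu$time_min == 5], 0)
})

test_that("synthetic titration hits isotherm limits and dilution defaults", {
  cu <- synth_mst(k_d = 45, probe = 25,
                  titrant = c(0, 1e7, 5000 / 2^(0:13)), noise_sd = 0)
  expect_equal(cu$response[cu$titrant_nM == 0], 0)
  expect_equal(cu$response[cu$titrant_nM == 1e7], 1, tolerance = 1e-4)
  # default series is a 16-point 1:2 serial dilution
  dflt <- synth_mst(k_d = 45, noise_sd = 0)
  expect_equal(nrow(dflt), 16L)
  expect_equal(unique(round(dflt$titrant_nM[-16] / dflt$titrant_nM[-1])), 2)
})

test_that("depletion isotherm reduces to the hyperbolic limit", {
  kd <- 500
  l <- 10^seq(0, 5, by = 0.25)
  fq <- remkin:::bound_fraction_quadratic(l, kd, probe = 0.01 * kd)
  fh <- remkin:::bound_fraction_hyperbolic(l, kd)
  expect_lt(max(abs(fq - fh)), 0.01)
  # stoichiometry: bound probe never exceeds probe or titrant
  probe <- 25
  fb <- remkin:::bound_fraction_quadratic(l, 45, probe)
  expect_true(all(fb * probe <= pmin(probe, l) + 1e-9))
})

test_that("scrambling preserves composition but changes order", {
  seq <- "KKRRDDEESSTTNNQQAAGGPPVVKKRR"
  sc <- scramble_sequence(seq, seed = 6)
  expect_equal(nchar(sc$sequence), nchar(seq))
  expect_false(sc$sequence == seq)
  expect_equal(count_composition(sc$sequence), count_composition(seq))
})

test_that("composition counting follows the stated convention", {
  expect_equal(count_composition("KRDE"),
               c(positive = 2L, negative = 2L, polar = 0L))
  expect_equal(count_composition(""),
               c(positive = 0L, negative = 0L, polar = 0L))
  # histidine is polar, not positive; G/A/P are neither
  expect_equal(count_composition("HHGAP"),
               c(positive = 0L, negative = 0L, polar = 2L))
  # region is 1-based inclusive
  expect_equal(count_composition("AKRDEA", region = c(2, 5)),
               c(positive = 2L, negative = 2L, polar = 0L))
  expect_error(count_composition("AKR", region = c(2, 9)),
               class = "remkin_domain_error")
  expect_error(count_composition("AKZ"), class = "remkin_domain_error")
  # the convention itself is configurable
  expect_equal(count_composition("HHR", positive = "KRH")[["positive"]], 3L)
})

test_that("charge editing reaches the targets exactly, preserving length", {
  wt <- synth_idr_sequence(seed = 7)
  expect_equal(nchar(wt$sequence), 136L)
  expect_equal(wt$positive_count, 32L)
  expect_equal(wt$negative_count, 30L)
  expect_equal(wt$polar_count, 40L)

  # emulate a basic-residue-depleted replacement (32 -> 15 positives)
  del_pos <- make_charge_edited_variant(wt$sequence, target_positive = 15,
                                        target_negative = 30, seed = 8)
  counts <- count_composition(del_pos$sequence)
  expect_equal(unname(counts["positive"]), 15L)
  expect_equal(unname(counts["negative"]), 30L)
  expect_equal(nchar(del_pos$sequence), 136L)
  # alanine substitution leaves the polar count unchanged
  expect_equal(unname(counts["polar"]), 40L)

  # raising charge works too, and a no-op edit returns the input
  up <- make_charge_edited_variant(wt$sequence, target_positive = 48,
                                   target_negative = 16, seed = 9)
  up_counts <- count_composition(up$sequence)
  expect_equal(unname(up_counts["positive"]), 48L)
  expect_equal(unname(up_counts["negative"]), 16L)
  same <- make_charge_edited_variant(wt$sequence, target_positive = 32,
                                     target_negative = 30, seed = 10)
  expect_identical(same$sequence, wt$sequence)
})

test_that("synthetic crosslink tables have the configured scale", {
  df <- synth_xl_table(n_total = 60, region = c(40, 60), n_region = 25,
                       n_residues = 200, seed = 11)
  expect_equal(nrow(df), 60L)
  xls <- xl_table(df)
  expect_equal(nrow(xls), 60L)  # unique by construction
  touching <- filter_by_region(xls, c(40, 60), mode = "either_end")
  expect_equal(nrow(touching), 25L)
})

test_that("sequences round-trip through FASTA", {
  wt <- synth_idr_sequence(seed = 12, name = "wt_idr")
  sc <- scramble_sequence(wt$sequence, seed = 13, name = "scram_idr")
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta_seq(list(wt, sc), path)
  back <- read_fasta_seq(path)
  expect_identical(names(back), c("wt_idr", "scram_idr"))
  expect_identical(unname(back[1]), wt$sequence)
  expect_identical(unname(back[2]), sc$sequence)
})
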