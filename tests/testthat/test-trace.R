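test_that("proximity ratio handles edge cases and round-trips exactly", {
  expect_equal(compute_fret(c(100, 100), c(100, 100)), c(0.5, 0.5))
  expect_equal(compute_fret(c(100, 50), c(0, 0)), c(0, 0))
  # nonpositive total frames are flagged invalid, not propagated
  e <- compute_fret(c(100, 0), c(100, 0))
  expect_true(is.na(e[2]))
  expect_error(compute_fret(c(0, 0), c(0, 0)),
               class = "remkin_unusable_trace")
  expect_error(compute_fret(1:3, 1:2), class = "remkin_domain_error")

  # noiseless synthesis -> analysis reproduces the configured efficiency
  sch <- kinetic_scheme(n_steps = 3, rate = 0.5, n_rounds = 1)
  tr <- simulate_trajectory(sch, max_time = 1e4, seed = 1)
  cfg <- trace_synth_config(noise_sd = 0, acceptor_bleach_rate = 0,
                            duration = 60)
  trace <- synth_trace(tr, cfg, seed = 1)
  bp <- exit_bp_at(tr, seq_along(trace$donor) / cfg$frame_rate)
  expect_equal(compute_fret(trace), fret_from_exit_bp(bp, cfg))
})

test_that("acceptor bleach step counting", {
  # no bleach: constant acceptor
  flat <- make_step_trace(0.67, len = 200, noise_sd = 10)
  expect_equal(detect_acceptor_bleach(flat)$n_steps, 0L)

  # one bleach step to background at a known frame
  one <- make_step_trace(c(0.67, 0.005), len = 150, noise_sd = 10)
  bl <- detect_acceptor_bleach(one)
  expect_equal(bl$n_steps, 1L)
  expect_lte(abs(bl$bleach_frame - 151L), 1L)

  # two stacked bleach steps (two-acceptor molecule): excluded downstream
  two <- make_step_trace(c(0.8, 0.1, 0.005), len = 120, noise_sd = 10)
  bl2 <- detect_acceptor_bleach(two)
  expect_equal(bl2$n_steps, 2L)
  expect_true(is.na(bl2$bleach_frame))

  # remodelling ejections alone are not bleach-like
  remod <- make_step_trace(c(0.67, 0.42, 0.17), len = 120,
                           donor_levels = c(0.33, 0.58, 0.83),
                           noise_sd = 10)
  expect_equal(detect_acceptor_bleach(remod)$n_steps, 0L)
})

test_that("molecule selection retains only mid-FRET single-bleach traces", {
  cfg <- trace_synth_config(noise_sd = 0, duration = 120,
                            acceptor_bleach_rate = 1 / 40)
  traces <- synth_population(60, class_weights = c(0.3, 0.4, 0.3),
                             scheme = kinetic_scheme(n_rounds = 2),
                             cfg = cfg, seed = 2)
  sel <- select_molecules(traces)
  classes <- vapply(traces, function(t) t$annotations$class, "")
  # precision 1.0 at zero noise: every retained trace is mid-FRET class
  expect_gt(length(sel$retained), 0L)
  expect_true(all(classes[sel$report$selected] == "mid"))
  # traces outside the FRET window carry the right rejection reason
  high_rej <- sel$report[classes == "high" & !sel$report$selected, ]
  expect_true(all(high_rej$reason %in% c("fret_range", "bleach_steps")))

  # explicit out-of-range trace is rejected for its FRET value
  t72 <- make_step_trace(c(0.72, 0.005), len = 150, noise_sd = 5)
  rep72 <- select_molecules(list(t72))$report
  expect_false(rep72$selected)
  expect_identical(rep72$reason, "fret_range")

  empty <- select_molecules(list())
  expect_equal(nrow(empty$report), 0L)
})

test_that("segmentation finds change points at the true frames", {
  # constant trace: no change points
  flat <- make_step_trace(0.6, len = 300, noise_sd = 8)
  expect_equal(length(segment_trace(flat)$change_points), 0L)

  # noiseless two-drop trace: exactly the true frames
  clean <- make_two_drop_trace(cp1 = 50, cp2 = 140, n = 400, noise_sd = 0)
  seg <- segment_trace(clean)
  expect_equal(seg$change_points, c(50L, 140L))
  expect_equal(seg$levels, c(0.67, 0.42, 0.17), tolerance = 1e-12)

  # 3%-of-total noise: >= 95% of change points within 2 frames
  hits <- 0L; total <- 0L
  for (s in 1:100) {
    cp <- withr::with_seed(s, {
      x <- sort(sample(30:370, 2))
      while (diff(x) < 25) x <- sort(sample(30:370, 2))
      x
    })
    tr <- make_two_drop_trace(cp1 = cp[1], cp2 = cp[2], n = 400,
                              noise_sd = 30, seed = s)
    got <- segment_trace(tr)$change_points
    for (true_cp in cp) {
      total <- total + 1L
      if (any(abs(got - true_cp) <= 2)) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("pause-time extraction covers complete, censored and compound drops", {
  # drops starting at frames 50 and 140 at 5 fps: tau_p = 18 s
  clean <- make_two_drop_trace(cp1 = 50, cp2 = 140, n = 400, noise_sd = 0)
  seg <- segment_trace(clean)
  pt <- extract_pause_time(seg, clean)
  expect_equal(pt$tau_p, 18)
  expect_false(pt$censored)
  expect_identical(pt$status, "complete")

  # only one drop observed: censored at the window end
  one <- make_step_trace(c(0.67, 0.42), len = 150,
                         donor_levels = c(0.33, 0.58), noise_sd = 5)
  pt1 <- extract_pause_time(segment_trace(one), one)
  expect_true(pt1$censored)
  expect_identical(pt1$status, "censored")
  expect_equal(pt1$tau_p, (300 + 1 - 151) / 5)

  # a compound (double-ejection) drop has no measurable intermediate
  comp <- make_step_trace(c(0.67, 0.17), len = 150,
                          donor_levels = c(0.33, 0.83), noise_sd = 5)
  ptc <- extract_pause_time(segment_trace(comp), comp)
  expect_identical(ptc$status, "no_intermediate")
  expect_true(is.na(ptc$tau_p))

  # no drop at all
  flat <- make_step_trace(0.67, len = 300, noise_sd = 5)
  expect_identical(extract_pause_time(segment_trace(flat), flat)$status,
                   "no_drop")
})

test_that("pause times are invariant to uniform intensity rescaling", {
  tr <- make_two_drop_trace(cp1 = 60, cp2 = 180, n = 400, noise_sd = 20,
                            seed = 42)
  tr2 <- fret_trace(3.7 * tr$donor, 3.7 * tr$acceptor,
                    frame_rate = tr$frame_rate, molecule_id = "scaled")
  pt1 <- extract_pause_time(segment_trace(tr), tr)
  pt2 <- extract_pause_time(segment_trace(tr2), tr2)
  expect_equal(pt1$tau_p, pt2$tau_p)
})

test_that("reversal detection and population fraction", {
  # monotone non-increasing levels: no reversals
  mono <- make_step_trace(c(0.67, 0.42, 0.17), len = 100,
                          donor_levels = c(0.33, 0.58, 0.83), noise_sd = 5)
  expect_equal(nrow(detect_reversals(segment_trace(mono))), 0L)

  # a sustained +0.25 excursion is detected
  rev_tr <- make_step_trace(c(0.67, 0.42, 0.67, 0.42), len = 100,
                            donor_levels = c(0.33, 0.58, 0.33, 0.58),
                            noise_sd = 5)
  revs <- detect_reversals(segment_trace(rev_tr))
  expect_equal(nrow(revs), 1L)
  expect_equal(revs$delta_e, 0.25, tolerance = 0.02)

  # population fraction tracks the simulator's reversal probability:
  # with two rounds, only a round-1 reversal falls inside an observable
  # inter-ejection window (a reversal after the final round follows the
  # last ejection immediately and spans no frames)
  sch <- kinetic_scheme(n_steps = 4, rate = 0.5, n_eject = 5,
                        n_rounds = 2, reversal_prob = 0.3)
  cfg <- trace_synth_config(noise_sd = 20, acceptor_bleach_rate = 0,
                            duration = 120)
  traces <- lapply(1:200, function(i) {
    synth_trace(simulate_trajectory(sch, max_time = 120,
                                    seed = 3000 + i,
                                    molecule_id = sprintf("m%d", i)),
                cfg, seed = 7000 + i)
  })
  p_true <- 0.3
  frac <- reversal_fraction(traces)
  expect_lt(abs(frac - p_true), 3 * sqrt(p_true * (1 - p_true) / 200) + 0.05)
})

test_that("mixture fit recovers the three FRET populations", {
  cfg <- trace_synth_config(noise_sd = 20, duration = 60,
                            acceptor_bleach_rate = 0)
  traces <- synth_population(300, class_weights = c(0.3, 0.4, 0.3),
                             scheme = kinetic_scheme(n_steps = 6,
                                                     rate = 0.001,
                                                     n_rounds = 1),
                             cfg = cfg, seed = 4)
  me <- molecule_mean_fret(traces)
  fit <- fit_fret_mixture(me, n_components = 3)
  expect_equal(fit$means, c(0.78, 0.67, 0.42), tolerance = 0.02)

  # single component reduces to the sample mean
  one <- fit_fret_mixture(me, n_components = 1)
  expect_equal(one$means, mean(me))
  expect_error(fit_fret_mixture(c(0.5, 0.6), n_components = 3),
               class = "remkin_insufficient_data")
})

test_that("selection never retains a multi-bleach trace", {
  two <- make_step_trace(c(0.8, 0.1, 0.005), len = 120, noise_sd = 10)
  mixed <- list(two,
                make_step_trace(c(0.67, 0.005), len = 150, noise_sd = 10,
                                molecule_id = "ok"))
  rep <- select_molecules(mixed)$report
  expect_false(rep$selected[1])
  expect_identical(rep$reason[1], "bleach_steps")
})

test_that("traces round-trip through the delimited-text format", {
  cfg <- trace_synth_config(noise_sd = 10, duration = 30)
  traces <- synth_population(3, cfg = cfg, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_traces(traces, path)
  back <- read_traces(path, frame_rate = 5)
  expect_equal(length(back), 3L)
  ids <- vapply(traces, `[[`, "", "molecule_id")
  expect_equal(sort(names(back)), sort(ids))
  orig <- traces[[which(ids == names(back)[1])]]
  expect_equal(back[[1]]$donor, orig$donor, tolerance = 1e-8)
})
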