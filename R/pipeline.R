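#' Default stage parameters for the analysis pipeline
#'
#' Central schema of the defaults shared by all stages: 5 frames per
#' second, 0.05 FRET per bp, the [0.55, 0.7] molecule-selection window,
#' the 35-Angstrom crosslink cutoff, the 25 nM probe concentration and
#' the 5-minute pre-injection baseline.  A pipeline run overrides these
#' per stage through the config's `params` blocks, so a figure-level
#' reanalysis is a config change, not a code change.
#'
#' @return Named list of per-stage parameter lists.
#' @export
default_params <- function() {
  list(
    simulate = list(n_molecules = 100, n_steps = 6, rate = 0.1,
                    extra_rate = NULL, n_eject = 5, n_rounds = 2,
                    reversal_prob = 0, max_time = 300),
    `synth-traces` = list(n_molecules = 100,
                          class_weights = c(0.3, 0.4, 0.3),
                          n_steps = 6, rate = 0.1, extra_rate = NULL,
                          n_eject = 5, n_rounds = 2, frame_rate = 5,
                          fret_per_bp = 0.05, noise_sd = 30,
                          total_intensity = 1000,
                          acceptor_bleach_rate = 1 / 150, duration = 300),
    `analyze-traces` = list(input = NULL, frame_rate = 5,
                            e_range = c(0.55, 0.7)),
    `fit-dwell` = list(input = NULL, model = "auto"),
    `unmasking-sweep` = list(n_steps = 6, extra_rate = 1,
                             rate_grid = c(0.01, 0.1, 1, 10, 100),
                             n_per_point = 2000),
    `fit-rtfa` = list(input = NULL, f_lim = 1, k_rtfa = 0.2,
                      pre_injection = 5, noise_sd = 0.01),
    `fit-mst` = list(input = NULL, k_d = 45, probe = 25, amplitude = 1,
                     baseline = 0, noise_sd = 0.02, n_replicates = 3),
    `xl-count` = list(input = NULL, region = "C1a_xl",
                      mode = "either_end"),
    `xl-satisfy` = list(input = NULL, structure = NULL, cutoff = 35),
    `make-idr-variants` = list(input = NULL, target_positive = 15,
                               target_negative = 30)
  )
}

pipeline_stages <- function() names(default_params())

#' Pipeline run configuration
#'
#' @param seed top-level integer seed; every stochastic stage draws from a
#'   child stream derived from it, so identical configs give identical
#'   outputs.
#' @param stages character vector of stage names to run, in order (see
#'   [default_params] for the available stages).
#' @param params named list of per-stage parameter overrides.
#' @param outdir output directory.
#' @param verbose print per-stage progress.
#' @return An object of class `run_config`.
#' @export
run_config <- function(seed = 1, stages = character(0), params = list(),
                       outdir = tempfile("remkin_run_"), verbose = FALSE) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop_remkin("config_error", "field 'seed' must be a single integer")
  }
  bad <- setdiff(stages, pipeline_stages())
  if (length(bad)) {
    stop_remkin("config_error",
                paste("unknown stage(s):", paste(bad, collapse = ", ")))
  }
  bad_p <- setdiff(names(params), pipeline_stages())
  if (length(bad_p)) {
    stop_remkin("config_error",
                paste("params for unknown stage(s):", paste(bad_p, collapse = ", ")))
  }
  merged <- default_params()
  for (st in names(params)) {
    for (key in names(params[[st]])) {
      if (!key %in% names(merged[[st]])) {
        stop_remkin("config_error",
                    sprintf("unknown parameter '%s' for stage '%s'", key, st))
      }
      merged[[st]][[key]] <- params[[st]][[key]]
    }
  }
  structure(list(seed = as.integer(seed), stages = stages, params = merged,
                 outdir = outdir, verbose = isTRUE(verbose)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file with fields `seed`, `stages`, `params`, `outdir`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("seed", "stages", "params", "outdir", "verbose")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    stop_remkin("config_error",
                paste("unknown config field(s):", paste(bad, collapse = ", ")))
  }
  run_config(seed = if (is.null(y$seed)) 1 else y$seed,
             stages = as.character(y$stages %||% character(0)),
             params = y$params %||% list(),
             outdir = y$outdir %||% tempfile("remkin_run_"),
             verbose = y$verbose %||% FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the configured analysis pipeline
#'
#' Validates the configuration, executes the requested stages in order and
#' writes a manifest listing every output file with its MD5 checksum and
#' the checksum of the configuration itself.  Stage failures abort with a
#' classed error after the manifest collected so far has been written.
#'
#' @param config a [run_config] (or path to a YAML config).
#' @return Invisibly, a list with `status` (0 on success), `outdir` and
#'   the `manifest` data frame.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(config$outdir, "config.yaml")
  yaml::write_yaml(list(seed = config$seed, stages = config$stages,
                        params = config$params), cfg_path)
  outputs <- character(0)
  log_stage <- function(st, msg) {
    if (config$verbose) message(sprintf("[%s] %s", st, msg))
  }
  status <- 0L
  err <- NULL
  for (i in seq_along(config$stages)) {
    st <- config$stages[i]
    p <- config$params[[st]]
    seed_st <- child_seed(config$seed, i * 1000L)
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch({
      outputs <- c(outputs, run_stage(st, p, seed_st, config$outdir))
      TRUE
    }, error = function(e) e)
    if (!isTRUE(res)) {
      status <- 1L
      err <- res
      break
    }
    log_stage(st, sprintf("done in %.2f s", proc.time()[["elapsed"]] - t0))
  }
  files <- c(cfg_path, outputs)
  manifest <- data.frame(
    file = basename(files),
    md5 = unname(tools::md5sum(files)),
    bytes = file.size(files),
    stringsAsFactors = FALSE
  )
  utils::write.table(manifest, file.path(config$outdir, "manifest.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  if (status != 0L) stop(err)
  invisible(list(status = status, outdir = config$outdir,
                 manifest = manifest))
}

# dispatch a single stage; returns the paths of the files it wrote
run_stage <- function(stage, p, seed, outdir) {
  out <- function(name) file.path(outdir, name)
  switch(
    stage,
    "simulate" = {
      scheme <- kinetic_scheme(n_steps = p$n_steps, rate = p$rate,
                               extra_rate = p$extra_rate,
                               n_eject = p$n_eject, n_rounds = p$n_rounds,
                               reversal_prob = p$reversal_prob)
      trajs <- lapply(seq_len(p$n_molecules), function(i) {
        simulate_trajectory(scheme, max_time = p$max_time,
                            seed = child_seed(seed, i),
                            molecule_id = sprintf("mol_%04d", i))
      })
      write_trajectory_events(trajs, out("trajectories.tsv"))
      out("trajectories.tsv")
    },
    "synth-traces" = {
      scheme <- kinetic_scheme(n_steps = p$n_steps, rate = p$rate,
                               extra_rate = p$extra_rate,
                               n_eject = p$n_eject, n_rounds = p$n_rounds)
      cfg <- trace_synth_config(frame_rate = p$frame_rate,
                                fret_per_bp = p$fret_per_bp,
                                noise_sd = p$noise_sd,
                                total_intensity = p$total_intensity,
                                acceptor_bleach_rate = p$acceptor_bleach_rate,
                                duration = p$duration)
      traces <- synth_population(p$n_molecules,
                                 class_weights = p$class_weights,
                                 scheme = scheme, cfg = cfg, seed = seed)
      write_traces(traces, out("traces.tsv"))
      truth <- lapply(traces, function(tr) {
        a <- tr$annotations
        list(molecule_id = tr$molecule_id, class = a$class,
             true_tau_p = a$true_tau_p %||% NA,
             bleach_frame = if (is.na(a$bleach_frame)) NULL else a$bleach_frame)
      })
      yaml::write_yaml(truth, out("traces_truth.yaml"))
      c(out("traces.tsv"), out("traces_truth.yaml"))
    },
    "analyze-traces" = {
      input <- p$input %||% out("traces.tsv")
      traces <- read_traces(input, frame_rate = p$frame_rate)
      an <- analyze_traces(traces, e_range = p$e_range)
      utils::write.table(an$results, out("trace_results.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      yaml::write_yaml(an$summary, out("trace_summary.yaml"))
      dw <- pause_times_from_analysis(an, condition = "pipeline")
      write_dwell_times(dw, out("dwell_times.tsv"))
      c(out("trace_results.tsv"), out("trace_summary.yaml"),
        out("dwell_times.tsv"))
    },
    "fit-dwell" = {
      input <- p$input %||% out("dwell_times.tsv")
      dw <- read_dwell_times(input)
      if (is.list(dw) && !inherits(dw, "dwell_times")) dw <- dw[[1L]]
      fit <- fit_dwell(dw, model = p$model)
      write_fit_report(fit, out("dwell_fit.yaml"))
      out("dwell_fit.yaml")
    },
    "unmasking-sweep" = {
      sw <- unmasking_sweep(p$n_steps, p$extra_rate, p$rate_grid,
                            n_per_point = p$n_per_point, seed = seed)
      utils::write.table(sw, out("unmasking_sweep.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      out("unmasking_sweep.tsv")
    },
    "fit-rtfa" = {
      curve <- if (!is.null(p$input)) read_rtfa_curve(p$input, p$pre_injection)
               else synth_rtfa(p$f_lim, p$k_rtfa,
                               pre_injection = p$pre_injection,
                               noise_sd = p$noise_sd, seed = seed)
      fit <- fit_rtfa(curve)
      write_fit_report(fit, out("rtfa_fit.yaml"))
      out("rtfa_fit.yaml")
    },
    "fit-mst" = {
      curve <- if (!is.null(p$input)) read_binding_curve(p$input, p$probe)
               else synth_mst(p$k_d, probe = p$probe,
                              amplitude = p$amplitude,
                              baseline = p$baseline, noise_sd = p$noise_sd,
                              n_replicates = p$n_replicates, seed = seed)
      fit <- fit_binding(curve)
      write_fit_report(fit, out("binding_fit.yaml"))
      out("binding_fit.yaml")
    },
    "xl-count" = {
      xls <- if (!is.null(p$input)) read_xl_table(p$input)
             else xl_table(synth_xl_table(seed = seed))
      sub <- filter_by_region(xls, p$region, mode = p$mode)
      yaml::write_yaml(list(n_total = nrow(xls), region = p$region,
                            mode = p$mode, n_in_region = nrow(sub)),
                       out("xl_counts.yaml"))
      out("xl_counts.yaml")
    },
    "xl-satisfy" = {
      xls <- if (!is.null(p$input)) read_xl_table(p$input)
             else xl_table(synth_xl_table(seed = seed))
      model <- if (!is.null(p$structure)) read_structure(p$structure)
               else synth_structure(1912, seed = child_seed(seed, 2))
      rep <- satisfaction_report(xls, model, cutoff = p$cutoff)
      utils::write.table(rep$table, out("xl_distances.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      yaml::write_yaml(list(fraction_satisfied = rep$fraction_satisfied,
                            fraction_all = rep$fraction_all,
                            n_resolved = rep$n_resolved,
                            n_unresolved = rep$n_unresolved,
                            cutoff = rep$cutoff),
                       out("xl_satisfaction.yaml"))
      c(out("xl_distances.tsv"), out("xl_satisfaction.yaml"))
    },
    "make-idr-variants" = {
      wt <- if (!is.null(p$input)) {
        s <- read_fasta_seq(p$input)
        idr_variant(names(s)[1L], s[[1L]])
      } else synth_idr_sequence(seed = child_seed(seed, 1), name = "wt")
      scram <- scramble_sequence(wt$sequence, seed = child_seed(seed, 2),
                                 name = "scram")
      del_pos <- make_charge_edited_variant(
        wt$sequence, target_positive = p$target_positive,
        target_negative = wt$negative_count,
        seed = child_seed(seed, 3), name = "del_plus")
      del_neg <- make_charge_edited_variant(
        wt$sequence, target_positive = wt$positive_count,
        target_negative = p$target_negative,
        seed = child_seed(seed, 4), name = "del_minus")
      write_fasta_seq(list(wt, scram, del_pos, del_neg),
                      out("idr_variants.fasta"))
      out("idr_variants.fasta")
    },
    stop_remkin("config_error", paste("unknown stage:", stage))
  )
}

#' Validate declared input files
#'
#' Checks that each file parses as its declared kind and reports row
#' counts and basic span statistics.
#'
#' @param paths file paths.
#' @param kinds declared kinds, one per path: `"traces"`, `"dwell"`,
#'   `"xl"`, `"fasta"`, `"structure"`, `"rtfa"`, `"mst"`,
#'   `"trajectory"`.
#' @return Data frame with `path`, `kind`, `ok`, `n_rows`, `detail`.
#' @export
validate_inputs <- function(paths, kinds) {
  if (length(paths) != length(kinds)) {
    stop_remkin("domain_error", "paths and kinds must have equal length")
  }
  known <- c("traces", "dwell", "xl", "fasta", "structure", "rtfa", "mst",
             "trajectory")
  bad <- setdiff(kinds, known)
  if (length(bad)) {
    stop_remkin("domain_error",
                paste("unknown kind(s):", paste(bad, collapse = ", ")))
  }
  rows <- lapply(seq_along(paths), function(i) {
    res <- tryCatch({
      switch(
        kinds[i],
        "traces" = {
          tr <- read_traces(paths[i])
          c(length(tr), sprintf("%d molecules", length(tr)))
        },
        "dwell" = {
          dw <- read_dwell_times(paths[i])
          if (inherits(dw, "dwell_times")) dw <- list(dw)
          n <- sum(vapply(dw, function(x) length(x$values), numeric(1)))
          rng <- range(unlist(lapply(dw, `[[`, "values")))
          c(n, sprintf("tau range [%.3g, %.3g] s", rng[1L], rng[2L]))
        },
        "xl" = {
          x <- read_xl_table(paths[i])
          c(nrow(x), sprintf("%d unique pairs, span %d-%d", nrow(x),
                             min(x$pos_i), max(x$pos_j)))
        },
        "fasta" = {
          s <- read_fasta_seq(paths[i])
          c(length(s), sprintf("lengths %s",
                               paste(nchar(s), collapse = "/")))
        },
        "structure" = {
          m <- read_structure(paths[i])
          c(nrow(m$coords), sprintf("residues %d-%d", min(m$positions),
                                    max(m$positions)))
        },
        "rtfa" = {
          cu <- read_rtfa_curve(paths[i])
          c(nrow(cu), sprintf("time span %.3g-%.3g min",
                              min(cu$time_min), max(cu$time_min)))
        },
        "mst" = {
          cu <- read_binding_curve(paths[i])
          c(nrow(cu), sprintf("titrant %.3g-%.3g nM",
                              min(cu$titrant_nM), max(cu$titrant_nM)))
        },
        "trajectory" = {
          ev <- read_trajectory_events(paths[i])
          c(nrow(ev), sprintf("%d molecules",
                              length(unique(ev$molecule_id))))
        }
      )
    }, error = function(e) c(NA, conditionMessage(e)))
    data.frame(path = paths[i], kind = kinds[i], ok = !is.na(res[1L]),
               n_rows = as.numeric(res[1L]), detail = res[2L],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
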