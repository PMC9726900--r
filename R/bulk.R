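#' Fit the asymptotic-exponential remodelling curve
#'
#' Nonlinear least-squares fit of y = F_lim (1 - exp(-k t)) to the
#' post-injection part of a real-time fluorescence assay, with t measured
#' from the ATP injection.
#'
#' @param curve an [rtfa_curve] (or data frame with `time_min`,
#'   `fluorescence` and an `injection_time` attribute).
#' @param injection_time override for the injection time (min).
#' @return An object of class `rtfa_fit`: `f_lim`, `k_rtfa` (min^-1),
#'   standard errors, residual standard deviation and point count.
#' @export
fit_rtfa <- function(curve, injection_time = NULL) {
  if (is.null(injection_time)) {
    injection_time <- attr(curve, "injection_time")
    if (is.null(injection_time)) injection_time <- 0
  }
  post <- curve[curve$time_min > injection_time, , drop = FALSE]
  if (nrow(post) < 5L) {
    stop_remkin("insufficient_data", "need >= 5 post-injection points")
  }
  tt <- post$time_min - injection_time
  y <- post$fluorescence
  if (diff(range(y)) <= .Machine$double.eps * max(abs(y), 1)) {
    stop_remkin("fit_failure",
                "flat curve: rate constant is unidentifiable")
  }
  f0 <- max(y)
  half_idx <- which(y >= f0 / 2)[1L]
  k0 <- if (!is.na(half_idx) && tt[half_idx] > 0) log(2) / tt[half_idx] else 1 / mean(tt)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ f_lim * (1 - exp(-k * tt)),
      start = list(f_lim = f0, k = k0),
      lower = c(f_lim = 0, k = 1e-10),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)
    ),
    error = function(e) {
      stop_remkin("fit_failure",
                  paste("RTFA fit did not converge:", conditionMessage(e)))
    }
  )
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(NA_real_, NA_real_))
  structure(
    list(f_lim = unname(est["f_lim"]), k_rtfa = unname(est["k"]),
         se = c(f_lim = unname(se[1L]), k_rtfa = unname(se[2L])),
         uncertainty = c(f_lim = unname(se[1L] / est["f_lim"]),
                         k_rtfa = unname(se[2L] / est["k"])),
         resid_sd = stats::sd(stats::resid(fit)), n = nrow(post)),
    class = "rtfa_fit"
  )
}

#' @export
print.rtfa_fit <- function(x, ...) {
  cat(sprintf("<rtfa_fit> F_lim = %.4g, k_RTFA = %.4g min^-1 (n = %d)\n",
              x$f_lim, x$k_rtfa, x$n))
  invisible(x)
}

#' Subtract a no-enzyme control curve
#'
#' @param curve,control [rtfa_curve] objects on the same time base.
#' @return An [rtfa_curve] with the control fluorescence subtracted.
#' @export
subtract_control <- function(curve, control) {
  if (nrow(curve) != nrow(control) ||
      any(abs(curve$time_min - control$time_min) > 1e-9)) {
    stop_remkin("domain_error", "curve and control must share a time base")
  }
  rtfa_curve(curve$time_min, curve$fluorescence - control$fluorescence,
             injection_time = attr(curve, "injection_time"))
}

#' Fit a 1:1 binding isotherm
#'
#' Fits response = baseline + amplitude x fraction bound.  The default
#' `"quadratic"` model computes the bound fraction from the exact 1:1
#' equilibrium with probe depletion (appropriate when the probe
#' concentration is comparable to the dissociation constant); the
#' `"hyperbolic"` model assumes probe << K_D.  Replicates are fitted
#' jointly with shared parameters.
#'
#' @param curve a [binding_curve] (attribute `probe` gives the labelled
#'   probe concentration for the quadratic model).
#' @param model `"quadratic"` (default) or `"hyperbolic"`.
#' @param probe override for the probe concentration (nM).
#' @return An object of class `binding_fit`: `k_d` (nM), `amplitude`,
#'   `baseline`, standard errors and the model used.
#' @export
fit_binding <- function(curve, model = c("quadratic", "hyperbolic"),
                        probe = NULL) {
  model <- match.arg(model)
  if (is.null(probe)) probe <- attr(curve, "probe")
  if (model == "quadratic" && (is.null(probe) || probe <= 0)) {
    stop_remkin("domain_error", "quadratic model needs a positive probe concentration")
  }
  if (nrow(curve) < 8L) {
    stop_remkin("insufficient_data", "need >= 8 titration points")
  }
  l <- curve$titrant_nM
  y <- curve$response
  if (stats::sd(y) == 0 || diff(range(y)) < 1e-12 * max(abs(y), 1)) {
    stop_remkin("fit_failure", "zero-amplitude curve: K_D is unidentifiable")
  }
  base0 <- min(y); amp0 <- diff(range(y))
  # titrant concentration where the response is nearest half-maximal
  half <- base0 + amp0 / 2
  kd0 <- max(l[which.min(abs(y - half))], min(l[l > 0]))
  fb_fun <- if (model == "quadratic") {
    function(l, kd) bound_fraction_quadratic(l, kd, probe)
  } else {
    function(l, kd) bound_fraction_hyperbolic(l, kd)
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ baseline + amplitude * fb_fun(l, kd),
      start = list(baseline = base0, amplitude = amp0, kd = kd0),
      lower = c(baseline = -Inf, amplitude = -Inf, kd = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12)
    ),
    error = function(e) {
      stop_remkin("fit_failure",
                  paste("binding fit did not converge:", conditionMessage(e)))
    }
  )
  est <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, 3L))
  kd <- unname(est["kd"])
  titrated <- range(l[l > 0])
  if (kd < titrated[1L] || kd > titrated[2L]) {
    warning(sprintf("K_D (%.3g nM) lies outside the titrated range [%.3g, %.3g] nM: extrapolation",
                    kd, titrated[1L], titrated[2L]))
  }
  structure(
    list(k_d = kd, amplitude = unname(est["amplitude"]),
         baseline = unname(est["baseline"]),
         se = c(baseline = unname(se[1L]), amplitude = unname(se[2L]),
                k_d = unname(se[3L])),
         uncertainty = c(k_d = unname(se[3L] / kd)),
         model = model, probe = probe, n = nrow(curve)),
    class = "binding_fit"
  )
}

#' @export
print.binding_fit <- function(x, ...) {
  cat(sprintf("<binding_fit> K_D = %.4g nM (%s isotherm, probe %.3g nM, n = %d)\n",
              x$k_d, x$model, if (is.null(x$probe)) NA else x$probe, x$n))
  invisible(x)
}

#' Ratio of two fitted parameters with propagated uncertainty
#'
#' First-order (delta-method) propagation assuming independent errors:
#' se(a/b) = |a/b| sqrt((se_a/a)^2 + (se_b/b)^2).
#'
#' @param a,b parameter estimates (numerator, denominator).
#' @param se_a,se_b their standard errors.
#' @return A list with `value` and `se`.
#' @export
fold_change <- function(a, b, se_a = 0, se_b = 0) {
  if (!is.numeric(a) || !is.numeric(b) || b == 0) {
    stop_remkin("domain_error", "a and b must be numeric with b != 0")
  }
  value <- a / b
  se <- if (a == 0) abs(se_a / b)
        else abs(value) * sqrt((se_a / a)^2 + (se_b / b)^2)
  list(value = value, se = se)
}

#' Read/write bulk-assay curves
#'
#' RTFA curves as `time_min,fluorescence` CSV; binding curves as
#' `titrant_nM,response,replicate` CSV.
#'
#' @param path file path.
#' @param injection_time injection time (min) stored on the curve.
#' @export
read_rtfa_curve <- function(path, injection_time = 5) {
  df <- utils::read.table(path, header = TRUE, sep = ",")
  need <- c("time_min", "fluorescence")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_remkin("format_error",
                paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  rtfa_curve(df$time_min, df$fluorescence, injection_time = injection_time)
}

#' @rdname read_rtfa_curve
#' @param curve the curve object to write.
#' @export
write_rtfa_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_rtfa_curve
#' @param probe probe concentration (nM) stored on the curve.
#' @export
read_binding_curve <- function(path, probe = 25) {
  df <- utils::read.table(path, header = TRUE, sep = ",")
  need <- c("titrant_nM", "response")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_remkin("format_error",
                paste("missing column(s):", paste(miss, collapse = ", ")))
  }
  if (is.null(df$replicate)) df$replicate <- 1L
  binding_curve(df$titrant_nM, df$response, replicate = df$replicate,
                probe = probe)
}

#' @rdname read_rtfa_curve
#' @export
write_binding_curve <- function(curve, path) {
  utils::write.table(as.data.frame(curve), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
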