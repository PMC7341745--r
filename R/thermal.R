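# Thermal-shift analysis of differential scanning fluorimetry curves.

#' Fit the melting midpoint of a DSF curve
#'
#' Least-squares fit of the Boltzmann sigmoid
#' `f(T) = f_min + (f_max - f_min) / (1 + exp((T_half - T)/s))`,
#' initialized from the grid point of maximum slope. Falling curves are
#' handled by the sign of the fitted amplitude.
#'
#' @param curve a `melt_curve` tibble (`temperature_C`, `fluorescence`),
#'   at least 6 points spanning the transition.
#' @param slope_init initial slope width, degrees C.
#' @return object of class `melt_fit` with `t_half`, `slope`, `f_min`,
#'   `f_max`, the `nls` fit, and the data; `tidy()`/`glance()` methods
#'   summarise it.
#' @export
fit_t_half <- function(curve, slope_init = 2) {
  Tv <- curve$temperature_C
  Fv <- curve$fluorescence
  if (length(Tv) < 6) abort("need at least 6 points to fit a transition")
  dFdT <- diff(Fv) / diff(Tv)
  i0 <- which.max(abs(dFdT))
  start <- list(t_half = mean(Tv[i0 + 0:1]), s = slope_init,
                f_min = min(Fv), f_max = max(Fv))
  if (dFdT[i0] < 0) {  # falling transition
    start$f_min <- max(Fv)
    start$f_max <- min(Fv)
  }
  fit <- NULL
  last_err <- NULL
  for (jit in list(c(0, 1), c(0.5, 1), c(-0.5, 1), c(0, 0.5), c(0, 2))) {
    st <- start
    st$t_half <- st$t_half + jit[1]
    st$s <- st$s * jit[2]
    fit <- tryCatch(
      minpack.lm::nlsLM(
        Fv ~ f_min + (f_max - f_min) / (1 + exp((t_half - Tv) / s)),
        start = st, control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) {
        last_err <<- conditionMessage(e)
        NULL
      })
    if (!is.null(fit)) break
  }
  if (is.null(fit)) {
    abort(paste0("melt-curve fit did not converge: ", last_err,
                 sprintf(" [init t_half=%.2f, s=%.2f]", start$t_half,
                         start$s)))
  }
  cf <- coef(fit)
  structure(list(t_half = unname(cf["t_half"]), slope = unname(cf["s"]),
                 f_min = unname(cf["f_min"]), f_max = unname(cf["f_max"]),
                 fit = fit, data = curve),
            class = "melt_fit")
}

#' @export
print.melt_fit <- function(x, ...) {
  cat(sprintf("<melt_fit> T1/2 = %.2f C (slope %.2f C)\n", x$t_half,
              x$slope))
  invisible(x)
}

#' @export
tidy.melt_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2])
}

#' @export
glance.melt_fit <- function(x, ...) {
  r <- stats::resid(x$fit)
  tibble(t_half = x$t_half, slope = x$slope,
         sigma = sqrt(sum(r^2) / (length(r) - 4)),
         nobs = length(r))
}

as_t_half_values <- function(x) {
  if (is.numeric(x)) return(x)
  if (inherits(x, "melt_fit")) return(x$t_half)
  if (is.data.frame(x)) {
    reps <- if ("replicate" %in% names(x)) unique(x$replicate) else 1
    return(vapply(reps, function(r) {
      cur <- if ("replicate" %in% names(x)) x[x$replicate == r, ] else x
      fit_t_half(cur)$t_half
    }, numeric(1)))
  }
  if (is.list(x)) return(vapply(x, function(e) as_t_half_values(e)[1],
                                numeric(1)))
  abort("cannot interpret replicates: give T1/2 values, curves, or fits")
}

#' Thermal shift between apo and ligand-bound melt curves
#'
#' `delta = mean(T1/2 holo) - mean(T1/2 apo)`; the shift is called
#' significant when it exceeds the sum of the two standard deviations
#' (sample sd over replicates, 0 for a single replicate). Positive delta
#' means stabilization by the ligand.
#'
#' @param apo,holo replicate `T1/2` values (numeric), melt-curve tibbles
#'   (with a `replicate` column), or lists of either.
#' @return object of class `thermal_shift_result` with `t_half_apo`,
#'   `t_half_holo`, `sd_apo`, `sd_holo`, `delta`, `significant`.
#' @export
thermal_shift <- function(apo, holo) {
  a <- as_t_half_values(apo)
  h <- as_t_half_values(holo)
  if (length(a) < 1 || length(h) < 1) abort("need at least one replicate each")
  sda <- if (length(a) > 1) sd(a) else 0
  sdh <- if (length(h) > 1) sd(h) else 0
  delta <- mean(h) - mean(a)
  structure(list(t_half_apo = mean(a), t_half_holo = mean(h),
                 sd_apo = sda, sd_holo = sdh, delta = delta,
                 significant = delta > sda + sdh),
            class = "thermal_shift_result")
}

#' @export
print.thermal_shift_result <- function(x, ...) {
  cat(sprintf(
    "<thermal_shift> apo %.2f +/- %.2f C, holo %.2f +/- %.2f C\n  delta = %+.2f C (%s)\n",
    x$t_half_apo, x$sd_apo, x$t_half_holo, x$sd_holo, x$delta,
    if (x$significant) "significant" else "not significant"))
  invisible(x)
}

#' @export
tidy.thermal_shift_result <- function(x, ...) {
  tibble(condition = c("apo", "holo"),
         t_half = c(x$t_half_apo, x$t_half_holo),
         sd = c(x$sd_apo, x$sd_holo))
}

#' @export
glance.thermal_shift_result <- function(x, ...) {
  tibble(delta = x$delta, significant = x$significant)
}
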