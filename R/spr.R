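#' Kinetic parameters of a 1:1 interaction
#'
#' @param ka Association rate constant (1/(M s)).
#' @param kd Dissociation rate constant (1/s).
#' @param Rmax Saturation response (RU).
#' @param kt Mass-transport coefficient (RU/(M s)); `Inf` means no
#'   transport limitation (pure Langmuir kinetics).
#' @param R0 Initial response (RU).
#' @return A `kinetic_params` list.
#' @export
kinetic_params <- function(ka, kd, Rmax, kt = Inf, R0 = 0) {
  if (any(c(ka, kd, Rmax) <= 0) || kt <= 0)
    rlang::abort("ka, kd, Rmax and kt must be positive")
  structure(list(ka = ka, kd = kd, Rmax = Rmax, kt = kt, R0 = R0),
            class = "kinetic_params")
}

#' Equilibrium dissociation constant from rate constants
#'
#' @param ka Association rate constant (1/(M s)); must be > 0.
#' @param kd Dissociation rate constant (1/s).
#' @return KD in molar, `kd / ka`.
#' @export
equilibrium_kd <- function(ka, kd) {
  if (any(ka <= 0)) rlang::abort("ka must be positive")
  kd / ka
}

# Closed-form Langmuir 1:1 (kt = Inf). General solution with initial
# response R0: R(t) = Req + (R0 - Req) * exp(-(ka*C + kd) * t)
langmuir_response <- function(t, ka, kd, Rmax, conc, R0 = 0) {
  kobs <- ka * conc + kd
  req <- if (conc > 0) ka * conc * Rmax / kobs else 0
  req + (R0 - req) * exp(-kobs * t)
}

# Quasi-steady two-compartment mass-transport model:
# dR/dt = (ka*C*(Rmax - R) - kd*R) / (1 + ka*(Rmax - R)/kt)
mt_phase <- function(times, R0, conc, p) {
  if (length(times) == 1) return(R0)
  deriv <- function(t, y, parms) {
    free <- parms$Rmax - y[1]
    list((parms$ka * parms$conc * free - parms$kd * y[1]) /
           (1 + parms$ka * free / parms$kt))
  }
  # lsoda occasionally reports that machine precision limits the local
  # error below rtol; the solution is still accurate, so that advisory is
  # muffled rather than surfaced on every fit iteration
  out <- withCallingHandlers(
    deSolve::lsoda(c(R = R0), times, deriv,
                   parms = list(ka = p$ka, kd = p$kd, Rmax = p$Rmax,
                                kt = p$kt, conc = conc),
                   rtol = 1e-8, atol = 1e-8, verbose = FALSE),
    warning = function(w) {
      if (grepl("precision|Returning early|TOLSF|excessive|maxsteps",
                conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  as.numeric(out[, "R"])
}

#' Simulate a 1:1 sensorgram with optional mass-transport limitation
#'
#' Association phase (analyte concentration `conc`) runs until `t_assoc`,
#' dissociation (concentration zero) thereafter. With `kt = Inf` the
#' closed-form Langmuir solution is used; otherwise the quasi-steady
#' two-compartment transport model
#' `dR/dt = (ka C (Rmax - R) - kd R) / (1 + ka (Rmax - R) / kt)`
#' is integrated with adaptive stepping.
#'
#' @param params A [kinetic_params()] object.
#' @param conc Analyte concentration (M).
#' @param times Time grid (s), strictly increasing, spanning both phases.
#' @param t_assoc End of the association phase (s).
#' @return Tibble `(time, response, conc)` with attribute `t_assoc`.
#' @export
simulate_sensorgram <- function(params, conc, times, t_assoc) {
  stopifnot(inherits(params, "kinetic_params"))
  if (any(diff(times) <= 0)) rlang::abort("times must be strictly increasing")
  if (conc < 0) rlang::abort("concentration must be non-negative")
  ta <- times[times <= t_assoc]
  td <- times[times > t_assoc]
  if (is.infinite(params$kt)) {
    ra <- langmuir_response(ta, params$ka, params$kd, params$Rmax, conc,
                            params$R0)
    r_end <- langmuir_response(t_assoc, params$ka, params$kd, params$Rmax,
                               conc, params$R0)
    rd <- r_end * exp(-params$kd * (td - t_assoc))
  } else {
    ra <- mt_phase(unique(c(0, ta)), params$R0, conc, params)
    if (ta[1] != 0 || length(ta) < length(unique(c(0, ta)))) ra <- ra[-1]
    r_end <- mt_phase(c(0, t_assoc), params$R0, conc, params)[2]
    rd <- if (length(td) > 0)
      mt_phase(unique(c(t_assoc, td)), r_end, 0, params)[-1] else numeric(0)
  }
  structure(tibble(time = times, response = c(ra, rd), conc = conc),
            t_assoc = t_assoc)
}

#' Globally fit 1:1 kinetics to a set of sensorgrams
#'
#' Least-squares fit of (ka, kd, Rmax[, kt]) shared across all
#' concentrations, in log-parameter space, by Levenberg-Marquardt from
#' multiple seeded log-uniform starts; the best-of-starts fit is returned.
#'
#' @param data Tibble with columns `time`, `response`, `conc` (one curve
#'   per distinct concentration/replicate).
#' @param t_assoc End of the association phase (s).
#' @param model `"langmuir"` (kt fixed at `Inf`) or `"mass_transport"`.
#' @param n_starts Number of random starts (default 8).
#' @param seed Seed for the start draws.
#' @return A `kinetic_fit`: list with `params` ([kinetic_params()]), `KD`
#'   (`kd/ka`, M), `sse`, `residuals`, `fitted` (input data plus `fitted`
#'   column), `starts` (per-start diagnostics tibble), `converged`.
#' @export
fit_sensorgrams <- function(data, t_assoc, model = c("mass_transport", "langmuir"),
                            n_starts = 8, seed = 1) {
  model <- match.arg(model)
  stopifnot(all(c("time", "response", "conc") %in% names(data)))
  if (!"curve" %in% names(data))
    data$curve <- match(data$conc, unique(data$conc))
  curves <- unique(data$curve)
  if (length(unique(data$conc)) < 2)
    rlang::warn("fitting a single concentration: rate constants may be poorly determined")

  predict_all <- function(p) {
    unlist(purrr::map(curves, function(cv) {
      d <- data[data$curve == cv, ]
      kp <- kinetic_params(p[["ka"]], p[["kd"]], p[["Rmax"]],
                           if (model == "langmuir") Inf else p[["kt"]])
      simulate_sensorgram(kp, d$conc[1], d$time, t_assoc)$response
    }))
  }
  obs <- unlist(purrr::map(curves, ~data$response[data$curve == .x]))

  par_names <- c("ka", "kd", "Rmax", if (model == "mass_transport") "kt")
  resid_fn <- function(logp) {
    p <- stats::setNames(exp(logp), par_names)
    tryCatch(predict_all(p) - obs, error = function(e) rep(1e6, length(obs)))
  }

  rmax_guess <- max(data$response)
  starts <- withr::with_seed(seed, purrr::map(seq_len(n_starts), function(i) {
    if (i == 1)
      return(log(c(ka = 1e6, kd = 1e-3, Rmax = rmax_guess * 1.2,
                   kt = 1e8)[par_names]))
    log(c(ka = 10^stats::runif(1, 4, 7), kd = 10^stats::runif(1, -5, -1),
          Rmax = rmax_guess * stats::runif(1, 1, 3),
          kt = 10^stats::runif(1, 6, 10))[par_names])
  }))

  runs <- purrr::map(starts, function(s0) {
    tryCatch({
      fit <- minpack.lm::nls.lm(par = s0, fn = resid_fn,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 200, ftol = 1e-12, ptol = 1e-12))
      list(fit = fit, sse = sum(fit$fvec^2), ok = fit$info %in% 1:4)
    }, error = function(e) list(fit = NULL, sse = Inf, ok = FALSE))
  })
  sses <- vapply(runs, function(r) r$sse, numeric(1))
  if (all(!vapply(runs, function(r) r$ok, logical(1))))
    rlang::abort(paste0("no start converged; best SSE ", min(sses)))
  best <- runs[[which.min(ifelse(vapply(runs, function(r) r$ok, logical(1)),
                                 sses, Inf))]]
  p <- stats::setNames(exp(best$fit$par), par_names)
  kp <- kinetic_params(p[["ka"]], p[["kd"]], p[["Rmax"]],
                       if (model == "langmuir") Inf else p[["kt"]])
  fitted_data <- data
  fitted_data$fitted <- NA_real_
  for (cv in curves) {
    d <- data[data$curve == cv, ]
    fitted_data$fitted[data$curve == cv] <-
      simulate_sensorgram(kp, d$conc[1], d$time, t_assoc)$response
  }
  structure(list(
    params = kp, KD = equilibrium_kd(kp$ka, kp$kd), model = model,
    sse = best$sse, t_assoc = t_assoc,
    residuals = fitted_data$response - fitted_data$fitted,
    fitted = fitted_data,
    starts = tibble(start = seq_len(n_starts), sse = sses,
                    converged = vapply(runs, function(r) r$ok, logical(1))),
    converged = best$fit$info %in% 1:4
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("<kinetic_fit> 1:1", x$model, "model\n")
  cat(sprintf("  ka = %.3g /M/s, kd = %.3g /s, Rmax = %.3g RU%s\n",
              x$params$ka, x$params$kd, x$params$Rmax,
              if (is.finite(x$params$kt))
                sprintf(", kt = %.3g RU/M/s", x$params$kt) else ""))
  cat(sprintf("  KD = %.3g M (%.3g pM); SSE = %.4g\n", x$KD, x$KD * 1e12, x$sse))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a kinetic fit into one row per parameter
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @method tidy kinetic_fit
#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble(term = c("ka", "kd", "Rmax", "kt", "KD"),
         estimate = c(x$params$ka, x$params$kd, x$params$Rmax, x$params$kt,
                      x$KD),
         unit = c("1/(M s)", "1/s", "RU", "RU/(M s)", "M"))
}

#' One-row summary of a kinetic fit
#' @param x A `kinetic_fit`.
#' @param ... Unused.
#' @method glance kinetic_fit
#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(ka = x$params$ka, kd = x$params$kd, KD = x$KD,
         Rmax = x$params$Rmax, kt = x$params$kt, sse = x$sse,
         n_obs = nrow(x$fitted), n_curves = length(unique(x$fitted$conc)),
         converged = x$converged)
}

#' Plot sensorgrams with the fitted model overlay
#' @param object A `kinetic_fit`.
#' @param ... Unused.
#' @method autoplot kinetic_fit
#' @export
autoplot.kinetic_fit <- function(object, ...) {
  d <- object$fitted
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, group = .data$conc)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$response), size = 0.4,
                        alpha = 0.5) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::labs(x = "time (s)", y = "response (RU)",
                  title = sprintf("1:1 %s fit, KD = %.3g pM",
                                  object$model, object$KD * 1e12)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
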