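#' Assemble retentostat observations
#'
#' The sampled time series of a retentostat cultivation: total biomass,
#' viable biomass (propidium-iodide-negative fraction of the dry mass) and,
#' when a producer strain is cultivated, the product titer in the
#' supernatant.
#'
#' @param t sampling times since retentostat start, h (strictly increasing).
#' @param C_X total biomass, g/L.
#' @param C_Xv viable biomass, g/L; default: equal to \code{C_X}.
#' @param C_P measured titer, g/L, or \code{NULL}.
#' @return a \code{data.frame} of class \code{"retentostat_obs"}.
#' @export
retentostat_obs <- function(t, C_X, C_Xv = C_X, C_P = NULL) {
  n <- length(t)
  stopifnot(length(C_X) == n, length(C_Xv) == n)
  if (any(diff(t) <= 0)) stop("'t' must be strictly increasing", call. = FALSE)
  if (any(C_X <= 0) || any(C_Xv <= 0))
    stop("biomass values must be positive", call. = FALSE)
  if (any(C_Xv > C_X * (1 + 1e-9)))
    stop("viable biomass cannot exceed total biomass", call. = FALSE)
  if (is.null(C_P)) C_P <- rep(NA_real_, n)
  d <- data.frame(t = t, C_X = C_X, C_Xv = C_Xv, C_P = C_P)
  class(d) <- c("retentostat_obs", "data.frame")
  d
}

#' Point-wise growth rate from interpolated biomass
#'
#' The specific growth rate over each sampling interval, taken from the
#' log-ratio of consecutive biomass measurements:
#' \code{mu = ln(C_X_i / C_X_{i-1}) / (t_i - t_{i-1})}, assigned to the
#' interval midpoint.
#'
#' @param t sampling times, h.
#' @param C_X biomass concentrations, g/L (> 0).
#' @return data.frame with \code{t_mid}, \code{t_start}, \code{t_end} and
#'   \code{mu} (h^-1), one row per interval.
#' @export
pointwise_mu <- function(t, C_X) {
  stopifnot(length(t) == length(C_X), length(t) >= 2)
  if (any(C_X <= 0)) stop("biomass values must be positive", call. = FALSE)
  if (any(diff(t) <= 0)) stop("'t' must be strictly increasing", call. = FALSE)
  i <- 2:length(t)
  dt <- t[i] - t[i - 1]
  data.frame(t_mid = (t[i] + t[i - 1]) / 2, t_start = t[i - 1], t_end = t[i],
             mu = log(C_X[i] / C_X[i - 1]) / dt)
}

#' Fit the retentostat biomass-accumulation model
#'
#' Non-linear least-squares regression of the observed biomass accumulation
#' profile against the forward retentostat model, with the maintenance
#' coefficient m_S as the only free parameter: the yields (Y_XS_max,
#' Y_PS_max) and the productivity model are held fixed at their
#' chemostat-derived values, the initial biomass is pinned to the first
#' observation, and the simulated profile is compared with the viable
#' biomass by default (the living fraction is what grows). Optimisation is
#' bounded Levenberg--Marquardt on m_S in \code{bounds}.
#'
#' The fitted object carries the model trajectory on the observation grid,
#' so the reconstructed mu(t) and q_S(t) and the terminal growth rate come
#' from the same code path as the objective.
#'
#' @param obs a \code{\link{retentostat_obs}} (span >= 7 days).
#' @param config a \code{\link{reactor_config}}.
#' @param params a \code{\link{pirt_params}}; its yields are held fixed and
#'   its m_S serves as the starting value unless \code{m_S_init} is given.
#' @param qp_model productivity model held fixed during the fit.
#' @param m_S_init optional starting value for m_S, g g^-1 h^-1.
#' @param signal fit the \code{"viable"} (default) or \code{"total"} biomass
#'   column.
#' @param bounds lower/upper bounds on m_S, g g^-1 h^-1.
#' @param fit_initial_biomass also free the initial biomass (default FALSE).
#' @return an object of class \code{"retentostat_fit"}.
#' @export
fit_retentostat <- function(obs, config, params, qp_model = qp_zero(),
                            m_S_init = NULL, signal = c("viable", "total"),
                            bounds = c(1e-4, 0.05),
                            fit_initial_biomass = FALSE) {
  stopifnot(inherits(obs, "retentostat_obs"), inherits(config, "reactor_config"),
            is_pirt_params(params), inherits(qp_model, "qp_model"))
  signal <- match.arg(signal)
  if (diff(range(obs$t)) < 168)
    stop("observations must span at least 7 days for an identifiable m_S fit",
         call. = FALSE)
  y <- if (signal == "viable") obs$C_Xv else obs$C_X
  times <- obs$t - obs$t[1]  # model grid is relative to the first sample
  if (is.null(m_S_init)) m_S_init <- params$m_S
  C_X0_obs <- y[1]

  sim_cx <- function(m_S, C_X0) {
    p <- pirt_params(m_S = m_S, Y_XS_max = params$Y_XS_max,
                     Y_PS_max = params$Y_PS_max)
    simulate_retentostat(config, p, qp_model, times = times, C_X0 = C_X0)
  }
  resid_fun <- if (fit_initial_biomass) {
    function(par) y - sim_cx(par[1], par[2])$C_X
  } else {
    function(par) y - sim_cx(par[1], C_X0_obs)$C_X
  }
  par0 <- if (fit_initial_biomass) c(m_S = m_S_init, C_X0 = C_X0_obs)
          else c(m_S = m_S_init)
  lower <- if (fit_initial_biomass) c(bounds[1], 0.1 * C_X0_obs) else bounds[1]
  upper <- if (fit_initial_biomass) c(bounds[2], 10 * C_X0_obs) else bounds[2]
  fit <- minpack.lm::nls.lm(
    par = par0, fn = resid_fun, lower = lower, upper = upper,
    control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                         ptol = 1e-12, gtol = 0))
  converged <- fit$info %in% 1:4
  if (!converged)
    stop(sprintf("retentostat fit did not converge (nls.lm info %d, m_S trace ends at %.5g)",
                 fit$info, fit$par[1]), call. = FALSE)
  m_S_hat <- unname(fit$par[1])
  if (m_S_hat <= bounds[1] * (1 + 1e-6) || m_S_hat >= bounds[2] * (1 - 1e-6))
    warning("fitted m_S sits at a bound; estimate is not interior", call. = FALSE)
  C_X0_hat <- if (fit_initial_biomass) unname(fit$par[2]) else C_X0_obs
  traj <- sim_cx(m_S_hat, C_X0_hat)
  res <- y - traj$C_X
  structure(list(
    m_S_hat = m_S_hat, C_X0 = C_X0_hat, residual_sse = sum(res^2),
    residuals = res, trajectory = traj, terminal_mu = traj$mu[nrow(traj)],
    converged = converged, signal = signal, obs = obs, config = config,
    params_fixed = params, qp_model = qp_model, nls = fit),
    class = "retentostat_fit")
}

#' @export
print.retentostat_fit <- function(x, ...) {
  cat("Retentostat biomass-accumulation fit (least squares on m_S)\n")
  cat(sprintf("  signal: %s biomass, %d observations over %.4g h\n",
              x$signal, nrow(x$obs), diff(range(x$obs$t))))
  cat(sprintf("  m_S         = %.4g g/g/h  (%.3g mg/g/h)\n",
              x$m_S_hat, 1000 * x$m_S_hat))
  cat(sprintf("  terminal mu = %.4g 1/h  (doubling time %.3g days)\n",
              x$terminal_mu,
              if (x$terminal_mu > 0) doubling_time(x$terminal_mu) else NA))
  cat(sprintf("  residual SSE = %.4g (g/L)^2\n", x$residual_sse))
  invisible(x)
}

#' @export
coef.retentostat_fit <- function(object, ...) {
  c(m_S = object$m_S_hat,
    Y_XS_max = object$params_fixed$Y_XS_max,
    Y_PS_max = object$params_fixed$Y_PS_max)
}

#' @export
residuals.retentostat_fit <- function(object, ...) object$residuals

#' @export
fitted.retentostat_fit <- function(object, ...) object$trajectory$C_X

#' @export
summary.retentostat_fit <- function(object, ...) {
  print(object)
  mu <- object$trajectory$mu
  cat(sprintf("  mu range: %.4g -> %.4g 1/h; q_S terminal %.4g g/g/h\n",
              mu[1], mu[length(mu)],
              object$trajectory$q_S[nrow(object$trajectory)]))
  invisible(object)
}

#' @export
predict.retentostat_fit <- function(object, times = NULL, ...) {
  if (is.null(times)) return(object$trajectory)
  p <- pirt_params(object$m_S_hat, object$params_fixed$Y_XS_max,
                   object$params_fixed$Y_PS_max)
  simulate_retentostat(object$config, p, object$qp_model,
                       times = times - times[1], C_X0 = object$C_X0)
}

#' @export
plot.retentostat_fit <- function(x, ...) {
  graphics::plot(x$obs$t, if (x$signal == "viable") x$obs$C_Xv else x$obs$C_X,
                 xlab = "t (h)", ylab = "biomass (g/L)",
                 main = "Retentostat biomass fit", ...)
  graphics::lines(x$obs$t, x$trajectory$C_X, lty = 2)
  graphics::legend("bottomright", c("observed", "model"),
                   pch = c(1, NA), lty = c(NA, 2), bty = "n")
  invisible(x)
}

#' (mu, q_P) pairs from a retentostat cultivation
#'
#' Joins the point-wise growth rate with the piecewise product-balance
#' productivity on a common uniform grid. The resulting pairs — optionally
#' pooled with steady-state chemostat (mu, q_P) points — are the input to
#' \code{\link{fit_qp_gompertz}}.
#'
#' @param obs a \code{\link{retentostat_obs}} with a titer column.
#' @param config a \code{\link{reactor_config}} (supplies phi).
#' @param grid_dt analysis grid, h (default 24).
#' @param correct_washout passed to \code{\link{qp_series}}.
#' @param signal biomass column used for normalisation and mu
#'   (\code{"total"} default, or \code{"viable"}).
#' @return data.frame with \code{mu}, \code{q_P}, \code{t_mid}, \code{flag}.
#' @export
qp_mu_pairs <- function(obs, config, grid_dt = 24, correct_washout = FALSE,
                        signal = c("total", "viable")) {
  stopifnot(inherits(obs, "retentostat_obs"), inherits(config, "reactor_config"))
  signal <- match.arg(signal)
  if (all(is.na(obs$C_P)))
    stop("observations carry no titer series", call. = FALSE)
  cx <- if (signal == "total") obs$C_X else obs$C_Xv
  ok <- !is.na(obs$C_P)
  qp <- qp_series(t_titer = obs$t[ok], titer = obs$C_P[ok],
                  t_biomass = obs$t, biomass = cx,
                  phi = config$phi, grid_dt = grid_dt,
                  correct_washout = correct_washout)
  data.frame(mu = qp$mu, q_P = qp$q_P, t_mid = qp$t_mid, flag = qp$flag,
             stringsAsFactors = FALSE)
}
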