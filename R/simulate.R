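# Solve the implicit mu <-> q_P coupling at one instant.
#
# mu must satisfy mu = Y_XS_max * (q_S - m_S - qp(mu)/Y_PS_max) with
# q_P = qp_model(mu). The coupling is weak (q_P/Y_PS_max << q_S), so a
# damped fixed-point iteration started from the previous step's mu converges
# in a handful of steps; a uniroot bracket on [g(mu_max), mu_max] guards
# pathological q_P models (valid for any monotone non-decreasing q_P(mu)).
solve_mu <- function(q_S, params, qp_model, mu_start,
                     tol = 1e-14, max_iter = 50L) {
  g <- function(mu) {
    params$Y_XS_max * (q_S - params$m_S - qp_at(qp_model, mu) / params$Y_PS_max)
  }
  if (inherits(qp_model, "qp_zero")) return(g(0))
  mu <- mu_start
  omega <- 1
  for (i in seq_len(max_iter)) {
    mu_new <- (1 - omega) * mu + omega * g(mu)
    if (abs(mu_new - mu) <= tol * max(1, abs(mu_new))) return(mu_new)
    if (i > 10L) omega <- 0.5
    mu <- mu_new
  }
  hi <- params$Y_XS_max * (q_S - params$m_S)   # q_P >= 0 bound
  lo <- g(hi)
  if (lo > hi) { tmp <- lo; lo <- hi; hi <- tmp }
  stats::uniroot(function(m) g(m) - m, c(lo - 1e-9, hi + 1e-9),
                 tol = 1e-15)$root
}

#' Forward simulation of a glucose-limited retentostat
#'
#' Integrates the near-zero-growth culture model from the chemostat steady
#' state: the broth volume is constant and all biomass is retained, so
#' \code{dC_X/dt = mu * C_X}; under strict glucose limitation the residual
#' glucose is zero and the biomass-specific uptake is supply over standing
#' biomass, \code{q_S = phi * C_S_feed(t) / C_X}; the growth rate follows
#' from the Pirt partition \code{mu = Y_XS_max * (q_S - m_S - q_P/Y_PS_max)}
#' with \code{q_P = qp_model(mu)} solved self-consistently; dissolved
#' product accumulates by secretion and leaves by perfusion washout,
#' \code{dC_P/dt = q_P * C_X - phi * C_P}. The feed glucose declines by the
#' closed-form mixing-vessel kernel (\code{\link{feed_glucose}}). As biomass
#' piles up, the supply per cell approaches the maintenance demand and mu
#' decays towards zero; if supply falls below maintenance, mu goes negative
#' and is reported as such, not clipped.
#'
#' Cumulative glucose supplied and glucose partitioned into growth,
#' maintenance and product are co-integrated so mass conservation can be
#' audited on any horizon.
#'
#' @param config a \code{\link{reactor_config}}.
#' @param params a \code{\link{pirt_params}}.
#' @param qp_model a \code{qp_model} (default: no production).
#' @param t_end simulation horizon, h (default 672 = 28 days).
#' @param output_dt output grid spacing, h (default 1).
#' @param times explicit output time vector (overrides \code{t_end} /
#'   \code{output_dt}); must start at 0 and be strictly increasing.
#' @param C_X0,C_P0 initial biomass and product, g/L; default: the chemostat
#'   steady state for the supplied parameters.
#' @param rtol,atol solver tolerances (lsoda).
#' @return a \code{data.frame} of class \code{"retentostat_trajectory"} with
#'   columns \code{t}, \code{C_X}, \code{C_S_feed}, \code{mu}, \code{q_S},
#'   \code{C_P}, \code{q_P}, \code{glc_in}, \code{glc_used} (cumulative g/L
#'   supplied and partitioned); the inputs are attached as attributes.
#' @examples
#' cfg <- reactor_config()
#' p <- pirt_params(0.0037, 0.544)
#' traj <- simulate_retentostat(cfg, p, t_end = 240, output_dt = 24)
#' tail(traj, 2)
#' @export
simulate_retentostat <- function(config, params, qp_model = qp_zero(),
                                 t_end = 672, output_dt = 1,
                                 C_X0 = NULL, C_P0 = NULL,
                                 times = NULL, rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(config, "reactor_config"), is_pirt_params(params),
            inherits(qp_model, "qp_model"))
  if (!is.finite(t_end) || t_end <= 0) stop("'t_end' must be > 0", call. = FALSE)
  ss <- chemostat_steady_state(config, params, qp_model)
  if (is.null(C_X0)) C_X0 <- ss$C_X0
  if (is.null(C_P0)) C_P0 <- if (inherits(qp_model, "qp_zero")) 0 else ss$C_P0
  if (C_X0 <= 0) stop("initial biomass must be positive", call. = FALSE)

  phi <- config$phi
  mu_cache <- new.env(parent = emptyenv())
  mu_cache$mu <- config$D_chemostat

  deriv <- function(t, y, parms) {
    C_X <- y[1]; C_P <- y[2]
    if (!is.finite(C_X) || C_X <= 1e-9)
      stop("degenerate culture: biomass collapsed to zero", call. = FALSE)
    Cs <- feed_glucose(t, config)
    q_S <- phi * Cs / C_X
    mu <- solve_mu(q_S, params, qp_model, mu_cache$mu)
    mu_cache$mu <- mu
    q_P <- qp_at(qp_model, mu)
    list(c(mu * C_X,
           q_P * C_X - phi * C_P,
           phi * Cs,
           C_X * (mu / params$Y_XS_max + params$m_S + q_P / params$Y_PS_max)),
         c(C_S_feed = Cs, mu = mu, q_S = q_S, q_P = q_P))
  }

  if (is.null(times)) {
    times <- seq(0, t_end, by = output_dt)
    if (times[length(times)] < t_end) times <- c(times, t_end)
  } else {
    if (times[1] != 0 || any(diff(times) <= 0))
      stop("'times' must start at 0 and be strictly increasing", call. = FALSE)
  }
  sol <- deSolve::ode(y = c(C_X = C_X0, C_P = C_P0, glc_in = 0, glc_used = 0),
                      times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed; last valid time ",
         max(sol[, "time"], na.rm = TRUE), call. = FALSE)
  out <- as.data.frame(sol)
  traj <- data.frame(t = out$time, C_X = out$C_X, C_S_feed = out$C_S_feed,
                     mu = out$mu, q_S = out$q_S, C_P = out$C_P,
                     q_P = out$q_P, glc_in = out$glc_in,
                     glc_used = out$glc_used)
  structure(traj, class = c("retentostat_trajectory", "data.frame"),
            config = config, params = params, qp_model = qp_model)
}

#' @export
print.retentostat_trajectory <- function(x, ...) {
  n <- nrow(x)
  cat(sprintf("Retentostat trajectory: %d points over %.5g h\n", n, x$t[n]))
  cat(sprintf("  biomass %.3g -> %.3g g/L; mu %.3g -> %.3g 1/h\n",
              x$C_X[1], x$C_X[n], x$mu[1], x$mu[n]))
  cat(sprintf("  terminal doubling time %.3g days\n",
              if (x$mu[n] > 0) doubling_time(x$mu[n]) else NA))
  if (any(x$C_P > 0))
    cat(sprintf("  product titer %.3g -> %.3g g/L; terminal q_P %.3g mg/g/h\n",
                x$C_P[1], x$C_P[n], 1000 * x$q_P[n]))
  invisible(x)
}

#' @export
plot.retentostat_trajectory <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1)); on.exit(graphics::par(op))
  graphics::plot(x$t, x$C_X, type = "l", xlab = "t (h)", ylab = "C_X (g/L)",
                 main = "Biomass", ...)
  graphics::plot(x$t, x$C_S_feed, type = "l", xlab = "t (h)",
                 ylab = "C_S feed (g/L)", main = "Feed glucose", ...)
  graphics::plot(x$t, x$mu, type = "l", log = "y", xlab = "t (h)",
                 ylab = "mu (1/h)", main = "Growth rate", ...)
  graphics::plot(x$t, x$C_P, type = "l", xlab = "t (h)", ylab = "C_P (g/L)",
                 main = "Product titer", ...)
  invisible(x)
}

#' Relative glucose mass-balance error of a simulated trajectory
#'
#' Compares cumulative glucose supplied with cumulative glucose partitioned
#' into growth, maintenance and product over the simulated horizon; both are
#' co-integrated with the state, so the difference measures only the
#' residual of the implicit mu solve and the integrator tolerance.
#'
#' @param traj a \code{\link{simulate_retentostat}} result.
#' @return maximum relative discrepancy over the trajectory (dimensionless).
#' @export
glucose_balance_error <- function(traj) {
  stopifnot(inherits(traj, "retentostat_trajectory"))
  i <- traj$glc_in > 0
  max(abs(traj$glc_in[i] - traj$glc_used[i]) / traj$glc_in[i])
}
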