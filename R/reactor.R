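#' Retentostat hardware configuration
#'
#' Describes the two-vessel retentostat setup: a level-controlled bioreactor
#' of working volume \code{v_reactor} whose effluent leaves through a
#' cell-retaining filter at perfusion rate \code{phi}, fed from a
#' level-controlled mixing vessel of volume \code{v_mix} whose glucose
#' concentration is shifted from \code{C_S_high} to \code{C_S_low} at the
#' start of the retentostat phase. Defaults are the study conditions:
#' 1.4 L broth, 1.5 L mixing vessel, phi = 0.025 h^-1 (equal to the
#' preceding chemostat dilution rate, so the switch is seamless), feed
#' declining from 10 to 3.5 g/L glucose.
#'
#' @param v_reactor broth working volume, L.
#' @param v_mix mixing-vessel working volume, L.
#' @param phi perfusion rate (effluent flow per broth volume), h^-1.
#' @param C_S_high feed glucose before the shift, g/L.
#' @param C_S_low feed glucose setpoint after the shift, g/L.
#' @param D_chemostat dilution rate of the preceding chemostat phase, h^-1.
#' @return an object of class \code{"reactor_config"}.
#' @export
reactor_config <- function(v_reactor = 1.4, v_mix = 1.5, phi = 0.025,
                           C_S_high = 10, C_S_low = 3.5,
                           D_chemostat = phi) {
  vals <- c(v_reactor = v_reactor, v_mix = v_mix, phi = phi,
            C_S_high = C_S_high, C_S_low = C_S_low, D_chemostat = D_chemostat)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all reactor_config values must be positive and finite", call. = FALSE)
  if (C_S_low > C_S_high)
    stop("'C_S_low' must not exceed 'C_S_high'", call. = FALSE)
  if (abs(phi - D_chemostat) > 1e-12)
    warning("phi differs from D_chemostat: the chemostat-to-retentostat switch ",
            "is then discontinuous", call. = FALSE)
  structure(as.list(vals), class = "reactor_config")
}

#' @export
print.reactor_config <- function(x, ...) {
  cat("Retentostat configuration\n")
  cat(sprintf("  broth volume %.3g L, mixing vessel %.3g L\n", x$v_reactor, x$v_mix))
  cat(sprintf("  perfusion phi = %.3g 1/h (chemostat D = %.3g 1/h)\n",
              x$phi, x$D_chemostat))
  cat(sprintf("  feed glucose %.3g -> %.3g g/L (half-decay %.3g h)\n",
              x$C_S_high, x$C_S_low,
              log(2) * x$v_mix / (x$phi * x$v_reactor)))
  invisible(x)
}

#' Feed glucose concentration during the retentostat phase
#'
#' The mixing vessel is level-controlled at constant volume \code{v_mix} and,
#' from t = 0, receives low-glucose medium at the broth feed rate
#' \code{phi * v_reactor}. Being well mixed, its glucose concentration decays
#' exponentially from \code{C_S_high} to \code{C_S_low} with rate constant
#' \code{k = phi * v_reactor / v_mix}; the closed form is exact, so no ODE is
#' integrated for the feed.
#'
#' @param t time since retentostat start, h (vectorised, >= 0).
#' @param config a \code{\link{reactor_config}}.
#' @return feed glucose concentration, g/L.
#' @export
feed_glucose <- function(t, config) {
  stopifnot(inherits(config, "reactor_config"))
  if (any(!is.finite(t)) || any(t < 0))
    stop("'t' must be finite and non-negative", call. = FALSE)
  k <- config$phi * config$v_reactor / config$v_mix
  config$C_S_low + (config$C_S_high - config$C_S_low) * exp(-k * t)
}

#' Steady state of the chemostat phase preceding the retentostat
#'
#' At steady state the specific growth rate equals the dilution rate
#' (mu = D), productivity follows the q_P model at D, uptake follows the
#' Pirt balance, and — under full glucose limitation — all supplied glucose
#' is consumed, fixing the biomass concentration at
#' \code{C_X0 = D * C_S_in / q_S}. The product concentration balances
#' secretion against dilution: \code{C_P0 = q_P * C_X0 / D}.
#'
#' @param config a \code{\link{reactor_config}} (the chemostat runs on the
#'   high-glucose feed, \code{C_S_high}).
#' @param params a \code{\link{pirt_params}}.
#' @param qp_model a \code{qp_model} (default: no production).
#' @return list with \code{C_X0}, \code{C_P0}, \code{q_S}, \code{q_P}
#'   (g/L, g/L, g/g/h, g/g/h).
#' @export
chemostat_steady_state <- function(config, params, qp_model = qp_zero()) {
  stopifnot(inherits(config, "reactor_config"), is_pirt_params(params),
            inherits(qp_model, "qp_model"))
  D <- config$D_chemostat
  q_P <- qp_at(qp_model, D)
  q_S <- pirt_qs(D, params, q_P)
  if (q_S <= 0)
    stop("infeasible parameters: steady-state q_S <= 0", call. = FALSE)
  C_X0 <- D * config$C_S_high / q_S
  list(C_X0 = C_X0, C_P0 = q_P * C_X0 / D, q_S = q_S, q_P = q_P)
}

#' First-order washout of a dissolved species through the retention filter
#'
#' Dissolved product (the cells are retained, the broth is not) dilutes out
#' of a perfused vessel as \code{C(t) = C(0) * exp(-phi * t)} — the kernel
#' shared by the forward simulator and the piecewise product balance.
#'
#' @param C_P_start initial concentration, g/L.
#' @param t elapsed time, h (>= 0, vectorised).
#' @param phi perfusion rate, h^-1 (>= 0).
#' @return concentration after washout, g/L.
#' @export
washout_only_decay <- function(C_P_start, t, phi) {
  if (any(!is.finite(t)) || any(t < 0)) stop("'t' must be >= 0", call. = FALSE)
  if (!is.finite(phi) || phi < 0) stop("'phi' must be >= 0", call. = FALSE)
  C_P_start * exp(-phi * t)
}
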