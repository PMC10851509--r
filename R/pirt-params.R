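#' Kinetic parameter set for the Pirt substrate balance
#'
#' Bundles the three constants that close the glucose balance of an aerobic,
#' glucose-limited culture: the maintenance coefficient \code{m_S}
#' (g glucose g biomass^-1 h^-1), the maximum biomass yield \code{Y_XS_max}
#' (g g^-1) and the maximum theoretical product yield \code{Y_PS_max}
#' (g g^-1). \code{Y_PS_max} is an externally supplied stoichiometric
#' constant (0.609 g g^-1 for the VHH product on glucose); it is consumed,
#' never estimated, by this package.
#'
#' @param m_S maintenance coefficient, g g^-1 h^-1.
#' @param Y_XS_max maximum biomass yield on glucose, g g^-1 (must be in (0, 1]).
#' @param Y_PS_max maximum product yield on glucose, g g^-1 (must be in (0, 1]).
#' @return An object of class \code{"pirt_params"}.
#' @examples
#' pirt_params(m_S = 0.00437, Y_XS_max = 0.544)
#' @export
pirt_params <- function(m_S, Y_XS_max, Y_PS_max = 0.609) {
  for (nm in c("m_S", "Y_XS_max", "Y_PS_max")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("'%s' must be a single positive finite number", nm), call. = FALSE)
  }
  if (Y_XS_max > 1) stop("'Y_XS_max' must not exceed 1 g/g", call. = FALSE)
  if (Y_PS_max > 1) stop("'Y_PS_max' must not exceed 1 g/g", call. = FALSE)
  structure(list(m_S = m_S, Y_XS_max = Y_XS_max, Y_PS_max = Y_PS_max),
            class = "pirt_params")
}

#' @export
print.pirt_params <- function(x, ...) {
  cat("Pirt kinetic parameters\n")
  cat(sprintf("  m_S      = %.4g g/g/h  (%.3g mg/g/h)\n", x$m_S, 1000 * x$m_S))
  cat(sprintf("  Y_XS_max = %.4g g/g\n", x$Y_XS_max))
  cat(sprintf("  Y_PS_max = %.4g g/g\n", x$Y_PS_max))
  invisible(x)
}

is_pirt_params <- function(x) inherits(x, "pirt_params")

# Unvalidated constructor for estimation results: noisy window averages can
# legitimately carry a non-positive m_S, which is reported, not clipped.
new_pirt_params <- function(m_S, Y_XS_max, Y_PS_max) {
  structure(list(m_S = m_S, Y_XS_max = Y_XS_max, Y_PS_max = Y_PS_max),
            class = "pirt_params")
}

#' Forward Pirt substrate balance
#'
#' The specific glucose uptake rate of a culture growing at rate \code{mu}
#' while secreting product at rate \code{q_P} is partitioned linearly into
#' growth, maintenance and product-formation demands:
#' \deqn{q_S = \mu / Y_{XS}^{max} + m_S + q_P / Y_{PS}^{max}.}
#'
#' @param mu specific growth rate, h^-1 (vectorised, must be >= 0).
#' @param params a \code{\link{pirt_params}} object.
#' @param q_P specific product secretion rate, g g^-1 h^-1 (>= 0, recycled
#'   against \code{mu}).
#' @return specific glucose uptake rate q_S, g g^-1 h^-1.
#' @examples
#' p <- pirt_params(0.00437, 0.544)
#' pirt_qs(0.1, p)               # growth + maintenance only
#' pirt_qs(0.17, p, q_P = 0.00064)
#' @export
pirt_qs <- function(mu, params, q_P = 0) {
  stopifnot(is_pirt_params(params))
  if (!is.numeric(mu) || any(!is.finite(mu)) || any(mu < 0))
    stop("'mu' must be finite and non-negative", call. = FALSE)
  if (!is.numeric(q_P) || any(!is.finite(q_P)) || any(q_P < 0))
    stop("'q_P' must be finite and non-negative", call. = FALSE)
  mu / params$Y_XS_max + params$m_S + q_P / params$Y_PS_max
}

#' Remove the product term from a measured uptake rate
#'
#' Subtracts the substrate flux diverted into product formation,
#' \code{q_P / Y_PS_max}, from a measured \code{q_S}, leaving the flux
#' attributable to growth and maintenance only. This linearises the Pirt
#' balance exactly, so ordinary regression of the corrected uptake on mu
#' yields \code{m_S} (intercept) and \code{1/Y_XS_max} (slope).
#'
#' @param q_S measured specific glucose uptake, g g^-1 h^-1 (vectorised).
#' @param q_P specific product secretion rate, g g^-1 h^-1 (0 for a
#'   non-producer).
#' @param Y_PS_max maximum product yield, g g^-1.
#' @return corrected uptake rate, g g^-1 h^-1.
#' @export
growth_corrected_qs <- function(q_S, q_P = 0, Y_PS_max = 0.609) {
  if (!is.numeric(q_S) || any(!is.finite(q_S)))
    stop("'q_S' must be finite", call. = FALSE)
  if (!is.numeric(q_P) || any(!is.finite(q_P)) || any(q_P < 0))
    stop("'q_P' must be finite and non-negative", call. = FALSE)
  if (!is.numeric(Y_PS_max) || length(Y_PS_max) != 1L || Y_PS_max <= 0)
    stop("'Y_PS_max' must be a single positive number", call. = FALSE)
  q_S - q_P / Y_PS_max
}

#' Doubling time of a culture growing exponentially at rate mu
#'
#' @param mu specific growth rate, h^-1 (> 0, vectorised).
#' @return doubling time ln(2)/mu, converted from hours to days.
#' @examples
#' doubling_time(0.00047)  # ~61.4 days, the near-zero-growth endpoint
#' @export
doubling_time <- function(mu) {
  if (!is.numeric(mu) || any(!is.finite(mu)) || any(mu <= 0))
    stop("'mu' must be finite and strictly positive", call. = FALSE)
  log(2) / mu / 24
}
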