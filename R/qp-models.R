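#' Productivity-versus-growth-rate models
#'
#' Specific productivity q_P of the secreted product depends on the specific
#' growth rate mu. Three model families are supported:
#' \itemize{
#'   \item \code{qp_zero()} — no production (non-producer strains);
#'   \item \code{qp_linear(slope, intercept)} — a straight line, used for the
#'     a-priori retentostat prediction from the lowest chemostat setpoints;
#'     evaluation is clamped at zero so extrapolation below the x-intercept
#'     never returns a negative rate;
#'   \item \code{qp_gompertz(a, b, c)} — the saturating double-exponential
#'     \eqn{q_P(\mu) = a\,e^{-b e^{-c\mu}}}, used once retentostat estimates
#'     are available.
#' }
#' All rates are g product g biomass^-1 h^-1; mu is h^-1.
#'
#' @param slope,intercept linear model coefficients (g g^-1 h^-1 per h^-1 and
#'   g g^-1 h^-1).
#' @param a,b,c Gompertz parameters: asymptote (g g^-1 h^-1), displacement
#'   (dimensionless, > 0) and rate (per h^-1 of mu, > 0).
#' @return an object of class \code{c("qp_<type>", "qp_model")}.
#' @name qp_models
NULL

#' @rdname qp_models
#' @export
qp_zero <- function() {
  structure(list(), class = c("qp_zero", "qp_model"))
}

#' @rdname qp_models
#' @export
qp_linear <- function(slope, intercept) {
  stopifnot(is.finite(slope), is.finite(intercept))
  if (intercept < 0)
    warning("linear q_P model has a negative intercept (q_P at zero growth < 0); ",
            "evaluation clamps q_P at 0", call. = FALSE)
  structure(list(slope = slope, intercept = intercept),
            class = c("qp_linear", "qp_model"))
}

#' @rdname qp_models
#' @export
qp_gompertz <- function(a, b, c) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c))
  if (a <= 0 || b <= 0 || c <= 0)
    stop("Gompertz q_P parameters must all be strictly positive", call. = FALSE)
  structure(list(a = a, b = b, c = c),
            class = c("qp_gompertz", "qp_model"))
}

#' Evaluate a productivity model at given growth rates
#'
#' @param model a \code{qp_model} object.
#' @param mu specific growth rate(s), h^-1. Negative values are admitted
#'   (transient feed undershoot) and evaluated by continuous extension.
#' @return q_P, g g^-1 h^-1 (never negative).
#' @export
qp_at <- function(model, mu) UseMethod("qp_at")

#' @export
qp_at.qp_zero <- function(model, mu) rep(0, length(mu))

#' @export
qp_at.qp_linear <- function(model, mu) {
  pmax(0, model$slope * mu + model$intercept)
}

#' @export
qp_at.qp_gompertz <- function(model, mu) {
  model$a * exp(-model$b * exp(-model$c * mu))
}

#' @export
print.qp_model <- function(x, ...) {
  if (inherits(x, "qp_zero")) {
    cat("q_P model: zero (non-producer)\n")
  } else if (inherits(x, "qp_linear")) {
    cat("q_P model: linear, clamped at 0\n")
    cat(sprintf("  slope     = %.4g (g/g/h per 1/h)\n", x$slope))
    cat(sprintf("  intercept = %.4g g/g/h  (%.3g mg/g/h at zero growth)\n",
                x$intercept, 1000 * x$intercept))
  } else {
    cat("q_P model: Gompertz  a*exp(-b*exp(-c*mu))\n")
    cat(sprintf("  a = %.4g g/g/h, b = %.4g, c = %.4g per (1/h)\n", x$a, x$b, x$c))
    cat(sprintf("  q_P(0) = %.3g mg/g/h, asymptote = %.3g mg/g/h\n",
                1000 * x$a * exp(-x$b), 1000 * x$a))
  }
  invisible(x)
}

#' @export
coef.qp_linear <- function(object, ...) c(slope = object$slope, intercept = object$intercept)

#' @export
coef.qp_gompertz <- function(object, ...) c(a = object$a, b = object$b, c = object$c)

#' @export
predict.qp_model <- function(object, mu, ...) qp_at(object, mu)

#' Fit the linear q_P--mu model to the lowest chemostat setpoints
#'
#' Ordinary least squares of q_P on mu over the \code{n_points} lowest
#' distinct dilution-rate setpoints (replicate observations at a setpoint
#' enter as individual points). The intercept is the extrapolated specific
#' productivity at zero growth. A negative intercept is reported with a
#' warning, not clipped.
#'
#' @param mu,q_P paired observations (h^-1 and g g^-1 h^-1).
#' @param n_points number of lowest distinct mu setpoints to use (default 3).
#' @return a \code{\link{qp_linear}} model with attributes \code{r_squared}
#'   and \code{n_used}.
#' @export
fit_qp_linear <- function(mu, q_P, n_points = 3) {
  stopifnot(length(mu) == length(q_P), all(is.finite(mu)), all(is.finite(q_P)))
  setp <- sort(unique(round(mu, 4)))
  if (length(setp) < 2)
    stop("need at least 2 distinct mu setpoints for a linear q_P fit", call. = FALSE)
  if (length(setp) < n_points)
    stop(sprintf("requested %d setpoints but only %d distinct mu present",
                 n_points, length(setp)), call. = FALSE)
  keep <- round(mu, 4) %in% setp[seq_len(n_points)]
  y <- q_P[keep]
  fit <- stats::lm(y ~ mu[keep])
  m <- qp_linear(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]))
  sst <- sum((y - mean(y))^2)
  attr(m, "r_squared") <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
  attr(m, "n_used") <- sum(keep)
  m
}

#' Fit the Gompertz q_P--mu model
#'
#' Non-linear least squares of \eqn{q_P(\mu) = a e^{-b e^{-c\mu}}} by
#' bounded Levenberg--Marquardt. Initialisation: a = max observed q_P,
#' b = 2, c = 2/median(mu); all parameters constrained to the positive
#' orthant, which guarantees a non-negative, monotone non-decreasing fitted
#' curve.
#'
#' @param mu,q_P paired observations (h^-1 and g g^-1 h^-1); at least 4
#'   points spanning a >= 5-fold range in mu.
#' @param max_iter maximum optimiser iterations.
#' @return a \code{\link{qp_gompertz}} model with attributes \code{rss}
#'   (residual sum of squares) and \code{converged}.
#' @export
fit_qp_gompertz <- function(mu, q_P, max_iter = 200) {
  stopifnot(length(mu) == length(q_P), all(is.finite(mu)), all(is.finite(q_P)))
  if (length(mu) < 4)
    stop("need at least 4 (mu, q_P) points for a Gompertz fit", call. = FALSE)
  pos <- mu[mu > 0]
  if (max(pos) / min(pos) < 5)
    stop("mu values must span at least a 5-fold range", call. = FALSE)
  resid_fun <- function(p) q_P - p[1] * exp(-p[2] * exp(-p[3] * mu))
  eps <- 1e-12
  c0 <- 2 / stats::median(mu)
  # the double exponential is multimodal in least squares; restart the
  # optimiser around the default initialisation and keep the best fit
  starts <- expand.grid(b = c(1, 2, 4), cs = c(0.1, 0.3, 1, 3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- minpack.lm::nls.lm(
      par = c(a = max(q_P), b = starts$b[i], c = c0 * starts$cs[i]),
      fn = resid_fun, lower = c(eps, eps, eps), upper = c(Inf, Inf, Inf),
      control = minpack.lm::nls.lm.control(
        maxiter = max_iter, ftol = 1e-15, ptol = 1e-15, gtol = 0))
    if (fit$info == 0 || fit$info == 9) next
    rss <- sum(resid_fun(fit$par)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    stop(sprintf("Gompertz fit did not converge after %d iterations from any start",
                 max_iter), call. = FALSE)
  fit <- best$fit
  m <- qp_gompertz(a = unname(fit$par[1]), b = unname(fit$par[2]),
                   c = unname(fit$par[3]))
  attr(m, "rss") <- best$rss
  attr(m, "converged") <- TRUE
  m
}
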