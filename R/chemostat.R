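#' Assemble a chemostat steady-state dataset
#'
#' A chemostat at steady state fixes the specific growth rate at the dilution
#' rate (mu = D), so a series of setpoints yields paired (mu, q_S) and
#' optionally (mu, q_P) observations — the raw material for moving-window
#' Pirt regression. Replicate cultivations at a setpoint are kept as
#' individual rows.
#'
#' @param mu specific growth rate = dilution rate at steady state, h^-1.
#' @param q_S specific glucose uptake rate, g g^-1 h^-1.
#' @param q_P specific product secretion rate, g g^-1 h^-1; \code{NULL} or
#'   \code{NA} rows denote non-producer data (treated as 0 in the balance).
#' @param replicate optional replicate/cultivation label per row.
#' @return a \code{data.frame} of class \code{"chemostat_dataset"}, sorted by
#'   ascending mu, with columns \code{mu}, \code{q_S}, \code{q_P},
#'   \code{replicate}.
#' @export
chemostat_dataset <- function(mu, q_S, q_P = NULL, replicate = NULL) {
  n <- length(mu)
  stopifnot(length(q_S) == n)
  if (!is.numeric(mu) || any(!is.finite(mu)) || any(mu <= 0))
    stop("'mu' must be finite and strictly positive", call. = FALSE)
  if (!is.numeric(q_S) || any(!is.finite(q_S)) || any(q_S <= 0))
    stop("'q_S' must be finite and strictly positive", call. = FALSE)
  if (is.null(q_P)) q_P <- rep(0, n)
  q_P[is.na(q_P)] <- 0
  if (length(q_P) != n || any(q_P < 0))
    stop("'q_P' must be non-negative and match 'mu' in length", call. = FALSE)
  if (is.null(replicate)) replicate <- rep(NA_character_, n)
  d <- data.frame(mu = mu, q_S = q_S, q_P = q_P,
                  replicate = as.character(replicate),
                  stringsAsFactors = FALSE)
  d <- d[order(d$mu), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("chemostat_dataset", "data.frame")
  d
}

# Distinct mu setpoints after rounding to 4 decimals (ties merged).
mu_setpoints <- function(data) sort(unique(round(data$mu, 4)))

#' Moving-window Pirt regression over consecutive dilution-rate setpoints
#'
#' Slides a window of \code{window} consecutive distinct mu setpoints along
#' the dataset and, within each window, regresses the growth-corrected
#' glucose uptake \code{q_S - q_P / Y_PS_max} on mu by ordinary least
#' squares. Per the Pirt balance, the intercept estimates the maintenance
#' coefficient m_S and the reciprocal slope the maximum biomass yield
#' Y_XS_max, both local to the window's growth-rate range — which is what
#' reveals growth-rate dependence of the parameters. Replicate rows at a
#' setpoint enter the regression as separate points; windows are defined
#' over distinct setpoints only.
#'
#' @param data a \code{\link{chemostat_dataset}}.
#' @param Y_PS_max maximum product yield used for the product correction,
#'   g g^-1.
#' @param window number of consecutive distinct setpoints per window
#'   (default 3).
#' @param level \code{"replicate"} (default) regresses on individual rows;
#'   \code{"mean"} first averages q_S and q_P per setpoint.
#' @return a \code{data.frame} of class \code{"pirt_windows"}, one row per
#'   window in ascending mu order, with columns \code{mu_min}, \code{mu_max},
#'   \code{mu_mid}, \code{m_S}, \code{Y_XS_max}, \code{slope},
#'   \code{r_squared}, \code{n_points}, \code{valid} (FALSE where the window
#'   slope was non-positive, making Y_XS_max meaningless).
#' @export
sliding_window_fit <- function(data, Y_PS_max = 0.609, window = 3,
                               level = c("replicate", "mean")) {
  stopifnot(inherits(data, "chemostat_dataset"))
  level <- match.arg(level)
  setp <- mu_setpoints(data)
  if (length(setp) < window)
    stop(sprintf("degenerate window: %d distinct mu setpoints available, window size %d",
                 length(setp), window), call. = FALSE)
  d <- data
  if (level == "mean") {
    key <- round(d$mu, 4)
    d <- data.frame(mu = setp,
                    q_S = tapply(d$q_S, key, mean)[as.character(setp)],
                    q_P = tapply(d$q_P, key, mean)[as.character(setp)])
  }
  qs_gm <- growth_corrected_qs(d$q_S, d$q_P, Y_PS_max)
  n_win <- length(setp) - window + 1L
  out <- vector("list", n_win)
  for (i in seq_len(n_win)) {
    win_mu <- setp[i:(i + window - 1L)]
    sel <- round(d$mu, 4) %in% win_mu
    x <- d$mu[sel]; y <- qs_gm[sel]
    if (length(unique(round(x, 4))) < 2)
      stop("degenerate window: all mu equal within window", call. = FALSE)
    fit <- stats::lm(y ~ x)
    b <- unname(stats::coef(fit))
    slope <- b[2]
    valid <- is.finite(slope) && slope > 0
    if (!valid)
      warning(sprintf("window [%.4g, %.4g]: non-positive slope; Y_XS_max invalid",
                      min(win_mu), max(win_mu)), call. = FALSE)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else 1
    out[[i]] <- data.frame(
      mu_min = min(win_mu), mu_max = max(win_mu), mu_mid = mean(win_mu),
      m_S = b[1], Y_XS_max = if (valid) 1 / slope else NA_real_,
      slope = slope, r_squared = r2, n_points = length(x), valid = valid)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("pirt_windows", "data.frame")
  attr(res, "Y_PS_max") <- Y_PS_max
  attr(res, "window") <- window
  res
}

#' Average the low-growth-rate window estimates into one parameter set
#'
#' At low specific growth rates the window estimates of m_S and Y_XS_max
#' stabilise; their arithmetic mean over all windows whose every member
#' setpoint lies at or below \code{mu_threshold} is taken as the parameter
#' set for retentostat prediction. The spread across qualifying windows is
#' reported as a standard deviation.
#'
#' @param windows a \code{\link{sliding_window_fit}} result.
#' @param mu_threshold largest mu admitted into the average, h^-1
#'   (default 0.100).
#' @param Y_PS_max maximum product yield packaged with the result, g g^-1.
#' @return a \code{\link{pirt_params}} object with attributes \code{sd_m_S},
#'   \code{sd_Y_XS_max} and \code{n_windows}.
#' @export
average_low_mu_params <- function(windows, mu_threshold = 0.100,
                                  Y_PS_max = 0.609) {
  stopifnot(inherits(windows, "pirt_windows"))
  keep <- windows$mu_max <= mu_threshold + 1e-12 & windows$valid
  if (!any(keep))
    stop(sprintf("no valid window lies entirely at mu <= %.4g h^-1", mu_threshold),
         call. = FALSE)
  w <- windows[keep, , drop = FALSE]
  m_S_bar <- mean(w$m_S)
  if (m_S_bar <= 0)
    warning("averaged maintenance coefficient is non-positive; ",
            "returned unclipped for the analyst to judge", call. = FALSE)
  p <- new_pirt_params(m_S = m_S_bar, Y_XS_max = mean(w$Y_XS_max),
                       Y_PS_max = Y_PS_max)
  attr(p, "sd_m_S") <- stats::sd(w$m_S)
  attr(p, "sd_Y_XS_max") <- stats::sd(w$Y_XS_max)
  attr(p, "n_windows") <- nrow(w)
  p
}

#' Chemostat Pirt analysis in one call
#'
#' Convenience model-fitting front end: runs
#' \code{\link{sliding_window_fit}} and \code{\link{average_low_mu_params}}
#' and returns both, as the classed result of the chemostat estimation
#' stage.
#'
#' @param data a \code{\link{chemostat_dataset}}.
#' @param window window size in distinct setpoints.
#' @param mu_threshold mu ceiling for the averaged parameter set, h^-1.
#' @param Y_PS_max maximum product yield constant, g g^-1.
#' @param level regression level passed to \code{\link{sliding_window_fit}}.
#' @return an object of class \code{"pirt_fit"}: list with \code{windows},
#'   \code{params}, and the call arguments.
#' @export
fit_pirt <- function(data, window = 3, mu_threshold = 0.100, Y_PS_max = 0.609,
                     level = "replicate") {
  windows <- sliding_window_fit(data, Y_PS_max = Y_PS_max, window = window,
                                level = level)
  params <- average_low_mu_params(windows, mu_threshold = mu_threshold,
                                  Y_PS_max = Y_PS_max)
  structure(list(windows = windows, params = params, data = data,
                 window = window, mu_threshold = mu_threshold,
                 Y_PS_max = Y_PS_max),
            class = "pirt_fit")
}

#' @export
print.pirt_fit <- function(x, ...) {
  cat("Moving-window Pirt regression of chemostat data\n")
  cat(sprintf("  %d setpoints, window = %d, %d windows (%d at mu <= %.3g h^-1)\n",
              length(mu_setpoints(x$data)), x$window, nrow(x$windows),
              attr(x$params, "n_windows"), x$mu_threshold))
  cat(sprintf("  m_S      = %.3g +/- %.2g mg/g/h\n",
              1000 * x$params$m_S, 1000 * attr(x$params, "sd_m_S")))
  cat(sprintf("  Y_XS_max = %.4g +/- %.2g g/g\n",
              x$params$Y_XS_max, attr(x$params, "sd_Y_XS_max")))
  invisible(x)
}

#' @export
coef.pirt_fit <- function(object, ...) {
  c(m_S = object$params$m_S, Y_XS_max = object$params$Y_XS_max,
    Y_PS_max = object$params$Y_PS_max)
}

#' @export
summary.pirt_fit <- function(object, ...) {
  print(object)
  cat("\nPer-window estimates:\n")
  print(as.data.frame(object$windows), digits = 4)
  invisible(object)
}

#' @export
predict.pirt_fit <- function(object, mu, q_P = 0, ...) {
  pirt_qs(mu, object$params, q_P)
}

#' @export
plot.pirt_fit <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  graphics::plot(x$data$mu, x$data$q_S, xlab = expression(mu ~ (h^-1)),
                 ylab = expression(q[S] ~ (g~g^-1~h^-1)),
                 main = "Chemostat uptake", ...)
  graphics::curve(pirt_qs(t, x$params), xname = "t", add = TRUE, lty = 2)
  graphics::plot(x$windows$mu_mid, 1000 * x$windows$m_S,
                 xlab = expression(mu[mid] ~ (h^-1)),
                 ylab = expression(m[S] ~ (mg~g^-1~h^-1)),
                 main = "Window maintenance estimates", ...)
  graphics::abline(h = 1000 * x$params$m_S, lty = 2)
  invisible(x)
}
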