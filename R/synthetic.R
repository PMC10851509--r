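# Run code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Multiplicative lognormal noise factors with unit mean and the given CV.
lognormal_factor <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  stats::rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Measurement-noise specification for the synthetic generators
#'
#' Measurements of rates, biomass and titer are positive with roughly
#' proportional error, so noise is multiplicative lognormal with unit mean
#' at the given coefficients of variation. The true measurement CVs of the
#' emulated assays are not published; the defaults (3\% on rates and
#' biomass, 5\% on titer) are the package's own realism choice. Viability
#' in the emulated retentostats stays high; the generator lets the viable
#' fraction decline linearly from 1 to \code{viability_floor} (default
#' 0.90) over the cultivation.
#'
#' @param cv_qs CV on specific uptake rates (0–0.5).
#' @param cv_cx CV on biomass concentrations (0–0.5).
#' @param cv_titer CV on product titers and secretion rates (0–0.5).
#' @param viability_floor terminal viable fraction, in (0, 1].
#' @param seed integer RNG seed; \code{NULL} uses the current RNG stream.
#' @return an object of class \code{"noise_spec"}.
#' @export
noise_spec <- function(cv_qs = 0.03, cv_cx = 0.03, cv_titer = 0.05,
                       viability_floor = 0.90, seed = NULL) {
  cvs <- c(cv_qs = cv_qs, cv_cx = cv_cx, cv_titer = cv_titer)
  if (any(cvs < 0) || any(cvs > 0.5))
    stop("coefficients of variation must lie in [0, 0.5]", call. = FALSE)
  if (viability_floor <= 0 || viability_floor > 1)
    stop("'viability_floor' must lie in (0, 1]", call. = FALSE)
  structure(list(cv_qs = cv_qs, cv_cx = cv_cx, cv_titer = cv_titer,
                 viability_floor = viability_floor, seed = seed),
            class = "noise_spec")
}

#' @rdname noise_spec
#' @details \code{no_noise()} is the noise-free, full-viability special case
#'   used for closure and round-trip checks.
#' @export
no_noise <- function(seed = NULL) {
  noise_spec(cv_qs = 0, cv_cx = 0, cv_titer = 0, viability_floor = 1,
             seed = seed)
}

#' Growth-rate-dependent Pirt parameter profile
#'
#' Both m_S and Y_XS_max of the emulated strain change with growth rate:
#' above a breakpoint growth rate they take "fast" values, below it "slow"
#' ones (the stabilised low-mu regime). Returns a step-profile function
#' usable wherever a fixed \code{\link{pirt_params}} is accepted by
#' \code{\link{make_chemostat_dataset}}.
#'
#' @param low a \code{\link{pirt_params}} for mu <= \code{mu_break}.
#' @param high a \code{\link{pirt_params}} for mu > \code{mu_break}.
#' @param mu_break breakpoint growth rate, h^-1 (default 0.100).
#' @return a function mu -> \code{pirt_params}.
#' @export
pirt_step_profile <- function(low, high, mu_break = 0.100) {
  stopifnot(is_pirt_params(low), is_pirt_params(high))
  function(mu) if (mu > mu_break) high else low
}

#' Generate a synthetic chemostat dataset
#'
#' Emulates the steady-state design of the study: 7 dilution-rate setpoints
#' spanning 0.015–0.170 h^-1 with at least two replicate cultivations per
#' setpoint. At each setpoint, true uptake follows the Pirt balance with the
#' (possibly growth-rate-dependent) parameters and the productivity model;
#' measured q_S and q_P carry multiplicative lognormal noise. Deterministic
#' for a given seed.
#'
#' @param params a \code{\link{pirt_params}}, or a function mu ->
#'   \code{pirt_params} (see \code{\link{pirt_step_profile}}).
#' @param qp_model a \code{qp_model} (default: non-producer).
#' @param mu_setpoints dilution-rate setpoints, h^-1.
#' @param replicates replicate cultivations per setpoint.
#' @param noise a \code{\link{noise_spec}}.
#' @return a \code{\link{chemostat_dataset}}.
#' @export
make_chemostat_dataset <- function(params, qp_model = qp_zero(),
                                   mu_setpoints = c(0.015, 0.025, 0.040,
                                                    0.070, 0.100, 0.140,
                                                    0.170),
                                   replicates = 2,
                                   noise = no_noise()) {
  stopifnot(inherits(noise, "noise_spec"))
  if (any(mu_setpoints <= 0) || anyDuplicated(round(mu_setpoints, 4)))
    stop("'mu_setpoints' must be positive and distinct", call. = FALSE)
  pfun <- if (is.function(params)) params else function(mu) params
  mu <- rep(sort(mu_setpoints), each = replicates)
  with_seed(noise$seed, {
    q_P_true <- qp_at(qp_model, mu)
    q_S_true <- vapply(seq_along(mu),
                       function(i) pirt_qs(mu[i], pfun(mu[i]), q_P_true[i]),
                       numeric(1))
    q_S <- q_S_true * lognormal_factor(length(mu), noise$cv_qs)
    q_P <- q_P_true * lognormal_factor(length(mu), noise$cv_titer)
    chemostat_dataset(mu = mu, q_S = q_S, q_P = q_P,
                      replicate = rep(seq_len(replicates),
                                      times = length(mu_setpoints)))
  })
}

#' Generate synthetic retentostat observations
#'
#' Runs the forward retentostat model and samples it at (by default) 24-h
#' intervals over 28 days, emulating the sampling scheme of the study:
#' multiplicative lognormal noise on biomass and titer, and a viable
#' fraction declining linearly from 1 to \code{viability_floor} across the
#' horizon (viable biomass = noisy total biomass times viability).
#' Deterministic for a given seed.
#'
#' @param config a \code{\link{reactor_config}}.
#' @param params a \code{\link{pirt_params}}.
#' @param qp_model a \code{qp_model}.
#' @param t_end horizon, h (default 672).
#' @param sample_dt sampling interval, h (default 24).
#' @param noise a \code{\link{noise_spec}}.
#' @return a \code{\link{retentostat_obs}} with attribute \code{trajectory}
#'   (the underlying noise-free simulation at the sampling times).
#' @export
make_retentostat_observations <- function(config, params,
                                          qp_model = qp_zero(),
                                          t_end = 672, sample_dt = 24,
                                          noise = no_noise()) {
  stopifnot(inherits(noise, "noise_spec"))
  traj <- simulate_retentostat(config, params, qp_model,
                               t_end = t_end, output_dt = sample_dt)
  n <- nrow(traj)
  with_seed(noise$seed, {
    C_X <- traj$C_X * lognormal_factor(n, noise$cv_cx)
    C_P <- traj$C_P * lognormal_factor(n, noise$cv_titer)
    viability <- 1 - (1 - noise$viability_floor) * traj$t / traj$t[n]
    obs <- retentostat_obs(t = traj$t, C_X = C_X, C_Xv = C_X * viability,
                           C_P = if (inherits(qp_model, "qp_zero")) NULL
                                 else C_P)
    attr(obs, "trajectory") <- traj
    obs
  })
}

#' Productivity model calibrated to the retentostat regime
#'
#' The default Gompertz productivity truth used by the synthetic generators:
#' a saturating q_P--mu relationship anchored so that productivity at zero
#' growth is about 0.019 mg/g/h, about 0.06 mg/g/h at mu = 0.008 h^-1,
#' about 0.23 mg/g/h at mu = 0.025 h^-1, and saturates near 0.65 mg/g/h at
#' fast growth — the shape of a glucose-limit-induced secretion system that
#' keeps producing, at strongly reduced rate, near zero growth.
#'
#' @return a \code{\link{qp_gompertz}} model.
#' @export
qp_gompertz_default <- function() qp_gompertz(a = 0.00065, b = 3.53, c = 49)
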