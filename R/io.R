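# CSV dialect: comma-separated, UTF-8, '.' decimal, mandatory header with
# units encoded in the column names, so mg/g confusion cannot pass silently.

check_header <- function(path, found, required) {
  missing <- setdiff(required, found)
  if (length(missing))
    stop(sprintf("'%s': missing required column(s) %s (is the file comma-separated with a header row?)",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
}

#' Read a chemostat dataset CSV
#'
#' Columns: \code{mu_per_h}, \code{qs_g_per_g_h}, optional
#' \code{qp_mg_per_g_h} (converted mg to g on read) and
#' \code{replicate_id}.
#'
#' @param path file path.
#' @return a \code{\link{chemostat_dataset}}.
#' @export
read_chemostat_csv <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  check_header(path, names(d), c("mu_per_h", "qs_g_per_g_h"))
  chemostat_dataset(
    mu = d$mu_per_h, q_S = d$qs_g_per_g_h,
    q_P = if ("qp_mg_per_g_h" %in% names(d)) d$qp_mg_per_g_h / 1000 else NULL,
    replicate = if ("replicate_id" %in% names(d)) d$replicate_id else NULL)
}

#' @rdname read_chemostat_csv
#' @param data a \code{\link{chemostat_dataset}} to write.
#' @export
write_chemostat_csv <- function(data, path) {
  stopifnot(inherits(data, "chemostat_dataset"))
  out <- data.frame(mu_per_h = data$mu, qs_g_per_g_h = data$q_S,
                    qp_mg_per_g_h = 1000 * data$q_P,
                    replicate_id = data$replicate)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read retentostat observation CSV
#'
#' Columns: \code{t_h}, \code{cx_g_l}, optional \code{cxv_g_l} and
#' \code{cp_g_l}.
#'
#' @param path file path.
#' @return a \code{\link{retentostat_obs}}.
#' @export
read_retentostat_csv <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  check_header(path, names(d), c("t_h", "cx_g_l"))
  retentostat_obs(
    t = d$t_h, C_X = d$cx_g_l,
    C_Xv = if ("cxv_g_l" %in% names(d)) d$cxv_g_l else d$cx_g_l,
    C_P = if ("cp_g_l" %in% names(d)) d$cp_g_l else NULL)
}

#' @rdname read_retentostat_csv
#' @param obs a \code{\link{retentostat_obs}} to write.
#' @export
write_retentostat_csv <- function(obs, path) {
  stopifnot(inherits(obs, "retentostat_obs"))
  out <- data.frame(t_h = obs$t, cx_g_l = obs$C_X, cxv_g_l = obs$C_Xv,
                    cp_g_l = obs$C_P)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a simulated trajectory CSV
#'
#' Columns: \code{t_h}, \code{cx_g_l}, \code{cs_feed_g_l}, \code{mu_per_h},
#' \code{qs_g_g_h}, \code{cp_g_l}, \code{qp_g_g_h}.
#'
#' @param traj a \code{\link{simulate_retentostat}} result.
#' @param path file path.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "retentostat_trajectory"))
  out <- data.frame(t_h = traj$t, cx_g_l = traj$C_X,
                    cs_feed_g_l = traj$C_S_feed, mu_per_h = traj$mu,
                    qs_g_g_h = traj$q_S, cp_g_l = traj$C_P,
                    qp_g_g_h = traj$q_P)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path, fileEncoding = "UTF-8")
  check_header(path, names(d), c("t_h", "cx_g_l", "cs_feed_g_l", "mu_per_h",
                                 "qs_g_g_h", "cp_g_l", "qp_g_g_h"))
  data.frame(t = d$t_h, C_X = d$cx_g_l, C_S_feed = d$cs_feed_g_l,
             mu = d$mu_per_h, q_S = d$qs_g_g_h, C_P = d$cp_g_l,
             q_P = d$qp_g_g_h)
}

#' Write a fitted parameter set as JSON with explicit units
#'
#' @param params a \code{\link{pirt_params}} (window-average attributes
#'   included when present).
#' @param path file path.
#' @export
write_params_json <- function(params, path) {
  stopifnot(is_pirt_params(params))
  obj <- list(
    m_S = list(value = 1000 * params$m_S, units = "mg/g/h"),
    Y_XS_max = list(value = params$Y_XS_max, units = "g/g"),
    Y_PS_max = list(value = params$Y_PS_max, units = "g/g"))
  if (!is.null(attr(params, "sd_m_S"))) {
    obj$m_S$sd <- 1000 * attr(params, "sd_m_S")
    obj$Y_XS_max$sd <- attr(params, "sd_Y_XS_max")
    obj$n_windows <- attr(params, "n_windows")
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a reactor/strain configuration file (YAML)
#'
#' Keys: \code{v_reactor_l}, \code{v_mix_l}, \code{phi_per_h},
#' \code{cs_high_g_l}, \code{cs_low_g_l}, \code{d_chemostat_per_h},
#' \code{ms_g_g_h}, \code{yxs_g_g}, \code{yps_g_g}, and \code{qp_model}
#' (a mapping with \code{type: linear|gompertz|zero} and the model's
#' parameters in g/g/h).
#'
#' @param path file path.
#' @return list with elements \code{config} (\code{\link{reactor_config}}),
#'   \code{params} (\code{\link{pirt_params}}) and \code{qp_model}.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("v_reactor_l", "v_mix_l", "phi_per_h", "cs_high_g_l",
            "cs_low_g_l", "ms_g_g_h", "yxs_g_g", "yps_g_g")
  miss <- setdiff(need, names(y))
  if (length(miss))
    stop(sprintf("'%s': missing config key(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  cfg <- reactor_config(
    v_reactor = y$v_reactor_l, v_mix = y$v_mix_l, phi = y$phi_per_h,
    C_S_high = y$cs_high_g_l, C_S_low = y$cs_low_g_l,
    D_chemostat = if (!is.null(y$d_chemostat_per_h)) y$d_chemostat_per_h
                  else y$phi_per_h)
  params <- pirt_params(y$ms_g_g_h, y$yxs_g_g, y$yps_g_g)
  qp <- if (is.null(y$qp_model) || identical(y$qp_model$type, "zero")) {
    qp_zero()
  } else if (identical(y$qp_model$type, "linear")) {
    qp_linear(y$qp_model$slope, y$qp_model$intercept)
  } else if (identical(y$qp_model$type, "gompertz")) {
    qp_gompertz(y$qp_model$a, y$qp_model$b, y$qp_model$c)
  } else {
    stop(sprintf("'%s': unknown qp_model type '%s'", path, y$qp_model$type),
         call. = FALSE)
  }
  list(config = cfg, params = params, qp_model = qp)
}

#' Run the whole analysis pipeline on synthetic data
#'
#' End-to-end reproduction driver: generates a chemostat dataset, estimates
#' the Pirt parameters by moving-window regression, fits the linear and
#' Gompertz productivity models, generates retentostat observations, fits
#' the retentostat maintenance coefficient, and estimates q_P(t) by the
#' piecewise product balance. All intermediates are written as CSV/JSON
#' into \code{out_dir}, together with a \code{summary.json} (headline
#' numbers) and a \code{manifest.json} (inputs, seed, package version,
#' timestamps).
#'
#' @param out_dir output directory (created if needed).
#' @param seed integer seed governing all synthetic noise.
#' @param config a \code{\link{reactor_config}}.
#' @param params_true generating \code{\link{pirt_params}} for the chemostat
#'   stage (low-mu regime).
#' @param params_retentostat generating parameters for the retentostat stage
#'   (defaults to \code{params_true}).
#' @param qp_true generating productivity model.
#' @param noise a \code{\link{noise_spec}} template (its seed is overridden
#'   stage by stage, derived from \code{seed}).
#' @return (invisibly) the summary list.
#' @export
run_pipeline <- function(out_dir, seed = 1, config = reactor_config(),
                         params_true = pirt_params(0.00437, 0.544),
                         params_retentostat = params_true,
                         qp_true = qp_gompertz_default(),
                         noise = noise_spec()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  status <- "complete"
  headline <- list()
  manifest <- list(command = "run_pipeline", seed = seed,
                   package_version = as.character(utils::packageVersion("retentoKin")),
                   started = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  result <- try({
    n1 <- noise; n1$seed <- seed
    chem <- make_chemostat_dataset(params_true, qp_true, noise = n1)
    write_chemostat_csv(chem, p("chemostat.csv"))

    pf <- fit_pirt(chem, Y_PS_max = params_true$Y_PS_max)
    write_params_json(pf$params, p("pirt_params.json"))

    qp_lin <- fit_qp_linear(chem$mu, chem$q_P)
    jsonlite::write_json(list(type = "linear", slope = qp_lin$slope,
                              intercept = qp_lin$intercept),
                         p("qp_linear.json"), auto_unbox = TRUE, digits = NA)

    n2 <- noise; n2$seed <- seed + 1000L
    obs <- make_retentostat_observations(config, params_retentostat, qp_true,
                                         noise = n2)
    write_retentostat_csv(obs, p("retentostat_obs.csv"))

    pairs <- qp_mu_pairs(obs, config)
    qp_gom <- fit_qp_gompertz(c(pairs$mu, chem$mu), c(pairs$q_P, chem$q_P))
    jsonlite::write_json(c(list(type = "gompertz"), as.list(coef(qp_gom))),
                         p("qp_gompertz.json"), auto_unbox = TRUE, digits = NA)

    rf <- fit_retentostat(obs, config, pf$params, qp_model = qp_gom)
    write_trajectory_csv(rf$trajectory, p("retentostat_fit_trajectory.csv"))

    qps <- qp_series(t_titer = obs$t[!is.na(obs$C_P)],
                     titer = obs$C_P[!is.na(obs$C_P)],
                     t_biomass = obs$t, biomass = obs$C_X, phi = config$phi)
    utils::write.csv(
      data.frame(t_start_h = qps$t_start, t_end_h = qps$t_end,
                 cp0_g_l = qps$C_P_0, cpn_g_l = qps$C_P_N,
                 qp_mg_g_h = 1000 * qps$q_P, flag = qps$flag),
      p("qp_series.csv"), row.names = FALSE, quote = FALSE)

    headline <- list(
      m_S_chemostat_mg_g_h = 1000 * pf$params$m_S,
      m_S_retentostat_mg_g_h = 1000 * rf$m_S_hat,
      terminal_mu_per_h = rf$terminal_mu,
      doubling_time_days = doubling_time(rf$terminal_mu),
      terminal_qp_mg_g_h = 1000 * qps$q_P[nrow(qps)])
    jsonlite::write_json(headline, p("summary.json"), auto_unbox = TRUE,
                         digits = NA)
  }, silent = TRUE)
  if (inherits(result, "try-error")) status <- paste("failed:", conditionMessage(attr(result, "condition")))
  manifest$status <- status
  manifest$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  manifest$outputs <- list.files(out_dir)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE)
  if (status != "complete")
    stop("pipeline failed: ", status, call. = FALSE)
  invisible(headline)
}
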