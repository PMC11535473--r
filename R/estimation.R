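# channel -> ODE state-column map shared by prediction and teacher forcing
.channel_state_map <- c(
  VCD = "Xv", TITER = "mAb",
  GLC = "GLC", GLN = "GLN", GLU = "GLU", LAC = "LAC", NH4 = "NH4", GAL = "GAL",
  UDP_GLC = "UDP_Glc", UDP_GAL = "UDP_Gal",
  UDP_GLCNAC = "UDP_GlcNAc", UDP_GALNAC = "UDP_GalNAc",
  G0F = "G0F", G1F = "G1F", G2F = "G2F"
)

# linear interpolation of a trajectory column at arbitrary times
.traj_interp <- function(traj, column, times) {
  stats::approx(traj$time_h, traj[[column]], xout = times, rule = 1)$y
}

#' Run a deterministic seeded computation without disturbing the global RNG
#' @noRd
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Default inverse-squared-mean channel weights
#'
#' Channels span nine orders of magnitude (cells/mL to mM); weighting each
#' channel's squared residuals by 1/mean(|value|)^2 makes the sum-of-squares
#' objective scale-invariant: rescaling a channel's units leaves the optimum
#' unchanged.
#'
#' @param data A culture table.
#' @return Named numeric vector of weights, one per channel present.
#' @export
default_channel_weights <- function(data) {
  data |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::group_by(.data$channel) |>
    dplyr::summarise(m = mean(abs(.data$value)), .groups = "drop") |>
    (\(d) stats::setNames(ifelse(d$m > 0, 1 / d$m^2, 1), d$channel))()
}

#' Weighted sum of squared errors of a trajectory against observations
#'
#' Sums `w_c * (obs - pred)^2` over all non-missing observations, with
#' predictions linearly interpolated from the trajectory. Under independent
#' Gaussian errors with variance 1/w_c this is -2 log-likelihood up to a
#' constant, which is the MLE--SSE equivalence the fitting relies on.
#'
#' @param traj A `fedbatch_trajectory`.
#' @param data A culture table; missing values contribute 0.
#' @param weights Named per-channel weights; defaults to
#'   [default_channel_weights()] of `data`.
#' @return A scalar SSE with attribute `per_channel`.
#' @export
weighted_sse <- function(traj, data, weights = default_channel_weights(data)) {
  obs <- dplyr::filter(data, !is.na(.data$value))
  if (nrow(obs) == 0) {
    return(structure(0, per_channel = numeric()))
  }
  if (any(obs$time_h < min(traj$time_h) | obs$time_h > max(traj$time_h))) {
    stop("observation time outside the simulated span", call. = FALSE)
  }
  per <- obs |>
    dplyr::group_by(.data$channel) |>
    dplyr::group_map(function(g, key) {
      chan <- key$channel
      pred <- .traj_interp(traj, .channel_state_map[[chan]], g$time_h)
      w <- if (chan %in% names(weights)) weights[[chan]] else 1
      tibble::tibble(channel = chan, sse = sum(w * (g$value - pred)^2))
    }) |>
    dplyr::bind_rows()
  structure(sum(per$sse), per_channel = stats::setNames(per$sse, per$channel))
}

# reset directly-mapped measured channels in a state vector; glycan fractions
# are reset jointly (rescaling the glycoform masses at fixed total) only when
# all three are measured.
.teacher_reset <- function(state, obs_row_tbl) {
  direct <- setdiff(names(.channel_state_map), glycan_channels())
  for (i in seq_len(nrow(obs_row_tbl))) {
    ch <- obs_row_tbl$channel[i]
    v <- obs_row_tbl$value[i]
    if (is.na(v)) next
    if (ch %in% direct) state[[.channel_state_map[[ch]]]] <- v
  }
  gly <- obs_row_tbl[obs_row_tbl$channel %in% glycan_channels() &
                       !is.na(obs_row_tbl$value), ]
  if (nrow(gly) == 3) {
    fr <- stats::setNames(gly$value, gly$channel)
    tot <- state[["M_G0F"]] + state[["M_G1F"]] + state[["M_G2F"]]
    state[["M_G0F"]] <- tot * fr[["G0F"]] / 100
    state[["M_G1F"]] <- tot * fr[["G1F"]] / 100
    state[["M_G2F"]] <- tot * fr[["G2F"]] / 100
  }
  state
}

#' Teacher-forcing residuals of a kinetic parameter set
#'
#' For consecutive observation times, the simulated state is re-initialized
#' to the measured values of every observed channel at the segment start
#' (unobserved channels carry the simulated value over), integrated to the
#' next observation time, and the residuals observed - predicted at the
#' segment end are emitted. This makes each residual depend only on its own
#' segment, which regularizes the likelihood surface of the ODE fit.
#'
#' @param p A [kinetic_params()] object.
#' @param data A culture table for one batch with at least two observation
#'   times.
#' @param schedule A [feed_schedule()].
#' @param init Initial state at the first observation time.
#' @param rtol,atol Solver tolerances.
#' @param maxsteps Maximum solver steps per output interval.
#' @return Tibble `time_h`, `channel`, `observed`, `predicted`, `residual`.
#' @export
teacher_forcing_residuals <- function(p, data, schedule, init = initial_state(),
                                      rtol = 1e-6, atol = 1e-8,
                                      maxsteps = 50000) {
  obs <- dplyr::filter(data, !is.na(.data$value))
  times <- sort(unique(obs$time_h))
  if (length(times) < 2) {
    stop("teacher forcing needs at least two observation times", call. = FALSE)
  }
  ev <- sort(unique(c(schedule$feed_events$time_h, schedule$sample_events$time_h)))
  state <- .teacher_reset(init, obs[obs$time_h == times[1], ])
  out <- list()
  for (k in seq_len(length(times) - 1)) {
    t0 <- times[k]; t1 <- times[k + 1]
    seg_sched <- schedule
    seg_sched$feed_events <- schedule$feed_events[
      schedule$feed_events$time_h > t0 & schedule$feed_events$time_h <= t1, ]
    seg_sched$sample_events <- schedule$sample_events[
      schedule$sample_events$time_h > t0 & schedule$sample_events$time_h <= t1, ]
    seg_sched$initial_volume_mL <- state[["V"]]
    t_eval <- sort(unique(c(t0, t1, ev[ev > t0 & ev <= t1])))
    traj <- simulate_fedbatch(p, init = state, schedule = seg_sched,
                              t_eval = t_eval, rtol = rtol, atol = atol,
                              maxsteps = maxsteps)
    end <- traj[nrow(traj), ]
    seg_obs <- obs[obs$time_h == t1, ]
    pred <- vapply(seg_obs$channel,
                   function(ch) end[[.channel_state_map[[ch]]]], numeric(1))
    out[[k]] <- tibble::tibble(
      time_h = t1, channel = seg_obs$channel,
      observed = seg_obs$value, predicted = unname(pred),
      residual = seg_obs$value - unname(pred)
    )
    # carry the full simulated state, then clamp measured channels to data
    state <- unlist(end[, setdiff(names(end), c("time_h", "G0F", "G1F", "G2F"))])
    state <- .teacher_reset(state, seg_obs)
  }
  dplyr::bind_rows(out)
}

#' Fit kinetic parameters by maximum likelihood (weighted least squares)
#'
#' Multi-start bound-constrained least squares for a configurable subset of
#' the kinetic parameters. With Gaussian measurement error the maximum
#' likelihood estimate is the minimizer of the weighted SSE, computed either
#' on free forward simulations from the initial state or on teacher-forcing
#' segment residuals. Optimization runs in log10 parameter space
#' (parameters are positive scale quantities) with the Levenberg--Marquardt
#' algorithm; starts are drawn log-uniform within the bounds from the given
#' seed, and the best-SSE start is reported. Deterministic for a fixed seed.
#'
#' @param p0 A [kinetic_params()] starting/reference set; parameters not in
#'   `fit_params` stay fixed at their `p0` values.
#' @param data Culture table of one batch (non-missing rows are used).
#' @param schedule A [feed_schedule()].
#' @param init Initial state for simulation.
#' @param fit_params Character vector of parameter names to estimate.
#' @param lower,upper Named bounds (original scale) for the fitted subset;
#'   default is p0/100 .. p0*100.
#' @param mode `"free"` or `"teacher_forcing"`.
#' @param n_starts Number of random starts (the first start is `p0` itself).
#' @param seed Integer seed controlling the starts.
#' @param weighting `"channel"` (per-channel inverse-squared-mean weights)
#'   or `"relative"` (per-observation 1/|obs| scaling, floored at 5% of the
#'   channel mean — the maximum likelihood weighting when measurement error
#'   is multiplicative with a constant CV).
#' @param weights Per-channel weights for `weighting = "channel"`; default
#'   [default_channel_weights()].
#' @param rtol,atol Solver tolerances used during fitting.
#' @param maxit Maximum LM iterations per start.
#' @param maxsteps Solver step budget per output interval during fitting;
#'   pathological parameter regions fail fast and are penalized.
#' @param epsfcn Relative finite-difference step for the numeric Jacobian;
#'   keep well above the squared solver tolerance so derivative estimates
#'   are not dominated by integration noise.
#' @return An `mmk_fit` object: fitted [kinetic_params()], SSE ledger,
#'   convergence diagnostics, seed and best start index.
#' @export
fit_kinetics <- function(p0, data, schedule = feed_schedule(),
                         init = initial_state(),
                         fit_params = c("mu_max", "K_glc", "Y_xglc"),
                         lower = NULL, upper = NULL,
                         mode = c("free", "teacher_forcing"),
                         n_starts = 8, seed = 1,
                         weighting = c("channel", "relative"),
                         weights = default_channel_weights(data),
                         rtol = 1e-6, atol = 1e-8, maxit = 50,
                         maxsteps = 3000, epsfcn = 1e-6) {
  mode <- match.arg(mode)
  weighting <- match.arg(weighting)
  data <- dplyr::filter(data, !is.na(.data$value))
  if (nrow(data) == 0) stop("no observations to fit", call. = FALSE)
  stopifnot(all(fit_params %in% names(p0)))
  theta0 <- unlist(p0[fit_params])
  if (is.null(lower)) lower <- theta0 / 100
  if (is.null(upper)) upper <- theta0 * 100
  lower <- lower[fit_params]; upper <- upper[fit_params]
  stopifnot(all(theta0 >= lower & theta0 <= upper), all(lower > 0))

  # sampling events only remove volume; every intensive state is unchanged,
  # so they cannot affect residuals — drop them to avoid integrator restarts
  schedule$sample_events <- schedule$sample_events[0, ]
  obs_times <- sort(unique(data$time_h))
  ev <- sort(unique(schedule$feed_events$time_h))
  t_eval <- sort(unique(c(obs_times, ev[ev >= min(obs_times) & ev <= max(obs_times)])))
  if (min(t_eval) > 0) t_eval <- c(0, t_eval)
  sqw <- function(chan) {
    sqrt(vapply(chan, function(ch) {
      if (ch %in% names(weights)) weights[[ch]] else 1
    }, numeric(1)))
  }
  # relative weighting matches the multiplicative (CV-based) error model:
  # residuals are scaled by 1/|obs|, floored at 5% of the channel mean so
  # near-zero observations do not dominate
  rel_scale <- function(values, chan) {
    m <- stats::ave(abs(values), chan, FUN = mean)
    1 / pmax(abs(values), 0.05 * m)
  }

  n_evals <- 0L
  resid_fun <- function(log_theta) {
    n_evals <<- n_evals + 1L
    p <- p0
    p[fit_params] <- as.list(10^log_theta)
    tryCatch(suppressWarnings({
      if (mode == "free") {
        traj <- simulate_fedbatch(p, init = init, schedule = schedule,
                                  t_eval = t_eval, rtol = rtol, atol = atol,
                                  maxsteps = maxsteps)
        pred <- vapply(seq_len(nrow(data)), function(i) {
          .traj_interp(traj, .channel_state_map[[data$channel[i]]],
                       data$time_h[i])
        }, numeric(1))
        if (weighting == "relative") {
          (data$value - pred) * rel_scale(data$value, data$channel)
        } else {
          (data$value - pred) * sqw(data$channel)
        }
      } else {
        r <- teacher_forcing_residuals(p, data, schedule, init = init,
                                       rtol = rtol, atol = atol,
                                       maxsteps = maxsteps)
        if (weighting == "relative") {
          r$residual * rel_scale(r$observed, r$channel)
        } else {
          r$residual * sqw(r$channel)
        }
      }
    }), error = function(e) rep(1e6, nrow(data)))
  }

  starts <- .with_seed(seed, {
    s <- matrix(0, nrow = n_starts, ncol = length(fit_params),
                dimnames = list(NULL, fit_params))
    s[1, ] <- log10(theta0)
    if (n_starts > 1) {
      for (i in seq(2, n_starts)) {
        s[i, ] <- stats::runif(length(fit_params), log10(lower), log10(upper))
      }
    }
    s
  })

  fits <- lapply(seq_len(n_starts), function(i) {
    tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], fn = resid_fun,
                         lower = log10(lower), upper = log10(upper),
                         control = minpack.lm::nls.lm.control(
                           maxiter = maxit, epsfcn = epsfcn)),
      error = function(e) NULL
    )
  })
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) stop("all optimization starts failed", call. = FALSE)
  sse <- vapply(fits, function(f) {
    if (is.null(f)) Inf else sum(f$fvec^2)
  }, numeric(1))
  best <- which.min(sse)
  fit <- fits[[best]]

  p_hat <- p0
  p_hat[fit_params] <- as.list(10^fit$par)
  traj <- simulate_fedbatch(p_hat, init = init, schedule = schedule,
                            t_eval = t_eval, rtol = rtol, atol = atol)
  final_sse <- weighted_sse(traj, data, weights)

  structure(list(
    params = p_hat, fit_params = fit_params,
    estimates = stats::setNames(as.numeric(10^fit$par), fit_params),
    lower = lower, upper = upper,
    sse = as.numeric(final_sse),
    per_channel_sse = attr(final_sse, "per_channel"),
    objective_sse = sse[best],
    n_function_evals = n_evals,
    converged = fit$info %in% 1:4,
    seed = seed, best_start = best, mode = mode,
    n_starts = n_starts
  ), class = "mmk_fit")
}

#' @export
print.mmk_fit <- function(x, ...) {
  cat("Kinetic model fit (", x$mode, " mode, ", x$n_starts, " starts)\n", sep = "")
  cat("  SSE:", signif(x$sse, 6), " converged:", x$converged, "\n")
  print(signif(x$estimates, 5))
  invisible(x)
}

#' Tidy and summarize a kinetic model fit
#'
#' `tidy()` returns one row per fitted parameter with the estimate and
#' bounds; `glance()` returns a one-row model summary.
#'
#' @param x An `mmk_fit` object.
#' @param ... Unused.
#' @export
tidy.mmk_fit <- function(x, ...) {
  tibble::tibble(
    term = x$fit_params,
    estimate = unname(x$estimates),
    lower = unname(x$lower),
    upper = unname(x$upper)
  )
}

#' @rdname tidy.mmk_fit
#' @export
glance.mmk_fit <- function(x, ...) {
  tibble::tibble(
    sse = x$sse, n_params = length(x$fit_params),
    n_function_evals = x$n_function_evals,
    converged = x$converged, best_start = x$best_start, seed = x$seed
  )
}
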