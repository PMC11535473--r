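# Shared fixtures and independent oracles for the test suite.

# small random culture table (values include missing cells)
random_culture_table <- function(n = 50, seed = 1, na_frac = 0.2) {
  withr::with_seed(seed, {
    chans <- culture_channels()$channel
    tbl <- tibble::tibble(
      batch_id = "b1", condition = "Control",
      replicate = 1L,
      time_h = rep(seq(0, by = 12, length.out = ceiling(n / 5)), each = 5)[1:n],
      channel = replicate(n, sample(chans, 1)),
      value = round(stats::runif(n, 0, 50), 6)
    ) |>
      dplyr::distinct(.data$time_h, .data$channel, .keep_all = TRUE)
    tbl$value[sample(nrow(tbl), floor(na_frac * nrow(tbl)))] <- NA_real_
    tbl
  })
}

zero_missingness <- function() {
  do.call(missingness_spec,
          as.list(stats::setNames(rep(0, 15), names(missingness_spec()))))
}

# independent PLS2 oracle: per component the weight is the first left
# singular vector of X'Y (the NIPALS fixed point), with standard deflation.
# Complete data only; X and Y are autoscaled internally.
pls2_oracle_predict <- function(X, Y, A) {
  xc <- colMeans(X); xs <- apply(X, 2, stats::sd)
  yc <- colMeans(Y); ys <- apply(Y, 2, stats::sd)
  Xc <- sweep(sweep(X, 2, xc), 2, xs, "/")
  Yc <- sweep(sweep(Y, 2, yc), 2, ys, "/")
  Yhat <- matrix(0, nrow(X), ncol(Y))
  for (a in seq_len(A)) {
    w <- svd(crossprod(Xc, Yc))$u[, 1]
    t <- Xc %*% w
    cc <- crossprod(Yc, t) / sum(t^2)
    p <- crossprod(Xc, t) / sum(t^2)
    Xc <- Xc - t %*% t(p)
    Yc <- Yc - t %*% t(cc)
    Yhat <- Yhat + t %*% t(cc)
  }
  sweep(sweep(Yhat, 2, ys, "*"), 2, yc, "+")
}

# studentized-range upper-tail probability by direct numeric double
# integration (independent of stats::ptukey): the inner integral is the
# probability that k normal draws span less than q*s, integrated over the
# chi distribution of the pooled-SD scale factor s.
ptukey_oracle <- function(q, k, df) {
  inner <- function(s) {
    f <- function(z) {
      k * stats::dnorm(z) * (stats::pnorm(z) - stats::pnorm(z - q * s))^(k - 1)
    }
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-10)$value
  }
  # density of s = sqrt(chi^2_df / df)
  dscale <- function(s) {
    exp((df / 2) * log(df / 2) - lgamma(df / 2) + (df - 1) * log(s) -
          df * s^2 / 2 + log(2))
  }
  p_le <- stats::integrate(function(s) {
    vapply(s, function(si) dscale(si) * inner(si), numeric(1))
  }, 0, Inf, rel.tol = 1e-9)$value
  1 - p_le
}

# fixed-step classical RK4 integrator over the same RHS, feeds applied
# between steps; independent of deSolve's adaptive machinery.
rk4_fedbatch <- function(p, init, schedule, t_end, dt = 0.01, t_record) {
  ev <- schedule$feed_events
  state <- init
  state[["V"]] <- schedule$initial_volume_mL
  times <- seq(0, t_end, by = dt)
  out <- list()
  rec_idx <- 1
  record <- function(t, s) out[[length(out) + 1]] <<- c(time_h = t, s)
  if (0 %in% t_record) record(0, state)
  for (i in seq_len(length(times) - 1)) {
    t0 <- times[i]; t1 <- times[i + 1]
    h <- t1 - t0
    k1 <- fedbatch_rhs(t0, state, p)[[1]]
    k2 <- fedbatch_rhs(t0 + h / 2, state + h / 2 * k1, p)[[1]]
    k3 <- fedbatch_rhs(t0 + h / 2, state + h / 2 * k2, p)[[1]]
    k4 <- fedbatch_rhs(t1, state + h * k3, p)[[1]]
    state <- state + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    state <- pmax(state, 0)
    if (nrow(ev) > 0) {
      hit <- which(abs(ev$time_h - t1) < dt / 2)
      for (j in hit) {
        state <- apply_feed_event(state, ev$species[j], ev$dose_mM[j])
      }
    }
    near <- which(abs(t_record - t1) < dt / 2)
    if (length(near) > 0) record(t_record[near[1]], state)
  }
  tibble::as_tibble(as.data.frame(do.call(rbind, out)))
}

# quick small dataset for the data-driven model tests: training conditions
# with modest noise, cached per session
cached_small_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(seed = 42, noise = noise_spec(0.03),
                                 missing = missingness_spec())
    }
    cache
  }
})
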