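#' Trainable parameter count of a one-hidden-layer network
#'
#' Fully connected `n_in`--`n_hidden`--`n_out` network with biases on the
#' hidden and output layers: `n_in*n_hidden + n_hidden + n_hidden*n_out +
#' n_out` parameters. The soft-sensor architecture (6 extracellular
#' metabolite inputs, 3 tanh hidden units, 8 response outputs) has 53.
#'
#' @param n_in,n_hidden,n_out Layer sizes, all >= 1.
#' @return Integer parameter count.
#' @examples
#' count_parameters(6, 3, 8) # 53
#' @export
count_parameters <- function(n_in, n_hidden, n_out) {
  if (any(c(n_in, n_hidden, n_out) < 1)) {
    stop("layer sizes must be positive", call. = FALSE)
  }
  as.integer(n_in * n_hidden + n_hidden + n_hidden * n_out + n_out)
}

# pack/unpack the parameter vector (column-major W1, b1, W2, b2)
.nn_unpack <- function(theta, p, h, q) {
  i <- 0
  W1 <- matrix(theta[i + seq_len(p * h)], p, h); i <- i + p * h
  b1 <- theta[i + seq_len(h)]; i <- i + h
  W2 <- matrix(theta[i + seq_len(h * q)], h, q); i <- i + h * q
  b2 <- theta[i + seq_len(q)]
  list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
}

.nn_pack <- function(W1, b1, W2, b2) c(as.numeric(W1), b1, as.numeric(W2), b2)

# forward pass on scaled inputs: Xs (n x p) -> scaled predictions (n x q)
.nn_forward_scaled <- function(Xs, W1, b1, W2, b2) {
  Z <- tanh(sweep(Xs %*% W1, 2, b1, "+"))
  sweep(Z %*% W2, 2, b2, "+")
}

#' Forward pass of the soft-sensor network
#'
#' Scales the input with the training statistics (missing inputs imputed to
#' the training mean), applies the tanh hidden layer, and de-scales the
#' output to original units. Outputs are unconstrained reals: negative
#' concentration predictions are possible and preserved.
#'
#' @param model An `nn_model`.
#' @param x Numeric factor vector (length `n_in`) or matrix (rows = cases).
#' @return Matrix of predictions in original units (rows x responses).
#' @export
nn_forward <- function(model, x) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  Xs <- sweep(sweep(X, 2, model$x_center), 2, model$x_scale, "/")
  Xs[is.na(Xs)] <- 0 # training mean in scaled units
  Ys <- .nn_forward_scaled(Xs, model$W1, model$b1, model$W2, model$b2)
  out <- sweep(sweep(Ys, 2, model$y_scale, "*"), 2, model$y_center, "+")
  colnames(out) <- model$y_names
  out
}

#' @export
predict.nn_model <- function(object, newdata, ...) nn_forward(object, newdata)

#' Penalized Gaussian likelihood objective of the network
#'
#' Negative log-likelihood proportional to the SSE over the non-missing
#' scaled responses, plus `lambda` times the sum of squared weights (biases
#' unpenalized). Rows missing a response contribute only their observed
#' channels; this skip-missing sum is what lets a nearly-empty response
#' channel be dropped without touching the rest.
#'
#' `nn_objective_gradient()` is the exact analytic gradient by
#' backpropagation, in the same parameter packing as the objective.
#'
#' @param theta Packed parameter vector.
#' @param Xs Scaled factor matrix (missing already imputed to 0).
#' @param Ys Scaled response matrix, `NA` for unobserved cells.
#' @param lambda Penalty weight, >= 0.
#' @return Scalar objective (`nn_objective`) or gradient vector.
#' @export
nn_objective <- function(theta, Xs, Ys, lambda = 0) {
  p <- ncol(Xs); q <- ncol(Ys)
  h <- (length(theta) - q) / (p + 1 + q)
  par <- .nn_unpack(theta, p, h, q)
  Pred <- .nn_forward_scaled(Xs, par$W1, par$b1, par$W2, par$b2)
  sse <- sum((Pred - Ys)^2, na.rm = TRUE)
  sse + lambda * (sum(par$W1^2) + sum(par$W2^2))
}

#' @rdname nn_objective
#' @export
nn_objective_gradient <- function(theta, Xs, Ys, lambda = 0) {
  p <- ncol(Xs); q <- ncol(Ys)
  h <- (length(theta) - q) / (p + 1 + q)
  par <- .nn_unpack(theta, p, h, q)
  Z <- tanh(sweep(Xs %*% par$W1, 2, par$b1, "+"))
  Pred <- sweep(Z %*% par$W2, 2, par$b2, "+")
  E <- 2 * (Pred - Ys)
  E[is.na(E)] <- 0
  gW2 <- crossprod(Z, E) + 2 * lambda * par$W2
  gb2 <- colSums(E)
  D <- (E %*% t(par$W2)) * (1 - Z^2)
  gW1 <- crossprod(Xs, D) + 2 * lambda * par$W1
  gb1 <- colSums(D)
  .nn_pack(gW1, gb1, gW2, gb2)
}

# BFGS with validation-likelihood stopping: optimize in chunks of `window`
# iterations and stop when the monitored objective stops improving.
.nn_bfgs <- function(theta, Xs, Ys, lambda, Xv, Yv, max_iter = 300,
                     window = 10, tol = 1e-8) {
  monitor <- function(th) {
    if (is.null(Xv) || nrow(Xv) == 0) nn_objective(th, Xs, Ys, lambda)
    else nn_objective(th, Xv, Yv, 0)
  }
  best_mon <- monitor(theta)
  log_rows <- list()
  iters <- 0
  while (iters < max_iter) {
    opt <- stats::optim(theta, fn = nn_objective, gr = nn_objective_gradient,
                        Xs = Xs, Ys = Ys, lambda = lambda, method = "BFGS",
                        control = list(maxit = window))
    theta <- opt$par
    iters <- iters + window
    mon <- monitor(theta)
    log_rows[[length(log_rows) + 1]] <- c(iter = iters, train = opt$value,
                                          monitored = mon)
    if (opt$convergence == 0) break      # inner BFGS converged
    if (mon > best_mon - tol) break      # validation no longer improving
    best_mon <- mon
  }
  list(theta = theta, train_obj = opt$value, monitored = best_mon,
       log = do.call(rbind, log_rows))
}

#' Fit the penalized tanh soft-sensor network
#'
#' Training mirrors the two-level scheme of penalized-likelihood network
#' fitting: normally distributed random starts (from `seed`), an initial fit
#' with the penalty at zero, then a golden-section line search on the log
#' penalty parameter with an inner BFGS (analytic gradient) for each
#' candidate. During each BFGS run the likelihood on the validation rows is
#' monitored and training stops once it no longer improves over a
#' 10-iteration window. Among the line-search candidates the model with the
#' best training likelihood is reported. Deterministic given the seed.
#'
#' @param train,valid Culture tables; `valid` may be empty (stopping then
#'   watches the training-objective plateau).
#' @param responses Response channels to predict. The default excludes
#'   UDP-GlcNAc, whose near-empty channel (87% missing) degrades the joint
#'   fit; set explicitly to include it.
#' @param n_hidden Hidden tanh units (default 3).
#' @param n_starts Random starts (default 16).
#' @param seed Integer seed (default 1234).
#' @param lambda Fix the penalty at this value and skip the line search
#'   (default `NULL`: search).
#' @param lambda_grid Log10 range searched for the penalty.
#' @param n_search Golden-section evaluations (default 8).
#' @param max_iter Maximum BFGS iterations per fit.
#' @return An `nn_model`: weight matrices, biases, scaling statistics, the
#'   selected penalty and the training log.
#' @export
fit_nn <- function(train, valid = NULL,
                   responses = setdiff(response_channels(), "UDP_GLCNAC"),
                   n_hidden = 3, n_starts = 16, seed = 1234,
                   lambda = NULL, lambda_grid = c(-4, 2), n_search = 8,
                   max_iter = 300) {
  dm <- culture_design_matrices(train, include_time = FALSE,
                                responses = responses)
  X <- dm$X; Y <- dm$Y
  keep <- rowSums(!is.na(Y)) > 0 # rows with every response missing are dropped
  X <- X[keep, , drop = FALSE]; Y <- Y[keep, , drop = FALSE]
  if (nrow(X) == 0) stop("no usable training rows", call. = FALSE)
  sx <- .autoscale(X); sy <- .autoscale(Y)
  Xs <- sx$M; Xs[is.na(Xs)] <- 0
  Ys <- sy$M
  p <- ncol(Xs); q <- ncol(Ys)
  n_par <- count_parameters(p, n_hidden, q)

  Xv <- Yv <- NULL
  if (!is.null(valid) && nrow(valid) > 0) {
    dv <- culture_design_matrices(valid, include_time = FALSE,
                                  responses = responses)
    kv <- rowSums(!is.na(dv$Y)) > 0
    Xv <- sweep(sweep(dv$X[kv, , drop = FALSE], 2, sx$center), 2, sx$scale, "/")
    Xv[is.na(Xv)] <- 0
    Yv <- sweep(sweep(dv$Y[kv, , drop = FALSE], 2, sy$center), 2, sy$scale, "/")
  }

  starts <- .with_seed(seed, {
    matrix(stats::rnorm(n_starts * n_par, sd = 0.5), n_starts, n_par)
  })

  # stage 1: all starts at the initial penalty, keep the best objective
  lambda0 <- if (is.null(lambda)) 0 else lambda
  runs0 <- lapply(seq_len(n_starts), function(i) {
    .nn_bfgs(starts[i, ], Xs, Ys, lambda0, Xv, Yv, max_iter = max_iter)
  })
  train0 <- vapply(runs0, function(r) r$train_obj, numeric(1))
  best_start <- which.min(train0)
  theta_warm <- starts[best_start, ]

  # stage 2: golden-section line search on log10(lambda), warm-started;
  # candidates scored for selection by training likelihood (SSE part)
  candidates <- list(list(lambda = lambda0, run = runs0[[best_start]]))
  gr <- (sqrt(5) - 1) / 2
  a <- lambda_grid[1]; b <- lambda_grid[2]
  evals <- list()
  eval_lambda <- function(lg) {
    key <- sprintf("%.10g", lg)
    if (!is.null(evals[[key]])) return(evals[[key]])
    run <- .nn_bfgs(theta_warm, Xs, Ys, 10^lg, Xv, Yv, max_iter = max_iter)
    res <- list(lambda = 10^lg, run = run,
                score = if (!is.null(Xv)) nn_objective(run$theta, Xv, Yv, 0)
                        else run$train_obj)
    evals[[key]] <<- res
    candidates[[length(candidates) + 1]] <<- res
    res
  }
  if (is.null(lambda)) {
    x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
    f1 <- eval_lambda(x1)$score; f2 <- eval_lambda(x2)$score
    for (i in seq_len(max(0, n_search - 2))) {
      if (f1 < f2) {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - gr * (b - a); f1 <- eval_lambda(x1)$score
      } else {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + gr * (b - a); f2 <- eval_lambda(x2)$score
      }
    }
  }

  train_like <- vapply(candidates, function(cand) {
    nn_objective(cand$run$theta, Xs, Ys, 0)
  }, numeric(1))
  chosen <- candidates[[which.min(train_like)]]
  par <- .nn_unpack(chosen$run$theta, p, n_hidden, q)

  structure(list(
    W1 = par$W1, b1 = par$b1, W2 = par$W2, b2 = par$b2,
    x_center = sx$center, x_scale = sx$scale,
    y_center = sy$center, y_scale = sy$scale,
    x_names = colnames(X), y_names = colnames(Y),
    lambda = chosen$lambda, n_parameters = n_par,
    seed = seed, n_starts = n_starts, best_start = best_start,
    train_nll = min(train_like),
    log = chosen$run$log
  ), class = "nn_model")
}

#' @export
print.nn_model <- function(x, ...) {
  cat("tanh soft-sensor network ", length(x$x_names), "-", ncol(x$W1), "-",
      length(x$y_names), " (", x$n_parameters, " parameters), lambda = ",
      signif(x$lambda, 4), "\n", sep = "")
  invisible(x)
}

#' Training/validation fit quality per response
#'
#' R-squared and root average squared error (RASE, `sqrt(SSE/n)`) of the
#' network on a culture table, per response channel; the overfit check
#' compares these between training and validation data.
#'
#' @param model An `nn_model`.
#' @param data A culture table.
#' @return Tibble with `channel`, `n`, `r_squared`, `rase`.
#' @export
nn_fit_quality <- function(model, data) {
  dm <- culture_design_matrices(data, include_time = FALSE,
                                responses = model$y_names)
  pred <- nn_forward(model, dm$X)
  purrr::map_dfr(model$y_names, function(ch) {
    y <- dm$Y[, ch]; yh <- pred[, ch]
    ok <- !is.na(y)
    if (sum(ok) < 2) {
      return(tibble::tibble(channel = ch, n = sum(ok),
                            r_squared = NA_real_, rase = NA_real_))
    }
    sse <- sum((y[ok] - yh[ok])^2)
    sst <- sum((y[ok] - mean(y[ok]))^2)
    tibble::tibble(channel = ch, n = sum(ok),
                   r_squared = 1 - sse / sst, rase = sqrt(sse / sum(ok)))
  })
}

#' One-at-a-time prediction profiler
#'
#' Sweeps one factor over a grid while the others stay at the reference
#' point, returning the predicted response curves; grid values outside 120%
#' of the training range are flagged as extrapolation.
#'
#' @param model An `nn_model`.
#' @param reference Named factor vector (length `n_in`); defaults to the
#'   training means.
#' @param factor Factor name or index to sweep.
#' @param grid Numeric grid of factor values.
#' @return Tibble `factor`, `value`, `extrapolated`, one column per response.
#' @export
nn_profile <- function(model, reference = model$x_center, factor, grid) {
  if (is.character(factor)) factor <- match(factor, model$x_names)
  if (is.na(factor) || factor < 1 || factor > length(model$x_names)) {
    stop("invalid factor index", call. = FALSE)
  }
  ctr <- model$x_center[factor]
  half <- 1.2 * abs(model$x_scale[factor]) * 3 # ~3 sd band, widened 20%
  X <- matrix(rep(as.numeric(reference), each = length(grid)),
              nrow = length(grid))
  X[, factor] <- grid
  pred <- nn_forward(model, X)
  out <- tibble::tibble(
    factor = model$x_names[factor], value = grid,
    extrapolated = abs(grid - ctr) > half
  )
  dplyr::bind_cols(out, tibble::as_tibble(pred))
}

#' Tidy and summarize a fitted network
#'
#' `tidy()` returns every trainable parameter as one row (layer, from, to,
#' value); `glance()` returns the architecture and training summary.
#'
#' @param x An `nn_model`.
#' @param ... Unused.
#' @export
tidy.nn_model <- function(x, ...) {
  w1 <- tibble::tibble(
    layer = "input-hidden",
    from = rep(x$x_names, times = ncol(x$W1)),
    to = rep(paste0("h", seq_len(ncol(x$W1))), each = nrow(x$W1)),
    value = as.numeric(x$W1)
  )
  b1 <- tibble::tibble(layer = "hidden-bias", from = "1",
                       to = paste0("h", seq_along(x$b1)), value = x$b1)
  w2 <- tibble::tibble(
    layer = "hidden-output",
    from = rep(paste0("h", seq_len(nrow(x$W2))), times = ncol(x$W2)),
    to = rep(x$y_names, each = nrow(x$W2)),
    value = as.numeric(x$W2)
  )
  b2 <- tibble::tibble(layer = "output-bias", from = "1", to = x$y_names,
                       value = x$b2)
  dplyr::bind_rows(w1, b1, w2, b2)
}

#' @rdname tidy.nn_model
#' @export
glance.nn_model <- function(x, ...) {
  tibble::tibble(
    n_in = length(x$x_names), n_hidden = ncol(x$W1),
    n_out = length(x$y_names), n_parameters = x$n_parameters,
    lambda = x$lambda, train_nll = x$train_nll, seed = x$seed
  )
}
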