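make_linear_data <- function(n = 20, p = 7, q = 9, seed = 1, noise = 0) {
  withr::with_seed(seed, {
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    B <- matrix(stats::rnorm(p * q), p, q)
    Y <- X %*% B + noise * matrix(stats::rnorm(n * q), n, q)
    colnames(Y) <- paste0("y", seq_len(q))
    list(X = X, Y = Y)
  })
}

test_that("a perfect univariate relation is captured by one component", {
  withr::with_seed(1, {
    x <- matrix(stats::rnorm(30), ncol = 1, dimnames = list(NULL, "x1"))
  })
  m <- fit_opls(x, x, A_pred = 1, A_orth = 0)
  expect_gt(utils::tail(m$r2y_cum, 1), 1 - 1e-10)
  expect_lt(max(abs(predict(m, x) - x)), 1e-8)
})

test_that("constructed geometry: predictive aligns with y, orthogonal with z", {
  withr::with_seed(4, {
    y <- stats::rnorm(50)
    z <- stats::residuals(stats::lm(stats::rnorm(50) ~ y))
  })
  X <- cbind(x1 = y, x2 = z)
  m <- fit_opls(X, matrix(y, ncol = 1, dimnames = list(NULL, "y")),
                A_pred = 1, A_orth = 1)
  expect_gt(abs(stats::cor(m$T[, 1], y)), 0.99)
  expect_gt(abs(stats::cor(m$T_o[, 1], z)), 0.99)
})

test_that("with no orthogonal components OPLS equals an independent PLS oracle", {
  d <- make_linear_data(n = 20, p = 7, q = 9, seed = 2, noise = 0.3)
  for (A in 1:3) {
    m <- fit_opls(d$X, d$Y, A_pred = A, A_orth = 0)
    expect_lt(max(abs(predict(m, d$X) - pls2_oracle_predict(d$X, d$Y, A))),
              1e-8)
  }
})

test_that("orthogonal scores are uncorrelated with Y and predictive scores", {
  d <- make_linear_data(n = 40, p = 6, q = 3, seed = 3, noise = 0.2)
  m <- fit_opls(d$X, d$Y, A_pred = 2, A_orth = 2)
  expect_lt(max(abs(stats::cor(m$T_o, d$Y))), 1e-6)
  expect_lt(max(abs(crossprod(m$T_o, m$T))) /
              sqrt(max(colSums(m$T_o^2)) * max(colSums(m$T^2))), 1e-8)
  expect_equal(unname(sqrt(colSums(m$W^2))), rep(1, m$A_pred))
  expect_equal(unname(sqrt(colSums(m$W_o^2))), rep(1, m$A_orth))
  expect_true(all(m$r2x_cum >= 0 & m$r2x_cum <= 1))
  expect_true(all(m$r2y_cum >= 0 & m$r2y_cum <= 1))
})

test_that("prediction is idempotent on training data and filters orthogonal noise", {
  d <- make_linear_data(n = 30, p = 5, q = 2, seed = 5, noise = 0.1)
  m <- fit_opls(d$X, d$Y, A_pred = 2, A_orth = 1)
  fitted_y <- predict(m, d$X)
  expect_equal(predict(m, d$X), fitted_y) # idempotence

  # an all-missing row predicts the training mean
  na_row <- matrix(NA_real_, 1, 5, dimnames = list(NULL, colnames(d$X)))
  expect_equal(unname(predict(m, na_row)[1, ]), unname(m$y_center))

  # pure orthogonal-direction perturbation leaves predictions unchanged
  withr::with_seed(6, {
    y <- stats::rnorm(50)
    z <- stats::residuals(stats::lm(stats::rnorm(50) ~ y))
  })
  X2 <- cbind(x1 = y, x2 = z)
  m2 <- fit_opls(X2, matrix(y, ncol = 1, dimnames = list(NULL, "y")),
                 A_pred = 1, A_orth = 1)
  base <- predict(m2, X2)
  Xn <- X2
  Xn[, 2] <- Xn[, 2] + withr::with_seed(7, stats::rnorm(50))
  expect_lt(max(abs(predict(m2, Xn) - base)), 1e-8)

  expect_error(predict(m, d$X[, 1:3]), "training")
})

test_that("column rescaling is absorbed by autoscaling", {
  d <- make_linear_data(n = 30, p = 5, q = 2, seed = 8, noise = 0.1)
  m <- fit_opls(d$X, d$Y, A_pred = 2, A_orth = 1)
  X2 <- d$X
  X2[, 3] <- X2[, 3] * 1e4
  m2 <- fit_opls(X2, d$Y, A_pred = 2, A_orth = 1)
  expect_equal(predict(m2, X2), predict(m, d$X), tolerance = 1e-8)
  # zero-variance column is a scaling error
  X3 <- d$X
  X3[, 2] <- 1
  expect_error(fit_opls(X3, d$Y, A_pred = 1, A_orth = 0), "zero-variance")
})

test_that("missing cells are tolerated and barely move strong-signal predictions", {
  # collinear factors driven by two latent dimensions (the PLS use case:
  # metabolites move together) and concentration-scale responses with
  # nonzero means, as culture channels have; a deleted cell is then
  # recoverable from its collinear neighbours
  d <- withr::with_seed(9, {
    n <- 80
    T2 <- matrix(stats::rnorm(n * 2), n, 2)
    P <- matrix(stats::rnorm(2 * 6), 2, 6)
    C <- matrix(stats::rnorm(2 * 4), 2, 4)
    X <- sweep(T2 %*% P + 0.05 * matrix(stats::rnorm(n * 6), n, 6), 2, 10, "+")
    colnames(X) <- paste0("x", 1:6)
    Y <- sweep(T2 %*% C + 0.05 * matrix(stats::rnorm(n * 4), n, 4), 2,
               c(8, 12, 20, 15), "+")
    colnames(Y) <- paste0("y", 1:4)
    list(X = X, Y = Y)
  })
  m_full <- fit_opls(d$X, d$Y, A_pred = 2, A_orth = 1)
  base <- predict(m_full, d$X)
  Xm <- d$X
  holes <- withr::with_seed(10, sample(length(Xm), round(0.1 * length(Xm))))
  Xm[holes] <- NA
  m_m <- fit_opls(Xm, d$Y, A_pred = 2, A_orth = 1)
  pred_m <- predict(m_m, Xm)
  rel_rms <- sqrt(mean((pred_m - base)^2)) / sqrt(mean(base^2))
  expect_lt(rel_rms, 0.05)
})

test_that("Q2 recovers strong signal, stays null-calibrated, and undercuts R2Y", {
  # with as many components as factors, PLS reproduces the exact linear map
  d <- make_linear_data(n = 60, p = 5, q = 3, seed = 11, noise = 0)
  q2 <- opls_q2(d$X, d$Y, A_pred = 5, A_orth = 0, folds = 5, seed = 1)
  expect_gt(utils::tail(q2, 1), 0.99)

  # identical seed -> identical folds -> identical Q2
  expect_identical(q2, opls_q2(d$X, d$Y, A_pred = 5, A_orth = 0, folds = 5,
                               seed = 1))

  # Y shuffled independently of X: Q2 is non-positive on average
  null_q2 <- vapply(1:20, function(s) {
    Yp <- d$Y[withr::with_seed(100 + s, sample(nrow(d$Y))), , drop = FALSE]
    utils::tail(opls_q2(d$X, Yp, A_pred = 1, A_orth = 0, folds = 5,
                        seed = s), 1)
  }, numeric(1))
  expect_lt(mean(null_q2), 0.05)

  # cross-validation pessimism: Q2 <= R2Y for each component count
  d2 <- make_linear_data(n = 40, p = 5, q = 3, seed = 12, noise = 0.5)
  m <- fit_opls(d2$X, d2$Y, A_pred = 3, A_orth = 0)
  q2b <- opls_q2(d2$X, d2$Y, A_pred = 3, A_orth = 0, folds = 5, seed = 2)
  expect_true(all(q2b <= m$r2y_cum + 1e-8))
})

test_that("VIP flags relevant predictors and satisfies its normalization", {
  withr::with_seed(13, {
    X <- matrix(stats::rnorm(60 * 6), 60, 6,
                dimnames = list(NULL, paste0("x", 1:6)))
    y <- matrix(2 * X[, 1] + 0.05 * stats::rnorm(60), ncol = 1,
                dimnames = list(NULL, "y"))
  })
  m <- fit_opls(X, y, A_pred = 2, A_orth = 0)
  vip <- opls_vip(m)
  expect_gt(vip[["x1"]], 1)
  expect_true(all(vip[-1] < vip[["x1"]]))
  expect_equal(mean(vip^2), 1, tolerance = 1e-8) # sum VIP^2 = p

  # identical predictors share VIP = 1 exactly
  withr::with_seed(14, x0 <- stats::rnorm(40))
  Xid <- cbind(x1 = x0, x2 = x0, x3 = x0)
  yid <- matrix(x0, ncol = 1, dimnames = list(NULL, "y"))
  vip_id <- opls_vip(fit_opls(Xid, yid, A_pred = 1, A_orth = 0))
  expect_equal(unname(vip_id), rep(1, 3), tolerance = 1e-8)
})

test_that("correlation matrix uses pairwise-complete cases with a floor", {
  withr::with_seed(15, {
    n <- 10000
    x <- stats::rnorm(n)
    y <- 0.8 * x + sqrt(1 - 0.64) * stats::rnorm(n)
  })
  tbl <- dplyr::bind_rows(
    tibble::tibble(batch_id = "b", condition = "Control", replicate = 1L,
                   time_h = seq_len(n), channel = "GLC", value = abs(x)),
    tibble::tibble(batch_id = "b", condition = "Control", replicate = 1L,
                   time_h = seq_len(n), channel = "GAL", value = abs(y))
  )
  # correlation of |x|,|y| differs from rho; instead compare on the raw pair
  wide_cor <- correlation_matrix(tbl, c("GLC", "GAL"))
  expect_equal(diag(wide_cor), c(GLC = 1, GAL = 1))
  expect_equal(wide_cor["GLC", "GAL"], stats::cor(abs(x), abs(y)),
               tolerance = 1e-12)

  # exact anti-correlation and the completeness floor
  tbl2 <- dplyr::bind_rows(
    tibble::tibble(batch_id = "b", condition = "Control", replicate = 1L,
                   time_h = 1:6, channel = "GLC", value = 1:6),
    tibble::tibble(batch_id = "b", condition = "Control", replicate = 1L,
                   time_h = 1:6, channel = "LAC", value = 7 - (1:6)),
    tibble::tibble(batch_id = "b", condition = "Control", replicate = 1L,
                   time_h = 1:6, channel = "GLN",
                   value = c(1, 2, NA, NA, NA, NA))
  )
  R <- correlation_matrix(tbl2, c("GLC", "LAC", "GLN"))
  expect_equal(R["GLC", "LAC"], -1)
  expect_true(is.na(R["GLC", "GLN"])) # only 2 complete pairs
})

test_that("seeded bivariate normal correlation lands within sampling error", {
  withr::with_seed(16, {
    n <- 10000
    x <- stats::rnorm(n)
    y <- 0.8 * x + 0.6 * stats::rnorm(n)
  })
  expect_equal(stats::cor(x, y), 0.8, tolerance = 0.02)
  tbl <- dplyr::bind_rows(
    tibble::tibble(batch_id = "b", condition = "Control", replicate = 1L,
                   time_h = seq_len(n), channel = "GLC", value = x + 10),
    tibble::tibble(batch_id = "b", condition = "Control", replicate = 1L,
                   time_h = seq_len(n), channel = "GAL", value = y + 10)
  )
  R <- correlation_matrix(tbl, c("GLC", "GAL"))
  expect_equal(R["GLC", "GAL"], 0.8, tolerance = 0.02)
})

test_that("tidiers summarize an OPLS fit", {
  d <- make_linear_data(n = 30, p = 5, q = 2, seed = 17, noise = 0.2)
  m <- fit_opls(d$X, d$Y, A_pred = 2, A_orth = 1)
  td <- tidy(m)
  expect_equal(nrow(td), 2 * 5)
  expect_named(td, c("component", "term", "weight", "loading", "vip"))
  g <- glance(m)
  expect_equal(g$a_pred, 2)
  expect_equal(g$a_orth, 1)
})
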