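# --- skip-missing linear algebra -------------------------------------------
# Inner products over present cells only (SIMCA-style NIPALS conventions):
# a score is the least-squares regression of a row on the weight vector using
# the row's present entries, and vice versa for loadings.

.skip_score <- function(X, w) {
  # t_i = sum_present(x_ij w_j) / sum_present(w_j^2)
  P <- !is.na(X)
  Xz <- ifelse(P, X, 0)
  num <- Xz %*% w
  den <- P %*% (w^2)
  as.numeric(ifelse(den > 0, num / den, 0))
}

.skip_loading <- function(X, t) {
  # p_j = sum_present(x_ij t_i) / sum_present(t_i^2)
  P <- !is.na(X)
  Xz <- ifelse(P, X, 0)
  num <- crossprod(Xz, t)
  den <- crossprod(P, t^2)
  as.numeric(ifelse(den > 0, num / den, 0))
}

.present_ss <- function(X) sum(X^2, na.rm = TRUE)

# deflate only present cells (missing cells stay missing)
.deflate <- function(X, t, p) {
  D <- X - outer(t, p)
  D[is.na(X)] <- NA
  D
}

# sign convention: the largest-|w| element is made positive
.fix_sign <- function(w) {
  j <- which.max(abs(w))
  if (w[j] < 0) -1 else 1
}

# one converged PLS2 weight/score/loading set on (X, Y), skip-missing
.nipals_component <- function(X, Y, max_sweeps = 500, tol = 1e-10) {
  yvar <- apply(Y, 2, function(col) stats::var(col, na.rm = TRUE))
  u <- Y[, which.max(ifelse(is.na(yvar), -Inf, yvar))]
  u[is.na(u)] <- 0
  t_old <- rep(0, nrow(X))
  best <- NULL
  best_delta <- Inf
  for (sweep in seq_len(max_sweeps)) {
    w <- .skip_loading(X, u)
    nw <- sqrt(sum(w^2))
    if (nw == 0) stop("NIPALS weight collapsed to zero", call. = FALSE)
    w <- w / nw
    t <- .skip_score(X, w)
    cc <- .skip_loading(Y, t)
    nc <- sqrt(sum(cc^2))
    u <- if (nc > 0) .skip_score(Y, cc) else t
    delta <- sqrt(sum((t - t_old)^2)) / max(sqrt(sum(t^2)), 1e-300)
    if (delta < best_delta) {
      best_delta <- delta
      sg <- .fix_sign(w)
      best <- list(w = sg * w, t = sg * t, c = sg * cc, u = sg * u)
    }
    if (delta < tol) return(best)
    t_old <- t
  }
  if (best_delta < 1e-6) return(best)
  # power iteration cycles when the two leading covariance directions are
  # nearly tied; resolve the tie deterministically with the SVD of the
  # (zero-filled) cross-covariance and one skip-missing refinement pass
  Xz <- ifelse(is.na(X), 0, X)
  Yz <- ifelse(is.na(Y), 0, Y)
  w <- svd(crossprod(Xz, Yz))$u[, 1]
  t <- .skip_score(X, w)
  cc <- .skip_loading(Y, t)
  u <- if (sum(cc^2) > 0) .skip_score(Y, cc) else t
  sg <- .fix_sign(w)
  list(w = sg * w, t = sg * t, c = sg * cc, u = sg * u)
}

# one-component NIPALS PCA weight (skip-missing power iteration)
.pca_weight <- function(Z, max_sweeps = 500, tol = 1e-10) {
  ss <- colSums(Z^2, na.rm = TRUE)
  w <- rep(0, ncol(Z)); w[which.max(ss)] <- 1
  for (sweep in seq_len(max_sweeps)) {
    t <- .skip_score(Z, w)
    w_new <- .skip_loading(Z, t)
    nw <- sqrt(sum(w_new^2))
    if (nw == 0) return(w)
    w_new <- w_new / nw
    if (sqrt(sum((w_new - w)^2)) < tol || sqrt(sum((w_new + w)^2)) < tol) {
      return(w_new)
    }
    w <- w_new
  }
  w
}

.autoscale <- function(M, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(M, na.rm = TRUE)
  if (is.null(scale)) scale <- apply(M, 2, stats::sd, na.rm = TRUE)
  if (any(!is.finite(scale)) || any(scale == 0, na.rm = TRUE)) {
    bad <- colnames(M)[!is.finite(scale) | scale == 0]
    stop("zero-variance column(s) cannot be autoscaled: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(M = sweep(sweep(M, 2, center), 2, scale, "/"), center = center,
       scale = scale)
}

# --- model -----------------------------------------------------------------

#' Fit an orthogonal partial least squares (OPLS) soft sensor
#'
#' Decomposes the autoscaled factor block X into variation predictive of the
#' response block Y and variation orthogonal to it. Orthogonal components are
#' extracted and removed first (each is the part of the current PLS loading
#' not spanned by its weight), then `A_pred` predictive PLS2 components are
#' fitted on the filtered X. Every inner product skips missing cells, so
#' heavily incomplete channels can participate without imputation.
#'
#' @param X Numeric factor matrix (n x p), `NA` allowed.
#' @param Y Numeric response matrix (n x q), `NA` allowed.
#' @param A_pred Number of predictive components.
#' @param A_orth Number of orthogonal components.
#' @return An `opls_model` with weights/loadings/scores per component, the
#'   scaling statistics, and the cumulative R2X/R2Y ledger.
#' @export
fit_opls <- function(X, Y, A_pred = 2, A_orth = 3) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  n <- nrow(X)
  if (n < A_pred + A_orth + 2) {
    stop("too few rows for the requested number of components", call. = FALSE)
  }
  if (any(colSums(!is.na(X)) == 0) || any(colSums(!is.na(Y)) == 0)) {
    stop("all-missing column in X or Y", call. = FALSE)
  }
  sx <- .autoscale(X); sy <- .autoscale(Y)
  Xc <- sx$M; Yc <- sy$M
  ssx_tot <- .present_ss(Xc); ssy_tot <- .present_ss(Yc)

  W_o <- P_o <- T_o <- NULL
  for (a in seq_len(A_orth)) {
    # Y-orthogonal weight: dominant principal direction of X after the whole
    # Y-covariant subspace (the span of X'Y) is projected out. The resulting
    # score has exactly zero sample covariance with every Y column.
    Xz <- ifelse(is.na(Xc), 0, Xc); Yz <- ifelse(is.na(Yc), 0, Yc)
    Cxy <- crossprod(Xz, Yz)
    keep <- colSums(Cxy^2) > 1e-24
    V <- NULL
    if (any(keep)) {
      qr_c <- qr(Cxy[, keep, drop = FALSE])
      # rank-truncated basis: qr.Q pads with arbitrary orthonormal
      # completions beyond the numerical rank, which must not be projected
      V <- qr.Q(qr_c)[, seq_len(qr_c$rank), drop = FALSE]
    }
    if (is.null(V) || ncol(V) < ncol(Xc)) {
      # the Y-covariant subspace has a nullspace: take the dominant
      # principal direction of X outside it (exactly zero Y covariance)
      Z <- Xz
      if (!is.null(V)) Z <- Xz - Xz %*% V %*% t(V)
      Z[is.na(Xc)] <- NA
      if (.present_ss(Z) < 1e-10 * ssx_tot) break # nothing structured left
      w_o <- .pca_weight(Z)
      if (!is.null(V)) w_o <- w_o - as.numeric(V %*% crossprod(V, w_o))
    } else {
      # X'Y numerically full rank (typical with many noisy responses): no
      # direction is exactly Y-free, so fall back to the classic
      # construction — the part of the X-loading not spanned by the
      # current predictive weight
      comp <- .nipals_component(Xc, Yc)
      p_load <- .skip_loading(Xc, comp$t)
      w_o <- p_load - as.numeric(crossprod(comp$w, p_load)) * comp$w
    }
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break
    w_o <- w_o / nw * .fix_sign(w_o / nw)
    t_o <- .skip_score(Xc, w_o)
    p_o <- .skip_loading(Xc, t_o)
    Xc <- .deflate(Xc, t_o, p_o)
    W_o <- cbind(W_o, w_o); P_o <- cbind(P_o, p_o); T_o <- cbind(T_o, t_o)
  }

  W <- P <- Tt <- C <- NULL
  r2x <- r2y <- numeric(0)
  for (a in seq_len(A_pred)) {
    comp <- .nipals_component(Xc, Yc)
    p_load <- .skip_loading(Xc, comp$t)
    Xc <- .deflate(Xc, comp$t, p_load)
    Yc <- .deflate(Yc, comp$t, comp$c)
    W <- cbind(W, comp$w); P <- cbind(P, p_load)
    Tt <- cbind(Tt, comp$t); C <- cbind(C, comp$c)
    r2x <- c(r2x, 1 - .present_ss(Xc) / ssx_tot)
    r2y <- c(r2y, 1 - .present_ss(Yc) / ssy_tot)
  }

  structure(list(
    x_center = sx$center, x_scale = sx$scale,
    y_center = sy$center, y_scale = sy$scale,
    W = W, P = P, T = Tt, C = C,
    W_o = W_o, P_o = P_o, T_o = T_o,
    A_pred = ncol(W), A_orth = if (is.null(W_o)) 0L else ncol(W_o),
    r2x_cum = r2x, r2y_cum = r2y,
    x_names = colnames(X), y_names = colnames(Y), n = n
  ), class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat("OPLS model: ", x$A_pred, " predictive + ", x$A_orth,
      " orthogonal component(s), n = ", x$n, "\n", sep = "")
  cat("  R2X(cum):", signif(utils::tail(x$r2x_cum, 1), 4),
      " R2Y(cum):", signif(utils::tail(x$r2y_cum, 1), 4), "\n")
  invisible(x)
}

#' Predict responses from an OPLS model
#'
#' New factor rows are scaled with the training statistics, the orthogonal
#' variation is projected out, and predictive scores are accumulated into
#' response predictions that are returned in original units. Rows with
#' missing cells use the skip-missing projection (a least-squares score over
#' the present entries); an all-missing row predicts the training mean.
#'
#' @param object An `opls_model`.
#' @param newdata Factor matrix with the training column set.
#' @param ncomp Number of predictive components to use (default all).
#' @param ... Unused.
#' @return Prediction matrix (rows of `newdata` x responses).
#' @export
predict.opls_model <- function(object, newdata, ncomp = object$A_pred, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != length(object$x_names)) {
    stop("newdata must have the training factor columns", call. = FALSE)
  }
  if (!is.null(colnames(X)) && !identical(colnames(X), object$x_names)) {
    if (!all(object$x_names %in% colnames(X))) {
      stop("newdata column names do not match the training factors",
           call. = FALSE)
    }
    X <- X[, object$x_names, drop = FALSE]
  }
  Xc <- sweep(sweep(X, 2, object$x_center), 2, object$x_scale, "/")
  for (a in seq_len(object$A_orth)) {
    t_o <- .skip_score(Xc, object$W_o[, a])
    Xc <- .deflate(Xc, t_o, object$P_o[, a])
  }
  Yhat <- matrix(0, nrow(Xc), length(object$y_names))
  for (a in seq_len(ncomp)) {
    t <- .skip_score(Xc, object$W[, a])
    Xc <- .deflate(Xc, t, object$P[, a])
    Yhat <- Yhat + outer(t, object$C[, a])
  }
  Yhat <- sweep(sweep(Yhat, 2, object$y_scale, "*"), 2, object$y_center, "+")
  colnames(Yhat) <- object$y_names
  Yhat
}

#' Cross-validated predictive ability Q2
#'
#' Rows are shuffled once with the given seed and dealt round-robin into
#' folds; each fold is predicted by a model fitted on the remaining rows.
#' Q2(cum) for `a` predictive components is `1 - PRESS_a / SS_Y`, with PRESS
#' accumulated over held-out rows in autoscaled units (training-fold
#' scaling) and SS_Y the held-out sum of squares about the training-fold
#' means.
#'
#' @inheritParams fit_opls
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed for the fold shuffle.
#' @return Numeric vector `Q2(cum)` of length `A_pred`.
#' @export
opls_q2 <- function(X, Y, A_pred = 2, A_orth = 3, folds = 7, seed = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (folds < 2) stop("need at least two folds", call. = FALSE)
  if (n < 2 * folds) stop("too few rows for ", folds, " folds", call. = FALSE)
  assign_fold <- .with_seed(seed, {
    ord <- sample.int(n)
    f <- integer(n)
    f[ord] <- rep_len(seq_len(folds), n)
    f
  })
  press <- rep(0, A_pred)
  ss <- 0
  for (k in seq_len(folds)) {
    hold <- assign_fold == k
    m <- fit_opls(X[!hold, , drop = FALSE], Y[!hold, , drop = FALSE],
                  A_pred = A_pred, A_orth = A_orth)
    Yh_scaled <- sweep(sweep(Y[hold, , drop = FALSE], 2, m$y_center), 2,
                       m$y_scale, "/")
    ss <- ss + sum(Yh_scaled^2, na.rm = TRUE)
    for (a in seq_len(A_pred)) {
      pred <- predict(m, X[hold, , drop = FALSE], ncomp = a)
      pred_scaled <- sweep(sweep(pred, 2, m$y_center), 2, m$y_scale, "/")
      press[a] <- press[a] + sum((Yh_scaled - pred_scaled)^2, na.rm = TRUE)
    }
  }
  1 - press / ss
}

#' Variable importance in projection (VIP)
#'
#' VIP of factor j over the predictive components:
#' `sqrt(p * sum_a SSY_a w_aj^2 / sum_a SSY_a)` with SSY_a the Y-variance
#' explained by component a. The mean squared VIP is 1 by construction.
#'
#' @param model A fitted `opls_model`.
#' @return Named numeric VIP per factor.
#' @export
opls_vip <- function(model) {
  if (model$A_pred < 1) stop("model has no predictive component", call. = FALSE)
  ssy <- diff(c(0, model$r2y_cum)) # per-component explained Y variance
  ssy[ssy < 0] <- 0
  if (sum(ssy) == 0) ssy <- rep(1, length(ssy))
  W <- model$W
  vip <- sqrt(length(model$x_names) *
                as.numeric(W^2 %*% ssy) / sum(ssy))
  stats::setNames(vip, model$x_names)
}

#' Factor--response Pearson correlation matrix
#'
#' Pairwise-complete Pearson correlations between the requested channels of
#' a culture table (one row per batch/replicate/time). Pairs with fewer than
#' `min_n` complete observations are reported as `NA`.
#'
#' @param tbl A culture table.
#' @param variables Channels to correlate; default factors then responses.
#' @param min_n Minimum pairwise-complete observations (default 3).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(tbl, variables = c(factor_channels(),
                                                  response_channels()),
                               min_n = 3) {
  wide <- pivot_culture_wide(dplyr::filter(tbl, .data$channel %in% variables))
  vars <- intersect(variables, colnames(wide))
  M <- as.matrix(wide[, vars, drop = FALSE])
  R <- suppressWarnings(stats::cor(M, use = "pairwise.complete.obs"))
  counts <- crossprod((!is.na(M)) * 1)
  R[counts < min_n] <- NA
  diag(R) <- 1
  R
}

#' Tidy and summarize an OPLS model
#'
#' `tidy()` returns one row per factor and predictive component with the
#' weight, loading and VIP; `glance()` returns the component-count and
#' cumulative variance ledger.
#'
#' @param x An `opls_model`.
#' @param ... Unused.
#' @export
tidy.opls_model <- function(x, ...) {
  vip <- opls_vip(x)
  purrr::map_dfr(seq_len(x$A_pred), function(a) {
    tibble::tibble(
      component = a, term = x$x_names,
      weight = x$W[, a], loading = x$P[, a], vip = unname(vip)
    )
  })
}

#' @rdname tidy.opls_model
#' @export
glance.opls_model <- function(x, ...) {
  tibble::tibble(
    n = x$n, a_pred = x$A_pred, a_orth = x$A_orth,
    r2x_cum = utils::tail(x$r2x_cum, 1),
    r2y_cum = utils::tail(x$r2y_cum, 1)
  )
}

#' Build factor and response design matrices from a culture table
#'
#' One row per (batch, replicate, time); the factor block holds the six
#' extracellular metabolites plus (by default) observation time, the
#' response block the glycan fractions, NSDs, VCD and titer.
#'
#' @param tbl A culture table.
#' @param include_time Include `time_h` as an extra factor column (default
#'   `TRUE`; time anchors the data-driven models against extrapolation).
#' @param responses Response channels (default [response_channels()]).
#' @return List with matrices `X`, `Y` and the row-identifier tibble `ids`.
#' @export
culture_design_matrices <- function(tbl, include_time = TRUE,
                                    responses = response_channels()) {
  wide <- pivot_culture_wide(tbl)
  fx <- intersect(factor_channels(), colnames(wide))
  X <- as.matrix(wide[, fx, drop = FALSE])
  if (include_time) X <- cbind(X, time_h = wide$time_h)
  ry <- intersect(responses, colnames(wide))
  Y <- as.matrix(wide[, ry, drop = FALSE])
  list(X = X, Y = Y,
       ids = wide[, c("batch_id", "condition", "replicate", "time_h")])
}
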