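#' One-way analysis of variance on grouped values
#'
#' Classical fixed-effects one-way ANOVA (via [stats::aov()]) on a list of
#' numeric groups.
#'
#' @param groups Named list of numeric vectors, one per level.
#' @return Tibble with `f_statistic`, `df_between`, `df_within`, `p_value`.
#' @examples
#' anova_oneway(list(a = c(1, 2, 3), b = c(4, 5, 6))) # F = 13.5
#' @export
anova_oneway <- function(groups) {
  if (length(groups) < 2) stop("need at least two groups", call. = FALSE)
  if (any(lengths(groups) == 0)) stop("empty group", call. = FALSE)
  df <- tibble::tibble(
    value = unlist(groups, use.names = FALSE),
    level = factor(rep(names(groups) %||% seq_along(groups), lengths(groups)))
  )
  if (nrow(df) - length(groups) < 2) {
    stop("need at least two residual degrees of freedom", call. = FALSE)
  }
  fit <- stats::aov(value ~ level, data = df)
  an <- stats::anova(fit)
  f <- an[["F value"]][1]
  tibble::tibble(
    f_statistic = if (is.na(f)) 0 else f,
    df_between = an[["Df"]][1], df_within = an[["Df"]][2],
    p_value = if (is.na(f)) 1 else an[["Pr(>F)"]][1]
  )
}

#' Tukey's HSD pairwise mean comparison
#'
#' All pairwise level comparisons after one-way ANOVA, using the studentized
#' range distribution with the Tukey--Kramer standard error
#' `sqrt(MSW (1/n_a + 1/n_b))` for unequal group sizes. Rows are oriented so
#' the difference is non-negative and sorted by descending absolute
#' difference, the layout of the model-vs-experiment comparison tables.
#'
#' @param groups Named list of numeric vectors, one per level.
#' @param alpha Significance level for the confidence limits (default 0.05).
#' @return A `tukey_table` tibble: `level_a`, `level_b`, `difference`,
#'   `std_err_dif`, `lower_cl`, `upper_cl`, `p_adj`.
#' @export
tukey_hsd <- function(groups, alpha = 0.05) {
  k <- length(groups)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_len(k))
  n <- lengths(groups)
  means <- vapply(groups, mean, numeric(1))
  df_w <- sum(n) - k
  if (df_w < 1) stop("no residual degrees of freedom", call. = FALSE)
  msw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) / df_w
  degenerate <- msw <= 0
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  rows <- purrr::map_dfr(pairs, function(pr) {
    a <- pr[1]; b <- pr[2]
    if (means[[a]] < means[[b]]) { a <- pr[2]; b <- pr[1] }
    diff <- means[[a]] - means[[b]]
    se <- sqrt(msw * (1 / n[[a]] + 1 / n[[b]]))
    if (degenerate) {
      p <- if (diff == 0) 1 else 0
      hw <- 0
    } else {
      q_stat <- sqrt(2) * abs(diff) / se
      p <- stats::ptukey(q_stat, nmeans = k, df = df_w, lower.tail = FALSE)
      hw <- stats::qtukey(1 - alpha, nmeans = k, df = df_w) / sqrt(2) * se
    }
    tibble::tibble(
      level_a = a, level_b = b, difference = diff, std_err_dif = se,
      lower_cl = diff - hw, upper_cl = diff + hw, p_adj = p,
      degenerate = degenerate
    )
  })
  out <- dplyr::arrange(rows, dplyr::desc(abs(.data$difference)))
  structure(out, class = c("tukey_table", class(out)))
}

#' @describeIn tukey_hsd Plot the pairwise differences with confidence limits.
#' @param object A `tukey_table`.
#' @param ... Unused.
#' @export
autoplot.tukey_table <- function(object, ...) {
  d <- tibble::as_tibble(object) |>
    dplyr::mutate(pair = paste(.data$level_a, "-", .data$level_b))
  ggplot2::ggplot(d, ggplot2::aes(y = stats::reorder(.data$pair, .data$difference))) +
    ggplot2::geom_point(ggplot2::aes(x = .data$difference)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lower_cl, xmax = .data$upper_cl), height = 0.2
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "difference of means", y = NULL)
}

#' Specific consumption/production rate
#'
#' `qs = (conc(t2) - conc(t1)) / IVCD(t1, t2)` with the integral viable cell
#' density computed by the trapezoid rule on the available points between
#' `t1` and `t2` (series are linearly interpolated to the window edges).
#' Consumption gives a negative rate.
#'
#' @param conc Tibble/data frame `time_h`, `value` (mM).
#' @param xv Tibble/data frame `time_h`, `value` (cells/mL).
#' @param t1,t2 Window edges (h), `t2 > t1`.
#' @return Specific rate in mM/(cell h).
#' @export
specific_rate <- function(conc, xv, t1, t2) {
  stopifnot(t2 > t1)
  c1 <- stats::approx(conc$time_h, conc$value, xout = t1)$y
  c2 <- stats::approx(conc$time_h, conc$value, xout = t2)$y
  if (is.na(c1) || is.na(c2)) {
    stop("concentration series does not cover the window", call. = FALSE)
  }
  tt <- sort(unique(c(t1, xv$time_h[xv$time_h > t1 & xv$time_h < t2], t2)))
  vv <- stats::approx(xv$time_h, xv$value, xout = tt)$y
  if (any(is.na(vv))) {
    stop("VCD series does not cover the window", call. = FALSE)
  }
  ivcd <- sum(diff(tt) * (utils::head(vv, -1) + utils::tail(vv, -1)) / 2)
  if (ivcd <= 0) stop("non-positive integral viable cell density", call. = FALSE)
  (c2 - c1) / ivcd
}

#' Fold change between two specific rates
#'
#' Ratio of magnitudes `|qs_b| / |qs_a|`; direction (increase vs decrease)
#' is read from whether the ratio is above or below 1.
#'
#' @param qs_a,qs_b Specific rates; `qs_a` nonzero.
#' @return Positive ratio.
#' @export
fold_change <- function(qs_a, qs_b) {
  if (qs_a == 0) stop("zero reference rate", call. = FALSE)
  abs(qs_b) / abs(qs_a)
}

#' Mean absolute percent error of feed-window concentration changes
#'
#' For each window, the change `value(t_end) - value(t_start)` is computed
#' for the predicted and observed series and compared as
#' `100 |delta_pred - delta_obs| / |delta_obs|`; the mean over windows is
#' returned. Offsetting both series by a constant leaves the metric
#' unchanged (it only sees differences).
#'
#' @param pred,obs Tibbles `time_h`, `value` covering every window.
#' @param windows List of `c(t_start, t_end)` pairs.
#' @return Mean absolute percent difference over the windows.
#' @export
feed_window_difference <- function(pred, obs, windows) {
  per <- vapply(windows, function(w) {
    dp <- diff(stats::approx(pred$time_h, pred$value, xout = w)$y)
    do <- diff(stats::approx(obs$time_h, obs$value, xout = w)$y)
    if (is.na(dp) || is.na(do)) {
      stop("series does not cover window [", w[1], ", ", w[2], "]",
           call. = FALSE)
    }
    if (do == 0) stop("observed change is zero in window [", w[1], ", ",
                      w[2], "]", call. = FALSE)
    100 * abs(dp - do) / abs(do)
  }, numeric(1))
  mean(per)
}

#' Galactosylation index
#'
#' Fraction of occupied galactosylation sites under the two-site model of a
#' biantennary glycan: `GI = (0.5 G1F + G2F) / (G0F + G1F + G2F)`.
#'
#' @param g0f,g1f,g2f Non-negative glycan percentages (or areas), not all
#'   zero.
#' @return Index in \[0, 1\].
#' @examples
#' galactosylation_index(50, 30, 20) # 0.35
#' @export
galactosylation_index <- function(g0f, g1f, g2f) {
  if (any(c(g0f, g1f, g2f) < 0)) stop("negative glycan input", call. = FALSE)
  tot <- g0f + g1f + g2f
  if (tot == 0) stop("all glycan fractions zero: index undefined", call. = FALSE)
  (0.5 * g1f + g2f) / tot
}

#' Model-vs-experiment comparison report
#'
#' For each requested channel, experimental and model-predicted values at
#' shared timepoints form the groups of a one-way ANOVA followed by Tukey's
#' HSD; "whole culture duration" channels (VCD, titer, NSDs) treat
#' timepoints as observations, and glycan channels are additionally
#' compared per timepoint across the supplied replicate draws when
#' `timepoints` is given.
#'
#' @param experimental Culture table of observed values (one condition).
#' @param predictions Named list of per-model culture tables (same
#'   condition/timepoints).
#' @param variables Channels to compare.
#' @param timepoints Optional times (h) for per-timepoint glycan comparisons.
#' @param alpha Confidence level for Tukey limits.
#' @return Tibble with columns `channel`, `time_h` (`NA` for whole-duration
#'   rows) and the nested `tukey` table columns unnested.
#' @export
compare_models <- function(experimental, predictions, variables,
                           timepoints = NULL, alpha = 0.05) {
  stopifnot(is.list(predictions), !is.null(names(predictions)))
  sources <- c(list(Exp = experimental), predictions)
  out <- list()
  for (ch in variables) {
    per_source <- purrr::map(sources, function(tbl) {
      tbl |>
        dplyr::filter(.data$channel == ch, !is.na(.data$value)) |>
        dplyr::group_by(.data$time_h) |>
        dplyr::summarise(value = mean(.data$value), .groups = "drop")
    })
    # a source that never reports this channel (e.g. a model that excludes
    # it) drops out of the comparison instead of blanking it for everyone
    per_source <- per_source[vapply(per_source, nrow, integer(1)) > 0]
    if (length(per_source) < 2) {
      stop("fewer than two sources report channel ", ch, call. = FALSE)
    }
    shared <- Reduce(intersect, purrr::map(per_source, "time_h"))
    if (length(shared) < 2) {
      stop("fewer than two shared timepoints for channel ", ch, call. = FALSE)
    }
    groups <- purrr::map(per_source, function(d) {
      d$value[match(shared, d$time_h)]
    })
    tk <- tukey_hsd(groups, alpha = alpha)
    out[[length(out) + 1]] <- dplyr::mutate(
      tibble::as_tibble(tk), channel = ch, time_h = NA_real_,
      .before = 1
    )
    if (!is.null(timepoints) && ch %in% glycan_channels()) {
      for (tp in intersect(timepoints, shared)) {
        reps <- purrr::map(sources, function(tbl) {
          v <- tbl$value[tbl$channel == ch & tbl$time_h == tp &
                           !is.na(tbl$value)]
          v
        })
        if (all(lengths(reps) >= 2)) {
          tk_t <- tukey_hsd(reps, alpha = alpha)
          out[[length(out) + 1]] <- dplyr::mutate(
            tibble::as_tibble(tk_t), channel = ch, time_h = tp, .before = 1
          )
        }
      }
    }
  }
  dplyr::bind_rows(out)
}
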