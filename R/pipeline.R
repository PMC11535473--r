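#' Default pipeline configuration
#'
#' Nested list mirroring the YAML schema (`design`, `kinetics`, `noise`,
#' `missingness`, `opls`, `nn`, `stats`, `seed`). A single global seed fans
#' out to per-stage seeds by fixed offsets, so every random draw in the
#' pipeline is a pure function of the one seed.
#'
#' @param seed Global seed (default 1).
#' @return Configuration list.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    design = list(n_reps = 2),
    kinetics = list(
      fit_params = c("mu_max", "K_glc"),
      n_starts = 2, mode = "free",
      channels = c("VCD", "GLC")
    ),
    noise = list(cv = 0.05),
    missingness = list(),
    opls = list(a_pred = 2, a_orth = 3, folds = 7),
    nn = list(n_starts = 4, n_search = 4, max_iter = 100),
    stats = list(
      channels = c("VCD", "TITER", nsd_channels(), glycan_channels()),
      alpha = 0.05
    ),
    stages = list(mmk = TRUE, opls = TRUE, nn = TRUE)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its [default_pipeline_config()] value.
#'
#' @param path YAML file path.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_pipeline_config(), user)
}

#' Build an initial ODE state from observed data
#'
#' t0 handling for forward simulation: extracellular states (and VCD/titer)
#' come from the t = 0 observations; the unmeasured-at-inoculation NSD and
#' glycan states are copied from the earliest measured values of the same
#' condition (in the study's sampling design that is roughly 72 h).
#'
#' @param data Culture table of one condition (pooled or single replicate).
#' @param base_init Fallback [initial_state()] for channels never observed.
#' @return Named state vector.
#' @export
initial_state_from_data <- function(data, base_init = initial_state()) {
  init <- base_init
  ext <- c("GLC", "GLN", "GLU", "LAC", "NH4", "GAL", "VCD", "TITER")
  t0 <- data[data$time_h == min(data$time_h) & !is.na(data$value), ]
  for (i in seq_len(nrow(t0))) {
    ch <- t0$channel[i]
    if (ch %in% ext) init[[.channel_state_map[[ch]]]] <- t0$value[i]
  }
  for (ch in nsd_channels()) {
    v <- data[data$channel == ch & !is.na(data$value), ]
    if (nrow(v) > 0) {
      init[[.channel_state_map[[ch]]]] <- v$value[which.min(v$time_h)]
    }
  }
  gly <- purrr::map_dbl(glycan_channels(), function(ch) {
    v <- data[data$channel == ch & !is.na(data$value), ]
    if (nrow(v) > 0) v$value[which.min(v$time_h)] else NA_real_
  })
  if (!any(is.na(gly))) {
    tot <- init[["M_G0F"]] + init[["M_G1F"]] + init[["M_G2F"]]
    init[["M_G0F"]] <- tot * gly[1] / 100
    init[["M_G1F"]] <- tot * gly[2] / 100
    init[["M_G2F"]] <- tot * gly[3] / 100
  }
  init
}

#' Run the full soft-sensor comparison pipeline
#'
#' Generate the synthetic study data, fit the three soft-sensor models on
#' the training conditions (Control, A, B), predict the validation
#' condition (the kinetic model by forward simulation from its observed
#' start, OPLS and the network from the validation factor measurements
#' timepoint by timepoint), and compare all models against the pooled
#' experimental values with ANOVA + Tukey's HSD. All artifacts are written
#' under `out_dir` as CSV/JSON; two runs with the same configuration produce
#' byte-identical reports.
#'
#' @param config Configuration list from [default_pipeline_config()] or
#'   [read_pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the fitted models, prediction tables and
#'   the comparison report.
#' @export
run_pipeline <- function(config = default_pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed
  truep <- do.call(kinetic_params, config$kinetics$true %||% list())

  # stage 1: data
  ds <- generate_dataset(
    true_params = truep,
    noise = do.call(noise_spec, config$noise),
    missing = do.call(missingness_spec, config$missingness),
    n_reps = config$design$n_reps, seed = seed + 11
  )
  write_culture_table(ds$observed, file.path(out_dir, "observed.csv"))
  write_culture_table(ds$truth, file.path(out_dir, "truth.csv"))

  train_obs <- dplyr::filter(ds$observed,
                             .data$condition %in% c("Control", "A", "B"))
  valid_obs <- dplyr::filter(ds$observed, .data$condition == "Validation")
  valid_pooled <- pool_replicates(valid_obs, "Validation")
  valid_cond <- default_design()[default_design()$name == "Validation", ]
  valid_times <- default_schedule(valid_cond)

  models <- list()
  predictions <- list()

  # stage 2: kinetic model fit on the pooled control batch, then forward
  # simulation of the validation condition
  if (isTRUE(config$stages$mmk)) {
    ctrl <- pool_replicates(ds$observed, "Control") |>
      dplyr::filter(.data$channel %in% config$kinetics$channels)
    fit <- fit_kinetics(
      truep, ctrl,
      schedule = condition_feed_schedule(
        default_design()[default_design()$name == "Control", ]),
      fit_params = config$kinetics$fit_params,
      mode = config$kinetics$mode,
      n_starts = config$kinetics$n_starts, seed = seed + 23
    )
    models$mmk <- fit
    sched_v <- condition_feed_schedule(valid_cond)
    init_v <- initial_state_from_data(valid_pooled)
    t_eval <- sort(unique(c(0, unlist(valid_times), sched_v$feed_events$time_h,
                            sched_v$sample_events$time_h)))
    traj <- simulate_fedbatch(fit$params, init = init_v, schedule = sched_v,
                              t_eval = t_eval, rtol = 1e-6, atol = 1e-8)
    predictions$MMK <- trajectory_to_culture_table(
      traj, batch_id = "mmk_pred", condition = "Validation", replicate = 1L)
    jsonlite::write_json(
      list(estimates = as.list(fit$estimates), sse = fit$sse,
           fit_params = fit$fit_params, seed = fit$seed,
           converged = fit$converged, mode = fit$mode),
      file.path(out_dir, "fit_mmk.json"), auto_unbox = TRUE, digits = NA)
  }

  # stage 3: OPLS on the training conditions (time as extra factor)
  if (isTRUE(config$stages$opls)) {
    dm <- culture_design_matrices(train_obs, include_time = TRUE)
    op <- fit_opls(dm$X, dm$Y, A_pred = config$opls$a_pred,
                   A_orth = config$opls$a_orth)
    models$opls <- op
    dv <- culture_design_matrices(valid_pooled, include_time = TRUE)
    yh <- predict(op, dv$X)
    predictions$OPLS <- .prediction_table(yh, dv$ids, "opls_pred")
    jsonlite::write_json(
      list(r2x_cum = op$r2x_cum, r2y_cum = op$r2y_cum,
           a_pred = op$A_pred, a_orth = op$A_orth,
           vip = as.list(opls_vip(op))),
      file.path(out_dir, "opls.json"), auto_unbox = TRUE, digits = NA)
  }

  # stage 4: neural network (validation rows monitor the stopping rule)
  if (isTRUE(config$stages$nn)) {
    nn <- fit_nn(train_obs, valid_obs,
                 n_starts = config$nn$n_starts, seed = seed + 37,
                 n_search = config$nn$n_search, max_iter = config$nn$max_iter)
    models$nn <- nn
    dv <- culture_design_matrices(valid_pooled, include_time = FALSE,
                                  responses = nn$y_names)
    yh <- nn_forward(nn, dv$X)
    predictions$NN <- .prediction_table(yh, dv$ids, "nn_pred")
    jsonlite::write_json(
      list(lambda = nn$lambda, n_parameters = nn$n_parameters,
           seed = nn$seed, train_nll = nn$train_nll),
      file.path(out_dir, "nn.json"), auto_unbox = TRUE, digits = NA)
  }

  for (nm in names(predictions)) {
    write_culture_table(predictions[[nm]],
                        file.path(out_dir, paste0("pred_",
                                                  tolower(nm), ".csv")))
  }

  # stage 5: comparison report
  report <- compare_models(valid_pooled, predictions,
                           variables = config$stats$channels,
                           alpha = config$stats$alpha)
  utils::write.csv(report, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)

  manifest <- list(
    seed = seed,
    stages = names(predictions),
    files = as.list(tools::md5sum(list.files(out_dir, full.names = TRUE,
                                             pattern = "\\.(csv|json)$")))
  )
  names(manifest$files) <- basename(names(manifest$files))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(models = models, predictions = predictions, report = report,
                 data = ds))
}

# wide prediction matrix -> long prediction culture table (no non-negativity
# validation: model output may go negative)
.prediction_table <- function(yhat, ids, batch_id) {
  out <- tibble::as_tibble(yhat)
  out$time_h <- ids$time_h
  out |>
    tidyr::pivot_longer(-"time_h", names_to = "channel", values_to = "value") |>
    dplyr::mutate(batch_id = batch_id, condition = "Validation",
                  replicate = 1L) |>
    dplyr::select("batch_id", "condition", "replicate", "time_h", "channel",
                  "value") |>
    dplyr::arrange(.data$time_h, .data$channel)
}
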