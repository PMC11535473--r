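#' Read and write tidy culture-observation tables
#'
#' A culture table is the lingua franca of the package: one row per
#' measurement, with columns `batch_id`, `condition`, `replicate`, `time_h`,
#' `channel` and `value`. Channels are sampled on different cadences, so the
#' long format represents "not measured" naturally: a missing value is an
#' empty CSV field (an `NA`), never a sentinel like 0 or -1.
#'
#' `read_culture_table()` validates on the way in: unknown channels are
#' rejected, unparseable numeric cells become `NA` with a warning, and
#' negative concentrations (or glycan fractions outside \[0, 100\]) raise an
#' error naming the offending rows. Model *predictions* may legitimately go
#' negative and are kept in separate tables; validation applies to observed
#' data only (`check_values = FALSE` disables it).
#'
#' @param path File path of a CSV with header
#'   `batch_id,condition,replicate,time_h,channel,value`.
#' @param schema Character vector of admissible channel names. Defaults to
#'   the fifteen enumerated channels.
#' @param check_values Validate non-negativity (and the \[0, 100\] band for
#'   glycan fractions)? Default `TRUE`.
#' @return A validated culture-table tibble.
#' @export
read_culture_table <- function(path, schema = culture_channels()$channel,
                               check_values = TRUE) {
  if (!file.exists(path)) {
    stop("culture table file not found: ", path, call. = FALSE)
  }
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = character())
  required <- c("batch_id", "condition", "replicate", "time_h", "channel", "value")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("culture table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  tbl <- tibble::tibble(
    batch_id  = raw$batch_id,
    condition = raw$condition,
    replicate = as.integer(raw$replicate),
    time_h    = as.numeric(raw$time_h),
    channel   = raw$channel,
    value     = parse_numeric_cells(raw$value)
  )
  validate_culture_table(tbl, schema = schema, check_values = check_values)
}

# "" -> NA silently (the missing-data convention); other unparseable text -> NA
# with a warning naming the cells.
parse_numeric_cells <- function(x) {
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !(x == "" | x %in% c("NA", "na", "NaN"))
  if (any(bad)) {
    warning("unparseable numeric value(s) set to missing: ",
            paste(utils::head(unique(x[bad]), 5), collapse = ", "),
            call. = FALSE)
  }
  out
}

#' Validate a culture table against the channel schema
#'
#' @param tbl A culture-table data frame.
#' @inheritParams read_culture_table
#' @return The table as a tibble, invisibly unchanged, if valid.
#' @export
validate_culture_table <- function(tbl, schema = culture_channels()$channel,
                                   check_values = TRUE) {
  tbl <- tibble::as_tibble(tbl)
  unknown <- setdiff(unique(tbl$channel), schema)
  if (length(unknown) > 0) {
    stop("unknown channel(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (nrow(tbl) > 0) {
    dup <- tbl |>
      dplyr::count(.data$batch_id, .data$replicate, .data$time_h, .data$channel) |>
      dplyr::filter(.data$n > 1)
    if (nrow(dup) > 0) {
      stop("duplicate (batch_id, replicate, time_h, channel) observation(s), e.g. ",
           dup$batch_id[1], " / t=", dup$time_h[1], " / ", dup$channel[1],
           call. = FALSE)
    }
    if (check_values) {
      neg <- which(!is.na(tbl$value) & tbl$value < 0)
      if (length(neg) > 0) {
        stop("negative observed value(s) at row(s): ",
             paste(utils::head(neg, 5), collapse = ", "), call. = FALSE)
      }
      gly <- which(tbl$channel %in% glycan_channels() &
                     !is.na(tbl$value) & tbl$value > 100)
      if (length(gly) > 0) {
        stop("glycan fraction(s) above 100% at row(s): ",
             paste(utils::head(gly, 5), collapse = ", "), call. = FALSE)
      }
    }
  }
  tbl
}

#' @rdname read_culture_table
#' @param tbl Culture table to write.
#' @export
write_culture_table <- function(tbl, path) {
  out <- tbl
  out$value <- ifelse(is.na(out$value), "",
                      formatC(out$value, digits = 17, format = "g"))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Pivot a culture table to one column per channel
#'
#' A wide view with one row per (batch, condition, replicate, time) and one
#' column per channel; cells a channel was not sampled at are `NA`.
#'
#' @param tbl A culture table.
#' @return A wide tibble.
#' @export
pivot_culture_wide <- function(tbl) {
  tbl |>
    tidyr::pivot_wider(
      id_cols = c("batch_id", "condition", "replicate", "time_h"),
      names_from = "channel", values_from = "value"
    ) |>
    dplyr::arrange(.data$batch_id, .data$replicate, .data$time_h)
}

#' Normalize glycan peak areas to percent composition
#'
#' HPLC peak areas (AUC) for G0F, G1F and G2F are normalized to the total
#' summed area so the three fractions add to 100%.
#'
#' @param areas Numeric vector of three non-negative areas (G0F, G1F, G2F).
#' @return Numeric vector of three percentages summing to 100.
#' @examples
#' normalize_glycan_fractions(c(30, 15, 5)) # 60 30 10
#' @export
normalize_glycan_fractions <- function(areas) {
  stopifnot(length(areas) == 3)
  if (any(is.na(areas)) || any(areas < 0)) {
    stop("glycan areas must be non-negative and non-missing", call. = FALSE)
  }
  total <- sum(areas)
  if (total <= 0) {
    stop("all glycan peak areas are zero: composition undefined", call. = FALSE)
  }
  100 * areas / total
}

#' Average biological replicates into a pooled pseudo-replicate
#'
#' Per (batch-free) condition, time and channel, replicate values are averaged
#' over the replicates that measured them; a cell is missing only if it is
#' missing in every replicate. The pooled rows carry `replicate = 0` (the
#' reserved pooled marker) and `batch_id = "<condition>_pooled"`.
#'
#' @param tbl A culture table.
#' @param group Condition name to pool. If `NULL` (default) every condition
#'   present is pooled.
#' @return A culture table of pooled observations.
#' @export
pool_replicates <- function(tbl, group = NULL) {
  sub <- if (is.null(group)) tbl else dplyr::filter(tbl, .data$condition %in% group)
  if (nrow(sub) == 0) {
    return(sub)
  }
  sub |>
    dplyr::group_by(.data$condition, .data$time_h, .data$channel) |>
    dplyr::summarise(
      value = if (all(is.na(.data$value))) NA_real_ else
        mean(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      batch_id = paste0(.data$condition, "_pooled"),
      replicate = 0L
    ) |>
    dplyr::select("batch_id", "condition", "replicate", "time_h",
                  "channel", "value")
}
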