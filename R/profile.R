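# Aggregation of per-limb metrics into the study-style summary table
# (median and range) and its CSV/JSON serialisation.

#' Median of a numeric vector
#'
#' Middle order statistic; for even n, the mean of the two central order
#' statistics (delegated to [stats::median()]).
#'
#' @param values Nonempty numeric vector.
#' @return The median.
#' @export
median_stat <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty-input error", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  stats::median(values)
}

#' Range statistic (max minus min)
#' @param values Nonempty numeric vector.
#' @return max(values) - min(values).
#' @export
range_stat <- function(values) {
  values <- as.numeric(values)
  if (!length(values)) stop("empty-input error", call. = FALSE)
  if (any(!is.finite(values))) stop("values must be finite", call. = FALSE)
  max(values) - min(values)
}

limbs_to_df <- function(limbs) {
  if (is.data.frame(limbs)) {
    missing <- setdiff(metric_names(), names(limbs))
    if (length(missing))
      stop("limb table lacks metric columns: ",
           paste(missing, collapse = ", "), call. = FALSE)
    return(limbs[, metric_names(), drop = FALSE])
  }
  if (inherits(limbs, "limb_metrics")) limbs <- list(limbs)
  if (!length(limbs)) stop("empty-input error: no limbs", call. = FALSE)
  do.call(rbind, lapply(limbs, as.data.frame.limb_metrics))
}

#' Summarise limbs into a median/range profile
#'
#' @param limbs A list of `limb_metrics` objects, or a data frame with one
#'   row per limb and the ten metric columns of [metric_names()].
#' @return An object of class `profile_summary`: list with `median` and
#'   `range` (named numeric vectors over the metrics) and `n`.
#' @export
summarize_limbs <- function(limbs) {
  df <- limbs_to_df(limbs)
  structure(list(
    median = vapply(df, median_stat, numeric(1L)),
    range = vapply(df, range_stat, numeric(1L)),
    n = nrow(df)
  ), class = "profile_summary")
}

#' Round half away from zero
#'
#' Reporting rounding used for serialised tables (200.65 -> 200.7,
#' -1.25 -> -1.3), as opposed to R's round-half-even. A small guard
#' absorbs binary floating-point representation error at the .5 boundary.
#'
#' @param x Numeric vector.
#' @param dp Decimal places.
#' @return Rounded vector.
#' @export
round_half_away <- function(x, dp = 1L) {
  s <- 10^dp
  sign(x) * floor(abs(x) * s + 0.5 + 1e-9) / s
}

#' Write a per-limb profile report
#'
#' Writes a CSV in the study's table layout — one row per limb followed by
#' Median and Range rows, metric columns in the canonical order — with
#' values rounded half-away-from-zero to `dp` decimals, and a JSON twin
#' carrying full precision.
#'
#' @param limbs As in [summarize_limbs()].
#' @param path Output CSV path; the JSON twin replaces the extension with
#'   `.json` (or set `json_path`).
#' @param json_path Optional explicit JSON path.
#' @param dp Reporting decimal places (default from [morph_config()]).
#' @return Invisibly, a list with the written `csv` and `json` paths and
#'   the rounded table.
#' @export
write_profile <- function(limbs, path, json_path = NULL,
                          dp = morph_config()$rounding_dp) {
  df <- limbs_to_df(limbs)
  summ <- summarize_limbs(df)
  full <- rbind(df, as.data.frame(as.list(summ$median)),
                as.data.frame(as.list(summ$range)))
  rounded <- as.data.frame(lapply(full, round_half_away, dp = dp))
  labels <- c(paste("Limb", seq_len(nrow(df))), "Median", "Range")
  out <- cbind(limb = labels, rounded)
  names(out) <- c("limb", "TL_mm", "FL_mm", "FlexionAngle_deg", "QCA_cm2",
                  "QCA.FL_cm2m", "MomentArm_mm", "TTProjectionIndex",
                  "TP.TT_Ratio", "PennationVL_deg", "PennationRF_deg")
  ok <- tryCatch({
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write profile CSV to ", path, ": ",
         conditionMessage(ok), call. = FALSE)
  if (is.null(json_path)) json_path <- sub("\\.[^.]*$", ".json", path)
  payload <- list(
    n = summ$n,
    limbs = stats::setNames(split(as.matrix(df), row(as.matrix(df))),
                            paste("Limb", seq_len(nrow(df)))),
    metrics = metric_names(),
    median = as.list(summ$median),
    range = as.list(summ$range)
  )
  ok <- tryCatch({
    jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok))
    stop("failed to write profile JSON to ", json_path, ": ",
         conditionMessage(ok), call. = FALSE)
  invisible(list(csv = path, json = json_path, table = out))
}

#' Read a per-limb metric table from CSV
#'
#' Accepts either the canonical report header written by [write_profile()]
#' or bare metric-name columns; `Median`/`Range` rows, if present, are
#' dropped so the result is one row per limb.
#'
#' @param path CSV path.
#' @return Data frame with the ten metric columns, one row per limb.
#' @export
read_limb_table <- function(path) {
  if (!file.exists(path)) stop("limb table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE)
  header_map <- c("TL_mm" = "tl", "FL_mm" = "fl",
                  "FlexionAngle_deg" = "flexion_angle", "QCA_cm2" = "qca",
                  "QCA.FL_cm2m" = "qca_fl", "MomentArm_mm" = "moment_arm",
                  "TTProjectionIndex" = "tt_projection_index",
                  "TP.TT_Ratio" = "tp_tt_ratio",
                  "PennationVL_deg" = "pennation_vl",
                  "PennationRF_deg" = "pennation_rf")
  hit <- names(df) %in% names(header_map)
  names(df)[hit] <- header_map[names(df)[hit]]
  if ("limb" %in% names(df)) {
    df <- df[!df$limb %in% c("Median", "Range"), , drop = FALSE]
  }
  missing <- setdiff(metric_names(), names(df))
  if (length(missing))
    stop("limb table lacks metric columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  df[, c(intersect("limb", names(df)), metric_names()), drop = FALSE]
}

#' @export
print.profile_summary <- function(x, ...) {
  cat("Profile summary over", x$n, "limbs\n")
  print(round(rbind(median = x$median, range = x$range), 3))
  invisible(x)
}
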