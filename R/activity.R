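#' @importFrom rlang %||% .data
#' @keywords internal
"_PACKAGE"

# column schema of an activity table (units: ha, kg, kg N / ha)
.activity_cols <- c("province", "crop", "year", "area_ha", "yield_kg",
                    "n_urea", "n_cf", "n_dap", "n_abc")

.rate_cols <- c("n_urea", "n_cf", "n_dap", "n_abc")

#' Validate a provincial activity table
#'
#' An activity table holds one row per (province, crop, year)
#' observation with sown area `area_ha` (ha), total grain yield
#' `yield_kg` (kg) and per-product N application rates `n_urea`,
#' `n_cf`, `n_dap`, `n_abc` (kg N per hectare). Provinces are
#' canonicalised and the agricultural `region` column is (re)resolved
#' from the region map.
#'
#' @param activity Data frame with the activity schema.
#' @param map Region map; defaults to [default_region_map()].
#' @return A validated tibble with a `region` column, rows ordered by
#'   (crop, province, year).
#' @export
validate_activity <- function(activity, map = default_region_map()) {
  activity <- tibble::as_tibble(activity)
  missing_cols <- setdiff(.activity_cols, names(activity))
  if (length(missing_cols) > 0) {
    stop("activity table missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(activity) == 0) stop("no records", call. = FALSE)
  num_cols <- setdiff(.activity_cols, c("province", "crop"))
  for (cl in num_cols) {
    v <- activity[[cl]]
    if (!is.numeric(v) || anyNA(v)) {
      stop("column '", cl, "' must be numeric with no missing values",
           call. = FALSE)
    }
  }
  .check_nonneg <- function(col, strict = FALSE) {
    v <- activity[[col]]
    bad <- if (strict) which(v <= 0) else which(v < 0)
    if (length(bad) > 0) {
      stop("row ", bad[1], ": '", col, "' must be ",
           if (strict) "> 0" else ">= 0", " (got ", v[bad[1]], ")",
           call. = FALSE)
    }
  }
  .check_nonneg("area_ha", strict = TRUE)
  .check_nonneg("yield_kg")
  for (cl in .rate_cols) .check_nonneg(cl)
  if (any(!activity$crop %in% crop_codes())) {
    bad <- setdiff(unique(activity$crop), crop_codes())
    stop("unknown crop(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  activity$province <- normalize_province(activity$province)
  activity$region <- resolve_region(activity$province, map)
  key <- activity[, c("province", "crop", "year")]
  if (anyDuplicated(key)) {
    stop("duplicate (province, crop, year) rows", call. = FALSE)
  }
  dplyr::arrange(
    activity[, c("province", "region", "crop", "year",
                 setdiff(.activity_cols,
                         c("province", "crop", "year")))],
    .data$crop, .data$province, .data$year
  )
}

#' Read an activity CSV
#'
#' Expects a UTF-8, comma-separated file with a header row matching the
#' activity schema: `province, crop, year, area_ha, yield_kg, n_urea,
#' n_cf, n_dap, n_abc`. Rows are validated and the agricultural region
#' resolved; errors name the offending row and field.
#'
#' @param path CSV file path.
#' @param map Region map; defaults to [default_region_map()].
#' @return Validated activity tibble (see [validate_activity()]).
#' @export
read_activity_csv <- function(path, map = default_region_map()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE)
  if (nrow(raw) == 0) stop("no records", call. = FALSE)
  validate_activity(raw, map = map)
}

#' Write an activity table to CSV
#'
#' Inverse of [read_activity_csv()]; the derived `region` column is
#' dropped so the file carries the canonical input schema.
#'
#' @param activity Activity tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_activity_csv <- function(activity, path) {
  out <- tibble::as_tibble(activity)[, .activity_cols]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
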