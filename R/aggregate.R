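# metric name -> results column; extensive metrics sum over strata,
# intensities are recomputed from pooled totals
.extensive_metrics <- c(
  em_urea = "em_urea", em_cf = "em_cf", em_dap = "em_dap",
  em_abc = "em_abc", em_total = "em_total_kg", ed_n2o = "ed_n2o_kg",
  total_co2eq = "total_co2eq_kg", area = "area_ha", yield = "yield_kg"
)
.intensity_metrics <- c("area_scaled", "yield_scaled")

#' Interannual mean and standard deviation
#'
#' Collapses one yearly value per year to a mean and a sample
#' (n - 1 denominator) standard deviation; a single year has sd 0.
#'
#' @param values Numeric vector of yearly values (length >= 1).
#' @return Tibble with `mean`, `sd`, `n_years`.
#' @export
#' @examples
#' mean_sd_over_years(c(1, 2, 3)) # mean 2, sd 1
mean_sd_over_years <- function(values) {
  if (length(values) == 0 || !is.numeric(values) || anyNA(values)) {
    stop("values must be a non-empty numeric vector", call. = FALSE)
  }
  tibble::tibble(
    mean = mean(values),
    sd = if (length(values) > 1) stats::sd(values) else 0,
    n_years = length(values)
  )
}

#' Stratified multi-year rollup of inventory results
#'
#' Aggregates per-record inventory results to province, region or
#' national scope. Extensive metrics (emissions, area, yield) are
#' summed within each year and the yearly totals averaged over years
#' (mean and sample SD — interannual variation is the error source).
#' Intensities (`area_scaled`, `yield_scaled`) are recomputed at the
#' aggregate scope from pooled totals, `sum(total_co2eq) / sum(area
#' or yield)` within each year — never averaged across provinces.
#'
#' @param results Output of [run_inventory()].
#' @param level `"province"`, `"region"` or `"national"`.
#' @param quantity Metric name: an extensive metric (`em_urea`,
#'   `em_cf`, `em_dap`, `em_abc`, `em_total`, `ed_n2o`, `total_co2eq`,
#'   `area`, `yield`) or an intensity (`area_scaled`, `yield_scaled`).
#' @param crop Optional crop filter. Results must contain a single
#'   crop after filtering; aggregating across crops is an error.
#' @return Tibble with `scope`, `group` (province/region name, or
#'   `"national"`), `crop`, `quantity`, `mean`, `sd`, `n_years`.
#' @export
#' @examples
#' fx <- china_uplands_fixture()
#' res <- run_inventory(fx$national_activity)
#' rollup(res, "national", "em_total", crop = "wheat")
rollup <- function(results,
                   level = c("province", "region", "national"),
                   quantity, crop = NULL) {
  level <- match.arg(level)
  quantity <- match.arg(quantity,
                        c(names(.extensive_metrics), .intensity_metrics))
  if (!is.null(crop)) {
    results <- results[results$crop == crop, , drop = FALSE]
  }
  if (nrow(results) == 0) stop("no records in scope", call. = FALSE)
  if (length(unique(results$crop)) > 1) {
    stop("results mix crops; aggregate one crop at a time",
         call. = FALSE)
  }
  group_col <- switch(level, province = "province", region = "region",
                      national = NULL)
  keys <- c(group_col, "crop", "year")
  yearly <- if (quantity %in% names(.extensive_metrics)) {
    col <- .extensive_metrics[[quantity]]
    dplyr::summarise(
      dplyr::group_by(results, dplyr::across(dplyr::all_of(keys))),
      value = sum(.data[[col]]), .groups = "drop")
  } else {
    denom <- if (quantity == "area_scaled") "area_ha" else "yield_kg"
    dplyr::summarise(
      dplyr::group_by(results, dplyr::across(dplyr::all_of(keys))),
      value = sum(.data$total_co2eq_kg) / sum(.data[[denom]]),
      .groups = "drop")
  }
  out <- dplyr::summarise(
    dplyr::group_by(yearly,
                    dplyr::across(dplyr::all_of(setdiff(keys, "year")))),
    mean = mean(.data$value),
    sd = if (dplyr::n() > 1) stats::sd(.data$value) else 0,
    n_years = dplyr::n(), .groups = "drop")
  out$scope <- level
  out$group <- if (is.null(group_col)) "national" else out[[group_col]]
  out$quantity <- quantity
  if (!is.null(group_col)) out[[group_col]] <- NULL
  out[, c("scope", "group", "crop", "quantity", "mean", "sd",
          "n_years")]
}

#' Percentage share of a part in a whole
#'
#' `100 * part / whole` where `part` and `whole` are either aggregate
#' rows from [rollup()] (the `mean` is used) or plain numbers.
#'
#' @param part,whole Single-row aggregate tibbles or numeric scalars.
#' @return Percent (numeric scalar).
#' @export
#' @examples
#' share_of_total(8.74, 41.44) # 21.1 % (Henan share of wheat
#'                             # manufacture emissions)
share_of_total <- function(part, whole) {
  take <- function(x, what) {
    if (is.data.frame(x)) {
      stopifnot(nrow(x) == 1, "mean" %in% names(x))
      x$mean
    } else {
      stopifnot(is.numeric(x), length(x) == 1)
      x
    }
  }
  if (is.data.frame(part) && is.data.frame(whole) &&
      all(c("quantity") %in% names(part)) &&
      all(c("quantity") %in% names(whole)) &&
      part$quantity != whole$quantity) {
    stop("part and whole measure different quantities", call. = FALSE)
  }
  p <- take(part)
  w <- take(whole)
  if (w <= 0) stop("whole must be > 0", call. = FALSE)
  100 * p / w
}

#' Area fractions by N application-rate class
#'
#' Bins each activity record by its total synthetic N rate (sum over
#' the four products, kg N per ha) into left-closed right-open
#' intervals and returns the fraction of sown area in each class.
#'
#' @param activity Activity tibble.
#' @param bin_edges Ascending numeric edges covering all observed
#'   rates; default `c(0, 50, ..., 300, Inf)` in 50 kg steps.
#' @return Tibble with `bin` (label), `lower`, `upper`,
#'   `area_fraction` (sums to 1).
#' @export
rate_class_area_fractions <- function(activity,
                                      bin_edges = c(seq(0, 300, 50),
                                                    Inf)) {
  if (is.unsorted(bin_edges, strictly = TRUE) || length(bin_edges) < 2) {
    stop("bin_edges must be strictly ascending", call. = FALSE)
  }
  rate <- rowSums(as.matrix(activity[, .rate_cols]))
  if (any(rate < bin_edges[1]) || any(rate >= bin_edges[length(bin_edges)])) {
    stop("rate(s) outside bin range [", bin_edges[1], ", ",
         bin_edges[length(bin_edges)], ")", call. = FALSE)
  }
  idx <- findInterval(rate, bin_edges, rightmost.closed = FALSE)
  nbin <- length(bin_edges) - 1
  area_by_bin <- vapply(seq_len(nbin), function(b) {
    sum(activity$area_ha[idx == b])
  }, numeric(1))
  lo <- bin_edges[-length(bin_edges)]
  hi <- bin_edges[-1]
  tibble::tibble(
    bin = paste0("[", lo, ",", ifelse(is.finite(hi), hi, "Inf"), ")"),
    lower = lo, upper = hi,
    area_fraction = area_by_bin / sum(activity$area_ha)
  )
}
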