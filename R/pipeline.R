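#' Run the end-to-end inventory pipeline
#'
#' Reads (or accepts) an activity table, applies the emission-factor
#' registry, computes per-record emissions and intensities, aggregates
#' to province, region and national scope, and builds the report
#' tables. All stages validate their inputs; any failure aborts with
#' an informative error.
#'
#' @param activity Activity tibble or path to an activity CSV.
#' @param ef_config An `ef_registry`, a path to a YAML EF config, or
#'   `NULL` for the shipped defaults.
#' @param crop Optional crop filter (`"wheat"` or `"maize"`).
#' @param out_dir Optional directory; when given, report tables are
#'   written there (`format` selects CSV or markdown) together with a
#'   JSON summary of national totals.
#' @param format Report file format, `"csv"` or `"markdown"`.
#' @param quiet Suppress the provenance log messages.
#' @return A list with `results` (per-record), `aggregates` (national
#'   and regional rollups of the main metrics), `report`
#'   ([build_report()] output) and `ef_source` (provenance string).
#' @export
run_pipeline <- function(activity, ef_config = NULL, crop = NULL,
                         out_dir = NULL, format = c("csv", "markdown"),
                         quiet = FALSE) {
  format <- match.arg(format)
  if (is.character(activity) && length(activity) == 1) {
    activity <- read_activity_csv(activity)
  } else {
    activity <- validate_activity(activity)
  }
  if (inherits(ef_config, "ef_registry")) {
    registry <- ef_config
    ef_source <- "user-supplied registry object"
  } else if (is.character(ef_config)) {
    registry <- read_ef_config(ef_config)
    ef_source <- paste0("config file: ", ef_config)
  } else {
    registry <- default_ef_registry()
    ef_source <- "shipped defaults"
  }
  if (!quiet) message("emission factors: ", ef_source)
  if (!is.null(crop)) {
    crop <- match.arg(crop, crop_codes())
    activity <- activity[activity$crop == crop, , drop = FALSE]
    if (nrow(activity) == 0) stop("no records", call. = FALSE)
  }
  results <- run_inventory(activity, registry)
  crops_here <- intersect(crop_codes(), unique(results$crop))
  aggregates <- dplyr::bind_rows(lapply(crops_here, function(cr) {
    dplyr::bind_rows(
      lapply(c("em_total", "ed_n2o", "total_co2eq",
               "area_scaled", "yield_scaled"), function(q) {
        dplyr::bind_rows(
          rollup(results, "national", q, crop = cr),
          rollup(results, "region", q, crop = cr))
      }))
  }))
  report <- build_report(results)
  if (!is.null(out_dir)) {
    paths <- write_report(report, out_dir, format)
    nat <- aggregates[aggregates$scope == "national", ]
    json_path <- file.path(out_dir, "national_summary.json")
    .write_json_summary(nat, json_path)
    if (!quiet) message("report written to ", out_dir)
  }
  list(results = results, aggregates = aggregates, report = report,
       ef_source = ef_source)
}

# flat JSON of national rollups without requiring jsonlite
.write_json_summary <- function(nat, path) {
  esc <- function(x) gsub('"', '\\\\"', x)
  entries <- vapply(seq_len(nrow(nat)), function(i) {
    sprintf('  "%s": {"mean": %.10g, "sd": %.10g, "n_years": %d}',
            esc(paste(nat$crop[i], nat$quantity[i], sep = "_")),
            nat$mean[i], nat$sd[i], nat$n_years[i])
  }, character(1))
  writeLines(c("{", paste(entries, collapse = ",\n"), "}"), path)
  invisible(path)
}

#' Reconcile the pipeline against the embedded benchmark values
#'
#' Recomputes the headline national quantities from the benchmark
#' fixture inputs (published rates, emission factors and implied
#' areas) and checks them — plus the arithmetic identities among the
#' published numbers and the regional sums of the provincial tables —
#' against the published values.
#'
#' @param fx Fixture from [china_uplands_fixture()].
#' @return Tibble with `check`, `computed`, `expected`, `tolerance`
#'   (relative, except rows flagged absolute), `pass`.
#' @export
#' @examples
#' rec <- reconcile_fixture()
#' all(rec$pass)
reconcile_fixture <- function(fx = china_uplands_fixture()) {
  reg <- fx$registry
  em <- manufacture_emissions(fx$national_activity, reg)
  em_mt <- stats::setNames(em$em_total_kg, em$crop) / 1e9
  comp <- fx$national_components
  get_comp <- function(cr, cp) comp$mean[comp$crop == cr &
                                           comp$component == cp]
  ed_gg <- c(wheat = get_comp("wheat", "ed_n2o"),
             maize = get_comp("maize", "ed_n2o"))
  ed_co2_mt <- co2eq_of_n2o(ed_gg * 1e6, reg) / 1e9
  total_mt <- c(wheat = get_comp("wheat", "total"),
                maize = get_comp("maize", "total"))
  em_pub <- c(wheat = 41.44, maize = 59.71)
  region_sum <- function(tab, region, crop_prefix) {
    v <- tab[[paste0(crop_prefix, "_mean")]][tab$region == region]
    sum(v, na.rm = TRUE)
  }
  rows <- list(
    list("national N consumption (Mt N)",
         sum(fx$national_n_mt), 12.63, 1e-9, FALSE),
    list("wheat manufacture emissions recomputed (Mt CO2-eq)",
         em_mt[["wheat"]], em_pub[["wheat"]], 0.005, FALSE),
    list("maize manufacture emissions recomputed (Mt CO2-eq)",
         em_mt[["maize"]], em_pub[["maize"]], 0.01, FALSE),
    list("wheat N2O in CO2-eq (Mt)",
         ed_co2_mt[["wheat"]], 10.67, 0.005, TRUE),
    list("maize N2O in CO2-eq (Mt)",
         ed_co2_mt[["maize"]], 20.69, 0.005, TRUE),
    list("wheat total = manufacture + N2O x GWP (Mt)",
         em_pub[["wheat"]] + 10.67, total_mt[["wheat"]], 1e-9, FALSE),
    list("maize total = manufacture + N2O x GWP (Mt)",
         em_pub[["maize"]] + 20.69, total_mt[["maize"]], 1e-9, FALSE),
    list("NWC wheat N2O from provincial rows (Gg)",
         region_sum(fx$provincial_n2o, "NWC", "wheat"),
         3.78, 1e-9, FALSE),
    list("NEC maize N2O from provincial rows (Gg)",
         region_sum(fx$provincial_n2o, "NEC", "maize"),
         16.48, 1e-9, FALSE),
    list("NWC maize N2O from provincial rows (Gg)",
         region_sum(fx$provincial_n2o, "NWC", "maize"),
         8.40, 1e-9, FALSE),
    list("wheat area-scaled intensity (t CO2-eq/ha)",
         area_scaled(em_pub[["wheat"]] * 1e9,
                     ed_gg[["wheat"]] * 1e6,
                     fx$implied_area_ha[["wheat"]], reg) / 1e3,
         2.23, 0.01, TRUE),
    list("maize area-scaled intensity (t CO2-eq/ha)",
         area_scaled(em_pub[["maize"]] * 1e9,
                     ed_gg[["maize"]] * 1e6,
                     fx$implied_area_ha[["maize"]], reg) / 1e3,
         2.13, 0.01, TRUE),
    list("Henan wheat manufacture share (%)",
         share_of_total(8.74, em_pub[["wheat"]]), 21.1, 0.05, TRUE),
    list("five-province manufacture share, both crops (%)",
         share_of_total(
           sum(fx$provincial_manufacture$wheat_mean[
             fx$provincial_manufacture$province %in%
               c("Henan", "Shandong", "Hebei", "Inner Mongolia",
                 "Heilongjiang")], na.rm = TRUE) +
           sum(fx$provincial_manufacture$maize_mean[
             fx$provincial_manufacture$province %in%
               c("Henan", "Shandong", "Hebei", "Inner Mongolia",
                 "Heilongjiang")], na.rm = TRUE),
           sum(em_pub)), 49.4, 0.05, TRUE)
  )
  out <- tibble::tibble(
    check = vapply(rows, `[[`, character(1), 1),
    computed = vapply(rows, `[[`, numeric(1), 2),
    expected = vapply(rows, `[[`, numeric(1), 3),
    tolerance = vapply(rows, `[[`, numeric(1), 4),
    absolute = vapply(rows, `[[`, logical(1), 5)
  )
  out$pass <- ifelse(
    out$absolute,
    abs(out$computed - out$expected) <= out$tolerance,
    abs(out$computed - out$expected) <=
      out$tolerance * pmax(abs(out$expected), 1e-12))
  out
}
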