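#' Format a mean and SD as "mean ± sd"
#'
#' @param mean,sd Numeric vectors.
#' @param digits Decimal places (default 2, the convention of the
#'   published tables).
#' @return Character vector like `"23.42 ± 0.19"`.
#' @export
format_mean_sd <- function(mean, sd, digits = 2) {
  paste0(formatC(mean, format = "f", digits = digits), " ± ",
         formatC(sd, format = "f", digits = digits))
}

.unit_scale <- c(kg = 1, t = 1e3, Gg = 1e6, Mt = 1e9)

# provincial table of one extensive metric, wheat and maize columns
.provincial_table <- function(results, quantity, unit, digits = 2) {
  scale <- .unit_scale[[unit]]
  per_crop <- lapply(intersect(crop_codes(), unique(results$crop)),
                     function(cr) {
    agg <- rollup(results, "province", quantity, crop = cr)
    tab <- tibble::tibble(province = agg$group,
                          val = format_mean_sd(agg$mean / scale,
                                               agg$sd / scale, digits))
    names(tab)[2] <- cr
    tab
  })
  map <- default_region_map()
  base <- tibble::tibble(region = map$region, province = map$province)
  for (tab in per_crop) base <- dplyr::left_join(base, tab, by = "province")
  present <- unique(results$province)
  base <- base[base$province %in% present, , drop = FALSE]
  for (cr in intersect(crop_codes(), names(base))) {
    base[[cr]][is.na(base[[cr]])] <- "–"
  }
  base
}

#' Build the inventory report tables
#'
#' Produces the four standard report tables from per-record inventory
#' results, rounded only at render time:
#' \describe{
#'   \item{`provincial_manufacture`}{Manufacture GHG emissions per
#'     province, Mt CO2-eq per year, wheat and maize columns,
#'     "mean ± sd" over years.}
#'   \item{`provincial_n2o`}{Direct N2O emissions per province, Gg N2O
#'     per year.}
#'   \item{`national_components`}{Per crop: manufacture emissions by
#'     product (Mt CO2-eq), direct N2O (Gg N2O), and the national
#'     CO2-eq total (Mt CO2-eq).}
#'   \item{`regional_intensity`}{Area-scaled (t CO2-eq per ha) and
#'     yield-scaled (kg CO2-eq per kg grain) emissions per region.}
#' }
#'
#' @param results Output of [run_inventory()].
#' @param digits Decimal places for rendered values (default 2).
#' @return A named list of tibbles (class `inventory_report`).
#' @export
build_report <- function(results, digits = 2) {
  crops_here <- intersect(crop_codes(), unique(results$crop))
  nat_rows <- list(
    c("em_urea", "Mt"), c("em_cf", "Mt"), c("em_dap", "Mt"),
    c("em_abc", "Mt"), c("ed_n2o", "Gg"), c("total_co2eq", "Mt")
  )
  nat_labels <- c(
    "GHG emissions from urea manufacture (Mt CO2-eq / yr)",
    "GHG emissions from CF manufacture (Mt CO2-eq / yr)",
    "GHG emissions from DAP manufacture (Mt CO2-eq / yr)",
    "GHG emissions from ABC manufacture (Mt CO2-eq / yr)",
    "Direct N2O emissions from the soil (Gg N2O / yr)",
    "Total national GHG emissions (Mt CO2-eq / yr)"
  )
  national <- tibble::tibble(quantity = nat_labels)
  for (cr in crops_here) {
    national[[cr]] <- vapply(nat_rows, function(q) {
      agg <- rollup(results, "national", q[1], crop = cr)
      sc <- .unit_scale[[q[2]]]
      format_mean_sd(agg$mean / sc, agg$sd / sc, digits)
    }, character(1))
  }
  regional <- tibble::tibble(region = region_codes())
  for (cr in crops_here) {
    for (m in c("area_scaled", "yield_scaled")) {
      agg <- rollup(results[results$crop == cr, ], "region", m)
      sc <- if (m == "area_scaled") 1e3 else 1  # t/ha vs kg/kg
      col <- tibble::tibble(
        region = agg$group,
        val = format_mean_sd(agg$mean / sc, agg$sd / sc, digits))
      names(col)[2] <- paste(m, cr, sep = "_")
      regional <- dplyr::left_join(regional, col, by = "region")
    }
  }
  regional <- regional[
    rowSums(!is.na(as.matrix(regional[, -1, drop = FALSE]))) > 0, ,
    drop = FALSE]
  for (cl in names(regional)[-1]) {
    regional[[cl]][is.na(regional[[cl]])] <- "–"
  }
  structure(
    list(
      provincial_manufacture =
        .provincial_table(results, "em_total", "Mt", digits),
      provincial_n2o =
        .provincial_table(results, "ed_n2o", "Gg", digits),
      national_components = national,
      regional_intensity = regional
    ),
    class = "inventory_report"
  )
}

#' @export
print.inventory_report <- function(x, ...) {
  for (nm in names(x)) {
    cat("== ", nm, " ==\n", sep = "")
    print(as.data.frame(x[[nm]]), row.names = FALSE)
    cat("\n")
  }
  invisible(x)
}

#' Write report tables to CSV or markdown
#'
#' @param report An `inventory_report` from [build_report()].
#' @param dir Output directory (created if needed).
#' @param format `"csv"` or `"markdown"`.
#' @return Character vector of written paths, invisibly.
#' @export
write_report <- function(report, dir, format = c("csv", "markdown")) {
  format <- match.arg(format)
  stopifnot(inherits(report, "inventory_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ext <- if (format == "csv") ".csv" else ".md"
  paths <- character(0)
  for (nm in names(report)) {
    path <- file.path(dir, paste0(nm, ext))
    if (format == "csv") {
      readr::write_csv(report[[nm]], path, progress = FALSE)
    } else {
      writeLines(.md_table(report[[nm]]), path)
    }
    paths <- c(paths, path)
  }
  invisible(paths)
}

.md_table <- function(df) {
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(as.matrix(df), 1, function(r) {
    paste0("| ", paste(r, collapse = " | "), " |")
  })
  c(hdr, sep, rows)
}
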