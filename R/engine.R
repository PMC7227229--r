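#' Manufacture emissions per fertilizer product
#'
#' For each product p, `E_M[p] = NR[p] * A * EF_M[p]`: the N
#' application rate (kg N per ha) times the sown area (ha) times the
#' life-cycle manufacture emission factor (kg CO2-eq per kg N). Linear
#' in both rate and area.
#'
#' @param activity Validated activity tibble (one or more records).
#' @param registry An `ef_registry`.
#' @return Tibble keyed by (province, crop, year) with one
#'   `em_<product>` column per product and their sum `em_total_kg`,
#'   all in kg CO2-eq.
#' @export
manufacture_emissions <- function(activity, registry = default_ef_registry()) {
  stopifnot(inherits(registry, "ef_registry"))
  keys <- intersect(c("province", "region", "crop", "year"),
                    names(activity))
  out <- activity[, c(keys, "area_ha")]
  for (p in product_codes()) {
    used <- activity[[paste0("n_", p)]] > 0
    if (any(used) && !p %in% names(registry$ef_m)) {
      stop("no manufacture emission factor for product: ", p,
           call. = FALSE)
    }
    ef <- if (p %in% names(registry$ef_m)) registry$ef_m[[p]] else 0
    out[[paste0("em_", p)]] <-
      activity[[paste0("n_", p)]] * activity$area_ha * ef
  }
  out$em_total_kg <- rowSums(as.matrix(
    out[, paste0("em_", product_codes())]))
  out$area_ha <- NULL
  out
}

#' Direct soil N2O emissions from fertilization
#'
#' `E_D = (sum of NR over products) * A * EF_D * 44/28`: the summed N
#' rate across all products is charged with a single region- and
#' crop-specific direct emission factor (synthetic N acts as a class),
#' and 44/28 converts N2O-N mass to N2O mass.
#'
#' @inheritParams manufacture_emissions
#' @return Tibble keyed by (province, crop, year) with `ed_n2o_kg`
#'   (kg N2O).
#' @export
direct_n2o_emissions <- function(activity, registry = default_ef_registry()) {
  stopifnot(inherits(registry, "ef_registry"))
  nr_total <- rowSums(as.matrix(activity[, .rate_cols]))
  ef <- ef_d_lookup(registry, activity$region, activity$crop)
  tibble::tibble(
    province = activity$province, region = activity$region,
    crop = activity$crop, year = activity$year,
    ed_n2o_kg = nr_total * activity$area_ha * ef * registry$n_to_n2o
  )
}

#' CO2-equivalent of an N2O mass
#'
#' @param e_d N2O mass, kg (non-negative).
#' @param registry An `ef_registry` (supplies `gwp_n2o`).
#' @return `e_d * gwp_n2o`, kg CO2-eq.
#' @export
#' @examples
#' co2eq_of_n2o(35.82e6) / 1e9 # 10.67 Mt CO2-eq from 35.82 Gg N2O
co2eq_of_n2o <- function(e_d, registry = default_ef_registry()) {
  stopifnot(inherits(registry, "ef_registry"))
  if (any(e_d < 0)) stop("e_d must be >= 0", call. = FALSE)
  e_d * registry$gwp_n2o
}

#' Area-scaled GHG emission intensity
#'
#' `(E_M + E_D * GWP) / A` in kg CO2-eq per hectare. Manufacture
#' emissions are already CO2-eq, so the GWP factor applies to the N2O
#' term only.
#'
#' @param e_m_total Manufacture emissions, kg CO2-eq.
#' @param e_d Direct N2O emissions, kg N2O.
#' @param area Sown area, ha (> 0).
#' @param registry An `ef_registry`.
#' @return kg CO2-eq per ha.
#' @export
area_scaled <- function(e_m_total, e_d, area,
                        registry = default_ef_registry()) {
  if (any(area <= 0)) stop("area must be > 0", call. = FALSE)
  (e_m_total + co2eq_of_n2o(e_d, registry)) / area
}

#' Yield-scaled GHG emission intensity
#'
#' `(E_M + E_D * GWP) / Y` in kg CO2-eq per kg grain. A zero yield
#' gives a defined `NA` intensity rather than an infinite value.
#'
#' @param e_m_total Manufacture emissions, kg CO2-eq.
#' @param e_d Direct N2O emissions, kg N2O.
#' @param yield_total Grain yield, kg (>= 0).
#' @param registry An `ef_registry`.
#' @return kg CO2-eq per kg grain; `NA` where `yield_total` is 0.
#' @export
yield_scaled <- function(e_m_total, e_d, yield_total,
                         registry = default_ef_registry()) {
  if (any(yield_total < 0)) stop("yield_total must be >= 0", call. = FALSE)
  total <- e_m_total + co2eq_of_n2o(e_d, registry)
  out <- ifelse(yield_total > 0, total / yield_total, NA_real_)
  # a record emitting nothing has zero intensity even at zero yield
  out[yield_total == 0 & total == 0] <- 0
  out
}

#' Run the full per-record inventory
#'
#' Composes the four inventory equations over every activity record:
#' per-product manufacture emissions, direct soil N2O, the
#' CO2-equivalent total `em_total_kg + ed_n2o_kg * gwp_n2o`, and the
#' area- and yield-scaled intensities.
#'
#' @param activity Activity tibble; validated first unless it already
#'   carries a `region` column from [validate_activity()].
#' @param registry An `ef_registry`.
#' @return Tibble with one row per (province, crop, year):
#'   activity columns plus `em_urea`, `em_cf`, `em_dap`, `em_abc`,
#'   `em_total_kg`, `ed_n2o_kg`, `total_co2eq_kg`,
#'   `area_scaled_kg_ha`, `yield_scaled_kg_kg`.
#' @export
#' @examples
#' fx <- china_uplands_fixture()
#' run_inventory(fx$national_activity)
run_inventory <- function(activity, registry = default_ef_registry()) {
  if (!"region" %in% names(activity)) {
    activity <- validate_activity(activity)
  }
  em <- manufacture_emissions(activity, registry)
  ed <- direct_n2o_emissions(activity, registry)
  res <- dplyr::bind_cols(
    activity[, c("province", "region", "crop", "year", "area_ha",
                 "yield_kg")],
    em[, c(paste0("em_", product_codes()), "em_total_kg")],
    ed[, "ed_n2o_kg", drop = FALSE]
  )
  res$total_co2eq_kg <- res$em_total_kg +
    co2eq_of_n2o(res$ed_n2o_kg, registry)
  res$area_scaled_kg_ha <-
    area_scaled(res$em_total_kg, res$ed_n2o_kg, res$area_ha, registry)
  res$yield_scaled_kg_kg <-
    yield_scaled(res$em_total_kg, res$ed_n2o_kg, res$yield_kg, registry)
  res
}
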