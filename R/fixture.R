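#' Embedded benchmark fixture: Chinese upland wheat and maize, 2015-2017
#'
#' Published national and provincial benchmark values for the
#' synthetic-N GHG inventory of Chinese upland wheat and maize
#' (2015-2017 averages), embedded as code so every pipeline stage can
#' be reconciled without external data.
#'
#' @return A list:
#' \describe{
#'   \item{`registry`}{The default [ef_registry()].}
#'   \item{`national_rates`}{Per-product national mean N rates, kg N
#'     per ha (wheat 124/72/17/9, maize 111/62/15/8).}
#'   \item{`national_mean_rate`}{Total mean N rate, kg per ha (wheat
#'     222, maize 197).}
#'   \item{`national_n_mt`}{Annual synthetic N consumption, Mt N
#'     (wheat 5.18, maize 7.45).}
#'   \item{`implied_area_ha`}{Sown area implied by consumption /
#'     mean rate (wheat approx. 2.33e7 ha).}
#'   \item{`national_activity`}{Two national-average pseudo-records in
#'     the activity schema built from the above (yields back-derived
#'     from the published yield-scaled intensities; `year = 0` marks
#'     them as multi-year averages).}
#'   \item{`national_components`}{National emission components per
#'     crop: manufacture by product (Mt CO2-eq/yr), direct soil N2O
#'     (Gg N2O/yr), total (Mt CO2-eq/yr), each mean and sd.}
#'   \item{`provincial_manufacture`}{Provincial manufacture emissions,
#'     Mt CO2-eq/yr (mean, sd) per crop; `NA` where the province does
#'     not grow the crop.}
#'   \item{`provincial_n2o`}{Provincial direct N2O emissions, Gg
#'     N2O/yr (mean, sd) per crop.}
#'   \item{`regional_manufacture`, `regional_n2o`}{Published regional
#'     totals (Mt CO2-eq/yr and Gg N2O/yr).}
#'   \item{`regional_intensity`}{Regional area-scaled (t CO2-eq/ha)
#'     and yield-scaled (kg CO2-eq/kg grain) intensities (mean, sd).}
#'   \item{`national_intensity`}{National area-scaled (t CO2-eq/ha)
#'     and yield-scaled (kg/kg) intensities.}
#'   \item{`rate_class_fractions`}{Published rate-class area anchors:
#'     wheat 200-250 kg/ha holds 42.5% of area, maize 150-200 holds
#'     64.0%.}
#' }
#' @export
#' @examples
#' fx <- china_uplands_fixture()
#' fx$implied_area_ha["wheat"]
china_uplands_fixture <- function() {
  national_rates <- list(
    wheat = c(urea = 124, cf = 72, dap = 17, abc = 9),
    maize = c(urea = 111, cf = 62, dap = 15, abc = 8)
  )
  national_mean_rate <- c(wheat = 222, maize = 197)
  national_n_mt <- c(wheat = 5.18, maize = 7.45)
  implied_area_ha <- national_n_mt * 1e9 / national_mean_rate
  national_intensity <- tibble::tibble(
    crop = c("wheat", "maize"),
    area_scaled_t_ha = c(2.23, 2.13),
    yield_scaled_kg_kg = c(0.41, 0.35)
  )
  total_mt <- c(wheat = 52.11, maize = 80.40)
  # yields implied by total emissions / yield-scaled intensity
  implied_yield_kg <- total_mt * 1e9 /
    national_intensity$yield_scaled_kg_kg
  national_activity <- tibble::tibble(
    province = "National", crop = c("wheat", "maize"), year = 0L,
    area_ha = unname(implied_area_ha),
    yield_kg = unname(implied_yield_kg),
    n_urea = c(124, 111), n_cf = c(72, 62),
    n_dap = c(17, 15), n_abc = c(9, 8)
  )
  national_components <- tibble::tribble(
    ~crop,   ~component, ~units,            ~mean,  ~sd,
    "wheat", "em_urea",  "Mt CO2-eq/yr",    23.42,  0.19,
    "wheat", "em_cf",    "Mt CO2-eq/yr",    12.47,  0.70,
    "wheat", "em_dap",   "Mt CO2-eq/yr",     4.03,  0.13,
    "wheat", "em_abc",   "Mt CO2-eq/yr",     1.53,  0.43,
    "wheat", "ed_n2o",   "Gg N2O/yr",       35.82,  1.20,
    "wheat", "total",    "Mt CO2-eq/yr",    52.11,  0.93,
    "maize", "em_urea",  "Mt CO2-eq/yr",    34.07,  1.00,
    "maize", "em_cf",    "Mt CO2-eq/yr",    17.49,  2.34,
    "maize", "em_dap",   "Mt CO2-eq/yr",     5.89,  0.34,
    "maize", "em_abc",   "Mt CO2-eq/yr",     2.25,  0.12,
    "maize", "ed_n2o",   "Gg N2O/yr",       69.44,  4.26,
    "maize", "total",    "Mt CO2-eq/yr",    80.40,  4.88
  )
  provincial_manufacture <- tibble::tribble(
    ~province,        ~wheat_mean, ~wheat_sd, ~maize_mean, ~maize_sd,
    "Liaoning",       NA,          NA,        3.32,        0.09,
    "Jilin",          NA,          NA,        5.14,        0.10,
    "Heilongjiang",   NA,          NA,        7.94,        0.68,
    "Hebei",          5.01,        0.12,      4.23,        0.22,
    "Shanxi",         1.16,        0.12,      2.65,        0.14,
    "Shandong",       6.65,        0.10,      5.12,        0.29,
    "Henan",          8.74,        0.20,      3.99,        0.06,
    "Inner Mongolia", 1.94,        0.19,      6.35,        0.59,
    "Jiangsu",        4.86,        0.38,      1.02,        0.12,
    "Anhui",          4.14,        0.56,      1.61,        0.20,
    "Hubei",          1.22,        0.01,      1.19,        0.05,
    "Shaanxi",        2.03,        0.20,      2.64,        0.17,
    "Gansu",          1.36,        0.07,      2.64,        0.17,
    "Xinjiang",       2.98,        0.18,      2.49,        0.12,
    "Chongqing",      NA,          NA,        0.75,        0.04,
    "Sichuan",        0.86,        0.26,      2.14,        0.34,
    "Guizhou",        NA,          NA,        1.62,        0.30,
    "Yunnan",         0.49,        0.09,      3.84,        0.36,
    "Guangxi",        NA,          NA,        1.04,        0.06
  )
  provincial_n2o <- tibble::tribble(
    ~province,        ~wheat_mean, ~wheat_sd, ~maize_mean, ~maize_sd,
    "Liaoning",       NA,          NA,        3.38,        0.10,
    "Jilin",          NA,          NA,        5.32,        0.16,
    "Heilongjiang",   NA,          NA,        7.78,        0.66,
    "Hebei",          2.71,        0.07,      5.78,        0.27,
    "Shanxi",         0.63,        0.07,      3.65,        0.20,
    "Shandong",       3.68,        0.05,      7.12,        0.44,
    "Henan",          4.92,        0.10,      5.71,        0.12,
    "Inner Mongolia", 1.01,        0.10,      8.42,        0.78,
    "Jiangsu",        8.32,        0.64,      1.34,        0.14,
    "Anhui",          7.22,        0.96,      2.17,        0.27,
    "Hubei",          2.20,        0.01,      1.63,        0.06,
    "Shaanxi",        1.22,        0.13,      2.96,        0.19,
    "Gansu",          0.82,        0.04,      2.85,        0.18,
    "Xinjiang",       1.74,        0.10,      2.59,        0.12,
    "Chongqing",      NA,          NA,        0.71,        0.04,
    "Sichuan",        0.89,        0.27,      2.06,        0.32,
    "Guizhou",        NA,          NA,        1.50,        0.28,
    "Yunnan",         0.48,        0.09,      3.50,        0.32,
    "Guangxi",        NA,          NA,        0.97,        0.06
  )
  for (tb in c("provincial_manufacture", "provincial_n2o")) {
    t <- get(tb)
    t$region <- resolve_region(t$province)
    assign(tb, t[, c("region", setdiff(names(t), "region"))])
  }
  regional_manufacture <- tibble::tribble(
    ~region, ~crop,   ~mean_mt,
    "NC",    "wheat", 23.49,
    "MLYR",  "wheat", 10.23,
    "NWC",   "wheat",  6.37,
    "SSWC",  "wheat",  1.35,
    "NC",    "maize", 22.34,
    "NEC",   "maize", 16.39,
    "SSWC",  "maize",  9.38,
    "NWC",   "maize",  7.77,
    "MLYR",  "maize",  3.82
  )
  regional_n2o <- tibble::tribble(
    ~region, ~crop,   ~mean_gg,
    "MLYR",  "wheat", 17.73,
    "NC",    "wheat", 12.94,
    "NWC",   "wheat",  3.78,
    "SSWC",  "wheat",  1.37,
    "NC",    "maize", 30.68,
    "NEC",   "maize", 16.48,
    "SSWC",  "maize",  8.74,
    "NWC",   "maize",  8.40,
    "MLYR",  "maize",  5.14
  )
  regional_intensity <- tibble::tribble(
    ~region, ~crop,   ~area_mean, ~area_sd, ~yield_mean, ~yield_sd,
    "NEC",   "maize", 1.78,       0.04,     0.27,        0.01,
    "NC",    "wheat", 2.10,       0.03,     0.35,        0.01,
    "NC",    "maize", 2.04,       0.07,     0.34,        0.02,
    "MLYR",  "wheat", 2.60,       0.07,     0.50,        0.01,
    "MLYR",  "maize", 2.48,       0.10,     0.48,        0.02,
    "NWC",   "wheat", 2.47,       0.03,     0.54,        0.01,
    "NWC",   "maize", 3.26,       0.10,     0.56,        0.02,
    "SSWC",  "wheat", 1.29,       0.06,     0.39,        0.02,
    "SSWC",  "maize", 2.37,       0.03,     0.47,        0.01
  )
  rate_class_fractions <- tibble::tibble(
    crop = c("wheat", "maize"),
    lower = c(200, 150), upper = c(250, 200),
    area_fraction = c(0.425, 0.640)
  )
  list(
    registry = default_ef_registry(),
    national_rates = national_rates,
    national_mean_rate = national_mean_rate,
    national_n_mt = national_n_mt,
    implied_area_ha = implied_area_ha,
    national_activity = national_activity,
    national_components = national_components,
    provincial_manufacture = provincial_manufacture,
    provincial_n2o = provincial_n2o,
    regional_manufacture = regional_manufacture,
    regional_n2o = regional_n2o,
    regional_intensity = regional_intensity,
    national_intensity = national_intensity,
    rate_class_fractions = rate_class_fractions
  )
}
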