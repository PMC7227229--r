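#' Configuration for the synthetic activity-data generator
#'
#' Describes a synthetic provincial activity dataset with the
#' statistical structure of Chinese upland crop statistics: 13 wheat /
#' 19 maize provinces in five agricultural regions, three years,
#' per-product N rates centred on the published national means.
#'
#' Rates are drawn per province from normal distributions truncated at
#' zero (mean = national product mean, relative SD = `rate_cv`), then
#' perturbed each year by a multiplicative factor shared within a
#' province (relative SD = `interannual_cv`). Sown areas follow a
#' log-normal law; per-hectare yields are uniform over
#' `yield_per_ha_range`.
#'
#' @param seed Integer RNG seed; identical seed + config gives an
#'   identical dataset.
#' @param n_years Number of years (default 3, labelled from
#'   `first_year`).
#' @param first_year First calendar year (default 2015).
#' @param crops Character subset of `c("wheat", "maize")`.
#' @param provinces Optional character subset of the default map; by
#'   default each crop uses its full benchmark province set.
#' @param rate_means Named list per crop of named per-product mean N
#'   rates, kg N per ha. Defaults: wheat urea 124, CF 72, DAP 17,
#'   ABC 9; maize 111/62/15/8.
#' @param rate_cv Relative SD of rates across provinces (default 0.25,
#'   a documented guess — cross-province dispersion is not published).
#' @param interannual_cv Relative SD of the yearly multiplicative
#'   perturbation (default 0.05).
#' @param area_mean_ha Named per-crop mean provincial sown area, ha
#'   (defaults sized so national totals land near the published
#'   2.33e7 ha wheat / 3.78e7 ha maize).
#' @param area_sdlog Log-scale SD of the provincial area law
#'   (default 0.6).
#' @param yield_per_ha_range Range of per-hectare grain yield, kg per
#'   ha (default 4000–7500).
#' @param fig1_mode If `TRUE`, provincial areas are reweighted so that
#'   the wheat 200–250 kg N/ha rate class holds 42.5% of wheat area
#'   and the maize 150–200 class holds 64.0% of maize area, matching
#'   the published rate-class distribution.
#' @return A `generator_config` list.
#' @export
generator_config <- function(seed = 1L,
                             n_years = 3L,
                             first_year = 2015L,
                             crops = crop_codes(),
                             provinces = NULL,
                             rate_means = list(
                               wheat = c(urea = 124, cf = 72,
                                         dap = 17, abc = 9),
                               maize = c(urea = 111, cf = 62,
                                         dap = 15, abc = 8)),
                             rate_cv = 0.25,
                             interannual_cv = 0.05,
                             area_mean_ha = c(wheat = 1.8e6,
                                              maize = 2.0e6),
                             area_sdlog = 0.6,
                             yield_per_ha_range = c(4000, 7500),
                             fig1_mode = FALSE) {
  stopifnot(length(seed) == 1, is.finite(seed),
            n_years >= 1, rate_cv >= 0, interannual_cv >= 0,
            area_sdlog >= 0, length(yield_per_ha_range) == 2,
            yield_per_ha_range[1] > 0,
            yield_per_ha_range[2] >= yield_per_ha_range[1])
  if (length(crops) == 0) stop("no crops selected", call. = FALSE)
  crops <- match.arg(crops, crop_codes(), several.ok = TRUE)
  for (cr in crops) {
    rm <- rate_means[[cr]]
    if (is.null(rm) || !all(product_codes() %in% names(rm)) ||
        any(rm < 0)) {
      stop("rate_means$", cr, " must name all four products with ",
           "non-negative means", call. = FALSE)
    }
  }
  if (!is.null(provinces)) {
    provinces <- normalize_province(provinces)
    unknown <- setdiff(provinces, default_region_map()$province)
    if (length(unknown) > 0) {
      stop("unknown province(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    if (length(provinces) == 0) stop("no provinces selected",
                                     call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_years = as.integer(n_years),
         first_year = as.integer(first_year), crops = crops,
         provinces = provinces, rate_means = rate_means,
         rate_cv = rate_cv, interannual_cv = interannual_cv,
         area_mean_ha = area_mean_ha, area_sdlog = area_sdlog,
         yield_per_ha_range = yield_per_ha_range,
         fig1_mode = isTRUE(fig1_mode)),
    class = "generator_config"
  )
}

# published rate-class anchors for figure-1 mode, per crop:
# target fraction of sown area in [lower, upper)
.fig1_targets <- list(
  wheat = list(lower = 200, upper = 250, fraction = 0.425),
  maize = list(lower = 150, upper = 200, fraction = 0.640)
)

#' Generate a synthetic provincial activity dataset
#'
#' One record per (province, crop, year) for the provinces growing
#' that crop. Deterministic given the config (the global RNG state is
#' saved and restored).
#'
#' @param config A [generator_config()].
#' @return Activity tibble in the schema of [validate_activity()]
#'   (with `region` resolved).
#' @export
#' @examples
#' act <- generate_activity(generator_config(seed = 42))
#' dplyr::count(act, crop)
generate_activity <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)
  years <- config$first_year + seq_len(config$n_years) - 1L
  all_prov <- unique(unlist(lapply(config$crops, crop_provinces)))
  if (!is.null(config$provinces)) {
    all_prov <- intersect(all_prov, config$provinces)
  }
  if (length(all_prov) == 0) {
    stop("empty province/crop selection", call. = FALSE)
  }
  # year factors shared within a province (across crops and products)
  yf <- matrix(pmax(stats::rnorm(length(all_prov) * config$n_years, 1,
                                 config$interannual_cv), 0),
               nrow = length(all_prov),
               dimnames = list(all_prov, as.character(years)))
  rows <- list()
  for (cr in config$crops) {
    provs <- intersect(crop_provinces(cr), all_prov)
    if (length(provs) == 0) next
    means <- config$rate_means[[cr]][product_codes()]
    for (pv in provs) {
      base <- pmax(stats::rnorm(4, means, config$rate_cv * means), 0)
      area <- stats::rlnorm(1,
                            log(config$area_mean_ha[[cr]]) -
                              config$area_sdlog^2 / 2,
                            config$area_sdlog)
      ypha <- stats::runif(1, config$yield_per_ha_range[1],
                           config$yield_per_ha_range[2])
      for (yi in seq_along(years)) {
        f <- yf[pv, yi]
        rows[[length(rows) + 1]] <- tibble::tibble(
          province = pv, crop = cr, year = years[yi],
          area_ha = area, yield_kg = area * ypha * f,
          n_urea = base[1] * f, n_cf = base[2] * f,
          n_dap = base[3] * f, n_abc = base[4] * f
        )
      }
    }
  }
  if (length(rows) == 0) stop("empty province/crop selection",
                              call. = FALSE)
  act <- dplyr::bind_rows(rows)
  if (config$fig1_mode) act <- .reweight_fig1(act)
  validate_activity(act)
}

# scale areas of in-target-bin records so the target rate class holds
# its published area fraction (yields scale with area)
.reweight_fig1 <- function(act) {
  for (cr in intersect(crop_codes(), unique(act$crop))) {
    tgt <- .fig1_targets[[cr]]
    sel <- act$crop == cr
    rate <- rowSums(as.matrix(act[sel, .rate_cols]))
    inbin <- rate >= tgt$lower & rate < tgt$upper
    a_in <- sum(act$area_ha[sel][inbin])
    a_out <- sum(act$area_ha[sel][!inbin])
    if (a_in == 0 || a_out == 0) {
      stop("cannot reweight ", cr, ": target rate class [",
           tgt$lower, ",", tgt$upper, ") is empty or exhaustive",
           call. = FALSE)
    }
    s <- tgt$fraction * a_out / ((1 - tgt$fraction) * a_in)
    idx <- which(sel)[inbin]
    act$area_ha[idx] <- act$area_ha[idx] * s
    act$yield_kg[idx] <- act$yield_kg[idx] * s
  }
  act
}
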