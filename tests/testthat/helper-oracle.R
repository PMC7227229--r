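# Independent naive oracle: literal transcription of the four
# inventory equations, row by row, kept deliberately separate from the
# package's vectorised implementation.
naive_record <- function(row, registry) {
  ef_m <- registry$ef_m
  e_m <- c(
    urea = row$n_urea * row$area_ha * ef_m[["urea"]],
    cf   = row$n_cf   * row$area_ha * ef_m[["cf"]],
    dap  = row$n_dap  * row$area_ha * ef_m[["dap"]],
    abc  = row$n_abc  * row$area_ha * ef_m[["abc"]]
  )
  ef_d_tab <- registry$ef_d
  ef_d <- ef_d_tab$ef[ef_d_tab$region == row$region &
                        ef_d_tab$crop == row$crop]
  stopifnot(length(ef_d) == 1)
  nr_total <- row$n_urea + row$n_cf + row$n_dap + row$n_abc
  e_d <- nr_total * row$area_ha * ef_d * (44 / 28)
  total <- sum(e_m) + e_d * registry$gwp_n2o
  list(e_m = e_m, e_d = e_d, total = total,
       area_scaled = total / row$area_ha,
       yield_scaled = if (row$yield_kg > 0) total / row$yield_kg
                      else NA_real_)
}

# random valid activity records over (region, crop) pairs with an EF_D
random_activity <- function(n, seed) {
  set.seed(seed)
  map <- default_region_map()
  rows <- lapply(seq_len(n), function(i) {
    crop <- sample(crop_codes(), 1)
    provs <- crop_provinces(crop)
    tibble::tibble(
      province = sample(provs, 1), crop = crop,
      year = sample(2015:2017, 1),
      area_ha = stats::runif(1, 1e3, 5e6),
      yield_kg = stats::runif(1, 1e6, 1e10),
      n_urea = stats::runif(1, 0, 200), n_cf = stats::runif(1, 0, 120),
      n_dap = stats::runif(1, 0, 40), n_abc = stats::runif(1, 0, 20)
    )
  })
  act <- dplyr::bind_rows(rows)
  act$year <- seq_len(n)  # keep (province, crop, year) keys unique
  validate_activity(act)
}
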