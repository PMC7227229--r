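reg <- default_ef_registry()

one_record <- function(province = "Hebei", crop = "wheat",
                       area = 1, yield = 5000,
                       urea = 0, cf = 0, dap = 0, abc = 0) {
  validate_activity(tibble::tibble(
    province = province, crop = crop, year = 2015,
    area_ha = area, yield_kg = yield,
    n_urea = urea, n_cf = cf, n_dap = dap, n_abc = abc))
}

test_that("manufacture emissions follow rate x area x EF per product", {
  rec <- one_record(area = 1000, urea = 100)
  em <- manufacture_emissions(rec, reg)
  expect_equal(em$em_urea, 100 * 1000 * 8.1) # 810,000 kg
  expect_equal(em$em_cf, 0)
  expect_equal(em$em_total_kg, 810000)
  zero <- manufacture_emissions(one_record(), reg)
  expect_equal(zero$em_total_kg, 0)
})

test_that("direct N2O charges the summed rate with one regional EF", {
  # NC wheat at the published national mean rate, 1 ha
  rec <- one_record(urea = 124, cf = 72, dap = 17, abc = 9)
  ed <- direct_n2o_emissions(rec, reg)
  expect_equal(ed$ed_n2o_kg, 222 * 0.0028 * 44 / 28)
  expect_equal(round(ed$ed_n2o_kg, 4), 0.9768)
  # generic rate/EF check against hand arithmetic
  rec2 <- one_record(province = "Jiangsu", urea = 100)
  expect_equal(direct_n2o_emissions(rec2, reg)$ed_n2o_kg,
               100 * 0.0086 * 44 / 28)
})

test_that("a record in a region without a factor errors at run time", {
  rec <- one_record(province = "Heilongjiang", crop = "wheat")
  expect_error(direct_n2o_emissions(rec, reg), "NEC/wheat")
  expect_error(run_inventory(rec, reg), "NEC/wheat")
})

test_that("CO2-equivalence and intensities satisfy their identities", {
  expect_equal(co2eq_of_n2o(0, reg), 0)
  expect_equal(round(co2eq_of_n2o(35.82e6, reg) / 1e9, 2), 10.67)
  expect_equal(round(co2eq_of_n2o(69.44e6, reg) / 1e9, 2), 20.69)
  # scale invariance of the area intensity
  expect_equal(area_scaled(1e6, 1e3, 50, reg),
               area_scaled(2e6, 2e3, 100, reg))
  expect_equal(yield_scaled(1000, 0, 5000, reg), 0.2)
  expect_equal(yield_scaled(0, 0, 5000, reg), 0)
  expect_error(area_scaled(1, 1, 0, reg), "area")
  # zero yield gives a defined NA, not Inf
  expect_true(is.na(yield_scaled(100, 0, 0, reg)))
  expect_equal(yield_scaled(0, 0, 0, reg), 0)
})

test_that("run_inventory composes the equations consistently", {
  act <- random_activity(25, seed = 11)
  res <- run_inventory(act, reg)
  expect_equal(res$total_co2eq_kg,
               res$em_total_kg + res$ed_n2o_kg * reg$gwp_n2o)
  expect_equal(res$area_scaled_kg_ha * res$area_ha, res$total_co2eq_kg)
  expect_equal(res$yield_scaled_kg_kg * res$yield_kg,
               res$total_co2eq_kg)
  # area_scaled / yield_scaled is yield per hectare
  expect_equal(res$area_scaled_kg_ha / res$yield_scaled_kg_kg,
               res$yield_kg / res$area_ha)
  expect_true(all(as.matrix(res[, c("em_urea", "em_cf", "em_dap",
                                    "em_abc", "ed_n2o_kg")]) >= 0))
})

test_that("the engine is linear in rates and additive over area splits", {
  act <- random_activity(10, seed = 21)
  res <- run_inventory(act, reg)
  k <- 3.7
  scaled <- act
  for (cl in c("n_urea", "n_cf", "n_dap", "n_abc")) {
    scaled[[cl]] <- scaled[[cl]] * k
  }
  res_k <- run_inventory(scaled, reg)
  expect_equal(res_k$em_total_kg, k * res$em_total_kg)
  expect_equal(res_k$ed_n2o_kg, k * res$ed_n2o_kg)
  expect_equal(res_k$total_co2eq_kg, k * res$total_co2eq_kg)

  # splitting a record into two sub-areas with the same rates conserves
  # every extensive emission
  w <- 0.3
  a1 <- act; a1$area_ha <- act$area_ha * w; a1$yield_kg <- act$yield_kg * w
  a2 <- act; a2$area_ha <- act$area_ha * (1 - w)
  a2$yield_kg <- act$yield_kg * (1 - w)
  r1 <- run_inventory(a1, reg); r2 <- run_inventory(a2, reg)
  expect_equal(r1$em_total_kg + r2$em_total_kg, res$em_total_kg)
  expect_equal(r1$ed_n2o_kg + r2$ed_n2o_kg, res$ed_n2o_kg)
  # the intensities of the sub-records are unchanged
  expect_equal(r1$area_scaled_kg_ha, res$area_scaled_kg_ha)
})

test_that("unit rescaling leaves dimensionless intensities unchanged", {
  act <- random_activity(10, seed = 31)
  res <- run_inventory(act, reg)
  # express rates in t N/ha and manufacture EFs per t N: E_M unchanged
  act_t <- act
  for (cl in c("n_urea", "n_cf", "n_dap", "n_abc")) {
    act_t[[cl]] <- act_t[[cl]] / 1e3
  }
  reg_t <- ef_registry(reg$ef_m * 1e3, reg$ef_d, reg$gwp_n2o,
                       reg$n_to_n2o * 1e3)
  res_t <- run_inventory(act_t, reg_t)
  expect_equal(res_t$area_scaled_kg_ha, res$area_scaled_kg_ha)
  expect_equal(res_t$yield_scaled_kg_kg, res$yield_scaled_kg_kg)
})

test_that("vectorised engine matches the naive oracle to 1e-12", {
  act <- random_activity(1000, seed = 99)
  res <- run_inventory(act, reg)
  for (i in seq_len(nrow(act))) {
    o <- naive_record(act[i, ], reg)
    expect_equal(res$em_total_kg[i], sum(o$e_m), tolerance = 1e-12)
    expect_equal(res$ed_n2o_kg[i], o$e_d, tolerance = 1e-12)
    expect_equal(res$total_co2eq_kg[i], o$total, tolerance = 1e-12)
    expect_equal(res$area_scaled_kg_ha[i], o$area_scaled,
                 tolerance = 1e-12)
    expect_equal(res$yield_scaled_kg_kg[i], o$yield_scaled,
                 tolerance = 1e-12)
  }
})
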