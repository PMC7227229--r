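reg <- default_ef_registry()

test_that("interannual mean/sd use the sample convention", {
  expect_equal(mean_sd_over_years(c(10, 10, 10)),
               tibble::tibble(mean = 10, sd = 0, n_years = 3L))
  expect_equal(mean_sd_over_years(c(1, 2, 3))$sd, 1)
  one <- mean_sd_over_years(5)
  expect_equal(one$mean, 5)
  expect_equal(one$sd, 0)
  expect_equal(one$n_years, 1L)
  expect_error(mean_sd_over_years(numeric(0)), "non-empty")
})

test_that("extensive rollups conserve totals across scopes", {
  act <- generate_activity(generator_config(seed = 5))
  res <- run_inventory(act, reg)
  for (cr in crop_codes()) {
    prov <- rollup(res, "province", "em_total", crop = cr)
    regn <- rollup(res, "region", "em_total", crop = cr)
    natl <- rollup(res, "national", "em_total", crop = cr)
    expect_equal(sum(prov$mean), natl$mean)
    expect_equal(sum(regn$mean), natl$mean)
    # single-province regions equal their provincial value
    map <- default_region_map()
    for (rg in unique(regn$group)) {
      in_rg <- prov$group %in% map$province[map$region == rg]
      expect_equal(sum(prov$mean[in_rg]),
                   regn$mean[regn$group == rg])
    }
  }
})

test_that("national SD comes from yearly national totals", {
  act <- generate_activity(generator_config(seed = 5))
  res <- run_inventory(act, reg)
  natl <- rollup(res, "national", "ed_n2o", crop = "wheat")
  yearly <- vapply(split(res$ed_n2o_kg[res$crop == "wheat"],
                         res$year[res$crop == "wheat"]), sum,
                   numeric(1))
  expect_equal(natl$mean, mean(yearly))
  expect_equal(natl$sd, sd(yearly))
  expect_equal(natl$n_years, 3L)
})

test_that("aggregate intensities are pooled, never averaged, and lie
           within the provincial range", {
  act <- generate_activity(generator_config(seed = 8))
  res <- run_inventory(act, reg)
  for (cr in crop_codes()) {
    rr <- res[res$crop == cr, ]
    regn <- rollup(rr, "region", "area_scaled")
    prov <- rollup(rr, "province", "area_scaled")
    map <- default_region_map()
    for (rg in regn$group) {
      sub <- rr[rr$region == rg, ]
      pooled <- vapply(split(sub, sub$year), function(d) {
        sum(d$total_co2eq_kg) / sum(d$area_ha)
      }, numeric(1))
      expect_equal(regn$mean[regn$group == rg], mean(pooled))
      provs_in <- map$province[map$region == rg]
      pv <- prov$mean[prov$group %in% provs_in]
      expect_gte(regn$mean[regn$group == rg], min(pv) - 1e-9)
      expect_lte(regn$mean[regn$group == rg], max(pv) + 1e-9)
    }
  }
})

test_that("rollup refuses mixed crops and empty scopes", {
  act <- generate_activity(generator_config(seed = 5))
  res <- run_inventory(act, reg)
  expect_error(rollup(res, "national", "em_total"), "mix")
  expect_no_error(rollup(res, "national", "em_total", crop = "wheat"))
  expect_error(rollup(res[0, ], "national", "em_total"), "no records")
})

test_that("shares are percentages and sum to 100 over a partition", {
  expect_equal(round(share_of_total(8.74, 41.44), 1), 21.1)
  expect_equal(round(share_of_total(6.65, 41.44), 1), 16.0)
  expect_equal(share_of_total(5, 5), 100)
  expect_error(share_of_total(1, 0), "> 0")
  act <- generate_activity(generator_config(seed = 3))
  res <- run_inventory(act, reg)
  prov <- rollup(res, "province", "total_co2eq", crop = "maize")
  natl <- rollup(res, "national", "total_co2eq", crop = "maize")
  shares <- vapply(prov$mean, share_of_total, numeric(1),
                   whole = natl$mean)
  expect_equal(sum(shares), 100, tolerance = 1e-9)
})

test_that("rate-class binning weights by area with half-open bins", {
  act <- validate_activity(tibble::tibble(
    province = c("Hebei", "Henan"), crop = "wheat", year = 2015,
    area_ha = c(100, 100), yield_kg = 1e6,
    n_urea = c(120, 220), n_cf = 0, n_dap = 0, n_abc = 0))
  fr <- rate_class_area_fractions(act, c(0, 150, 200, 250, Inf))
  expect_equal(fr$area_fraction, c(0.5, 0, 0.5, 0))
  expect_equal(sum(fr$area_fraction), 1)
  one <- rate_class_area_fractions(act[1, ], c(0, 150, 200, 250, Inf))
  expect_equal(one$area_fraction, c(1, 0, 0, 0))
  # boundary value falls in the right-hand (closed-left) bin
  act$n_urea <- c(150, 150)
  fr2 <- rate_class_area_fractions(act, c(0, 150, 200, 250, Inf))
  expect_equal(fr2$area_fraction[2], 1)
  expect_error(
    rate_class_area_fractions(act, c(0, 50, 100)), "outside")
  expect_error(rate_class_area_fractions(act, c(100, 50)),
               "ascending")
})

test_that("report tables have the published shape and reconcile
           with the national rollup", {
  act <- generate_activity(generator_config(seed = 5))
  res <- run_inventory(act, reg)
  rep <- build_report(res)
  expect_named(rep, c("provincial_manufacture", "provincial_n2o",
                      "national_components", "regional_intensity"))
  expect_equal(nrow(rep$provincial_manufacture), 19)
  expect_true(all(c("wheat", "maize") %in%
                    names(rep$provincial_manufacture)))
  # wheat-less provinces render an em-dash
  necs <- rep$provincial_manufacture$region == "NEC"
  expect_true(all(rep$provincial_manufacture$wheat[necs] == "–"))
  expect_match(rep$national_components$wheat[1],
               "^\\d+\\.\\d{2} ± \\d+\\.\\d{2}$")
  # rendered national manufacture total equals the rollup, rounded
  natl <- rollup(res, "national", "em_urea", crop = "wheat")
  expect_equal(rep$national_components$wheat[1],
               format_mean_sd(natl$mean / 1e9, natl$sd / 1e9))
  # empty input still yields headers
  rep0 <- build_report(res[res$crop == "wheat", ])
  expect_false("maize" %in% names(rep0$national_components))
})

test_that("report files are written in both formats", {
  act <- generate_activity(generator_config(seed = 5, crops = "wheat"))
  rep <- build_report(run_inventory(act, reg))
  dir <- withr::local_tempdir()
  paths_csv <- write_report(rep, dir, "csv")
  paths_md <- write_report(rep, dir, "markdown")
  expect_length(c(paths_csv, paths_md), 8)
  expect_true(all(file.exists(c(paths_csv, paths_md))))
  back <- readr::read_csv(file.path(dir, "national_components.csv"),
                          show_col_types = FALSE)
  expect_equal(nrow(back), 6)
})
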