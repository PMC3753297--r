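test_that("single-pool stocks match hand arithmetic and trivial limits", {
  base <- make_test_provinces()[1, ]

  p <- base
  p$area_urban <- 1000; p$green_frac <- 0.31; p$d_green <- 1.5
  expect_equal(vegetation_carbon(p), 0.465) # 1000e6 m2 x 0.31 x 1.5 kg m-2
  p$area_urban <- 1; p$green_frac <- 1; p$d_green <- 1
  expect_equal(vegetation_carbon(p), 0.001)
  p$green_frac <- 0
  expect_equal(vegetation_carbon(p), 0)

  p <- base
  p$area_urban <- 100; p$green_frac <- 0.3; p$d_sgreen <- 8; p$d_simp <- 6
  expect_equal(soil_carbon(p), 0.66) # 100e6 x (0.3*8 + 0.7*6) x 1e-9
  p$green_frac <- 1
  expect_equal(soil_carbon(p), 100e6 * 8 * 1e-9)
  p$green_frac <- 0
  expect_equal(soil_carbon(p), 100e6 * 6 * 1e-9)

  p <- base
  p$pop_urban <- 0
  expect_equal(human_carbon(p), 0)
  p$pop_urban <- 1
  expect_equal(human_carbon(p), 9e-12) # 60 kg x 0.3 x 0.5 = 9 kg C
  p$pop_urban <- 5.77e8
  expect_equal(human_carbon(p), 5.193)

  p <- base
  p$floor_resid <- 0; p$floor_total <- 0; p$n_set <- 0; p$n_household <- 0
  expect_equal(building_carbon(p), 0)
  p$floor_resid <- 1; p$floor_total <- 1
  expect_equal(building_carbon(p), 9e-5) # 1e4 m2 x 0.045 x 0.4 t x 0.5
  p$floor_resid <- 0; p$floor_total <- 0; p$n_set <- 1; p$n_household <- 1
  # 20 x (0.8*0.067 + 0.2*0.026) = 1.176 m3 -> x0.4 t x 0.5 = 0.2352 t C
  expect_equal(building_carbon(p), 0.2352e3 / 1e9)
  bd <- building_carbon(p, breakdown = TRUE)
  expect_equal(bd$c_constru, 0)
  expect_equal(bd$c_furn, bd$c_building)
})

test_that("pool functions reject invalid inputs naming the field", {
  p <- make_test_provinces()
  bad <- p; bad$d_green[2] <- -1
  expect_error(vegetation_carbon(bad), "d_green")
  bad <- p; bad$area_urban[1] <- NaN
  expect_error(soil_carbon(bad), "area_urban")
  bad <- p; bad$pop_urban[3] <- -5
  expect_error(human_carbon(bad), "pop_urban")
  bad <- p; bad$floor_resid[1] <- bad$floor_total[1] + 1
  expect_error(building_carbon(bad), "floor_resid")
  expect_error(validate_provinces(p[, -3]), "area_urban")
  expect_error(validate_provinces(p[0, ]), "empty")
})

test_that("province_pools satisfies additivity, density, and fraction invariants", {
  p <- make_test_provinces()
  pools <- province_pools(p)
  expect_equal(pools$c_total,
               pools$c_veg + pools$c_soil + pools$c_human + pools$c_building,
               tolerance = 1e-12)
  # compositional oracle: total equals the sum of the four single-pool ops
  expect_equal(pools$c_total,
               vegetation_carbon(p) + soil_carbon(p) + human_carbon(p) +
                 building_carbon(p))
  fr <- pools$frac_veg + pools$frac_soil + pools$frac_human +
    pools$frac_building
  expect_equal(fr, rep(1, nrow(p)))
  # density = total / area with kg m-2 from Tg and km2
  expect_equal(pools$density, pools$c_total * 1e9 / (p$area_urban * 1e6))
  # hand oracle agreement
  orc <- oracle_pools(p)
  expect_equal(pools$c_veg, orc$veg)
  expect_equal(pools$c_soil, orc$soil)
  expect_equal(pools$c_human, orc$human)
  expect_equal(pools$c_building, orc$building)
})

test_that("an all-zero-stock province is reported with zero fractions and a flag", {
  p <- make_veg_only_province()
  p$d_green <- 0
  pools <- province_pools(p)
  expect_equal(pools$c_total, 0)
  expect_equal(pools$density, 0)
  expect_true(pools$zero_total)
  expect_equal(pools$frac_veg + pools$frac_soil + pools$frac_human +
                 pools$frac_building, 0)
})

test_that("area scaling is exactly linear for land pools and inert for the rest", {
  p <- make_test_provinces()
  base <- province_pools(p)
  for (lambda in c(0.5, 2, 7.25)) {
    q <- p
    q$area_urban <- p$area_urban * lambda
    scaled <- province_pools(q)
    expect_equal(scaled$c_veg, base$c_veg * lambda)
    expect_equal(scaled$c_soil, base$c_soil * lambda)
    expect_equal(scaled$c_human, base$c_human)
    expect_equal(scaled$c_building, base$c_building)
  }
})

test_that("unit conversions round-trip and Tg/kg paths agree", {
  p <- make_test_provinces()
  x <- province_pools(p)$c_total
  expect_equal(kg_to_tg(tg_to_kg(x)), x, tolerance = 1e-10)
  # computing in kg then converting equals computing in Tg directly
  orc <- oracle_pools(p)
  kg_total <- orc$total * 1e9
  expect_equal(kg_to_tg(kg_total), x, tolerance = 1e-10)
})

test_that("furniture carbon ignores the wood/steel split when volumes per piece are equal", {
  p <- make_test_provinces()
  c1 <- model_constants(f7 = 0.8, f9 = 0.2, f8 = 0.05, f10 = 0.05)
  c2 <- model_constants(f7 = 0.3, f9 = 0.7, f8 = 0.05, f10 = 0.05)
  expect_equal(building_carbon(p, c1), building_carbon(p, c2))
})

test_that("model constants enforce their invariants and allow overrides", {
  cst <- model_constants()
  expect_equal(cst$weight_ave, 60)
  expect_equal(cst$f7 + cst$f9, 1)
  expect_equal(model_constants(beta = 0.3)$beta, 0.3)
  expect_error(model_constants(f7 = 0.9), "f7 \\+ f9")
  expect_error(model_constants(f2 = 1.5), "f2")
  expect_error(model_constants(f4 = -1), "positive")
  expect_error(model_constants(nonsense = 1), "unknown")
  # config-file overrides
  tmp <- tempfile(fileext = ".yaml")
  writeLines(c("f6: 30", "beta: 0.2"), tmp)
  cst2 <- read_constants(tmp)
  expect_equal(cst2$f6, 30)
  expect_equal(cst2$beta, 0.2)
  expect_equal(cst2$f3, 0.045)
})
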