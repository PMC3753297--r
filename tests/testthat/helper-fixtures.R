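# Small deterministic fixtures built in code.

# Two-region, three-province table with round numbers so pool stocks can be
# recomputed by hand in oracles.
make_test_provinces <- function() {
  data.frame(
    province_id = c("A", "B", "C"),
    region = c("East", "East", "West"),
    area_urban = c(1000, 500, 200),
    green_frac = c(0.3, 0.4, 0.2),
    d_green = c(1.5, 2.0, 1.0),
    d_sgreen = c(8, 10, 6),
    d_simp = c(6, 5, 7),
    sd_simp = c(1.5, 1.0, 2.0),
    pop_urban = c(2e7, 1e7, 4e6),
    floor_resid = c(30000, 18000, 6000),
    floor_total = c(50000, 25000, 10000),
    n_set = c(1.0, 1.2, 0.8),
    n_household = c(6e6, 3e6, 1.2e6),
    stringsAsFactors = FALSE
  )
}

# One province whose only nonzero pool is vegetation.
make_veg_only_province <- function() {
  data.frame(
    province_id = "V", region = "East", area_urban = 1000, green_frac = 0.31,
    d_green = 1.5, d_sgreen = 0, d_simp = 0, sd_simp = 0, pop_urban = 0,
    floor_resid = 0, floor_total = 0, n_set = 0, n_household = 0,
    stringsAsFactors = FALSE
  )
}

# Independent arithmetic recomputation of the four pools (kg -> Tg by 1e-9),
# written without calling the package's pool functions.
oracle_pools <- function(p, cst = model_constants()) {
  veg <- p$area_urban * 1e6 * p$green_frac * p$d_green * 1e-9
  imp <- if (is.null(p$impervious_frac)) 1 - p$green_frac else p$impervious_frac
  soil <- p$area_urban * 1e6 *
    (p$green_frac * p$d_sgreen + imp * p$d_simp) * 1e-9
  hum <- p$pop_urban * cst$weight_ave * cst$f1 * cst$f2 * 1e-9
  constru <- (p$floor_resid * cst$f3 +
                (p$floor_total - p$floor_resid) * cst$f5) * 1e4 *
    cst$f4 * 1e3 * cst$f2 * 1e-9
  furn <- p$n_set * p$n_household * cst$f6 *
    (cst$f7 * cst$f8 + cst$f9 * cst$f10) * cst$f4 * 1e3 * cst$f2 * 1e-9
  list(veg = veg, soil = soil, human = hum, constru = constru, furn = furn,
       building = constru + furn,
       total = veg + soil + hum + constru + furn)
}
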