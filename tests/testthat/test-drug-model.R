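test_that("bosentan metabolism combines saturable and linear paths", {
  expect_equal(bosentan_metabolism(0, 10, 5, 0.2), 0)
  # CL = 0 reduces to Michaelis-Menten with half saturation at Km
  expect_equal(bosentan_metabolism(5, 10, 5, 0), 5)
  # 10*5/10 + 0.2*5 = 6
  expect_equal(bosentan_metabolism(5, 10, 5, 0.2), 6)
  expect_error(bosentan_metabolism(-1, 10, 5, 0.2), "domain error")
})

test_that("microsomal scaling follows the 32 mg/g and 99e6 cells/g factors", {
  phys <- default_parameters()$physiology
  sc <- scale_microsomal_parameters(1, 0, phys, WL = 1400)
  expect_equal(sc$Vmax, 1 * 32 * 1400 * 60)  # 2.688e6 µmol/h
  expect_equal(sc$CL, 0)
  expect_equal(scale_microsomal_parameters(0, 1, phys, 1400)$CL, 99 * 1400)
  # liver-weight linearity
  sc2 <- scale_microsomal_parameters(1, 1, phys, WL = 2800)
  expect_equal(sc2$Vmax, 2 * sc$Vmax)
  expect_error(scale_microsomal_parameters(-1, 0, phys, 1400), "domain error")
})

test_that("non-competitive inhibition reduces to and modulates Eq.-1 efflux", {
  # zero inhibitors: exact reduction
  expect_identical(inhibited_bsep_efflux(40, 0, 0, 100, 10, 12, 8.5),
                   bsep_efflux(40, 100, 10))
  # inhibitor at its Ki halves the apparent Vmax: 100/2 * 40/50 = 40
  expect_equal(inhibited_bsep_efflux(40, 12, 0, 100, 10, 12, 8.5), 40)
  # strictly decreasing in each inhibitor concentration
  e_bos <- vapply(c(0, 2, 5, 12, 30), function(cb)
    inhibited_bsep_efflux(40, cb, 0, 100, 10, 12, 8.5), numeric(1))
  e_ro <- vapply(c(0, 2, 5, 12, 30), function(cm)
    inhibited_bsep_efflux(40, 0, cm, 100, 10, 12, 8.5), numeric(1))
  expect_true(all(diff(e_bos) < 0))
  expect_true(all(diff(e_ro) < 0))
  expect_error(inhibited_bsep_efflux(40, -1, 0, 100, 10, 12, 8.5),
               "domain error")
})

test_that("drug dose accounting closes at all times", {
  ps <- ref_ps()
  tr <- simulate_drug(ps, days = 2, dt_out = 0.02, rtol = 1e-6, atol = 1e-8)
  dosed <- attr(tr, "dose_total_umol")
  # total over depot + body + sinks must step up by Fa x dose at each dose
  tot <- rowSums(tr$amounts)
  per_dose <- mg_to_umol(ps$drug$ODOSEmg, ps$physchem$bosentan$MW) * ps$drug$Fa
  n_doses_by_t <- vapply(tr$time, function(t)
    sum(bapbk:::build_event_schedule(2, numeric(0), c(8, 20), 1)$time <= t),
    numeric(1))
  expect_lt(max(abs(tot - per_dose * n_doses_by_t)), 1e-6 * dosed)
})

test_that("zero dose yields an all-zero drug trajectory", {
  tr <- simulate_drug(ref_ps(), days = 1, dose_mg = 0, dt_out = 0.1)
  expect_true(all(tr$amounts == 0))
})

test_that("twice-daily dosing reaches a stable repeating pattern by day 3", {
  tr <- simulate_drug(ref_ps(), days = 4, dt_out = 0.02, rtol = 1e-6,
                      atol = 1e-8)
  for (s in c("plasma_bosentan", "plasma_ro")) {
    c3 <- extract_cmax(tr, s, window = c(48, 72))$cmax
    c4 <- extract_cmax(tr, s, window = c(72, 96))$cmax
    expect_lt(abs(c4 - c3) / c3, 0.01)
  }
})

test_that("metabolite Tmax lags the parent", {
  tr <- simulate_drug(ref_ps(), days = 1, dt_out = 0.02, rtol = 1e-6,
                      atol = 1e-8)
  tp <- extract_cmax(tr, "plasma_bosentan", window = c(8, 20))$tmax
  tm <- extract_cmax(tr, "plasma_ro", window = c(8, 20))$tmax
  expect_gt(tm, tp)
})

test_that("bosentan plasma Cmax scales linearly with dose in the linear regime", {
  ps <- ref_ps()
  cm <- vapply(c(1, 2), function(mg)
    extract_cmax(simulate_drug(ps, days = 1, dose_mg = mg, dt_out = 0.05,
                               rtol = 1e-8, atol = 1e-12),
                 "plasma_bosentan")$cmax, numeric(1))
  expect_equal(cm[2] / cm[1], 2, tolerance = 1e-3)
})

test_that("Ki -> Inf reproduces the uninhibited bile-acid trajectory", {
  ps <- ref_ps("drug.Ki_bosentan" = 1e12, "drug.Ki_ro" = 1e12)
  coupled <- quick_coupled(ps, days = 1)
  control <- quick_ba(ref_ps(), days = 1)
  expect_equal(coupled$amounts[, bapbk:::.ba_states],
               control$amounts, tolerance = 1e-6)
})

test_that("inhibition can only raise plasma bile-acid levels", {
  for (s in c(0.5, 1.5)) {
    dosed <- extract_cmax(quick_coupled(days = 2, sens = s), "plasma")$cmax
    ctrl <- extract_cmax(quick_ba(days = 2, sens = s), "plasma")$cmax
    expect_gte(dosed, ctrl)
  }
  # and at a low BSEP abundance as well
  ps <- ref_ps("ba.aBSEP" = 0.6)
  expect_gte(extract_cmax(quick_coupled(ps, days = 2), "plasma")$cmax,
             extract_cmax(quick_ba(ps, days = 2), "plasma")$cmax)
})

test_that("drug_rhs matches the compiled drug model", {
  ps <- ref_ps()
  tr <- simulate_drug(ps, days = 1, dt_out = 0.25, rtol = 1e-8, atol = 1e-10)
  i <- which(abs(tr$time - 10) < 1e-9)
  y <- tr$amounts[i, ]
  d <- drug_rhs(y, ps)
  # finite-difference check against the trajectory itself
  ynext <- tr$amounts[i + 1, ]
  fd <- (ynext - y) / 0.25
  expect_equal(unname(d[c("bos_blood", "ro_blood")]),
               unname(fd[c("bos_blood", "ro_blood")]), tolerance = 0.05)
  # conservation: derivatives sum to zero after absorption bookkeeping
  expect_equal(sum(d), 0, tolerance = 1e-10)
})
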