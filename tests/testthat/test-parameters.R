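test_that("empty configuration yields the full reference individual", {
  ps <- load_parameter_set(NULL)
  expect_s3_class(ps, "ba_parameter_set")
  expect_equal(total_pool_size(ps), 3079)
  expect_equal(ps$ba$synthesis, 46.8)
  expect_equal(ps$ba$fecal_excretion, 46.8)
  expect_equal(ps$ba$CBfs, 2.4)
  expect_equal(ps$physchem$ba$BP, 0.55)
  # liver weight rule: 20 g per kg body weight
  expect_equal(derived_physiology(ps)$WL, 20 * ps$physiology$BW)
})

test_that("configuration overrides propagate to derived quantities", {
  ps <- load_parameter_set(list(physiology = list(BW = 80)))
  expect_equal(derived_physiology(ps)$WL, 1600)
  # pool is re-targeted to 3079 under the new blood volume
  expect_equal(total_pool_size(ps), 3079)
  # JSON string route
  ps2 <- load_parameter_set('{"physiology": {"BW": 80}}')
  expect_equal(ps2$physiology$BW, 80)
})

test_that("invalid configurations raise named errors", {
  expect_error(load_parameter_set(list(physchem = list(ba = list(fu = 0)))),
               "physchem.ba.fu")
  expect_error(load_parameter_set(list(ba = list(nonsense_key = 1))),
               "unknown key 'ba.nonsense_key'")
  expect_error(load_parameter_set(list(ba = list(QIb = 1.2))), "ba.QIb")
  expect_error(load_parameter_set(list(ba = list(Km_BSEP = -1))), "Km_BSEP")
  expect_error(load_parameter_set(list(schedule = list(meal_times = c(25)))),
               "meal_times")
  # fecal excretion must track synthesis if both are supplied inconsistently
  expect_error(load_parameter_set(list(ba = list(synthesis = 50,
                                                 fecal_excretion = 40))),
               "fecal_excretion")
})

test_that("sens scaling multiplies exactly the pool-determining parameters", {
  ps <- default_parameters()
  s1 <- apply_sens_scaling(ps, 1)
  expect_equal(s1, ps)

  s15 <- apply_sens_scaling(ps, 1.5)
  expect_equal(round_half_up(total_pool_size(s15)), 4619)
  s05 <- apply_sens_scaling(ps, 0.5)
  expect_equal(round_half_up(total_pool_size(s05)), 1540)

  for (f in c("Gdose", "CBfs", "synthesis", "fecal_excretion"))
    expect_equal(s15$ba[[f]], 1.5 * ps$ba[[f]])
  # everything else untouched
  s15$ba[c("Gdose", "CBfs", "synthesis", "fecal_excretion")] <-
    ps$ba[c("Gdose", "CBfs", "synthesis", "fecal_excretion")]
  s15$sens <- 1
  expect_equal(s15, ps)

  expect_error(apply_sens_scaling(ps, 0), "domain error")
  expect_error(apply_sens_scaling(ps, -1), "domain error")
})

test_that("sens scaling is multiplicative and keeps fecal tied to synthesis", {
  ps <- default_parameters()
  ab <- apply_sens_scaling(apply_sens_scaling(ps, 0.7), 1.3)
  once <- apply_sens_scaling(ps, 0.7 * 1.3)
  expect_equal(ab$ba, once$ba, tolerance = 1e-12)
  for (s in c(0.25, 1, 3.7)) {
    psi <- apply_sens_scaling(ps, s)
    expect_identical(psi$ba$fecal_excretion, psi$ba$synthesis)
  }
})

test_that("serialization round-trips bit-identically", {
  ps <- default_parameters()
  tmp <- withr::local_tempfile(fileext = ".json")
  write_parameter_set(ps, tmp)
  ps2 <- load_parameter_set(tmp)
  expect_identical(unclass(ps2), unclass(ps))
})

test_that("unit helpers behave", {
  expect_equal(mg_to_umol(500, 551.6), 500 / 551.6 * 1000)
  expect_error(mg_to_umol(10, 0), "positive")
  # half-up decimal rounding (base round() would give 4618 here)
  expect_equal(round_half_up(4618.5), 4619)
  expect_equal(round_half_up(1539.5), 1540)
  expect_equal(round_half_up(0.25, 1), 0.3)
  expect_equal(round_half_up(-0.25, 1), -0.3)
})

test_that("the shipped reference config is the package default", {
  path <- system.file("extdata", "reference_config.json", package = "bapbk")
  expect_true(nzchar(path))
  expect_identical(unclass(load_parameter_set(path)),
                   unclass(default_parameters()))
})
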