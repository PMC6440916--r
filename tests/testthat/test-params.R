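test_that("default parameters carry the tabulated values and derived extremes", {
  p <- base_params
  expect_s3_class(p, "ptg_params")
  expect_no_error(validate_parameters(p))

  expect_equal(p$gland$A, 0.12)        # maximal release, pmol/min
  expect_equal(p$gland$B, 0.001)
  expect_equal(p$gland$s_r, 1.1881)    # set-point, mmol/L
  expect_equal(p$gland$m, 50)
  expect_equal(p$gland$k_cl, 0.632)
  expect_equal(p$gland$k_sq, 2e-3)
  expect_equal(p$gland$k_qs, 5e-4)
  expect_equal(p$gland$k_a, 1e-3)

  # derived pathway extremes: half basal for degradation, twice basal else
  expect_equal(p$pathways$degradation$A, 0.012)
  expect_equal(p$pathways$degradation$B, 0.006)
  expect_equal(p$pathways$production$B, 2 * p$pathways$production$A)
  expect_equal(p$pathways$proliferation$B, 2 * p$pathways$proliferation$A)

  # any deviation from the literal table must be documented
  expect_gt(length(p$reconciliation_notes), 0)
})

test_that("calcium unit conversion follows the 4.008 mg/dL per mmol/L factor", {
  expect_identical(ca_mgdl_to_mmol(0), 0)
  expect_equal(ca_mgdl_to_mmol(4.008), 1)
  expect_equal(ca_mgdl_to_mmol(5), 5 / 4.008)
  expect_error(ca_mgdl_to_mmol(-1), "non-negative")
})

test_that("configuration loading overrides defaults and rejects bad input", {
  expect_equal(load_parameters(list()), base_params)

  halved <- load_parameters(list(gland.k_cl = 0.316))
  expect_equal(halved$gland$k_cl, 0.316)
  halved$gland$k_cl <- base_params$gland$k_cl
  expect_equal(halved, base_params)

  # nested maps are equivalent to dotted keys
  nested <- load_parameters(list(gland = list(k_cl = 0.316)))
  expect_equal(nested$gland$k_cl, 0.316)

  expect_error(load_parameters(list(gland.k_zz = 1)), "unknown parameter key")
  expect_error(load_parameters(list(gland.m = -1)), "positive")
  expect_error(load_parameters(list(gland.a_s = 1.5)), "a_s")
})

test_that("overriding a basal pathway rate re-derives its extreme", {
  p <- update_parameters(base_params, pathways.production.A = 100)
  expect_equal(p$pathways$production$B, 200)
  p <- update_parameters(base_params, pathways.degradation.A = 0.02)
  expect_equal(p$pathways$degradation$B, 0.01)
})

test_that("parameters round-trip through the YAML configuration", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_parameters(base_params, path)
  reread <- load_parameters(path)
  expect_equal(reread, base_params)

  # and survive a non-default value
  p2 <- update_parameters(base_params, gland.k_cl = 0.316,
                          pathways.production.p = 50)
  write_parameters(p2, path)
  expect_equal(load_parameters(path), p2)
})

test_that("JSON export records the full parameter set with provenance notes", {
  path <- withr::local_tempfile(fileext = ".json")
  write_parameters_json(base_params, path)
  j <- jsonlite::read_json(path)
  expect_equal(j$gland$s_r, 1.1881)
  expect_true(length(j$reconciliation_notes) >= 1)
})
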