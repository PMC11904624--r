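test_that("permeability correlations evaluate their closed forms exactly", {
  # direct evaluation at the reference porosity 0.61
  expect_equal(predict_KL(0.61), exp(4.719 * log(0.61) + 0.61 + 5.097))
  expect_lt(abs(predict_KL(0.61) - 29.2), 0.05)
  expect_equal(predict_KT(0.61), exp(5.567 * log(0.61) + 0.61 + 4.239))
  expect_lt(abs(predict_KT(0.61) - 8.1), 0.06)
  # byte-match against independent re-evaluation on a dense grid
  phi <- seq(0.001, 0.999, length.out = 1000)
  expect_identical(predict_KL(phi), exp(4.719 * log(phi) + phi + 5.097))
  expect_identical(predict_KT(phi), exp(5.567 * log(phi) + phi + 4.239))
  # domain errors
  expect_error(predict_KL(0), "strictly")
  expect_error(predict_KL(1), "strictly")
  expect_error(predict_KT(-0.1), "strictly")
})

test_that("longitudinal exceeds transverse permeability across tissue porosities", {
  phi <- seq(0.301, 0.799, length.out = 200)
  expect_true(all(predict_KL(phi) > predict_KT(phi)))
})

test_that("the modulus quadratic is anchored at 1 and decays with porosity", {
  expect_identical(predict_En(0), 1)
  expect_equal(predict_En(0.5), 0.75625)
  phi <- seq(0, 1, length.out = 1000)
  expect_identical(predict_En(phi), 1 - 1.1456 * phi^2 + 0.0853 * phi)
  # strictly decreasing beyond the quadratic's vertex at phi = 0.03723
  dec <- seq(0.2, 1, length.out = 300)
  expect_true(all(diff(predict_En(dec)) < 0))
  # clamped variant never goes negative (the raw fit dips below 0 near 1)
  expect_lt(predict_En(1), 0)
  expect_gte(min(predict_En(seq(0, 1, 0.01), clamp = TRUE)), 0)
  expect_error(predict_En(1.01), "\\[0, 1\\]")
})

test_that("permeability reduction ratio matches its definition", {
  expect_equal(permeability_reduction(10, 10), 0)
  expect_equal(permeability_reduction(10, 0), 1)
  expect_equal(permeability_reduction(14.97, 7.485), 0.5)
  expect_error(permeability_reduction(0, 1), "positive")
  expect_error(permeability_reduction(1, -1), "non-negative")
})

test_that("CT-to-porosity mapping is linear, clipped and mask-aware", {
  cal <- list(ct = c(0, 255), porosity = c(1, 0))
  img <- matrix(c(0, 127.5, 255, 300), 2)
  pm <- porosity_from_ct(img, cal)
  expect_equal(pm$porosity[1, 1], 1)
  expect_equal(pm$porosity[2, 1], 0.5)
  expect_equal(pm$porosity[1, 2], 0)
  expect_equal(pm$porosity[2, 2], 0) # extrapolation clipped at 0
  # clipping at the upper end
  cal2 <- list(ct = c(0, 100), porosity = c(0, 1))
  expect_equal(porosity_from_ct(matrix(120), cal2)$porosity[1, 1], 1)
  # masking propagates as missing
  pm2 <- porosity_from_ct(img, cal, mask = matrix(TRUE, 2, 2))
  expect_true(all(is.na(pm2$porosity)))
  expect_error(porosity_from_ct(img, list(ct = c(5, 5), porosity = c(0, 1))),
               "distinct")
})

test_that("property maps apply the correlations element-wise with missingness", {
  pm <- porosity_from_ct(matrix(0.61 * 100, 3, 3),
                         list(ct = c(0, 100), porosity = c(0, 1)))
  maps <- property_maps(pm)
  expect_true(all(abs(maps$KL - predict_KL(0.61)) < 1e-12))
  expect_true(all(abs(maps$KT - predict_KT(0.61)) < 1e-12))
  expect_true(all(abs(maps$En - predict_En(0.61)) < 1e-12))
  # a masked pixel is missing everywhere; phi = 0 is missing only in K maps
  img <- matrix(c(50, 0), 1)
  pm2 <- porosity_from_ct(img, list(ct = c(0, 100), porosity = c(0, 1)),
                          mask = matrix(c(TRUE, FALSE), 1))
  maps2 <- property_maps(pm2)
  expect_true(is.na(maps2$KL[1, 1]) && is.na(maps2$En[1, 1]))
  expect_true(is.na(maps2$KL[1, 2]))  # phi = 0 outside the K domain
  expect_equal(maps2$En[1, 2], 1)     # but modulus is defined there
  # monotonicity: more porous pixels are more permeable and less stiff
  pm3 <- porosity_from_ct(matrix(c(30, 60), 1),
                          list(ct = c(0, 100), porosity = c(0, 1)))
  maps3 <- property_maps(pm3)
  expect_gt(maps3$KL[1, 2], maps3$KL[1, 1])
  expect_lt(maps3$En[1, 2], maps3$En[1, 1])
})

test_that("refitting utilities recover coefficients of synthetic data", {
  phi <- withr::with_seed(4, runif(200, 0.35, 0.8))
  K <- withr::with_seed(5, exp(4.719 * log(phi) + phi + 5.097) *
                          exp(rnorm(200, 0, 0.05)))
  fit <- fit_permeability_correlation(data.frame(phi = phi, K = K))
  expect_lt(abs(fit$coef[["a"]] - 4.719), 0.15)
  expect_lt(abs(fit$coef[["c"]] - 5.097), 0.15)
  expect_rel_error_lt(predict(fit, 0.61), predict_KL(0.61), 0.05)
  En <- withr::with_seed(6, 1 - 1.1456 * phi^2 + 0.0853 * phi +
                           rnorm(200, 0, 0.01))
  fit2 <- fit_modulus_correlation(data.frame(phi = phi, En = En))
  expect_lt(abs(fit2$coef[["b2"]] + 1.1456), 0.1)
  td <- tidy(fit2)
  expect_true(all(c("term", "estimate", "p.value") %in% names(td)))
  gl <- glance(fit)
  expect_gt(gl$r.squared, 0.9)
})
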