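test_that("virtual patients anchor on the study means and stay valid", {
  anchor <- meanPhysiology()
  p0 <- makeVirtualPatient(seed = 1, variation_cv = 0)
  expect_equal(p0$volume, anchor$volume)
  # independently drawn flows equal the means; the two dependent flows are
  # rebuilt so the balances close exactly
  indep <- setdiff(names(anchor$flow), c("lung", "liver_total"))
  expect_equal(p0$flow[indep], anchor$flow[indep])
  expect_equal(unname(p0$flow["liver_total"]),
               unname(p0$flow["liver_artery"] +
                        sum(p0$flow[c("spleen", "pancreas", "stomach",
                                      "small_intestine", "large_intestine")])))
  expect_error(makeVirtualPatient(weight = 20), "implausible weight")
  expect_error(makeVirtualPatient(height = 230), "implausible height")

  set.seed(2)
  kidney <- replicate(100, makeVirtualPatient()$volume[["kidney"]])
  cv <- sd(kidney) / mean(kidney)
  expect_gt(cv, 0.10)
  expect_lt(cv, 0.20)
})

test_that("truth draws are strictly interior to the bounds", {
  b <- defaultBounds()
  lo <- b$lower * (b$upper / b$lower)^0.1
  hi <- b$upper * (b$lower / b$upper)^0.1
  set.seed(3)
  for (i in 1:200) {
    th <- as.numeric(makeTruthParameters(b))
    expect_true(all(th >= lo - 1e-12))
    expect_true(all(th <= hi + 1e-12))
  }
  expect_identical(as.numeric(makeTruthParameters(seed = 9)),
                   as.numeric(makeTruthParameters(seed = 9)))
})

test_that("forward objectives reproduce the simulator and carry calibrated noise", {
  p <- makeVirtualPatient(seed = 4, variation_cv = 0)
  truth <- makeTruthParameters(seed = 5)
  clean <- forwardObjectives(p, truth, noise_cv = 0)
  direct <- computeObservables(simulatePBPK(p, truth))
  expect_equal(ssr(clean, direct), 0)
  # noiseless recoveries cannot exceed the administered dose
  expect_lte(sum(clean[1:9]), 100)

  set.seed(6)
  noisy <- replicate(200, clean *
    exp(rnorm(13, -log(1 + 0.1^2) / 2, sqrt(log(1 + 0.1^2)))))
  percv <- apply(noisy, 1, sd) / rowMeans(noisy)
  expect_true(all(percv > 0.07 & percv < 0.13))
  # the exported path applies exactly that noise model
  o1 <- forwardObjectives(p, truth, noise_cv = 0.1, seed = 7)
  o2 <- forwardObjectives(p, truth, noise_cv = 0.1, seed = 7)
  expect_identical(o1, o2)
  expect_false(identical(unname(o1), unname(clean)))
})

test_that("synthetic studies are reproducible and pass input validation", {
  st <- makeSyntheticStudy(n_patients = 2, noise_cv = 0.05, seed = 21)
  st2 <- makeSyntheticStudy(n_patients = 2, noise_cv = 0.05, seed = 21)
  expect_equal(st$inputs$objectives, st2$inputs$objectives)
  expect_s3_class(st$inputs, "study_inputs")
  for (tr in st$truth) {
    expect_true(all(as.numeric(tr) > st$inputs$bounds$lower))
    expect_true(all(as.numeric(tr) < st$inputs$bounds$upper))
  }
})
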