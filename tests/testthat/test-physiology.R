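test_that("printed demographics reproduce BMI and flow closure", {
  pats <- studyPatients()
  expect_length(pats, 7L)
  expect_equal(round(bmi(pats[[1]]), 1), 37.1)
  expect_equal(round(bmi(pats[[6]]), 1), 18.4)
  expect_equal(round(vapply(pats, bmi, 0), 1),
               c(patient_1 = 37.1, patient_2 = 31.0, patient_3 = 23.7,
                 patient_4 = 29.5, patient_5 = 30.2, patient_6 = 18.4,
                 patient_7 = 23.4))
  # patient 1: hepatic artery + splanchnic flows close on the printed total
  p1 <- pats[[1]]
  splanchnic <- sum(p1$flow[c("spleen", "pancreas", "stomach",
                              "small_intestine", "large_intestine")])
  expect_equal(unname(p1$flow["liver_artery"] + splanchnic), 14.9)
  expect_equal(unname(p1$flow["liver_total"]), 14.9)
  expect_equal(portalFlow(p1), 14.9 - 3.8)
})

test_that("every packaged patient satisfies the physiology invariants", {
  for (p in studyPatients()) {
    expect_true(all(p$volume > 0))
    expect_true(all(p$flow > 0))
    expect_lt(p$flow["liver_artery"], p$flow["liver_total"])
    venous <- sum(p$flow[c("heart", "brain", "muscle", "adipose", "skin",
                           "bone", "kidney", "liver_total")])
    expect_lt(abs(p$flow["lung"] - venous), 1.0)
  }
})

test_that("validation rejects broken records with a named organ", {
  p1 <- studyPatients()[[1]]
  rec <- list(patient_id = "x", sex = "M", age = 60, height = 170,
              weight = 70, dose = 1000, infusion_duration = 90,
              volume = p1$volume, flow = p1$flow)
  bad <- rec; bad$flow["kidney"] <- 0
  expect_error(buildPhysiology(bad), "kidney")
  bad <- rec; bad$volume <- bad$volume[-3]
  expect_error(buildPhysiology(bad), "missing organ volume")
  bad <- rec; bad$flow["liver_artery"] <- bad$flow["liver_total"] + 1
  expect_error(buildPhysiology(bad), "hepatic artery")
  bad <- rec; bad$flow["lung"] <- 99
  expect_error(buildPhysiology(bad), "flow balance")
  expect_s3_class(buildPhysiology(rec), "patient_physiology")
})
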