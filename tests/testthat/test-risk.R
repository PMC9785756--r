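test_that("unit conversion is exact and round-trips losslessly", {
  expect_equal(to_mg_per_L(1000, "ng/L"), 0.001)
  expect_equal(to_mg_per_L(2.5, "ug/L"), 0.0025)
  expect_equal(to_mg_per_L(3, "mg/L"), 3)
  expect_equal(to_mg_per_L(1.7, "µg/L"), 0.0017)  # micro sign
  set.seed(2)
  v <- 10^runif(20, -3, 3)
  expect_equal(to_mg_per_L(v, "ng/L") / 1e-6, v, tolerance = 1e-12)
  expect_error(to_mg_per_L(1, "ppm"), "unrecognised")
})

test_that("PNEC divides the EC50 by the assessment factor", {
  expect_equal(pnec(0.612), 0.000612)
  expect_equal(pnec(0.056), 5.6e-5)
  expect_equal(pnec(3.2, assessment_factor = 1), 3.2)
  expect_error(pnec(-1), "> 0")
  expect_error(pnec(1, assessment_factor = 0), "> 0")
})

test_that("risk grades step exactly at 0.01, 0.1 and 1 with closed-left
           boundaries", {
  expect_equal(classify_risk(0.005), "insignificant")
  expect_equal(classify_risk(0.01), "low")
  expect_equal(classify_risk(0.1), "medium")
  expect_equal(classify_risk(1), "high")
  expect_equal(classify_risk(0), "insignificant")
  expect_error(classify_risk(-0.1), ">= 0")

  # dense-grid step-function property: grade changes only at the three
  # breakpoints
  grid <- sort(c(10^seq(-4, 2, length.out = 400), 0.01, 0.1, 1))
  g <- classify_risk(grid)
  changes <- grid[which(g[-1] != g[-length(g)]) + 1]
  expect_equal(changes, c(0.01, 0.1, 1))
})

test_that("intrinsic toxicity bands follow the directive with
           closed-left boundaries", {
  expect_equal(classify_toxicity(0.612), "very_toxic")
  expect_equal(classify_toxicity(3.235), "toxic")
  expect_equal(classify_toxicity(0.056), "very_toxic")
  expect_equal(classify_toxicity(1), "toxic")
  expect_equal(classify_toxicity(10), "harmful")
  expect_equal(classify_toxicity(100), "harmful")
  expect_equal(classify_toxicity(101), "unclassified_low_concern")
  expect_error(classify_toxicity(0), "> 0")
})

test_that("MEC/PNEC quotients are additive, permutation-invariant and
           dominate every component", {
  tox <- data.frame(compound_id = c("SMX", "X"),
                    trophic_level = "algae",
                    ec50_mg_L = c(0.612, 1))
  expo <- data.frame(compound_id = "SMX", mec = 0.5, mec_unit = "ug/L")
  res <- rq_mec_pnec(expo, tox)
  expect_equal(res$rq, 0.0005 / 0.000612)  # 0.8169..., hand arithmetic
  expect_equal(res$grade, "medium")

  zero <- rq_mec_pnec(data.frame(compound_id = "SMX", mec = 0,
                                 mec_unit = "ng/L"), tox)
  expect_equal(zero$rq, 0)
  expect_equal(zero$grade, "insignificant")

  # additivity contract: components with RQ 0.8169... and 0.5
  expo2 <- data.frame(compound_id = c("SMX", "X"),
                      mec = c(0.5, 0.5), mec_unit = "ug/L")
  res2 <- rq_mec_pnec(expo2, tox)
  expect_equal(res2$rq, 0.0005 / 0.000612 + 0.5)
  expect_equal(res2$grade, "high")
  expect_gte(res2$rq, max(res2$per_compound$rq))
  expect_equal(res2$driver, "SMX")

  flipped <- rq_mec_pnec(expo2[2:1, ], tox)
  expect_equal(flipped$rq, res2$rq)

  expect_error(rq_mec_pnec(data.frame(compound_id = "Y", mec = 1,
                                      mec_unit = "ug/L"), tox),
               "Y")
  expect_error(rq_mec_pnec(data.frame(compound_id = "SMX", mec = 1,
                                      mec_unit = "ppb"), tox),
               "unrecognised")
})

test_that("toxic-unit summation takes the worst trophic level and
           reduces to MEC/PNEC for algae-only data", {
  tox <- data.frame(
    compound_id = rep(c("A", "B"), 3),
    trophic_level = rep(c("algae", "daphnia", "fish"), each = 2),
    ec50_mg_L = c(0.612, 3.235, 10, 20, 50, 100))
  expo <- data.frame(compound_id = c("A", "B"), mec = c(0.001, 0.002),
                     mec_unit = "mg/L")
  res <- rq_stu(expo, tox)
  stu_algae <- 0.001 / 0.612 + 0.002 / 3.235   # spreadsheet arithmetic
  expect_equal(res$rq, stu_algae * 1000)
  expect_equal(round(res$rq, 3), 2.252)
  expect_equal(res$grade, "high")
  expect_equal(res$driver, "algae")

  # single compound, algae only: identical to MEC/PNEC with the same AF
  tox1 <- data.frame(compound_id = "A", trophic_level = "algae",
                     ec50_mg_L = 0.612)
  expo1 <- data.frame(compound_id = "A", mec = 0.5, mec_unit = "ug/L")
  expect_equal(rq_stu(expo1, tox1)$rq, rq_mec_pnec(expo1, tox1)$rq)

  expo0 <- data.frame(compound_id = c("A", "B"), mec = 0,
                      mec_unit = "ng/L")
  expect_equal(rq_stu(expo0, tox)$rq, 0)

  # partial coverage is skipped with a warning, never partially summed
  tox_partial <- tox[-4, ]  # drop daphnia EC50 of B
  expect_warning(res_p <- rq_stu(expo, tox_partial), "daphnia")
  expect_equal(res_p$rq, res$rq)  # algae still drives

  expect_error(
    suppressWarnings(rq_stu(expo, tox_partial[tox_partial$trophic_level ==
                                              "daphnia", , drop = FALSE])),
    "coverage")
})

test_that("RQ_STU is monotone in exposures and toxicities", {
  tox <- data.frame(compound_id = c("A", "B"), trophic_level = "algae",
                    ec50_mg_L = c(1, 2))
  expo <- data.frame(compound_id = c("A", "B"), mec = c(1, 1),
                     mec_unit = "ug/L")
  base <- rq_stu(expo, tox)$rq
  expo_up <- transform(expo, mec = mec * c(2, 1))
  expect_gt(rq_stu(expo_up, tox)$rq, base)
  tox_up <- transform(tox, ec50_mg_L = ec50_mg_L * c(2, 1))
  expect_lt(rq_stu(expo, tox_up)$rq, base)
})

test_that("the packaged demonstration fixture matches the hand-computed
           spreadsheet oracle exactly", {
  expo <- read.csv(system.file("extdata", "exposures_synthetic.csv",
                               package = "toxmix"))
  tox <- read.csv(system.file("extdata", "toxicity_synthetic.csv",
                              package = "toxmix"))
  sw <- expo[expo$environment == "surface_water", ]

  # spreadsheet oracle: plain arithmetic on the fixture values (mg/L)
  oracle_rq <- 0.0019 / (0.612 / 1000) +
               0.00063 / (3.235 / 1000) +
               0.0017 / (0.056 / 1000)
  res_mp <- rq_mec_pnec(sw, tox)
  expect_equal(res_mp$rq, oracle_rq)
  expect_equal(res_mp$grade, "high")

  oracle_stu <- max(
    0.0019 / 0.612 + 0.00063 / 3.235 + 0.0017 / 0.056,    # algae
    0.0019 / 25.2 + 0.00063 / 202.3 + 0.0017 / 9.1,       # daphnia
    0.0019 / 562 + 0.00063 / 100.5 + 0.0017 / 349) * 1000 # fish
  res_stu <- rq_stu(sw, tox)
  expect_equal(res_stu$rq, oracle_stu)
  expect_equal(res_stu$driver, "algae")
  expect_equal(res_stu$rq, res_mp$rq)  # algae drives; same AF
})
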