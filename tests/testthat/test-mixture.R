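test_that("mixture designs validate proportions and resolve ratio
           rules", {
  expect_error(mixture_design(c("A", "B"), proportions = c(0.4, 0.4)),
               "sum to 1")
  expect_error(mixture_design(c("A", "B"), proportions = c(1.2, -0.2)),
               "> 0")
  expect_error(mixture_design(c("A", "A")), "distinct")
  expect_error(mixture_design(c("A", "B"), ratio_rule = "custom"),
               "proportions")

  crvs <- list(A = llog4(ec50 = 1, hillslope = 1),
               B = llog4(ec50 = 3, hillslope = 1))
  d_eq <- mixture_design(c("A", "B"), ratio_rule = "fixed_equal")
  expect_equal(unname(toxmix:::resolve_proportions(d_eq, crvs)),
               c(0.5, 0.5))
  d_ec <- mixture_design(c("A", "B"))  # ec50_proportional default
  expect_equal(unname(toxmix:::resolve_proportions(d_ec, crvs)),
               c(1 / 4, 3 / 4))
  expect_error(ca_ecx(crvs["A"], d_ec, 50), "no fitted curve")
})

test_that("concentration addition satisfies the sham-combination and
           closed-form identities", {
  crv <- llog4(top = 100, ec50 = 0.8, hillslope = 2.2)
  crvs <- list(A = crv, B = crv)
  d <- mixture_design(c("A", "B"), proportions = c(0.3, 0.7))
  for (x in c(5, 10, 30, 50, 70, 90, 95)) {
    expect_equal(ca_ecx(crvs, d, x), ecx(crv, x), tolerance = 1e-12)
  }

  # hand arithmetic: EC50s (1, 3), equal proportions
  crvs2 <- list(A = llog4(ec50 = 1, hillslope = 1),
                B = llog4(ec50 = 3, hillslope = 1))
  d2 <- mixture_design(c("A", "B"), proportions = c(0.5, 0.5))
  expect_equal(ca_ecx(crvs2, d2, 50), 1.5)

  # EC50-proportional blend with equal hill slopes: the CA EC50 is the
  # arithmetic mean of the component EC50s
  crvs3 <- list(SMX = llog4(ec50 = 0.6120, hillslope = 2),
                SMZ = llog4(ec50 = 3.235, hillslope = 2))
  d3 <- mixture_design(c("SMX", "SMZ"))
  expect_equal(ca_ecx(crvs3, d3, 50), (0.6120 + 3.235) / 2,
               tolerance = 1e-9)
})

test_that("equal-hillslope EC50-proportional CA reduces to
           k(x) * mean(EC50) for 2 and 3 components", {
  for (n in 2:3) {
    ec50s <- c(0.4, 1.7, 6.2)[1:n]
    hill <- 1.8
    crvs <- lapply(ec50s, function(e) llog4(ec50 = e, hillslope = hill))
    names(crvs) <- LETTERS[1:n]
    d <- mixture_design(LETTERS[1:n])
    for (x in c(10, 30, 50, 70, 90)) {
      k <- (x / (100 - x))^(1 / hill)
      expect_equal(ca_ecx(crvs, d, x), k * sum(ec50s) / n,
                   tolerance = 1e-9)
    }
  }
})

test_that("CA is homogeneous of degree one in a joint EC50 rescaling", {
  crvs <- list(A = llog4(ec50 = 0.5, hillslope = 1.2),
               B = llog4(ec50 = 2, hillslope = 3))
  d <- mixture_design(c("A", "B"), proportions = c(0.6, 0.4))
  scaled <- list(A = llog4(ec50 = 0.5 * 7, hillslope = 1.2),
                 B = llog4(ec50 = 2 * 7, hillslope = 3))
  for (x in c(10, 50, 90)) {
    expect_equal(ca_ecx(scaled, d, x), 7 * ca_ecx(crvs, d, x),
                 tolerance = 1e-12)
  }
})

test_that("independent action multiplies non-effects and dominates the
           strongest component", {
  # component effects 0.2 and 0.3 at their partial concentrations
  crvs <- list(A = llog4(ec50 = 4, hillslope = 1),
               B = llog4(ec50 = 7 / 3, hillslope = 1))
  d <- mixture_design(c("A", "B"), proportions = c(0.5, 0.5))
  expect_equal(ia_effect(crvs, d, 2), 1 - 0.8 * 0.7, tolerance = 1e-12)

  # vanishing proportion reduces to the other component's curve
  d_eps <- mixture_design(c("A", "B"),
                          proportions = c(1 - 1e-9, 1e-9))
  expect_equal(ia_effect(crvs, d_eps, 2), effect_at(crvs$A, 2) / 100,
               tolerance = 1e-6)

  # an absorbing component at full effect forces full mixture effect
  steep <- list(A = llog4(ec50 = 1e-6, hillslope = 8),
                B = llog4(ec50 = 5, hillslope = 1))
  d5 <- mixture_design(c("A", "B"), proportions = c(0.5, 0.5))
  expect_equal(ia_effect(steep, d5, 10), 1, tolerance = 1e-9)

  # dominance: bounded below by the max component effect at its partial
  # concentration and above by the sum of component effects
  set.seed(12)
  for (i in 1:50) {
    crv2 <- list(A = random_curve(), B = random_curve())
    prop <- runif(1, 0.1, 0.9)
    dd <- mixture_design(c("A", "B"), proportions = c(prop, 1 - prop))
    ct <- 10^runif(1, -2, 2)
    e_parts <- c(effect_at(crv2$A, prop * ct),
                 effect_at(crv2$B, (1 - prop) * ct)) / 100
    e_mix <- ia_effect(crv2, dd, ct)
    expect_gte(e_mix, max(e_parts) - 1e-12)
    expect_lte(e_mix, min(1, sum(e_parts)) + 1e-12)
  }
})

test_that("IA ECx inversion round-trips, is monotone, and reports the
           attainable ceiling", {
  crvs <- list(A = llog4(ec50 = 0.3, hillslope = 1.4),
               B = llog4(ec50 = 2.5, hillslope = 2.8))
  d <- mixture_design(c("A", "B"))
  xs <- c(10, 30, 50, 70, 90)
  ec <- ia_ecx(crvs, d, xs)
  expect_true(all(diff(ec) > 0))
  expect_equal(ia_effect(crvs, d, ec), xs / 100, tolerance = 1e-8)

  # degenerate single-component design: IA and CA coincide with the
  # component curve
  d1 <- mixture_design("A", proportions = 1)
  expect_equal(ia_ecx(crvs["A"], d1, 50), ecx(crvs$A, 50),
               tolerance = 1e-8)
  expect_equal(ca_ecx(crvs["A"], d1, 50), ecx(crvs$A, 50),
               tolerance = 1e-12)

  # limited asymptotes: the ceiling 1 - (1 - t1)(1 - t2) is enforced
  low <- list(A = llog4(top = 60, ec50 = 1, hillslope = 2),
              B = llog4(top = 50, ec50 = 2, hillslope = 2))
  d2 <- mixture_design(c("A", "B"), ratio_rule = "fixed_equal")
  expect_error(ia_ecx(low, d2, 90), "bounded above by 80")
  expect_silent(ia_ecx(low, d2, 70))
})

test_that("for identical curves and equal blending the CA-vs-IA ECx
           ordering follows its closed-form slope boundary", {
  # For a sham pair at equal proportions, CA gives ECx = r^(1/h) * EC50
  # (r = x / (100 - x)) while IA gives 2 * s^(1/h) * EC50 with
  # s = e / (1 - e), e = 1 - sqrt(1 - x/100). Hence CA <= IA exactly
  # when h >= log2(r / s): the conventional "CA is conservative"
  # ordering holds at steep slopes but reverses at shallow ones.
  for (hill in c(0.7, 1, 1.5, 2.2, 4)) {
    for (ec50 in c(0.1, 1, 5)) {
      crv <- llog4(ec50 = ec50, hillslope = hill)
      crvs <- list(A = crv, B = crv)
      d <- mixture_design(c("A", "B"), ratio_rule = "fixed_equal")
      for (x in c(10, 30, 50, 70, 90)) {
        e <- 1 - sqrt(1 - x / 100)
        h_star <- log2((x / (100 - x)) / (e / (1 - e)))
        ca <- ca_ecx(crvs, d, x)
        ia <- ia_ecx(crvs, d, x)
        if (hill >= h_star + 1e-6) {
          expect_lte(ca, ia + 1e-9)
        } else {
          expect_gte(ca, ia - 1e-9)
        }
      }
    }
  }
})

test_that("predict_mixture tabulates strictly increasing ECx profiles
           per model", {
  crvs <- list(A = llog4(ec50 = 0.6, hillslope = 2),
               B = llog4(ec50 = 3.2, hillslope = 1.5))
  d <- mixture_design(c("A", "B"))
  pred <- predict_mixture(crvs, d)
  expect_setequal(unique(pred$model), c("CA", "IA"))
  for (m in c("CA", "IA")) {
    expect_true(all(diff(pred$predicted_ecx_mg_L[pred$model == m]) > 0))
  }
})
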