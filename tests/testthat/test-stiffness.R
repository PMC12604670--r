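test_that("thermal energy has the right scale", {
  expect_equal(kBT_pN_um(298), 4.1143e-3, tolerance = 1e-4)
  expect_error(kBT_pN_um(-1))
})

test_that("plateau-route stiffness follows the equipartition identity", {
  est <- stiffness_from_plateau(0.2, temperature = 298)
  expect_equal(est$kappa * est$input, 2 * est$kBT)   # exact by construction
  expect_equal(stiffness_from_plateau(2 * kBT_pN_um(298))$kappa, 1)
  half <- stiffness_from_plateau(0.1)
  expect_equal(half$kappa, 2 * stiffness_from_plateau(0.2)$kappa)
  expect_error(stiffness_from_plateau(0), "> 0")
  ## accepts an msd_plateau() result directly
  est2 <- stiffness_from_plateau(list(value = 0.2), temperature = 298)
  expect_equal(est2$kappa, est$kappa)
})

test_that("pair-route stiffness follows kappa = 2 kBT / sigma^2", {
  est <- stiffness_from_pairs(0.17, temperature = 298)
  expect_equal(est$kappa * 0.17^2, 2 * est$kBT)
  expect_equal(stiffness_from_pairs(sqrt(2 * kBT_pN_um(298)))$kappa, 1)
  expect_error(stiffness_from_pairs(-0.1), "> 0")
})

test_that("pair-route stiffness is consistent with a simulated spring", {
  ## two beads joined by a spring of stiffness k_pair: the separation
  ## vector fluctuates with Var = kBT / k_pair per axis, so at large mean
  ## distance sd(|d|) -> sqrt(kBT / k_pair) and the estimator returns
  ## 2 k_pair; checked by direct Monte Carlo of the estimator chain
  k_pair <- 0.5; temp <- 298
  kT <- kBT_pN_um(temp)
  set.seed(7)
  n <- 20000
  dx <- rnorm(n, 3, sqrt(kT / k_pair))
  dy <- rnorm(n, 0, sqrt(kT / k_pair))
  dd <- sqrt(dx^2 + dy^2)
  est <- stiffness_from_pairs(sd(dd), temperature = temp)
  expect_equal(est$kappa, 2 * k_pair, tolerance = 0.1 * 2 * k_pair)
})
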