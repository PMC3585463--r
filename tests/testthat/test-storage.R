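p <- default_params
G1_0 <- p$G1_0

test_that("provision steady state is the documented Hill curve", {
  expect_equal(provision_steady_state(p$P0, p), 0.5)
  expect_equal(provision_steady_state(0, p), 0)
  ## direct arithmetic on the Hill form at a physiological glucose value
  expect_equal(provision_steady_state(80, p),
               80^5 / (186.506^5 + 80^5), tolerance = 1e-14)
  expect_true(all(provision_steady_state(c(1, 50, 500, 5000), p) < 1))
  expect_error(provision_steady_state(-1, p), "non-negative")
})

test_that("cumulative target matches half-saturation, linearity and quadrature", {
  expect_equal(target_cumulative(p$C, G1_0, p), p$Xbar_max / 2)
  expect_equal(target_cumulative(p$C, G1_0, p), 0.825e-3)
  expect_identical(target_cumulative(c(10, 100, 1000), 0, p), c(0, 0, 0))
  ## monotone and saturating
  g <- seq(1, 2000, by = 1)
  xc <- target_cumulative(g, G1_0, p)
  expect_true(all(diff(xc) > 0))
  expect_lt(xc[length(xc)], p$Xbar_max)
  ## independent trapezoid quadrature of the density reproduces the cumulative
  q <- trap_quad(function(th) target_density(th, G1_0, p), 0, 200)
  expect_equal(target_cumulative(200, G1_0, p), q, tolerance = 1e-6)
})

test_that("target density vanishes at the origin, integrates to the capacity, and peaks between 100 and 200", {
  expect_identical(target_density(0, G1_0, p), 0)
  total <- trap_quad(function(th) target_density(th, G1_0, p), 0, 20000,
                     n = 200001)
  expect_equal(total, storage_capacity(G1_0, p), tolerance = 1e-4)
  th <- seq(0, 500, by = 0.25)
  peak <- th[which.max(target_density(th, G1_0, p))]
  expect_gt(peak, 100)
  expect_lt(peak, 200)
})

test_that("compartment integrals are exact complements and match quadrature", {
  for (G in c(10, 80, 149.78, 200, 600)) {
    ab <- compartment_integrals(G, G1_0, p)
    ## conservation holds to the last representable digit
    expect_equal(ab$A + ab$B, storage_capacity(G1_0, p), tolerance = 1e-15)
  }
  ab <- compartment_integrals(p$C, G1_0, p)
  expect_equal(ab$A, ab$B)
  ab0 <- compartment_integrals(0, G1_0, p)
  expect_identical(ab0$A, 0)
  expect_equal(ab0$B, storage_capacity(G1_0, p), tolerance = 1e-15)
  ## quadrature oracle for both sides at G = 150
  ab <- compartment_integrals(150, G1_0, p)
  expect_equal(ab$A,
               trap_quad(function(th) target_density(th, G1_0, p), 0, 150),
               tolerance = 1e-6)
  expect_equal(ab$B,
               trap_quad(function(th) target_density(th, G1_0, p), 150, 2e4,
                         n = 200001),
               tolerance = 1e-3)
})

test_that("redistribution factor is positive, finite and inversely proportional to cell mass", {
  ft <- redistribution_factor(100, G1_0, p)
  expect_true(is.finite(ft) && ft > 0)
  expect_equal(redistribution_factor(100, 2 * G1_0, p), ft / 2)
  ## finite across the whole physiological glucose range
  G <- exp(seq(log(1e-2), log(1e4), length.out = 500))
  expect_true(all(is.finite(redistribution_factor(G, G1_0, p))))
  expect_true(all(redistribution_factor(G, G1_0, p) > 0))
  expect_error(redistribution_factor(0, G1_0, p), "positive")
})

test_that("transition functions satisfy their algebraic identities", {
  set.seed(42)
  G <- runif(100, 1, 1000)
  G1 <- exp(runif(100, log(1e3), log(1e9)))
  u <- transition_functions(G, p)
  for (i in seq_along(G)) {
    ab <- compartment_integrals(G[i], G1[i], p)
    ft <- redistribution_factor(G[i], G1[i], p)
    expect_equal(u$u3[i] * G1[i], p$f * ab$A, tolerance = 1e-12)
    expect_equal(u$u4[i] * G1[i], p$f * ab$B, tolerance = 1e-12)
    expect_equal(u$u1[i], ft * ab$B, tolerance = 1e-12)
    expect_equal(u$u2[i], ft * ab$A, tolerance = 1e-12)
  }
  expect_equal(u$u3 / u$u4, (G / p$C)^p$k, tolerance = 1e-12)
})

test_that("storage functions scale linearly in cell mass", {
  G <- c(50, 150, 400)
  for (lam in c(2, 10)) {
    expect_equal(storage_capacity(lam * G1_0, p),
                 lam * storage_capacity(G1_0, p))
    expect_equal(target_cumulative(G, lam * G1_0, p),
                 lam * target_cumulative(G, G1_0, p))
    expect_equal(target_density(G, lam * G1_0, p),
                 lam * target_density(G, G1_0, p))
    expect_equal(redistribution_factor(G, lam * G1_0, p),
                 redistribution_factor(G, G1_0, p) / lam)
  }
  ## the u's carry the fixed normalisation and do not depend on cell mass
  expect_equal(transition_functions(G, p), transition_functions(G, p))
})
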