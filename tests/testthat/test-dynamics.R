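p <- default_params
Ghat <- glucose_threshold(p)

## constant-coefficient matrix of the cell-cycle block at frozen glucose,
## written down independently of the package's right-hand side
cc_matrix <- function(G, p) {
  trans <- p$p1 * (1 + p$p5 * G)
  matrix(c(-(trans + p$p4), trans, 0,
           0, -p$p2, p$p2,
           2 * p$p3, 0, -p$p3), 3, 3)
}

test_that("cell-cycle rates balance replication against apoptosis at the threshold", {
  ## at G = Ghat the effective G1 loss rate equals the apoptosis rate
  r <- rhs_cell_cycle(1, 0, 0, Ghat, p)
  expect_equal(r[["G1"]], -2 * p$p4, tolerance = 1e-12)
  ## empty system is the trivial fixed point
  expect_equal(unname(rhs_cell_cycle(0, 0, 0, 123, p)), c(0, 0, 0))
  ## at G = 200 > Ghat the frozen-glucose block has a growing mode
  expect_gt(max(Re(eigen(cc_matrix(200, p))$values)), 0)
  expect_error(rhs_cell_cycle(-1, 0, 0, 100, p), "non-negative")
})

test_that("frozen-glucose cell-cycle block at the threshold is exactly balanced", {
  ev <- eigen(cc_matrix(Ghat, p))$values
  expect_lt(max(Re(ev)), 1e-12 * max(Mod(ev)))
  expect_lt(abs(det(cc_matrix(Ghat, p))), 1e-24)
})

test_that("population grows above the threshold and decays below it over long horizons", {
  run_cc <- function(G) {
    rhs <- function(t, y, q) list(as.numeric(cc_matrix(G, p) %*% y))
    out <- deSolve::ode(c(958000, 14000, 28000), c(0, 1e6), rhs, NULL,
                        method = "lsoda", rtol = 1e-8, atol = 1e-6)
    sum(out[nrow(out), -1]) / sum(out[1, -1])
  }
  expect_gt(run_cc(Ghat * 1.25), 1)
  expect_lt(run_cc(Ghat * 0.75), 1)
})

test_that("blood rates reproduce the production-uptake and secretion-decay balances", {
  ## insulin-free glucose balance at G = p6/p7
  expect_equal(rhs_blood(p$p6 / p$p7, 0, 0, p)[["G"]], 0)
  ## secretion balances decay at X1 = bv p10 I / p9
  I <- 0.004
  expect_equal(rhs_blood(100, I, p$bv * p$p10 * I / p$p9, p)[["I"]], 0,
               tolerance = 1e-15)
  ## plain arithmetic on the published constants
  r <- rhs_blood(200, 0.01, 0.0012, p)
  expect_equal(r[["G"]], 0.3 - (0.003 + 0.36 * 0.01) * 200)
  expect_equal(r[["G"]], -1.02)
})

test_that("storage rates have the documented structure", {
  ## no glucose movement, no provision, empty stores: only P relaxes
  r <- rhs_storage(150, 0, 1e6, 0, 0, 0, p)
  expect_equal(unname(r), c(0, 0, p$p11 * provision_steady_state(150, p)))
  ## redistribution conserves X1 + X2: with Gdot = 0 and P = 0 the total
  ## only loses the secreted amount
  for (G in c(60, 150, 300)) {
    r <- rhs_storage(G, 0, 5e5, 8e-4, 3e-4, 0, p)
    expect_equal(r[["X1"]] + r[["X2"]], -p$p9 * 8e-4, tolerance = 1e-12)
  }
  expect_error(rhs_storage(0, 0, 1e6, 0, 0, 0, p), "guard rail")
})

test_that("storage rates scale linearly with cell mass", {
  base <- rhs_storage(180, -0.5, 958000, 1e-3, 4e-4, 0.3, p)
  for (lam in c(2, 7)) {
    scaled <- rhs_storage(180, -0.5, lam * 958000, lam * 1e-3, lam * 4e-4,
                          0.3, p)
    expect_equal(scaled[["X1"]], lam * base[["X1"]], tolerance = 1e-12)
    expect_equal(scaled[["X2"]], lam * base[["X2"]], tolerance = 1e-12)
  }
})

test_that("the assembled right-hand side is the exact concatenation of its blocks", {
  y <- islet_initial_state()
  full <- rhs_full(0, y, p)
  cc <- rhs_cell_cycle(y[["G1"]], y[["S"]], y[["G2M"]], y[["G"]], p)
  bl <- rhs_blood(y[["G"]], y[["I"]], y[["X1"]], p)
  st <- rhs_storage(y[["G"]], bl[["G"]], y[["G1"]], y[["X1"]], y[["X2"]],
                    y[["P"]], p)
  expect_identical(unname(full), unname(c(cc, bl, st)))
  ## glucose falls from the high initial value
  expect_lt(full[["G"]], 0)
  expect_error(rhs_full(0, c(y[-1], NA), p), "finite")
})

test_that("boundary rates are positive everywhere the corollary condition requires", {
  rep <- check_positivity(p, n_samples = 300, seed = 20121119)
  expect_true(attr(rep, "pass"))
  expect_identical(rep$component, state_names())
  ## the glucose boundary rate is the constant production
  expect_equal(rep$min_rate[rep$component == "G"], p$p6)
  ## sampling is reproducible under the fixed seed
  rep2 <- check_positivity(p, n_samples = 300, seed = 20121119)
  expect_identical(rep, rep2)
})
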