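p <- default_params

test_that("physiological run reproduces the qualitative solution shape", {
  traj <- cached_scenario("physiological")
  expect_identical(length(traj$time), 121L)
  expect_equal(unname(traj$state[1, ]), unname(islet_initial_state()))
  G <- traj$state[, "G"]
  expect_true(all(diff(G) < 0))                  # strictly decreasing
  expect_gt(G[121], glucose_threshold(p))        # still above the threshold
  ## releasable insulin is biphasic: the first-phase peak is the initial
  ## stored release, then an interior minimum, then a provision-driven rise
  ex <- find_local_extrema(traj, "X1", include_boundary = TRUE)
  expect_gte(nrow(ex), 3L)
  expect_identical(ex$kind[1:3], c("max", "min", "max"))
  expect_gt(ex$value[3], ex$value[2])
  ## blood insulin follows with the same biphasic signature; its dynamic
  ## range is dominated by the initial spike, so the second-phase bump needs
  ## a lower prominence threshold
  exI <- find_local_extrema(traj, "I", min_prominence_rel = 0.002)
  expect_true(all(c("min", "max") %in% exI$kind))
  ## non-releasable insulin keeps rising late in the run
  expect_true(all(diff(traj$state[101:121, "X2"]) > 0))
  ## the cell cycle barely moves in two hours: G1 shrinks slightly while the
  ## downstream phases fill, and the total population changes by a few percent
  tot <- rowSums(traj$state[, c("G1", "S", "G2M")])
  expect_lt(abs(tot[121] / tot[1] - 1), 0.1)
  expect_lt(traj$state[121, "G1"], traj$state[1, "G1"])
  expect_gt(traj$state[121, "S"], traj$state[1, "S"])
  expect_gt(traj$state[121, "G2M"], traj$state[1, "G2M"])
})

test_that("all builtin scenarios stay positive over their full horizon", {
  for (name in c("physiological", "infusion", "type2", "type1")) {
    traj <- cached_scenario(name)
    expect_true(all(traj$state >= 0), info = name)
    expect_true(all(traj$state[-1, ] > 0), info = name)
    expect_true(all(traj$state[, "G"] > 0), info = name)
  }
})

test_that("sustained glucose infusion expands the beta-cell mass", {
  traj <- cached_scenario("infusion")
  expect_equal(traj$params$p6, 8.6806)
  expect_equal(max(traj$time), 5760)
  expect_gt(traj$state[nrow(traj$state), "G1"], traj$state[1, "G1"])
})

test_that("insulin resistance keeps glucose above the physiological curve", {
  phys <- cached_scenario("physiological")
  t2 <- cached_scenario("type2")
  cmp <- compare_glucose(t2, phys)
  expect_equal(cmp$fraction_ge, 1.0)
  expect_gt(cmp$max_gap, 0)
})

test_that("raised apoptosis drives the beta-cell mass down", {
  traj <- cached_scenario("type1")
  expect_lt(traj$state[nrow(traj$state), "G1"], traj$state[1, "G1"])
})

test_that("scenario definitions carry the documented overrides", {
  expect_identical(builtin_scenario("physiological")$overrides, list())
  expect_identical(builtin_scenario("physiological")$duration, 120)
  expect_equal(builtin_scenario("infusion")$overrides$p6, 8.6806)
  expect_equal(builtin_scenario("type2")$overrides$p8, 360e-5)
  expect_equal(builtin_scenario("type1")$overrides$p4, 10 * 3.3194e-4)
  expect_equal(builtin_scenario("type1", p4_multiplier = 3)$overrides$p4,
               3 * 3.3194e-4)
  expect_error(builtin_scenario("unknown"), "physiological")
})

test_that("integration contract rejects degenerate requests", {
  expect_error(simulate_islet(duration = 0), "positive")
  expect_error(simulate_islet(duration = -5), "positive")
  tiny <- simulate_islet(duration = 0.25, grid_dt = 1)
  expect_identical(tiny$time, c(0, 0.25))
})

test_that("halving the tolerances leaves the endpoint unchanged to 1e-4", {
  ref <- cached_scenario("physiological")
  tight <- simulate_islet(duration = 120, rtol = 5e-9,
                          atol = .5 * c(1e-3, 1e-3, 1e-3, 1e-10, 1e-10,
                                        1e-14, 1e-14, 1e-12))
  dG <- abs(tight$state[121, "G"] - ref$state[121, "G"]) / ref$state[121, "G"]
  expect_lt(dG, 1e-4)
})

test_that("a long physiological run settles monotonically toward the stable state", {
  f2 <- nontrivial_steady_state(p)$state
  traj <- simulate_islet(duration = 1e5, grid_dt = 2000, method = "lsoda",
                         rtol = 1e-10)
  gap <- abs(traj$state[, "G"] - f2[["G"]])
  last_decade <- traj$time >= 1e4
  expect_true(all(diff(gap[last_decade]) < 0))
})

test_that("the non-trivial state is the long-time attractor", {
  f2 <- nontrivial_steady_state(p)$state
  traj <- simulate_islet(duration = 1e6, grid_dt = 1e5, method = "lsoda",
                         rtol = 1e-10)
  final <- traj$state[nrow(traj$state), ]
  expect_lt(max(abs(final - f2) / abs(f2)), 1e-4)
})

test_that("local extrema detection matches closed forms on synthetic input", {
  t <- seq(0, 4 * pi, by = 0.005)
  ex <- find_local_extrema(sin(t), time = t)
  expect_identical(ex$kind, c("max", "min", "max", "min"))
  expect_equal(ex$time, c(pi / 2, 3 * pi / 2, 5 * pi / 2, 7 * pi / 2),
               tolerance = 1e-2)
  ## strictly monotone series has no interior extrema
  expect_identical(nrow(find_local_extrema(seq(0, 1, 0.01))), 0L)
  ## small wiggles are filtered by the prominence threshold
  y <- sin(t) + 1e-4 * sin(40 * t)
  expect_identical(nrow(find_local_extrema(y, time = t,
                                           min_prominence_rel = 0.05)), 4L)
  expect_error(find_local_extrema(c(1, 2)), "3 samples")
})

test_that("glucose comparison reports dominance and gaps", {
  a <- cached_scenario("physiological")
  cmp <- compare_glucose(a, a)
  expect_equal(cmp$fraction_ge, 1.0)
  expect_equal(cmp$max_gap, 0)
  expect_equal(cmp$min_gap, 0)
  short <- simulate_islet(duration = 10)
  expect_error(compare_glucose(a, short), "time grid")
})

test_that("trajectory methods expose the record coherently", {
  traj <- cached_scenario("physiological")
  df <- as.data.frame(traj)
  expect_identical(names(df), c("time_min", state_names()))
  expect_identical(nrow(df), 121L)
  s <- summary(traj)
  expect_equal(s$end_state, traj$state[121, ])
  expect_output(print(traj), "physiological")
  expect_output(print(s), "glucose range")
})
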