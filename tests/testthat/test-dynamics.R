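test_that("shunting equilibrium matches the closed form and respects bounds", {
  p <- sim_params()
  # constant-input cell settles onto (B E - D I)/(A + E + I)
  cases <- expand.grid(E = c(0.3, 1, 4), I = c(0, 0.5, 3))
  for (i in seq_len(nrow(cases))) {
    E <- cases$E[i]; I <- cases$I[i]
    x <- 0
    for (step in 1:600) x <- shunt_update(x, E, I, p)
    expect_equal(x, (p$B * E - p$D * I) / (p$A + E + I), tolerance = 1e-6)
  }

  # randomized nonnegative inputs never push activity out of [-D, B]
  set.seed(1)
  x <- runif(500)
  for (step in 1:1000) {
    E <- runif(500, 0, 8); I <- runif(500, 0, 8)
    x <- shunt_update(x, E, I, p)
    expect_true(all(x >= -p$D - 1e-12 & x <= p$B + 1e-12))
  }
})

test_that("a zero-input network stays at rest", {
  blank <- make_texture_pair()$background
  p <- sim_params(n_steps = 10L)
  run <- run_model(blank, lesion_config("intact"), p)
  expect_equal(max(abs(convex_field(run))), 0)
  expect_equal(max(abs(run$state$teardrop)), 0)
  expect_true(run$converged)
})

test_that("simulations are deterministic and reproducible", {
  p <- sim_params(n_steps = 20L, convergence_tol = 1e-12)
  d <- make_cross(5, 19)
  r1 <- suppressWarnings(run_model(d, lesion_config("intact"), p))
  r2 <- suppressWarnings(run_model(d, lesion_config("intact"), p))
  expect_identical(r1$state$convex, r2$state$convex)
  expect_identical(r1$state$teardrop, r2$state$teardrop)
  expect_identical(r1$scale_max, r2$scale_max)
})

test_that("non-convergence is reported and trajectories can be recorded", {
  p <- sim_params(n_steps = 5L, convergence_tol = 1e-12)
  d <- make_rectangle(1, 12)
  expect_warning(run <- run_model(d, lesion_config("none"), p,
                                  record_stride = 2L), "converge")
  expect_false(run$converged)
  expect_equal(run$steps, 5L)
  expect_gte(length(run$trajectory), 2)
  expect_equal(run$trajectory[[length(run$trajectory)]]$t, 5L)
})

test_that("probe traces follow the recorded cells", {
  p <- sim_params(n_steps = 15L, convergence_tol = 1e-12)
  d <- make_rectangle(1, 17)
  pr <- data.frame(row = 32, col = 32, scale = 4)
  run <- suppressWarnings(run_model(d, lesion_config("intact"), p, probes = pr))
  tr <- time_course(run, 32, 32, 4)
  expect_length(tr, run$steps)
  expect_equal(tr[run$steps], run$state$convex[32, 32, 4])
  expect_error(time_course(run, 1, 1, 1), "probe")
  run2 <- suppressWarnings(run_model(d, lesion_config("intact"), p))
  expect_error(time_course(run2, 32, 32, 4), "probes")
})

test_that("interior enhancement: figure vs background-only texture displays", {
  pair <- make_texture_pair()
  p <- cached_params()
  probe <- data.frame(row = 32, col = 32, scale = 4)
  rf <- suppressWarnings(run_model(pair$figure, lesion_config("intact"), p,
                                   probes = probe))
  rb <- suppressWarnings(run_model(pair$background, lesion_config("intact"), p,
                                   probes = probe))
  tf <- time_course(rf, 32, 32, 4)
  tb <- time_course(rb, 32, 32, 4)
  nm <- min(length(tf), length(tb))
  expect_true(all(tf[seq_len(nm)] >= tb[seq_len(nm)]))
  expect_gt(tf[length(tf)], tb[length(tb)])
})

test_that("C-shape: feedback decides medial axis vs concavity", {
  pr <- c_shape_probes()
  probes <- pr[, c("row", "col", "scale")]
  eq <- sapply(c("intact", "none"), function(cond) {
    run <- cached_run("c_shape", cond, probes = probes)
    run$traces[nrow(run$traces), ]
  })
  # intact: medial response exceeds the concavity response
  expect_gt(eq[1, "intact"], eq[2, "intact"])
  # no feedback: the ordering reverses (or equalises)
  expect_lte(eq[1, "none"], eq[2, "none"] + 1e-6)
})
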