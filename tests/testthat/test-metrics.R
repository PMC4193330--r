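make_masks <- function() {
  fig <- matrix(FALSE, 10, 10); fig[3:8, 3:8] <- TRUE
  med <- matrix(FALSE, 10, 10); med[5:6, 5:6] <- TRUE
  bnd <- matrix(FALSE, 10, 10); bnd[3, 3:8] <- TRUE
  list(figure = fig, ground = !fig, medial_band = med,
       interior_rest = fig & !med, boundary_band = bnd, elsewhere = !bnd)
}

test_that("indices evaluate their defining contrasts", {
  m <- make_masks()
  map <- matrix(0.2, 10, 10)
  expect_equal(ioi(map, m), 0)          # equal means
  map_fig <- matrix(0, 10, 10); map_fig[m$figure] <- 0.5
  expect_equal(ioi(map_fig, m), 1)      # no ground activity

  map2 <- matrix(0, 10, 10)
  map2[m$figure] <- 0.3; map2[m$ground] <- 0.1
  expect_equal(ioi(map2, m), 0.5)       # (0.3 - 0.1)/(0.3 + 0.1)

  expect_equal(mai(map, m), 0)
  map3 <- matrix(0, 10, 10); map3[m$medial_band] <- 0.7
  expect_equal(mai(map3, m), 1)

  expect_equal(bi(map, m), 0)
  map4 <- matrix(0, 10, 10)
  map4[m$boundary_band] <- 0.4; map4[m$elsewhere] <- 0.1
  expect_equal(bi(map4, m), 0.6)        # (0.4 - 0.1)/(0.4 + 0.1)

  expect_warning(z <- ioi(matrix(0, 10, 10), m), "0/0")
  expect_equal(z, 0)
  bad <- m; bad$ground <- matrix(FALSE, 10, 10)
  expect_error(ioi(map, bad), "empty")
})

test_that("indices agree with the brute-force mask-mean oracle and are scale invariant", {
  set.seed(42)
  m <- make_masks()
  for (i in 1:20) {
    map <- matrix(runif(100), 10, 10)
    expect_equal(ioi(map, m), oracle_index(map, m$figure, m$ground),
                 tolerance = 1e-12)
    expect_equal(mai(map, m), oracle_index(map, m$medial_band, m$interior_rest),
                 tolerance = 1e-12)
    expect_equal(bi(map, m), oracle_index(map, m$boundary_band, m$elsewhere),
                 tolerance = 1e-12)
    for (c in c(0.25, 3, 40)) {
      expect_equal(ioi(c * map, m), ioi(map, m), tolerance = 1e-12)
      expect_equal(mai(c * map, m), mai(map, m), tolerance = 1e-12)
      expect_equal(bi(c * map, m), bi(map, m), tolerance = 1e-12)
    }
    expect_true(abs(ioi(map, m)) <= 1 && abs(mai(map, m)) <= 1 &&
                  abs(bi(map, m)) <= 1)
  }
})

test_that("scale-profile kurtosis matches closed forms", {
  # equal mass on the two extreme scales: mu4/mu2^2 = 1
  expect_equal(scale_profile_kurtosis(c(0.5, 0, 0, 0, 0, 0, 0.5)), 1)
  # uniform mass over 7 scales: mu2 = 4, mu4 = 28
  expect_equal(scale_profile_kurtosis(rep(1, 7)), 28 / 16)
  # a narrow unimodal profile is more kurtotic than the uniform one
  expect_gt(scale_profile_kurtosis(c(0.01, 0.05, 1, 0.05, 0.01, 0.01, 0.01)),
            scale_profile_kurtosis(rep(1, 7)))
  expect_error(scale_profile_kurtosis(rep(0, 7)), "zero")
  expect_true(is.infinite(scale_profile_kurtosis(c(0, 0, 1, 0, 0, 0, 0))))
})

test_that("medial readout picks the dominant scale with small-scale ties", {
  conv <- array(0, c(12, 12, 7))
  conv[4, 9, 3] <- 0.8
  ro <- readout_medial(conv)
  expect_equal(ro$scale, 3L)
  expect_equal(unname(ro$peak), c(4L, 9L))
  # ties break toward the smaller scale
  conv[7, 7, 5] <- 0.8
  expect_equal(readout_medial(conv)$scale, 3L)
  expect_error(readout_medial(array(0, c(4, 4, 7))), "zero")
})

test_that("square readout lands on the ground-truth skeleton near the center", {
  run <- cached_run("square", "intact")
  ro <- readout_medial(convex_field(run), rho = cached_params()$rho_readout)
  band <- teardrop:::dilate_mask(cached_exemplars()$square$medial_mask, 1L)
  on_band <- band[cbind(ro$positions[, 1], ro$positions[, 2])]
  expect_true(all(on_band))
})

test_that("metrics reports summarise runs and normalisation is min-max", {
  run <- cached_run("square", "intact")
  rep <- metrics_report(run)
  expect_s3_class(rep, "metrics_report")
  df <- as.data.frame(rep)
  expect_equal(nrow(df), 1)
  expect_true(all(c("ioi", "mai", "bi", "kurtosis", "peak_scale") %in% names(df)))
  expect_length(rep$per_scale_max, 7)

  x <- c(0.2, 0.9, 0.4, 0.6)
  nx <- normalize_indices(x)
  expect_equal(range(nx), c(0, 1))
  expect_equal(nx[2], 1)
  expect_equal(normalize_indices(rep(0.3, 4)), rep(0.5, 4))
})
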