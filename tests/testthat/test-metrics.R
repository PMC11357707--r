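# a tiny field with two snapshots for interpolation checks
make_field <- function(fun0, fun1, dm = c(10, 10, 10), spacing = 1e-3) {
  g <- homogeneous_grid(dm, "muscle", spacing)
  co <- voxel_coords(g)
  ii <- arrayInd(seq_len(prod(dm)), dm)
  X <- co$x[ii[, 1]]; Y <- co$y[ii[, 2]]; Z <- co$z[ii[, 3]]
  v0 <- array(fun0(X, Y, Z), dim = dm)
  v1 <- array(fun1(X, Y, Z), dim = dm)
  structure(list(grid = g, times = c(0, 10), values = list(v0, v1),
                 bc = boundary_conditions(),
                 protocol = ablation_protocol(80, 40, 10, 20)),
            class = "temperature_field")
}

test_that("probe sampling reproduces nodal and midpoint values exactly", {
  f <- make_field(function(x, y, z) 20 + 0 * x,
                  function(x, y, z) 1000 * x + 2000 * y + 500 * z + 30)
  g <- f$grid
  co <- voxel_coords(g)
  # voxel center: nodal value
  p <- probe_spec("c", c(co$x[4], co$y[5], co$z[6]), 0)
  lg <- sample_probe(f, p)
  expect_identical(lg$temperatures[2], f$values[[2]][4, 5, 6])
  # midpoint on one axis: arithmetic mean of the two nodal values
  p <- probe_spec("m", c((co$x[4] + co$x[5]) / 2, co$y[5], co$z[6]), 0)
  lg <- sample_probe(f, p)
  expect_equal(lg$temperatures[2],
               (f$values[[2]][4, 5, 6] + f$values[[2]][5, 5, 6]) / 2,
               tolerance = 1e-12)
})

test_that("trilinear sampling is exact on affine fields", {
  a <- c(37, 1500, -800, 300)
  f <- make_field(function(x, y, z) 20 + 0 * x,
                  function(x, y, z) a[1] + a[2] * x + a[3] * y + a[4] * z)
  set.seed(7)
  for (i in 1:25) {
    pos <- runif(3, -4e-3, 4e-3)
    lg <- sample_probe(f, probe_spec("p", pos, 0))
    want <- a[1] + sum(a[2:4] * pos)
    expect_lt(abs(lg$temperatures[2] - want), 1e-9)
  }
})

test_that("probes outside the domain are rejected", {
  f <- make_field(function(x, y, z) 20 + 0 * x, function(x, y, z) 30 + 0 * x)
  expect_error(sample_probe(f, probe_spec("out", c(1, 0, 0), 0)),
               "outside")
})

test_that("delta_T reproduces the printed initial/final arithmetic", {
  mk <- function(ti, tf) sensor_log("T", c(0, 0, 0), c(0, 210), c(ti, tf),
                                    provenance = "measured")
  expect_equal(delta_T(mk(20, 81.4))$delta, 61.4)
  expect_equal(delta_T(mk(37, 43.8))$delta, 6.8)
  expect_equal(delta_T(mk(20, 51.3))$delta, 31.3)
  expect_identical(delta_T(mk(25, 25))$delta, 0)
})

test_that("percent_diff rounds half away from zero with the printed sign", {
  expect_identical(percent_diff(33.6, 31.3), -7L)
  expect_identical(percent_diff(10.8, 6.8), -37L)
  expect_identical(percent_diff(12, 12), 0L)
  expect_identical(percent_diff(10, 10.25), 3L)   # +2.5 -> +3 (away from zero)
  expect_identical(percent_diff(10, 9.75), -3L)   # -2.5 -> -3
  expect_error(percent_diff(0, 5), "nonzero")
})

test_that("ablation extent recovers a constructed spherical hot region", {
  a <- 4e-3
  f <- make_field(function(x, y, z) 20 + 0 * x,
                  function(x, y, z)
                    ifelse(sqrt(x^2 + y^2 + z^2) <= a, 70, 30),
                  dm = c(24, 24, 24))
  pose <- applicator_pose(tip_position = c(-6e-3, 0, 0),
                          active_center_offset = 6e-3, shaft_length = 12e-3)
  ext <- ablation_extent(f, 55, pose)
  sp <- f$grid$spacing
  expect_lt(abs(ext$depth_D - a), sp / 2 + 1e-9)
  expect_lt(abs(ext$length_L - 2 * a), sp + 1e-9)

  # empty region
  ext0 <- ablation_extent(f, 100, pose)
  expect_identical(ext0$depth_D, 0)
  expect_identical(ext0$length_L, 0)

  # nesting: lower isotherm encloses the higher one
  e55 <- ablation_extent(f, 55, pose)
  e60 <- ablation_extent(f, 60, pose)
  expect_gte(e55$depth_D, e60$depth_D)
  expect_gte(e55$length_L, e60$length_L)
})

test_that("extent is monotone non-increasing in the isotherm", {
  f <- make_field(function(x, y, z) 20 + 0 * x,
                  function(x, y, z) 80 * exp(-(x^2 + y^2 + z^2) / 2e-5) + 20,
                  dm = c(20, 20, 20))
  pose <- applicator_pose(tip_position = c(-5e-3, 0, 0),
                          active_center_offset = 5e-3, shaft_length = 10e-3)
  ds <- vapply(c(40, 50, 60, 70), function(iso)
    ablation_extent(f, iso, pose)$depth_D, numeric(1))
  expect_true(all(diff(ds) <= 1e-12))
})

test_that("replicate summaries use the n-1 standard deviation", {
  mk <- function(ti, tf, cond = "c1", ch = "T1", d = 9.5e-3)
    sensor_log(ch, c(0, 0, 0), c(0, 210), c(ti, tf),
               provenance = "synthetic", nominal_distance = d,
               condition = cond)
  logs <- list(mk(20, 30), mk(20, 32), mk(20, 34))
  s <- summarize_replicates(logs)
  expect_equal(s$T_final_mean, 32)
  expect_equal(s$T_final_sd, 2)
  expect_equal(s$delta_mean, 12)
  expect_equal(s$delta_sd, 2)

  # identical logs: zero spread; single replicate: sd flagged NA
  s2 <- summarize_replicates(list(mk(20, 30), mk(20, 30)))
  expect_equal(s2$T_final_sd, 0)
  s1 <- summarize_replicates(list(mk(20, 30)))
  expect_true(is.na(s1$T_final_sd))
  expect_equal(s1$T_final_mean, 30)

  # permutation invariance
  s3 <- summarize_replicates(logs[c(3, 1, 2)])
  expect_equal(s3, s)
})

test_that("comparison table reproduces the printed percent differences", {
  ref <- reference_comparison_inputs()
  tab <- build_comparison_table(ref$experiment, ref$simulation)
  key <- paste(tab$condition, tab$channel)
  want <- ref$expected_percent
  wkey <- paste(want$condition, want$channel)
  expect_setequal(key, wkey)
  expect_identical(tab$percent_diff[match(wkey, key)], want$percent)
  # simulated dT1 sits within 3-7% of experiment in magnitude
  t1 <- tab[tab$channel == "T1", ]
  expect_true(all(abs(t1$percent_diff) >= 3 & abs(t1$percent_diff) <= 7))
  # simulation below experiment everywhere: all negative
  expect_true(all(tab$percent_diff < 0))

  # identical inputs give all-zero differences
  tab0 <- build_comparison_table(ref$experiment, ref$experiment)
  expect_true(all(tab0$percent_diff == 0L))

  # unmatched rows are reported and skipped
  extra <- rbind(ref$experiment,
                 data.frame(condition = "P999", channel = "T1", delta = 1))
  expect_message(tab2 <- build_comparison_table(extra, ref$simulation),
                 "skipped")
  expect_identical(nrow(tab2), 6L)
})

test_that("sensor logs round-trip through CSV", {
  lg <- sensor_log("T1", c(0, 0, 0), c(0, 5, 10), c(20, 25.5, 31.2),
                   provenance = "measured")
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensor_logs(list(lg), path)
  back <- read_sensor_logs(path)
  expect_equal(back[["T1"]]$temperatures, lg$temperatures)
  expect_equal(back[["T1"]]$times, lg$times)
})
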