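mk3 <- function(N, E, Z, fs = 200) {
  list(N = trace(N, fs, 0, "N", "seismic"),
       E = trace(E, fs, 0, "E", "seismic"),
       Z = trace(Z, fs, 0, "Z", "seismic"))
}

test_that("degenerate polarizations give the expected extremes", {
  t <- (0:1999) / 200
  s <- sin(2 * pi * 18 * t)
  vert <- mk3(1e-9 * rnorm(2000), 1e-9 * rnorm(2000), s)
  pv <- particle_motion(vert$N, vert$E, vert$Z, band = c(16, 20))
  expect_gt(pv$vh_ratio, 100)
  expect_gt(pv$incidence_angle, 85)
  expect_equal(pv$classification, "rayleigh_like")

  horiz <- mk3(s * cos(pi / 3), s * sin(pi / 3), 1e-9 * rnorm(2000))
  ph <- particle_motion(horiz$N, horiz$E, horiz$Z, band = c(16, 20))
  expect_lt(ph$vh_ratio, 0.01)
  expect_lt(ph$incidence_angle, 5)
  expect_equal(ph$classification, "love_like")
  expect_gt(ph$rectilinearity, 0.95)

  zero <- mk3(rep(0, 2000), rep(0, 2000), rep(0, 2000))
  expect_error(particle_motion(zero$N, zero$E, zero$Z), "zero-energy")
})

test_that("quadrature ellipse matches the closed-form covariance ratio", {
  # retrograde ellipse in the vertical-radial plane: Z and N in quadrature.
  # For Z = aZ sin, N = aN cos, the component variances are aZ^2/2 and
  # aN^2/2, so vh_ratio = aZ^2 / aN^2 exactly.
  t <- (0:3999) / 200
  aZ <- 2.0; aN <- 1.25
  ell <- mk3(aN * cos(2 * pi * 18 * t), 1e-9 * rnorm(4000),
             aZ * sin(2 * pi * 18 * t))
  pe <- particle_motion(ell$N, ell$E, ell$Z, band = c(16, 20))
  expect_equal(pe$vh_ratio, aZ^2 / aN^2, tolerance = 0.05)
})

test_that("vh_ratio is invariant under horizontal rotation", {
  set.seed(8)
  t <- (0:1999) / 200
  N <- sin(2 * pi * 18 * t) + 0.3 * rnorm(2000)
  E <- 0.5 * sin(2 * pi * 18 * t + 1) + 0.3 * rnorm(2000)
  Z <- 0.8 * sin(2 * pi * 18 * t + 2) + 0.3 * rnorm(2000)
  th <- 37 * pi / 180
  tr0 <- mk3(N, E, Z)
  trr <- mk3(cos(th) * N - sin(th) * E, sin(th) * N + cos(th) * E, Z)
  p0 <- particle_motion(tr0$N, tr0$E, tr0$Z, band = c(16, 20))
  pr <- particle_motion(trr$N, trr$E, trr$Z, band = c(16, 20))
  expect_equal(p0$vh_ratio, pr$vh_ratio, tolerance = 1e-8)
})

test_that("isotropic noise sits near the 0.5 ratio and classifies mixed", {
  ratios <- vapply(1:100, function(seed) {
    set.seed(seed)
    iso <- mk3(rnorm(1200), rnorm(1200), rnorm(1200))
    particle_motion(iso$N, iso$E, iso$Z, band = c(10, 40))$vh_ratio
  }, 0)
  expect_gte(stats::median(ratios), 0.3)
  expect_lte(stats::median(ratios), 0.7)
})

test_that("a polarized synthetic call separates Rayleigh-like and Love-like bands", {
  sp <- rumble_spec(apex_frequency = 18, duration = 4, n_harmonics = 1,
                    peak_ground_velocity = 5)
  call3 <- synth_rumble_polarized(sp, 200)
  tr <- mk3(call3$N, call3$E, call3$Z)
  bands <- classify_band_polarization(tr$N, tr$E, tr$Z)
  expect_equal(bands$classification[bands$f_lo == 16], "rayleigh_like")
  expect_equal(bands$classification[bands$f_lo == 30], "love_like")
})
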