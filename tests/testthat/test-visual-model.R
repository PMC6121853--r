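test_that("quantum catch reduces to closed forms", {
  g <- seq(400, 500, 1)
  one <- spectrum(g, rep(1, length(g)), "sensitivity")
  rec <- receptor_class("r", one, weber_fraction = 0.1)
  illum <- spectrum(g, rep(1, length(g)), "irradiance")
  expect_equal(quantum_catch(spectrum(g, rep(0, length(g)), "reflectance"),
                             illum, rec), 0)
  # trapezoid of the constant 1 over 400-500 nm
  expect_equal(quantum_catch(spectrum(g, rep(1, length(g)), "reflectance"),
                             illum, rec), 100)
})

test_that("quantum catch agrees with a 10x finer quadrature oracle", {
  coarse <- seq(400, 700, 2)
  fine <- seq(400, 700, 0.2)
  sens_f <- function(l) exp(-((l - 520) / 35)^2)
  rec_c <- receptor_class("r", spectrum(coarse, sens_f(coarse), "sensitivity"),
                          weber_fraction = 0.1)
  rec_f <- receptor_class("r", spectrum(fine, sens_f(fine), "sensitivity"),
                          weber_fraction = 0.1)
  q_c <- quantum_catch(flat_spec(0.5, grid = coarse),
                       flat_spec(1, "irradiance", coarse), rec_c)
  q_f <- quantum_catch(flat_spec(0.5, grid = fine),
                       flat_spec(1, "irradiance", fine), rec_f)
  expect_lt(abs(q_c - q_f) / q_f, 0.001)
})

test_that("quantum catch validates its inputs", {
  g <- seq(400, 500, 1)
  rec <- receptor_class("r", spectrum(g, rep(1, length(g)), "sensitivity"),
                        weber_fraction = 0.1)
  expect_error(quantum_catch(flat_spec(1, grid = seq(400, 500, 2)),
                             spectrum(g, rep(1, 101), "irradiance"), rec),
               "different grids")
  expect_error(quantum_catch(flat_spec(1, grid = g),
                             spectrum(g, rep(0, 101), "irradiance"), rec),
               "identically zero")
})

test_that("von Kries adaptation maps white to one and cancels intensity", {
  sys <- toy_system(c(0.1, 0.07, 0.05))
  g <- sys$chromatic_receptors[[1]]$sensitivity$wavelength_nm
  illum <- spectrum(g, 1 + (g - 400) / 300, "irradiance")
  white <- flat_spec(1, grid = g)
  qw <- adapt(white, illum, sys)
  expect_equal(unname(qw$adapted_catches), rep(1, 3))
  expect_equal(qw$luminance_catch, 1)
  set.seed(21)
  patch <- spectrum(g, runif(length(g), 0.05, 0.9), "reflectance")
  q1 <- adapt(patch, illum, sys)
  illum_scaled <- spectrum(g, illum$value * 37.5, "irradiance")
  q2 <- adapt(patch, illum_scaled, sys)
  expect_equal(q1$adapted_catches, q2$adapted_catches, tolerance = 1e-12)
  expect_equal(q1$luminance_catch, q2$luminance_catch, tolerance = 1e-12)
})

test_that("adaptation matches a hand-integration oracle on a toy dichromat", {
  g <- seq(450, 650, 50)
  s1 <- c(1, 0.6, 0.2, 0.05, 0)
  s2 <- c(0, 0.2, 0.7, 1, 0.4)
  recs <- list(receptor_class("a", spectrum(g, s1, "sensitivity"),
                              weber_fraction = 0.1),
               receptor_class("b", spectrum(g, s2, "sensitivity"),
                              weber_fraction = 0.1))
  sys <- visual_system(recs)
  refl <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  ill <- c(2, 3, 4, 3, 2)
  hand_trapz <- function(v) {
    tot <- 0
    for (i in 1:(length(g) - 1))
      tot <- tot + (g[i + 1] - g[i]) * (v[i] + v[i + 1]) / 2
    tot
  }
  q <- adapt(spectrum(g, refl, "reflectance"), spectrum(g, ill, "irradiance"),
             sys)
  expect_equal(unname(q$adapted_catches[1]),
               hand_trapz(refl * ill * s1) / hand_trapz(ill * s1),
               tolerance = 1e-12)
  expect_equal(unname(q$adapted_catches[2]),
               hand_trapz(refl * ill * s2) / hand_trapz(ill * s2),
               tolerance = 1e-12)
})

test_that("chromatic contrast closed forms and oracles agree", {
  di <- toy_system(c(0.1, 0.1))
  expect_equal(chromatic_contrast(qcv(c(1, 1)), qcv(c(1, 1)), di), 0)
  # one channel scaled by e: |1 - 0| / sqrt(0.02)
  expect_equal(chromatic_contrast(qcv(c(exp(1) * 0.4, 0.7)),
                                  qcv(c(0.4, 0.7)), di),
               7.07106781186548, tolerance = 1e-9)
  tri <- toy_system(c(0.1, 0.07, 0.05))
  df <- c(0.2, -0.1, 0.05)
  got <- chromatic_contrast(qcv(exp(df)), qcv(c(1, 1, 1)), tri)
  expect_equal(got, rnl_minimization_oracle(df, c(0.1, 0.07, 0.05)),
               tolerance = 1e-9)
})

test_that("general-n contrast matches the minimization oracle", {
  set.seed(31)
  for (n in c(2, 3, 4)) {
    w <- runif(n, 0.03, 0.2)
    sys <- toy_system(w)
    for (rep in 1:5) {
      df <- rnorm(n, 0, 0.5)
      got <- chromatic_contrast(qcv(exp(df)), qcv(rep(1, n)), sys)
      expect_equal(got, rnl_minimization_oracle(df, w), tolerance = 1e-7)
    }
  }
})

test_that("contrast is symmetric, scales linearly in log signals, and
           reduces under equal Weber fractions", {
  sys <- toy_system(c(0.08, 0.08, 0.08))
  set.seed(32)
  df <- rnorm(3, 0, 0.3)
  a <- qcv(exp(df)); b <- qcv(rep(1, 3))
  expect_equal(chromatic_contrast(a, b, sys), chromatic_contrast(b, a, sys))
  for (cc in c(0.5, 2, 3.7))
    expect_equal(chromatic_contrast(qcv(exp(cc * df)), b, sys),
                 cc * chromatic_contrast(a, b, sys), tolerance = 1e-10)
  # equal-omega trichromat reduction
  w <- 0.08
  want <- sqrt(sum((df[c(1, 1, 2)] - df[c(2, 3, 3)])^2) / 3) / w
  expect_equal(chromatic_contrast(a, b, sys), want, tolerance = 1e-10)
})

test_that("contrasts reject non-positive catches", {
  sys <- toy_system(c(0.1, 0.1))
  expect_error(chromatic_contrast(qcv(c(0, 1)), qcv(c(1, 1)), sys),
               "strictly positive")
})

test_that("achromatic contrast has its closed forms", {
  sys <- toy_system(c(0.1, 0.1), luminance_weber = 0.05)
  expect_equal(achromatic_contrast(qcv(c(1, 1), 0.3), qcv(c(2, 2), 0.3), sys),
               0)
  expect_equal(achromatic_contrast(qcv(c(1, 1), exp(1) * 0.2),
                                   qcv(c(1, 1), 0.2), sys), 20)
})

test_that("flat black vs white under flat light gives ln(20)/0.05 JND", {
  sys <- toy_system(c(0.1, 0.1, 0.1), luminance_weber = 0.05)
  g <- sys$chromatic_receptors[[1]]$sensitivity$wavelength_nm
  illum <- flat_spec(1, "irradiance", g)
  black <- adapt(flat_spec(0.04, grid = g), illum, sys)
  white <- adapt(flat_spec(0.80, grid = g), illum, sys)
  expect_equal(achromatic_contrast(black, white, sys), log(20) / 0.05,
               tolerance = 1e-6)
  # flat spectra are chromatically identical
  expect_lt(chromatic_contrast(black, white, sys), 1e-9)
})

test_that("Maxwell coordinates place catches barycentrically", {
  expect_equal(maxwell_coordinates(qcv(c(1, 1, 1))), c(0, 0),
               tolerance = 1e-12)
  eps <- 1e-9
  v1 <- maxwell_coordinates(qcv(c(1, eps, eps)))
  expect_equal(v1, c(0, 1 / sqrt(3)), tolerance = 1e-6)
  q <- c(0.5, 0.3, 0.2)
  verts <- rbind(c(0, 1 / sqrt(3)), c(-0.5, -1 / (2 * sqrt(3))),
                 c(0.5, -1 / (2 * sqrt(3))))
  expect_equal(maxwell_coordinates(qcv(q)),
               as.numeric((q / sum(q)) %*% verts), tolerance = 1e-12)
  expect_error(maxwell_coordinates(qcv(c(1, 2))), "trichromatic")
})
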