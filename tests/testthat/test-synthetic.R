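test_that("toy scaffolds have the advertised geometry and are deterministic", {
  s1 <- make_toy_structure("two-site-scaffold")
  s2 <- make_toy_structure("two-site-scaffold")
  expect_identical(s1$atoms, s2$atoms)
  expect_equal(atom_distance(s1, "A:5:CB", "B:105:CB"), 45, tolerance = 1e-9)
  s3 <- make_toy_structure("two-site-scaffold", separation_A = 60)
  expect_equal(atom_distance(s3, "A:5:CB", "B:105:CB"), 60, tolerance = 1e-9)
  # reporter atom sits 10 A from the first site CB
  expect_equal(atom_distance(s1, "A:5:CB", "R:500:CD1"), 10, tolerance = 1e-9)
  # helix geometry: consecutive CA-CA distance ~ 3.8 A
  expect_equal(atom_distance(s1, "A:1:CA", "A:2:CA"), 3.8, tolerance = 0.02)
})

test_that("scaffold inter-label distribution peaks at the design separation", {
  s <- make_toy_structure("two-site-scaffold", separation_A = 45)
  e1 <- generate_ensemble(s, "A:5", n = 80, seed = 1)
  e2 <- generate_ensemble(s, "B:105", n = 80, seed = 2)
  pd <- interlabel_distribution(e1, e2)
  modes <- find_modes(pd)
  expect_true(any(abs(modes - 4.5) <= 0.3))
})

test_that("synthetic DEER traces are reproducible and carry their truth", {
  d1 <- make_deer_dataset(noise_sd = 0.02, seed = 5)
  d2 <- make_deer_dataset(noise_sd = 0.02, seed = 5)
  expect_identical(d1$trace$v, d2$trace$v)
  expect_identical(find_modes(d1$truth$P), 4.5)
  # file round trip is bitwise identical for the same seed
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_trace(d1$trace, f1); write_trace(d2$trace, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("multi-component regime: short modes recovered, long mode flagged", {
  ds <- make_deer_dataset(
    components = list(c(2.5, 0.15, 0.35), c(3.5, 0.2, 0.35), c(5.5, 0.3, 0.3)),
    t_max = 4, n_points = 400, noise_sd = 0.01, seed = 1)
  bf <- fit_background(ds$trace)
  p <- tikhonov_invert(bf$form_factor, lambda_mod = bf$background$lambda)
  modes <- find_modes(p)
  expect_true(any(abs(modes - 2.5) <= 0.2))
  expect_true(any(abs(modes - 3.5) <= 0.2))
  expect_true(p$metadata$modes_beyond_advisory ||
                any(modes > 0.85 * p$metadata$r_max_advisory_nm))
})

test_that("PRE generator follows the r^-6 attenuation model", {
  pre <- make_pre_dataset(c(A = 25, B = 12, C = 40), noise_rms = 0, seed = 1)
  tr <- pre$truth
  expect_equal(tr$true_ratio[tr$residue_id == "A"], 0.5, tolerance = 1e-9)
  # plug-in of the stated model: 0.5^((25/r)^6)
  expect_equal(tr$true_ratio[tr$residue_id == "C"], 0.5^((25 / 40)^6),
               tolerance = 1e-9)
  expect_equal(tr$true_ratio[tr$residue_id == "B"], 1e-3)  # bleached, floored
  expect_equal(tr$expected, c("attenuated", "attenuated", "unaffected"))
  # determinism with noise
  pa <- make_pre_dataset(c(A = 20, B = 30), noise_rms = 5, seed = 9)
  pb <- make_pre_dataset(c(A = 20, B = 30), noise_rms = 5, seed = 9)
  expect_identical(pa$para$intensity, pb$para$intensity)
})

test_that("dispersion generator: ladders accepted, truth recorded, seeded", {
  expect_silent(make_dispersion_dataset(seed = 1))  # 1.2-10 kHz, 2.5-80 ms
  expect_warning(make_dispersion_dataset(nu1_khz = c(0.01, 1, 2, 5), seed = 1),
                 "plausible")
  s1 <- make_dispersion_dataset(seed = 4)
  s2 <- make_dispersion_dataset(seed = 4)
  expect_identical(s1$points, s2$points)
  expect_equal(s1$truth$r2eff[1],
               20 + 5e5 * 1e4 / (1e4^2 + (2 * pi * 1200)^2))
  flat <- make_dispersion_dataset(exchange = FALSE, seed = 4)
  expect_true(all(flat$truth$r2eff == 20))
})
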