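test_that("ratio and error propagation arithmetic", {
  para <- intensity_table(c("I1", "I2"), c(100, 20), c(5, 2), "para")
  dia <- intensity_table(c("I1", "I2"), c(100, 100), c(5, 5), "dia")
  r <- compute_ratios(para, dia)
  expect_equal(r$ratio, c(1.0, 0.2))
  expect_equal(r$sigma[1], 1.0 * sqrt(2) * 0.05, tolerance = 1e-12)
  expect_equal(r$sigma[2], 0.2 * sqrt(0.01 + 0.0025), tolerance = 1e-12)
  # doubling both noises doubles sigma exactly
  para2 <- intensity_table(c("I1", "I2"), c(100, 20), c(10, 4), "para")
  dia2 <- intensity_table(c("I1", "I2"), c(100, 100), c(10, 10), "dia")
  expect_equal(compute_ratios(para2, dia2)$sigma, 2 * r$sigma)
})

test_that("mismatched residues are dropped and reported; empty overlap errors", {
  para <- intensity_table(c("I1", "I2"), c(10, 20), c(1, 1), "para")
  dia <- intensity_table(c("I2", "I3"), c(10, 20), c(1, 1), "dia")
  r <- compute_ratios(para, dia)
  expect_equal(r$residue_id, "I2")
  expect_setequal(attr(r, "mismatched"), c("I1", "I3"))
  dia2 <- intensity_table("I9", 10, 1, "dia")
  expect_error(compute_ratios(para, dia2), "share no residue")
})

test_that("normalization to the maximum ratio, reference bookkeeping, idempotence", {
  tab <- data.frame(residue_id = c("A", "B", "C"), ratio = c(0.5, 1.25, 1.0),
                    sigma = c(0.05, 0.05, 0.05))
  n <- normalize_to_max(tab)
  expect_equal(n$norm_ratio, c(0.4, 1.0, 0.8))
  expect_equal(attr(n, "reference_residue"), "B")
  expect_equal(n$norm_sigma, n$sigma / 1.25)
  n2 <- normalize_to_max(n)
  expect_equal(n2$norm_ratio, n$norm_ratio)
  one <- normalize_to_max(data.frame(residue_id = "X", ratio = 0.7, sigma = 0.1))
  expect_equal(one$norm_ratio, 1)
})

test_that("z-test matches the normal-CDF oracle and honors the null", {
  # three references with sigma 0.02 * sqrt(3) each -> weighted ref sigma 0.02
  tab <- data.frame(residue_id = c("X", "A", "B", "C"),
                    ratio = c(0.90, 1, 1, 1),
                    sigma = c(0.03, rep(0.02 * sqrt(3), 3)))
  res <- compare_attenuation(tab, "X", c("A", "B", "C"))
  z_oracle <- 0.10 / sqrt(0.02^2 + 0.03^2)
  expect_equal(res$z, z_oracle, tolerance = 1e-9)
  expect_equal(res$p, pnorm(-z_oracle), tolerance = 1e-12)
  expect_true(res$significant_05 && res$significant_01)
  # null case: residue equal to reference mean
  tab$ratio[1] <- 1
  null <- compare_attenuation(tab, "X", c("A", "B", "C"))
  expect_equal(null$z, 0)
  expect_equal(null$p, 0.5)
  expect_false(null$significant_05)
  expect_error(compare_attenuation(tab, "A", c("A", "B")), "references")
})

test_that("z statistic is invariant under max-normalization and rescaling", {
  set.seed(2)
  ip <- rnorm(4, 1000, 10); id <- rnorm(4, 1000, 10)
  para <- intensity_table(paste0("I", 1:4), ip, rep(10, 4), "para")
  dia <- intensity_table(paste0("I", 1:4), id, rep(10, 4), "dia")
  raw <- compute_ratios(para, dia)
  norm <- normalize_to_max(raw)
  z_raw <- compare_attenuation(raw, "I1", c("I2", "I3", "I4"))$z
  z_norm <- compare_attenuation(norm, "I1", c("I2", "I3", "I4"))$z
  expect_equal(z_raw, z_norm, tolerance = 1e-12)
  # scaling one table's intensities and noises leaves the normalized table unchanged
  para_scaled <- intensity_table(paste0("I", 1:4), 3.7 * ip, 3.7 * rep(10, 4), "para")
  norm2 <- normalize_to_max(compute_ratios(para_scaled, dia))
  expect_equal(norm2$norm_ratio, norm$norm_ratio, tolerance = 1e-12)
  expect_equal(norm2$norm_sigma, norm$norm_sigma, tolerance = 1e-12)
})

test_that("classification against predicted distances, with merged peaks", {
  tab <- data.frame(residue_id = c("I10", "I40a", "I40b", "I252+I420"),
                    ratio = c(0.2, 0.95, 0.4, 0.55), sigma = rep(0.02, 4))
  tab <- normalize_to_max(tab)
  dists <- c(I10 = 12, I40a = 40, I40b = 40, I252 = 12, I420 = 32)
  cls <- classify_against_structure(tab, dists)
  expect_equal(cls$expected,
               c("attenuated", "unaffected", "unaffected", "attenuated"))
  # close residue bleached: concordant; distant residue quiet: concordant;
  # distant residue attenuated: the discordant minor-conformer candidate
  expect_true(cls$concordant[cls$residue_id == "I10"])
  expect_true(cls$concordant[cls$residue_id == "I40a"])
  expect_false(cls$concordant[cls$residue_id == "I40b"])
  # merged peak uses the minimum of the component distances (12 A)
  expect_equal(cls$distance_A[cls$residue_id == "I252+I420"], 12)
  expect_error(classify_against_structure(tab, dists[-1]), "I10")
})

test_that("zero-noise synthetic PRE with unequal scales round-trips the truth", {
  pre <- make_pre_dataset(c(I8 = 8, I12 = 12, I16 = 16, I20 = 20, I24 = 24,
                            I30 = 30, I35 = 35, I40 = 40, I45 = 45),
                          scale_para = 1.3, scale_dia = 0.9, noise_rms = 0,
                          seed = 1)
  ratios <- normalize_to_max(compute_ratios(pre$para, pre$dia))
  # raw ratios carry the scale offset; normalization removes it
  expect_equal(max(compute_ratios(pre$para, pre$dia)$ratio),
               1.3 / 0.9 * max(pre$truth$true_ratio), tolerance = 1e-6)
  expect_equal(ratios$norm_ratio[match(pre$truth$residue_id, ratios$residue_id)],
               pre$truth$true_norm_ratio, tolerance = 1e-6)
  cls <- classify_against_structure(
    ratios, setNames(pre$truth$distance_A, pre$truth$residue_id))
  expect_true(all(cls$concordant))
  expect_equal(cls$observed[match(pre$truth$residue_id, cls$residue_id)],
               pre$truth$expected)
})
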