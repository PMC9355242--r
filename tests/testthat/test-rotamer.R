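test_that("R1 conformers reproduce the template internal geometry", {
  s <- make_toy_structure("exposed-helix")
  e <- generate_ensemble(s, "A:8", n = 20, seed = 3)
  tmpl <- r1_template_geometry()
  cb <- spinsight:::atom_xyz(substitute_to_cys(s, "A", 8), "A", 8, "CB")
  for (conf in e$conformers[1:5]) {
    pos <- rbind(CB = cb, conf)
    for (i in seq_len(nrow(tmpl))) {
      ref <- tmpl$ref3[i]  # the atom the new one bonds to
      if (!ref %in% rownames(pos)) next
      d <- sqrt(sum((pos[tmpl$atom[i], ] - pos[ref, ])^2))
      expect_equal(d, tmpl$bond[i], tolerance = 0.01)
    }
    # paramagnetic center is the N-O bond midpoint
    mid <- (conf["N1", ] + conf["O1", ]) / 2
    expect_equal(unname(e$midpoints[match(list(conf), e$conformers), ]),
                 unname(mid))
  }
})

test_that("accepted conformers pass an independent brute-force clash re-check", {
  s <- make_toy_structure("exposed-helix")
  e <- generate_ensemble(s, "A:8", n = 30, seed = 5)
  sub <- substitute_to_cys(s, "A", 8)
  env <- spinsight:::heavy_atoms(sub)
  env <- env[!(env$chain == "A" & env$resno == 8), ]
  env_xyz <- as.matrix(env[, c("x", "y", "z")])
  for (conf in e$conformers) {
    dmin <- min(apply(conf, 1, function(p)
      min(sqrt(rowSums(sweep(env_xyz, 2, p)^2)))))
    expect_gte(dmin, 2.5)
  }
})

test_that("exposed site fills the request; buried cage errors; determinism holds", {
  s <- make_toy_structure("exposed-helix")
  e <- generate_ensemble(s, "A:8", n = 40, seed = 11)
  expect_length(e$conformers, 40)
  expect_gte(e$n_attempted, 40)

  cage <- make_toy_structure("buried-cage")
  expect_error(generate_ensemble(cage, "C:3", n = 5, seed = 1), "buried")

  e1 <- generate_ensemble(s, "A:8", n = 25, seed = 42)
  e2 <- generate_ensemble(s, "A:8", n = 25, seed = 42)
  expect_identical(e1$conformers, e2$conformers)
  expect_identical(e1$midpoints, e2$midpoints)
})

test_that("growing n with a fixed seed only appends conformers (prefix property)", {
  s <- make_toy_structure("exposed-helix")
  small <- generate_ensemble(s, "A:8", n = 15, seed = 9)
  big <- generate_ensemble(s, "A:8", n = 45, seed = 9)
  expect_identical(big$conformers[seq_along(small$conformers)], small$conformers)
})

test_that("mean_label_position averages the paramagnetic centers", {
  e1 <- fake_single_conformer_ensemble(c(1, 2, 3))
  expect_equal(mean_label_position(e1), c(1, 2, 3))
  e2 <- e1
  e2$midpoints <- rbind(c(0, 0, 0), c(2, 0, 0))
  e2$conformers <- c(e2$conformers, e2$conformers)
  expect_equal(mean_label_position(e2), c(1, 0, 0))
  e0 <- e1; e0$conformers <- list()
  expect_error(mean_label_position(e0), "empty")
})

test_that("label_to_atom_distances reports sorted per-residue distances", {
  at <- data.frame(serial = 1:3,
                   name = c("CD1", "CD1", "CA"),
                   resname = c("ILE", "ILE", "ALA"),
                   chain = "A", resno = c(12, 4, 1),
                   x = c(10, 0, 1), y = c(0, 6, 1), z = c(0, 8, 1),
                   element = "C")
  s <- spin_structure(at)
  e <- fake_single_conformer_ensemble(c(0, 0, 0))
  d <- label_to_atom_distances(e, s, "ILE:CD1")
  expect_equal(d$resno, c(4, 12))            # sorted by residue number
  expect_equal(d$distance_A, c(10, 10))      # 6-8-10 triangle and straight 10
  expect_equal(d$residue_id, c("I4", "I12"))
  expect_error(label_to_atom_distances(e, s, "TRP:NE1"), "matches no atom")
})

test_that("interlabel distribution: delta pair, normalization, symmetry", {
  a <- fake_single_conformer_ensemble(c(0, 0, 0))
  b <- fake_single_conformer_ensemble(c(40, 0, 0))
  pd <- interlabel_distribution(a, b)
  expect_equal(find_modes(pd), 4.0)
  dr <- mean(diff(pd$r))
  expect_equal(sum(pd$p) * dr, 1, tolerance = 1e-9)

  s <- make_toy_structure("two-site-scaffold")
  e1 <- generate_ensemble(s, "A:5", n = 60, seed = 1)
  e2 <- generate_ensemble(s, "B:105", n = 60, seed = 2)
  p12 <- interlabel_distribution(e1, e2)
  p21 <- interlabel_distribution(e2, e1)
  expect_equal(p12$p, p21$p)
  # mean of distribution equals mean pairwise distance within the grid step
  pw <- mean(spinsight:::cross_dist(e1$midpoints, e2$midpoints)) / 10
  expect_equal(distribution_mean(p12), pw, tolerance = 0.02)
  # grid not spanning the distances is a range error reporting the range
  expect_error(interlabel_distribution(e1, e2, r_grid = seq(1, 2, 0.02)),
               "does not span")
})
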