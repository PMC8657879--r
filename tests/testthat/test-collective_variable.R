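test_that("switching function hits its anchor values", {
  p <- switching_params()
  expect_equal(rcs_rel(7.273, p), 1.0)
  expect_equal(round(rcs_rel(6.516, p), 2), 0.24)   # ideal pi-helix residue
  expect_equal(round(rcs_rel(7.523, p), 2), 0.74)   # ideal 3-10 helix
  expect_equal(rcs_rel(7.273 + 0.421, p), 0.5)      # |x| = 1 limit m/n
  expect_equal(rcs_rel(7.273 - 0.421, p), 0.5)
})

test_that("rational form and simplified form agree; limit is continuous", {
  p <- switching_params()
  xs <- seq(-6, 6, by = 0.01)
  simplified <- rcs_rel(p$ref + xs * p$tol, p)
  generic <- (1 - xs^2) / (1 - xs^4)
  generic[abs(abs(xs) - 1) < 1e-12] <- 0.5
  expect_lt(max(abs(simplified - generic)), 1e-12)

  # general even exponents: value at |x| = 1 is m/n and continuous
  p48 <- switching_params(m = 4, n = 8)
  expect_equal(rcs_rel(p48$ref + p48$tol, p48), 0.5)
  expect_equal(rcs_rel(p48$ref + (1 + 1e-8) * p48$tol, p48), 0.5,
               tolerance = 1e-6)
  expect_error(switching_params(m = 3, n = 4), "even")
  expect_error(switching_params(m = 4, n = 2), "m < n")
  expect_error(switching_params(tol = 0), "tol")
})

test_that("switching function is bounded, peaked at the reference, and
           monotone in the tolerance", {
  p <- switching_params()
  rcs <- seq(0, 12, by = 0.05)
  v <- rcs_rel(rcs, p)
  expect_true(all(v > 0 & v <= 1))
  expect_equal(rcs[which.max(v)], p$ref, tolerance = 0.05)
  dev <- abs(rcs - p$ref)
  ord <- order(dev)
  expect_true(all(diff(v[ord]) <= 1e-12))   # decreasing in |x|

  loose <- switching_params(tol = 1.0)
  off_ref <- rcs[abs(rcs - p$ref) > 1e-9]
  expect_true(all(rcs_rel(off_ref, loose) > rcs_rel(off_ref, p)))
})

test_that("ideal-motif table reproduces the per-category scores", {
  tab <- ideal_motif_table()
  expect_equal(tab$category,
               c("H", "G", "I", "E", "B", "T", "S", "P", "C"))
  expect_equal(tab$scs_display,
               c(1.00, 0.74, 0.24, 0.01, 0.01, 0.59, 0.03, 0.01, 0.01))
  expect_equal(tab$scs[tab$category == "H"], 1.0)  # reference = H mean
})

test_that("segment means average the per-residue scores", {
  p <- switching_params()
  seg <- segment_definition("s", 1, 2)
  # rcs at x = 2 scores 0.2, at x = 0.5 scores 0.8 -> mean 0.5
  prof <- fake_profile(1:2, p$ref + c(2, 0.5) * p$tol)
  expect_equal(scs_rel(prof, seg), 0.5, tolerance = 1e-12)

  # ideal T and S motifs under the helical reference
  expect_equal(round(scs_rel(fake_profile(1:4, rep(6.923, 4)),
                             segment_definition("t", 1, 4)), 2), 0.59)
  expect_equal(round(scs_rel(fake_profile(1:4, rep(4.850, 4)),
                             segment_definition("s", 1, 4)), 2), 0.03)

  expect_error(scs_rel(fake_profile(1:3, c(7, NA, 7)),
                       segment_definition("x", 1, 3)), "undefined")
  expect_error(scs_rel(prof, segment_definition("y", 5, 8)),
               "not fully resolvable|matches no residues")
})

test_that("reference modes build the documented per-residue parameters", {
  prof <- fake_profile(1:8, c(NA, 7.1, 7.3, 7.5, 5.0, 3.1, 3.3, NA))
  seg <- segment_definition("seg", 2, 7)

  rm_mean <- make_reference("segment_mean", seg, reference_profile = prof)
  expect_equal(unique(rm_mean$ref), mean(c(7.1, 7.3, 7.5, 5.0, 3.1, 3.3)))
  expect_equal(unique(rm_mean$tol), 1.0)

  rm_res <- make_reference("per_residue", seg, reference_profile = prof)
  expect_equal(rm_res$ref, c(7.1, 7.3, 7.5, 5.0, 3.1, 3.3))
  # a frame identical to the reference scores exactly 1
  expect_equal(scs_rel(prof, rm_res), 1.0)

  rm_hel <- make_reference("helicality", seg)
  expect_equal(unique(rm_hel$ref), 7.273)
  expect_equal(unique(rm_hel$tol), 0.421)

  labs <- data.frame(chain = "A", resno = 2:7,
                     label = c("H", "H", "G", "S", "E", "E"))
  rm_cat <- make_reference("category", seg, labels = labs)
  expect_equal(rm_cat$ref, c(7.273, 7.273, 7.523, 4.850, 2.730, 2.730))
  expect_equal(unique(rm_cat$tol), 1.0)
  rm_sd <- make_reference("category", seg, labels = labs, tol = "sd")
  expect_equal(rm_sd$tol, c(0.421, 0.421, 0.840, 2.166, 0.966, 0.966))

  expect_error(make_reference("category", seg), "labels")
  expect_error(make_reference("segment_mean", seg), "reference profile")
  expect_error(make_reference("per_residue",
                              segment_definition("z", 1, 3),
                              reference_profile = prof), "undefined")
})

test_that("CV time series over a trajectory behaves deterministically", {
  ref_chain <- build_backbone(ideal_helix_spec(10))
  f <- tempfile(fileext = ".pdb")
  write_backbone_pdb(list(ref_chain, ref_chain, ref_chain), f)
  # reference profile from the file itself, so frames match it exactly
  ref_prof <- rcs_profile(parse_structure(f)[[1]])
  seg <- segment_definition("s1", 2, 9)
  ref <- make_reference("per_residue", seg, reference_profile = ref_prof)

  # identical frames: constant series of exactly 1
  ser <- cv_timeseries(f, ref)
  expect_equal(nrow(ser), 3L)
  expect_equal(ser$scs, rep(1, 3))
  expect_false(any(ser$flagged))

  # single-frame trajectory
  f1 <- tempfile(fileext = ".pdb")
  write_backbone_pdb(ref_chain, f1)
  expect_equal(nrow(cv_timeseries(f1, ref)), 1L)

  # segment spanning a terminus gets flagged, not silently averaged
  bad <- make_reference("helicality", segment_definition("t", 1, 5))
  ser_bad <- cv_timeseries(f1, bad)
  expect_true(ser_bad$flagged)
  expect_true(is.na(ser_bad$scs))
})

test_that("two-state trajectories give a bimodal CV near theoretical modes", {
  # states at characteristic alpha-helix and extended-strand angles
  traj <- two_state_cv_trajectory(
    120,
    state_a = list(phi = -64.70, psi = -39.56, sd = 2),
    state_b = list(phi = -110.89, psi = 122.38, sd = 2),
    switch_prob = 0.1, n_res = 10, seed = 21)
  f <- tempfile(fileext = ".pdb")
  write_trajectory_pdb(traj, f)
  seg <- segment_definition("s", 2, 9)
  ser <- cv_timeseries(f, make_reference("helicality", seg))
  expect_false(any(ser$flagged))

  theo_a <- rcs_rel(constant_angle_rcs(-64.70, -39.56))
  theo_b <- rcs_rel(constant_angle_rcs(-110.89, 122.38))
  expect_gt(theo_a - theo_b, 0.3)       # well-separated modes
  mean_a <- mean(ser$scs[traj$states == 1])
  mean_b <- mean(ser$scs[traj$states == 2])
  expect_lt(abs(mean_a - theo_a), 0.15)
  expect_lt(abs(mean_b - theo_b), 0.15)
  # histogram is bimodal: hardly any frames between the modes
  mid <- (theo_a + theo_b) / 2
  gap <- mean(ser$scs > mid - 0.07 & ser$scs < mid + 0.07)
  expect_lt(gap, 0.15)
})
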