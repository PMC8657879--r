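test_that("adjacency matrix has the documented size, diagonal and order", {
  sp <- internal_coords(rep(180, 3), rep(180, 3), rep(180, 3))
  A <- build_adjacency(sp)
  expect_equal(A$size, 6L)
  expect_equal(A$diag, rep(-1, 6))
  m <- as.matrix(A)
  expect_true(isSymmetric(m))
  expect_equal(m[cbind(1:5, 2:6)], rep(1, 5))

  sp90 <- internal_coords(rep(90, 3), rep(90, 3), rep(90, 3))
  expect_equal(build_adjacency(sp90)$diag, rep(0, 6))

  # vertex 3(k-1) must carry cos(phi_k), vertex 3(k-1)+1 cos(psi_k)
  sp2 <- internal_coords(phi = c(NA, 10, 20, 30), psi = c(40, 50, 60, NA),
                         omega = c(70, 80, 90, NA))
  A2 <- build_adjacency(sp2)
  k <- 2:3
  expect_equal(A2$diag[3 * (k - 1)], cos(c(10, 20) * pi / 180))
  expect_equal(A2$diag[3 * (k - 1) + 1], cos(c(50, 60) * pi / 180))
  expect_error(build_adjacency(internal_coords(c(NA, NA, 3), rep(1, 3),
                                               rep(2, 3))), "undefined")
})

test_that("centralities match closed forms and the expm oracle", {
  expect_equal(centralities(matrix(c(0, 1, 1, 0), 2)),
               rep(cosh(1), 2), tolerance = 1e-12)
  expect_equal(centralities(matrix(0.37)), exp(0.37), tolerance = 1e-14)

  skip_if_not_installed("Matrix")
  set.seed(5)
  for (n in c(4, 7, 12, 21, 30)) {
    m <- diag(runif(n, -1, 1))
    idx <- seq_len(n - 1)
    m[cbind(idx, idx + 1)] <- 1
    m[cbind(idx + 1, idx)] <- 1
    oracle <- diag(as.matrix(Matrix::expm(Matrix::Matrix(m))))
    expect_lt(max(abs(centralities(m) - oracle)), 1e-8)
  }
})

test_that("full-method profile has the documented structure", {
  sp <- random_dihedrals(3, 1, seed = 2)[[1]]
  fit <- rcs_full(sp)
  expect_equal(sum(!is.na(fit$rcs)), 1L)      # only k = 2 defined
  expect_true(is.na(fit$rcs[1]) && is.na(fit$rcs[3]))
  expect_equal(fit$mean_cs, mean(fit$cs), tolerance = 1e-12)
  expect_true(all(fit$cs > 0))
})

test_that("4x4 block matches its expm oracle and is even in the angles", {
  skip_if_not_installed("Matrix")
  m <- diag(c(-1, 0, 0, -1))
  m[cbind(1:3, 2:4)] <- 1
  m[cbind(2:4, 1:3)] <- 1
  oracle <- sum(diag(as.matrix(Matrix::expm(Matrix::Matrix(m))))[2:3])
  expect_lt(abs(rcs_block(90, 90, 180, 180) - oracle), 1e-10)

  v <- rcs_block(-64.7, -39.56, 179, -178)
  expect_identical(rcs_block(64.7, 39.56, -179, 178), v)  # cosine is even
  expect_error(rcs_block(NA, 0, 180, 180), "undefined")
})

test_that("local-window RCS stays within 1% of the full calculation", {
  # ideal helix at the characteristic alpha-helical angles
  helix <- internal_coords(rep(-64.70, 20), rep(-39.56, 20), rep(180, 20))
  full <- rcs_full(helix)$rcs
  blk <- rcs_local(helix)$rcs
  expect_lt(max(abs(blk - full) / full, na.rm = TRUE), 0.01)

  # random-angle ensemble (the harsh case)
  sets <- random_dihedrals(30, 20, seed = 11)
  for (s in sets) {
    f <- rcs_full(s)$rcs
    b <- rcs_local(s)$rcs
    expect_lt(max(abs(b - f) / f, na.rm = TRUE), 0.01)
    expect_true(all(b[!is.na(b)] > 0))
    expect_true(all(f[!is.na(f)] > 0))
  }

  # the strict 4x4 window is coarser but stays within a few percent
  devs4 <- vapply(sets, function(s) {
    max(abs(rcs_local(s, window = 1)$rcs - rcs_full(s)$rcs) /
          rcs_full(s)$rcs, na.rm = TRUE)
  }, numeric(1))
  expect_lt(max(devs4), 0.05)
  expect_gt(max(devs4), max(vapply(sets, function(s)
    max(abs(rcs_local(s)$rcs - rcs_full(s)$rcs) / rcs_full(s)$rcs,
        na.rm = TRUE), numeric(1))))
})

test_that("RCS is invariant under sign flips of any angle subset", {
  set.seed(13)
  sp <- random_dihedrals(8, 1, seed = 13)[[1]]
  base <- rcs_local(sp)$rcs
  for (i in 1:5) {
    flip <- sp
    cols <- sample(c("phi", "psi", "omega"), sample(1:3, 1))
    for (cc in cols) flip[[cc]] <- -flip[[cc]]
    expect_identical(rcs_local(flip)$rcs, base)
  }
})

test_that("chain profiles leave termini undefined and methods agree", {
  ch <- helix_chain(12)
  pb <- rcs_profile(ch, "block")
  pf <- rcs_profile(ch, "full")
  expect_s3_class(pb, "folding_profile")
  expect_true(all(is.na(pb$rcs[c(1, 12)])))
  expect_false(anyNA(pb$rcs[2:11]))
  ok <- !is.na(pb$rcs)
  expect_lt(max(abs(pb$rcs[ok] - pf$rcs[ok]) / pf$rcs[ok]), 0.01)
  expect_true(is.na(attr(pb, "mean_cs")))
  expect_gt(attr(pf, "mean_cs"), 0)
  # chains too short for any interior residue: all-NA profile
  p2 <- rcs_profile(helix_chain(2))
  expect_true(all(is.na(p2$rcs)))
})

test_that("block-method cost grows linearly in residue count", {
  # operation-count proxy: the block path solves one fixed-size window per
  # interior residue, so defined values scale linearly and even long
  # chains stay cheap
  p100 <- rcs_profile(helix_chain(100), "block")
  p200 <- rcs_profile(helix_chain(200), "block")
  expect_equal(sum(!is.na(p100$rcs)), 98L)
  expect_equal(sum(!is.na(p200$rcs)) - sum(!is.na(p100$rcs)), 100L)
})

test_that("theoretical surface obeys symmetry, counting and argmax", {
  expect_error(theoretical_surface(0), "positive")
  s <- theoretical_surface(90)
  expect_equal(dim(s$rcs), c(4L, 4L))
  expect_equal(s$phi, c(-180, -90, 0, 90))

  # RCS(phi, psi) = RCS(-phi, -psi) = RCS(-phi, psi) = RCS(phi, -psi)
  for (ang in list(c(30, 75), c(-120, 45), c(160, -10))) {
    v <- rcs_block(ang[1], ang[2], 180, 180)
    expect_identical(rcs_block(-ang[1], -ang[2], 180, 180), v)
    expect_identical(rcs_block(-ang[1], ang[2], 180, 180), v)
    expect_identical(rcs_block(ang[1], -ang[2], 180, 180), v)
  }

  s45 <- theoretical_surface(45)
  peak <- which(s45$rcs == max(s45$rcs), arr.ind = TRUE)
  expect_equal(unname(s45$phi[peak[1, 1]]), 0)   # maximum at phi = psi = 0
  expect_equal(unname(s45$psi[peak[1, 2]]), 0)

  f <- tempfile(fileext = ".csv")
  write_surface_csv(s, f)
  back <- read.table(f, sep = ",", header = TRUE, check.names = FALSE)
  expect_equal(as.numeric(back[2, -1]), s$rcs[2, ], tolerance = 1e-12)
})
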