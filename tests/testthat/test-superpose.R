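test_that("kabsch_fit handles identity, pure translation and degenerate input", {
  set.seed(1)
  p <- matrix(rnorm(30), 10, 3)
  fit <- kabsch_fit(p, p)
  expect_equal(fit$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit$rotation, diag(3), tolerance = 1e-8)

  q <- sweep(p, 2, c(5, 0, 0), `+`)
  fit2 <- kabsch_fit(p, q)
  expect_equal(fit2$rmsd, 0, tolerance = 1e-10)
  expect_equal(fit2$rotation, diag(3), tolerance = 1e-8)
  expect_equal(fit2$translation, c(5, 0, 0), tolerance = 1e-8)

  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_fit(line, line), "collinear")
  expect_error(kabsch_fit(p[1:2, ], p[1:2, ]), "at least 3")
})

test_that("kabsch rotations are proper and orthonormal, and reflections are excluded", {
  set.seed(2)
  for (i in 1:5) {
    p <- matrix(rnorm(30), 10, 3)
    q <- matrix(rnorm(30), 10, 3)
    R <- kabsch_fit(p, q)$rotation
    expect_equal(t(R) %*% R, diag(3), tolerance = 1e-8)
    expect_equal(det(R), 1, tolerance = 1e-8)
  }
  ## a mirrored cloud must still map through a proper rotation
  p <- matrix(rnorm(30), 10, 3)
  q <- p %*% diag(c(-1, 1, 1))
  fit <- kabsch_fit(p, q)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-8)
  expect_gt(fit$rmsd, 0.1)
})

test_that("kabsch matches a brute-force rotational optimizer on random clouds", {
  set.seed(3)
  for (i in 1:5) {
    p <- matrix(rnorm(30, sd = 4), 10, 3)
    q <- matrix(rnorm(30, sd = 4), 10, 3)
    analytic <- kabsch_fit(p, q)$rmsd
    numeric <- bruteforce_min_rmsd(p, q)
    expect_lt(abs(analytic - numeric), 1e-6)
    expect_lte(analytic, numeric + 1e-9)  # closed form is the true minimum
  }
})

test_that("weighted fits prioritize the heavily weighted points", {
  set.seed(4)
  p <- matrix(rnorm(18), 6, 3)
  tr <- rigid_transform(rotation_about_axis(c(1, 0, 2), 0.9), c(3, -1, 2))
  q <- apply_transform(p, tr)
  q[6, ] <- q[6, ] + c(4, 4, 4)   # one corrupted pair
  w <- c(rep(1, 5), 1e-6)
  fit <- kabsch_fit(p, q, weights = w)
  fitted <- apply_transform(p, rigid_transform(fit$rotation, fit$translation))
  expect_lt(max(sqrt(rowSums((fitted[1:5, ] - q[1:5, ])^2))), 1e-3)
  ## unweighted, the corrupted pair distorts the fit
  fit0 <- kabsch_fit(p, q)
  fitted0 <- apply_transform(p, rigid_transform(fit0$rotation, fit0$translation))
  expect_gt(max(sqrt(rowSums((fitted0[1:5, ] - q[1:5, ])^2))), 0.1)
})

test_that("RMSD is invariant under rigid transforms and consistent across rigid copies", {
  pent <- fixture_pentamer()
  aln <- fixture_alignment()
  a <- pent$structure
  b <- perturb_state(pent, noise_sd = 0.2, seed = 4)$structure
  corr <- alignment_correspondence(aln, "A", "A", a, "A", b, "A")
  base_rmsd <- superpose_subset(a, b, corr)$rmsd

  a2 <- apply_random_rigid(a, seed = 21)
  b2 <- apply_random_rigid(b, seed = 22)
  corr2 <- alignment_correspondence(aln, "A", "A", a2, "A", b2, "A")
  expect_equal(superpose_subset(a2, b2, corr2)$rmsd, base_rmsd,
               tolerance = 1e-8)

  ## three rigid copies of one structure: all pairwise RMSDs vanish
  copies <- list(c1 = a, c2 = apply_random_rigid(a, 31),
                 c3 = apply_random_rigid(a, 32))
  m <- pairwise_rmsd(copies, mode = "alignment", aln = aln)
  expect_lt(max(m$matrix), 1e-6)
})

test_that("a planted ECD twist leaves the TMD subset unmoved", {
  pent <- fixture_pentamer()
  aln <- fixture_alignment()
  st <- perturb_state(pent, twist = 10, seed = 5)$structure
  corr <- alignment_correspondence(aln, "A", "A", pent$structure, "A", st, "A")
  truth <- pent$truth
  tmd <- plgicmap:::truth_keys(truth, "A")[truth$domain == "TMD"]
  ecd <- plgicmap:::truth_keys(truth, "A")[truth$domain == "ECD"]
  expect_lt(superpose_subset(pent$structure, st, corr, tmd, "TMD")$rmsd, 1e-6)
  expect_lt(superpose_subset(pent$structure, st, corr, ecd, "ECD")$rmsd, 1e-6)
  whole <- superpose_subset(pent$structure, st, corr)$rmsd
  expect_gt(whole, 0.5)
})

test_that("domain-wise RMSD never exceeds the whole-subunit RMSD", {
  pent <- fixture_pentamer()
  aln <- fixture_alignment()
  st <- perturb_state(pent, twist = 8, tilt = 3, noise_sd = 0.15, seed = 6)$structure
  corr <- alignment_correspondence(aln, "A", "A", pent$structure, "A", st, "A")
  truth <- pent$truth
  whole <- superpose_subset(pent$structure, st, corr)$rmsd
  for (dom in c("ECD", "TMD")) {
    keys <- plgicmap:::truth_keys(truth, "A")[truth$domain == dom]
    expect_lte(superpose_subset(pent$structure, st, corr, keys, dom)$rmsd,
               whole + 1e-9)
  }
})

test_that("pentamer-mode RMSD minimizes over cyclic assignments and never exceeds fixed order", {
  pent <- fixture_pentamer()
  aln <- fixture_alignment()
  st <- perturb_state(pent, twist = 6, noise_sd = 0.1, seed = 7)$structure
  pair <- list(a = pent$structure, b = st)
  fixed <- pairwise_rmsd(pair, mode = "alignment", aln = aln,
                         pentamer_mode = FALSE, chains = LETTERS[1:5])$matrix[1, 2]
  cyc <- pairwise_rmsd(pair, mode = "alignment", aln = aln,
                       pentamer_mode = TRUE)$matrix[1, 2]
  expect_lte(cyc, fixed + 1e-9)

  ## within-state entries stay below between-state entries
  ens <- list(
    a1 = pent$structure,
    a2 = perturb_state(pent, noise_sd = 0.1, seed = 8)$structure,
    b1 = perturb_state(pent, twist = 20, tilt = 6, noise_sd = 0.1, seed = 9)$structure,
    b2 = perturb_state(pent, twist = 20, tilt = 6, noise_sd = 0.1, seed = 10)$structure
  )
  m <- pairwise_rmsd(ens, mode = "alignment", aln = aln, pentamer_mode = TRUE)$matrix
  within <- c(m["a1", "a2"], m["b1", "b2"])
  between <- c(m["a1", "b1"], m["a1", "b2"], m["a2", "b1"], m["a2", "b2"])
  expect_lt(max(within), min(between))
})

test_that("an unmatchable pair is flagged missing while the matrix is still returned", {
  pent <- fixture_pentamer()
  aln <- fixture_alignment()
  tiny <- plgicmap:::new_structure("TINY", pent$structure$atoms[1:8, ])
  m <- pairwise_rmsd(list(a = pent$structure, b = pent$structure, bad = tiny),
                     mode = "alignment", aln = aln)
  expect_true(is.na(m$matrix["a", "bad"]))
  expect_equal(m$matrix["a", "b"], 0, tolerance = 1e-8)
})

test_that("domain motion recovers planted twist and tilt within half a degree", {
  pent <- fixture_pentamer()
  aln <- fixture_alignment()
  truth <- pent$truth
  ecd <- plgicmap:::truth_keys(truth, "A")[truth$domain == "ECD"]
  tmd <- plgicmap:::truth_keys(truth, "A")[truth$domain == "TMD"]

  same <- alignment_correspondence(aln, "A", "A", pent$structure, "A",
                                   pent$structure, "A")
  dm0 <- domain_motion(pent$structure, pent$structure, same, ecd, tmd)
  expect_true(dm0$degenerate)
  expect_equal(dm0$twist, 0)
  expect_equal(dm0$tilt, 0)

  st <- perturb_state(pent, twist = 5, seed = 12)$structure
  corr <- alignment_correspondence(aln, "A", "A", pent$structure, "A", st, "A")
  dm <- domain_motion(pent$structure, st, corr, ecd, tmd)
  expect_equal(dm$twist, 5, tolerance = 0.5)
  expect_lt(dm$tilt, 0.5)

  st2 <- perturb_state(pent, tilt = 6, seed = 13)$structure
  corr2 <- alignment_correspondence(aln, "A", "A", pent$structure, "A", st2, "A")
  dm2 <- domain_motion(pent$structure, st2, corr2, ecd, tmd)
  expect_equal(dm2$tilt, 6, tolerance = 0.5)
  expect_lt(dm2$twist, 0.5)
})

test_that("per-domain residual RMSDs stay below the whole-subunit RMSD for a twisted pair", {
  pent <- fixture_pentamer()
  aln <- fixture_alignment()
  truth <- pent$truth
  st <- perturb_state(pent, twist = 12, tilt = 4, noise_sd = 0.1, seed = 14)$structure
  corr <- alignment_correspondence(aln, "A", "A", pent$structure, "A", st, "A")
  ecd <- plgicmap:::truth_keys(truth, "A")[truth$domain == "ECD"]
  tmd <- plgicmap:::truth_keys(truth, "A")[truth$domain == "TMD"]
  dm <- domain_motion(pent$structure, st, corr, ecd, tmd)
  whole <- superpose_subset(pent$structure, st, corr)$rmsd
  expect_lt(dm$residual_rmsd_ecd, whole)
  expect_lt(dm$residual_rmsd_tmd, whole)
})
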