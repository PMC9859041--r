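test_that("pseudo-symmetry transform recovers exact C2 symmetry", {
  withr::local_seed(21)
  p <- random_points(6)
  rx <- rotation_about_axis(c(0, 0, 1), pi)
  q <- p %*% t(rx)
  sym <- pseudo_symmetry_transform(p, q)
  expect_lt(sym$rmsd, 1e-9)
  expect_equal(abs(sym$axis[3]), 1, tolerance = 1e-8)
  expect_equal(sym$angle, pi, tolerance = 1e-8)
})

test_that("pseudo-symmetry transform matches the quaternion oracle", {
  withr::local_seed(22)
  for (rep in 1:20) {
    a <- random_points(6); b <- random_points(6)
    sym <- pseudo_symmetry_transform(a, b)
    oracle <- quaternion_superpose_oracle(rbind(b, a), rbind(a, b))
    expect_lt(max(abs(sym$transform$R - oracle$R)), 1e-8)
    expect_lt(max(abs(sym$transform$t - oracle$t)), 1e-8)
  }
})

test_that("noisy symmetric sets keep a near-180-degree rotation", {
  withr::local_seed(23)
  angs <- replicate(50, {
    p <- random_points(6)
    q <- p %*% t(rotation_about_axis(c(0, 0, 1), pi)) +
      matrix(rnorm(18, 0, 0.1), 6, 3)
    pseudo_symmetry_transform(p, q)$angle
  })
  expect_true(all(abs(angs - pi) < 2 * pi / 180))
})

test_that("fixture complex yields identity frames; frames are equivariant", {
  cx <- make_synthetic_complex(synthetic_spec(seed = 24))
  cores <- locate_core_residues(cx)
  fm <- build_mhc_frame(cx, cores)
  expect_lt(max(abs(fm$origin)), 1e-6)
  expect_lt(max(abs(fm$axes - diag(3))), 1e-6)
  withr::local_seed(25)
  for (rep in 1:5) {
    tf <- random_transform()
    moved <- tcrpmhc:::transform_residues(cx, tf)
    fm2 <- build_mhc_frame(moved, cores)
    ft2 <- build_tcr_frame(moved, cores)
    fm_exp <- transform_frame(tf, fm)
    ft_exp <- transform_frame(tf, build_tcr_frame(cx, cores))
    expect_lt(max(abs(fm2$origin - fm_exp$origin)), 1e-8)
    expect_lt(max(abs(fm2$axes - fm_exp$axes)), 1e-8)
    expect_lt(max(abs(ft2$axes - ft_exp$axes)), 1e-8)
  }
})

test_that("MHC frame x-axis flips when the peptide moves to the -x side", {
  cx <- make_synthetic_complex(synthetic_spec(seed = 26))
  cores <- locate_core_residues(cx)
  flipped <- cx
  pep <- flipped$residues$role == "peptide"
  flipped$residues$x[pep] <- -flipped$residues$x[pep]
  f1 <- build_mhc_frame(cx, cores)
  f2 <- build_mhc_frame(flipped, cores)
  expect_equal(f2$axes[, 1], -f1$axes[, 1], tolerance = 1e-8)
})

test_that("swapping the TCR alpha/beta cores negates the z-axis", {
  cx <- make_synthetic_complex(synthetic_spec(seed = 27))
  cores <- locate_core_residues(cx)
  swapped <- core_residue_set(cores$mhc_n_half, cores$mhc_c_half,
                              cores$tcrb_core, cores$tcra_core)
  # swap roles too so the alpha indices address the beta chain
  sw <- cx
  sw$residues$role[sw$residues$role == "tcra"] <- "tmp"
  sw$residues$role[sw$residues$role == "tcrb"] <- "tcra"
  sw$residues$role[sw$residues$role == "tmp"] <- "tcrb"
  f1 <- build_tcr_frame(cx, cores)
  f2 <- build_tcr_frame(sw, cores)
  expect_equal(f2$axes[, 3], -f1$axes[, 3], tolerance = 1e-6)
})

test_that("constructed axial case gives the expected parameters", {
  mhc <- identity_frame()
  tcr <- coordinate_frame(c(30, 0, 0),
                          cbind(c(-1, 0, 0), c(0, 1, 0), c(0, 0, -1)))
  g <- compute_docking_geometry(mhc, tcr)
  expect_equal(g$d, 30)
  expect_equal(g$mhc_unit, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(g$tcr_unit, c(1, 0, 0), tolerance = 1e-12)
  expect_error(compute_docking_geometry(mhc, mhc), "coincident")
})

test_that("geometry chart round-trips and is invariant to global motion", {
  withr::local_seed(28)
  for (rep in 1:200) {
    g <- random_docking_geometry()
    tf <- geometry_to_transform(g)
    g2 <- compute_docking_geometry(identity_frame(), transform_to_frame(tf))
    dv <- geometry_vector(g) - geometry_vector(g2)
    dv[c(2, 4, 6)] <- tcrpmhc:::wrap_angle(dv[c(2, 4, 6)])
    expect_lt(max(abs(dv)), 1e-6)
    # invariance under a shared rigid motion
    glob <- random_transform()
    f_m <- transform_frame(glob, identity_frame())
    f_t <- transform_frame(glob, transform_to_frame(tf))
    g3 <- compute_docking_geometry(f_m, f_t)
    dv3 <- geometry_vector(g) - geometry_vector(g3)
    dv3[c(2, 4, 6)] <- tcrpmhc:::wrap_angle(dv3[c(2, 4, 6)])
    expect_lt(max(abs(dv3)), 1e-8)
  }
})

test_that("distribution fit recovers known parameters and handles wrap", {
  g0 <- consensus_geometry()
  dist0 <- fit_geometry_distribution(rep(list(g0), 10))
  expect_equal(as.numeric(dist0$mean), as.numeric(geometry_vector(g0)),
               tolerance = 1e-9)
  expect_equal(dist0$covariance, 1e-6 * diag(6), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(fit_geometry_distribution(rep(list(g0), 6)), "at least 7")

  withr::local_seed(29)
  mu <- c(29, 0.6, 0.5, 0.3, 0.6, -0.4)
  sd <- c(2, 0.2, 0.1, 0.15, 0.1, 0.15)
  V <- sapply(seq_along(mu), function(j) rnorm(500, mu[j], sd[j]))
  fit <- fit_geometry_distribution(apply(V, 1, vector_to_geometry))
  se <- sd / sqrt(500)
  expect_true(all(abs(fit$mean - mu) < 3.5 * se))

  # torsions straddling +/- pi unwrap to a mean near pi, not 0
  tor <- c(pi - 0.1 + rnorm(10, 0, 0.02), -pi + 0.1 + rnorm(10, 0, 0.02))
  gs <- lapply(tor, function(t) vector_to_geometry(c(29, t, mu[3:6])))
  fit2 <- fit_geometry_distribution(gs)
  expect_gt(abs(fit2$mean[2]), 2.8)
})

test_that("Mahalanobis Z is zero at the mean and scales linearly", {
  withr::local_seed(30)
  gs <- replicate(100, random_docking_geometry(), simplify = FALSE)
  dist <- fit_geometry_distribution(gs)
  expect_equal(mahalanobis_z(vector_to_geometry(dist$mean), dist), 0,
               tolerance = 1e-8)
  dv <- c(1, 0.05, 0.02, 0.03, -0.02, 0.01)
  z1 <- mahalanobis_z(vector_to_geometry(dist$mean + dv), dist)
  z2 <- mahalanobis_z(vector_to_geometry(dist$mean + 2 * dv), dist)
  expect_equal(z2, 2 * z1, tolerance = 1e-6)
})

test_that("Z^2 of in-distribution samples follows chi-squared(6)", {
  withr::local_seed(31)
  # place the distribution well inside the chart (polar angles away from
  # the boundary at 0) so Gaussian samples stay in the chart's domain
  mu <- c(29, 0.6, 0.9, 0.3, 0.8, -0.4)
  sd <- c(2, 0.2, 0.08, 0.15, 0.08, 0.15)
  gs <- lapply(1:200, function(i)
    vector_to_geometry(mu + rnorm(6, 0, sd)))
  dist <- fit_geometry_distribution(gs)
  L <- chol(dist$covariance)
  n <- 10000
  Z <- matrix(rnorm(n * 6), n, 6) %*% L
  V <- sweep(Z, 2, dist$mean, "+")
  z2 <- vapply(seq_len(n), function(i)
    mahalanobis_z(vector_to_geometry(V[i, ]), dist)^2, 0)
  expect_lt(abs(mean(z2) - 6) / 6, 0.05)
  expect_gt(stats::ks.test(z2, stats::pchisq, df = 6)$p.value, 1e-3)
})

test_that("geometry TSV round-trips", {
  withr::local_seed(32)
  gs <- replicate(5, random_docking_geometry(), simplify = FALSE)
  names(gs) <- sprintf("pdb%d", 1:5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_docking_geometries(gs, path, mhc_class = 1)
  gs2 <- read_docking_geometries(path)
  expect_identical(names(gs2), names(gs))
  for (i in 1:5)
    expect_equal(geometry_vector(gs2[[i]]), geometry_vector(gs[[i]]),
                 tolerance = 1e-12)
})
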