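# Shared helpers for the test suite. All fixtures are generated in code.

# Independent superposition oracle: Horn's closed-form quaternion method
# (eigenvector of the 4x4 profile matrix), a different algorithm from the
# package's SVD/Kabsch route.
quaternion_superpose_oracle <- function(fixed, mobile, weights = NULL) {
  n <- nrow(fixed)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cf <- colSums(fixed * w); cm <- colSums(mobile * w)
  A <- sweep(fixed, 2, cf); B <- sweep(mobile, 2, cm)
  M <- t(B * w) %*% A
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy, Szx - Sxz, Sxy - Syx,
    Syz - Szy, Sxx - Syy - Szz, Sxy + Syx, Szx + Sxz,
    Szx - Sxz, Sxy + Syx, -Sxx + Syy - Szz, Syz + Szy,
    Sxy - Syx, Szx + Sxz, Syz + Szy, -Sxx - Syy + Szz), 4, 4)
  q <- eigen(K, symmetric = TRUE)$vectors[, 1]
  w0 <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w0 * z), 2 * (x * z - w0 * y),
    2 * (x * y - w0 * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w0 * x),
    2 * (x * z + w0 * y), 2 * (y * z - w0 * x), 1 - 2 * (x^2 + y^2)), 3, 3)
  t_vec <- cf - as.numeric(R %*% cm)
  list(R = R, t = t_vec)
}

random_points <- function(n, scale = 10) {
  matrix(stats::runif(n * 3, -scale, scale), n, 3)
}

# Small perturbation of a docking geometry in its 6-vector chart.
perturb_geometry <- function(g, sd = 0.05) {
  v <- geometry_vector(g)
  v <- v + stats::rnorm(6, 0, sd * c(10, 1, 1, 1, 1, 1) / 10)
  v[1] <- max(v[1], 1)
  vector_to_geometry(v)
}

# 12 well-separated base geometries (deterministic): vary distance and
# torsion on a grid so inter-cluster docking RMSDs are large.
planted_base_geometries <- function(k = 12) {
  lapply(seq_len(k), function(i) {
    docking_geometry(
      d = 24 + 2 * ((i - 1) %% 4),
      torsion = -pi + (i - 1) * (2 * pi / k) + 0.1,
      mhc_unit = c(cos(0.3 + 0.1 * (i %% 3)),
                   sin(0.3 + 0.1 * (i %% 3)) * cos(i),
                   sin(0.3 + 0.1 * (i %% 3)) * sin(i)),
      tcr_unit = c(cos(0.4), sin(0.4) * cos(i + 1), sin(0.4) * sin(i + 1)))
  })
}

# Template database of synthetic complexes with distinct peptides and CDR3s.
make_template_db <- function(n = 10, seed = 100) {
  peptides <- c("GILGFVFTL", "ELAGIGILT", "NLVPMVATV", "LLWNGPMAV",
                "YLQPRTFLL", "KLGGALQAK", "IVTDFSVIK", "RAKFKQLLQ",
                "SLYNTVATL", "GLCTLVAML", "FLYALALLL", "ALWGPDPAAA")
  cdr3as <- c("CAVSNTGKLI", "CAGQWDMRFG", "CILRDSSYKL", "CAVNRDDKII",
              "CAYRSAQAGG", "CAFMKPFTSG", "CAVEDMNTGF", "CALSEAGGTS",
              "CAMREGRDDK", "CAVRDTNAGK", "CAESIRGFGN", "CAARLNGMWI")
  cdr3bs <- c("CASSIRSSYE", "CASSLAPGAT", "CSARDGTGNG", "CASSYVGNTG",
              "CASRPGLAGG", "CASSFWGSET", "CSVEDRNTGE", "CASSPWGAGG",
              "CASSQDRDTQ", "CASSLSFGTE", "CASNRDRGRY", "CASSDWGSQN")
  withr::with_seed(seed, {
    lapply(seq_len(n), function(i) {
      cx <- make_synthetic_complex(
        synthetic_spec(geometry = perturb_geometry(consensus_geometry(), 0.3),
                       peptide = peptides[(i - 1) %% length(peptides) + 1],
                       cdr3a = cdr3as[(i - 1) %% length(cdr3as) + 1],
                       cdr3b = cdr3bs[(i - 1) %% length(cdr3bs) + 1],
                       seed = seed + i),
        pdb_id = sprintf("synt%02d", i),
        deposit_date = as.Date("2015-01-01") + 90 * i)
      template_record(cx)
    })
  })
}

paired_tcr_from_cdr3 <- function(cdr3a, cdr3b, id = "t",
                                 va = "TRAV-SYN1", vb = "TRBV-SYN1") {
  paired_tcr(tcr_chain(va, cdr3 = cdr3a), tcr_chain(vb, cdr3 = cdr3b),
             id = id)
}
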