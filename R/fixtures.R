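#' Synthetic complexes, PAE matrices and repertoires
#'
#' Generators used to exercise every other module without downloading
#' structures. Complexes are idealized: C-alpha only, exactly C2-symmetric
#' core residue sets, beta-strand-like 3.8 Angstrom spacing, with the TCR
#' placed by an exact docking-geometry transform, so that at zero noise the
#' frame construction recovers the generating geometry to machine
#' precision. PAE matrices are simulated with additive TCR-intrinsic and
#' peptide-intrinsic offsets plus a planted cognate-binding signal.
#'
#' @name fixtures_synthetic
NULL

## Evaluate expr with a locally seeded RNG, restoring the caller's stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

## 6 base points of the MHC groove-floor N-half; the C-half is the exact
## 180-degree rotation about x. Column means: x = 0 and y = 0 (so the core
## COM lies on the symmetry axis and the z-axis is exactly +z), mean z < 0.
mhc_core_base_points <- function() {
  matrix(c(-2.5, -9.0, -5.0,
           -1.5, -5.5, -4.2,
           -0.5, -2.0, -4.8,
            0.5,  2.0, -4.1,
            1.5,  5.5, -4.9,
            2.5,  9.0, -4.5), ncol = 3, byrow = TRUE)
}

## 13 base points of the TCR alpha core; beta core is the exact 180-degree
## rotation about x. Same column-mean constraints as above.
tcr_core_base_points <- function() {
  y <- (seq_len(13) - 7) * 2.0
  x <- c(-1.2, 1.2, -0.8, 0.8, -0.4, 0.4, 0, -1.0, 1.0, -0.6, 0.6, -0.2, 0.2)
  z <- c(-4.6, -5.4, -4.8, -5.2, -5.0, -4.7, -5.3, -4.9, -5.1, -5.0,
         -4.5, -5.5, -5.0)
  cbind(x, y, z)
}

rot_x_pi <- function(p) cbind(p[, 1], -p[, 2], -p[, 3])

## CDR loop centers in TCR-local coordinates (alpha loops on the -z side).
CDR_LOOP_CENTERS <- list(
  cdr1a = c(4.5, -7, -4), cdr2a = c(4.5, 7, -4),
  cdr25a = c(5.5, 0, -4.5), cdr3a = c(6.5, 0, -1.5),
  cdr1b = c(4.5, -7, 4), cdr2b = c(4.5, 7, 4),
  cdr25b = c(5.5, 0, 4.5), cdr3b = c(6.5, 0, 1.5))

loop_local_coords <- function(center, len) {
  i <- seq_len(len) - 1
  cbind(center[1] + 0.3 * (i %% 2 * 2 - 1),
        center[2] + (i - (len - 1) / 2) * 2.0,
        center[3])
}

## TCR chain local coordinates: cores + 4 loops + framework fillers.
tcr_chain_local <- function(which_chain, cdr3_len) {
  spans <- default_cdr_spans(cdr3_len, cdr3_len)
  q <- tcr_core_base_points()
  if (which_chain == "b") q <- rot_x_pi(q)
  zsign <- if (which_chain == "a") -1 else 1
  n <- 26L + cdr3_len + 8L
  xyz <- matrix(NA_real_, n, 3)
  xyz[TCR_REF_CORE + 1L, ] <- q
  for (loop in CDR_LOOPS) {
    span <- spans[[paste0(loop, which_chain)]]
    xyz[(span[1] + 1L):span[2], ] <-
      loop_local_coords(CDR_LOOP_CENTERS[[paste0(loop, which_chain)]],
                        span[2] - span[1])
  }
  fill <- which(is.na(xyz[, 1]))
  xyz[fill, ] <- cbind(-6, -11 + 2.2 * (seq_along(fill) - 1), zsign * 8)
  xyz
}

mhc_chain_local <- function() {
  p <- mhc_core_base_points()
  xyz <- matrix(NA_real_, nchar(MHC_REF_SEQ), 3)
  xyz[MHC_REF_N_HALF + 1L, ] <- p
  xyz[MHC_REF_C_HALF + 1L, ] <- rot_x_pi(p)
  fill <- which(is.na(xyz[, 1]))
  xyz[fill, ] <- cbind(-5 - 0.03 * (seq_along(fill) - 1),
                       -24 + 1.8 * (seq_along(fill) - 1), -8)
  xyz
}

peptide_local <- function(len) {
  cbind(6, (seq_len(len) - (len + 1) / 2) * 3.8, 0)
}

#' Consensus-like docking geometry
#'
#' A class I-like diagonal binding mode used as the default for synthetic
#' complexes: 29 Angstrom inter-origin distance with both frame x-axes
#' tilted modestly off the inter-origin axis.
#'
#' @return A [docking_geometry()].
#' @export
consensus_geometry <- function() {
  docking_geometry(29, 0.6,
                   vunit(c(0.95, 0.20, 0.24)),
                   vunit(c(0.94, -0.25, 0.23)))
}

#' Random docking geometry
#'
#' Draws from a broad distribution around the consensus binding mode:
#' distance uniform on 24-34 Angstrom, torsion uniform on the circle, and
#' each frame unit vector uniform within a 45-degree cone about the frame
#' x-axis. Uses the current RNG stream.
#'
#' @return A [docking_geometry()].
#' @export
random_docking_geometry <- function() {
  cone <- function() {
    polar <- stats::runif(1, 0, pi / 4)
    azim <- stats::runif(1, -pi, pi)
    c(cos(polar), sin(polar) * cos(azim), sin(polar) * sin(azim))
  }
  docking_geometry(stats::runif(1, 24, 34), stats::runif(1, -pi, pi),
                   cone(), cone())
}

#' Specification of a synthetic ternary complex
#'
#' @param geometry Generating [docking_geometry()].
#' @param coordinate_noise Gaussian noise s.d. added to every coordinate,
#'   Angstrom (>= 0).
#' @param peptide Peptide sequence (8-13 residues).
#' @param cdr3a,cdr3b CDR3 sequences (length >= 5).
#' @param seed Integer seed; a fixed seed yields byte-identical output.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(geometry = consensus_geometry(),
                           coordinate_noise = 0,
                           peptide = "GILGFVFTL",
                           cdr3a = "CAVSNTGKLI", cdr3b = "CASSIRSSYE",
                           seed = 1L) {
  stopifnot(coordinate_noise >= 0, nchar(cdr3a) >= 5, nchar(cdr3b) >= 5)
  structure(list(geometry = geometry, coordinate_noise = coordinate_noise,
                 peptide = peptide, cdr3a = cdr3a, cdr3b = cdr3b,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

## reference V-domain sequence with the CDR3 swapped in
tcr_chain_seq_for <- function(ref, cdr3) {
  paste0(substr(ref, 1, 26), cdr3, substr(ref, 37, nchar(ref)))
}

#' Generate a synthetic ternary complex
#'
#' Builds an idealized complex whose MHC frame is exactly the identity
#' frame in the emitted coordinates and whose TCR is placed by
#' `geometry_to_transform(spec$geometry)`, so at zero noise the recovered
#' docking geometry equals the generating one to machine precision.
#'
#' @param spec A [synthetic_spec()].
#' @param pdb_id,deposit_date Labels stored on the complex.
#' @return A `ternary_complex`.
#' @export
make_synthetic_complex <- function(spec = synthetic_spec(), pdb_id = "synt",
                                   deposit_date = as.Date("2020-01-01")) {
  la <- nchar(spec$cdr3a); lb <- nchar(spec$cdr3b)
  mhc_xyz <- mhc_chain_local()
  pep_xyz <- peptide_local(nchar(spec$peptide))
  tf <- geometry_to_transform(spec$geometry)
  tcra_xyz <- apply_transform(tf, tcr_chain_local("a", la))
  tcrb_xyz <- apply_transform(tf, tcr_chain_local("b", lb))
  pmhc <- rbind(mhc_xyz, pep_xyz)
  tcr <- rbind(tcra_xyz, tcrb_xyz)
  dmin <- sqrt(min(outer(rowSums(pmhc^2), rowSums(tcr^2), "+") -
                     2 * pmhc %*% t(tcr)))
  if (!is.finite(dmin) || dmin < 1) {
    stop(sprintf(
      "geometry places TCR inside the pMHC (min C-alpha distance %.2f A)",
      dmin))
  }
  seqs <- list(mhc = MHC_REF_SEQ,
               peptide = spec$peptide,
               tcra = tcr_chain_seq_for(TCRA_REF_SEQ, spec$cdr3a),
               tcrb = tcr_chain_seq_for(TCRB_REF_SEQ, spec$cdr3b))
  xyzs <- list(mhc = mhc_xyz, peptide = pep_xyz,
               tcra = tcra_xyz, tcrb = tcrb_xyz)
  chains <- c(mhc = "A", peptide = "C", tcra = "D", tcrb = "E")
  res <- do.call(rbind, lapply(names(seqs), function(role) {
    n <- nchar(seqs[[role]])
    data.frame(role = role, chain_id = chains[[role]], resno = seq_len(n),
               aa = strsplit(seqs[[role]], "")[[1]],
               x = xyzs[[role]][, 1], y = xyzs[[role]][, 2],
               z = xyzs[[role]][, 3], stringsAsFactors = FALSE)
  }))
  if (spec$coordinate_noise > 0) {
    noise <- with_seed(spec$seed,
                       matrix(stats::rnorm(nrow(res) * 3,
                                           sd = spec$coordinate_noise),
                              ncol = 3))
    res$x <- res$x + noise[, 1]
    res$y <- res$y + noise[, 2]
    res$z <- res$z + noise[, 3]
  }
  ann <- chain_annotation(
    organism = "human", mhc_class = 1, mhc_allele = "A*02:01",
    peptide = spec$peptide, va = "TRAV-SYN1", ja = "TRAJ-SYN1",
    vb = "TRBV-SYN1", jb = "TRBJ-SYN1",
    cdr3a = spec$cdr3a, cdr3b = spec$cdr3b,
    cdr_spans = default_cdr_spans(la, lb))
  ternary_complex(res, ann, pdb_id = pdb_id, deposit_date = deposit_date)
}

#' Canonical generic CDR centers of mass
#'
#' The CDR loop centers of mass of the idealized reference complex,
#' expressed in its TCR frame; used as the default COM set for
#' [docking_rmsd()] so the metric is usable without a template database.
#'
#' @return A [generic_cdr_coms()].
#' @export
default_generic_cdr_coms <- function() {
  spans <- default_cdr_spans(10, 10)
  pts <- t(vapply(LOOP_NAMES, function(loop) {
    span <- spans[[loop]]
    colMeans(loop_local_coords(CDR_LOOP_CENTERS[[loop]], span[2] - span[1]))
  }, numeric(3)))
  generic_cdr_coms(pts, n_source_structures = 1L)
}

#' Specification of a simulated PAE matrix
#'
#' Emulates the empirical structure of interface-PAE matrices: some TCRs
#' score consistently better or worse than average (TCR-intrinsic offsets
#' `tau`), some pMHCs likewise (`pi`), and cognate TCR:peptide pairs gain
#' an accuracy bonus `beta` on top.
#'
#' @param n_tcrs,n_peptides Matrix dimensions.
#' @param tau_sd,pi_sd S.d. of the TCR- and peptide-intrinsic offsets.
#' @param beta Planted cognate-pair signal (subtracted from cognate
#'   entries; PAE is lower = better).
#' @param sigma Residual noise s.d. (>= 0).
#' @param cognate_map Integer vector, length `n_tcrs`: cognate peptide
#'   column per TCR (default: column 1, the wild type).
#' @param n_background Background TCRs used for the per-peptide means.
#' @param baseline Mean interface PAE level. All effect and noise draws are
#'   truncated at 4 standard deviations, so with the defaults the simulated
#'   PAE values are guaranteed non-negative.
#' @param seed Integer seed.
#' @return An object of class `pae_sim_spec`.
#' @export
pae_sim_spec <- function(n_tcrs = 50L, n_peptides = 10L, tau_sd = 2,
                         pi_sd = 1, beta = 3, sigma = 1,
                         cognate_map = rep(1L, n_tcrs),
                         n_background = 50L, baseline = 20, seed = 1L) {
  stopifnot(sigma >= 0, all(cognate_map >= 1), all(cognate_map <= n_peptides),
            length(cognate_map) == n_tcrs, n_background >= 1)
  structure(list(n_tcrs = as.integer(n_tcrs),
                 n_peptides = as.integer(n_peptides),
                 tau_sd = tau_sd, pi_sd = pi_sd, beta = beta, sigma = sigma,
                 cognate_map = as.integer(cognate_map),
                 n_background = as.integer(n_background),
                 baseline = baseline, seed = as.integer(seed)),
            class = "pae_sim_spec")
}

## truncate draws at +/- 4 sd so simulated PAE stays non-negative
rnorm_trunc <- function(n, sd) {
  if (sd == 0) return(rep(0, n))
  pmax(pmin(stats::rnorm(n, 0, sd), 4 * sd), -4 * sd)
}

#' Simulate a PAE matrix with planted binding signal
#'
#' `PAE[i, j] = baseline + tau_i + pi_j - beta * [j == cognate(i)] + noise`;
#' background means are computed from `n_background` independent mock TCRs
#' against the same peptide-intrinsic offsets.
#'
#' @param spec A [pae_sim_spec()].
#' @return List with `pae` ([pae_matrix()]), `background`
#'   ([background_means()]), and `truth` (the cognate map).
#' @export
make_synthetic_pae <- function(spec = pae_sim_spec()) {
  with_seed(spec$seed, {
    n <- spec$n_tcrs; p <- spec$n_peptides
    tau <- rnorm_trunc(n, spec$tau_sd)
    pi_j <- rnorm_trunc(p, spec$pi_sd)
    M <- spec$baseline + outer(tau, pi_j, "+") +
      matrix(rnorm_trunc(n * p, spec$sigma), n, p)
    M[cbind(seq_len(n), spec$cognate_map)] <-
      M[cbind(seq_len(n), spec$cognate_map)] - spec$beta
    bg_tau <- rnorm_trunc(spec$n_background, spec$tau_sd)
    BG <- spec$baseline + outer(bg_tau, pi_j, "+") +
      matrix(rnorm_trunc(spec$n_background * p, spec$sigma),
             spec$n_background, p)
    peptides <- sprintf("PEP%02d", seq_len(p))
    list(pae = pae_matrix(M, tcr_ids = sprintf("tcr%03d", seq_len(n)),
                          peptides = peptides, wt_index = 1L),
         background = background_means(colMeans(BG),
                                       n_background = spec$n_background),
         truth = spec$cognate_map)
  })
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Simulate a paired-TCR repertoire around center sequences
#'
#' Each simulated TCR copies a center [paired_tcr()] and mutates every
#' CDR3 position independently with probability `spread` to a random
#' different amino acid; germline loops (CDR1/2/2.5) stay tied to the
#' V gene, so repertoires round-trip through the V-gene-based TSV layout.
#' Cluster sizes follow `sizes`.
#'
#' @param n Total TCRs (ignored when `sizes` is given).
#' @param centers List of [paired_tcr()] cluster centers; default one
#'   center built from the synthetic reference chains.
#' @param spread Per-position mutation probability in \[0, 1\].
#' @param sizes Optional per-center counts (must sum to `n` if both given).
#' @param seed Integer seed.
#' @return List of [paired_tcr()].
#' @export
make_synthetic_repertoire <- function(n = 50L, centers = NULL, spread = 0.1,
                                      sizes = NULL, seed = 1L) {
  if (is.null(centers))
    centers <- list(paired_tcr(
      tcr_chain("TRAV-SYN1", cdr3 = "CAVSNTGKLI"),
      tcr_chain("TRBV-SYN1", cdr3 = "CASSIRSSYE"), id = "center1"))
  if (is.null(sizes)) {
    base <- n %/% length(centers)
    sizes <- rep(base, length(centers))
    sizes[seq_len(n - base * length(centers))] <-
      sizes[seq_len(n - base * length(centers))] + 1L
  }
  stopifnot(length(sizes) == length(centers))
  mutate_str <- function(s, p) {
    ch <- strsplit(s, "")[[1]]
    hit <- stats::runif(length(ch)) < p
    if (any(hit))
      ch[hit] <- vapply(ch[hit], function(a)
        sample(setdiff(AA20, a), 1), "")
    paste(ch, collapse = "")
  }
  with_seed(seed, {
    out <- list()
    k <- 0L
    for (ci in seq_along(centers)) {
      cen <- centers[[ci]]
      for (m in seq_len(sizes[ci])) {
        k <- k + 1L
        mut_chain <- function(chain) {
          tcr_chain(chain$v_gene, cdr1 = chain$cdr1, cdr2 = chain$cdr2,
                    cdr25 = chain$cdr25,
                    cdr3 = mutate_str(chain$cdr3, spread))
        }
        out[[k]] <- paired_tcr(mut_chain(cen$alpha), mut_chain(cen$beta),
                               id = sprintf("sim%03d", k))
      }
    }
    out
  })
}
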