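#' Accuracy metrics for TCR:pMHC models
#'
#' Three measures: CDR RMSD (C-alpha RMSD over the CDR loops after
#' superposition on the MHC, CDR3 residues up-weighted 3-fold), peptide
#' RMSD (same convention over peptide C-alphas, uniform weights), and a
#' sequence-independent docking RMSD between two docking geometries via
#' displacement of generic CDR centers of mass (CDR3 COMs up-weighted
#' 3-fold), computed without superposition.
#'
#' @name rmsd_metrics
NULL

#' Weighted least-squares rigid superposition
#'
#' Kabsch/SVD closed form with determinant correction (proper rotations
#' only). Weights enter the squared sum; the reported RMSD is
#' `sqrt(sum(w_i |p_i - T(q_i)|^2) / sum(w_i))`.
#'
#' @param fixed,mobile Equal-count (>= 3) n x 3 coordinate matrices.
#' @param weights Non-negative per-point weights, not all zero.
#' @return List with `transform` (`rigid_transform` mapping `mobile` onto
#'   `fixed`) and `rmsd`.
#' @export
weighted_superpose <- function(fixed, mobile, weights = rep(1, nrow(fixed))) {
  fixed <- as.matrix(fixed); mobile <- as.matrix(mobile)
  stopifnot(nrow(fixed) == nrow(mobile), nrow(fixed) >= 3L,
            length(weights) == nrow(fixed), all(weights >= 0))
  W <- sum(weights)
  if (W <= 0) stop("weights must not all be zero")
  w <- weights / W
  cf <- colSums(fixed * w); cm <- colSums(mobile * w)
  A <- sweep(fixed, 2, cf)
  B <- sweep(mobile, 2, cm)
  H <- t(B * w) %*% A
  sv <- svd(H)
  dcorr <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, dcorr)) %*% t(sv$u)
  if (max(svd(H)$d) < 1e-12) stop("degenerate geometry: zero covariance")
  t_vec <- cf - as.numeric(R %*% cm)
  tf <- rigid_transform(R, t_vec)
  dev <- fixed - apply_transform(tf, mobile)
  list(transform = tf, rmsd = sqrt(sum(w * rowSums(dev^2))))
}

#' Weighted RMSD without superposition
#'
#' @param p,q Equal-count n x 3 coordinate matrices.
#' @param weights Non-negative per-point weights.
#' @return `sqrt(sum(w_i |p_i - q_i|^2) / sum(w_i))`.
#' @export
weighted_rmsd <- function(p, q, weights = rep(1, nrow(p))) {
  p <- as.matrix(p); q <- as.matrix(q)
  stopifnot(nrow(p) == nrow(q), length(weights) == nrow(p))
  sqrt(sum(weights * rowSums((p - q)^2)) / sum(weights))
}

## Superpose model onto native over shared MHC C-alphas and return the
## transformed model. `mhc_subset` optionally restricts to the 12 core
## residues.
superpose_on_mhc <- function(native, model, mhc_subset = NULL) {
  nat <- role_coords(native, "mhc", mhc_subset)
  mod <- role_coords(model, "mhc", mhc_subset)
  n <- min(nrow(nat), nrow(mod))
  if (n < 3L) stop("fewer than 3 shared MHC C-alphas for superposition")
  fit <- weighted_superpose(nat[seq_len(n), , drop = FALSE],
                            mod[seq_len(n), , drop = FALSE])
  transform_residues(model, fit$transform)
}

## Per-residue CDR coordinates and weights (CDR3 residues weight 3).
cdr_points <- function(complex) {
  pts <- NULL; w <- NULL
  for (loop in LOOP_NAMES) {
    p <- cdr_coords(complex, loop)
    pts <- rbind(pts, p)
    w <- c(w, rep(if (grepl("^cdr3", loop)) 3 else 1, nrow(p)))
  }
  list(points = pts, weights = w)
}

#' CDR RMSD between a native structure and a model
#'
#' The model is first superposed on the native via the MHC C-alphas
#' (unweighted); a weighted C-alpha RMSD is then computed over all 8 CDR
#' loops without further superposition, with every CDR3 residue weighted 3
#' and all other CDR residues weighted 1.
#'
#' @param native,model `ternary_complex` objects sharing CDR spans.
#' @param mhc_core Optional [core_residue_set()]; if given, superposition
#'   uses only the 12 MHC core residues instead of all shared MHC C-alphas.
#' @return RMSD in Angstrom.
#' @export
cdr_rmsd <- function(native, model, mhc_core = NULL) {
  if (!identical(native$annotation$cdr_spans, model$annotation$cdr_spans))
    stop("native and model CDR spans differ")
  subset <- if (is.null(mhc_core)) NULL else
    c(mhc_core$mhc_n_half, mhc_core$mhc_c_half)
  model <- superpose_on_mhc(native, model, subset)
  a <- cdr_points(native); b <- cdr_points(model)
  weighted_rmsd(a$points, b$points, a$weights)
}

#' Peptide RMSD between a native structure and a model
#'
#' Same MHC-superposition convention as [cdr_rmsd()], computed over the
#' peptide C-alphas with uniform weights.
#'
#' @inheritParams cdr_rmsd
#' @return RMSD in Angstrom.
#' @export
peptide_rmsd <- function(native, model, mhc_core = NULL) {
  if (nchar(native$annotation$peptide) != nchar(model$annotation$peptide))
    stop("native and model peptide lengths differ")
  subset <- if (is.null(mhc_core)) NULL else
    c(mhc_core$mhc_n_half, mhc_core$mhc_c_half)
  model <- superpose_on_mhc(native, model, subset)
  weighted_rmsd(role_coords(native, "peptide"), role_coords(model, "peptide"))
}

#' Generic CDR centers of mass
#'
#' @param points 8 x 3 matrix of loop centers of mass in TCR-frame
#'   coordinates, rows named `cdr1a ... cdr3b`.
#' @param n_source_structures How many structures were averaged.
#' @return An object of class `generic_cdr_coms` with `points` and
#'   `weights` (3 for the CDR3 rows, 1 otherwise).
#' @export
generic_cdr_coms <- function(points, n_source_structures = 1L) {
  points <- as.matrix(points)
  stopifnot(nrow(points) == 8L, ncol(points) == 3L)
  if (is.null(rownames(points))) rownames(points) <- LOOP_NAMES
  stopifnot(setequal(rownames(points), LOOP_NAMES))
  points <- points[LOOP_NAMES, , drop = FALSE]
  structure(list(points = points,
                 weights = ifelse(grepl("^cdr3", LOOP_NAMES), 3, 1),
                 n_source_structures = as.integer(n_source_structures)),
            class = "generic_cdr_coms")
}

#' Average CDR centers of mass over a structure database
#'
#' For each structure, each CDR loop's C-alpha center of mass is expressed
#' in that structure's own TCR coordinate frame; the per-loop positions are
#' then averaged over structures. Frame-relative, hence invariant to rigid
#' motion of any input structure.
#'
#' @param db List of `ternary_complex`.
#' @return A [generic_cdr_coms()].
#' @export
compute_generic_cdr_coms <- function(db) {
  stopifnot(length(db) >= 1L)
  per <- lapply(db, function(cx) {
    fr <- build_tcr_frame(cx)
    t(vapply(LOOP_NAMES, function(loop) {
      com <- colMeans(cdr_coords(cx, loop))
      as.numeric(t(fr$axes) %*% (com - fr$origin))
    }, numeric(3)))
  })
  avg <- Reduce(`+`, per) / length(per)
  rownames(avg) <- LOOP_NAMES
  generic_cdr_coms(avg, n_source_structures = length(db))
}

#' Sequence-independent docking RMSD between two docking geometries
#'
#' With the MHC frame fixed at the identity, each geometry places a TCR
#' frame; the 8 generic CDR centers of mass are mapped through both frames
#' and a weighted point RMSD (CDR3 COMs weight 3) is computed without
#' superposition.
#'
#' @param g1,g2 `docking_geometry` objects.
#' @param coms A [generic_cdr_coms()]; defaults to the canonical set of
#'   the synthetic reference complex.
#' @return RMSD in Angstrom.
#' @export
docking_rmsd <- function(g1, g2, coms = default_generic_cdr_coms()) {
  p1 <- apply_transform(geometry_to_transform(g1), coms$points)
  p2 <- apply_transform(geometry_to_transform(g2), coms$points)
  weighted_rmsd(p1, p2, coms$weights)
}

#' Pairwise docking RMSD matrix
#'
#' @param geoms List of `docking_geometry`.
#' @inheritParams docking_rmsd
#' @return Symmetric matrix of docking RMSDs.
#' @export
docking_rmsd_matrix <- function(geoms, coms = default_generic_cdr_coms()) {
  mapped <- lapply(geoms, function(g)
    apply_transform(geometry_to_transform(g), coms$points))
  n <- length(geoms)
  D <- matrix(0, n, n, dimnames = list(names(geoms), names(geoms)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <- weighted_rmsd(mapped[[i]], mapped[[j]], coms$weights)
  }
  D
}
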