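#' Docking geometry of a TCR:pMHC complex
#'
#' The docking geometry is the 6-degree-of-freedom rigid-body relation
#' between the MHC coordinate frame and the TCR coordinate frame. Both
#' frames are anchored on internal approximate 2-fold symmetry: the MHC
#' frame on the 6+6 beta-sheet core residues of the peptide-binding groove
#' floor, the TCR frame on the 13+13 conserved framework residues of the
#' alpha/beta variable domains. Because the x-axes of both frames point
#' toward the typical location of the partner molecule, the relation admits
#' a smooth local 6-parameter chart: the inter-origin distance, a dihedral
#' (torsion) about the inter-origin axis, and two unit vectors (each two
#' spherical angles) giving the partner direction in each frame.
#'
#' @name frames_and_geometry
NULL

#' Pseudo 2-fold symmetry transform of paired residue halves
#'
#' Finds the least-squares rigid transform mapping the concatenated point
#' set `(half_a, half_b)` onto `(half_b, half_a)`, i.e. the transform that
#' maps the residues onto themselves while interchanging the two halves.
#' For an exactly C2-symmetric point set the residual RMSD is 0 and the
#' rotation angle is 180 degrees.
#'
#' @param half_a,half_b Equal-count (>= 3) C-alpha coordinate matrices,
#'   paired row-by-row (row i of `half_a` is the symmetry partner of row i
#'   of `half_b`).
#' @return A list: `transform` (`rigid_transform`), `axis` (unit rotation
#'   axis), `angle` (radians), `rmsd` (residual, Angstrom).
#' @export
pseudo_symmetry_transform <- function(half_a, half_b) {
  half_a <- as.matrix(half_a); half_b <- as.matrix(half_b)
  stopifnot(nrow(half_a) == nrow(half_b), nrow(half_a) >= 3L)
  mobile <- rbind(half_a, half_b)
  fixed <- rbind(half_b, half_a)
  fit <- weighted_superpose(fixed, mobile)
  aa <- rotation_axis_angle(fit$transform$R)
  list(transform = fit$transform, axis = aa$axis, angle = aa$angle,
       rmsd = fit$rmsd)
}

## Shared frame construction: symmetry axis -> x (sign toward `toward`),
## z from COM(half_a) to COM(half_b) orthogonalized against x, y = z cross x,
## origin at the overall core COM.
symmetry_frame <- function(half_a, half_b, toward) {
  sym <- pseudo_symmetry_transform(half_a, half_b)
  origin <- colMeans(rbind(half_a, half_b))
  x <- sym$axis
  if (sum(x * (toward - origin)) < 0) x <- -x
  z_raw <- colMeans(half_b) - colMeans(half_a)
  z <- z_raw - sum(z_raw * x) * x
  if (vnorm(z) < 1e-8)
    stop("degenerate frame: z-axis vanishes after orthogonalization")
  z <- z / vnorm(z)
  y <- vcross(z, x)
  coordinate_frame(origin, cbind(x, y, z))
}

#' Build the MHC coordinate frame
#'
#' The x-axis is the rotation axis of the pseudo 2-fold symmetry transform
#' of the 12 groove-floor core residues, oriented toward the peptide; the
#' z-axis points from the center of mass (COM) of the 6 N-terminal core
#' C-alphas to the COM of the 6 C-terminal ones (orthogonalized against x);
#' y completes a right-handed frame; the origin is the COM of all 12.
#'
#' @param complex A `ternary_complex`.
#' @param cores A [core_residue_set()]; located on the fly if missing.
#' @return A `frame`.
#' @export
build_mhc_frame <- function(complex, cores = locate_core_residues(complex)) {
  n_half <- role_coords(complex, "mhc", cores$mhc_n_half)
  c_half <- role_coords(complex, "mhc", cores$mhc_c_half)
  pep_com <- colMeans(role_coords(complex, "peptide"))
  symmetry_frame(n_half, c_half, pep_com)
}

#' Build the TCR coordinate frame
#'
#' Same construction as [build_mhc_frame()] with the halves replaced by the
#' 13 TCR alpha and 13 TCR beta conserved core residues: x points along the
#' TCR pseudo-symmetry axis toward the CDR loops (COM of the CDR3 alpha and
#' beta C-alphas), z points from the COM of the alpha core to the COM of
#' the beta core.
#'
#' @inheritParams build_mhc_frame
#' @return A `frame`.
#' @export
build_tcr_frame <- function(complex, cores = locate_core_residues(complex)) {
  a_core <- role_coords(complex, "tcra", cores$tcra_core)
  b_core <- role_coords(complex, "tcrb", cores$tcrb_core)
  cdr3_com <- colMeans(rbind(cdr_coords(complex, "cdr3a"),
                             cdr_coords(complex, "cdr3b")))
  symmetry_frame(a_core, b_core, cdr3_com)
}

#' Docking geometry constructor
#'
#' @param d Inter-origin distance, Angstrom (> 0).
#' @param torsion Dihedral about the inter-origin axis, radians.
#' @param mhc_unit Unit vector: direction from MHC to TCR, in MHC frame
#'   coordinates.
#' @param tcr_unit Unit vector: direction from TCR to MHC, in TCR frame
#'   coordinates.
#' @return An object of class `docking_geometry`.
#' @export
docking_geometry <- function(d, torsion, mhc_unit, tcr_unit) {
  stopifnot(d > 0)
  if (abs(vnorm(mhc_unit) - 1) > 1e-8 || abs(vnorm(tcr_unit) - 1) > 1e-8)
    stop("mhc_unit and tcr_unit must be unit vectors")
  structure(list(d = d, torsion = wrap_angle(torsion),
                 mhc_unit = as.numeric(mhc_unit),
                 tcr_unit = as.numeric(tcr_unit)),
            class = "docking_geometry")
}

#' @export
print.docking_geometry <- function(x, ...) {
  cat(sprintf("docking_geometry d=%.2f A torsion=%.1f deg\n",
              x$d, x$torsion * 180 / pi))
  invisible(x)
}

#' Compute the docking geometry relating two frames
#'
#' @param mhc_frame,tcr_frame `frame` objects with distinct origins.
#' @return A [docking_geometry()].
#' @export
compute_docking_geometry <- function(mhc_frame, tcr_frame) {
  v <- tcr_frame$origin - mhc_frame$origin
  d <- vnorm(v)
  if (d < 1e-6) stop("coincident frame origins")
  u <- v / d
  torsion <- dihedral_angle(mhc_frame$origin + mhc_frame$axes[, 1],
                            mhc_frame$origin, tcr_frame$origin,
                            tcr_frame$origin + tcr_frame$axes[, 1])
  docking_geometry(
    d = d, torsion = torsion,
    mhc_unit = as.numeric(t(mhc_frame$axes) %*% u),
    tcr_unit = as.numeric(t(tcr_frame$axes) %*% (-u)))
}

#' 6-vector chart of a docking geometry
#'
#' Components: distance, torsion, then for each unit vector the polar angle
#' from the frame x-axis and the azimuth in the frame's y-z plane
#' (`atan2(z, y)`).
#'
#' @param g A `docking_geometry`.
#' @return Named numeric 6-vector
#'   `(d, torsion, mhc_polar, mhc_azim, tcr_polar, tcr_azim)`.
#' @export
geometry_vector <- function(g) {
  ang <- function(u) c(polar = acos(max(-1, min(1, u[1]))),
                       azim = atan2(u[3], u[2]))
  m <- ang(g$mhc_unit); t <- ang(g$tcr_unit)
  c(d = g$d, torsion = g$torsion,
    mhc_polar = m[["polar"]], mhc_azim = m[["azim"]],
    tcr_polar = t[["polar"]], tcr_azim = t[["azim"]])
}

#' @rdname geometry_vector
#' @param v Numeric 6-vector as produced by `geometry_vector`.
#' @export
vector_to_geometry <- function(v) {
  unit <- function(polar, azim)
    c(cos(polar), sin(polar) * cos(azim), sin(polar) * sin(azim))
  docking_geometry(v[1], v[2], unit(v[3], v[4]), unit(v[5], v[6]))
}

## indices of circular components in the 6-vector chart
GEOM_CIRCULAR <- c(2L, 4L, 6L)

#' Reconstruct the MHC-to-TCR transform from a docking geometry
#'
#' Places the TCR frame relative to an MHC frame fixed at the identity;
#' [compute_docking_geometry()] of the reconstructed frames reproduces the
#' input to 1e-6.
#'
#' @param g A `docking_geometry`.
#' @return A `rigid_transform` whose rotation/translation are the TCR frame
#'   axes/origin in MHC-frame (world) coordinates.
#' @export
geometry_to_transform <- function(g) {
  u <- g$mhc_unit                     # MHC frame = identity, so world coords
  origin_t <- g$d * u
  r0 <- rotation_between(g$tcr_unit, -u)
  torsion0 <- dihedral_angle(c(1, 0, 0), c(0, 0, 0), origin_t,
                             origin_t + r0[, 1])
  r_t <- rotation_about_axis(u, torsion0 - g$torsion) %*% r0
  rigid_transform(r_t, origin_t)
}

#' Fit a Gaussian distribution of docking geometries
#'
#' Sample mean and covariance of the 6-vector chart, with the circular
#' components (torsion and the two azimuths) unwrapped around their
#' circular means so that geometries straddling the +/-pi seam are pooled
#' correctly. The covariance is regularized by `+1e-6 I`.
#'
#' @param geoms List of `docking_geometry` (>= 7, one MHC class).
#' @param mhc_class Class label stored with the fit.
#' @return An object of class `geometry_distribution` with `mean`,
#'   `covariance`, `mhc_class`, `n_samples`.
#' @export
fit_geometry_distribution <- function(geoms, mhc_class = 1) {
  n <- length(geoms)
  if (n < 7L)
    stop("need at least 7 geometries for a rank-6 covariance, got ", n)
  V <- t(vapply(geoms, geometry_vector, numeric(6)))
  for (j in GEOM_CIRCULAR) {
    cm <- atan2(mean(sin(V[, j])), mean(cos(V[, j])))
    V[, j] <- cm + wrap_angle(V[, j] - cm)
  }
  mu <- colMeans(V)
  S <- stats::cov(V) + 1e-6 * diag(6)
  structure(list(mean = mu, covariance = S, mhc_class = mhc_class,
                 n_samples = n),
            class = "geometry_distribution")
}

#' Mahalanobis Z score of a docking geometry
#'
#' Measures how far a docking geometry diverges from the consensus binding
#' mode of its MHC class: `Z = sqrt((v - mu)' Sigma^-1 (v - mu))` with `v`
#' the 6-vector chart unwrapped against the fitted mean. For geometries
#' drawn from the fitted Gaussian, `Z^2 ~ chi-squared(6)`.
#'
#' @param g A `docking_geometry`.
#' @param dist A `geometry_distribution`.
#' @return Non-negative scalar.
#' @export
mahalanobis_z <- function(g, dist) {
  v <- geometry_vector(g)
  v[GEOM_CIRCULAR] <- dist$mean[GEOM_CIRCULAR] +
    wrap_angle(v[GEOM_CIRCULAR] - dist$mean[GEOM_CIRCULAR])
  q <- tryCatch(
    stats::mahalanobis(matrix(v, 1), dist$mean, dist$covariance),
    error = function(e) stop("singular covariance: ", conditionMessage(e)))
  sqrt(max(0, q))
}

#' Docking geometry TSV serialization
#'
#' Columns: pdbid, mhc_class, d, torsion, mhc_unit_x..z, tcr_unit_x..z.
#'
#' @param geoms Named list of `docking_geometry` (names = pdbid) or a
#'   data.frame row set from a previous write.
#' @param mhc_class Per-geometry class vector (recycled).
#' @param path TSV file.
#' @return `write_docking_geometries`: the path; `read_docking_geometries`:
#'   a named list of `docking_geometry` with `mhc_class` attribute.
#' @export
write_docking_geometries <- function(geoms, path, mhc_class = 1) {
  stopifnot(length(geoms) >= 1)
  ids <- names(geoms)
  if (is.null(ids)) ids <- sprintf("g%03d", seq_along(geoms))
  tab <- do.call(rbind, lapply(seq_along(geoms), function(i) {
    g <- geoms[[i]]
    data.frame(pdbid = ids[i],
               mhc_class = rep_len(mhc_class, length(geoms))[i],
               d = g$d, torsion = g$torsion,
               mhc_unit_x = g$mhc_unit[1], mhc_unit_y = g$mhc_unit[2],
               mhc_unit_z = g$mhc_unit[3],
               tcr_unit_x = g$tcr_unit[1], tcr_unit_y = g$tcr_unit[2],
               tcr_unit_z = g$tcr_unit[3])
  }))
  utils::write.table(format(tab, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_docking_geometries
#' @export
read_docking_geometries <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(tab)), function(i) {
    docking_geometry(tab$d[i], tab$torsion[i],
                     vunit(c(tab$mhc_unit_x[i], tab$mhc_unit_y[i],
                             tab$mhc_unit_z[i])),
                     vunit(c(tab$tcr_unit_x[i], tab$tcr_unit_y[i],
                             tab$tcr_unit_z[i])))
  })
  names(out) <- tab$pdbid
  attr(out, "mhc_class") <- tab$mhc_class
  out
}
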