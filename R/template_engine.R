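#' Template selection and hybrid template assembly
#'
#' The modeling pipeline hands a structure predictor hybrid templates:
#' chimeric complexes built from four single-chain template sets (pMHC,
#' TCR alpha, TCR beta) oriented by one of 12 representative docking
#' geometries. Three runs of four templates each cover the 12 geometries;
#' the same chain templates are reused across runs. In benchmark mode,
#' templates too similar to the target are excluded so that accuracy
#' estimates are not inflated by near-duplicates of the answer.
#'
#' @name template_engine
NULL

#' Target specification for template selection
#'
#' @param mhc_class MHC class (1 or 2).
#' @param mhc_seq MHC (groove domain) sequence.
#' @param peptide Peptide sequence.
#' @param alpha,beta [tcr_chain()] objects.
#' @param tcra_seq,tcrb_seq Full V-domain sequences used for
#'   target-to-template alignment maps; default: the synthetic reference
#'   V-domain with the target CDR3 substituted.
#' @param id Label.
#' @return An object of class `target_spec`.
#' @export
target_spec <- function(mhc_class, mhc_seq, peptide, alpha, beta,
                        tcra_seq = tcr_chain_seq_for(TCRA_REF_SEQ, alpha$cdr3),
                        tcrb_seq = tcr_chain_seq_for(TCRB_REF_SEQ, beta$cdr3),
                        id = "target") {
  stopifnot(inherits(alpha, "tcr_chain"), inherits(beta, "tcr_chain"))
  structure(list(mhc_class = mhc_class, mhc_seq = mhc_seq, peptide = peptide,
                 alpha = alpha, beta = beta, tcra_seq = tcra_seq,
                 tcrb_seq = tcrb_seq, id = id),
            class = "target_spec")
}

#' Template database record
#'
#' @param complex A `ternary_complex`.
#' @param geometry Its [docking_geometry()]; computed from the structure
#'   when missing.
#' @param cores Its [core_residue_set()]; located when missing.
#' @return An object of class `template_record`.
#' @export
template_record <- function(complex, geometry = NULL, cores = NULL) {
  if (is.null(cores)) cores <- locate_core_residues(complex)
  if (is.null(geometry))
    geometry <- compute_docking_geometry(build_mhc_frame(complex, cores),
                                         build_tcr_frame(complex, cores))
  structure(list(pdb_id = complex$pdb_id, complex = complex,
                 geometry = geometry, cores = cores,
                 deposit_date = complex$deposit_date),
            class = "template_record")
}

## paired_tcr of a record, with CDR loops read off the structure's spans
record_tcr <- function(rec) {
  ann <- rec$complex$annotation
  loop_seq <- function(chain, loop) {
    span <- ann$cdr_spans[[paste0(loop, chain)]]
    role <- if (chain == "a") "tcra" else "tcrb"
    substr(role_seq(rec$complex, role), span[1] + 1, span[2])
  }
  paired_tcr(
    tcr_chain(ann$va, loop_seq("a", "cdr1"), loop_seq("a", "cdr2"),
              loop_seq("a", "cdr25"), ann$cdr3a),
    tcr_chain(ann$vb, loop_seq("b", "cdr1"), loop_seq("b", "cdr2"),
              loop_seq("b", "cdr25"), ann$cdr3b),
    id = rec$pdb_id)
}

## identical aligned (non-gap) positions under a global alignment
seq_identity <- function(s1, s2) {
  if (nchar(s1) == nchar(s2)) {
    return(sum(strsplit(s1, "")[[1]] == strsplit(s2, "")[[1]]))
  }
  map <- align_index_map(s1, s2)
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  ok <- !is.na(map)
  sum(c1[ok] == c2[map[ok] + 1L])
}

#' Per-record template usability flags
#'
#' In benchmark mode a record is unusable as a pMHC template when its
#' peptide has fewer than `pep_thresh` mismatches with the target; as a
#' TCR chain template when its single-chain TCRdist to the target chain is
#' at most `chain_thresh`; and as a docking-geometry source when its
#' peptide has fewer than `pep_thresh` mismatches or its paired TCRdist is
#' at most `geom_thresh`. In production mode only the deposit-date cutoff
#' applies.
#'
#' @param target A [target_spec()].
#' @param db List of [template_record()].
#' @param mode `"benchmark"` or `"production"`.
#' @param pep_thresh,chain_thresh,geom_thresh Exclusion thresholds
#'   (defaults 3, 36, 48).
#' @param date_cutoff Deposit-date cutoff (default 2021-08-05).
#' @return data.frame with columns `pdb_id` and logical flags `pmhc`,
#'   `tcra`, `tcrb`, `geometry`.
#' @export
exclusion_mask <- function(target, db, mode = c("benchmark", "production"),
                           pep_thresh = 3, chain_thresh = 36,
                           geom_thresh = 48,
                           date_cutoff = as.Date("2021-08-05")) {
  mode <- match.arg(mode)
  stopifnot(length(db) >= 1)
  rows <- lapply(db, function(rec) {
    date_ok <- rec$deposit_date <= as.Date(date_cutoff)
    if (mode == "production") {
      return(data.frame(pdb_id = rec$pdb_id, pmhc = date_ok, tcra = date_ok,
                        tcrb = date_ok, geometry = date_ok))
    }
    tcr <- record_tcr(rec)
    mm <- peptide_mismatches(target$peptide, rec$complex$annotation$peptide)
    da <- single_chain_tcrdist(target$alpha, tcr$alpha)
    db_ <- single_chain_tcrdist(target$beta, tcr$beta)
    data.frame(pdb_id = rec$pdb_id,
               pmhc = date_ok && mm >= pep_thresh,
               tcra = date_ok && da > chain_thresh,
               tcrb = date_ok && db_ > chain_thresh,
               geometry = date_ok && mm >= pep_thresh &&
                 (da + db_) > geom_thresh)
  })
  mask <- do.call(rbind, rows)
  if (!any(mask$pmhc) || !any(mask$tcra) || !any(mask$tcrb) ||
      !any(mask$geometry))
    stop("no usable templates after masking (pmhc=", sum(mask$pmhc),
         " tcra=", sum(mask$tcra), " tcrb=", sum(mask$tcrb),
         " geometry=", sum(mask$geometry), ")")
  mask
}

#' Select ranked chain templates for a target
#'
#' pMHC templates are ranked by total sequence identity over the MHC plus
#' the peptide (descending); TCR chain templates by single-chain TCRdist
#' to the target chain (ascending). Ties are broken by earlier deposit
#' date, then pdb id.
#'
#' @param target A [target_spec()].
#' @param db List of [template_record()].
#' @param mask An [exclusion_mask()] result for this db.
#' @param n Templates per role (default 4).
#' @return List with elements `pmhc`, `tcra`, `tcrb`: lists of the top `n`
#'   records each.
#' @export
select_chain_templates <- function(target, db, mask, n = 4L) {
  counts <- c(pmhc = sum(mask$pmhc), tcra = sum(mask$tcra),
              tcrb = sum(mask$tcrb))
  if (any(counts < n))
    stop("fewer than ", n, " allowed templates: ",
         paste(names(counts), counts, sep = "=", collapse = " "))
  dates <- as.numeric(vapply(db, function(r) as.numeric(r$deposit_date), 0))
  ids <- vapply(db, `[[`, "", "pdb_id")
  pick <- function(allowed, key, decreasing) {
    idx <- which(allowed)
    o <- order(if (decreasing) -key[idx] else key[idx],
               dates[idx], ids[idx])
    db[idx[o][seq_len(n)]]
  }
  ident <- vapply(db, function(rec) {
    seq_identity(target$mhc_seq, role_seq(rec$complex, "mhc")) +
      seq_identity(target$peptide, rec$complex$annotation$peptide)
  }, 0)
  da <- vapply(db, function(rec)
    single_chain_tcrdist(target$alpha, record_tcr(rec)$alpha), 0)
  db_ <- vapply(db, function(rec)
    single_chain_tcrdist(target$beta, record_tcr(rec)$beta), 0)
  list(pmhc = pick(mask$pmhc, ident, decreasing = TRUE),
       tcra = pick(mask$tcra, da, decreasing = FALSE),
       tcrb = pick(mask$tcrb, db_, decreasing = FALSE))
}

#' Representative docking geometries by hierarchical clustering
#'
#' The pairwise docking-RMSD matrix is hierarchically clustered and the
#' tree cut at the threshold giving exactly `k` clusters; each cluster is
#' represented by its medoid (the member with the smallest mean docking
#' RMSD to its co-members). Representatives are returned in decreasing
#' cluster-size order, ties by first member index.
#'
#' @param geoms List of class-matched `docking_geometry` (length >= k).
#' @param coms A [generic_cdr_coms()].
#' @param k Number of representatives (default 12).
#' @param linkage Linkage criterion: `"single"` (default), `"average"`, or
#'   `"complete"`.
#' @return List of `k` geometries, with integer attribute `indices` (their
#'   positions in `geoms`) and `cluster_sizes`.
#' @export
select_representative_geometries <- function(geoms,
                                             coms = default_generic_cdr_coms(),
                                             k = 12L,
                                             linkage = c("single", "average",
                                                         "complete")) {
  linkage <- match.arg(linkage)
  if (length(geoms) < k)
    stop("need at least ", k, " geometries, got ", length(geoms))
  D <- docking_rmsd_matrix(geoms, coms)
  cl <- stats::cutree(stats::hclust(stats::as.dist(D), method = linkage),
                      k = k)
  reps <- integer(k); sizes <- integer(k)
  for (c_id in seq_len(k)) {
    members <- which(cl == c_id)
    sizes[c_id] <- length(members)
    if (length(members) == 1L) {
      reps[c_id] <- members
    } else {
      mean_d <- vapply(members, function(i)
        mean(D[i, setdiff(members, i)]), 0)
      reps[c_id] <- members[which.min(mean_d)]
    }
  }
  o <- order(-sizes, reps)
  out <- geoms[reps[o]]
  attr(out, "indices") <- reps[o]
  attr(out, "cluster_sizes") <- sizes[o]
  attr(out, "clusters") <- cl
  out
}

#' Assemble a hybrid template complex
#'
#' The TCRA template keeps its native coordinates. The TCRB donor
#' structure is rigidly superposed onto the TCRA template over the 13 TCRA
#' core residues and its beta chain appended. A hybrid TCR frame is
#' computed from the merged alpha/beta cores, and the pMHC donor
#' coordinates are rigidly mapped so that the realized MHC-to-TCR docking
#' geometry equals `rep_geom`.
#'
#' @param pmhc_t,tcra_t,tcrb_t [template_record()] donors.
#' @param rep_geom Representative [docking_geometry()] to realize.
#' @param geometry_index Which of the 12 representatives this is (1..12).
#' @param target Optional [target_spec()]; when given, per-chain
#'   target-to-template alignment maps are attached.
#' @return An object of class `hybrid_template` with elements `residues`,
#'   `source_ids`, `alignment`, `geometry_index`, `realized_geometry`.
#' @export
assemble_hybrid_template <- function(pmhc_t, tcra_t, tcrb_t, rep_geom,
                                     geometry_index = 1L, target = NULL) {
  # beta donor onto alpha template over the 13 TCRA core residues
  a_fixed <- role_coords(tcra_t$complex, "tcra", tcra_t$cores$tcra_core)
  a_mobile <- role_coords(tcrb_t$complex, "tcra", tcrb_t$cores$tcra_core)
  fit <- weighted_superpose(a_fixed, a_mobile)
  if (fit$rmsd > 5)
    warning(sprintf("TCRA core superposition RMSD %.2f A exceeds 5 A",
                    fit$rmsd))
  tcrb_moved <- transform_residues(tcrb_t$complex, fit$transform)

  # hybrid TCR frame from the merged cores
  b_core <- role_coords(tcrb_moved, "tcrb", tcrb_t$cores$tcrb_core)
  cdr3_com <- colMeans(rbind(cdr_coords(tcra_t$complex, "cdr3a"),
                             cdr_coords(tcrb_moved, "cdr3b")))
  tcr_frame <- symmetry_frame(
    role_coords(tcra_t$complex, "tcra", tcra_t$cores$tcra_core),
    b_core, cdr3_com)

  # place the pMHC so that geometry(MHC frame, TCR frame) == rep_geom
  mhc_frame_target <- transform_to_frame(compose_transforms(
    frame_to_transform(tcr_frame),
    invert_transform(geometry_to_transform(rep_geom))))
  donor_mhc_frame <- build_mhc_frame(pmhc_t$complex, pmhc_t$cores)
  move <- compose_transforms(
    frame_to_transform(mhc_frame_target),
    invert_transform(frame_to_transform(donor_mhc_frame)))
  pmhc_moved <- transform_residues(pmhc_t$complex, move)

  take <- function(cx, role, chain_id) {
    r <- cx$residues[cx$residues$role == role, , drop = FALSE]
    r$chain_id <- chain_id
    r$resno <- seq_len(nrow(r))
    r
  }
  residues <- rbind(take(pmhc_moved, "mhc", "A"),
                    take(pmhc_moved, "peptide", "C"),
                    take(tcra_t$complex, "tcra", "D"),
                    take(tcrb_moved, "tcrb", "E"))
  rownames(residues) <- NULL

  alignment <- NULL
  if (!is.null(target)) {
    alignment <- list(
      mhc = align_index_map(target$mhc_seq, role_seq(pmhc_t$complex, "mhc")),
      peptide = seq_len(min(nchar(target$peptide),
                            nchar(pmhc_t$complex$annotation$peptide))) - 1L,
      tcra = align_index_map(target$tcra_seq,
                             role_seq(tcra_t$complex, "tcra")),
      tcrb = align_index_map(target$tcrb_seq,
                             role_seq(tcrb_t$complex, "tcrb")))
  }

  # re-measure the realized geometry from the assembled coordinates
  realized_mhc_frame <- local({
    cores <- pmhc_t$cores
    n_half <- role_coords(pmhc_moved, "mhc", cores$mhc_n_half)
    c_half <- role_coords(pmhc_moved, "mhc", cores$mhc_c_half)
    symmetry_frame(n_half, c_half, colMeans(role_coords(pmhc_moved, "peptide")))
  })
  realized <- compute_docking_geometry(realized_mhc_frame, tcr_frame)
  dev <- max(abs(realized$d - rep_geom$d),
             abs(wrap_angle(realized$torsion - rep_geom$torsion)),
             max(abs(realized$mhc_unit - rep_geom$mhc_unit)),
             max(abs(realized$tcr_unit - rep_geom$tcr_unit)))
  if (dev > 1e-3)
    warning(sprintf("realized geometry deviates from requested (%.2g)", dev))

  structure(list(residues = residues,
                 source_ids = c(pmhc = pmhc_t$pdb_id, tcra = tcra_t$pdb_id,
                                tcrb = tcrb_t$pdb_id),
                 alignment = alignment,
                 geometry_index = as.integer(geometry_index),
                 realized_geometry = realized),
            class = "hybrid_template")
}

#' Build the 3-run x 4-template manifest for a target
#'
#' Assembles 12 hybrid templates: chain templates of rank 1..4 are paired
#' across roles, run r (1..3) uses representative geometries 4(r-1)+1..4r,
#' and geometry j is assembled with the chain-template set of rank
#' ((j-1) mod 4)+1 — so every geometry appears exactly once and the chain
#' templates are identical across runs. Templates are written as PDB files
#' plus a JSON manifest.
#'
#' @param target A [target_spec()].
#' @param chain_templates Result of [select_chain_templates()] (4 per role).
#' @param rep_geoms 12 representative geometries.
#' @param out_dir Output directory (created if needed).
#' @param n_runs,n_per_run Manifest shape (defaults 3 and 4).
#' @return The manifest as a list (also written to
#'   `<out_dir>/<target id>_manifest.json`), with per-run template PDB
#'   paths.
#' @export
build_run_manifest <- function(target, chain_templates, rep_geoms,
                               out_dir = ".", n_runs = 3L, n_per_run = 4L) {
  k <- n_runs * n_per_run
  if (length(rep_geoms) != k)
    stop("need exactly ", k, " representative geometries, got ",
         length(rep_geoms))
  for (role in c("pmhc", "tcra", "tcrb"))
    if (length(chain_templates[[role]]) != n_per_run)
      stop("need exactly ", n_per_run, " ", role, " templates, got ",
           length(chain_templates[[role]]))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  target_seq <- paste(target$mhc_seq, target$peptide, target$tcra_seq,
                      target$tcrb_seq, sep = "/")
  runs <- vector("list", n_runs)
  for (j in seq_len(k)) {
    run <- (j - 1L) %/% n_per_run + 1L
    rank <- (j - 1L) %% n_per_run + 1L
    hyb <- assemble_hybrid_template(chain_templates$pmhc[[rank]],
                                    chain_templates$tcra[[rank]],
                                    chain_templates$tcrb[[rank]],
                                    rep_geoms[[j]], geometry_index = j,
                                    target = target)
    path <- file.path(out_dir, sprintf("%s_run%d_geom%02d.pdb",
                                       target$id, run, j))
    write_complex_pdb(hyb, path)
    entry <- list(template_pdb = path,
                  geometry_index = j,
                  chain_template_rank = rank,
                  source_ids = as.list(hyb$source_ids),
                  alignment = lapply(hyb$alignment, as.vector))
    runs[[run]] <- c(runs[[run]], list(entry))
  }
  manifest <- list(target_id = target$id,
                   target_sequence = target_seq,
                   msa_mode = "single_sequence",
                   n_runs = n_runs, n_templates_per_run = n_per_run,
                   runs = runs)
  jsonlite::write_json(manifest,
                       file.path(out_dir,
                                 paste0(target$id, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}
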