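#' Annotated ternary TCR:pMHC complexes
#'
#' A ternary complex holds the C-alpha coordinates of an MHC (optionally
#' with beta-2 microglobulin), a bound peptide, and the TCR alpha and beta
#' chains, together with a sequence-level annotation (organism, MHC allele,
#' peptide, V/J genes, CDR3s, and CDR loop spans). All geometry in the
#' package operates on these objects.
#'
#' @name structure_model
NULL

#' Chain-level annotation of a TCR:pMHC complex
#'
#' @param organism Organism label (e.g. `"human"`).
#' @param mhc_class MHC class, 1 or 2.
#' @param mhc_allele Allele name string.
#' @param peptide Peptide sequence (length 8-13 for class I).
#' @param va,ja,vb,jb TCR V/J gene names.
#' @param cdr3a,cdr3b CDR3 sequences (non-empty).
#' @param cdr_spans Named list of 0-based half-open `c(start, end)` spans
#'   for the 8 CDR loops (`cdr1a` ... `cdr3b`); see [default_cdr_spans()].
#' @return An object of class `chain_annotation`.
#' @export
chain_annotation <- function(organism, mhc_class, mhc_allele, peptide,
                             va, ja, vb, jb, cdr3a, cdr3b, cdr_spans) {
  stopifnot(nzchar(cdr3a), nzchar(cdr3b))
  if (nchar(peptide) < 8 || nchar(peptide) > 13)
    stop("peptide length must be 8-13, got ", nchar(peptide))
  missing_loops <- setdiff(LOOP_NAMES, names(cdr_spans))
  if (length(missing_loops))
    stop("cdr_spans missing loops: ", paste(missing_loops, collapse = ", "))
  for (chain in c("a", "b")) {
    sp <- cdr_spans[paste0(CDR_LOOPS, chain)]
    m <- do.call(rbind, sp)
    if (any(m[, 2] <= m[, 1])) stop("empty CDR span")
    o <- order(m[, 1])
    if (any(m[o, 1][-1] < m[o, 2][-nrow(m)]))
      stop("overlapping CDR spans on chain ", chain)
  }
  structure(list(organism = organism, mhc_class = mhc_class,
                 mhc_allele = mhc_allele, peptide = peptide,
                 va = va, ja = ja, vb = vb, jb = jb,
                 cdr3a = cdr3a, cdr3b = cdr3b, cdr_spans = cdr_spans),
            class = "chain_annotation")
}

COMPLEX_ROLES <- c("mhc", "b2m", "peptide", "tcra", "tcrb")

#' Construct a ternary complex from a residue table
#'
#' @param residues data.frame with columns `role` (one of mhc, b2m,
#'   peptide, tcra, tcrb), `chain_id`, `resno` (author numbering),
#'   `aa` (one-letter code), `x`, `y`, `z` (C-alpha, Angstrom). Rows must
#'   be grouped by role in the order above and ordered within role.
#' @param annotation A [chain_annotation()].
#' @param pdb_id Structure label.
#' @param deposit_date Deposition date (`Date` or parseable string).
#' @return An object of class `ternary_complex`.
#' @export
ternary_complex <- function(residues, annotation, pdb_id = "synt",
                            deposit_date = as.Date("2021-08-05")) {
  stopifnot(is.data.frame(residues),
            all(c("role", "chain_id", "resno", "aa", "x", "y", "z") %in%
                  names(residues)))
  if (!all(residues$role %in% COMPLEX_ROLES))
    stop("unknown role(s): ",
         paste(setdiff(unique(residues$role), COMPLEX_ROLES), collapse = ", "))
  for (r in c("mhc", "peptide", "tcra", "tcrb"))
    if (!any(residues$role == r)) stop("missing role: ", r)
  if (length(unique(residues$chain_id[residues$role == "peptide"])) != 1L)
    stop("exactly one peptide chain required")
  xyz <- as.matrix(residues[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite C-alpha coordinates")
  # canonical role order, stable within role
  residues <- residues[order(match(residues$role, COMPLEX_ROLES)), , drop = FALSE]
  residues$seq_index <- stats::ave(seq_len(nrow(residues)), residues$role,
                                   FUN = function(i) seq_along(i) - 1L)
  rownames(residues) <- NULL
  obj <- structure(list(residues = residues, annotation = annotation,
                        pdb_id = pdb_id, deposit_date = as.Date(deposit_date)),
                   class = "ternary_complex")
  np <- sum(residues$role == "peptide")
  if (np != nchar(annotation$peptide))
    stop("peptide chain has ", np, " residues but annotation peptide has ",
         nchar(annotation$peptide))
  # every CDR span must resolve to residues with coordinates
  for (loop in LOOP_NAMES) {
    span <- annotation$cdr_spans[[loop]]
    role <- if (grepl("a$", loop)) "tcra" else "tcrb"
    n <- sum(residues$role == role)
    if (span[2] > n)
      stop("CDR span ", loop, " [", span[1], ",", span[2],
           ") exceeds ", role, " length ", n)
  }
  obj
}

#' @export
print.ternary_complex <- function(x, ...) {
  counts <- table(factor(x$residues$role, levels = COMPLEX_ROLES))
  cat("ternary_complex", x$pdb_id, "(",
      paste(names(counts)[counts > 0], counts[counts > 0],
            sep = ":", collapse = " "),
      ")\n  peptide:", x$annotation$peptide,
      " MHC:", x$annotation$mhc_allele, "\n")
  invisible(x)
}

#' Extract coordinates or sequence for a role
#'
#' @param complex A `ternary_complex` (or hybrid template).
#' @param role Role name; `NULL` for all residues.
#' @param indices Optional 0-based residue indices within the role.
#' @return `role_coords`: an n x 3 coordinate matrix; `role_seq`: a string.
#' @export
role_coords <- function(complex, role = NULL, indices = NULL) {
  res <- complex$residues
  if (!is.null(role)) res <- res[res$role == role, , drop = FALSE]
  if (!is.null(indices)) {
    pos <- match(indices, res$seq_index)
    if (anyNA(pos))
      stop("missing residues at 0-based indices: ",
           paste(indices[is.na(pos)], collapse = ", "))
    res <- res[pos, , drop = FALSE]
  }
  as.matrix(res[, c("x", "y", "z")])
}

#' @rdname role_coords
#' @export
role_seq <- function(complex, role) {
  paste(complex$residues$aa[complex$residues$role == role], collapse = "")
}

#' CDR loop C-alpha coordinates
#'
#' @param complex A `ternary_complex`.
#' @param loop Loop name, e.g. `"cdr3a"`.
#' @return n x 3 coordinate matrix.
#' @export
cdr_coords <- function(complex, loop) {
  span <- complex$annotation$cdr_spans[[loop]]
  if (is.null(span)) stop("unknown CDR loop: ", loop)
  role <- if (grepl("a$", loop)) "tcra" else "tcrb"
  role_coords(complex, role, seq.int(span[1], span[2] - 1L))
}

## Apply a rigid transform to all coordinates of a complex/template.
transform_residues <- function(obj, tf) {
  xyz <- apply_transform(tf, as.matrix(obj$residues[, c("x", "y", "z")]))
  obj$residues$x <- xyz[, 1]
  obj$residues$y <- xyz[, 2]
  obj$residues$z <- xyz[, 3]
  obj
}

#' Read a ternary complex from a PDB file
#'
#' Parses C-alpha records with [bio3d::read.pdb()], resolves alternate
#' locations to the highest-occupancy conformer, orders residues by author
#' numbering (insertion-coded residues kept in author order), and groups
#' chains by role according to `chain_map`.
#'
#' @param path PDB file.
#' @param annotation A [chain_annotation()].
#' @param chain_map Named character vector mapping roles (`mhc`, `peptide`,
#'   `tcra`, `tcrb`, optionally `b2m`) to chain identifiers.
#' @param pdb_id,deposit_date Passed through to [ternary_complex()].
#' @return A `ternary_complex`.
#' @export
read_ternary_pdb <- function(path, annotation, chain_map,
                             pdb_id = basename(path),
                             deposit_date = as.Date("2021-08-05")) {
  required <- c("mhc", "peptide", "tcra", "tcrb")
  missing_roles <- setdiff(required, names(chain_map))
  if (length(missing_roles))
    stop("chain_map missing role(s): ", paste(missing_roles, collapse = ", "))
  pdb <- bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
  atoms <- pdb$atom[pdb$atom$elety == "CA" & pdb$atom$type == "ATOM", , drop = FALSE]
  out <- list()
  for (role in COMPLEX_ROLES) {
    if (!role %in% names(chain_map)) next
    ch <- chain_map[[role]]
    if (is.na(ch)) next
    sel <- atoms[atoms$chain == ch, , drop = FALSE]
    if (nrow(sel) == 0L) stop("no C-alpha atoms for role '", role,
                              "' (chain ", ch, ")")
    ins <- ifelse(is.na(sel$insert), "", sel$insert)
    key <- paste(sel$resno, ins)
    # altloc: highest occupancy wins; keep author order of first occurrence
    keep <- unlist(lapply(split(seq_len(nrow(sel)), factor(key, levels = unique(key))),
                          function(i) i[which.max(sel$o[i])]),
                   use.names = FALSE)
    sel <- sel[sort(keep), , drop = FALSE]
    out[[role]] <- data.frame(
      role = role, chain_id = ch, resno = sel$resno,
      aa = bio3d::aa321(sel$resid), x = sel$x, y = sel$y, z = sel$z,
      stringsAsFactors = FALSE)
  }
  ternary_complex(do.call(rbind, out), annotation,
                  pdb_id = pdb_id, deposit_date = deposit_date)
}

#' Write a complex or hybrid template as a PDB file
#'
#' Emits C-alpha ATOM records in role order mhc, b2m, peptide, tcra, tcrb
#' with TER records between chains. Coordinates round-trip through
#' [read_ternary_pdb()] to 0.001 Angstrom.
#'
#' @param x A `ternary_complex` or `hybrid_template`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_complex_pdb <- function(x, path) {
  res <- x$residues
  xyz <- as.matrix(res[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite coordinates; refusing to write")
  res <- res[order(match(res$role, COMPLEX_ROLES)), , drop = FALSE]
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(res[, c("x", "y", "z")]))),
                   resno = res$resno,
                   resid = bio3d::aa123(res$aa),
                   chain = res$chain_id,
                   elety = rep("CA", nrow(res)),
                   o = rep(1, nrow(res)),
                   b = rep(0, nrow(res)))
  invisible(path)
}

#' Core residue set anchoring the coordinate frames
#'
#' @param mhc_n_half,mhc_c_half 0-based indices of the 6+6 MHC beta-sheet
#'   core residues; the i-th N-half residue is the 2-fold symmetry partner
#'   of the i-th C-half residue.
#' @param tcra_core,tcrb_core 0-based indices of the 13 conserved framework
#'   residues per TCR chain, aligned pairwise between chains.
#' @return An object of class `core_residue_set`.
#' @export
core_residue_set <- function(mhc_n_half, mhc_c_half, tcra_core, tcrb_core) {
  stopifnot(length(mhc_n_half) == 6L, length(mhc_c_half) == 6L,
            length(tcra_core) == 13L, length(tcrb_core) == 13L)
  structure(list(mhc_n_half = as.integer(mhc_n_half),
                 mhc_c_half = as.integer(mhc_c_half),
                 tcra_core = as.integer(tcra_core),
                 tcrb_core = as.integer(tcrb_core)),
            class = "core_residue_set")
}

## Map 0-based reference indices to 0-based target indices through a global
## pairwise alignment (BLOSUM62). Returns NA where a reference position
## aligns to a gap.
align_index_map <- function(ref_seq, target_seq) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  aln <- Biostrings::pairwiseAlignment(
    ref_seq, target_seq, substitutionMatrix = get("BLOSUM62"),
    gapOpening = 10, gapExtension = 0.5, type = "global")
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  map <- rep(NA_integer_, nchar(ref_seq))
  ri <- 0L; ti <- 0L
  for (k in seq_along(p)) {
    if (p[k] != "-") ri <- ri + 1L
    if (s[k] != "-") ti <- ti + 1L
    if (p[k] != "-" && s[k] != "-") map[ri] <- ti - 1L
  }
  map
}

#' Locate core residues in an annotated complex
#'
#' Maps the reference core index sets onto the target by global pairwise
#' sequence alignment of each chain against the shipped reference profile
#' for the complex's MHC class. Purely sequence-based, hence invariant
#' under any rigid motion of the coordinates.
#'
#' @param complex A `ternary_complex`.
#' @param reference A profile as returned by [reference_core_profile()].
#' @return A [core_residue_set()].
#' @export
locate_core_residues <- function(complex,
                                 reference = reference_core_profile(
                                   complex$annotation$mhc_class)) {
  map_one <- function(ref, target_seq, idx, label) {
    map <- align_index_map(ref, target_seq)
    got <- map[idx + 1L]
    if (anyNA(got))
      stop("alignment failed to cover ", label, " core position(s): ",
           paste(idx[is.na(got)], collapse = ", "))
    got
  }
  mhc_seq <- role_seq(complex, "mhc")
  core_residue_set(
    mhc_n_half = map_one(reference$mhc$seq, mhc_seq,
                         reference$mhc$n_half, "MHC N-half"),
    mhc_c_half = map_one(reference$mhc$seq, mhc_seq,
                         reference$mhc$c_half, "MHC C-half"),
    tcra_core = map_one(reference$tcra$seq, role_seq(complex, "tcra"),
                        reference$tcra$core, "TCRA"),
    tcrb_core = map_one(reference$tcrb$seq, role_seq(complex, "tcrb"),
                        reference$tcrb$core, "TCRB"))
}

#' Count peptide mismatches
#'
#' Hamming distance for equal-length peptides; `Inf` for peptides of
#' different length, so cross-length pairs always exceed any similarity
#' threshold.
#'
#' @param p1,p2 Peptide sequences.
#' @return Non-negative count, or `Inf`.
#' @export
peptide_mismatches <- function(p1, p2) {
  if (nchar(p1) != nchar(p2)) return(Inf)
  sum(strsplit(p1, "")[[1]] != strsplit(p2, "")[[1]])
}

#' Read and write the structure annotation table
#'
#' TSV with columns pdbid, organism, mhc_class, mhc, peptide, va, ja,
#' cdr3a, vb, jb, cdr3b, chain_map, deposit_date. `chain_map` packs the
#' role-to-chain assignment as e.g. `"mhc=A,peptide=C,tcra=D,tcrb=E"`.
#'
#' @param path TSV file.
#' @return A data.frame.
#' @export
read_annotation_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(mhc_class = "integer"))
}

#' @rdname read_annotation_table
#' @param tab data.frame in the same layout.
#' @export
write_annotation_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_annotation_table
#' @param chain_map_str Packed chain-map string.
#' @export
parse_chain_map <- function(chain_map_str) {
  parts <- strsplit(strsplit(chain_map_str, ",")[[1]], "=")
  stats::setNames(vapply(parts, `[`, "", 2L), vapply(parts, `[`, "", 1L))
}
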