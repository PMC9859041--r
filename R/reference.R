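#' Reference sequences and core-residue profiles
#'
#' Core residues anchor the MHC and TCR coordinate frames: 12 beta-sheet
#' residues in the MHC groove floor (6 from the N-terminal half, 6 from the
#' C-terminal half, paired by the approximate 2-fold symmetry), and 13
#' structurally conserved framework residues in each TCR variable domain.
#' New structures are annotated by aligning each chain to a shipped
#' reference sequence and mapping the reference core indices through the
#' alignment (see [locate_core_residues()]).
#'
#' The shipped profile is a synthetic reference: an idealized class I
#' groove-domain sequence and synthetic TCR V-domain sequences that match
#' the complexes produced by [make_synthetic_complex()]. All indices are
#' 0-based.
#'
#' @name reference_cores
NULL

# Idealized class I groove-domain reference (48 residues)
MHC_REF_SEQ <- "GSHSMRYFFTSVSRPGRGEPRFIAVGYVDDTQFVRFDSDAASQRMEPR"
MHC_REF_N_HALF <- c(4L, 6L, 8L, 10L, 12L, 14L)
MHC_REF_C_HALF <- c(30L, 32L, 34L, 36L, 38L, 40L)

# Synthetic TCR V-domain references (44 residues each); framework / CDR layout:
# [0,4) fw1, [4,8) CDR1, [8,12) fw2, [12,16) CDR2, [16,20) fw3a,
# [20,23) CDR2.5, [23,26) fw3b, [26,36) CDR3, [36,44) fw4
TCRA_REF_SEQ <- "GQSVDSAIYWYRIQSSKDKEFKGYSLCAVSNTGKLIWGQGTKLT"
TCRB_REF_SEQ <- "GQEVSNHLYFYWFRNQEGKNSVPFPLCASSIRSSYEWGPGTRLT"
TCR_REF_CORE <- c(0L, 1L, 2L, 3L, 8L, 9L, 10L, 11L, 16L, 17L, 18L, 19L, 24L)

#' Reference core profile for an MHC class
#'
#' @param mhc_class MHC class, 1 or 2. Only the class I profile ships with
#'   the package; class II requires a user-supplied profile.
#' @return A list with components `mhc` (reference sequence plus `n_half`
#'   and `c_half` index sets), `tcra` and `tcrb` (reference sequence plus
#'   13-residue `core` index set). Indices are 0-based.
#' @export
reference_core_profile <- function(mhc_class = 1) {
  if (!mhc_class %in% c(1, 2))
    stop("mhc_class must be 1 or 2")
  if (mhc_class == 2)
    stop("no reference core profile ships for MHC class 2; supply your own")
  list(
    mhc = list(seq = MHC_REF_SEQ, n_half = MHC_REF_N_HALF, c_half = MHC_REF_C_HALF),
    tcra = list(seq = TCRA_REF_SEQ, core = TCR_REF_CORE),
    tcrb = list(seq = TCRB_REF_SEQ, core = TCR_REF_CORE)
  )
}

#' CDR loop spans of the reference V-domain layout
#'
#' Spans are 0-based half-open `[start, end)` intervals within the chain.
#' CDR3 length may differ from the 10-residue reference; downstream
#' framework positions shift accordingly.
#'
#' @param cdr3a_len,cdr3b_len CDR3 lengths (>= 5).
#' @return Named list of `c(start, end)` integer pairs with names
#'   `cdr1a, cdr2a, cdr25a, cdr3a, cdr1b, cdr2b, cdr25b, cdr3b`.
#' @export
default_cdr_spans <- function(cdr3a_len = 10, cdr3b_len = 10) {
  stopifnot(cdr3a_len >= 5, cdr3b_len >= 5)
  one <- function(len) {
    list(cdr1 = c(4L, 8L), cdr2 = c(12L, 16L), cdr25 = c(20L, 23L),
         cdr3 = c(26L, 26L + as.integer(len)))
  }
  a <- one(cdr3a_len); b <- one(cdr3b_len)
  list(cdr1a = a$cdr1, cdr2a = a$cdr2, cdr25a = a$cdr25, cdr3a = a$cdr3,
       cdr1b = b$cdr1, cdr2b = b$cdr2, cdr25b = b$cdr25, cdr3b = b$cdr3)
}

CDR_LOOPS <- c("cdr1", "cdr2", "cdr25", "cdr3")
LOOP_NAMES <- c("cdr1a", "cdr2a", "cdr25a", "cdr3a",
                "cdr1b", "cdr2b", "cdr25b", "cdr3b")

#' Look up germline CDR loop sequences for a V gene
#'
#' Reads the V-gene table shipped under `extdata/vgene_cdr_loops.tsv`
#' (synthetic V genes used by the synthetic-data module and test suite;
#' full germline databases are out of scope).
#'
#' @param v_gene V gene name, e.g. `"TRAV-SYN1"`.
#' @return Named list with `cdr1`, `cdr2`, `cdr25` strings.
#' @export
vgene_cdr_loops <- function(v_gene) {
  tab <- utils::read.delim(
    system.file("extdata", "vgene_cdr_loops.tsv", package = "tcrpmhc"),
    stringsAsFactors = FALSE)
  i <- match(v_gene, tab$v_gene)
  if (is.na(i)) stop("unknown V gene: ", v_gene)
  list(cdr1 = tab$cdr1[i], cdr2 = tab$cdr2[i], cdr25 = tab$cdr25[i])
}
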