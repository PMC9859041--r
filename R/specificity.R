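#' PAE-based epitope specificity scoring
#'
#' A structure predictor's inter-chain predicted aligned error (PAE) is a
#' confidence proxy for the TCR:pMHC interface. Raw interface PAE mixes
#' genuine binding signal with TCR-intrinsic and pMHC-intrinsic offsets;
#' the binding-score correction removes both by subtracting a per-peptide
#' background mean (over irrelevant TCRs) and then centering each TCR's
#' row at zero. Lower binding score = stronger predicted binding.
#'
#' @name specificity_scoring
NULL

#' N x P matrix of mean interface PAE values
#'
#' @param values Numeric N x P matrix (rows = TCRs, columns = peptides),
#'   finite and non-negative.
#' @param tcr_ids,peptides Row/column labels.
#' @param wt_index Column index of the wild-type peptide.
#' @return An object of class `pae_matrix`.
#' @export
pae_matrix <- function(values, tcr_ids = rownames(values),
                       peptides = colnames(values), wt_index = 1L) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("PAE values must be finite and non-negative")
  if (is.null(tcr_ids)) tcr_ids <- sprintf("tcr%03d", seq_len(nrow(values)))
  if (is.null(peptides)) peptides <- sprintf("pep%02d", seq_len(ncol(values)))
  stopifnot(length(tcr_ids) == nrow(values),
            length(peptides) == ncol(values),
            wt_index >= 1, wt_index <= ncol(values))
  dimnames(values) <- list(tcr_ids, peptides)
  structure(list(values = values, tcr_ids = tcr_ids, peptides = peptides,
                 wt_index = as.integer(wt_index)),
            class = "pae_matrix")
}

#' Per-peptide background PAE means
#'
#' @param means Numeric vector, one mean interface PAE per peptide,
#'   computed over complexes with irrelevant background TCRs.
#' @param n_background How many background TCRs were averaged (>= 1).
#' @return An object of class `background_means`.
#' @export
background_means <- function(means, n_background = 1L) {
  stopifnot(n_background >= 1, all(is.finite(means)))
  structure(list(means = as.numeric(means),
                 n_background = as.integer(n_background)),
            class = "background_means")
}

#' Mean interface PAE from a full residue-residue PAE matrix
#'
#' Pools the entries `(i, j)` and `(j, i)` for all TCR residue `i` and
#' pMHC residue `j` (both directions, since PAE is asymmetric) and returns
#' their mean. With `pool = "sum"` the pooled sum is returned instead;
#' ranks are unaffected for fixed complex sizes.
#'
#' @param pae_full Square numeric matrix over all residues of the complex.
#' @param tcr_span,pmhc_span Disjoint 1-based residue index vectors.
#' @param pool `"mean"` (default) or `"sum"`.
#' @return Scalar interface PAE.
#' @export
mean_interface_pae <- function(pae_full, tcr_span, pmhc_span,
                               pool = c("mean", "sum")) {
  pool <- match.arg(pool)
  pae_full <- as.matrix(pae_full)
  stopifnot(nrow(pae_full) == ncol(pae_full))
  if (length(intersect(tcr_span, pmhc_span)))
    stop("tcr_span and pmhc_span overlap")
  stopifnot(all(c(tcr_span, pmhc_span) >= 1),
            all(c(tcr_span, pmhc_span) <= nrow(pae_full)))
  vals <- c(pae_full[tcr_span, pmhc_span], pae_full[pmhc_span, tcr_span])
  if (pool == "mean") mean(vals) else sum(vals)
}

#' Select the best of several models by interface PAE
#'
#' @param interface_paes Numeric vector of per-run interface PAEs.
#' @return Index of the smallest value; ties go to the lowest run index.
#' @export
select_best_model <- function(interface_paes) {
  stopifnot(length(interface_paes) >= 1, all(is.finite(interface_paes)))
  which.min(interface_paes)
}

#' Corrected binding scores from interface PAE
#'
#' `B[i, j] = (PAE[i, j] - bg[j]) - mean_j(PAE[i, ] - bg)`: the per-peptide
#' background mean removes pMHC-intrinsic accuracy offsets, then each row
#' is shifted to mean zero to remove TCR-intrinsic offsets. Every row mean
#' of the result is 0 (to 1e-9); column means reflect the repertoire-level
#' preference for each peptide.
#'
#' @param pae A [pae_matrix()].
#' @param bg A [background_means()] with one mean per peptide column.
#' @return An object of class `binding_score_matrix` with `values`,
#'   `tcr_ids`, `peptides`, `wt_index`.
#' @export
binding_scores <- function(pae, bg) {
  if (length(bg$means) != ncol(pae$values))
    stop("background means length ", length(bg$means),
         " != number of peptides ", ncol(pae$values))
  adj <- sweep(pae$values, 2, bg$means)
  B <- adj - rowMeans(adj)
  structure(list(values = B, tcr_ids = pae$tcr_ids, peptides = pae$peptides,
                 wt_index = pae$wt_index,
                 n_background = bg$n_background),
            class = "binding_score_matrix")
}

#' Rank of the wild-type peptide within a TCR's scores
#'
#' Counts peptides scoring strictly lower (better) than the wild type;
#' ties do not count against the wild type. 0 = best possible.
#'
#' @param row Numeric score vector over peptides (lower = better).
#' @param wt_index Wild-type column index.
#' @return Integer in `[0, length(row) - 1]`.
#' @export
wt_rank <- function(row, wt_index) {
  sum(row < row[wt_index])
}

#' @rdname wt_rank
#' @param B A `binding_score_matrix`.
#' @return `wt_ranks`: integer vector of per-TCR wild-type ranks.
#' @export
wt_ranks <- function(B) {
  apply(B$values, 1, wt_rank, wt_index = B$wt_index)
}

#' Repertoire-level binding scores
#'
#' Column means of the binding-score matrix over a TCR subset (all rows by
#' default). Subset averaging also serves per-clade scores when coloring
#' repertoire trees.
#'
#' @param B A `binding_score_matrix`.
#' @param group Optional row subset (indices or ids).
#' @return Named numeric vector, one score per peptide.
#' @export
repertoire_scores <- function(B, group = NULL) {
  V <- B$values
  if (!is.null(group)) V <- V[group, , drop = FALSE]
  colMeans(V)
}

#' Area under the ROC curve for binder/decoy discrimination
#'
#' Probability that a randomly chosen true binder scores below (better
#' than) a randomly chosen decoy, ties counted 1/2; equals the normalized
#' Wilcoxon-Mann-Whitney statistic computed via midranks.
#'
#' @param scores Numeric scores, lower = predicted binder.
#' @param labels Logical (or 0/1): `TRUE` for true binders.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)  # midranks
  # rank-sum of decoys: decoys should score high
  (sum(r[!labels]) - n0 * (n0 + 1) / 2) / (n0 * n1)
}

#' ROC curve points
#'
#' @inheritParams auroc
#' @return data.frame with `threshold`, `tpr` (binders called), `fpr`
#'   (decoys called), sweeping the score cutoff.
#' @export
roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  o <- order(scores)
  data.frame(threshold = scores[o],
             tpr = cumsum(labels[o]) / sum(labels),
             fpr = cumsum(!labels[o]) / sum(!labels))
}

#' Alanine-scan mutant peptides
#'
#' One mutant per position: residue to alanine, alanine residues to
#' glycine.
#'
#' @param wt Wild-type peptide sequence.
#' @return data.frame with `position` (1-based), `peptide`.
#' @export
alanine_scan_peptides <- function(wt) {
  stopifnot(nzchar(wt))
  ch <- strsplit(wt, "")[[1]]
  muts <- vapply(seq_along(ch), function(p) {
    m <- ch
    m[p] <- if (ch[p] == "A") "G" else "A"
    paste(m, collapse = "")
  }, "")
  data.frame(position = seq_along(ch), peptide = muts,
             stringsAsFactors = FALSE)
}

#' Per-position alanine-scan deltas
#'
#' Difference between each mutant's repertoire-averaged binding score and
#' the wild type's; positive delta = mutation predicted to weaken binding.
#'
#' @param rep_scores Named numeric vector of repertoire scores whose
#'   `wt_index` entry is the wild type and remaining entries are the
#'   positional mutants in position order.
#' @param wt_index Index of the wild-type column (default 1).
#' @return Numeric vector of deltas, one per mutated position.
#' @export
scan_deltas <- function(rep_scores, wt_index = 1L) {
  rep_scores[-wt_index] - rep_scores[wt_index]
}

#' Deterministic mock peptide:MHC binding predictor
#'
#' A fixed hash-based pseudo-score standing in for a neural pMHC binding
#' predictor in tests and examples. Maps (peptide, allele) to a
#' reproducible value in `[0, 1)`; lower = better predicted binder.
#'
#' @param peptide Peptide sequence.
#' @param allele MHC allele name (folded into the hash).
#' @return Score in `[0, 1)`.
#' @export
mock_mhc_predictor <- function(peptide, allele = "") {
  codes <- utf8ToInt(paste0(allele, ":", peptide))
  h <- 0
  for (c in codes) h <- (h * 131 + c) %% 1000003
  h / 1000003
}

#' Select decoy peptides from a shuffled artificial antigen
#'
#' Concatenates the source antigen sequences, shuffles the characters with
#' a fixed seed, truncates to `pool_len` residues, scores every
#' `length`-mer with the supplied predictor, and returns the top `k`
#' unique peptides (best score first), excluding any peptide identical to
#' a supplied wild-type epitope.
#'
#' @param antigens Character vector of source antigen sequences
#'   (concatenated length >= `pool_len`).
#' @param predictor Function `(peptide, allele) -> score`, lower = better;
#'   default [mock_mhc_predictor()].
#' @param allele Allele passed to the predictor.
#' @param length Peptide length (default 9).
#' @param k Number of decoys (default 9).
#' @param pool_len Length of the shuffled artificial antigen (default
#'   1500).
#' @param exclude Wild-type epitopes never returned as decoys.
#' @param seed Integer shuffle seed.
#' @return Character vector of `k` decoy peptides, best score first.
#' @export
select_decoys <- function(antigens, predictor = mock_mhc_predictor,
                          allele = "", length = 9L, k = 9L,
                          pool_len = 1500L, exclude = character(0),
                          seed = 1L) {
  pool <- strsplit(paste(antigens, collapse = ""), "")[[1]]
  if (base::length(pool) < pool_len)
    stop("concatenated antigens have ", base::length(pool),
         " residues; need >= ", pool_len)
  pool <- with_seed(seed, sample(pool))[seq_len(pool_len)]
  starts <- seq_len(pool_len - length + 1L)
  kmers <- vapply(starts, function(s)
    paste(pool[s:(s + length - 1L)], collapse = ""), "")
  kmers <- setdiff(unique(kmers), exclude)
  scores <- vapply(kmers, predictor, 0, allele = allele)
  o <- order(scores, kmers)
  if (base::length(kmers) < k)
    stop("fewer than ", k, " unique candidate peptides")
  kmers[o][seq_len(k)]
}

#' Read and write pooled PAE / binding-score tables
#'
#' TSV layout: first column `tcr_id`, remaining columns one per peptide.
#'
#' @param path TSV file.
#' @param wt_index Wild-type column (among the peptide columns).
#' @return `read_pae_tsv`: a [pae_matrix()].
#' @export
read_pae_tsv <- function(path, wt_index = 1L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  M <- as.matrix(tab[, -1, drop = FALSE])
  rownames(M) <- tab[[1]]
  pae_matrix(M, wt_index = wt_index)
}

#' @rdname read_pae_tsv
#' @param x A `pae_matrix` or `binding_score_matrix`.
#' @export
write_score_tsv <- function(x, path) {
  tab <- data.frame(tcr_id = x$tcr_ids, x$values, check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-complex PAE JSON file
#'
#' JSON with fields `pae` (square matrix), `tcr_span`, `pmhc_span`
#' (1-based index arrays).
#'
#' @param path JSON file.
#' @param pool Passed to [mean_interface_pae()].
#' @return Scalar interface PAE.
#' @export
read_pae_json <- function(path, pool = "mean") {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mean_interface_pae(obj$pae, obj$tcr_span, obj$pmhc_span, pool = pool)
}
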