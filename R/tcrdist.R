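#' TCRdist-style sequence distances and repertoire operations
#'
#' An additive weighted mismatch distance over the CDR loops: CDR1, CDR2
#' and CDR2.5 contribute with weight 1, CDR3 with weight 3. The
#' per-position substitution cost is `min(4, 4 - BLOSUM62(a, b))` (0 for an
#' identical pair, capped at 4 for non-conservative changes); gaps cost 4.
#' CDR3 loops are compared after trimming fixed flanks (3 N-terminal, 2
#' C-terminal residues) and center-gapping the shorter trimmed loop.
#'
#' @name tcr_distance
NULL

#' Single TCR chain sequence
#'
#' @param v_gene V gene name; when `cdr1`/`cdr2`/`cdr25` are omitted they
#'   are filled from the shipped V-gene lookup table ([vgene_cdr_loops()]).
#' @param cdr1,cdr2,cdr25 Germline CDR loop sequences.
#' @param cdr3 CDR3 sequence (length >= 5).
#' @return An object of class `tcr_chain`.
#' @export
tcr_chain <- function(v_gene, cdr1 = NULL, cdr2 = NULL, cdr25 = NULL, cdr3) {
  if (is.null(cdr1) || is.null(cdr2) || is.null(cdr25)) {
    loops <- vgene_cdr_loops(v_gene)
    if (is.null(cdr1)) cdr1 <- loops$cdr1
    if (is.null(cdr2)) cdr2 <- loops$cdr2
    if (is.null(cdr25)) cdr25 <- loops$cdr25
  }
  stopifnot(nzchar(cdr1), nzchar(cdr2), nzchar(cdr25), nchar(cdr3) >= 5)
  structure(list(v_gene = v_gene, cdr1 = cdr1, cdr2 = cdr2,
                 cdr25 = cdr25, cdr3 = cdr3),
            class = "tcr_chain")
}

#' Paired alpha/beta TCR
#'
#' @param alpha,beta [tcr_chain()] objects.
#' @param id Label.
#' @return An object of class `paired_tcr`.
#' @export
paired_tcr <- function(alpha, beta, id = "tcr") {
  stopifnot(inherits(alpha, "tcr_chain"), inherits(beta, "tcr_chain"))
  structure(list(alpha = alpha, beta = beta, id = id), class = "paired_tcr")
}

## BLOSUM62 cached at first use
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

## per-position substitution cost; gap ('-') costs gap_cost
tcrdist_position_cost <- function(a, b, cap = 4, gap_cost = 4) {
  if (a == "-" || b == "-") return(gap_cost)
  if (a == b) return(0)
  B <- blosum62_matrix()
  if (!(a %in% rownames(B)) || !(b %in% colnames(B))) return(cap)
  min(cap, cap - B[a, b])
}

## align two loops of possibly different length by center-gapping the
## shorter; returns a 2 x L character matrix
center_gap_align <- function(s1, s2) {
  c1 <- strsplit(s1, "")[[1]]; c2 <- strsplit(s2, "")[[1]]
  L <- max(length(c1), length(c2))
  pad <- function(ch) {
    gaps <- L - length(ch)
    if (gaps == 0) return(ch)
    head_n <- ceiling(length(ch) / 2)
    c(ch[seq_len(head_n)], rep("-", gaps), ch[-seq_len(head_n)])
  }
  rbind(pad(c1), pad(c2))
}

loop_mismatch_cost <- function(s1, s2, cap = 4, gap_cost = 4) {
  al <- center_gap_align(s1, s2)
  sum(vapply(seq_len(ncol(al)),
             function(k) tcrdist_position_cost(al[1, k], al[2, k],
                                               cap, gap_cost),
             numeric(1)))
}

trim_cdr3 <- function(s, n_trim = 3, c_trim = 2) {
  n <- nchar(s)
  if (n <= n_trim + c_trim) return("")
  substr(s, n_trim + 1, n - c_trim)
}

#' Single-chain TCRdist
#'
#' @param a,b [tcr_chain()] objects.
#' @param cdr3_weight Weight of the CDR3 contribution (default 3).
#' @param cap,gap_cost Substitution cost cap and gap cost (default 4 each).
#' @return Non-negative distance; 0 iff all four loops are identical.
#' @export
single_chain_tcrdist <- function(a, b, cdr3_weight = 3, cap = 4,
                                 gap_cost = 4) {
  d <- loop_mismatch_cost(a$cdr1, b$cdr1, cap, gap_cost) +
    loop_mismatch_cost(a$cdr2, b$cdr2, cap, gap_cost) +
    loop_mismatch_cost(a$cdr25, b$cdr25, cap, gap_cost)
  d + cdr3_weight * loop_mismatch_cost(trim_cdr3(a$cdr3), trim_cdr3(b$cdr3),
                                       cap, gap_cost)
}

#' Paired TCRdist
#'
#' Sum of the alpha- and beta-chain single-chain distances.
#'
#' @param t1,t2 [paired_tcr()] objects.
#' @inheritParams single_chain_tcrdist
#' @return Non-negative distance.
#' @export
paired_tcrdist <- function(t1, t2, cdr3_weight = 3, cap = 4, gap_cost = 4) {
  single_chain_tcrdist(t1$alpha, t2$alpha, cdr3_weight, cap, gap_cost) +
    single_chain_tcrdist(t1$beta, t2$beta, cdr3_weight, cap, gap_cost)
}

#' Pairwise paired-TCRdist matrix
#'
#' @param tcrs List of [paired_tcr()].
#' @return Symmetric distance matrix with TCR ids as dimnames.
#' @export
paired_tcrdist_matrix <- function(tcrs) {
  n <- length(tcrs)
  ids <- vapply(tcrs, `[[`, "", "id")
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n < 2) return(D)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- paired_tcrdist(tcrs[[i]], tcrs[[j]])
  D
}

#' Redundancy filter for structure/repertoire entries
#'
#' Greedy scan in input order (use deposit-date order to keep the earliest
#' structure): an entry is dropped when some already-kept entry has both
#' fewer than `pep_thresh` peptide mismatches and a paired TCRdist less
#' than or equal to `dist_thresh`. The kept set satisfies the pairwise
#' guarantee that no two members violate both thresholds.
#'
#' @param entries List of `list(tcr = paired_tcr, peptide = string)`.
#' @param pep_thresh Peptide mismatch threshold (default 3).
#' @param dist_thresh Paired TCRdist threshold (default 120).
#' @return Integer indices of the kept entries.
#' @export
redundancy_filter <- function(entries, pep_thresh = 3, dist_thresh = 120) {
  kept <- integer(0)
  for (i in seq_along(entries)) {
    redundant <- FALSE
    for (k in kept) {
      if (peptide_mismatches(entries[[i]]$peptide,
                             entries[[k]]$peptide) < pep_thresh &&
          paired_tcrdist(entries[[i]]$tcr, entries[[k]]$tcr) <= dist_thresh) {
        redundant <- TRUE
        break
      }
    }
    if (!redundant) kept <- c(kept, i)
  }
  kept
}

#' Density-based repertoire subsampling
#'
#' Selects up to `n` representatives preferring denser regions of TCR
#' space while avoiding redundancy: each candidate is scored by a Gaussian
#' kernel density over paired TCRdist (`sum(exp(-d^2 / (2 bandwidth^2)))`),
#' and candidates are accepted in decreasing density order provided their
#' distance to every already-selected TCR exceeds `min_dist`. Exact density
#' ties are broken by a seeded random jitter, so the result is
#' deterministic given the seed and stable under input permutation up to
#' ties.
#'
#' @param tcrs List of [paired_tcr()].
#' @param n Maximum representatives (default 50).
#' @param bandwidth Kernel bandwidth in TCRdist units (default 120).
#' @param min_dist Minimum pairwise TCRdist among selected (default 24).
#' @param seed Integer seed for tie-breaking.
#' @return Integer indices of the selected TCRs, densest first.
#' @export
kde_subsample <- function(tcrs, n = 50L, bandwidth = 120, min_dist = 24,
                          seed = 1L) {
  stopifnot(n >= 1)
  m <- length(tcrs)
  if (m == 0) return(integer(0))
  D <- paired_tcrdist_matrix(tcrs)
  density <- rowSums(exp(-D^2 / (2 * bandwidth^2)))
  jitter <- with_seed(seed, stats::runif(m, 0, 1e-9))
  ord <- order(-(density + jitter))
  selected <- integer(0)
  for (i in ord) {
    if (length(selected) >= n) break
    if (length(selected) == 0 || all(D[i, selected] > min_dist))
      selected <- c(selected, i)
  }
  selected
}

#' Average-linkage tree of a TCR repertoire
#'
#' Hierarchical clustering (average linkage) over paired TCRdist, exported
#' as a `phylo` tree / newick string for downstream repertoire displays.
#'
#' @param tcrs List of [paired_tcr()].
#' @param path Optional file; when given, the newick string is written.
#' @return An [ape::as.phylo()] tree, invisibly if written to file.
#' @export
tcr_cluster_tree <- function(tcrs, path = NULL) {
  D <- paired_tcrdist_matrix(tcrs)
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  tree <- ape::as.phylo(hc)
  if (!is.null(path)) {
    ape::write.tree(tree, file = path)
    return(invisible(tree))
  }
  tree
}

#' Read and write repertoire TSV files
#'
#' Columns: id, organism, va, ja, cdr3a, vb, jb, cdr3b, epitope.
#'
#' @param path TSV file.
#' @return `read_repertoire`: list of [paired_tcr()] with `epitope` and
#'   `organism` attributes per element.
#' @export
read_repertoire <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(tab)), function(i) {
    tcr <- paired_tcr(tcr_chain(tab$va[i], cdr3 = tab$cdr3a[i]),
                      tcr_chain(tab$vb[i], cdr3 = tab$cdr3b[i]),
                      id = tab$id[i])
    attr(tcr, "epitope") <- tab$epitope[i]
    attr(tcr, "organism") <- tab$organism[i]
    tcr
  })
}

#' @rdname read_repertoire
#' @param tcrs List of [paired_tcr()].
#' @param epitope,organism Recycled annotation columns.
#' @export
write_repertoire <- function(tcrs, path, epitope = "", organism = "human") {
  tab <- data.frame(
    id = vapply(tcrs, `[[`, "", "id"),
    organism = rep_len(organism, length(tcrs)),
    va = vapply(tcrs, function(t) t$alpha$v_gene, ""),
    ja = "TRAJ-SYN1",
    cdr3a = vapply(tcrs, function(t) t$alpha$cdr3, ""),
    vb = vapply(tcrs, function(t) t$beta$v_gene, ""),
    jb = "TRBJ-SYN1",
    cdr3b = vapply(tcrs, function(t) t$beta$cdr3, ""),
    epitope = rep_len(epitope, length(tcrs)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
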