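test_that("interface PAE pools both off-diagonal blocks", {
  M <- matrix(1:16, 4, 4)
  # TCR residues {1,2}, pMHC residues {3,4}: eight off-block entries
  hand <- mean(c(M[1, 3], M[1, 4], M[2, 3], M[2, 4],
                 M[3, 1], M[3, 2], M[4, 1], M[4, 2]))
  expect_equal(mean_interface_pae(M, c(1, 2), c(3, 4)), hand)
  expect_equal(mean_interface_pae(matrix(7, 5, 5), c(1, 3), c(2, 4)), 7)
  # permuting residues within a span changes nothing
  expect_equal(mean_interface_pae(M, c(2, 1), c(4, 3)),
               mean_interface_pae(M, c(1, 2), c(3, 4)))
  expect_equal(mean_interface_pae(M, c(1, 2), c(3, 4), pool = "sum"),
               8 * hand)
  expect_error(mean_interface_pae(M, c(1, 2), c(2, 3)), "overlap")
})

test_that("best-of-three model selection takes the lowest PAE", {
  expect_identical(select_best_model(c(5.1, 4.2, 6.0)), 2L)
  expect_identical(select_best_model(c(4, 4, 4)), 1L)
  expect_identical(select_best_model(c(5.1, 4.2, 6.0) + 10), 2L)
})

test_that("binding-score correction removes intrinsic effects", {
  # pure intrinsic structure cancels exactly
  sim0 <- make_synthetic_pae(pae_sim_spec(n_tcrs = 20, beta = 0, sigma = 0,
                                          seed = 81))
  B0 <- binding_scores(sim0$pae, sim0$background)
  expect_lt(max(abs(B0$values)), 1e-9)
  # any input: every row mean is zero
  sim <- make_synthetic_pae(pae_sim_spec(seed = 82))
  B <- binding_scores(sim$pae, sim$background)
  expect_lt(max(abs(rowMeans(B$values))), 1e-9)
  # hand-computed 2 x 3 case
  P <- matrix(c(5, 7, 6, 9, 8, 10), 2, 3)
  bg <- c(1, 2, 3)
  adj <- sweep(P, 2, bg)
  hand <- adj - rowMeans(adj)
  got <- binding_scores(pae_matrix(P, wt_index = 1),
                        background_means(bg, 5))
  expect_equal(unname(got$values), hand)
  expect_error(binding_scores(pae_matrix(P), background_means(c(1, 2), 5)),
               "!=")
})

test_that("binding scores are invariant to row/column shifts", {
  sim <- make_synthetic_pae(pae_sim_spec(n_tcrs = 10, seed = 83))
  B <- binding_scores(sim$pae, sim$background)
  # add per-row constants to the PAE
  shifted <- sim$pae
  rowc <- seq_len(nrow(shifted$values))
  shifted$values <- shifted$values + rowc
  B2 <- binding_scores(shifted, sim$background)
  expect_equal(B2$values, B$values, tolerance = 1e-9)
  # add per-column constants to PAE and background simultaneously
  colc <- seq_len(ncol(sim$pae$values))
  shifted2 <- sim$pae
  shifted2$values <- sweep(sim$pae$values, 2, colc, "+")
  bg2 <- background_means(sim$background$means + colc,
                          sim$background$n_background)
  B3 <- binding_scores(shifted2, bg2)
  expect_equal(B3$values, B$values, tolerance = 1e-9)
})

test_that("wild-type rank counts strictly better decoys only", {
  expect_identical(wt_rank(c(1, 5, 9, 2), 1), 0L)
  expect_identical(wt_rank(c(1:9, 10), 10), 9L)
  row <- c(3, 1, 3, 4, 5, 6, 7, 8, 9, 10)  # WT (col 1) tied with col 3
  expect_identical(wt_rank(row, 1), 1L)
  # invariant under strictly monotone transforms
  withr::local_seed(84)
  for (rep in 1:20) {
    r <- rnorm(10)
    expect_identical(wt_rank(r, 3), wt_rank(exp(2 * r) - 5, 3))
  }
})

test_that("repertoire scores are column means over the chosen subset", {
  sim <- make_synthetic_pae(pae_sim_spec(n_tcrs = 6, seed = 85))
  B <- binding_scores(sim$pae, sim$background)
  expect_equal(sum(repertoire_scores(B)), 0, tolerance = 1e-9)
  expect_equal(repertoire_scores(B, 4), B$values[4, ])
  expect_equal(repertoire_scores(B, c(2, 5)),
               colMeans(B$values[c(2, 5), ]))
})

test_that("AUROC equals pairwise concordance and handles ties", {
  expect_equal(auroc(c(1, 2, 8, 9), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(auroc(rep(3, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  brute <- function(s, l) {
    b <- s[l]; d <- s[!l]
    mean(outer(b, d, function(x, y) (x < y) + 0.5 * (x == y)))
  }
  withr::local_seed(86)
  for (rep in 1:20) {
    s <- sample(1:6, 30, replace = TRUE)  # many ties
    l <- runif(30) < 0.4
    if (!any(l) || all(l)) next
    expect_equal(auroc(s, l), brute(s, l))
  }
  # independent labels: AUROC near 1/2 at large n
  s <- rnorm(10000); l <- runif(10000) < 0.5
  expect_lt(abs(auroc(s, l) - 0.5), 0.02)
  # cross-check against an established ROC implementation
  skip_if_not_installed("pROC")
  s <- rnorm(200); l <- runif(200) < 0.5
  ref <- as.numeric(pROC::auc(pROC::roc(response = l, predictor = s,
                                        direction = ">", quiet = TRUE)))
  expect_equal(auroc(s, l), ref, tolerance = 1e-12)
})

test_that("alanine scan mutates every position; A goes to G", {
  scan <- alanine_scan_peptides("ASNENMETM")
  expect_equal(nrow(scan), 9)
  expect_identical(scan$peptide[1], "GSNENMETM")
  expect_identical(scan$peptide[2], "AANENMETM")
  scan2 <- alanine_scan_peptides("GILGFVFTL")
  expect_equal(nrow(scan2), 9)
  expect_false(any(scan2$peptide == "GILGFVFTL"))
  for (p in seq_len(9))
    expect_equal(sum(strsplit(scan2$peptide[p], "")[[1]] !=
                       strsplit("GILGFVFTL", "")[[1]]), 1)
})

test_that("scan deltas difference mutants against the wild type", {
  rs <- c(wt = 0.0, m1 = 0.0, m2 = 1.5, m3 = -0.5)
  expect_equal(unname(scan_deltas(rs, 1)), c(0, 1.5, -0.5))
  # hand-computed 2x3 case through the full stack
  P <- matrix(c(5, 7, 6, 9, 8, 10), 2, 3)
  B <- binding_scores(pae_matrix(P, wt_index = 1), background_means(c(0, 0, 0), 1))
  expect_equal(unname(scan_deltas(repertoire_scores(B), 1)),
               unname(colMeans(B$values)[2:3] - colMeans(B$values)[1]))
})

test_that("decoy selection is deterministic and honors the mock ranking", {
  antigens <- withr::with_seed(87, replicate(9, paste(
    sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 180, TRUE),
    collapse = "")))
  d1 <- select_decoys(antigens, length = 9, k = 9, seed = 5)
  d2 <- select_decoys(antigens, length = 9, k = 9, seed = 5)
  expect_identical(d1, d2)
  expect_length(d1, 9)
  expect_true(all(nchar(d1) == 9))
  expect_equal(anyDuplicated(d1), 0)
  # brute-force oracle: lexicographic mock predictor picks the k
  # alphabetically first unique 9-mers of the shuffled pool
  lex <- function(peptide, allele = "") {
    codes <- utf8ToInt(peptide) - 65
    sum(codes * 26^(rev(seq_along(codes)) - 1)) / 26^length(codes)
  }
  pool <- withr::with_seed(5, sample(strsplit(paste(antigens, collapse = ""),
                                              "")[[1]]))[1:1500]
  kmers <- unique(vapply(1:1492, function(s)
    paste(pool[s:(s + 8)], collapse = ""), ""))
  expect_identical(select_decoys(antigens, predictor = lex, length = 9,
                                 k = 9, seed = 5),
                   sort(kmers)[1:9])
  # wild-type exclusion
  wt <- d1[1]
  d3 <- select_decoys(antigens, length = 9, k = 9, seed = 5, exclude = wt)
  expect_false(wt %in% d3)
  expect_length(d3, 9)
})

test_that("planted binding signal is recovered; no signal gives chance", {
  sim <- make_synthetic_pae(pae_sim_spec(n_tcrs = 50, n_peptides = 10,
                                         beta = 3, sigma = 1, seed = 88))
  B <- binding_scores(sim$pae, sim$background)
  expect_gt(mean(wt_ranks(B) == 0), 0.9)
  labels <- col(B$values) == B$wt_index
  expect_gt(auroc(as.numeric(B$values), as.logical(labels)), 0.95)
  # null: beta = 0 gives AUROC near 1/2 over replicates
  aucs <- vapply(1:20, function(r) {
    s <- make_synthetic_pae(pae_sim_spec(n_tcrs = 50, beta = 0, sigma = 1,
                                         seed = 100 + r))
    b <- binding_scores(s$pae, s$background)
    auroc(as.numeric(b$values), as.logical(col(b$values) == b$wt_index))
  }, 0)
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("PAE TSV and JSON readers round-trip", {
  sim <- make_synthetic_pae(pae_sim_spec(n_tcrs = 5, seed = 89))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_score_tsv(sim$pae, path)
  back <- read_pae_tsv(path, wt_index = 1)
  expect_equal(back$values, sim$pae$values, tolerance = 1e-9)
  jpath <- withr::local_tempfile(fileext = ".json")
  M <- matrix(runif(64, 1, 20), 8, 8)
  jsonlite::write_json(list(pae = M, tcr_span = 1:3, pmhc_span = 5:8),
                       jpath, digits = NA)
  expect_equal(read_pae_json(jpath), mean_interface_pae(M, 1:3, 5:8),
               tolerance = 1e-12)
})
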