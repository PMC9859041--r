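db10 <- make_template_db(10)

target_from_record <- function(rec) {
  tcr <- tcrpmhc:::record_tcr(rec)
  target_spec(mhc_class = 1,
              mhc_seq = role_seq(rec$complex, "mhc"),
              peptide = rec$complex$annotation$peptide,
              alpha = tcr$alpha, beta = tcr$beta,
              id = paste0("tg_", rec$pdb_id))
}

test_that("benchmark masking excludes self and near-identical records", {
  target <- target_from_record(db10[[1]])
  mask <- exclusion_mask(target, db10, mode = "benchmark")
  self <- mask[mask$pdb_id == db10[[1]]$pdb_id, ]
  expect_false(any(unlist(self[, c("pmhc", "tcra", "tcrb", "geometry")])))
  # flags agree with the quoted thresholds, record by record
  for (i in seq_along(db10)) {
    rec <- db10[[i]]
    tcr <- tcrpmhc:::record_tcr(rec)
    mm <- peptide_mismatches(target$peptide, rec$complex$annotation$peptide)
    da <- single_chain_tcrdist(target$alpha, tcr$alpha)
    dbd <- single_chain_tcrdist(target$beta, tcr$beta)
    expect_identical(mask$pmhc[i], mm >= 3)
    expect_identical(mask$tcra[i], da > 36)
    expect_identical(mask$geometry[i], mm >= 3 && (da + dbd) > 48)
  }
  # production mode: only the date cutoff applies
  prod <- exclusion_mask(target, db10, mode = "production")
  expect_true(all(prod$pmhc & prod$tcra & prod$tcrb & prod$geometry))
  old <- exclusion_mask(target, db10, mode = "production",
                        date_cutoff = db10[[5]]$deposit_date)
  expect_identical(prod$pdb_id[old$pmhc], prod$pdb_id[1:5])
})

test_that("paired TCRdist at the geometry threshold behaves as a boundary", {
  rec <- db10[[2]]
  tcr <- tcrpmhc:::record_tcr(rec)
  # target differing by exactly four non-conservative CDR3 subs: dist 48
  # (record 2 carries CDR3a "CAGQWDMRFG"; the trimmed region QWDMR is
  # mutated at four positions to residues with BLOSUM62 <= 0)
  at48 <- tcr_chain("TRAV-SYN1", cdr3 = "CAGWPWMWFG")
  expect_equal(single_chain_tcrdist(at48, tcr$alpha), 48)
  tg48 <- target_spec(1, tcrpmhc:::MHC_REF_SEQ, "AAAAAAAAA",
                      alpha = at48, beta = tcr$beta)
  m48 <- exclusion_mask(tg48, db10, mode = "benchmark")
  expect_false(m48$geometry[2])  # 48 <= 48: excluded
  # one extra conservative CDR1 sub (I->V, cost 1) pushes it to 49
  at49 <- tcr_chain("TRAV-SYN1", cdr1 = "DSAV", cdr2 = "IQSS", cdr25 = "FKG",
                    cdr3 = at48$cdr3)
  tg49 <- target_spec(1, tcrpmhc:::MHC_REF_SEQ, "AAAAAAAAA",
                      alpha = at49, beta = tcr$beta)
  m49 <- exclusion_mask(tg49, db10, mode = "benchmark")
  expect_true(m49$geometry[2])  # 49 > 48: usable
})

test_that("chain template selection ranks by identity / tcrdist with ties", {
  target <- target_from_record(db10[[1]])
  mask <- exclusion_mask(target, db10, mode = "production")
  sel <- select_chain_templates(target, db10, mask, n = 4)
  # the identical record ranks first for every role in production mode
  expect_identical(sel$pmhc[[1]]$pdb_id, db10[[1]]$pdb_id)
  expect_identical(sel$tcra[[1]]$pdb_id, db10[[1]]$pdb_id)
  expect_identical(sel$tcrb[[1]]$pdb_id, db10[[1]]$pdb_id)
  # equally distant records: earlier deposit date wins (db is date-ordered,
  # and records 2.. share the target's distance ordering computed here)
  da <- vapply(db10, function(r)
    single_chain_tcrdist(target$alpha, tcrpmhc:::record_tcr(r)$alpha), 0)
  expected <- vapply(db10, `[[`, "", "pdb_id")[order(da, seq_along(db10))][1:4]
  expect_identical(vapply(sel$tcra, `[[`, "", "pdb_id"), expected)

  # benchmark mode with some records disallowed returns only allowed ones
  bmask <- exclusion_mask(target_from_record(db10[[3]]), db10,
                          mode = "benchmark")
  bsel <- select_chain_templates(target_from_record(db10[[3]]), db10, bmask,
                                 n = 4)
  allowed <- bmask$pdb_id[bmask$tcra]
  expect_true(all(vapply(bsel$tcra, `[[`, "", "pdb_id") %in% allowed))
  # too few templates is a clear error
  expect_error(select_chain_templates(target, db10, mask, n = 40), "fewer")
})

test_that("representative geometries recover planted clusters as medoids", {
  withr::local_seed(71)
  bases <- planted_base_geometries(12)
  geoms <- list(); labels <- integer(0)
  for (b in seq_along(bases)) {
    size <- 2 + (b %% 3)
    for (m in seq_len(size)) {
      geoms <- c(geoms, list(perturb_geometry(bases[[b]], sd = 0.01)))
      labels <- c(labels, b)
    }
  }
  # sanity: planted structure is separable
  D <- docking_rmsd_matrix(geoms)
  reps <- select_representative_geometries(geoms, k = 12)
  idx <- attr(reps, "indices")
  expect_length(reps, 12)
  expect_setequal(labels[idx], 1:12)  # one representative per planted cluster
  # medoid property, brute force within each recovered cluster
  cl <- attr(reps, "clusters")
  for (c_id in unique(cl)) {
    members <- which(cl == c_id)
    rep_i <- intersect(idx, members)
    expect_length(rep_i, 1)
    if (length(members) > 1) {
      mean_d <- vapply(members, function(i) mean(D[i, setdiff(members, i)]), 0)
      expect_equal(mean_d[members == rep_i], min(mean_d), tolerance = 1e-12)
    }
  }
  # exactly k distinct inputs: the input set itself
  just12 <- select_representative_geometries(bases, k = 12)
  expect_setequal(attr(just12, "indices"), 1:12)
  expect_error(select_representative_geometries(bases[1:5], k = 12),
               "at least 12")
})

test_that("hybrid self-assembly reproduces the source structure", {
  rec <- db10[[4]]
  hyb <- assemble_hybrid_template(rec, rec, rec, rec$geometry,
                                  geometry_index = 1)
  src <- rec$complex$residues
  src <- src[src$role %in% c("mhc", "peptide", "tcra", "tcrb"), ]
  expect_identical(hyb$residues$role, src$role)
  expect_lt(max(abs(as.matrix(hyb$residues[, c("x", "y", "z")]) -
                      as.matrix(src[, c("x", "y", "z")]))), 1e-3)
  gv <- geometry_vector(hyb$realized_geometry) - geometry_vector(rec$geometry)
  gv[c(2, 4, 6)] <- tcrpmhc:::wrap_angle(gv[c(2, 4, 6)])
  expect_lt(max(abs(gv)), 1e-6)
})

test_that("assembly realizes the requested geometry for mixed donors", {
  withr::local_seed(72)
  for (rep in 1:5) {
    donors <- sample(seq_along(db10), 3)
    g <- random_docking_geometry()
    hyb <- assemble_hybrid_template(db10[[donors[1]]], db10[[donors[2]]],
                                    db10[[donors[3]]], g)
    gv <- geometry_vector(hyb$realized_geometry) - geometry_vector(g)
    gv[c(2, 4, 6)] <- tcrpmhc:::wrap_angle(gv[c(2, 4, 6)])
    expect_lt(max(abs(gv[-1])), 1e-5)
    expect_lt(abs(gv[1]), 1e-3)
    expect_identical(unname(hyb$source_ids),
                     vapply(db10[donors], `[[`, "", "pdb_id"))
  }
})

test_that("run manifest is 3 runs x 4 templates covering 12 geometries once", {
  withr::local_seed(73)
  db14 <- make_template_db(14, seed = 142)
  target <- target_from_record(db14[[1]])
  mask <- exclusion_mask(target, db14, mode = "production")
  sel <- select_chain_templates(target, db14, mask, n = 4)
  reps <- select_representative_geometries(
    lapply(db14, `[[`, "geometry"), k = 12)
  out <- withr::local_tempdir()
  manifest <- build_run_manifest(target, sel, reps, out_dir = out)
  expect_length(manifest$runs, 3)
  expect_true(all(lengths(manifest$runs) == 4))
  entries <- do.call(c, manifest$runs)
  expect_setequal(vapply(entries, `[[`, 0L, "geometry_index"), 1:12)
  expect_length(list.files(out, pattern = "\\.pdb$"), 12)
  expect_true(file.exists(file.path(out, paste0(target$id, "_manifest.json"))))
  # chain-template assignment identical across runs
  ranks <- vapply(manifest$runs, function(run)
    paste(vapply(run, function(e)
      paste(unlist(e$source_ids), collapse = "|"), ""), collapse = ";"), "")
  expect_length(unique(ranks), 1)
  expect_error(build_run_manifest(target, sel, reps[1:11], out_dir = out),
               "12")
})
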