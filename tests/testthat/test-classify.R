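test_that("residues qualify by the sign of their enrichment factor", {
  expect_equal(qualify_residue(0.45), "T")
  expect_equal(qualify_residue(-0.05), "H")
  expect_equal(qualify_residue(0), "unclassified")
  expect_equal(qualify_residue(c(0.2, -0.3, 0)),
               c("T", "H", "unclassified"))
})

test_that("contacts qualify from both endpoints", {
  expect_equal(qualify_contact("T", "T"), "T")
  expect_equal(qualify_contact("H", "H"), "H")
  expect_equal(qualify_contact("T", "H"), "mixed")
  expect_equal(qualify_contact("T", "unclassified"), "unclassified")
  expect_equal(qualify_contact("H", "unclassified"), "unclassified")
})

test_that("contact counts add up and degenerate members are flagged", {
  synth <- default_synth()
  tab <- synth$tab
  enr <- synth$enr
  rec <- classification_records(tab, enr, mode = "aa")
  expect_equal(rec$n_T + rec$n_H + rec$n_other + rec$n_not_shared,
               rep(nrow(tab$contacts), nrow(rec)))
  # at full signal every planted contact of a T protein counts toward n_T
  expect_true(all(rec$n_T[rec$truth == "T"] >= 6))
  expect_true(all(rec$n_H[rec$truth == "H"] >= 6))

  # a member sharing nothing is degenerate
  tab2 <- tab
  tab2$status[, "H01"] <- "absent"
  r <- count_contacts(tab2, enr, "H01", mode = "aa")
  expect_true(attr(r, "degenerate"))
  expect_equal(r$n_shared, 0)
})

test_that("label swap mirrors counts and predictions", {
  synth <- default_synth()
  tab <- synth$tab
  swapped <- tab
  swapped$groups[] <- ifelse(tab$groups == "T", "H",
                             ifelse(tab$groups == "H", "T", tab$groups))
  enr <- full_enrichment_table(tab)
  enr_sw <- full_enrichment_table(swapped)
  rec <- classification_records(tab, enr, mode = "aa")
  rec_sw <- classification_records(swapped, enr_sw, mode = "aa")
  expect_equal(rec_sw$n_T, rec$n_H)
  expect_equal(rec_sw$n_H, rec$n_T)
})

test_that("records at a centroid take that centroid's label", {
  rec <- data.frame(id = c("a", "b"), n_T = c(10, 0), n_H = c(0, 10),
                    n_other = 0, n_not_shared = 0, n_shared = 10,
                    truth = c("T", "H"))
  cent <- fit_centroids(rec)
  out <- classify_enzyme(rec, cent)
  expect_equal(out$predicted, c("T", "H"))
  # exact tie goes to H
  tie <- data.frame(id = "t", n_T = 5, n_H = 5, n_other = 0,
                    n_not_shared = 0, n_shared = 10, truth = "unknown")
  expect_equal(classify_enzyme(tie, cent)$predicted, "H")
  # threshold rule agrees on separable data
  expect_equal(classify_enzyme(rec, cent, rule = "t_threshold")$predicted,
               c("T", "H"))
})

test_that("leave-one-out at full signal classifies every enzyme correctly", {
  synth <- default_synth()
  res <- classify_loo(synth$tab, mode = "aa")
  expect_equal(attr(res, "accuracy"), 1.0)
  expect_equal(nrow(res), 14)
  res_pair <- classify_loo(synth$tab, mode = "pair")
  expect_equal(attr(res_pair, "accuracy"), 1.0)
})

test_that("holdout evaluation refuses overlapping ids", {
  synth <- default_synth()
  expect_error(evaluate_holdout(synth$ds, synth$structs["T01"]),
               "overlap")
})

test_that("accuracy trends upward with planted signal strength", {
  accs <- vapply(c(0.15, 0.5, 1.0), function(p) {
    spec <- synthetic_spec(signal = p, seed = 77, contact_dropout = 0)
    dsd <- generate_dataset(spec, file.path(tempdir(),
                                            paste0("sigtrend", p * 100)))
    structs <- read_dataset(dsd$manifest)
    ds <- prepare_dataset(structs, "T01",
                          alignments = file.path(dsd$dir, "alignment.fasta"))
    attr(classify_loo(build_shared_table(ds), mode = "aa"), "accuracy")
  }, numeric(1))
  expect_true(accs[3] == 1)
  expect_true(stats::cor(accs, 1:3, method = "spearman") > 0)
})
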