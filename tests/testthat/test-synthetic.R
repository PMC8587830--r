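test_that("generation is byte-identical under the same seed", {
  spec <- synthetic_spec(seed = 9, n_T = 2, n_H = 3, n_residues = 30)
  d1 <- generate_dataset(spec, file.path(tempdir(), "det1"))
  d2 <- generate_dataset(spec, file.path(tempdir(), "det2"))
  f1 <- sort(list.files(d1$dir)); f2 <- sort(list.files(d2$dir))
  expect_equal(f1, f2)
  for (f in f1) {
    expect_identical(readLines(file.path(d1$dir, f)),
                     readLines(file.path(d2$dir, f)))
  }
  d3 <- generate_dataset(synthetic_spec(seed = 10, n_T = 2, n_H = 3,
                                        n_residues = 30),
                         file.path(tempdir(), "det3"))
  expect_false(identical(readLines(file.path(d1$dir, "T01.pdb")),
                         readLines(file.path(d3$dir, "T01.pdb"))))
})

test_that("full signal plants the preferred residue in every member", {
  synth <- default_synth()
  ps <- synth$spec$planted_sites
  for (id in names(synth$structs)) {
    s <- synth$structs[[id]]
    aa <- s$residues$aa
    for (r in seq_len(nrow(ps))) {
      want <- if (s$group == "T") ps$aa_T[r] else ps$aa_H[r]
      expect_equal(aa[ps$position[r]], want)
    }
  }
})

test_that("zero dropout reproduces the full scaffold contact set in every
           protein", {
  spec <- synthetic_spec(seed = 13, contact_dropout = 0)
  dsd <- generate_dataset(spec, file.path(tempdir(), "nodrop"))
  structs <- read_dataset(dsd$manifest)
  sc <- spec$geometry$contacts
  for (id in c("T01", "T04", "H01", "H10")) {
    cm <- build_contact_map(structs[[id]], 5, "all_atom", 2)
    expect_equal(unname(cm$contacts), unname(sc))
  }
})

test_that("emitted files round-trip through the structure reader", {
  synth <- default_synth()
  for (id in names(synth$structs)) {
    s <- synth$structs[[id]]
    truth_p <- synth$dsd$truth$proteins[[id]]
    expect_equal(extract_sequence(s), truth_p$sequence)
    cm <- synth$ds$cms[[id]]
    expect_equal(unname(cm$contacts), unname(as.matrix(truth_p$contacts)))
    expect_equal(s$group, truth_p$group)
  }
})

test_that("dropout removes contacts relative to the scaffold and the
           ground truth tracks it", {
  spec <- synthetic_spec(seed = 17, contact_dropout = 0.3)
  dsd <- generate_dataset(spec, file.path(tempdir(), "drop30"))
  structs <- read_dataset(dsd$manifest)
  sc_keys <- paste(spec$geometry$contacts[, 1], spec$geometry$contacts[, 2])
  any_dropped <- FALSE
  for (id in names(structs)) {
    cm <- build_contact_map(structs[[id]], 5, "all_atom", 2)
    keys <- paste(cm$contacts[, 1], cm$contacts[, 2])
    expect_true(all(keys %in% sc_keys))
    if (length(keys) < length(sc_keys)) any_dropped <- TRUE
    # planted contacts survive dropout
    ps <- spec$planted_sites
    expect_true(all(paste(ps$i, ps$j) %in% keys))
  }
  expect_true(any_dropped)
})

test_that("expected enrichment has the degenerate closed forms", {
  spec1 <- synthetic_spec(signal = 1, seed = 1)
  ee1 <- expected_enrichment(spec1)
  expect_true(all(ee1$expected_delta[ee1$aa %in% spec1$planted_sites$aa_T]
                  == 1))
  spec0 <- synthetic_spec(signal = 0, seed = 1)
  ee0 <- expected_enrichment(spec0)
  expect_true(all(ee0$expected_delta == 0))
  spec5 <- synthetic_spec(signal = 0.5, seed = 1)
  ee5 <- expected_enrichment(spec5)
  expect_equal(sort(unique(ee5$expected_delta)), c(-0.5, 0.5))
})

test_that("empirical deltas converge to the closed form at large group
           sizes", {
  spec <- synthetic_spec(n_T = 200, n_H = 200, n_residues = 30,
                         n_planted = 2, signal = 0.5, contact_dropout = 0,
                         seed = 23)
  dsd <- generate_dataset(spec, file.path(tempdir(), "bigsynth"))
  structs <- read_dataset(dsd$manifest)
  ds <- prepare_dataset(structs, "T01",
                        alignments = file.path(dsd$dir, "alignment.fasta"))
  tab <- build_shared_table(ds)
  ps <- spec$planted_sites
  se <- sqrt(0.5 * 0.5 / 200)  # binomial SE of faa_T at p = 0.5
  for (r in seq_len(nrow(ps))) {
    ef <- enrichment_factor(tab, c(ps$i[r], ps$j[r]), ps$endpoint[r],
                            ps$aa_T[r])
    expect_lt(abs(ef$delta - 0.5), 3 * se)
  }
})

test_that("requesting more planted contacts than the scaffold has fails", {
  expect_error(synthetic_spec(n_residues = 12, n_planted = 50),
               "not enough scaffold contacts")
  expect_error(synthetic_spec(planted_sites = data.frame(
    i = 1, j = 10, endpoint = "i", position = 1, aa_T = "A", aa_H = "A",
    p = 1)), "must differ")
})
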