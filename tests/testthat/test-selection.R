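test_that("amino-acid level selection recovers exactly the planted
           positions", {
  d <- three_site_dataset()
  crit <- selection_criteria(direction = "toT")
  cand <- select_aa_level(d$tab, d$enr, d$cons, "H01", crit, ds = d$ds)
  expect_setequal(cand$position, d$dsd$truth$qualifying_positions)
  expect_true(all(cand$proposed_delta > cand$wild_delta))
  expect_true(all(cand$wild_delta <= 0))
  expect_true(all(cand$proposed_delta >= 0.2))
  expect_true(all(cand$conservation_count >=
                    crit$min_conservation_count))
  # planted replacements are the transferase-preferred residues
  expect_setequal(cand$proposed_aa, c("W", "Y", "F"))
})

test_that("an unreachable conservation threshold rejects every position
           with the conservation reason", {
  d <- three_site_dataset()
  crit <- selection_criteria(direction = "toT", min_conservation_count = 15)
  cand <- select_aa_level(d$tab, d$enr, d$cons, "H01", crit, ds = d$ds)
  expect_equal(nrow(cand), 0)
  rej <- attr(cand, "rejected")
  expect_true(all(rej$reason == "conservation"))
})

test_that("tightening any threshold never enlarges the candidate set", {
  d <- three_site_dataset()
  key <- function(cand) paste(cand$position, cand$proposed_aa)
  set.seed(71)
  for (rep in 1:8) {
    mc <- sort(sample(6:15, 2)); wd <- sort(runif(2, -0.4, 0.4))
    cd <- sort(runif(2, 0.05, 0.9))
    loose <- selection_criteria("toT", min_conservation_count = mc[1],
                                wild_delta_max = wd[2],
                                candidate_delta_min = cd[1])
    for (tight in list(
      selection_criteria("toT", min_conservation_count = mc[2],
                         wild_delta_max = wd[2],
                         candidate_delta_min = cd[1]),
      selection_criteria("toT", min_conservation_count = mc[1],
                         wild_delta_max = wd[1],
                         candidate_delta_min = cd[1]),
      selection_criteria("toT", min_conservation_count = mc[1],
                         wild_delta_max = wd[2],
                         candidate_delta_min = cd[2]))) {
      a <- select_aa_level(d$tab, d$enr, d$cons, "H02", loose, ds = d$ds)
      b <- select_aa_level(d$tab, d$enr, d$cons, "H02", tight, ds = d$ds)
      expect_true(all(key(b) %in% key(a)))
    }
  }
})

test_that("direction toH on label-swapped data mirrors direction toT", {
  d <- three_site_dataset()
  swapped <- d$tab
  swapped$groups[] <- ifelse(d$tab$groups == "T", "H",
                             ifelse(d$tab$groups == "H", "T",
                                    d$tab$groups))
  enr_sw <- full_enrichment_table(swapped)
  toT <- select_aa_level(d$tab, d$enr, d$cons, "H01",
                         selection_criteria("toT"), ds = d$ds)
  toH <- select_aa_level(swapped, enr_sw, d$cons, "H01",
                         selection_criteria("toH"), ds = d$ds)
  expect_setequal(toT$position, toH$position)
  expect_equal(toH[match(toT$position, toH$position), "proposed_aa"],
               toT$proposed_aa)
})

test_that("pair-level selection applies conservation, enrichment-extreme
           and betweenness filters", {
  tab <- make_shared_table(
    contacts = rbind(c(2, 4), c(1, 5), c(3, 6)),
    members = c("T1", "T2", "H1", "H2"),
    groups = c("T", "T", "H", "H"),
    status = matrix("shared", 3, 4),
    aa_i = rbind(c("W", "W", "D", "D"),
                 c("A", "A", "A", "A"),
                 c("Y", "Y", "E", "E")),
    aa_j = rbind(c("W", "W", "D", "D"),
                 c("C", "C", "C", "C"),
                 c("Y", "Y", "E", "E")))
  enr <- full_enrichment_table(tab)
  cons <- conservation_profile(tab)
  bc <- data.frame(node = 1:6, degree = 2,
                   bc = c(1, 10, 0, 9, 2, 0),
                   percentile = c(40, 100, 0, 80, 60, 0))
  crit <- selection_criteria("toT", min_conservation_count = 2,
                             pair_extreme_fraction = 0.3,
                             betweenness_fraction = 0.4,
                             candidate_delta_min = 0.2)
  cand <- select_pair_level(tab, enr, cons, bc, "H1", crit)
  expect_setequal(cand$position, c(2, 4))
  expect_true(all(cand$proposed_aa == "W"))
  expect_true(all(cand$wild_aa == "D"))
  rej <- attr(cand, "rejected")
  expect_equal(rej$reason[rej$i == 1 & rej$j == 5], "enrichment")
  expect_equal(rej$reason[rej$i == 3 & rej$j == 6], "betweenness")
})

test_that("candidate explanations echo the stored evidence", {
  d <- three_site_dataset()
  crit <- selection_criteria("toT")
  cand <- select_aa_level(d$tab, d$enr, d$cons, "H01", crit, ds = d$ds)
  out <- explain_candidate(cand, 1, crit)
  expect_true(any(grepl(sprintf("position %d", cand$position[1]), out)))
  expect_true(any(grepl("pass", out)))
  expect_false(any(grepl("FAIL", out)))
})

test_that("ligand-contacting positions are demoted, not removed", {
  d <- three_site_dataset()
  lig <- d$dsd$truth$ligand$het_id
  crit <- selection_criteria("toT", ligand_contact_cutoff = 30)
  cand <- select_aa_level(d$tab, d$enr, d$cons, "H01", crit, ds = d$ds,
                          site = list(hetero = lig))
  # with a huge cutoff everything is "ligand contacting": still reported
  expect_equal(nrow(cand), 3)
  expect_true(all(cand$ligand_contact))
  crit2 <- selection_criteria("toT", ligand_contact_cutoff = 5)
  cand2 <- select_aa_level(d$tab, d$enr, d$cons, "H01", crit2, ds = d$ds,
                           site = list(hetero = lig))
  if (any(cand2$ligand_contact) && any(!cand2$ligand_contact)) {
    expect_true(max(which(!cand2$ligand_contact)) <
                  min(which(cand2$ligand_contact)))
  }
  expect_true(all(cand2$distance_to_site >= 0))
})
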