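make_four_member_table <- function() {
  # contacts (1,5) and (2,6); members T1 T2 H1 H2
  make_shared_table(
    contacts = rbind(c(1, 5), c(2, 6)),
    members = c("T1", "T2", "H1", "H2"),
    groups = c("T", "T", "H", "H"),
    status = rbind(rep("shared", 4),
                   c("shared", "shared", "absent", "shared")),
    aa_i = rbind(c("A", "A", "A", "G"),
                 c("W", "W", NA, "L")),
    aa_j = rbind(c("C", "C", "C", "C"),
                 c("Y", "Y", NA, "Y")))
}

test_that("frequencies count sharing group members and normalize to one", {
  tab <- make_four_member_table()
  expect_equal(aa_frequencies(tab, c(1, 5), "i", "T"), c(A = 1.0))
  expect_equal(aa_frequencies(tab, c(1, 5), "i", "H"), c(A = 0.5, G = 0.5))
  expect_equal(sum(aa_frequencies(tab, c(2, 6), "i", "T")), 1)
  # H1 does not share contact (2,6): denominator is the single sharing H
  expect_equal(aa_frequencies(tab, c(2, 6), "i", "H"), c(L = 1.0))
})

test_that("enrichment deltas follow faa_T - faa_H with zeros for unobserved", {
  tab <- make_four_member_table()
  ef <- enrichment_factor(tab, c(1, 5), "i", "A")
  expect_equal(ef$delta, 0.5)
  expect_equal(enrichment_factor(tab, c(1, 5), "i", "W")$delta, 0)
  expect_equal(enrichment_factor(tab, c(1, 5), "j", "C")$delta, 0)
  pe <- pair_enrichment_factor(tab, c(2, 6), c("W", "Y"))
  expect_equal(pe$delta_pair, 1.0)
  expect_equal(pair_enrichment_factor(tab, c(1, 5), "CC")$faap_T, 0)
})

test_that("the full table enumerates observed amino acids and skips
           one-group contacts", {
  tab <- make_four_member_table()
  enr <- full_enrichment_table(tab)
  c1 <- enr$aa[enr$aa$ref_contact_i == 1, ]
  expect_equal(nrow(c1[c1$endpoint == "i", ]), 2)  # A and G observed
  expect_equal(nrow(c1[c1$endpoint == "j", ]), 1)  # only C observed
  expect_equal(nrow(enr$skipped), 0)

  # make contact (2,6) T-only
  tab2 <- make_four_member_table()
  tab2$status[2, c("H1", "H2")] <- "absent"
  enr2 <- full_enrichment_table(tab2)
  expect_equal(nrow(enr2$skipped), 1)
  expect_match(enr2$skipped$reason, "hydrolase")
  expect_true(is.na(delta_lookup(enr2, 2, 6, "i", "W")))
})

test_that("positions with nonstandard residues are excluded from counts
           without invalidating the contact", {
  tab <- make_four_member_table()
  tab$aa_i[1, "H2"] <- "X"
  f <- aa_frequencies(tab, c(1, 5), "i", "H")
  expect_equal(f, c(A = 1.0))  # only H1 counted
  expect_equal(aa_frequencies(tab, c(1, 5), "j", "H"),
               c(C = 1.0))     # endpoint j unaffected
})

test_that("per-endpoint frequencies sum to one and deltas sum to zero on
           synthetic data", {
  synth <- default_synth()
  tab <- synth$tab
  enr <- synth$enr
  expect_true(all(enr$aa$delta >= -1 & enr$aa$delta <= 1))
  expect_true(all(enr$pair$delta >= -1 & enr$pair$delta <= 1))
  agg <- stats::aggregate(delta ~ ref_contact_i + ref_contact_j + endpoint,
                          data = enr$aa, FUN = sum)
  expect_true(all(abs(agg$delta) < 1e-12))
  for (ct in list(c(1, 2), c(5, 8))) {
    r <- sample(nrow(tab$contacts), 1)
    contact <- tab$contacts[r, ]
    for (g in c("T", "H")) {
      f <- aa_frequencies(tab, contact, "i", g)
      if (length(f) > 0) expect_equal(sum(f), 1)
    }
  }
})

test_that("swapping the group labels negates every delta exactly", {
  synth <- default_synth()
  tab <- synth$tab
  swapped <- tab
  swapped$groups[] <- ifelse(tab$groups == "T", "H",
                             ifelse(tab$groups == "H", "T", tab$groups))
  enr <- full_enrichment_table(tab)
  enr_sw <- full_enrichment_table(swapped)
  key <- function(d) paste(d$ref_contact_i, d$ref_contact_j, d$endpoint, d$aa)
  m <- match(key(enr$aa), key(enr_sw$aa))
  expect_false(anyNA(m))
  expect_equal(enr_sw$aa$delta[m], -enr$aa$delta)
  keyp <- function(d) paste(d$ref_contact_i, d$ref_contact_j, d$aa_i, d$aa_j)
  mp <- match(keyp(enr$pair), keyp(enr_sw$pair))
  expect_equal(enr_sw$pair$delta[mp], -enr$pair$delta)
})

test_that("statuses in the shared table match a per-contact recomputation", {
  synth <- default_synth()
  ds <- synth$ds
  tab <- synth$tab
  for (id in c("T03", "H05")) {
    pm <- ds$maps[[id]]
    for (r in seq(1, nrow(tab$contacts), by = 7)) {
      expect_equal(unname(tab$status[r, id]),
                   map_contact(tab$contacts[r, ], pm, ds$cms[[id]]))
    }
  }
  # the reference shares every one of its own contacts
  expect_true(all(tab$status[, tab$ref_id] == "shared"))
})

test_that("the group-size denominator changes magnitudes but keeps bounds", {
  tab <- make_four_member_table()
  f <- aa_frequencies(tab, c(2, 6), "i", "H", denominator = "group_size")
  expect_equal(f, c(L = 0.5))  # 1 of 2 hydrolases
  enr <- full_enrichment_table(tab, denominator = "group_size")
  expect_true(all(enr$aa$delta >= -1 & enr$aa$delta <= 1))
})
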