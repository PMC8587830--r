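test_that("residue minimum distance matches simple geometry", {
  s <- make_structure(list(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(residue_min_distance(s, 1, 2), 3.0)
  s2 <- make_structure(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(residue_min_distance(s2, 1, 2), 0.0)
})

test_that("multi-atom residue distance equals the brute-force minimum", {
  set.seed(11)
  for (rep in 1:10) {
    A <- matrix(runif(9, 0, 10), 3, 3)
    B <- matrix(runif(12, 0, 10), 4, 3)
    s <- make_structure(list(A, B))
    expect_equal(residue_min_distance(s, 1, 2), oracle_min_dist(A, B))
    expect_equal(residue_min_distance(s, 2, 1), residue_min_distance(s, 1, 2))
  }
})

test_that("the distance cutoff is inclusive", {
  near <- make_structure(list(c(0, 0, 0), c(0, 20, 0), c(4.9, 0, 0)))
  cm <- build_contact_map(near, cutoff = 5, min_separation = 2)
  expect_true(has_contact(cm, 1, 3))
  far <- make_structure(list(c(0, 0, 0), c(0, 20, 0), c(5.1, 0, 0)))
  cm2 <- build_contact_map(far, cutoff = 5, min_separation = 2)
  expect_false(has_contact(cm2, 1, 3))
  exact <- make_structure(list(c(0, 0, 0), c(0, 20, 0), c(5.0, 0, 0)))
  cm3 <- build_contact_map(exact, cutoff = 5, min_separation = 2)
  expect_true(has_contact(cm3, 1, 3))
})

test_that("contact maps equal an independent all-pairs scan", {
  set.seed(21)
  for (rep in 1:5) {
    coords <- lapply(1:20, function(k)
      matrix(runif(6, 0, 18), 2, 3))
    s <- make_structure(coords)
    cm <- build_contact_map(s, cutoff = 5, min_separation = 2)
    expect_equal(unname(cm$contacts),
                 unname(oracle_contacts(s, 5, "all_atom", 2)))
  }
})

test_that("cutoff, scheme and separation obey their nesting relations", {
  synth <- default_synth()
  s <- synth$structs[["H03"]]
  key <- function(cm) paste(cm$contacts[, 1], cm$contacts[, 2])
  cm5 <- build_contact_map(s, 5); cm6 <- build_contact_map(s, 6)
  expect_true(all(key(cm5) %in% key(cm6)))
  ca5 <- build_contact_map(s, 5, scheme = "ca")
  expect_true(all(key(ca5) %in% key(cm5)))
  sep0 <- build_contact_map(s, 5, min_separation = 0)
  sep4 <- build_contact_map(s, 5, min_separation = 4)
  expect_true(all(key(sep4) %in% key(sep0)))
  expect_true(all(cm5$contacts[, 2] - cm5$contacts[, 1] >= 2))
})

test_that("missing CA under the ca scheme is an error", {
  s <- make_structure(list(c(0, 0, 0), c(3, 0, 0)),
                      elety = list("CB", "CA"))
  expect_error(build_contact_map(s, 5, scheme = "ca"), "CA")
})

test_that("distance to a site is an exhaustive all-atom minimum", {
  s <- make_structure(list(c(0, 0, 0), c(4, 0, 0), c(8, 0, 0)))
  s$hetero <- data.frame(het_id = "LIG_A9", resid3 = "LIG", resno = 9,
                         elety = "C1", x = 0, y = 7.2, z = 0)
  expect_equal(distance_to_site(s, 1, list(hetero = "LIG_A9")), 7.2)
  expect_equal(distance_to_site(s, 2, list(residues = c(1, 2))), 0)
  expect_error(distance_to_site(s, 1, list()), "empty site")

  set.seed(31)
  lig <- matrix(runif(9, 0, 10), 3, 3)
  s$hetero <- data.frame(het_id = "LIG_A9", resid3 = "LIG", resno = 9,
                         elety = c("C1", "C2", "C3"),
                         x = lig[, 1], y = lig[, 2], z = lig[, 3])
  A <- as.matrix(s$atoms[s$atoms$res_index == 1, c("x", "y", "z")])
  expect_equal(distance_to_site(s, 1, list(hetero = "LIG_A9")),
               oracle_min_dist(A, lig))
})

test_that("contact-map text files round-trip bit-exactly", {
  synth <- default_synth()
  cm <- synth$ds$cms[["T02"]]
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_contact_map(cm, f1)
  cm2 <- read_contact_map(f1)
  write_contact_map(cm2, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(unname(cm2$contacts), unname(cm$contacts))
  expect_equal(cm2$cutoff, cm$cutoff)
  expect_equal(cm2$min_separation, cm$min_separation)
})
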