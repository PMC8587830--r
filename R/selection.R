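# Mutation-site selection: conservation, enrichment, betweenness and
# active-site distance criteria applied to a query structure, in either
# specificity direction (hydrolase -> transglycosidase or the reverse).

#' Selection criteria
#'
#' @param direction \code{"toT"} proposes substitutions toward
#'   transferase-enriched residues, \code{"toH"} toward
#'   hydrolase-enriched residues (all enrichment signs mirrored).
#' @param min_conservation_count Minimum number of dataset members sharing
#'   a contact for it to count as conserved (default 10, out of the
#'   canonical 14-member dataset; inclusive comparison).
#' @param wild_delta_max The current residue must have (direction-adjusted)
#'   enrichment at or below this (default 0; a stricter -0.2 reading is
#'   also in circulation and available here).
#' @param candidate_delta_min Minimum (direction-adjusted) enrichment of a
#'   proposed replacement (default 0.2).
#' @param pair_extreme_fraction Fraction defining the extreme tails of the
#'   pair-enrichment distribution for pair-level selection (default 0.01).
#' @param betweenness_fraction Top betweenness fraction both endpoints must
#'   reach in pair-level selection (default 0.10; 0.20 is the wider
#'   screening setting).
#' @param prefer_non_ligand_contact Demote (not remove) positions in
#'   contact with the bound ligand / transition-state analogue.
#' @param ligand_contact_cutoff Distance (Angstrom) under which a position
#'   counts as ligand-contacting.
#' @param max_candidates Cap on the number of reported candidates.
#' @return List of class \code{"selection_criteria"}.
#' @export
selection_criteria <- function(direction = c("toT", "toH"),
                               min_conservation_count = 10,
                               wild_delta_max = 0,
                               candidate_delta_min = 0.2,
                               pair_extreme_fraction = 0.01,
                               betweenness_fraction = 0.10,
                               prefer_non_ligand_contact = TRUE,
                               ligand_contact_cutoff = 5,
                               max_candidates = Inf) {
  direction <- match.arg(direction)
  stopifnot(pair_extreme_fraction > 0, pair_extreme_fraction <= 1,
            betweenness_fraction > 0, betweenness_fraction <= 1)
  structure(list(direction = direction,
                 min_conservation_count = min_conservation_count,
                 wild_delta_max = wild_delta_max,
                 candidate_delta_min = candidate_delta_min,
                 pair_extreme_fraction = pair_extreme_fraction,
                 betweenness_fraction = betweenness_fraction,
                 prefer_non_ligand_contact = prefer_non_ligand_contact,
                 ligand_contact_cutoff = ligand_contact_cutoff,
                 max_candidates = max_candidates),
            class = "selection_criteria")
}

.dir_sign <- function(criteria) if (criteria$direction == "toT") 1 else -1

.query_position_info <- function(tab, ds, query_id, positions, site,
                                 criteria) {
  # distance to active site and ligand-contact flag, per reference position
  dist <- rep(NA_real_, length(positions))
  ligand <- rep(FALSE, length(positions))
  if (!is.null(ds) && !is.null(site)) {
    s <- ds$structures[[query_id]]
    pmq <- ds$maps[[query_id]]
    for (k in seq_along(positions)) {
      qpos <- .map_lookup(pmq, positions[k])
      if (is.na(qpos)) next
      dist[k] <- distance_to_site(s, qpos, site)
      ligand[k] <- dist[k] <= criteria$ligand_contact_cutoff
    }
  }
  list(dist = dist, ligand = ligand)
}

.rank_candidates <- function(cand, criteria) {
  if (nrow(cand) == 0) return(cand)
  demote <- if (criteria$prefer_non_ligand_contact) cand$ligand_contact
  else rep(FALSE, nrow(cand))
  ord <- order(demote, -cand$rank_score, -cand$conservation_count,
               -ifelse(is.na(cand$distance_to_site), -Inf,
                       cand$distance_to_site))
  cand <- cand[ord, , drop = FALSE]
  if (is.finite(criteria$max_candidates))
    cand <- utils::head(cand, criteria$max_candidates)
  rownames(cand) <- NULL
  cand
}

#' Select mutation sites from amino-acid level enrichment
#'
#' A reference position qualifies when (i) some contact containing it is
#' shared by at least \code{min_conservation_count} dataset members,
#' (ii) the query's current residue has direction-adjusted enrichment at
#' or below \code{wild_delta_max} on that contact endpoint, and (iii) some
#' alternative amino acid observed there has direction-adjusted enrichment
#' of at least \code{candidate_delta_min}. Candidates are ranked by the
#' enrichment gain (proposed minus wild), ties by conservation then by
#' distance to the active site (farther first); ligand-contacting
#' positions are demoted to the bottom, not removed.
#'
#' @param tab A \code{shared_contact_table} containing the query as a
#'   member.
#' @param enr \code{enrichment_tables} fitted on the labelled dataset.
#' @param cons \code{conservation_profile} of the reference.
#' @param query_id Member id of the query structure.
#' @param criteria A \code{\link{selection_criteria}}.
#' @param ds Optional \code{contact_dataset} (needed for distances).
#' @param site Optional active site, see \code{\link{distance_to_site}}.
#' @return Data frame of class \code{"mutation_candidates"}, one row per
#'   qualifying (position, proposed residue): \code{position} (reference
#'   linear index), \code{query_resno}, \code{wild_aa}, \code{proposed_aa},
#'   \code{wild_delta}, \code{proposed_delta}, \code{conservation_count},
#'   \code{betweenness_percentile}, \code{distance_to_site},
#'   \code{ligand_contact}, \code{contacts_involved},
#'   \code{pass_conservation}, \code{pass_wild_delta},
#'   \code{pass_candidate_delta}, \code{rank_score}. Rejected positions
#'   with their blocking criterion are in attribute \code{"rejected"}.
#' @export
select_aa_level <- function(tab, enr, cons, query_id, criteria, ds = NULL,
                            site = NULL) {
  if (is.null(enr)) stop("enrichment tables required")
  sgn <- .dir_sign(criteria)
  st <- tab$status[, query_id]
  shared_rows <- which(st == "shared")
  # per (position, contact, endpoint) evidence
  ev <- list()
  for (r in shared_rows) {
    i <- tab$contacts[r, 1]; j <- tab$contacts[r, 2]
    for (ep in c("i", "j")) {
      pos <- if (ep == "i") i else j
      wild <- if (ep == "i") tab$aa_i[r, query_id] else tab$aa_j[r, query_id]
      if (is.na(wild) || wild == "X") next
      wd <- delta_lookup(enr, i, j, ep, wild)
      if (is.na(wd)) next
      alts <- enr$aa[enr$aa$ref_contact_i == i & enr$aa$ref_contact_j == j &
                       enr$aa$endpoint == ep & enr$aa$aa != wild, ,
                     drop = FALSE]
      best_alt <- NA_character_; best_delta <- NA_real_
      if (nrow(alts) > 0) {
        adj <- sgn * alts$delta
        bk <- which.max(adj)
        best_alt <- alts$aa[bk]; best_delta <- alts$delta[bk]
      }
      ev[[length(ev) + 1]] <- data.frame(
        position = pos, contact_i = i, contact_j = j, endpoint = ep,
        wild_aa = wild, wild_delta = wd,
        proposed_aa = best_alt, proposed_delta = best_delta,
        conservation_count = cons$n_sharing[r],
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(position = integer(), query_resno = integer(),
                      wild_aa = character(), proposed_aa = character(),
                      wild_delta = numeric(), proposed_delta = numeric(),
                      conservation_count = integer(),
                      betweenness_percentile = numeric(),
                      distance_to_site = numeric(),
                      ligand_contact = logical(),
                      contacts_involved = character(),
                      pass_conservation = logical(),
                      pass_wild_delta = logical(),
                      pass_candidate_delta = logical(),
                      rank_score = numeric())
  class(empty) <- c("mutation_candidates", class(empty))
  if (length(ev) == 0) {
    attr(empty, "rejected") <- data.frame(position = integer(),
                                          reason = character())
    return(empty)
  }
  ev <- do.call(rbind, ev)
  ev$pass_conservation <- ev$conservation_count >= criteria$min_conservation_count
  ev$pass_wild_delta <- sgn * ev$wild_delta <= criteria$wild_delta_max
  ev$pass_candidate_delta <- !is.na(ev$proposed_delta) &
    sgn * ev$proposed_delta >= criteria$candidate_delta_min
  ev$pass <- ev$pass_conservation & ev$pass_wild_delta & ev$pass_candidate_delta
  ev$gain <- sgn * (ev$proposed_delta - ev$wild_delta)

  positions <- sort(unique(ev$position))
  info <- .query_position_info(tab, ds, query_id, positions, site, criteria)
  rows <- list(); rejected <- list()
  pmq <- if (!is.null(ds)) ds$maps[[query_id]] else NULL
  qres <- if (!is.null(ds)) ds$structures[[query_id]]$residues else NULL
  for (k in seq_along(positions)) {
    p <- positions[k]
    sub <- ev[ev$position == p, , drop = FALSE]
    ok <- sub[sub$pass, , drop = FALSE]
    if (nrow(ok) == 0) {
      reason <- if (!any(sub$pass_conservation)) "conservation"
      else if (!any(sub$pass_conservation & sub$pass_wild_delta)) "wild_delta"
      else "candidate_delta"
      rejected[[length(rejected) + 1]] <-
        data.frame(position = p, reason = reason)
      next
    }
    best <- ok[order(-ok$gain, -ok$conservation_count), , drop = FALSE][1, ]
    qpos <- if (!is.null(pmq)) .map_lookup(pmq, p) else NA_integer_
    rows[[length(rows) + 1]] <- data.frame(
      position = p,
      query_resno = if (!is.na(qpos) && !is.null(qres))
        qres$resno[qpos] else NA_integer_,
      wild_aa = best$wild_aa, proposed_aa = best$proposed_aa,
      wild_delta = best$wild_delta, proposed_delta = best$proposed_delta,
      conservation_count = best$conservation_count,
      betweenness_percentile = NA_real_,
      distance_to_site = info$dist[k],
      ligand_contact = info$ligand[k],
      contacts_involved = paste(
        unique(paste0(ok$contact_i, "-", ok$contact_j)), collapse = ";"),
      pass_conservation = TRUE, pass_wild_delta = TRUE,
      pass_candidate_delta = TRUE,
      rank_score = best$gain,
      stringsAsFactors = FALSE)
  }
  cand <- if (length(rows) > 0) do.call(rbind, rows) else empty
  cand <- .rank_candidates(cand, criteria)
  class(cand) <- c("mutation_candidates", class(cand))
  attr(cand, "rejected") <- if (length(rejected) > 0)
    do.call(rbind, rejected) else data.frame(position = integer(),
                                             reason = character())
  attr(cand, "direction") <- criteria$direction
  cand
}

#' Select mutation sites from pair-level enrichment and betweenness
#'
#' A contact passes when (i) it is conserved
#' (\code{min_conservation_count} sharing members), (ii) the pair
#' enrichment of the query's observed pair lies in the extreme
#' \code{pair_extreme_fraction} tails of the global pair-enrichment
#' distribution, and (iii) both endpoints are in the top
#' \code{betweenness_fraction} of betweenness centrality on the reference
#' contact network. Proposed substitutions are drawn from the pair most
#' enriched in the target group at that contact: each endpoint where the
#' query residue differs yields one candidate.
#'
#' @inheritParams select_aa_level
#' @param bc \code{betweenness_result} for the reference contact network
#'   (indices in reference numbering).
#' @return A \code{mutation_candidates} data frame (see
#'   \code{\link{select_aa_level}}); contact-level rejections in attribute
#'   \code{"rejected"} with reasons \code{"conservation"},
#'   \code{"enrichment"}, \code{"betweenness"}.
#' @export
select_pair_level <- function(tab, enr, cons, bc, query_id, criteria,
                              ds = NULL, site = NULL) {
  if (is.null(enr) || nrow(enr$pair) == 0) stop("pair enrichment required")
  if (is.null(bc)) stop("betweenness result required")
  sgn <- .dir_sign(criteria)
  all_delta <- enr$pair$delta
  hi <- stats::quantile(all_delta, 1 - criteria$pair_extreme_fraction,
                        names = FALSE, type = 7)
  lo <- stats::quantile(all_delta, criteria$pair_extreme_fraction,
                        names = FALSE, type = 7)
  top_nodes <- top_percentile(bc, criteria$betweenness_fraction)
  pctl <- stats::setNames(bc$percentile, bc$node)

  st <- tab$status[, query_id]
  shared_rows <- which(st == "shared")
  rows <- list(); rejected <- list()
  for (r in shared_rows) {
    i <- tab$contacts[r, 1]; j <- tab$contacts[r, 2]
    ai <- tab$aa_i[r, query_id]; aj <- tab$aa_j[r, query_id]
    if (is.na(ai) || is.na(aj) || ai == "X" || aj == "X") next
    ccount <- cons$n_sharing[r]
    if (ccount < criteria$min_conservation_count) {
      rejected[[length(rejected) + 1]] <-
        data.frame(i = i, j = j, reason = "conservation")
      next
    }
    dq <- delta_pair_lookup(enr, i, j, ai, aj)
    if (is.na(dq) || (dq < hi && dq > lo)) {
      rejected[[length(rejected) + 1]] <-
        data.frame(i = i, j = j, reason = "enrichment")
      next
    }
    if (!(i %in% top_nodes) || !(j %in% top_nodes)) {
      rejected[[length(rejected) + 1]] <-
        data.frame(i = i, j = j, reason = "betweenness")
      next
    }
    # best pair for the target direction at this contact
    pr <- enr$pair[enr$pair$ref_contact_i == i & enr$pair$ref_contact_j == j, ,
                   drop = FALSE]
    bk <- which.max(sgn * pr$delta)
    tgt_i <- pr$aa_i[bk]; tgt_j <- pr$aa_j[bk]
    tgt_delta <- pr$delta[bk]
    if (sgn * tgt_delta < criteria$candidate_delta_min) next
    for (ep in c("i", "j")) {
      wild <- if (ep == "i") ai else aj
      prop <- if (ep == "i") tgt_i else tgt_j
      if (wild == prop) next
      pos <- if (ep == "i") i else j
      info <- .query_position_info(tab, ds, query_id, pos, site, criteria)
      qpos <- if (!is.null(ds)) .map_lookup(ds$maps[[query_id]], pos)
      else NA_integer_
      rows[[length(rows) + 1]] <- data.frame(
        position = pos,
        query_resno = if (!is.null(ds) && !is.na(qpos))
          ds$structures[[query_id]]$residues$resno[qpos] else NA_integer_,
        wild_aa = wild, proposed_aa = prop,
        wild_delta = dq, proposed_delta = tgt_delta,
        conservation_count = ccount,
        betweenness_percentile = unname(pctl[as.character(pos)]),
        distance_to_site = info$dist[1],
        ligand_contact = info$ligand[1],
        contacts_involved = paste0(i, "-", j),
        pass_conservation = TRUE, pass_wild_delta = TRUE,
        pass_candidate_delta = TRUE,
        rank_score = sgn * (tgt_delta - dq),
        stringsAsFactors = FALSE)
    }
  }
  empty <- utils::head(
    data.frame(position = integer(), query_resno = integer(),
               wild_aa = character(), proposed_aa = character(),
               wild_delta = numeric(), proposed_delta = numeric(),
               conservation_count = integer(),
               betweenness_percentile = numeric(),
               distance_to_site = numeric(), ligand_contact = logical(),
               contacts_involved = character(),
               pass_conservation = logical(), pass_wild_delta = logical(),
               pass_candidate_delta = logical(), rank_score = numeric()), 0)
  cand <- if (length(rows) > 0) do.call(rbind, rows) else empty
  cand <- .rank_candidates(cand, criteria)
  class(cand) <- c("mutation_candidates", class(cand))
  attr(cand, "rejected") <- if (length(rejected) > 0)
    do.call(rbind, rejected) else data.frame(i = integer(), j = integer(),
                                             reason = character())
  attr(cand, "direction") <- criteria$direction
  cand
}

#' Human-readable report for one mutation candidate
#'
#' @param cand A \code{mutation_candidates} data frame.
#' @param row Row index of the candidate to explain.
#' @param criteria The \code{selection_criteria} used for selection.
#' @return Character vector of report lines (also printed).
#' @export
explain_candidate <- function(cand, row = 1, criteria = selection_criteria()) {
  c1 <- cand[row, ]
  fmt <- function(x) ifelse(is.na(x), "NA", format(round(x, 3)))
  lines <- c(
    sprintf("Candidate %s%s%s (reference position %d)",
            c1$wild_aa, ifelse(is.na(c1$query_resno), "", c1$query_resno),
            c1$proposed_aa, c1$position),
    sprintf("  direction           : %s", criteria$direction),
    sprintf("  wild delta          : %s (threshold <= %s)  [%s]",
            fmt(c1$wild_delta), fmt(criteria$wild_delta_max),
            ifelse(c1$pass_wild_delta, "pass", "FAIL")),
    sprintf("  proposed delta      : %s (threshold >= %s)  [%s]",
            fmt(c1$proposed_delta), fmt(criteria$candidate_delta_min),
            ifelse(c1$pass_candidate_delta, "pass", "FAIL")),
    sprintf("  conservation count  : %d (threshold >= %d)  [%s]",
            c1$conservation_count, criteria$min_conservation_count,
            ifelse(c1$pass_conservation, "pass", "FAIL")),
    sprintf("  betweenness pctile  : %s", fmt(c1$betweenness_percentile)),
    sprintf("  distance to site    : %s A", fmt(c1$distance_to_site)),
    sprintf("  ligand contact      : %s%s", c1$ligand_contact,
            ifelse(c1$ligand_contact && criteria$prefer_non_ligand_contact,
                   " (demoted in ranking)", "")),
    sprintf("  contacts involved   : %s", c1$contacts_involved),
    sprintf("  rank score (gain)   : %s", fmt(c1$rank_score)))
  cat(lines, sep = "\n")
  invisible(lines)
}
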