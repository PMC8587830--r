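# Differential amino-acid enrichment over shared residue-residue contacts.
#
# For a contact endpoint shared between a reference and a labelled dataset,
# faa is the frequency of an amino acid among the members of one functional
# group that share the contact; the enrichment factor is the transferase
# minus hydrolase frequency difference, delta = faa_T - faa_H, and its
# pair-level analogue uses the frequency of ordered amino-acid pairs.

#' Assemble structures, contact maps and position maps into a dataset
#'
#' Builds the contact map of every structure at the given parameters and a
#' position map from the reference to every member (identity for the
#' reference itself). User-supplied alignments override the built-in
#' aligner.
#'
#' @param structures Named list of \code{structure_model}s (names are ids).
#' @param ref_id Id of the reference structure; must be in
#'   \code{structures}.
#' @param cutoff,scheme,min_separation Contact-map parameters, see
#'   \code{\link{build_contact_map}}.
#' @param alignments Optional named list of \code{position_map}s (reference
#'   to member), or a path to an aligned FASTA containing all ids.
#' @param params \code{\link{align_params}} for the built-in aligner.
#' @return Object of class \code{"contact_dataset"}: list with
#'   \code{ref_id}, \code{structures}, \code{cms}, \code{maps},
#'   \code{cutoff}, \code{scheme}, \code{min_separation}.
#' @export
prepare_dataset <- function(structures, ref_id, cutoff = 5,
                            scheme = "all_atom", min_separation = 2,
                            alignments = NULL, params = align_params()) {
  ids <- names(structures)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- vapply(structures, function(s) s$id, "")
  names(structures) <- ids
  if (!(ref_id %in% ids)) stop("reference id not in dataset: ", ref_id)
  cms <- lapply(structures, build_contact_map, cutoff = cutoff,
                scheme = scheme, min_separation = min_separation)
  ref_seq <- extract_sequence(structures[[ref_id]])
  maps <- vector("list", length(ids))
  names(maps) <- ids
  for (id in ids) {
    if (id == ref_id) {
      L <- nrow(structures[[ref_id]]$residues)
      maps[[id]] <- position_map(ref_id, id, cbind(seq_len(L), seq_len(L)))
    } else if (is.character(alignments)) {
      maps[[id]] <- load_alignment(alignments, ref_id, id)
    } else if (!is.null(alignments) && !is.null(alignments[[id]])) {
      maps[[id]] <- alignments[[id]]
    } else {
      maps[[id]] <- align_pair(ref_seq, extract_sequence(structures[[id]]),
                               ref_id, id, params = params)
    }
  }
  structure(list(ref_id = ref_id, structures = structures, cms = cms,
                 maps = maps, cutoff = cutoff, scheme = scheme,
                 min_separation = as.integer(min_separation)),
            class = "contact_dataset")
}

#' Tabulate reference contacts against every dataset member
#'
#' For each contact of the reference structure and each dataset member,
#' records whether the mapped contact is shared, absent, or unalignable,
#' and for shared cells the amino acids occupying the two mapped endpoints
#' (ordered by reference endpoint).
#'
#' @param ds A \code{contact_dataset} from \code{\link{prepare_dataset}}.
#' @return Object of class \code{"shared_contact_table"}: list with
#'   \code{ref_id}, \code{contacts} (m x 2), \code{members},
#'   \code{groups} (named H/T/unknown), and m x n character matrices
#'   \code{status}, \code{aa_i}, \code{aa_j}.
#' @export
build_shared_table <- function(ds) {
  stopifnot(inherits(ds, "contact_dataset"))
  ref_cm <- ds$cms[[ds$ref_id]]
  contacts <- ref_cm$contacts
  members <- names(ds$structures)
  m <- nrow(contacts)
  n <- length(members)
  status <- matrix(NA_character_, m, n, dimnames = list(NULL, members))
  aa_i <- aa_j <- matrix(NA_character_, m, n, dimnames = list(NULL, members))
  for (id in members) {
    pm <- ds$maps[[id]]
    if (is.null(pm)) stop("missing position map for member: ", id)
    cm <- ds$cms[[id]]
    mi <- .map_lookup(pm, contacts[, 1])
    mj <- .map_lookup(pm, contacts[, 2])
    un <- is.na(mi) | is.na(mj)
    sh <- !un & has_contact(cm, ifelse(un, 1L, mi), ifelse(un, 1L, mj))
    status[, id] <- ifelse(un, "unalignable", ifelse(sh, "shared", "absent"))
    aa <- ds$structures[[id]]$residues$aa
    aa_i[sh, id] <- aa[mi[sh]]
    aa_j[sh, id] <- aa[mj[sh]]
  }
  groups <- vapply(ds$structures, function(s) s$group, "")
  structure(list(ref_id = ds$ref_id, contacts = contacts, members = members,
                 groups = groups, status = status, aa_i = aa_i, aa_j = aa_j),
            class = "shared_contact_table")
}

#' @export
print.shared_contact_table <- function(x, ...) {
  cat("shared_contact_table: ", nrow(x$contacts), " reference ('",
      x$ref_id, "') contacts x ", length(x$members), " members (",
      sum(x$groups == "T"), " T, ", sum(x$groups == "H"), " H)\n", sep = "")
  invisible(x)
}

.contact_row <- function(tab, contact) {
  r <- which(tab$contacts[, 1] == contact[1] & tab$contacts[, 2] == contact[2])
  if (length(r) != 1) stop("not a reference contact: (", contact[1], ", ",
                           contact[2], ")")
  r
}

.group_members <- function(tab, group, members = NULL) {
  ids <- if (is.null(members)) tab$members else intersect(tab$members, members)
  ids[tab$groups[ids] == group]
}

#' Amino-acid frequencies at a shared-contact endpoint within a group
#'
#' The frequency of an amino acid is its count among the group members that
#' share the contact (and carry a standard residue at the endpoint),
#' divided by the number of such members, so frequencies sum to one over
#' observed amino acids.
#'
#' @param tab A \code{shared_contact_table}.
#' @param contact Integer pair (i, j) in reference indices.
#' @param endpoint \code{"i"} or \code{"j"}.
#' @param group \code{"T"} or \code{"H"}.
#' @param members Optional subset of member ids (e.g. for leave-one-out).
#' @param denominator \code{"sharing"} (default; members sharing the
#'   contact) or \code{"group_size"} (all group members, changes the
#'   magnitudes and breaks the sum-to-one normalization).
#' @return Named numeric vector of frequencies over observed amino acids;
#'   empty (length 0) when no group member shares the contact.
#' @export
aa_frequencies <- function(tab, contact, endpoint = c("i", "j"),
                           group = c("T", "H"), members = NULL,
                           denominator = c("sharing", "group_size")) {
  endpoint <- match.arg(endpoint)
  group <- match.arg(group)
  denominator <- match.arg(denominator)
  r <- .contact_row(tab, contact)
  ids <- .group_members(tab, group, members)
  aam <- if (endpoint == "i") tab$aa_i else tab$aa_j
  sharing <- ids[tab$status[r, ids] == "shared"]
  aa <- aam[r, sharing]
  aa <- aa[!is.na(aa) & aa != "X"]
  if (length(aa) == 0) return(stats::setNames(numeric(0), character(0)))
  denom <- if (denominator == "sharing") length(aa) else length(ids)
  tt <- table(aa)
  stats::setNames(as.numeric(tt) / denom, names(tt))
}

#' Enrichment factor of an amino acid at a shared-contact endpoint
#'
#' delta = faa_T - faa_H: the frequency of the amino acid among
#' transferases sharing the contact minus its frequency among hydrolases
#' sharing it; an amino acid unobserved in a group contributes frequency 0.
#'
#' @inheritParams aa_frequencies
#' @param aa One-letter amino-acid code.
#' @return List with \code{faa_T}, \code{faa_H}, \code{delta}; \code{NA}s
#'   when either group has no sharing member (undefined frequency).
#' @export
enrichment_factor <- function(tab, contact, endpoint, aa, members = NULL,
                              denominator = "sharing") {
  fT <- aa_frequencies(tab, contact, endpoint, "T", members, denominator)
  fH <- aa_frequencies(tab, contact, endpoint, "H", members, denominator)
  if (length(fT) == 0 || length(fH) == 0)
    return(list(faa_T = NA_real_, faa_H = NA_real_, delta = NA_real_))
  t1 <- if (aa %in% names(fT)) fT[[aa]] else 0
  h1 <- if (aa %in% names(fH)) fH[[aa]] else 0
  list(faa_T = t1, faa_H = h1, delta = t1 - h1)
}

.pair_frequencies <- function(tab, row, group, members, denominator) {
  ids <- .group_members(tab, group, members)
  sharing <- ids[tab$status[row, ids] == "shared"]
  pi <- tab$aa_i[row, sharing]
  pj <- tab$aa_j[row, sharing]
  ok <- !is.na(pi) & !is.na(pj) & pi != "X" & pj != "X"
  pairs <- paste0(pi[ok], pj[ok])
  if (length(pairs) == 0) return(stats::setNames(numeric(0), character(0)))
  denom <- if (denominator == "sharing") length(pairs) else length(ids)
  tt <- table(pairs)
  stats::setNames(as.numeric(tt) / denom, names(tt))
}

#' Enrichment factor of an ordered amino-acid pair at a shared contact
#'
#' delta_pair = faap_T - faap_H over ordered (by reference endpoint, i
#' before j) amino-acid pairs among the members sharing the contact.
#'
#' @inheritParams aa_frequencies
#' @param aa_pair Character of length 2 like \code{c("A","G")}, or a
#'   2-character string \code{"AG"}.
#' @return List with \code{faap_T}, \code{faap_H}, \code{delta_pair};
#'   \code{NA}s when either group has no sharing member.
#' @export
pair_enrichment_factor <- function(tab, contact, aa_pair, members = NULL,
                                   denominator = "sharing") {
  if (length(aa_pair) == 2) aa_pair <- paste0(aa_pair[1], aa_pair[2])
  r <- .contact_row(tab, contact)
  fT <- .pair_frequencies(tab, r, "T", members, denominator)
  fH <- .pair_frequencies(tab, r, "H", members, denominator)
  if (length(fT) == 0 || length(fH) == 0)
    return(list(faap_T = NA_real_, faap_H = NA_real_, delta_pair = NA_real_))
  t1 <- if (aa_pair %in% names(fT)) fT[[aa_pair]] else 0
  h1 <- if (aa_pair %in% names(fH)) fH[[aa_pair]] else 0
  list(faap_T = t1, faap_H = h1, delta_pair = t1 - h1)
}

#' Full amino-acid and pair enrichment tables
#'
#' Computes enrichment entries for every (contact, endpoint, observed amino
#' acid) and every (contact, observed ordered pair). Contacts with no
#' sharing member in one of the two groups are skipped and listed with a
#' reason.
#'
#' @inheritParams aa_frequencies
#' @return Object of class \code{"enrichment_tables"}: list with data
#'   frames \code{aa} (ref_contact_i, ref_contact_j, endpoint, aa, n_T,
#'   n_H, faa_T, faa_H, delta), \code{pair} (analogous with aa_i, aa_j,
#'   delta_pair in column \code{delta}) and \code{skipped} (i, j, reason).
#' @export
full_enrichment_table <- function(tab, members = NULL,
                                  denominator = "sharing") {
  m <- nrow(tab$contacts)
  aa_rows <- list(); pair_rows <- list(); skip_rows <- list()
  for (r in seq_len(m)) {
    i <- tab$contacts[r, 1]; j <- tab$contacts[r, 2]
    fTi <- aa_frequencies(tab, c(i, j), "i", "T", members, denominator)
    fHi <- aa_frequencies(tab, c(i, j), "i", "H", members, denominator)
    if (length(fTi) == 0 || length(fHi) == 0) {
      reason <- if (length(fTi) == 0 && length(fHi) == 0)
        "no sharing member in either group"
      else if (length(fTi) == 0) "no sharing transferase"
      else "no sharing hydrolase"
      skip_rows[[length(skip_rows) + 1]] <-
        data.frame(i = i, j = j, reason = reason)
      next
    }
    fTj <- aa_frequencies(tab, c(i, j), "j", "T", members, denominator)
    fHj <- aa_frequencies(tab, c(i, j), "j", "H", members, denominator)
    nTs <- .n_sharing(tab, r, "T", members)
    nHs <- .n_sharing(tab, r, "H", members)
    for (ep in c("i", "j")) {
      fT <- if (ep == "i") fTi else fTj
      fH <- if (ep == "i") fHi else fHj
      aas <- sort(union(names(fT), names(fH)))
      for (a in aas) {
        t1 <- if (a %in% names(fT)) fT[[a]] else 0
        h1 <- if (a %in% names(fH)) fH[[a]] else 0
        aa_rows[[length(aa_rows) + 1]] <- data.frame(
          ref_contact_i = i, ref_contact_j = j, endpoint = ep, aa = a,
          n_T = nTs, n_H = nHs, faa_T = t1, faa_H = h1, delta = t1 - h1)
      }
    }
    pT <- .pair_frequencies(tab, r, "T", members, denominator)
    pH <- .pair_frequencies(tab, r, "H", members, denominator)
    prs <- sort(union(names(pT), names(pH)))
    for (p in prs) {
      t1 <- if (p %in% names(pT)) pT[[p]] else 0
      h1 <- if (p %in% names(pH)) pH[[p]] else 0
      pair_rows[[length(pair_rows) + 1]] <- data.frame(
        ref_contact_i = i, ref_contact_j = j,
        aa_i = substr(p, 1, 1), aa_j = substr(p, 2, 2),
        n_T = nTs, n_H = nHs, faap_T = t1, faap_H = h1, delta = t1 - h1)
    }
  }
  bindr <- function(x, proto) if (length(x) > 0) do.call(rbind, x) else proto
  structure(list(
    aa = bindr(aa_rows, data.frame(ref_contact_i = integer(),
                                   ref_contact_j = integer(),
                                   endpoint = character(), aa = character(),
                                   n_T = integer(), n_H = integer(),
                                   faa_T = numeric(), faa_H = numeric(),
                                   delta = numeric())),
    pair = bindr(pair_rows, data.frame(ref_contact_i = integer(),
                                       ref_contact_j = integer(),
                                       aa_i = character(), aa_j = character(),
                                       n_T = integer(), n_H = integer(),
                                       faap_T = numeric(), faap_H = numeric(),
                                       delta = numeric())),
    skipped = bindr(skip_rows, data.frame(i = integer(), j = integer(),
                                          reason = character()))),
    class = "enrichment_tables")
}

.n_sharing <- function(tab, row, group, members = NULL) {
  ids <- .group_members(tab, group, members)
  sum(tab$status[row, ids] == "shared")
}

#' @export
print.enrichment_tables <- function(x, ...) {
  cat("enrichment_tables: ", nrow(x$aa), " aa-level entries, ",
      nrow(x$pair), " pair-level entries, ", nrow(x$skipped),
      " skipped contact(s)\n", sep = "")
  invisible(x)
}

#' Look up the amino-acid level enrichment factor
#'
#' @param enr An \code{enrichment_tables} object.
#' @param i,j Reference contact pair.
#' @param endpoint \code{"i"} or \code{"j"}.
#' @param aa One-letter code.
#' @return delta value, or 0 with a warning-free fall-through when the
#'   amino acid was never observed at that endpoint in training (never
#'   extrapolated), or \code{NA} when the contact was skipped.
#' @export
delta_lookup <- function(enr, i, j, endpoint, aa) {
  if (nrow(enr$skipped) > 0 &&
      any(enr$skipped$i == i & enr$skipped$j == j)) return(NA_real_)
  d <- enr$aa
  hit <- d$ref_contact_i == i & d$ref_contact_j == j &
    d$endpoint == endpoint & d$aa == aa
  if (!any(hit)) return(0)
  d$delta[hit][1]
}

#' Look up the pair-level enrichment factor
#'
#' @param enr An \code{enrichment_tables} object.
#' @param i,j Reference contact pair.
#' @param aa_i,aa_j One-letter codes at the two endpoints.
#' @return delta_pair value, 0 for unobserved pairs, \code{NA} for skipped
#'   contacts.
#' @export
delta_pair_lookup <- function(enr, i, j, aa_i, aa_j) {
  if (nrow(enr$skipped) > 0 &&
      any(enr$skipped$i == i & enr$skipped$j == j)) return(NA_real_)
  d <- enr$pair
  hit <- d$ref_contact_i == i & d$ref_contact_j == j &
    d$aa_i == aa_i & d$aa_j == aa_j
  if (!any(hit)) return(0)
  d$delta[hit][1]
}

#' Write enrichment tables as TSV files
#'
#' @param enr An \code{enrichment_tables} object.
#' @param dir Output directory (created if needed); writes
#'   \code{enrichment_aa.tsv}, \code{enrichment_pair.tsv},
#'   \code{enrichment_skipped.tsv}.
#' @return The directory, invisibly.
#' @export
write_enrichment <- function(enr, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(enr$aa, file.path(dir, "enrichment_aa.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(enr$pair, file.path(dir, "enrichment_pair.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(enr$skipped, file.path(dir, "enrichment_skipped.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
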