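# Synthetic two-group structure datasets with planted contact-level
# amino-acid preferences.
#
# The scaffold is a deterministic serpentine sheet: residues advance along
# antiparallel rows (3.8 A spacing within a row, 4.5 A between rows), so
# residues vertically adjacent across rows form robust long-range contacts
# at the 5 A all-atom cutoff while diagonal neighbours appear only at 6 A.
# Each residue carries its alpha-carbon plus one pseudo side-chain atom;
# amino-acid identity is encoded in the residue name, not in geometry, so
# group-specific amino-acid preferences can be planted at chosen contact
# endpoints without touching the contact geometry.

.aa1_to_aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                 Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
                 L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                 S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")

.AA20 <- names(.aa1_to_aa3)

#' Serpentine scaffold geometry
#'
#' @param n_residues Number of residues.
#' @param strand_len Residues per row.
#' @param spacing In-row CA spacing (Angstrom).
#' @param row_gap Distance between rows (Angstrom).
#' @return List with \code{coords} (n x 3 CA coordinates), \code{row},
#'   \code{col} (physical column) per residue, and \code{contacts}: the
#'   analytic scaffold contact set at the 5 A all-atom cutoff with minimum
#'   separation 2 (vertically adjacent residues across rows).
#' @keywords internal
scaffold_geometry <- function(n_residues, strand_len = 10, spacing = 3.8,
                              row_gap = 4.5) {
  idx <- seq_len(n_residues)
  k <- (idx - 1) %/% strand_len          # row
  p <- (idx - 1) %% strand_len           # ordinal within row
  px <- ifelse(k %% 2 == 0, p, strand_len - 1 - p)  # physical column
  coords <- cbind(x = px * spacing, y = k * row_gap, z = 0)
  pairs <- list()
  for (cc in unique(px)) {
    members <- idx[px == cc]
    members <- members[order(k[members])]
    if (length(members) < 2) next
    for (m in seq_len(length(members) - 1)) {
      a <- members[m]; b <- members[m + 1]
      if (k[b] - k[a] != 1) next            # only adjacent rows
      lo <- min(a, b); hi <- max(a, b)
      if (hi - lo < 2) next                 # turn pairs are bonded neighbours
      pairs[[length(pairs) + 1]] <- c(lo, hi)
    }
  }
  contacts <- if (length(pairs) > 0) do.call(rbind, pairs)
  else matrix(integer(), 0, 2)
  contacts <- contacts[order(contacts[, 1], contacts[, 2]), , drop = FALSE]
  storage.mode(contacts) <- "integer"
  colnames(contacts) <- c("i", "j")
  list(coords = coords, row = k, col = px, contacts = contacts,
       strand_len = strand_len, spacing = spacing, row_gap = row_gap)
}

#' Specification of a synthetic two-group dataset
#'
#' Defaults mirror the canonical study conditions: 4 transglycosidases and
#' 10 hydrolases on a 60-residue scaffold, with amino-acid preferences
#' planted at 6 scaffold contacts (both endpoints of each).
#'
#' @param n_T,n_H Group sizes.
#' @param n_residues Scaffold length.
#' @param planted_sites Data frame with columns \code{i}, \code{j},
#'   \code{endpoint} ("i"/"j"), \code{position}, \code{aa_T}, \code{aa_H},
#'   \code{p}; NULL builds the default set of \code{n_planted} contacts
#'   spread over the scaffold at signal \code{signal}.
#' @param n_planted Number of planted contacts for the default layout.
#' @param signal Signal strength p in [0, 1]: the probability that a
#'   planted endpoint carries its group's preferred amino acid; otherwise
#'   the residue is uniform over the 18 amino acids that are preferred by
#'   neither group, so at p = 0 the two groups are exchangeable.
#' @param contact_dropout Probability that each non-planted scaffold
#'   contact is broken in a given protein (realized by displacing one
#'   endpoint residue out of the sheet plane, which also breaks that
#'   residue's other scaffold contacts; the ground truth records the
#'   realized contact set).
#' @param unrelated_scaffold Add one outgroup protein on a different
#'   serpentine geometry with its own random sequence (group label
#'   "unknown").
#' @param strand_len Residues per scaffold row.
#' @param seed Integer seed; the same spec and seed produce byte-identical
#'   output files.
#' @return List of class \code{"synthetic_spec"}.
#' @export
synthetic_spec <- function(n_T = 4, n_H = 10, n_residues = 60,
                           planted_sites = NULL, n_planted = 6,
                           signal = 1.0, contact_dropout = 0.1,
                           unrelated_scaffold = FALSE, strand_len = 10,
                           seed = 1) {
  stopifnot(n_T >= 1, n_H >= 1, signal >= 0, signal <= 1,
            contact_dropout >= 0, contact_dropout <= 1)
  geom <- scaffold_geometry(n_residues, strand_len)
  if (is.null(planted_sites)) {
    nc <- nrow(geom$contacts)
    if (n_planted > nc) stop("not enough scaffold contacts to plant ",
                             n_planted, " sites (have ", nc, ")")
    pick <- unique(round(seq(1, nc, length.out = n_planted)))
    aa_T_pal <- rep_len(c("W", "Y", "F", "M", "I", "V"), length(pick))
    aa_H_pal <- rep_len(c("D", "E", "K", "R", "N", "Q"), length(pick))
    rows <- list()
    for (s in seq_along(pick)) {
      ct <- geom$contacts[pick[s], ]
      for (ep in c("i", "j")) {
        rows[[length(rows) + 1]] <- data.frame(
          i = ct[1], j = ct[2], endpoint = ep,
          position = if (ep == "i") ct[1] else ct[2],
          aa_T = aa_T_pal[s], aa_H = aa_H_pal[s], p = signal,
          stringsAsFactors = FALSE)
      }
    }
    planted_sites <- do.call(rbind, rows)
  }
  if (any(planted_sites$aa_T == planted_sites$aa_H))
    stop("aa_T must differ from aa_H at every planted site")
  if (any(planted_sites$p < 0 | planted_sites$p > 1))
    stop("signal probabilities must be in [0, 1]")
  structure(list(n_T = n_T, n_H = n_H, n_residues = n_residues,
                 planted_sites = planted_sites,
                 contact_dropout = contact_dropout,
                 unrelated_scaffold = unrelated_scaffold,
                 strand_len = strand_len, seed = as.integer(seed),
                 geometry = geom),
            class = "synthetic_spec")
}

.draw_planted_aa <- function(group_aa, other_aa, p) {
  if (stats::runif(1) < p) group_aa
  else sample(setdiff(.AA20, c(group_aa, other_aa)), 1)
}

.write_synthetic_pdb <- function(path, seq1, coords, displaced,
                                 ligand_xyz = NULL) {
  n <- length(seq1)
  dz <- rep(0, n)
  dz[displaced$idx] <- displaced$dz
  ca <- cbind(coords[, 1], coords[, 2], coords[, 3] + dz)
  cb <- cbind(coords[, 1], coords[, 2], coords[, 3] + dz + 1.0)
  xyz <- numeric(0)
  for (r in seq_len(n)) xyz <- c(xyz, ca[r, ], cb[r, ])
  resid3 <- .aa1_to_aa3[seq1]
  args <- list(
    file = path,
    xyz = as.numeric(xyz),
    resno = rep(seq_len(n), each = 2),
    resid = rep(resid3, each = 2),
    elety = rep(c("CA", "CB"), n),
    chain = rep("A", 2 * n),
    type = rep("ATOM", 2 * n),
    eleno = seq_len(2 * n))
  if (!is.null(ligand_xyz)) {
    args$xyz <- c(args$xyz, as.numeric(ligand_xyz))
    args$resno <- c(args$resno, n + 1L)
    args$resid <- c(args$resid, "LIG")
    args$elety <- c(args$elety, "C1")
    args$chain <- c(args$chain, "A")
    args$type <- c(args$type, "HETATM")
    args$eleno <- c(args$eleno, 2L * n + 1L)
  }
  do.call(bio3d::write.pdb, args)
  invisible(path)
}

#' Generate a synthetic labelled structure dataset
#'
#' Emits one minimal standard-conformant PDB file per protein (CA plus one
#' pseudo side-chain atom per residue, plus a single-atom ligand marking
#' the "active site"), a 4-column manifest TSV, and a ground-truth JSON
#' with the realized sequences, displacements and contact sets.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @param dir Output directory (created).
#' @return List of class \code{"synthetic_dataset"}: \code{dir},
#'   \code{manifest} (path), \code{truth} (ground-truth list, also written
#'   to \code{ground_truth.json}).
#' @export
generate_dataset <- function(spec, dir = tempfile("synthdata")) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(spec$seed)
  geom <- spec$geometry
  L <- spec$n_residues
  base_seq <- sample(.AA20, L, replace = TRUE)
  planted_pos <- unique(spec$planted_sites$position)
  planted_keys <- unique(paste(spec$planted_sites$i, spec$planted_sites$j))
  contact_keys <- paste(geom$contacts[, 1], geom$contacts[, 2])
  nonplanted_rows <- which(!(contact_keys %in% planted_keys))

  ids <- c(sprintf("T%02d", seq_len(spec$n_T)),
           sprintf("H%02d", seq_len(spec$n_H)))
  groups <- c(rep("T", spec$n_T), rep("H", spec$n_H))

  # ligand: single pseudo-atom floating over the centre of the sheet
  centre <- colMeans(geom$coords)
  ligand_xyz <- c(centre[1], centre[2], 3.5)

  truth_proteins <- list()
  manifest_lines <- c("id\tpath\tgroup\tchain")
  for (k in seq_along(ids)) {
    id <- ids[k]; grp <- groups[k]
    seq1 <- base_seq
    realized_planted <- list()
    for (rr in seq_len(nrow(spec$planted_sites))) {
      ps <- spec$planted_sites[rr, ]
      grp_aa <- if (grp == "T") ps$aa_T else ps$aa_H
      oth_aa <- if (grp == "T") ps$aa_H else ps$aa_T
      aa <- .draw_planted_aa(grp_aa, oth_aa, ps$p)
      seq1[ps$position] <- aa
      realized_planted[[rr]] <- list(position = ps$position, aa = aa)
    }
    # contact dropout: displace the higher-index endpoint of each selected
    # non-planted contact (never a planted position)
    displaced_idx <- integer(0)
    if (spec$contact_dropout > 0 && length(nonplanted_rows) > 0) {
      broken <- nonplanted_rows[stats::runif(length(nonplanted_rows)) <
                                  spec$contact_dropout]
      for (b in broken) {
        i <- geom$contacts[b, 1]; j <- geom$contacts[b, 2]
        victim <- if (!(j %in% planted_pos)) j
        else if (!(i %in% planted_pos)) i else NA_integer_
        if (!is.na(victim)) displaced_idx <- c(displaced_idx, victim)
      }
      displaced_idx <- sort(unique(displaced_idx))
    }
    dzs <- ifelse((geom$row[displaced_idx] + geom$col[displaced_idx]) %% 2
                  == 0, 6, -6)
    keep <- !(geom$contacts[, 1] %in% displaced_idx |
                geom$contacts[, 2] %in% displaced_idx)
    realized_contacts <- geom$contacts[keep, , drop = FALSE]

    path <- file.path(dir, paste0(id, ".pdb"))
    .write_synthetic_pdb(path, seq1, geom$coords,
                         list(idx = displaced_idx, dz = dzs), ligand_xyz)
    manifest_lines <- c(manifest_lines,
                        paste(id, basename(path), grp, "A", sep = "\t"))
    truth_proteins[[id]] <- list(
      group = grp, sequence = paste(seq1, collapse = ""),
      displaced = displaced_idx,
      contacts = realized_contacts,
      planted = realized_planted)
  }

  if (spec$unrelated_scaffold) {
    og <- scaffold_geometry(spec$n_residues, strand_len = 7, spacing = 3.8,
                            row_gap = 4.6)
    og_seq <- sample(.AA20, spec$n_residues, replace = TRUE)
    path <- file.path(dir, "OUT01.pdb")
    .write_synthetic_pdb(path, og_seq, og$coords,
                         list(idx = integer(0), dz = numeric(0)), NULL)
    manifest_lines <- c(manifest_lines,
                        paste("OUT01", basename(path), "unknown", "A",
                              sep = "\t"))
    truth_proteins[["OUT01"]] <- list(
      group = "unknown", sequence = paste(og_seq, collapse = ""),
      displaced = integer(0), contacts = og$contacts,
      planted = list())
  }

  manifest_path <- file.path(dir, "manifest.tsv")
  con <- file(manifest_path, "wb")
  writeLines(manifest_lines, con, sep = "\n")
  close(con)

  # all emitted sequences are position-aligned by construction (equal-length
  # substitution variants of the scaffold), so the trivial gapless MSA is
  # the exact alignment; usable via prepare_dataset(alignments = ...)
  fasta_lines <- unlist(lapply(names(truth_proteins), function(id)
    c(paste0(">", id), truth_proteins[[id]]$sequence)))
  con <- file(file.path(dir, "alignment.fasta"), "wb")
  writeLines(fasta_lines, con, sep = "\n")
  close(con)

  truth <- list(
    seed = spec$seed, n_T = spec$n_T, n_H = spec$n_H,
    n_residues = spec$n_residues,
    base_sequence = paste(base_seq, collapse = ""),
    scaffold_contacts = geom$contacts,
    planted_sites = spec$planted_sites,
    qualifying_positions = sort(unique(spec$planted_sites$position)),
    ligand = list(het_id = paste0("LIG_A", L + 1), xyz = ligand_xyz),
    proteins = truth_proteins)
  jsonlite::write_json(
    truth, file.path(dir, "ground_truth.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "columns")

  structure(list(dir = dir, manifest = manifest_path, truth = truth),
            class = "synthetic_dataset")
}

#' Closed-form expected enrichment at the planted sites
#'
#' Under the generator, a planted endpoint in group G carries the group's
#' preferred amino acid with probability p and is otherwise uniform over
#' the 18 amino acids preferred by neither group. The
#' transferase-preferred amino acid aa_T therefore has expected frequency
#' p among transferases and 0 among hydrolases, giving
#' E[delta(aa_T)] = p and symmetrically E[delta(aa_H)] = -p; at p = 0 the
#' two groups are exchangeable and every expected delta is 0.
#'
#' @param spec A \code{\link{synthetic_spec}}.
#' @return Data frame: \code{i}, \code{j}, \code{endpoint},
#'   \code{position}, \code{aa}, \code{expected_faa_T},
#'   \code{expected_faa_H}, \code{expected_delta}, for both planted amino
#'   acids at every planted endpoint.
#' @export
expected_enrichment <- function(spec) {
  ps <- spec$planted_sites
  rows <- list()
  for (r in seq_len(nrow(ps))) {
    p <- ps$p[r]
    rows[[length(rows) + 1]] <- data.frame(
      i = ps$i[r], j = ps$j[r], endpoint = ps$endpoint[r],
      position = ps$position[r], aa = ps$aa_T[r],
      expected_faa_T = p, expected_faa_H = 0,
      expected_delta = p, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      i = ps$i[r], j = ps$j[r], endpoint = ps$endpoint[r],
      position = ps$position[r], aa = ps$aa_H[r],
      expected_faa_T = 0, expected_faa_H = p,
      expected_delta = -p, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
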