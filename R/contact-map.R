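# Residue-residue contact maps at a distance cutoff.

.check_scheme <- function(scheme) match.arg(scheme, c("all_atom", "ca"))

.residue_coords <- function(s, i, scheme) {
  a <- s$atoms[s$atoms$res_index == i, , drop = FALSE]
  if (scheme == "ca") {
    a <- a[a$elety == "CA", , drop = FALSE]
    if (nrow(a) == 0)
      stop("residue ", i, " of ", s$id, " has no CA atom (scheme 'ca')")
  }
  if (nrow(a) == 0) stop("residue ", i, " of ", s$id, " has no atoms")
  as.matrix(a[, c("x", "y", "z")])
}

.min_pairwise_dist <- function(A, B) {
  # minimum Euclidean distance between two coordinate sets (rows)
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(max(0, min(d2)))
}

#' Minimum inter-residue atomic distance
#'
#' @param s A \code{structure_model}.
#' @param i,j Linear residue indices.
#' @param scheme Atom scheme: \code{"all_atom"} uses every atom of the
#'   residue (hydrogens included when present), \code{"ca"} uses the
#'   alpha-carbon only.
#' @return Minimum Euclidean distance in Angstrom over all permitted atom
#'   pairs; symmetric in \code{i}, \code{j}.
#' @export
residue_min_distance <- function(s, i, j, scheme = "all_atom") {
  scheme <- .check_scheme(scheme)
  .min_pairwise_dist(.residue_coords(s, i, scheme),
                     .residue_coords(s, j, scheme))
}

#' Build the residue-residue contact map of a structure
#'
#' Two residues are in contact when their minimum inter-atomic distance
#' under the atom scheme is less than or equal to \code{cutoff} (inclusive)
#' and their linear-index separation is at least \code{min_separation}.
#'
#' @param s A \code{structure_model}.
#' @param cutoff Distance cutoff in Angstrom (the analyses here use 5 for
#'   amino-acid level work and 6 for pair/network level work).
#' @param scheme \code{"all_atom"} or \code{"ca"}.
#' @param min_separation Minimum sequence separation \code{j - i}; the
#'   default 2 excludes trivial bonded-neighbour contacts, 0 reproduces a
#'   raw all-pairs map.
#' @return Object of class \code{"contact_map"}: list with
#'   \code{structure_id}, \code{cutoff}, \code{scheme},
#'   \code{min_separation}, \code{n_res} and \code{contacts}, an m x 2
#'   integer matrix of pairs with \code{i < j}, ordered lexicographically.
#' @export
build_contact_map <- function(s, cutoff = 5, scheme = "all_atom",
                              min_separation = 2) {
  scheme <- .check_scheme(scheme)
  stopifnot(cutoff > 0, min_separation >= 0)
  L <- nrow(s$residues)
  at <- s$atoms
  if (scheme == "ca") {
    at <- at[at$elety == "CA", , drop = FALSE]
    missing_ca <- setdiff(seq_len(L), unique(at$res_index))
    if (length(missing_ca) > 0)
      stop("residues without CA atom under scheme 'ca': ",
           paste(utils::head(missing_ca, 10), collapse = ", "))
  }
  xyz <- as.matrix(at[, c("x", "y", "z")])
  ridx <- at$res_index
  rlev <- sort(unique(ridx))
  coords_by_res <- split.data.frame(xyz, factor(ridx, levels = rlev))

  # coarse screen on per-residue centroids (lower bound on the atom-pair
  # minimum: centroid distance minus both residues' radii), then exact
  # atom-pair minimum for surviving pairs
  cent <- t(vapply(coords_by_res, colMeans, numeric(3)))
  spread <- vapply(seq_along(rlev), function(k) {
    m <- coords_by_res[[k]]
    sqrt(max(rowSums((m - matrix(cent[k, ], nrow(m), 3, byrow = TRUE))^2)))
  }, numeric(1))
  nr <- length(rlev)
  dc2 <- outer(rowSums(cent^2), rowSums(cent^2), "+") - 2 * tcrossprod(cent)
  dc <- sqrt(pmax(dc2, 0))
  sep_ok <- outer(rlev, rlev, function(a, b) b - a >= pmax(min_separation, 1))
  cand <- which(sep_ok & dc - outer(spread, spread, "+") <= cutoff,
                arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    keep[k] <- .min_pairwise_dist(coords_by_res[[cand[k, 1]]],
                                  coords_by_res[[cand[k, 2]]]) <= cutoff
  }
  cand <- cand[keep, , drop = FALSE]
  contacts <- if (nrow(cand) > 0) {
    m <- cbind(rlev[cand[, 1]], rlev[cand[, 2]])
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  } else matrix(integer(), 0, 2)
  storage.mode(contacts) <- "integer"
  colnames(contacts) <- c("i", "j")
  structure(list(structure_id = s$id, cutoff = cutoff, scheme = scheme,
                 min_separation = as.integer(min_separation),
                 n_res = L, contacts = contacts),
            class = "contact_map")
}

#' @export
print.contact_map <- function(x, ...) {
  cat("contact_map '", x$structure_id, "': ", nrow(x$contacts),
      " contacts over ", x$n_res, " residues (cutoff ", x$cutoff,
      " A, ", x$scheme, ", min separation ", x$min_separation, ")\n",
      sep = "")
  invisible(x)
}

#' Test contact membership
#'
#' @param cm A \code{contact_map}.
#' @param i,j Residue indices (any order).
#' @return Logical vector: is each (i, j) pair a contact of \code{cm}?
#' @export
has_contact <- function(cm, i, j) {
  lo <- pmin(i, j); hi <- pmax(i, j)
  key <- paste(lo, hi)
  key %in% paste(cm$contacts[, 1], cm$contacts[, 2])
}

#' Minimum distance from a residue to a site
#'
#' The site is a set of residue positions and/or hetero groups (e.g. the
#' catalytic residues plus a bound transition-state analogue); the result is
#' the minimum all-atom distance from the residue at \code{position} to any
#' atom of any site member. A position that is itself part of the site gives
#' 0.
#'
#' @param s A \code{structure_model}.
#' @param position Linear residue index.
#' @param site List with elements \code{residues} (integer linear indices)
#'   and/or \code{hetero} (character \code{het_id} values as found in
#'   \code{s$hetero$het_id}); at least one member required.
#' @return Distance in Angstrom.
#' @export
distance_to_site <- function(s, position, site) {
  res_idx <- site$residues
  het_ids <- site$hetero
  if ((is.null(res_idx) || length(res_idx) == 0) &&
      (is.null(het_ids) || length(het_ids) == 0))
    stop("empty site")
  if (!is.null(res_idx) && position %in% res_idx) return(0)
  A <- .residue_coords(s, position, "all_atom")
  coords <- list()
  if (!is.null(res_idx) && length(res_idx) > 0) {
    m <- s$atoms[s$atoms$res_index %in% res_idx, c("x", "y", "z"), drop = FALSE]
    coords[[length(coords) + 1]] <- as.matrix(m)
  }
  if (!is.null(het_ids) && length(het_ids) > 0) {
    h <- s$hetero[s$hetero$het_id %in% het_ids, c("x", "y", "z"), drop = FALSE]
    if (nrow(h) == 0)
      stop("no hetero atoms matching site ids: ",
           paste(het_ids, collapse = ", "))
    coords[[length(coords) + 1]] <- as.matrix(h)
  }
  B <- do.call(rbind, coords)
  .min_pairwise_dist(A, B)
}

#' Write a contact map to its text format
#'
#' Format: header lines \code{#id}, \code{#cutoff}, \code{#scheme},
#' \code{#min_separation}, \code{#n_res}, then one tab-separated
#' \code{i<TAB>j} pair per line (1-based, i < j). Round-trips bit-exactly
#' through \code{\link{read_contact_map}}.
#'
#' @param cm A \code{contact_map}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @export
write_contact_map <- function(cm, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c(paste0("#id\t", cm$structure_id),
           paste0("#cutoff\t", format(cm$cutoff)),
           paste0("#scheme\t", cm$scheme),
           paste0("#min_separation\t", cm$min_separation),
           paste0("#n_res\t", cm$n_res))
  body <- if (nrow(cm$contacts) > 0)
    paste(cm$contacts[, 1], cm$contacts[, 2], sep = "\t") else character()
  writeLines(c(hdr, body), con, sep = "\n")
  invisible(path)
}

#' Read a contact map from its text format
#'
#' @param path File written by \code{\link{write_contact_map}}.
#' @return A \code{contact_map}.
#' @export
read_contact_map <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- strsplit(sub("^#", "", hdr), "\t")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  need <- c("id", "cutoff", "scheme", "min_separation", "n_res")
  if (!all(need %in% keys)) stop("malformed contact-map file: ", path)
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  contacts <- if (length(body) > 0) {
    m <- do.call(rbind, strsplit(body, "\t"))
    matrix(as.integer(m), ncol = 2)
  } else matrix(integer(), 0, 2)
  colnames(contacts) <- c("i", "j")
  structure(list(structure_id = vals[keys == "id"],
                 cutoff = as.numeric(vals[keys == "cutoff"]),
                 scheme = vals[keys == "scheme"],
                 min_separation = as.integer(vals[keys == "min_separation"]),
                 n_res = as.integer(vals[keys == "n_res"]),
                 contacts = contacts),
            class = "contact_map")
}
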