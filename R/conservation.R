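# Contact conservation scores and the pairwise contact-similarity
# coefficient.

#' Contact conservation profile of a reference
#'
#' For every reference contact, the number of dataset members (including
#' the reference itself) in which the mapped contact is present, and the
#' conservation score n_sharing / N. Because the reference shares its own
#' contacts, scores lie in (0, 1].
#'
#' @param tab A \code{shared_contact_table}.
#' @return Data frame of class \code{"conservation_profile"}: \code{i},
#'   \code{j}, \code{n_sharing}, \code{score}, \code{n_absent},
#'   \code{n_unalignable}; attribute \code{"N"} (dataset size) and
#'   \code{"ref_id"}.
#' @export
conservation_profile <- function(tab) {
  N <- length(tab$members)
  n_sharing <- rowSums(tab$status == "shared")
  out <- data.frame(i = tab$contacts[, 1], j = tab$contacts[, 2],
                    n_sharing = n_sharing, score = n_sharing / N,
                    n_absent = rowSums(tab$status == "absent"),
                    n_unalignable = rowSums(tab$status == "unalignable"))
  attr(out, "N") <- N
  attr(out, "ref_id") <- tab$ref_id
  class(out) <- c("conservation_profile", class(out))
  out
}

#' Contact-similarity coefficient between two conservation profiles
#'
#' The contacts of A whose mapped pair (under the A-to-B position map) is
#' also a contact of B form the point set; the coefficient is the squared
#' Pearson correlation between the two conservation-score vectors over
#' those points. Contacts that are unalignable or absent in B are dropped,
#' not imputed.
#'
#' @param profile_A,profile_B \code{conservation_profile}s computed on the
#'   same dataset.
#' @param pm \code{position_map} from A to B.
#' @return List with \code{n_points}, \code{r}, \code{r_squared};
#'   \code{r}/\code{r_squared} are \code{NA} when fewer than 3 points or
#'   zero variance on either axis.
#' @export
similarity_coefficient <- function(profile_A, profile_B, pm) {
  mi <- .map_lookup(pm, profile_A$i)
  mj <- .map_lookup(pm, profile_A$j)
  lo <- pmin(mi, mj); hi <- pmax(mi, mj)
  keyB <- paste(profile_B$i, profile_B$j)
  hit <- match(paste(lo, hi), keyB)
  ok <- !is.na(mi) & !is.na(mj) & !is.na(hit)
  n <- sum(ok)
  if (n < 3) return(list(n_points = n, r = NA_real_, r_squared = NA_real_))
  x <- profile_A$score[ok]
  y <- profile_B$score[hit[ok]]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(n_points = n, r = NA_real_, r_squared = NA_real_))
  r <- stats::cor(x, y)
  list(n_points = n, r = r, r_squared = r^2)
}

#' All-against-all contact-similarity matrix
#'
#' Computes every protein's conservation profile (each in turn as the
#' reference of the whole dataset) and the pairwise similarity
#' coefficients. One alignment is computed per unordered pair and its
#' inverse reused for the reverse direction, so the matrix is exactly
#' symmetric. Undefined coefficients (fewer than 3 shared mapped contacts,
#' or zero variance) are reported as 0: no demonstrable similarity.
#'
#' @param structures Named list of \code{structure_model}s.
#' @param cutoff,scheme,min_separation Contact-map parameters.
#' @param params Alignment parameters.
#' @return List of class \code{"similarity_matrix"}: \code{r_squared}
#'   (symmetric matrix, unit diagonal), \code{n_points} (matrix) and
#'   \code{profiles} (per-protein conservation profiles).
#' @export
similarity_matrix <- function(structures, cutoff = 5, scheme = "all_atom",
                              min_separation = 2, params = align_params()) {
  ids <- names(structures)
  if (length(ids) < 2) stop("need at least 2 structures")
  cms <- lapply(structures, build_contact_map, cutoff = cutoff,
                scheme = scheme, min_separation = min_separation)
  seqs <- vapply(structures, extract_sequence, "")

  pm <- vector("list", length(ids)); names(pm) <- ids
  for (a in ids) { pm[[a]] <- vector("list", length(ids)); names(pm[[a]]) <- ids }
  for (ai in seq_along(ids)) {
    a <- ids[ai]
    L <- nrow(structures[[a]]$residues)
    pm[[a]][[a]] <- position_map(a, a, cbind(seq_len(L), seq_len(L)))
    for (bi in seq_along(ids)) {
      if (bi <= ai) next
      b <- ids[bi]
      pm[[a]][[b]] <- align_pair(seqs[[a]], seqs[[b]], a, b, params = params)
      pm[[b]][[a]] <- invert_map(pm[[a]][[b]])
    }
  }

  profiles <- vector("list", length(ids)); names(profiles) <- ids
  for (a in ids) {
    ds <- structure(list(ref_id = a, structures = structures, cms = cms,
                         maps = pm[[a]], cutoff = cutoff, scheme = scheme,
                         min_separation = as.integer(min_separation)),
                    class = "contact_dataset")
    profiles[[a]] <- conservation_profile(build_shared_table(ds))
  }

  n <- length(ids)
  R2 <- matrix(0, n, n, dimnames = list(ids, ids))
  NP <- matrix(0L, n, n, dimnames = list(ids, ids))
  diag(R2) <- 1
  for (ai in seq_len(n)) {
    NP[ai, ai] <- nrow(profiles[[ai]])
    for (bi in seq_len(n)) {
      if (bi <= ai) next
      sc <- similarity_coefficient(profiles[[ids[ai]]], profiles[[ids[bi]]],
                                   pm[[ids[ai]]][[ids[bi]]])
      v <- if (is.na(sc$r_squared)) 0 else sc$r_squared
      R2[ai, bi] <- R2[bi, ai] <- v
      NP[ai, bi] <- NP[bi, ai] <- sc$n_points
    }
  }
  structure(list(r_squared = R2, n_points = NP, profiles = profiles),
            class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("similarity_matrix over", nrow(x$r_squared), "proteins\n")
  print(round(x$r_squared, 3))
  invisible(x)
}

#' Write a conservation profile and similarity matrix as TSV
#'
#' @param profile A \code{conservation_profile}.
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_conservation <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
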