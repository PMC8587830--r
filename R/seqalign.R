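# Position mapping between reference and target structures.

#' Alignment parameters
#'
#' Defaults follow the common EMBOSS-needle style global protein alignment:
#' BLOSUM62 with affine gaps, opening penalty 10, extension penalty 0.5.
#'
#' @param matrix Name of a substitution matrix available in Biostrings
#'   (e.g. "BLOSUM62", "BLOSUM50", "PAM250").
#' @param gap_open Gap opening penalty (positive).
#' @param gap_extend Gap extension penalty (positive).
#' @return List of class \code{"align_params"}.
#' @export
align_params <- function(matrix = "BLOSUM62", gap_open = 10, gap_extend = 0.5) {
  structure(list(matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend), class = "align_params")
}

#' Position map constructor
#'
#' A partial, one-to-one, strictly order-preserving mapping from reference
#' linear indices to target linear indices.
#'
#' @param ref_id,tgt_id Structure labels.
#' @param pairs Two-column integer matrix (ref index, tgt index), rows in
#'   increasing reference order.
#' @return Object of class \code{"position_map"}.
#' @export
position_map <- function(ref_id, tgt_id, pairs) {
  pairs <- matrix(as.integer(pairs), ncol = 2,
                  dimnames = list(NULL, c("ref", "tgt")))
  if (nrow(pairs) > 1) {
    if (any(diff(pairs[, 1]) <= 0) || any(diff(pairs[, 2]) <= 0))
      stop("position map must be strictly increasing in both coordinates")
  }
  structure(list(ref_id = ref_id, tgt_id = tgt_id, pairs = pairs),
            class = "position_map")
}

#' @export
print.position_map <- function(x, ...) {
  cat("position_map ", x$ref_id, " -> ", x$tgt_id, ": ",
      nrow(x$pairs), " aligned positions\n", sep = "")
  invisible(x)
}

.map_lookup <- function(pm, ref_idx) {
  # target index for each reference index, NA when unmapped
  pm$pairs[match(ref_idx, pm$pairs[, 1]), 2]
}

#' Invert a position map
#'
#' @param pm A \code{position_map}.
#' @return The inverse \code{position_map} (target as reference).
#' @export
invert_map <- function(pm) {
  position_map(pm$tgt_id, pm$ref_id, pm$pairs[, c(2, 1), drop = FALSE])
}

.map_from_gapped <- function(ref_id, tgt_id, g_ref, g_tgt) {
  a <- strsplit(g_ref, "")[[1]]
  b <- strsplit(g_tgt, "")[[1]]
  if (length(a) != length(b)) stop("ragged alignment")
  gap <- c("-", ".")
  ra <- cumsum(!(a %in% gap))
  rb <- cumsum(!(b %in% gap))
  keep <- !(a %in% gap) & !(b %in% gap)
  position_map(ref_id, tgt_id, cbind(ra[keep], rb[keep]))
}

#' Globally align two sequences and return the position map
#'
#' Global (Needleman-Wunsch) alignment with affine gap penalties under a
#' substitution matrix, computed with \code{Biostrings::pairwiseAlignment}.
#' The map contains exactly the columns where both sequences have a residue.
#' For faithful reproduction of an externally computed alignment, supply it
#' via \code{\link{load_alignment}} instead.
#'
#' @param ref_seq,tgt_seq Amino-acid strings (may contain "X").
#' @param ref_id,tgt_id Labels for the two sequences.
#' @param params An \code{\link{align_params}} object.
#' @return A \code{position_map}; the alignment score is attached as
#'   attribute \code{"score"}.
#' @export
align_pair <- function(ref_seq, tgt_seq, ref_id = "ref", tgt_id = "tgt",
                       params = align_params()) {
  stopifnot(nchar(ref_seq) > 0, nchar(tgt_seq) > 0)
  mat <- .get_subst_matrix(params$matrix)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(ref_seq), Biostrings::AAString(tgt_seq),
    substitutionMatrix = mat, gapOpening = params$gap_open,
    gapExtension = params$gap_extend, type = "global")
  pm <- .map_from_gapped(
    ref_id, tgt_id,
    as.character(Biostrings::alignedPattern(pa)),
    as.character(Biostrings::alignedSubject(pa)))
  attr(pm, "score") <- Biostrings::score(pa)
  pm
}

.subst_matrix_cache <- new.env(parent = emptyenv())

.get_subst_matrix <- function(name) {
  if (!exists(name, envir = .subst_matrix_cache)) {
    e <- new.env()
    utils::data(list = name, package = "Biostrings", envir = e)
    assign(name, get(name, envir = e), envir = .subst_matrix_cache)
  }
  get(name, envir = .subst_matrix_cache)
}

#' Extract a position map from a FASTA multiple alignment
#'
#' @param fasta_msa Path to an aligned FASTA file (gap characters "-" or
#'   "."); all aligned sequences must have equal length.
#' @param ref_id,tgt_id Sequence identifiers present in the file (matched
#'   against the first whitespace-delimited token of each header).
#' @return A \code{position_map} over the matched non-gap columns.
#' @export
load_alignment <- function(fasta_msa, ref_id, tgt_id) {
  aln <- Biostrings::readAAStringSet(fasta_msa)
  nm <- vapply(strsplit(names(aln), "\\s+"), `[`, "", 1)
  if (!(ref_id %in% nm)) stop("id not in alignment: ", ref_id)
  if (!(tgt_id %in% nm)) stop("id not in alignment: ", tgt_id)
  if (length(unique(Biostrings::width(aln))) != 1)
    stop("ragged alignment: sequences have unequal aligned lengths")
  .map_from_gapped(ref_id, tgt_id,
                   as.character(aln[[match(ref_id, nm)]]),
                   as.character(aln[[match(tgt_id, nm)]]))
}

#' Map a reference contact onto a target contact map
#'
#' @param contact Integer pair (i, j) of reference linear indices.
#' @param pm \code{position_map} from the reference to the target.
#' @param tgt_cm \code{contact_map} of the target.
#' @return One of \code{"shared"}, \code{"absent"}, \code{"unalignable"}:
#'   unalignable when either endpoint is unmapped, shared when the mapped
#'   (sorted) pair is a target contact, absent otherwise.
#' @export
map_contact <- function(contact, pm, tgt_cm) {
  mi <- .map_lookup(pm, contact[1])
  mj <- .map_lookup(pm, contact[2])
  if (is.na(mi) || is.na(mj)) return("unalignable")
  if (has_contact(tgt_cm, mi, mj)) "shared" else "absent"
}
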