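# Structure input: PDB/mmCIF parsing into a uniform in-memory model.

#' Amino-acid three-letter to one-letter mapping
#'
#' The 20 standard residues plus common modified residues that have a
#' standard parent (e.g. selenomethionine MSE -> M). Residues without a
#' standard parent map to "X"; such positions are kept for contact geometry
#' but excluded from enrichment counting.
#'
#' @return Named character vector mapping 3-letter codes to 1-letter codes.
#' @keywords internal
aa3_to_aa1_table <- function() {
  c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
    GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
    LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
    SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
    # modified residues with a standard parent
    MSE = "M", SEP = "S", TPO = "T", PTR = "Y", CSO = "C",
    CME = "C", CSD = "C", MLY = "K", HYP = "P", KCX = "K",
    PCA = "E", FME = "M")
}

#' Convert residue names to one-letter codes
#'
#' @param resid3 Character vector of 3-letter residue names.
#' @return Character vector of 1-letter codes; unknown names become "X".
#' @export
aa321x <- function(resid3) {
  tab <- aa3_to_aa1_table()
  out <- unname(tab[toupper(resid3)])
  out[is.na(out)] <- "X"
  out
}

.water_names <- c("HOH", "WAT", "DOD", "H2O")

#' Read a protein structure into a structure model
#'
#' Parses a PDB or mmCIF file (dispatch on file extension: \code{.cif} is
#' mmCIF, anything else PDB) and reduces it to a single-chain polymer model
#' with 1-based linear residue indices, plus non-water hetero groups.
#' Alternate locations are resolved to the highest occupancy (first in file
#' on ties); only the first model of multi-model files is used; waters are
#' dropped everywhere.
#'
#' @param path Path to a \code{.pdb}/\code{.ent} or \code{.cif} file.
#' @param chain Chain identifier, or \code{"auto"} to select the chain with
#'   the most amino-acid residues (ties broken by lexicographic chain id).
#' @param id Label for the structure; defaults to the file stem.
#' @param group Functional group label: \code{"H"}, \code{"T"} or
#'   \code{"unknown"}.
#' @return An object of class \code{"structure_model"}: a list with
#'   \code{id}, \code{chain}, \code{group}, \code{residues} (data frame with
#'   \code{index}, \code{resno}, \code{icode}, \code{resid3}, \code{aa}),
#'   \code{atoms} (polymer atoms: \code{res_index}, \code{elety}, \code{x},
#'   \code{y}, \code{z}) and \code{hetero} (non-water hetero atoms with a
#'   \code{het_id} grouping key).
#' @export
read_structure <- function(path, chain = "auto", id = NULL, group = "unknown") {
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (is.null(id)) id <- sub("\\.(pdb|ent|cif)$", "", basename(path))
  ext <- tolower(tools::file_ext(path))
  pdb <- tryCatch(
    if (ext == "cif") bio3d::read.cif(path, verbose = FALSE, rm.alt = FALSE)
    else bio3d::read.pdb(path, verbose = FALSE, multi = FALSE,
                         rm.alt = FALSE),
    error = function(e) stop("cannot parse structure file '", path, "': ",
                             conditionMessage(e)))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0) stop("no atoms in file: ", path)
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1

  # altloc resolution: within each (chain, resno, insert, elety) keep the
  # highest-occupancy record, ties to the first in file
  dup_key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
  if (anyDuplicated(dup_key)) {
    ord <- order(dup_key, -at$o, seq_len(nrow(at)))
    at <- at[ord, , drop = FALSE]
    at <- at[!duplicated(dup_key[ord]), , drop = FALSE]
    at <- at[order(as.integer(rownames(at))), , drop = FALSE]
  }

  is_water <- toupper(at$resid) %in% .water_names
  at <- at[!is_water, , drop = FALSE]
  std <- at$type == "ATOM" & toupper(at$resid) %in% names(aa3_to_aa1_table())

  poly <- at[std, , drop = FALSE]
  if (chain == "auto") {
    res_key <- paste(poly$chain, poly$resno, poly$insert, sep = "\r")
    per_chain <- tapply(res_key, poly$chain, function(k) length(unique(k)))
    if (length(per_chain) == 0) stop("no amino-acid residues in file: ", path)
    per_chain <- per_chain[order(-per_chain, names(per_chain))]
    chain <- names(per_chain)[1]
  }
  poly <- poly[poly$chain == chain, , drop = FALSE]
  if (nrow(poly) == 0)
    stop("no amino-acid residues in chain '", chain, "' of ", path)

  res_key <- paste(poly$resno, poly$insert, sep = "\r")
  uk <- unique(res_key)   # file order
  res_index <- match(res_key, uk)
  first <- match(uk, res_key)
  residues <- data.frame(
    index  = seq_along(uk),
    resno  = poly$resno[first],
    icode  = poly$insert[first],
    resid3 = toupper(poly$resid[first]),
    aa     = aa321x(poly$resid[first]),
    stringsAsFactors = FALSE)
  atoms <- data.frame(
    res_index = res_index,
    elety = poly$elety,
    x = poly$x, y = poly$y, z = poly$z,
    stringsAsFactors = FALSE)

  het <- at[at$type == "HETATM" &
              !(toupper(at$resid) %in% names(aa3_to_aa1_table())), ,
            drop = FALSE]
  hetero <- if (nrow(het) > 0) {
    data.frame(
      het_id = paste0(toupper(het$resid), "_", het$chain, het$resno),
      resid3 = toupper(het$resid),
      resno  = het$resno,
      elety  = het$elety,
      x = het$x, y = het$y, z = het$z,
      stringsAsFactors = FALSE)
  } else {
    data.frame(het_id = character(), resid3 = character(),
               resno = integer(), elety = character(),
               x = numeric(), y = numeric(), z = numeric(),
               stringsAsFactors = FALSE)
  }

  structure(list(id = id, chain = chain, group = group,
                 residues = residues, atoms = atoms, hetero = hetero),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat("structure_model '", x$id, "' chain ", x$chain,
      " (group ", x$group, ")\n", sep = "")
  cat("  ", nrow(x$residues), " residues, ", nrow(x$atoms), " polymer atoms, ",
      length(unique(x$hetero$het_id)), " hetero group(s)\n", sep = "")
  invisible(x)
}

#' Extract the one-letter amino-acid sequence of a structure model
#'
#' @param s A \code{structure_model}.
#' @return Character scalar of length-L one-letter codes in linear-index
#'   order ("X" for residues without a standard parent).
#' @export
extract_sequence <- function(s) {
  stopifnot(inherits(s, "structure_model"))
  if (nrow(s$residues) == 0) stop("empty polymer in structure ", s$id)
  paste(s$residues$aa, collapse = "")
}

#' Read a dataset manifest
#'
#' The manifest is a tab-separated file with a header line containing the
#' columns \code{id}, \code{path}, \code{group} and \code{chain}; lines
#' starting with \code{#} are comments. \code{group} must be one of
#' \code{H}, \code{T} or \code{unknown}.
#'
#' @param path Path to the manifest TSV.
#' @return A data frame of validated manifest entries, class
#'   \code{"dataset_manifest"}.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         colClasses = "character")
  need <- c("id", "path", "group", "chain")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  m <- m[, need]
  if (anyDuplicated(m$id))
    stop("duplicate id in manifest: ",
         paste(unique(m$id[duplicated(m$id)]), collapse = ", "))
  bad <- setdiff(unique(m$group), c("H", "T", "unknown"))
  if (length(bad) > 0)
    stop("unknown group label(s) in manifest: ", paste(bad, collapse = ", "),
         " (allowed: H, T, unknown)")
  class(m) <- c("dataset_manifest", class(m))
  m
}

#' Read all structures listed in a manifest
#'
#' Relative paths in the manifest are resolved against the manifest's own
#' directory.
#'
#' @param manifest A \code{dataset_manifest} or path to one.
#' @param base_dir Directory against which relative paths are resolved;
#'   defaults to the manifest directory when \code{manifest} is a path.
#' @return Named list of \code{structure_model} objects.
#' @export
read_dataset <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  }
  if (is.null(base_dir)) base_dir <- "."
  out <- vector("list", nrow(manifest))
  names(out) <- manifest$id
  for (k in seq_len(nrow(manifest))) {
    p <- manifest$path[k]
    if (!file.exists(p)) p <- file.path(base_dir, manifest$path[k])
    ch <- manifest$chain[k]
    if (is.na(ch) || ch == "") ch <- "auto"
    out[[k]] <- read_structure(p, chain = ch, id = manifest$id[k],
                               group = manifest$group[k])
  }
  out
}
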