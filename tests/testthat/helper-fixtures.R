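# Shared fixtures: in-code structure models and a cached default synthetic
# dataset (built once per test run).

# build a structure_model directly from coordinates; coords is a list of
# per-residue atom coordinate matrices (rows = atoms), aa a 1-letter vector
make_structure <- function(coords, aa = NULL, id = "toy", group = "unknown",
                           elety = NULL) {
  n <- length(coords)
  if (is.null(aa)) aa <- rep("A", n)
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL", X = "UNK")
  atoms <- do.call(rbind, lapply(seq_len(n), function(k) {
    m <- coords[[k]]
    if (is.null(dim(m))) m <- matrix(m, ncol = 3)
    ety <- if (is.null(elety)) c("CA", paste0("C", seq_len(max(0, nrow(m) - 1))))
    else elety[[k]]
    data.frame(res_index = k, elety = ety[seq_len(nrow(m))],
               x = m[, 1], y = m[, 2], z = m[, 3],
               stringsAsFactors = FALSE)
  }))
  structure(list(
    id = id, chain = "A", group = group,
    residues = data.frame(index = seq_len(n), resno = seq_len(n),
                          icode = "", resid3 = unname(aa3[aa]), aa = aa,
                          stringsAsFactors = FALSE),
    atoms = atoms,
    hetero = data.frame(het_id = character(), resid3 = character(),
                        resno = integer(), elety = character(),
                        x = numeric(), y = numeric(), z = numeric(),
                        stringsAsFactors = FALSE)),
    class = "structure_model")
}

# hand-built shared_contact_table for frequency/enrichment unit tests
make_shared_table <- function(contacts, members, groups, status, aa_i, aa_j,
                              ref_id = members[1]) {
  dn <- list(NULL, members)
  structure(list(ref_id = ref_id,
                 contacts = matrix(as.integer(contacts), ncol = 2,
                                   dimnames = list(NULL, c("i", "j"))),
                 members = members,
                 groups = stats::setNames(groups, members),
                 status = matrix(status, ncol = length(members),
                                 dimnames = dn),
                 aa_i = matrix(aa_i, ncol = length(members), dimnames = dn),
                 aa_j = matrix(aa_j, ncol = length(members), dimnames = dn)),
            class = "shared_contact_table")
}

# default synthetic dataset at full signal, cached across test files
.fixture_cache <- new.env(parent = emptyenv())

# dataset with exactly three planted qualifying positions (one endpoint of
# three scaffold contacts), cached
three_site_dataset <- function() {
  if (!exists("three_site", envir = .fixture_cache)) {
    base <- contactdelta::synthetic_spec(seed = 5)  # for scaffold geometry
    ct <- base$geometry$contacts[c(3, 15, 30), ]
    planted <- data.frame(i = ct[, 1], j = ct[, 2], endpoint = "i",
                          position = ct[, 1],
                          aa_T = c("W", "Y", "F"), aa_H = c("D", "E", "K"),
                          p = 1.0, stringsAsFactors = FALSE)
    spec <- contactdelta::synthetic_spec(planted_sites = planted, seed = 5)
    dsd <- contactdelta::generate_dataset(spec, file.path(tempdir(),
                                                          "synth_3site"))
    structs <- contactdelta::read_dataset(dsd$manifest)
    ds <- contactdelta::prepare_dataset(
      structs, "T01", alignments = file.path(dsd$dir, "alignment.fasta"))
    tab <- contactdelta::build_shared_table(ds)
    assign("three_site",
           list(spec = spec, dsd = dsd, ds = ds, tab = tab,
                enr = contactdelta::full_enrichment_table(tab),
                cons = contactdelta::conservation_profile(tab)),
           envir = .fixture_cache)
  }
  get("three_site", envir = .fixture_cache)
}

default_synth <- function() {
  if (!exists("synth", envir = .fixture_cache)) {
    spec <- contactdelta::synthetic_spec(seed = 101)
    dsd <- contactdelta::generate_dataset(spec, file.path(tempdir(),
                                                          "synth_default"))
    structs <- contactdelta::read_dataset(dsd$manifest)
    ds <- contactdelta::prepare_dataset(
      structs, "T01", alignments = file.path(dsd$dir, "alignment.fasta"))
    tab <- contactdelta::build_shared_table(ds)
    enr <- contactdelta::full_enrichment_table(tab)
    assign("synth", list(spec = spec, dsd = dsd, structs = structs,
                         ds = ds, tab = tab, enr = enr),
           envir = .fixture_cache)
  }
  get("synth", envir = .fixture_cache)
}
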