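# Run configuration: flat key-value files, analysis profiles, defaults.

#' Run configuration
#'
#' Bundles every tunable parameter of the pipeline. Two profiles encode
#' the two standard parameterizations: \code{"analysis1"} (5 A cutoff,
#' amino-acid level enrichment, used for classification, conservation and
#' amino-acid level site selection) and \code{"analysis2"} (6 A cutoff,
#' pair-level enrichment plus betweenness screening).
#'
#' @param profile \code{"analysis1"} or \code{"analysis2"}; sets cutoff
#'   and selection mode defaults, which later arguments may override.
#' @param cutoff Contact distance cutoff in Angstrom.
#' @param scheme Atom scheme, \code{"all_atom"} or \code{"ca"}.
#' @param min_separation Minimum sequence separation of contacts.
#' @param mode Selection/classification mode, \code{"aa"} or \code{"pair"}.
#' @param align Alignment parameters, see \code{\link{align_params}}.
#' @param criteria Selection criteria, see
#'   \code{\link{selection_criteria}}.
#' @param denominator Frequency denominator, see
#'   \code{\link{aa_frequencies}}.
#' @param seed Integer seed for any stochastic step.
#' @return List of class \code{"run_config"}.
#' @export
run_config <- function(profile = c("analysis1", "analysis2"),
                       cutoff = NULL, scheme = "all_atom",
                       min_separation = 2, mode = NULL,
                       align = align_params(),
                       criteria = selection_criteria(),
                       denominator = "sharing", seed = 1) {
  profile <- match.arg(profile)
  if (is.null(cutoff)) cutoff <- if (profile == "analysis1") 5 else 6
  if (is.null(mode)) mode <- if (profile == "analysis1") "aa" else "pair"
  structure(list(profile = profile, cutoff = cutoff, scheme = scheme,
                 min_separation = as.integer(min_separation), mode = mode,
                 align = align, criteria = criteria,
                 denominator = denominator, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a flat key-value configuration file
#'
#' Lines of the form \code{key = value} (or \code{key: value}); '#'
#' comments allowed. Recognized keys: profile, cutoff, scheme,
#' min_separation, mode, seed, denominator, matrix, gap_open, gap_extend,
#' and every \code{\link{selection_criteria}} field.
#'
#' @param path Config file path.
#' @param base A \code{run_config} supplying defaults for absent keys.
#' @return A \code{run_config}.
#' @export
read_config <- function(path, base = run_config()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*[=:]\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  get1 <- function(key, default) if (key %in% keys) vals[keys == key][1]
  else default
  num <- function(key, default) as.numeric(get1(key, default))
  cfg <- run_config(
    profile = get1("profile", base$profile),
    cutoff = num("cutoff", base$cutoff),
    scheme = get1("scheme", base$scheme),
    min_separation = num("min_separation", base$min_separation),
    mode = get1("mode", base$mode),
    align = align_params(
      matrix = get1("matrix", base$align$matrix),
      gap_open = num("gap_open", base$align$gap_open),
      gap_extend = num("gap_extend", base$align$gap_extend)),
    criteria = selection_criteria(
      direction = get1("direction", base$criteria$direction),
      min_conservation_count = num("min_conservation_count",
                                   base$criteria$min_conservation_count),
      wild_delta_max = num("wild_delta_max", base$criteria$wild_delta_max),
      candidate_delta_min = num("candidate_delta_min",
                                base$criteria$candidate_delta_min),
      pair_extreme_fraction = num("pair_extreme_fraction",
                                  base$criteria$pair_extreme_fraction),
      betweenness_fraction = num("betweenness_fraction",
                                 base$criteria$betweenness_fraction),
      prefer_non_ligand_contact = as.logical(
        get1("prefer_non_ligand_contact",
             base$criteria$prefer_non_ligand_contact)),
      ligand_contact_cutoff = num("ligand_contact_cutoff",
                                  base$criteria$ligand_contact_cutoff)),
    denominator = get1("denominator", base$denominator),
    seed = num("seed", base$seed))
  cfg
}

.provenance_header <- function(cfg) {
  paste0("#config\tprofile=", cfg$profile, ";cutoff=", cfg$cutoff,
         ";scheme=", cfg$scheme, ";min_separation=", cfg$min_separation,
         ";mode=", cfg$mode, ";package=contactdelta_",
         as.character(utils::packageVersion("contactdelta")))
}
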