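# Qualify residues/contacts as hydrolytic or transglycosidic and classify
# whole enzymes from their contact composition.

#' Qualify a residue from its enrichment factor
#'
#' @param delta Numeric vector of enrichment factors.
#' @return Character vector: \code{"T"} for delta > 0 (transglycosidic),
#'   \code{"H"} for delta < 0 (hydrolytic), \code{"unclassified"} for
#'   delta exactly 0, \code{NA} propagated.
#' @export
qualify_residue <- function(delta) {
  out <- rep(NA_character_, length(delta))
  out[!is.na(delta) & delta > 0] <- "T"
  out[!is.na(delta) & delta < 0] <- "H"
  out[!is.na(delta) & delta == 0] <- "unclassified"
  out
}

#' Qualify a contact from its two endpoint qualifications
#'
#' A contact is transglycosidic when both endpoints are, hydrolytic when
#' both are, unclassified when either endpoint is unclassified, and mixed
#' otherwise.
#'
#' @param q_i,q_j Endpoint qualifications from \code{\link{qualify_residue}}.
#' @return Character vector over \code{"T"}, \code{"H"}, \code{"mixed"},
#'   \code{"unclassified"}.
#' @export
qualify_contact <- function(q_i, q_j) {
  n <- max(length(q_i), length(q_j))
  q_i <- rep_len(q_i, n); q_j <- rep_len(q_j, n)
  out <- rep(NA_character_, n)
  una <- q_i == "unclassified" | q_j == "unclassified"
  out[!is.na(una) & una] <- "unclassified"
  both_t <- q_i == "T" & q_j == "T"
  both_h <- q_i == "H" & q_j == "H"
  out[!is.na(both_t) & both_t] <- "T"
  out[!is.na(both_h) & both_h] <- "H"
  out[is.na(out) & !is.na(q_i) & !is.na(q_j)] <- "mixed"
  out
}

#' Count qualified contacts for one dataset member
#'
#' Walks the member's shared reference contacts, qualifies each either
#' from the two endpoint amino-acid enrichment factors (\code{mode="aa"})
#' or from the sign of the pair enrichment factor of the observed pair
#' (\code{mode="pair"}), and tallies the outcome.
#'
#' @param tab A \code{shared_contact_table}.
#' @param enr An \code{enrichment_tables} object (typically fitted on a
#'   labelled training subset).
#' @param member Member id.
#' @param mode \code{"aa"} or \code{"pair"}.
#' @return One-row data frame: \code{id}, \code{n_T}, \code{n_H},
#'   \code{n_other} (mixed/unclassified/NA), \code{n_not_shared},
#'   \code{n_shared}, \code{truth}. Attribute \code{"degenerate"} is TRUE
#'   when the member shares no contact.
#' @export
count_contacts <- function(tab, enr, member, mode = c("aa", "pair")) {
  mode <- match.arg(mode)
  if (!(member %in% tab$members)) stop("unknown member: ", member)
  st <- tab$status[, member]
  shared <- which(st == "shared")
  n_T <- n_H <- n_other <- 0L
  for (r in shared) {
    i <- tab$contacts[r, 1]; j <- tab$contacts[r, 2]
    ai <- tab$aa_i[r, member]; aj <- tab$aa_j[r, member]
    lab <- if (mode == "aa") {
      if (is.na(ai) || is.na(aj) || ai == "X" || aj == "X") NA_character_
      else qualify_contact(
        qualify_residue(delta_lookup(enr, i, j, "i", ai)),
        qualify_residue(delta_lookup(enr, i, j, "j", aj)))
    } else {
      if (is.na(ai) || is.na(aj) || ai == "X" || aj == "X") NA_character_
      else qualify_residue(delta_pair_lookup(enr, i, j, ai, aj))
    }
    if (is.na(lab) || lab %in% c("mixed", "unclassified"))
      n_other <- n_other + 1L
    else if (lab == "T") n_T <- n_T + 1L
    else n_H <- n_H + 1L
  }
  rec <- data.frame(id = member, n_T = n_T, n_H = n_H, n_other = n_other,
                    n_not_shared = nrow(tab$contacts) - length(shared),
                    n_shared = length(shared),
                    truth = unname(tab$groups[member]),
                    stringsAsFactors = FALSE)
  attr(rec, "degenerate") <- length(shared) == 0
  rec
}

#' Classification records for a set of members
#'
#' @inheritParams count_contacts
#' @param members Member ids; defaults to all members of \code{tab}.
#' @return Data frame, one row per member (see \code{\link{count_contacts}}).
#' @export
classification_records <- function(tab, enr, members = NULL,
                                   mode = c("aa", "pair")) {
  mode <- match.arg(mode)
  if (is.null(members)) members <- tab$members
  do.call(rbind, lapply(members, function(id)
    count_contacts(tab, enr, id, mode)))
}

.normalized_counts <- function(rec) {
  denom <- pmax(rec$n_shared, 1L)
  cbind(h = rec$n_H / denom, t = rec$n_T / denom)
}

#' Fit per-group centroids of normalized contact counts
#'
#' @param records Labelled classification records (truth in H/T).
#' @return List of class \code{"classification_centroids"} with the mean
#'   normalized (n_H, n_T) point of each group.
#' @export
fit_centroids <- function(records) {
  records <- records[records$truth %in% c("H", "T"), , drop = FALSE]
  if (!all(c("H", "T") %in% records$truth))
    stop("need at least one labelled member of each group to fit centroids")
  z <- .normalized_counts(records)
  structure(list(H = colMeans(z[records$truth == "H", , drop = FALSE]),
                 T = colMeans(z[records$truth == "T", , drop = FALSE])),
            class = "classification_centroids")
}

#' Classify enzymes by nearest centroid in normalized count space
#'
#' Each record is placed at (n_H, n_T) normalized by its shared-contact
#' count and assigned the label of the nearer centroid (Euclidean metric);
#' exact ties go to H, the conservative majority class in the datasets
#' this method was designed around. An alternative pure-threshold rule on
#' the normalized transglycosidic count is available.
#'
#' @param records Classification records (any truth labels).
#' @param centroids A \code{classification_centroids} fit.
#' @param rule \code{"centroid"} (default) or \code{"t_threshold"}, which
#'   predicts T when the normalized n_T exceeds the midpoint of the two
#'   centroids' n_T coordinates.
#' @return \code{records} with a \code{predicted} column appended; members
#'   sharing no contact get \code{NA}.
#' @export
classify_enzyme <- function(records, centroids, rule = c("centroid",
                                                         "t_threshold")) {
  rule <- match.arg(rule)
  z <- .normalized_counts(records)
  pred <- character(nrow(records))
  for (k in seq_len(nrow(records))) {
    if (records$n_shared[k] == 0) { pred[k] <- NA_character_; next }
    if (rule == "centroid") {
      dh <- sum((z[k, ] - centroids$H)^2)
      dt <- sum((z[k, ] - centroids$T)^2)
      pred[k] <- if (dt < dh) "T" else "H"
    } else {
      thr <- (centroids$H[["t"]] + centroids$T[["t"]]) / 2
      pred[k] <- if (z[k, "t"] > thr) "T" else "H"
    }
  }
  records$predicted <- pred
  records
}

#' Leave-one-out classification over a labelled dataset
#'
#' For each member, the enrichment tables and centroids are re-fitted with
#' that member's column excluded, and the member is then classified.
#'
#' @param tab A \code{shared_contact_table} whose members are labelled.
#' @param mode \code{"aa"} or \code{"pair"}.
#' @param rule Decision rule, see \code{\link{classify_enzyme}}.
#' @param denominator Frequency denominator, see
#'   \code{\link{aa_frequencies}}.
#' @return Data frame of records with \code{predicted}, plus attribute
#'   \code{"accuracy"}.
#' @export
classify_loo <- function(tab, mode = c("aa", "pair"), rule = "centroid",
                         denominator = "sharing") {
  mode <- match.arg(mode)
  labelled <- tab$members[tab$groups[tab$members] %in% c("H", "T")]
  out <- vector("list", length(labelled))
  for (k in seq_along(labelled)) {
    id <- labelled[k]
    train <- setdiff(labelled, id)
    enr <- full_enrichment_table(tab, members = train,
                                 denominator = denominator)
    train_rec <- classification_records(tab, enr, members = train, mode = mode)
    cent <- fit_centroids(train_rec)
    rec <- classification_records(tab, enr, members = id, mode = mode)
    out[[k]] <- classify_enzyme(rec, cent, rule = rule)
  }
  res <- do.call(rbind, out)
  ok <- !is.na(res$predicted)
  attr(res, "accuracy") <- mean(res$predicted[ok] == res$truth[ok])
  res
}

#' Train-on-one-dataset, classify-another evaluation
#'
#' Enrichment tables and centroids are fitted on the training dataset only;
#' every test structure is then aligned to the same reference, its shared
#' contacts qualified with the training deltas, and classified.
#'
#' @param train_ds A \code{contact_dataset} with labelled members (must
#'   contain the reference).
#' @param test_structures Named list of labelled \code{structure_model}s;
#'   ids must be disjoint from the training ids.
#' @param mode,rule,denominator See \code{\link{classify_loo}}.
#' @param params Alignment parameters for mapping test structures onto the
#'   reference.
#' @return Data frame of test records with \code{predicted}; attribute
#'   \code{"accuracy"}.
#' @export
evaluate_holdout <- function(train_ds, test_structures, mode = c("aa", "pair"),
                             rule = "centroid", denominator = "sharing",
                             params = align_params()) {
  mode <- match.arg(mode)
  overlap <- intersect(names(train_ds$structures), names(test_structures))
  if (length(overlap) > 0)
    stop("train and test ids overlap: ", paste(overlap, collapse = ", "))
  train_tab <- build_shared_table(train_ds)
  enr <- full_enrichment_table(train_tab, denominator = denominator)
  train_rec <- classification_records(train_tab, enr, mode = mode)
  train_rec <- train_rec[train_rec$truth %in% c("H", "T"), , drop = FALSE]
  cent <- fit_centroids(train_rec)

  # test members ride on the training reference: one combined dataset whose
  # frequency computations are restricted to the training members
  all_structs <- c(train_ds$structures, test_structures)
  ds <- prepare_dataset(all_structs, train_ds$ref_id,
                        cutoff = train_ds$cutoff, scheme = train_ds$scheme,
                        min_separation = train_ds$min_separation,
                        alignments = train_ds$maps, params = params)
  tab <- build_shared_table(ds)
  enr_train_only <- full_enrichment_table(
    tab, members = names(train_ds$structures), denominator = denominator)
  rec <- classification_records(tab, enr_train_only,
                                members = names(test_structures), mode = mode)
  res <- classify_enzyme(rec, cent, rule = rule)
  ok <- !is.na(res$predicted) & res$truth %in% c("H", "T")
  attr(res, "accuracy") <- mean(res$predicted[ok] == res$truth[ok])
  res
}

#' Scatter plot of classification records
#'
#' Normalized hydrolytic count against normalized transglycosidic count,
#' coloured by truth label (red hydrolases, green transglycosidases, grey
#' unknown).
#'
#' @param records Classification records.
#' @param file Optional PNG path; plots to the active device when NULL.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, the plotted coordinates.
#' @export
plot_classification <- function(records, file = NULL, ...) {
  z <- .normalized_counts(records)
  col <- ifelse(records$truth == "H", "red3",
                ifelse(records$truth == "T", "green4", "grey50"))
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(z[, "h"], z[, "t"], col = col, pch = 19,
                 xlab = "hydrolytic contacts / shared contacts",
                 ylab = "transglycosidic contacts / shared contacts", ...)
  graphics::legend("topright", legend = c("H", "T"),
                   col = c("red3", "green4"), pch = 19, bty = "n")
  invisible(data.frame(id = records$id, h = z[, "h"], t = z[, "t"]))
}
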