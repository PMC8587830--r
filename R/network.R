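# Alpha-carbon contact network and betweenness centrality.
#
# The contact map is turned into an undirected, unweighted graph with one
# node per polymer residue (located at its alpha-carbon) and one edge per
# residue-residue contact. The betweenness centrality of node x is the sum
# over unordered node pairs {u, v}, u != x != v, of the fraction of
# shortest u-v paths that pass through x; disconnected pairs contribute 0;
# values are left unnormalized.

#' Build the residue contact graph
#'
#' @param cm A \code{contact_map}.
#' @param s The matching \code{structure_model}; every residue must have a
#'   CA atom.
#' @return Object of class \code{"contact_graph"}: \code{n_nodes},
#'   \code{edges} (m x 2), \code{coords} (CA coordinates, n x 3),
#'   \code{degree}, \code{structure_id}.
#' @export
build_graph <- function(cm, s) {
  stopifnot(inherits(cm, "contact_map"), inherits(s, "structure_model"))
  n <- cm$n_res
  ca <- s$atoms[s$atoms$elety == "CA", , drop = FALSE]
  missing_ca <- setdiff(seq_len(n), unique(ca$res_index))
  if (length(missing_ca) > 0)
    stop("residues without CA atom: ",
         paste(utils::head(missing_ca, 10), collapse = ", "))
  ca <- ca[!duplicated(ca$res_index), , drop = FALSE]
  ca <- ca[order(ca$res_index), , drop = FALSE]
  deg <- tabulate(c(cm$contacts[, 1], cm$contacts[, 2]), nbins = n)
  structure(list(n_nodes = n, edges = cm$contacts,
                 coords = as.matrix(ca[, c("x", "y", "z")]),
                 degree = deg, structure_id = cm$structure_id),
            class = "contact_graph")
}

#' @export
print.contact_graph <- function(x, ...) {
  cat("contact_graph '", x$structure_id, "': ", x$n_nodes, " nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

.adjacency_list <- function(n, edges) {
  adj <- vector("list", n)
  for (k in seq_len(nrow(edges))) {
    i <- edges[k, 1]; j <- edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

#' Betweenness centrality of every node
#'
#' Unnormalized shortest-path betweenness over unordered pairs with
#' endpoints excluded, computed with the Brandes accumulation algorithm
#' (one BFS per source plus dependency back-propagation).
#'
#' @param g A \code{contact_graph}, or a list with \code{n_nodes} and
#'   \code{edges}.
#' @return Data frame of class \code{"betweenness_result"}: \code{node},
#'   \code{degree}, \code{bc}, \code{percentile} (percentile rank of bc in
#'   [0, 100]).
#' @export
betweenness_centrality <- function(g) {
  n <- g$n_nodes
  edges <- g$edges
  bc <- numeric(n)
  if (n > 0 && nrow(edges) > 0) {
    adj <- .adjacency_list(n, edges)
    for (src in seq_len(n)) {
      # BFS from src: sigma = shortest-path counts, preds = predecessor lists
      sigma <- numeric(n); sigma[src] <- 1
      dist <- rep(-1L, n); dist[src] <- 0L
      preds <- vector("list", n)
      order_visited <- integer(0)
      queue <- c(src); qh <- 1L
      while (qh <= length(queue)) {
        v <- queue[qh]; qh <- qh + 1L
        order_visited <- c(order_visited, v)
        for (w in adj[[v]]) {
          if (dist[w] < 0) {
            dist[w] <- dist[v] + 1L
            queue <- c(queue, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      # dependency accumulation in reverse BFS order
      delta <- numeric(n)
      for (w in rev(order_visited)) {
        for (v in preds[[w]]) {
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
        }
        if (w != src) bc[w] <- bc[w] + delta[w]
      }
    }
    bc <- bc / 2  # each unordered pair counted from both endpoints
  }
  deg <- if (!is.null(g$degree)) g$degree
  else tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  pct <- if (n > 1) 100 * (rank(bc, ties.method = "average") - 1) / (n - 1)
  else rep(100, n)
  out <- data.frame(node = seq_len(n), degree = deg, bc = bc,
                    percentile = pct)
  class(out) <- c("betweenness_result", class(out))
  out
}

#' Nodes in the top betweenness fraction
#'
#' Returns the ceiling(fraction * n) highest-betweenness nodes; nodes tied
#' with the boundary value are all included, so the set may be larger than
#' the ceiling count.
#'
#' @param result A \code{betweenness_result}.
#' @param fraction Fraction in (0, 1]; the analyses here use 0.10
#'   (pair-level screening) and 0.20 (site selection), both exposed as
#'   criteria knobs.
#' @return Integer vector of node indices, ascending.
#' @export
top_percentile <- function(result, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- nrow(result)
  k <- ceiling(fraction * n)
  ord <- order(-result$bc)
  boundary <- result$bc[ord[k]]
  sort(result$node[result$bc >= boundary])
}

#' Write the per-node network table as TSV
#'
#' @param result A \code{betweenness_result}.
#' @param s Matching \code{structure_model} (for author residue numbers).
#' @param path Output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_network_table <- function(result, s, path) {
  out <- data.frame(node = result$node,
                    resno = s$residues$resno[result$node],
                    aa = s$residues$aa[result$node],
                    degree = result$degree, bc = result$bc,
                    percentile = result$percentile)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
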