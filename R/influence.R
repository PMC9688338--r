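# Range-normalize a vector to [1, 100]; constant vectors map to 1 so that
# downstream products never vanish and carry no spurious spread.
range_normalize_1_100 <- function(x) {
  rng <- range(x)
  if (diff(rng) == 0) return(rep(1, length(x)))
  1 + 99 * (x - rng[1L]) / (rng[2L] - rng[1L])
}

# Node h-index on a binary graph: max h such that the node has >= h
# neighbours of degree >= h.
node_h_index <- function(adj) {
  k <- rowSums(adj)
  vapply(seq_len(nrow(adj)), function(i) {
    nb <- which(adj[i, ] > 0)
    if (length(nb) == 0L) return(0)
    degs <- sort(k[nb], decreasing = TRUE)
    sum(degs >= seq_along(degs))
  }, numeric(1))
}

#' Six centrality measures for influence analysis
#'
#' Computes, per node: degree centrality (DC), neighborhood connectivity
#' (NC, mean degree of neighbours), ClusterRank
#' (CR = 10^(-c_i) * sum over neighbours of (k_j + 1), with c_i the local
#' clustering coefficient), local H-index (LH = own h-index plus the sum of
#' the neighbours' h-indices), betweenness centrality (BC), and collective
#' influence (CI = (k_i - 1) * sum of (k_j - 1) over nodes exactly at
#' graph distance `ci_radius`).  All measures except BC are evaluated on the
#' binarized support graph (edge iff weight > 0); BC uses weighted shortest
#' paths with lengths 1/w so strong connections are short.  Each measure is
#' then range-normalized to [1, 100] (constant measures map to 1).
#'
#' @param W a `weighted_network` or non-negative symmetric matrix with at
#'   least 2 nodes.
#' @param ci_radius frontier distance of collective influence.
#' @param mode `"binary"` (default) binarizes the support for all measures
#'   except BC; `"weighted"` additionally feeds the weights to the degree
#'   (strength) and neighborhood terms.
#' @return Data frame of class `centrality_table`: raw columns `DC`, `NC`,
#'   `CR`, `LH`, `BC`, `CI` and primed (normalized) counterparts.
#' @export
centrality_suite <- function(W, ci_radius = 2L, mode = c("binary", "weighted")) {
  mode <- match.arg(mode)
  W <- unclass(as.matrix(W))
  n <- nrow(W)
  if (n < 2L) stop("need at least 2 nodes")
  if (any(W < 0)) stop("weights must be non-negative")
  A <- (W > 0) * 1
  diag(A) <- 0
  k <- rowSums(A)
  DC <- if (mode == "binary") k else rowSums(W)
  NC <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) == 0L) 0 else mean(k[nb])
  }, numeric(1))
  gb <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  ci_loc <- igraph::transitivity(gb, type = "localundirected",
                                 isolates = "zero")
  ci_loc[is.na(ci_loc)] <- 0
  CR <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    if (length(nb) == 0L) return(0)
    10^(-ci_loc[i]) * sum(k[nb] + 1)
  }, numeric(1))
  h <- node_h_index(A)
  LH <- vapply(seq_len(n), function(i) {
    nb <- which(A[i, ] > 0)
    h[i] + sum(h[nb])
  }, numeric(1))
  gw <- as_igraph_weighted(W)
  BC <- igraph::betweenness(gw, weights = igraph::E(gw)$length)
  dmat <- igraph::distances(gb)
  CI <- vapply(seq_len(n), function(i) {
    frontier <- which(dmat[i, ] == ci_radius)
    (k[i] - 1) * sum(k[frontier] - 1)
  }, numeric(1))
  CI[k == 0] <- 0
  tab <- data.frame(node = seq_len(n), DC = DC, NC = NC, CR = CR,
                    LH = LH, BC = BC, CI = CI)
  for (col in c("DC", "NC", "CR", "LH", "BC", "CI"))
    tab[[paste0(col, "_p")]] <- range_normalize_1_100(tab[[col]])
  class(tab) <- c("centrality_table", "data.frame")
  tab
}

#' Integrated value of influence
#'
#' Fuses the normalized centralities into the spreading score
#' `(NC' + CR') * (BC' + CI')`, the hubness score `DC' + LH'`, and their
#' product, the IVI, which is then range-normalized to [1, 100].  Nodes with
#' IVI strictly above the mean plus one standard deviation form the
#' influential set.
#'
#' @param tab a `centrality_table` from [centrality_suite()].
#' @param node_labels optional node labels.
#' @return List of class `ivi_result`: `table` (node, spreading, hubness,
#'   IVI, influential flag), `influential` (node indices), `threshold`.
#' @export
integrated_value_of_influence <- function(tab, node_labels = NULL) {
  stopifnot(inherits(tab, "centrality_table"))
  spreading <- (tab$NC_p + tab$CR_p) * (tab$BC_p + tab$CI_p)
  hubness <- tab$DC_p + tab$LH_p
  ivi <- range_normalize_1_100(hubness * spreading)
  thr <- mean(ivi) + stats::sd(ivi)
  infl <- which(ivi > thr)
  out <- data.frame(node = tab$node, spreading = spreading,
                    hubness = hubness, IVI = ivi, influential = ivi > thr)
  if (!is.null(node_labels)) out$label <- node_labels[tab$node]
  structure(list(table = out, influential = infl, threshold = thr,
                 node_labels = node_labels),
            class = "ivi_result")
}

#' @export
print.ivi_result <- function(x, ...) {
  cat(sprintf("<ivi_result> %d node(s); %d influential (IVI > mean + SD = %.2f)\n",
              nrow(x$table), length(x$influential), x$threshold))
  invisible(x)
}

#' Influential nodes of an IVI result
#'
#' Nodes whose IVI strictly exceeds the mean plus one standard deviation.
#'
#' @param res an `ivi_result`.
#' @return Node labels when available, otherwise node indices.
#' @export
influential_nodes <- function(res) {
  stopifnot(inherits(res, "ivi_result"))
  if (!is.null(res$node_labels)) res$node_labels[res$influential]
  else res$influential
}
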