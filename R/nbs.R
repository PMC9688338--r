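# Canonicalize paired-connectivity input to a subjects x edges matrix.
# Accepts subjects x nodes x nodes arrays (upper triangle taken) or an
# already-flat subjects x edges matrix.  Returns list(mat, edge_i, edge_j, n_nodes).
as_edge_matrix <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L) {
    n <- dim(x)[2L]
    ut <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    m <- apply(x, 1L, function(mm) mm[upper.tri(mm)])
    # apply returns edges x subjects for > 1 edge, a plain vector for 1 edge
    m <- if (is.null(dim(m))) matrix(m, ncol = 1L) else t(m)
    list(mat = m, edge_i = ut[, 1L], edge_j = ut[, 2L], n_nodes = n)
  } else {
    m <- as.matrix(x)
    list(mat = m, edge_i = NULL, edge_j = NULL, n_nodes = NA_integer_)
  }
}

#' Edge-wise paired t statistics
#'
#' Paired t on per-subject differences `A - B` for every edge.  Edges with
#' zero-variance differences get t = 0 with a warning.
#'
#' @param tensorA,tensorB subjects x edges matrices, or subjects x nodes x
#'   nodes arrays (upper triangles are used); same subjects, same order.
#' @return If array input, a nodes x nodes symmetric matrix of t values;
#'   otherwise a vector of per-edge t values.
#' @export
paired_t_matrix <- function(tensorA, tensorB) {
  a <- as_edge_matrix(tensorA); b <- as_edge_matrix(tensorB)
  if (!all(dim(a$mat) == dim(b$mat)))
    stop("subject/edge mismatch between the two conditions")
  n <- nrow(a$mat)
  if (n < 2L) stop("need at least 2 subjects")
  D <- a$mat - b$mat
  m <- colMeans(D)
  s2 <- (colSums(D^2) - n * m^2) / (n - 1)
  s2[s2 < 0] <- 0
  tval <- ifelse(s2 == 0, 0, m / sqrt(s2 / n))
  if (any(s2 == 0 & m != 0))
    warning("zero-variance differences at some edges; t set to 0")
  if (!is.null(a$edge_i)) {
    out <- matrix(0, a$n_nodes, a$n_nodes)
    out[cbind(a$edge_i, a$edge_j)] <- tval
    out + t(out)
  } else tval
}

# Largest component extent (edge count) of the graph on selected edges.
max_component_extent <- function(sel, ei, ej, n_nodes) {
  if (!any(sel)) return(0L)
  g <- igraph::graph_from_edgelist(cbind(ei[sel], ej[sel]), directed = FALSE)
  memb <- igraph::components(g)$membership
  max(tabulate(memb[ei[sel]]))
}

#' Paired network-based statistic
#'
#' Cluster-based permutation inference on the graph of suprathreshold paired
#' t statistics: (1) edges with t above the primary threshold `T` form the
#' suprathreshold graph; (2) its connected components are enumerated, each
#' scored by extent (edge count); (3) the null distribution of the maximum
#' component extent is built from `n_perm` random within-subject condition
#' flips; (4) each observed component receives the family-wise-corrected
#' p-value `(1 + #,\{null max >= observed\}) / (1 + n_perm)`.
#'
#' @param tensorA,tensorB subjects x nodes x nodes connectivity arrays (or a
#'   connectivity_tensor sliced to one frequency), same subjects.
#' @param T primary t threshold (> 0); the study design uses T = 1 for the
#'   main analysis and T = 3.5 for the strict low-density variant.
#' @param n_perm number of permutations.
#' @param seed integer seed for the permutation draw.
#' @param tail `"A>B"` tests for edges larger in A; `"B>A"` the reverse.
#' @return Object of class `nbs_result`: `t_matrix`, `threshold`,
#'   `components` (list of edge data frames), `component_p`, `null_max`,
#'   `n_perm`, `seed`, `tail`.
#' @export
nbs_paired <- function(tensorA, tensorB, T = 1, n_perm = 5000L, seed = 1L,
                       tail = c("A>B", "B>A")) {
  tail <- match.arg(tail)
  if (T <= 0) stop("threshold T must be positive")
  if (n_perm < 1) stop("n_perm must be >= 1")
  a <- as_edge_matrix(tensorA); b <- as_edge_matrix(tensorB)
  if (is.null(a$edge_i)) stop("nbs_paired needs nodes x nodes array input")
  if (!all(dim(a$mat) == dim(b$mat)))
    stop("subject/edge mismatch between the two conditions")
  n <- nrow(a$mat); n_e <- ncol(a$mat)
  D <- a$mat - b$mat
  if (tail == "B>A") D <- -D
  ss <- colSums(D^2)
  t_of <- function(Dm) {
    m <- colMeans(Dm)
    s2 <- (ss - n * m^2) / (n - 1)
    s2[s2 < 1e-300] <- 1e-300
    m / sqrt(s2 / n)
  }
  t_obs <- t_of(D)
  sel_obs <- t_obs > T
  # observed components
  components <- list(); comp_sizes <- integer(0)
  if (any(sel_obs)) {
    g <- igraph::graph_from_edgelist(
      cbind(a$edge_i[sel_obs], a$edge_j[sel_obs]), directed = FALSE)
    memb <- igraph::components(g)$membership
    ecomp <- memb[a$edge_i[sel_obs]]
    for (cid in sort(unique(ecomp))) {
      idx <- which(sel_obs)[ecomp == cid]
      components[[length(components) + 1L]] <-
        data.frame(node_i = a$edge_i[idx], node_j = a$edge_j[idx],
                   t = t_obs[idx])
      comp_sizes <- c(comp_sizes, length(idx))
    }
  }
  # permutation null of the maximum component extent
  set.seed(seed)
  null_max <- integer(n_perm)
  chunk <- 500L
  done <- 0L
  while (done < n_perm) {
    k <- min(chunk, n_perm - done)
    signs <- matrix(sample(c(-1, 1), k * n, replace = TRUE), nrow = k)
    M <- (signs %*% D) / n
    S2 <- sweep(-n * M^2, 2L, ss, `+`) / (n - 1)
    S2[S2 < 1e-300] <- 1e-300
    Tm <- M / sqrt(S2 / n)
    for (p in seq_len(k))
      null_max[done + p] <- max_component_extent(Tm[p, ] > T,
                                                 a$edge_i, a$edge_j,
                                                 a$n_nodes)
    done <- done + k
  }
  component_p <- vapply(comp_sizes, function(sz)
    (1 + sum(null_max >= sz)) / (1 + n_perm), numeric(1))
  t_mat <- matrix(0, a$n_nodes, a$n_nodes)
  t_mat[cbind(a$edge_i, a$edge_j)] <- t_obs
  t_mat <- t_mat + t(t_mat)
  structure(list(t_matrix = t_mat, threshold = T, components = components,
                 component_sizes = comp_sizes, component_p = component_p,
                 null_max = null_max, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), tail = tail),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("<nbs_result> T = %g, %d permutation(s), tail %s\n",
              x$threshold, x$n_perm, x$tail))
  if (length(x$components) == 0L) cat("  no suprathreshold components\n")
  else for (i in seq_along(x$components))
    cat(sprintf("  component %d: %d edge(s), p = %.4g\n", i,
                x$component_sizes[i], x$component_p[i]))
  invisible(x)
}

#' Binary adjacency of significant components
#'
#' A 1 marks an edge belonging to any component whose family-wise-corrected
#' p-value is below `alpha`; all other entries are 0.
#'
#' @param res an `nbs_result`.
#' @param alpha significance level.
#' @return Symmetric 0/1 matrix with zero diagonal.
#' @export
significant_adjacency <- function(res, alpha = 0.05) {
  stopifnot(inherits(res, "nbs_result"))
  n <- nrow(res$t_matrix)
  adj <- matrix(0L, n, n)
  for (i in seq_along(res$components)) {
    if (res$component_p[i] < alpha) {
      e <- res$components[[i]]
      adj[cbind(e$node_i, e$node_j)] <- 1L
      adj[cbind(e$node_j, e$node_i)] <- 1L
    }
  }
  adj
}

#' Weighted modified connectivity matrix
#'
#' Replaces each significant marker 1 in the adjacency with the magnitude of
#' the corresponding connectivity value; non-significant edges stay zero.
#' Graph analyses downstream require non-negative weights, hence the absolute
#' value of the (signed) imaginary coherence.
#'
#' @param adj symmetric 0/1 adjacency matrix.
#' @param conn nodes x nodes connectivity matrix, or a `connectivity_tensor`
#'   together with `subject` and `frequency` selecting one slice.
#' @param subject,frequency tensor indices (frequency in Hz) when `conn` is a
#'   4-d connectivity tensor.
#' @param node_labels optional labels attached to the result.
#' @return Object of class `weighted_network`: non-negative symmetric weight
#'   matrix with zero diagonal.
#' @export
apply_adjacency_weights <- function(adj, conn, subject = NULL,
                                    frequency = NULL, node_labels = NULL) {
  if (inherits(conn, "connectivity_tensor")) {
    if (is.null(subject) || is.null(frequency))
      stop("subject and frequency are required with a connectivity tensor")
    fidx <- match(frequency, attr(conn, "freqs"))
    if (is.na(fidx)) stop("frequency not present in the tensor")
    if (is.null(node_labels)) node_labels <- attr(conn, "node_labels")
    conn <- conn[subject, fidx, , ]
  }
  conn <- as.matrix(conn)
  if (!all(dim(adj) == dim(conn))) stop("node set mismatch")
  w <- abs(conn) * (adj != 0)
  w <- (w + t(w)) / 2
  diag(w) <- 0
  weighted_network(w, node_labels)
}

#' Weighted network container
#'
#' @param w symmetric non-negative weight matrix, zero diagonal.
#' @param node_labels optional node labels.
#' @return The matrix with class `weighted_network` and a `node_labels`
#'   attribute.
#' @export
weighted_network <- function(w, node_labels = NULL) {
  w <- as.matrix(w)
  if (any(w < 0)) stop("weights must be non-negative")
  if (max(abs(w - t(w))) > 1e-12 * max(1, max(abs(w))))
    stop("weight matrix must be symmetric")
  diag(w) <- 0
  if (!is.null(node_labels) && length(node_labels) != nrow(w))
    stop("node_labels length mismatch")
  structure(w, node_labels = node_labels, class = "weighted_network")
}

#' Export an NBS result as an edge list
#'
#' @param res an `nbs_result`.
#' @return Data frame with columns node_i, node_j, t, component, p.
#' @export
nbs_edge_list <- function(res) {
  stopifnot(inherits(res, "nbs_result"))
  if (length(res$components) == 0L)
    return(data.frame(node_i = integer(0), node_j = integer(0),
                      t = numeric(0), component = integer(0),
                      p = numeric(0)))
  do.call(rbind, lapply(seq_along(res$components), function(i) {
    e <- res$components[[i]]
    data.frame(node_i = e$node_i, node_j = e$node_j, t = e$t,
               component = i, p = res$component_p[i])
  }))
}
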