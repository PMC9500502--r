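as_weight_matrix <- function(W) {
  if (inherits(W, "band_matrix")) W$values else as.matrix(W)
}

# fast undirected igraph construction from the upper triangle of a matrix,
# avoiding graph_from_adjacency_matrix's symmetry re-checks in hot loops
graph_from_upper <- function(mask, weights = NULL) {
  M <- nrow(mask)
  idx <- which(mask & upper.tri(mask))
  i <- ((idx - 1L) %% M) + 1L
  j <- ((idx - 1L) %/% M) + 1L
  g <- igraph::make_graph(rbind(i, j), n = M, directed = FALSE)
  if (!is.null(weights)) igraph::E(g)$weight <- weights[idx]
  g
}

#' Symmetrize a directed connectivity matrix
#'
#' `w_ij <- max(w_ij, w_ji)`, diagonal zeroed. Used to fold directed DTF
#' matrices into the undirected weights required by MCC binarization and the
#' global graph metrics; the max preserves a strong influence in either
#' direction.
#'
#' @param W a `band_matrix` or square non-negative matrix.
#' @return Same type as the input, symmetric with zero diagonal.
#' @export
symmetrize <- function(W) {
  v <- as_weight_matrix(W)
  stopifnot(nrow(v) == ncol(v), all(v >= 0))
  s <- pmax(v, t(v))
  diag(s) <- 0
  if (inherits(W, "band_matrix")) {
    W$values <- s; W$directed <- FALSE; W
  } else s
}

#' Minimum-connected-component (MCC) binarization
#'
#' Thresholds a weighted undirected network at the *largest* cutoff `t` for
#' which the graph with edge set `{w_ij >= t}` still spans all nodes in one
#' connected component — the bottleneck weight of the maximum spanning tree.
#' This keeps only the strongest connections compatible with a connected
#' network, replacing any arbitrary manual threshold. Ties at the threshold
#' weight are all retained.
#'
#' @param W a `band_matrix` or symmetric non-negative matrix with zero
#'   diagonal (symmetrize directed matrices first; see [symmetrize()]).
#' @return Object of class `binary_network`: logical `adjacency`,
#'   `mcc_threshold`, `n_edges`, plus the source `measure`/`band` when the
#'   input was a `band_matrix`.
#' @export
mcc_binarize <- function(W) {
  v <- as_weight_matrix(W)
  M <- nrow(v)
  stopifnot(M == ncol(v), all(v >= 0))
  if (max(abs(v - t(v))) > 1e-12 * max(1, max(v)))
    stop("weight matrix must be symmetric; use symmetrize() first")
  v <- (v + t(v)) / 2
  diag(v) <- 0
  deg <- rowSums(v > 0)
  if (any(deg == 0)) {
    lab <- rownames(v)
    nm <- if (!is.null(lab)) lab[which(deg == 0)[1]]
      else as.character(which(deg == 0)[1])
    stop(sprintf("node %s has no positive-weight edge: isolated at every threshold", nm))
  }
  g <- graph_from_upper(v > 0, v)
  if (!igraph::is_connected(g))
    stop("positive-weight graph is disconnected: no threshold yields a connected network")
  mstg <- igraph::mst(g, weights = -igraph::E(g)$weight)
  thr <- min(igraph::E(mstg)$weight)
  A <- v >= thr
  diag(A) <- FALSE
  structure(list(adjacency = A, mcc_threshold = thr,
                 n_edges = sum(A) / 2,
                 measure = if (inherits(W, "band_matrix")) W$measure else NA,
                 band = if (inherits(W, "band_matrix")) W$band else NA,
                 labels = rownames(v)),
            class = "binary_network")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges, MCC threshold %.4g (%s/%s)\n",
              nrow(x$adjacency), x$n_edges, x$mcc_threshold,
              x$measure, x$band))
  invisible(x)
}

as_binary_graph <- function(G) {
  A <- if (inherits(G, "binary_network")) G$adjacency else as.matrix(G) != 0
  g <- graph_from_upper(A | t(A))
  if (!igraph::is_connected(g)) stop("graph is disconnected")
  g
}

#' Global graph metrics
#'
#' Three global metrics of a connected binary network, on unweighted
#' (hop-count) shortest paths:
#' * `net_diameter` — the maximum eccentricity, i.e. the greatest
#'   shortest-path distance between any pair of vertices;
#' * `global_efficiency` — `1/(N(N-1)) * sum_{i != j} 1/d_ij`, the mean
#'   inverse shortest-path length over ordered pairs;
#' * `net_transitivity` — `3 x triangles / connected triples`
#'   (equivalently `trace(A^3) / sum_i k_i (k_i - 1)`); a graph with no
#'   connected triple returns 0 with a warning.
#'
#' @param G a `binary_network` or boolean adjacency matrix (must be
#'   connected).
#' @return A single numeric value.
#' @export
net_diameter <- function(G) {
  as.integer(igraph::diameter(as_binary_graph(G), directed = FALSE,
                              unconnected = FALSE))
}

#' @rdname net_diameter
#' @export
global_efficiency <- function(G) {
  igraph::global_efficiency(as_binary_graph(G), directed = FALSE)
}

#' @rdname net_diameter
#' @export
net_transitivity <- function(G) {
  tr <- igraph::transitivity(as_binary_graph(G), type = "global")
  if (is.nan(tr)) {
    warning("no connected triple: transitivity defined as 0")
    tr <- 0
  }
  tr
}

#' Graph metrics for one subject's band matrices
#'
#' For every (measure, band) weight matrix: symmetrize if directed, apply
#' MCC binarization, and compute the three global metrics.
#'
#' @param band_list list of `band_matrix` objects (e.g. concatenated
#'   [band_average()] output for DTF and iCoh).
#' @param subject,group identifiers copied into the output rows.
#' @return Tidy data frame: subject, group, measure, band, diameter,
#'   global_efficiency, transitivity, mcc_threshold, n_edges.
#' @export
subject_metrics <- function(band_list, subject = NA_character_,
                            group = NA_character_) {
  n <- length(band_list)
  measure <- band <- character(n)
  diam <- nedge <- integer(n)
  eff <- trans <- thr <- numeric(n)
  for (k in seq_len(n)) {
    bm <- band_list[[k]]
    stopifnot(inherits(bm, "band_matrix"))
    w <- if (isTRUE(bm$directed)) symmetrize(bm) else bm
    bn <- mcc_binarize(w)
    g <- graph_from_upper(bn$adjacency)    # one graph for all three metrics
    measure[k] <- bm$measure; band[k] <- bm$band
    diam[k] <- as.integer(igraph::diameter(g, directed = FALSE,
                                           unconnected = FALSE))
    eff[k] <- igraph::global_efficiency(g, directed = FALSE)
    tr <- igraph::transitivity(g, type = "global")
    trans[k] <- if (is.nan(tr)) 0 else tr
    thr[k] <- bn$mcc_threshold; nedge[k] <- bn$n_edges
  }
  data.frame(subject = subject, group = group, measure = measure,
             band = band, diameter = diam, global_efficiency = eff,
             transitivity = trans, mcc_threshold = thr, n_edges = nedge)
}
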