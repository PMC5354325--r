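# Fisher-z correlation matrices and density-thresholded weighted graphs.

#' Fisher-z correlation matrix from node time series
#'
#' Pearson correlation of every node pair, variance-stabilized with Fisher's
#' formula `z = atanh(r)`. Negative edges can be excluded (set to zero),
#' as is standard after global-signal regression.
#'
#' @param ts frames x nodes matrix, or a `netsel_clean_ts`.
#' @param drop_negatives logical; zero out negative entries.
#' @return A `netsel_zmatrix`: `z` (symmetric node x node matrix, zero
#'   diagonal), `node_id`, `negatives_removed`.
#' @export
correlation_zmatrix <- function(ts, drop_negatives = TRUE) {
  if (inherits(ts, "netsel_clean_ts")) ts <- ts$series
  ts <- as.matrix(ts)
  if (nrow(ts) < 3) stop("need at least 3 frames")
  sds <- apply(ts, 2L, stats::sd)
  if (any(sds == 0))
    stop("zero-variance node(s): ",
         paste(colnames(ts)[sds == 0], collapse = ", "))
  r <- stats::cor(ts)
  diag(r) <- 0
  if (any(abs(r) >= 1 - 1e-12)) {
    bad <- which(abs(r) >= 1 - 1e-12, arr.ind = TRUE)[1, ]
    stop(sprintf("|r| = 1 between nodes %s and %s; Fisher z diverges",
                 colnames(ts)[bad[1]], colnames(ts)[bad[2]]))
  }
  z <- atanh(r)
  if (drop_negatives) z[z < 0] <- 0
  zmatrix(z, colnames(ts), negatives_removed = drop_negatives)
}

#' Construct a z-matrix object from a matrix of values
#'
#' @param z symmetric node x node matrix of Fisher-z values (diagonal ignored).
#' @param node_id node identifiers; defaults to the matrix dimnames.
#' @param negatives_removed whether negative entries have been excluded.
#' @return A `netsel_zmatrix`.
#' @export
zmatrix <- function(z, node_id = rownames(z), negatives_removed = FALSE) {
  z <- as.matrix(z)
  if (nrow(z) != ncol(z)) stop("z must be square")
  if (max(abs(z - t(z))) > 1e-12) stop("z must be symmetric")
  if (is.null(node_id)) node_id <- sprintf("n%03d", seq_len(nrow(z)))
  diag(z) <- 0
  if (negatives_removed && any(z < 0))
    stop("negatives_removed is set but negative entries remain")
  dimnames(z) <- list(node_id, node_id)
  structure(list(z = z, node_id = node_id,
                 negatives_removed = negatives_removed),
            class = "netsel_zmatrix")
}

#' Mean group z-matrix
#'
#' Entrywise mean of participant z-matrices (averaging z, not r), with
#' negative entries excluded from the mean matrix afterwards.
#'
#' @param z_list list of `netsel_zmatrix` objects with identical node sets.
#' @param drop_negatives exclude negative entries of the mean matrix.
#' @return A `netsel_zmatrix`.
#' @export
mean_zmatrix <- function(z_list, drop_negatives = TRUE) {
  stopifnot(length(z_list) >= 1)
  ids <- z_list[[1]]$node_id
  zm <- Reduce(`+`, lapply(z_list, function(x) {
    stopifnot(identical(x$node_id, ids))
    x$z
  })) / length(z_list)
  if (drop_negatives) zm[zm < 0] <- 0
  zmatrix(zm, ids, negatives_removed = drop_negatives)
}

# canonical edge table of the upper triangle, ordered for deterministic
# thresholding: decreasing weight, ties by (i, j) lexicographic order
edge_table <- function(zm) {
  n <- length(zm$node_id)
  ut <- which(upper.tri(zm$z))
  j <- ((ut - 1L) %/% n) + 1L
  i <- ((ut - 1L) %% n) + 1L
  w <- zm$z[ut]
  pos <- w > 0
  df <- data.frame(i = i[pos], j = j[pos], w = w[pos])
  df[order(-df$w, df$i, df$j), , drop = FALSE]
}

#' Threshold a z-matrix at a target edge density
#'
#' Retains the `round(density * N * (N - 1) / 2)` strongest edges (round half
#' up) with their weights; the graph stays weighted. Ties at the cutoff are
#' broken by lexicographic (i, j) node order so the retained set is
#' deterministic, and thresholds are nested: the edge set at a lower density
#' is a subset of the edge set at any higher density. If fewer positive edges
#' exist than requested, all positive edges are kept with a warning and the
#' achieved density is recorded.
#'
#' @param zm a `netsel_zmatrix` with negatives removed.
#' @param density target proportion of possible edges, in (0, 1\].
#' @return A `netsel_graph`: `edges` (data.frame i, j, w with integer node
#'   indices), `node_id`, `density` (requested), `achieved_density`.
#' @export
threshold_density <- function(zm, density) {
  stopifnot(inherits(zm, "netsel_zmatrix"))
  if (!zm$negatives_removed)
    stop("remove negative edges before density thresholding")
  if (!(density > 0 && density <= 1)) stop("density must be in (0, 1]")
  n <- length(zm$node_id)
  m_poss <- n * (n - 1) / 2
  k <- floor(density * m_poss + 0.5)  # round half up
  et <- edge_table(zm)
  if (nrow(et) < k) {
    warning(sprintf(
      "only %d positive edges available for %d requested; keeping all",
      nrow(et), k))
    k <- nrow(et)
  }
  edges <- et[seq_len(k), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, node_id = zm$node_id, density = density,
                 achieved_density = k / m_poss),
            class = "netsel_graph")
}

#' Weighted node strength
#'
#' Total retained edge weight incident to each node.
#'
#' @param graph a `netsel_graph`.
#' @return Named numeric vector over all nodes (0 for isolated nodes).
#' @export
node_strength <- function(graph) {
  stopifnot(inherits(graph, "netsel_graph"))
  n <- length(graph$node_id)
  s <- numeric(n)
  if (nrow(graph$edges)) {
    inc <- c(graph$edges$i, graph$edges$j)
    w <- rep(graph$edges$w, 2L)
    agg <- tapply(w, inc, sum)
    s[as.integer(names(agg))] <- agg
  }
  stats::setNames(s, graph$node_id)
}
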