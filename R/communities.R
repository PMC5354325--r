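# Community detection, reference-label matching, and bootstrap consensus
# assignment across edge densities.

#' Detect communities on a weighted graph
#'
#' Runs a map-equation-minimizing community detection (Infomap, via igraph)
#' on the thresholded weighted graph. Isolated nodes become singleton
#' communities. Given the same seed the result is deterministic.
#'
#' @param graph a `netsel_graph` from [threshold_density()].
#' @param seed integer seed for the stochastic optimizer (optional; if NULL
#'   the current RNG state is used).
#' @param method `"infomap"` (default) or `"louvain"`; the backend is
#'   pluggable behind this argument.
#' @param nb_trials Infomap optimization attempts per call.
#' @return A `netsel_partition`: `membership` (named integer vector,
#'   contiguous labels from 1), `node_id`, `quality` (codelength or
#'   modularity), `seed`, `method`.
#' @export
detect_communities <- function(graph, seed = NULL,
                               method = c("infomap", "louvain"),
                               nb_trials = 5) {
  stopifnot(inherits(graph, "netsel_graph"))
  method <- match.arg(method)
  n <- length(graph$node_id)
  if (n == 0) stop("empty graph")
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(graph$edges))
    g <- igraph::add_edges(g, rbind(graph$edges$i, graph$edges$j),
                           weight = graph$edges$w)
  if (!is.null(seed)) set.seed(seed)
  cl <- switch(method,
    infomap = igraph::cluster_infomap(g, e.weights = igraph::E(g)$weight,
                                      nb.trials = nb_trials),
    louvain = igraph::cluster_louvain(g, weights = igraph::E(g)$weight))
  memb <- as.integer(igraph::membership(cl))
  memb <- match(memb, unique(memb))  # contiguous from 1
  quality <- tryCatch(igraph::code_len(cl), error = function(e) NA_real_)
  if (is.na(quality) || !length(quality))
    quality <- suppressWarnings(igraph::modularity(g, memb,
                                                   weights = igraph::E(g)$weight))
  structure(list(membership = stats::setNames(memb, graph$node_id),
                 node_id = graph$node_id, quality = quality,
                 seed = seed, method = method),
            class = "netsel_partition")
}

# Minimum-cost perfect assignment on an n x n matrix (Hungarian algorithm,
# shortest-augmenting-path formulation with potentials). Returns, for each
# row, the assigned column. O(n^3).
hungarian_min <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  # column index 1 is a dummy; real columns are 2..n+1
  u <- numeric(n); v <- numeric(n + 1)
  p <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 1L
    minv <- rep(Inf, n + 1); used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in seq.int(2L, n + 1L)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          if (p[j] > 0L) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]; p[j0] <- p[j1]; j0 <- j1
      if (j0 == 1L) break
    }
  }
  out <- integer(n)
  for (j in seq.int(2L, n + 1L)) if (p[j] > 0L) out[p[j]] <- j - 1L
  out
}

# maximum-overlap one-to-one assignment; rectangular matrices are padded
# with zeros to square
assign_max_overlap <- function(overlap) {
  nr <- nrow(overlap); nc <- ncol(overlap)
  n <- max(nr, nc)
  m <- matrix(0, n, n)
  m[seq_len(nr), seq_len(nc)] <- overlap
  cols <- hungarian_min(-m)
  cols[seq_len(nr)]
}

#' Label detected communities by overlap with a reference partition
#'
#' Each detected community receives the reference system name that maximizes
#' node overlap, under an optimal one-to-one assignment of communities to
#' reference systems on the overlap-count matrix. Communities smaller than
#' `min_nodes`, communities with zero overlap with every reference system,
#' and communities left without a reference system (when more communities
#' than systems exist) are labeled `"unassigned"`. Relabeling the detected
#' communities never changes the result.
#'
#' @param partition a `netsel_partition` (or named integer membership vector).
#' @param reference data.frame with columns node_id, system, system_type.
#' @param min_nodes minimum community size eligible for a system label.
#' @return data.frame node_id, system, system_type (NA for unassigned).
#' @export
match_labels <- function(partition, reference, min_nodes = 5) {
  memb <- if (inherits(partition, "netsel_partition"))
    partition$membership else partition
  if (!all(names(memb) %in% reference$node_id))
    stop("partition and reference must share node IDs")
  ref_sys <- reference$system[match(names(memb), reference$node_id)]
  systems <- sort(unique(reference$system))
  comms <- sort(unique(memb))
  overlap <- vapply(systems, function(s)
    vapply(comms, function(cm) sum(memb == cm & ref_sys == s), 0L),
    integer(length(comms)))
  overlap <- matrix(overlap, nrow = length(comms),
                    dimnames = list(comms, systems))
  sizes <- tabulate(match(memb, comms), length(comms))
  eligible <- sizes >= min_nodes & rowSums(overlap) > 0

  label_of <- rep(NA_character_, length(comms))
  if (any(eligible)) {
    sub <- overlap[eligible, , drop = FALSE]
    cols <- assign_max_overlap(sub)
    lab <- rep(NA_character_, nrow(sub))
    valid <- which(cols <= length(systems))
    valid <- valid[sub[cbind(valid, cols[valid])] > 0]
    lab[valid] <- systems[cols[valid]]
    label_of[eligible] <- lab
  }
  system <- label_of[match(memb, comms)]
  type_map <- unique(reference[, c("system", "system_type")])
  out <- data.frame(
    node_id = names(memb),
    system = ifelse(is.na(system), "unassigned", system),
    system_type = type_map$system_type[match(system, type_map$system)],
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Bootstrap consensus system assignment across edge densities
#'
#' For each of `n_boot` bootstrap replicates: resample participants with
#' replacement, average their z-matrices, threshold at each edge density,
#' detect communities, and label them against the reference partition. The
#' consensus label of a node at a density is its modal label across
#' replicates; ties are broken deterministically toward the lowest label in
#' sorted order and recorded.
#'
#' @param z_list list of participant `netsel_zmatrix` objects (negatives need
#'   not be removed; the bootstrap mean is cleaned before thresholding).
#' @param densities numeric vector of edge densities (proportions).
#' @param n_boot number of bootstrap replicates.
#' @param reference data.frame node_id, system, system_type.
#' @param seed integer seed governing resampling and the optimizer.
#' @param min_nodes minimum community size for labeling.
#' @param method community detection backend, see [detect_communities()].
#' @return A `netsel_consensus`: `labels` (node x density character matrix),
#'   `agreement` (modal-label proportion, same shape), `tied` (logical, same
#'   shape), `densities`, `node_id`, `reference`.
#' @export
consensus_assignment <- function(z_list, densities, n_boot, reference,
                                 seed, min_nodes = 5, method = "infomap") {
  stopifnot(length(z_list) >= 2, n_boot >= 1)
  ids <- z_list[[1]]$node_id
  n <- length(ids); P <- length(z_list)
  arr <- array(unlist(lapply(z_list, `[[`, "z")), dim = c(n, n, P))
  set.seed(seed)
  boot_seeds <- sample.int(.Machine$integer.max, n_boot)

  dn <- paste0("d", format(densities))
  votes <- array(NA_character_, dim = c(n, length(densities), n_boot))
  for (b in seq_len(n_boot)) {
    set.seed(boot_seeds[b])
    idx <- sample.int(P, P, replace = TRUE)
    zm <- rowMeans(arr[, , idx, drop = FALSE], dims = 2L)
    zm[zm < 0] <- 0
    zmb <- zmatrix(zm, ids, negatives_removed = TRUE)
    for (d in seq_along(densities)) {
      g <- threshold_density(zmb, densities[d])
      part <- detect_communities(g, method = method)
      votes[, d, b] <- match_labels(part, reference, min_nodes)$system
    }
  }

  labels <- matrix(NA_character_, n, length(densities),
                   dimnames = list(ids, dn))
  agreement <- matrix(NA_real_, n, length(densities), dimnames = list(ids, dn))
  tied <- matrix(FALSE, n, length(densities), dimnames = list(ids, dn))
  for (d in seq_along(densities)) {
    for (i in seq_len(n)) {
      tab <- table(votes[i, d, ])
      top <- max(tab)
      winners <- sort(names(tab)[tab == top])
      labels[i, d] <- winners[1]
      agreement[i, d] <- top / n_boot
      tied[i, d] <- length(winners) > 1
    }
  }
  structure(list(labels = labels, agreement = agreement, tied = tied,
                 densities = densities, node_id = ids,
                 reference = reference),
            class = "netsel_consensus")
}

#' Modal system of each node across densities
#'
#' Collapses a consensus assignment to one system label per node (the modal
#' label over densities, ties toward the lowest label in sorted order), used
#' when a single per-node system is needed, e.g. for connector
#' classification on density-summed participation coefficients.
#'
#' @param consensus a `netsel_consensus`.
#' @return data.frame node_id, system, system_type.
#' @export
consensus_modal_system <- function(consensus) {
  stopifnot(inherits(consensus, "netsel_consensus"))
  sys <- apply(consensus$labels, 1L, function(x) {
    tab <- table(x)
    sort(names(tab)[tab == max(tab)])[1]
  })
  type_map <- unique(consensus$reference[, c("system", "system_type")])
  data.frame(node_id = consensus$node_id,
             system = unname(sys),
             system_type = type_map$system_type[match(sys, type_map$system)],
             stringsAsFactors = FALSE)
}

#' Chance-corrected agreement between two partitions
#'
#' Adjusted Rand index between two labelings, computed over the nodes that
#' carry a proper label in both (entries that are NA or `"unassigned"` are
#' dropped).
#'
#' @param x,y label vectors of equal length.
#' @return Adjusted Rand index (1 = identical up to relabeling).
#' @export
partition_agreement <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- !is.na(x) & !is.na(y) & x != "unassigned" & y != "unassigned"
  if (!any(keep)) return(NA_real_)
  mclust::adjustedRandIndex(x[keep], y[keep])
}
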