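# Weighted participation coefficients, density-summed PC, and
# connector / non-connector classification.

#' Weighted participation coefficient
#'
#' `PC_i = 1 - sum_s (k_i(s) / k_i)^2`, where `k_i(s)` is node i's total
#' retained edge weight to nodes of system s and `k_i` its total retained
#' weight. The sum runs over all systems including the node's own, so a node
#' whose weight lies entirely within its own system has PC 0 and a node
#' splitting its weight evenly over S systems approaches `1 - 1/S`
#' (`variant = "literal"` instead omits the own-system term, in which case a
#' fully within-system node scores 1). Edges to nodes of unassigned system
#' are dropped from both the numerator and `k_i`. Nodes with no remaining
#' weight get PC 0, with the affected nodes recorded in the `"isolated"`
#' attribute.
#'
#' @param graph a `netsel_graph`.
#' @param partition data.frame node_id, system (system `"unassigned"` or NA
#'   excluded), covering the graph's nodes.
#' @param variant `"standard"` (sum over all systems) or `"literal"`
#'   (own-system term omitted).
#' @return Named numeric vector of PC per node.
#' @export
participation_coefficient <- function(graph, partition,
                                      variant = c("standard", "literal")) {
  stopifnot(inherits(graph, "netsel_graph"))
  variant <- match.arg(variant)
  sys <- partition$system[match(graph$node_id, partition$node_id)]
  sys[is.na(sys)] <- "unassigned"
  n <- length(graph$node_id)
  systems <- sort(unique(sys[sys != "unassigned"]))
  kis <- matrix(0, n, length(systems), dimnames = list(NULL, systems))
  e <- graph$edges
  if (nrow(e)) {
    from <- c(e$i, e$j); to <- c(e$j, e$i); w <- rep(e$w, 2L)
    keep <- sys[to] != "unassigned"
    if (any(keep)) {
      sidx <- match(sys[to[keep]], systems)
      for (col in seq_along(systems)) {
        sel <- sidx == col
        if (any(sel)) {
          agg <- tapply(w[keep][sel], from[keep][sel], sum)
          kis[as.integer(names(agg)), col] <- agg
        }
      }
    }
  }
  k <- rowSums(kis)
  frac2 <- (kis / ifelse(k > 0, k, 1))^2
  if (variant == "literal") {
    own <- match(sys, systems)
    has_own <- !is.na(own)
    frac2[cbind(which(has_own), own[has_own])] <- 0
  }
  pc <- 1 - rowSums(frac2)
  pc[k == 0] <- 0
  isolated <- graph$node_id[k == 0]
  if (length(isolated))
    warning(length(isolated),
            " node(s) had no retained weight to assigned systems; PC set to 0")
  structure(stats::setNames(pc, graph$node_id), isolated = isolated)
}

#' Participation coefficients summed over edge densities
#'
#' Thresholds a z-matrix at each edge density, computes the weighted PC with
#' that density's system assignment, and sums the per-density PCs per node to
#' absorb variations of graph configuration across densities.
#'
#' @param zm a `netsel_zmatrix` with negatives removed.
#' @param assignment either a `netsel_consensus` (per-density labels) or a
#'   single data.frame node_id, system\[, system_type\] used at every density.
#' @param densities edge densities; defaults to the consensus densities when
#'   `assignment` is a consensus object.
#' @param variant PC formula variant, see [participation_coefficient()].
#' @return List: `pc_sum` (named vector), `pc_by_density` (node x density
#'   matrix).
#' @export
summed_pc <- function(zm, assignment, densities = NULL,
                      variant = "standard") {
  if (inherits(assignment, "netsel_consensus")) {
    if (is.null(densities)) densities <- assignment$densities
    if (!all(densities %in% assignment$densities))
      stop("consensus does not cover every requested density")
  } else if (is.null(densities)) {
    stop("densities must be given when assignment is a plain partition")
  }
  pcs <- vapply(seq_along(densities), function(d) {
    part <- if (inherits(assignment, "netsel_consensus")) {
      di <- match(densities[d], assignment$densities)
      data.frame(node_id = assignment$node_id,
                 system = assignment$labels[, di],
                 stringsAsFactors = FALSE)
    } else assignment
    g <- threshold_density(zm, densities[d])
    suppressWarnings(as.numeric(participation_coefficient(g, part, variant)))
  }, numeric(length(zm$node_id)))
  dimnames(pcs) <- list(zm$node_id, paste0("d", format(densities)))
  list(pc_sum = stats::setNames(rowSums(pcs), zm$node_id),
       pc_by_density = pcs)
}

#' Classify connector and non-connector nodes within systems
#'
#' Within each system, a node is a connector if its (density-summed) PC
#' exceeds the median PC of the nodes of that system, and a non-connector if
#' its PC is less than or equal to the median. Nodes of unassigned system are
#' `"excluded"`. With ties going to non-connector, each system has at most as
#' many connectors as non-connectors.
#'
#' @param pc_sum named numeric vector of per-node PC (e.g. from [summed_pc()]).
#' @param partition data.frame node_id, system\[, system_type\].
#' @return data.frame node_id, system, pc_sum, role.
#' @export
classify_connectors <- function(pc_sum, partition) {
  sys <- partition$system[match(names(pc_sum), partition$node_id)]
  sys[is.na(sys)] <- "unassigned"
  role <- rep("excluded", length(pc_sum))
  for (s in unique(sys[sys != "unassigned"])) {
    idx <- which(sys == s)
    if (length(idx) < 2)
      stop(sprintf("system %s has fewer than 2 nodes; cannot classify", s))
    med <- stats::median(pc_sum[idx])
    role[idx] <- ifelse(pc_sum[idx] > med, "connector", "non-connector")
  }
  out <- data.frame(node_id = names(pc_sum), system = sys,
                    pc_sum = as.numeric(pc_sum), role = role,
                    stringsAsFactors = FALSE)
  if ("system_type" %in% names(partition))
    out$system_type <- partition$system_type[match(out$node_id,
                                                   partition$node_id)]
  rownames(out) <- NULL
  out
}

#' Full node-topology table for one z-matrix
#'
#' Convenience wrapper: per-density PC, density-summed PC, and
#' connector role, grouped by the consensus modal system.
#'
#' @param zm a `netsel_zmatrix` with negatives removed.
#' @param consensus a `netsel_consensus`.
#' @param densities edge densities (default: the consensus densities).
#' @param variant PC formula variant.
#' @return data.frame node_id, system, system_type, per-density PC columns,
#'   pc_sum, role.
#' @export
node_topology <- function(zm, consensus, densities = NULL,
                          variant = "standard") {
  if (is.null(densities)) densities <- consensus$densities
  sp <- summed_pc(zm, consensus, densities, variant)
  modal <- consensus_modal_system(consensus)
  roles <- classify_connectors(sp$pc_sum, modal)
  cbind(roles[, c("node_id", "system")],
        system_type = modal$system_type[match(roles$node_id, modal$node_id)],
        as.data.frame(sp$pc_by_density),
        pc_sum = roles$pc_sum, role = roles$role,
        row.names = NULL)
}
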