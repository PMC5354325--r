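# Activation selectivity: relating node topology (PC) to task activation.

#' Activation selectivity score
#'
#' `selectivity = -1 * r(PC, beta)` over the included nodes: the negated
#' correlation between per-node participation coefficients and task beta
#' estimates. A positive score means greater activation at low-PC
#' (non-connector) nodes; a negative score means greater activation at
#' high-PC (connector) nodes. Nodes of the default system are excluded by
#' default, to avoid conflating task-evoked activation and deactivation;
#' unassigned nodes are always excluded.
#'
#' @param pc named numeric vector of per-node PC values (typically
#'   density-summed).
#' @param beta data.frame node_id, beta (one task), or a named numeric vector.
#' @param partition data.frame node_id, system, system_type (used for the
#'   default-system and unassigned exclusions).
#' @param include_default keep default-system nodes.
#' @param node_mask optional character vector of node IDs to restrict to.
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @return List: `score`, `n_nodes`, `r` (the raw correlation).
#' @export
selectivity_score <- function(pc, beta, partition,
                              include_default = FALSE, node_mask = NULL,
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (is.data.frame(beta))
    beta <- stats::setNames(beta$beta, beta$node_id)
  ids <- intersect(names(pc), names(beta))
  sys <- partition$system[match(ids, partition$node_id)]
  type <- partition$system_type[match(ids, partition$node_id)]
  keep <- !is.na(sys) & sys != "unassigned"
  if (!include_default) keep <- keep & !is.na(type) & type != "default"
  if (!is.null(node_mask)) keep <- keep & ids %in% node_mask
  ids <- ids[keep]
  if (length(ids) < 3) stop("fewer than 3 nodes after masking")
  x <- pc[ids]; y <- beta[ids]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant PC or beta after masking; correlation undefined")
  r <- stats::cor(x, y, method = method)
  list(score = -1 * r, n_nodes = length(ids), r = r)
}

#' Selectivity by system type
#'
#' Computes the selectivity score separately over sensory-motor and over
#' association nodes (default-system nodes excluded throughout).
#'
#' @inheritParams selectivity_score
#' @return data.frame scope, score, n_nodes.
#' @export
system_type_selectivity <- function(pc, beta, partition,
                                    method = "pearson") {
  scopes <- c("sensory-motor", "association")
  out <- lapply(scopes, function(tp) {
    ids <- partition$node_id[!is.na(partition$system_type) &
                               partition$system_type == tp &
                               partition$system != "unassigned"]
    s <- selectivity_score(pc, beta, partition, node_mask = ids,
                           method = method)
    data.frame(scope = tp, score = s$score, n_nodes = s$n_nodes,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Mean activation by node role and system type
#'
#' Cell means and standard errors of task beta over the role x system-type
#' grid (connector / non-connector by sensory-motor / association), for one
#' participant. Default-system and excluded nodes are omitted.
#'
#' @param beta data.frame node_id, beta, or named numeric vector.
#' @param roles data.frame node_id, role (from [classify_connectors()]).
#' @param partition data.frame node_id, system, system_type.
#' @return data.frame system_type, role, mean_beta, se_beta, n_nodes.
#' @export
activation_by_node_type <- function(beta, roles, partition) {
  if (is.data.frame(beta))
    beta <- stats::setNames(beta$beta, beta$node_id)
  ids <- names(beta)
  role <- roles$role[match(ids, roles$node_id)]
  type <- partition$system_type[match(ids, partition$node_id)]
  keep <- !is.na(role) & role %in% c("connector", "non-connector") &
    !is.na(type) & type %in% c("sensory-motor", "association")
  df <- data.frame(beta = as.numeric(beta[keep]), role = role[keep],
                   type = type[keep], stringsAsFactors = FALSE)
  grid <- expand.grid(system_type = c("sensory-motor", "association"),
                      role = c("connector", "non-connector"),
                      stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(seq_len(nrow(grid)), function(k) {
    cell <- df$beta[df$type == grid$system_type[k] & df$role == grid$role[k]]
    if (!length(cell))
      stop(sprintf("empty cell: %s x %s", grid$system_type[k], grid$role[k]))
    data.frame(system_type = grid$system_type[k], role = grid$role[k],
               mean_beta = mean(cell),
               se_beta = stats::sd(cell) / sqrt(length(cell)),
               n_nodes = length(cell), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Permutation test of the role effect on activation
#'
#' Observed non-connector minus connector mean beta difference, against the
#' null distribution obtained by shuffling role labels across nodes.
#'
#' @param beta data.frame node_id, beta, or named numeric vector.
#' @param roles data.frame node_id, role.
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return List: `observed`, `null` (vector of permuted differences),
#'   `ci95` (2.5/97.5 percentiles of the null), `p` (two-sided).
#' @export
role_permutation_test <- function(beta, roles, n_perm = 1000, seed = 1) {
  if (is.data.frame(beta))
    beta <- stats::setNames(beta$beta, beta$node_id)
  role <- roles$role[match(names(beta), roles$node_id)]
  keep <- !is.na(role) & role %in% c("connector", "non-connector")
  b <- as.numeric(beta[keep]); role <- role[keep]
  diff_of <- function(rl) mean(b[rl == "non-connector"]) -
    mean(b[rl == "connector"])
  obs <- diff_of(role)
  set.seed(seed)
  null <- replicate(n_perm, diff_of(sample(role)))
  list(observed = obs, null = null,
       ci95 = stats::quantile(null, c(0.025, 0.975), names = FALSE),
       p = (1 + sum(abs(null) >= abs(obs))) / (1 + n_perm))
}

#' Cohort summary of selectivity scores
#'
#' Mean and SD of selectivity per task and scope, the Pearson correlation of
#' score with age, and LOESS-smoothed trend points (descriptive only,
#' span 0.75).
#'
#' @param scores data.frame with columns participant, task, scope, score.
#' @param ages named numeric vector of ages per participant (any monotone
#'   transform of age; normalized age in \[0,1\] for synthetic cohorts).
#' @return data.frame per task x scope: mean, sd, n, r_age, plus a `trend`
#'   attribute (list of per-task/scope data.frames age, fitted).
#' @export
cohort_summary <- function(scores, ages) {
  stopifnot(all(c("participant", "task", "scope", "score") %in% names(scores)))
  scores$age <- ages[scores$participant]
  if (length(unique(scores$participant)) < 4)
    stop("need at least 4 participants")
  groups <- unique(scores[, c("task", "scope")])
  trend <- list()
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(k) {
    g <- scores[scores$task == groups$task[k] & scores$scope == groups$scope[k], ]
    if (stats::sd(g$score) == 0 || stats::sd(g$age) == 0)
      stop("constant scores or ages; correlation undefined")
    lo <- stats::loess(score ~ age, data = g, span = 0.75, degree = 1)
    grid <- seq(min(g$age), max(g$age), length.out = 25)
    trend[[paste(groups$task[k], groups$scope[k], sep = ":")]] <<-
      data.frame(age = grid, fitted = stats::predict(lo, newdata =
                                                       data.frame(age = grid)))
    data.frame(task = groups$task[k], scope = groups$scope[k],
               mean = mean(g$score), sd = stats::sd(g$score), n = nrow(g),
               r_age = stats::cor(g$score, g$age),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  attr(out, "trend") <- trend
  out
}
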