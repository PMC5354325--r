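# Shared fixtures and oracles, all built in code.

# Weighted graph from a full symmetric weight matrix (all positive entries
# become edges), for direct participation-coefficient tests.
graph_from_weights <- function(w, node_id = NULL) {
  if (is.null(node_id)) node_id <- sprintf("n%03d", seq_len(nrow(w)))
  zm <- zmatrix(w, node_id, negatives_removed = TRUE)
  suppressWarnings(threshold_density(zm, 1))
}

partition_df <- function(node_id, system, system_type = NULL) {
  df <- data.frame(node_id = node_id, system = system,
                   stringsAsFactors = FALSE)
  df$system_type <- if (is.null(system_type)) NA_character_ else system_type
  df
}

# Naive double-loop participation coefficient: the independent oracle.
naive_pc <- function(graph, partition, variant = "standard") {
  n <- length(graph$node_id)
  sys <- partition$system[match(graph$node_id, partition$node_id)]
  sys[is.na(sys)] <- "unassigned"
  w <- matrix(0, n, n)
  for (k in seq_len(nrow(graph$edges))) {
    i <- graph$edges$i[k]; j <- graph$edges$j[k]
    w[i, j] <- w[j, i] <- graph$edges$w[k]
  }
  pc <- numeric(n)
  systems <- sort(unique(sys[sys != "unassigned"]))
  for (i in seq_len(n)) {
    k_tot <- 0; k_s <- stats::setNames(numeric(length(systems)), systems)
    for (j in seq_len(n)) {
      if (j == i || w[i, j] == 0 || sys[j] == "unassigned") next
      k_tot <- k_tot + w[i, j]
      k_s[sys[j]] <- k_s[sys[j]] + w[i, j]
    }
    if (k_tot == 0) { pc[i] <- 0; next }
    terms <- (k_s / k_tot)^2
    if (variant == "literal" && sys[i] %in% systems)
      terms[sys[i]] <- 0
    pc[i] <- 1 - sum(terms)
  }
  stats::setNames(pc, graph$node_id)
}

# Brute-force maximum-overlap one-to-one assignment by permutation
# enumeration (small matrices only).
brute_assignment_max <- function(m) {
  n <- max(nrow(m), ncol(m))
  sq <- matrix(0, n, n)
  sq[seq_len(nrow(m)), seq_len(ncol(m))] <- m
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- -Inf
  for (p in perms(seq_len(n))) {
    val <- sum(sq[cbind(seq_len(n), p)])
    if (val > best) best <- val
  }
  best
}

# Small strong-signal spec for fast planted-structure tests.
small_spec <- function(...) {
  cohort_spec(n_participants = 4, age_grid = rep(0, 4), ...)
}

# Fisher-z matrix of the noise-free planted correlation matrix.
planted_zmatrix <- function(spec, age) {
  pc <- plant_covariance(spec, age)
  zmatrix(atanh(pc$corr * (1 - 1e-12)), pc$truth$node_id,
          negatives_removed = TRUE)
}

# Preprocess one synthetic participant to its z-matrices.
participant_z <- function(p, drop_negatives = TRUE) {
  cl <- clean_rsfc(p$ts, friston24(p$motion), compute_fd(p$motion))
  correlation_zmatrix(cl, drop_negatives = drop_negatives)
}

densities_band <- seq(0.02, 0.10, by = 0.01)
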