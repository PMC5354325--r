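# Synthetic cohort generator: planted systems, connector roles, age-graded
# dedifferentiation, motion spikes, task beta maps.

#' Task specification for synthetic beta maps
#'
#' Describes one task condition of the synthetic cohort: which system types it
#' recruits, the baseline activation per system type, and the planted
#' non-connector activation bonus (`delta`) restricted to task-relevant
#' system types. `delta_age_slope` attenuates the bonus linearly in
#' normalized age, so that activation selectivity declines over the adult
#' life span of the simulated cohort.
#'
#' @param relevant_types character, system types ("sensory-motor",
#'   "association", "default") whose non-connector nodes receive the bonus.
#' @param beta_base named numeric, baseline beta per system type (arbitrary
#'   BOLD units). Names must cover every system type in the cohort spec.
#' @param delta non-connector activation bonus in task-relevant system types.
#' @param beta_noise_sd standard deviation of i.i.d. Gaussian node noise.
#' @param delta_age_slope per-unit-age multiplicative attenuation of `delta`;
#'   the realized bonus at normalized age `a` is `delta * (1 - delta_age_slope * a)`.
#' @return A `netsel_task_spec` list.
#' @export
task_spec <- function(relevant_types,
                      beta_base,
                      delta = 1,
                      beta_noise_sd = 0.5,
                      delta_age_slope = 0.8) {
  stopifnot(is.character(relevant_types),
            is.numeric(beta_base), !is.null(names(beta_base)),
            is.numeric(delta), length(delta) == 1L,
            beta_noise_sd >= 0)
  structure(list(relevant_types = relevant_types,
                 beta_base = beta_base,
                 delta = delta,
                 beta_noise_sd = beta_noise_sd,
                 delta_age_slope = delta_age_slope),
            class = "netsel_task_spec")
}

#' Default pair of synthetic tasks
#'
#' Two task conditions emulating a lifespan imaging battery: a "visual"-like
#' task whose activation bonus is planted in sensory-motor systems, and a
#' "semantic"-like task whose bonus is planted in association systems.
#' Baselines are loosely patterned on typical block/event-related GLM beta
#' magnitudes.
#'
#' @return Named list of [task_spec()] objects.
#' @export
default_task_specs <- function() {
  list(
    visual = task_spec(
      relevant_types = "sensory-motor",
      beta_base = c("sensory-motor" = 1.7, "association" = 0.9, "default" = 0),
      delta = 1.0, beta_noise_sd = 0.5, delta_age_slope = 0.8),
    semantic = task_spec(
      relevant_types = "association",
      beta_base = c("sensory-motor" = 0.1, "association" = 0.1, "default" = 0),
      delta = 0.45, beta_noise_sd = 0.5, delta_age_slope = 0.8)
  )
}

#' Specification of a synthetic resting-state cohort
#'
#' Defines the planted network and activation structure of a simulated cohort:
#' block-structured node correlations with one latent factor per system plus a
#' global factor, a designated connector subset per system with genuine
#' cross-system coupling, an age-graded erosion of the within/between coupling
#' contrast (dedifferentiation), motion spikes, and per-task beta maps.
#'
#' Within-system coupling is heterogeneous across nodes: non-connector
#' targets are evenly spaced over `rho_within +/- within_spread` (homogeneous
#' blocks would make top-k edge retention at 2-10% density an all-or-nothing
#' affair), while connectors occupy the upper half of the coupling range
#' (hub-like). Each connector carries one dedicated strong cross-system link
#' (a two-node bridge factor) of correlation about
#' `rho_between + connector_boost` to a rank-matched connector of the next
#' system; with age, the most strongly attached non-connectors progressively
#' acquire bridges of their own (`dediff_slope_between`) while non-connector
#' within-system coupling shrinks (`dediff_slope_within`) — so the
#' connector/non-connector participation contrast erodes across the life
#' span.
#'
#' @param n_participants number of participants.
#' @param age_grid normalized ages in \[0, 1\] (0 maps to age 20, 1 to age 89);
#'   recycled to `n_participants`. A fixed grid, not a random draw.
#' @param n_systems number of planted systems.
#' @param nodes_per_system nodes per system (>= 4).
#' @param system_types character of length `n_systems`; values among
#'   "sensory-motor", "association", "default". At least one default system is
#'   recommended so that the default-exclusion rule is exercised.
#' @param connector_fraction proportion of connector nodes per system,
#'   strictly in (0, 1).
#' @param rho_within baseline mean within-system correlation of
#'   non-connector pairs at age 0.
#' @param rho_between baseline between-system correlation (global coupling).
#' @param within_spread half-range of the deterministic even spread of
#'   within-system coupling targets across a system's nodes.
#' @param connector_boost extra correlation (above `rho_between`) carried by
#'   a connector's dedicated cross-system link to its designated partner
#'   connector in a neighboring system.
#' @param connector_within_bump scale of the connector within-system coupling
#'   range: connectors span `rho_within` to
#'   `rho_within + connector_within_bump * within_spread` (the upper half of
#'   the system's coupling range at the default of 1), making them hub-like.
#' @param dediff_slope_within per-unit-age reduction of non-connector
#'   within-system coupling.
#' @param dediff_slope_between full strength (extra correlation) of the
#'   cross-system link an aged non-connector acquires; links switch on
#'   staggered across age so the re-coupled fraction of non-connectors grows
#'   roughly linearly from age 0 to 1.
#' @param n_frames frames per resting-state run.
#' @param tr_seconds sampling interval (s).
#' @param spike_prob per-frame probability of a motion spike.
#' @param spike_fd_mm framewise displacement magnitude of a spike (mm).
#' @param spike_artifact_sd amplitude (in signal SD units) of the shared
#'   artifact added to all nodes at spike frames.
#' @param jitter_trans_sd SD (mm) of continuous translation jitter.
#' @param jitter_rot_sd SD (radians) of continuous rotation jitter.
#' @param task_specs named list of [task_spec()] objects.
#' @return A validated `netsel_cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 20,
                        age_grid = seq(0, 1, length.out = n_participants),
                        n_systems = 5,
                        nodes_per_system = 20,
                        system_types = c("sensory-motor", "sensory-motor",
                                         "association", "association",
                                         "default"),
                        connector_fraction = 0.5,
                        rho_within = 0.40,
                        rho_between = 0.05,
                        within_spread = 0.12,
                        connector_boost = 0.42,
                        connector_within_bump = 1,
                        dediff_slope_within = 0.02,
                        dediff_slope_between = 0.42,
                        n_frames = 1000,
                        tr_seconds = 2,
                        spike_prob = 0.05,
                        spike_fd_mm = 0.6,
                        spike_artifact_sd = 3,
                        jitter_trans_sd = 0.01,
                        jitter_rot_sd = 1e-4,
                        task_specs = default_task_specs()) {
  if (length(system_types) != n_systems)
    stop("system_types must have length n_systems")
  if (!all(system_types %in% c("sensory-motor", "association", "default")))
    stop("system_types must be 'sensory-motor', 'association' or 'default'")
  if (!(connector_fraction > 0 && connector_fraction < 1))
    stop("connector_fraction must be strictly between 0 and 1")
  if (nodes_per_system < 4) stop("nodes_per_system must be >= 4")
  if (any(age_grid < 0 | age_grid > 1)) stop("age_grid must lie in [0, 1]")
  for (r in c(rho_within, rho_between))
    if (abs(r) >= 1) stop("correlations must lie in (-1, 1)")
  if (rho_within - within_spread <= rho_between)
    stop("rho_within - within_spread must exceed rho_between ",
         "(own-factor loading would be imaginary)")
  if (rho_within + connector_within_bump * within_spread >= 1)
    stop("connector within-system coupling reaches 1; reduce ",
         "connector_within_bump or within_spread")
  if (!is.list(task_specs) || is.null(names(task_specs)))
    stop("task_specs must be a named list of task_spec objects")
  for (ts in task_specs) {
    if (!inherits(ts, "netsel_task_spec")) stop("invalid task_spec entry")
    if (!all(unique(system_types) %in% names(ts$beta_base)))
      stop("task beta_base must name every system type in use")
  }

  spec <- structure(
    list(n_participants = n_participants,
         age_grid = rep_len(age_grid, n_participants),
         n_systems = n_systems, nodes_per_system = nodes_per_system,
         system_types = system_types,
         connector_fraction = connector_fraction,
         rho_within = rho_within, rho_between = rho_between,
         within_spread = within_spread, connector_boost = connector_boost,
         connector_within_bump = connector_within_bump,
         dediff_slope_within = dediff_slope_within,
         dediff_slope_between = dediff_slope_between,
         n_frames = n_frames, tr_seconds = tr_seconds,
         spike_prob = spike_prob, spike_fd_mm = spike_fd_mm,
         spike_artifact_sd = spike_artifact_sd,
         jitter_trans_sd = jitter_trans_sd, jitter_rot_sd = jitter_rot_sd,
         task_specs = task_specs),
    class = "netsel_cohort_spec")

  # the planted model must stay a valid correlation matrix over the age range
  for (a in range(spec$age_grid)) plant_covariance(spec, a)
  spec
}

# Deterministic role pattern: exactly round(fraction * m) connectors per
# system, spread evenly across the within-coupling gradient (Bresenham rule).
role_pattern <- function(m, fraction) {
  n_conn <- round(fraction * m)
  if (n_conn == 0L || n_conn == m)
    stop("connector_fraction leaves a system without both roles")
  k <- seq_len(m)
  ifelse((k * n_conn) %% m < n_conn, "connector", "non-connector")
}

# Loading matrix of the planted factor model at a given age.
# Factors: one per system, one global factor, and one dedicated "bridge"
# factor per planted cross-system link. A bridge factor is loaded by exactly
# two nodes in different systems and raises their pairwise correlation by the
# bridge strength without touching any other pair, so cross-system coupling
# can be planted at edge strengths comparable to within-system coupling
# without creating spurious cliques among the nodes that would otherwise
# share a partner-system factor.
plant_loadings <- function(spec, age) {
  S <- spec$n_systems; m <- spec$nodes_per_system
  n <- S * m
  system_of <- rep(seq_len(S), each = m)
  roles <- rep(role_pattern(m, spec$connector_fraction), times = S)
  node_id <- sprintf("n%03d", seq_len(n))

  offsets <- if (m > 1)
    seq(-spec$within_spread, spec$within_spread, length.out = m) else 0

  base <- matrix(0, n, S + 1L)
  for (i in seq_len(n)) {
    s <- system_of[i]
    j <- ((i - 1L) %% m) + 1L
    # connectors are hub-like: their within-system coupling spans the upper
    # half of the system's coupling range and does not erode with age;
    # non-connectors span the full range and lose within coupling with age
    u <- if (m > 1 && spec$within_spread > 0)
      (offsets[j] + spec$within_spread) / (2 * spec$within_spread) else 0.5
    w <- if (roles[i] == "connector")
      spec$rho_within + spec$connector_within_bump * spec$within_spread *
        (1 + u) / 2
    else spec$rho_within + offsets[j] - spec$dediff_slope_within * age
    lam2 <- w - spec$rho_between
    if (lam2 <= 0)
      stop(sprintf(
        "planted within-coupling of node %s (system %d) fell to %.3f, at or below rho_between %.3f at age %.2f",
        node_id[i], s, w, spec$rho_between, age))
    if (w >= 1)
      stop(sprintf("planted within correlation of node %s is >= 1",
                   node_id[i]))
    base[i, s] <- sqrt(lam2)
    base[i, S + 1L] <- sqrt(spec$rho_between)
  }

  # bridge pairing: within a candidate pool per system (in ascending
  # within-coupling order), the first half initiates one link each to the
  # second half of the next system's pool (cyclic), rank-matched so that
  # strongly coupled nodes bridge to strongly coupled nodes; every pool node
  # carries at most one bridge (exactly one when pool sizes are even)
  bridge_pairs <- function(role, upper_only = FALSE) {
    pool <- function(s) {
      members <- which(system_of == s & roles == role)
      if (upper_only && length(members) > 1)
        members <- members[seq.int(ceiling(length(members) / 2),
                                   length(members))]
      members
    }
    out <- NULL
    for (s in seq_len(S)) {
      members <- pool(s)
      targets <- pool((s %% S) + 1L)
      n_init <- floor(length(members) / 2)
      if (n_init == 0L || length(targets) == 0L) next
      init <- members[seq_len(n_init)]
      upper <- targets[seq.int(max(1L, length(targets) - n_init + 1L),
                               length(targets))]
      recv <- upper[((seq_len(n_init) - 1L) %% length(upper)) + 1L]
      out <- rbind(out, cbind(init, recv))
    }
    out
  }

  # bridge strengths are spread over [0.93, 1.07] of the nominal value,
  # ascending with the endpoint coupling rank: retention of cross links at a
  # given edge density then degrades gradually rather than all-or-nothing
  # when the retention threshold moves
  strength_spread <- function(bp, nominal) {
    src <- system_of[bp[, 1]]
    r <- stats::ave(seq_len(nrow(bp)), src, FUN = seq_along)
    k <- stats::ave(seq_len(nrow(bp)), src, FUN = length)
    v <- ifelse(k > 1, (r - 1) / (k - 1), 1)
    nominal * (0.93 + 0.14 * v)
  }

  bridges <- NULL
  if (spec$connector_boost > 0) {
    bp <- bridge_pairs("connector")
    if (!is.null(bp))
      bridges <- rbind(bridges,
                       cbind(bp, strength_spread(bp, spec$connector_boost)))
  }
  if (spec$dediff_slope_between > 0 && age > 0) {
    # ageing non-connectors acquire connector-like cross links at full
    # strength, staggered in age (the k-th link ramps in over the age window
    # [k/n, k/n + 0.15]): the re-coupled fraction of non-connectors, hence
    # their mean PC, grows smoothly toward the connector level. Links are
    # restricted to the upper-half (well-attached) non-connectors because a
    # node needs retained within-system edges for cross links to register as
    # participation at the analysis densities.
    bp <- bridge_pairs("non-connector", upper_only = TRUE)
    if (!is.null(bp)) {
      nb <- nrow(bp)
      # activation order interleaves systems (dedifferentiation progresses
      # evenly across the network) and starts with the most strongly attached
      # non-connectors, whose acquired cross links register as participation
      # immediately
      src <- system_of[bp[, 1]]
      rank_in_sys <- stats::ave(seq_len(nb), src, FUN = seq_along)
      a0 <- (order(order(-rank_in_sys, src)) - 1) / nb * 0.85
      ramp <- pmin(1, pmax(0, (age - a0) / 0.15))
      keep <- ramp > 0
      if (any(keep))
        bridges <- rbind(bridges,
                         cbind(bp[keep, , drop = FALSE],
                               strength_spread(bp, spec$dediff_slope_between)[keep] *
                                 ramp[keep]))
    }
  }

  n_bridge <- if (is.null(bridges)) 0L else nrow(bridges)
  L <- cbind(base, matrix(0, n, n_bridge))
  partner <- integer(n)
  if (n_bridge > 0L) {
    for (k in seq_len(n_bridge)) {
      a <- bridges[k, 1]; b <- bridges[k, 2]
      L[a, S + 1L + k] <- sqrt(bridges[k, 3])
      L[b, S + 1L + k] <- sqrt(bridges[k, 3])
      partner[a] <- system_of[b]
      partner[b] <- system_of[a]
    }
  }
  uniq <- numeric(n)
  for (i in seq_len(n)) {
    u <- 1 - sum(L[i, ]^2)
    if (u < 0)
      stop(sprintf(
        "loadings of node %s (system %d) exceed unit variance (sum of squares %.3f); reduce connector_boost / dediff slopes",
        node_id[i], system_of[i], 1 - u))
    uniq[i] <- u
  }


  truth <- structure(
    list(node_id = node_id,
         partition = data.frame(
           node_id = node_id,
           system = sprintf("S%02d", system_of),
           system_type = spec$system_types[system_of],
           stringsAsFactors = FALSE),
         roles = stats::setNames(roles, node_id),
         partner_system = stats::setNames(partner, node_id),
         age = age,
         planted_selectivity = vapply(
           spec$task_specs,
           function(ts) ts$delta * (1 - ts$delta_age_slope * age),
           numeric(1))),
    class = "netsel_truth")

  list(L = L, uniq = uniq, truth = truth)
}

#' Planted node correlation matrix at a given age
#'
#' Builds the noise-free correlation matrix of the factor model: each node
#' loads on its own-system factor, a global factor, and (for connectors, and
#' increasingly for aging non-connectors) a partner-system factor. The result
#' is symmetric, unit-diagonal and positive semidefinite by construction.
#'
#' @param spec a [cohort_spec()].
#' @param age normalized age in \[0, 1\].
#' @return List with `corr` (node x node correlation matrix, dimnames set to
#'   node IDs) and `truth` (planted partition, roles, age, realized planted
#'   selectivity per task).
#' @export
plant_covariance <- function(spec, age) {
  stopifnot(inherits(spec, "netsel_cohort_spec"), age >= 0, age <= 1)
  pl <- plant_loadings(spec, age)
  corr <- tcrossprod(pl$L)
  diag(corr) <- 1
  dimnames(corr) <- list(pl$truth$node_id, pl$truth$node_id)
  if (any(abs(corr[upper.tri(corr)]) >= 1)) {
    bad <- which(abs(corr) >= 1 & upper.tri(corr), arr.ind = TRUE)[1, ]
    stop(sprintf("planted correlation between %s and %s is outside (-1, 1)",
                 pl$truth$node_id[bad[1]], pl$truth$node_id[bad[2]]))
  }
  list(corr = corr, truth = pl$truth)
}

#' Generate one synthetic participant
#'
#' Samples a resting-state run from a zero-mean Gaussian with the planted
#' covariance, a six-parameter realignment trace (continuous jitter plus
#' single-frame motion spikes of framewise displacement
#' approximately `spike_fd_mm`), and per-task node beta maps
#' `beta = base(type) + delta * (1 - delta_age_slope * age)` for planted
#' non-connectors in task-relevant system types, plus i.i.d. Gaussian noise.
#' Spike frames additionally receive a shared additive BOLD artifact so that
#' censoring them matters. Identical `(spec, age, seed)` reproduces identical
#' values.
#'
#' @param spec a [cohort_spec()].
#' @param age normalized age in \[0, 1\].
#' @param seed integer seed for this participant.
#' @return A `netsel_participant` list: `ts` (frames x nodes), `motion`
#'   (frames x 6: trans_x/y/z mm, rot_x/y/z radians), `betas` (data.frame
#'   node_id, task, beta), `truth`, `age`, `seed`, `tr_seconds`.
#' @export
generate_participant <- function(spec, age, seed) {
  stopifnot(inherits(spec, "netsel_cohort_spec"))
  pl <- plant_loadings(spec, age)
  n <- nrow(pl$L)
  if (spec$n_frames < 2 * n)
    warning("n_frames < 2 * nodes; correlation estimates will be noisy")

  set.seed(seed)
  # fixed draw order: factors, unique noise, motion jitter, spikes,
  # spike artifact, task betas
  f <- matrix(stats::rnorm(spec$n_frames * ncol(pl$L)), spec$n_frames)
  e <- matrix(stats::rnorm(spec$n_frames * n), spec$n_frames)
  ts <- f %*% t(pl$L) + sweep(e, 2L, sqrt(pl$uniq), `*`)
  colnames(ts) <- pl$truth$node_id

  motion <- cbind(
    matrix(stats::rnorm(spec$n_frames * 3, sd = spec$jitter_trans_sd),
           spec$n_frames),
    matrix(stats::rnorm(spec$n_frames * 3, sd = spec$jitter_rot_sd),
           spec$n_frames))
  colnames(motion) <- c("trans_x", "trans_y", "trans_z",
                        "rot_x", "rot_y", "rot_z")
  spike <- stats::runif(spec$n_frames) < spec$spike_prob
  spike[1] <- FALSE  # FD at frame 1 is defined as 0; keep spikes detectable
  if (any(spike)) {
    # single-frame translation offset split over x/y/z: FD = spike_fd_mm at
    # the spike frame (and again at the return frame)
    motion[spike, 1:3] <- motion[spike, 1:3] + spec$spike_fd_mm / 3
    ts[spike, ] <- ts[spike, ] +
      stats::rnorm(sum(spike), sd = spec$spike_artifact_sd)
  }

  types <- pl$truth$partition$system_type
  nc <- pl$truth$roles == "non-connector"
  betas <- do.call(rbind, lapply(names(spec$task_specs), function(tk) {
    tsk <- spec$task_specs[[tk]]
    delta_a <- tsk$delta * (1 - tsk$delta_age_slope * age)
    b <- unname(tsk$beta_base[types]) +
      delta_a * as.numeric(nc & types %in% tsk$relevant_types) +
      stats::rnorm(n, sd = tsk$beta_noise_sd)
    data.frame(node_id = pl$truth$node_id, task = tk, beta = b,
               stringsAsFactors = FALSE)
  }))

  structure(list(ts = ts, motion = motion, betas = betas,
                 truth = pl$truth, age = age, seed = seed,
                 tr_seconds = spec$tr_seconds),
            class = "netsel_participant")
}

#' Generate a full synthetic cohort
#'
#' Draws one participant per entry of the spec's age grid, with per-participant
#' seeds derived deterministically from the cohort seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer cohort seed.
#' @return A `netsel_cohort` list: `participants` (list of
#'   [generate_participant()] results), `spec`, `seed`.
#' @export
generate_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "netsel_cohort_spec"))
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, spec$n_participants)
  participants <- lapply(seq_len(spec$n_participants), function(i)
    generate_participant(spec, spec$age_grid[i], seeds[i]))
  names(participants) <- sprintf("sub%03d", seq_len(spec$n_participants))
  structure(list(participants = participants, spec = spec, seed = seed),
            class = "netsel_cohort")
}

#' Reference system partition of a synthetic spec
#'
#' The planted node-to-system assignment with system-type annotation, in the
#' shape expected by [match_labels()] and [consensus_assignment()].
#'
#' @param spec a [cohort_spec()].
#' @return data.frame with columns node_id, system, system_type.
#' @export
reference_partition <- function(spec) {
  plant_covariance(spec, 0)$truth$partition
}
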