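# End-to-end pipeline: simulate (or ingest) -> preprocess -> graphs ->
# consensus communities -> node topology -> activation selectivity.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with its standard default: edge
#' densities 2-10% in steps of 1%, FD censoring threshold 0.3 mm, minimum 75
#' surviving frames, band-pass 0.009-0.08 Hz, 1000 bootstrap replicates, the
#' standard PC formula, and default-system exclusion from activation
#' analyses. Every run records the fully resolved configuration and seed in
#' its manifest.
#'
#' @param cohort a [cohort_spec()] to simulate, or NULL when reading inputs
#'   from `input_dir`.
#' @param input_dir directory of per-participant inputs (`<id>_ts.tsv`,
#'   `<id>_motion.tsv`, `<id>_betas.tsv`, plus `reference_partition.tsv` and
#'   `ages.tsv` with columns participant, age) used when `cohort` is NULL.
#' @param out_dir output directory for stage artifacts.
#' @param densities edge densities (proportions).
#' @param fd_threshold FD censoring threshold (mm).
#' @param min_frames minimum surviving frames per participant.
#' @param band band-pass edges in Hz, length 2.
#' @param n_boot bootstrap replicates for the consensus assignment.
#' @param min_nodes minimum community size for reference labeling.
#' @param pc_variant `"standard"` or `"literal"` PC formula.
#' @param include_default_system include default-system nodes in selectivity.
#' @param seed top-level integer seed; all stage randomness derives from it.
#' @return A `netsel_config` list.
#' @export
pipeline_config <- function(cohort = NULL, input_dir = NULL, out_dir,
                            densities = seq(0.02, 0.10, by = 0.01),
                            fd_threshold = 0.3, min_frames = 75,
                            band = c(0.009, 0.08), n_boot = 1000,
                            min_nodes = 5,
                            pc_variant = c("standard", "literal"),
                            include_default_system = FALSE, seed = 1) {
  if (is.null(cohort) && is.null(input_dir))
    stop("either a cohort spec or an input_dir is required")
  structure(list(cohort = cohort, input_dir = input_dir, out_dir = out_dir,
                 densities = densities, fd_threshold = fd_threshold,
                 min_frames = min_frames, band = band, n_boot = n_boot,
                 min_nodes = min_nodes,
                 pc_variant = match.arg(pc_variant),
                 include_default_system = include_default_system,
                 seed = seed),
            class = "netsel_config")
}

read_input_cohort <- function(input_dir) {
  ages <- utils::read.delim(file.path(input_dir, "ages.tsv"),
                            colClasses = c("character", "numeric"))
  participants <- lapply(ages$participant, function(id) {
    list(ts = read_timeseries_tsv(file.path(input_dir,
                                            paste0(id, "_ts.tsv"))),
         motion = read_timeseries_tsv(file.path(input_dir,
                                                paste0(id, "_motion.tsv"))),
         betas = read_betas_tsv(file.path(input_dir,
                                          paste0(id, "_betas.tsv"))),
         age = ages$age[ages$participant == id])
  })
  names(participants) <- ages$participant
  list(participants = participants,
       reference = read_partition_tsv(file.path(input_dir,
                                                "reference_partition.tsv")))
}

#' Run the full analysis pipeline
#'
#' Executes simulate/ingest, preprocessing (nuisance regression, band-pass,
#' FD scrubbing with interpolation and refiltering), Fisher-z graph
#' construction, bootstrap consensus community assignment across edge
#' densities, density-summed participation coefficients with connector
#' classification on the group-mean graph, per-participant activation
#' selectivity (all-node and per system type), and the cohort summary.
#' Participants failing the minimum-frames rule are excluded and listed in
#' the manifest. Result artifacts are written to `config$out_dir` and are
#' byte-identical across runs with identical config and seed (stage timings
#' go to `run_log.txt`, which is informational only).
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a result bundle: `consensus`, `topology` (group node
#'   table), `scores` (per participant/task/scope), `summary`, `ages`,
#'   `excluded`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "netsel_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log_lines <- character()
  stage <- function(msg) {
    log_lines <<- c(log_lines,
                    sprintf("[%+8.1fs] %s",
                            as.numeric(difftime(Sys.time(), t0, units = "secs")),
                            msg))
  }

  set.seed(config$seed)
  sub_seeds <- sample.int(.Machine$integer.max, 2)  # simulate, consensus

  # --- simulate or ingest -------------------------------------------------
  if (!is.null(config$cohort)) {
    cohort <- generate_cohort(config$cohort, sub_seeds[1])
    participants <- cohort$participants
    reference <- reference_partition(config$cohort)
    ages <- stats::setNames(config$cohort$age_grid, names(participants))
    truth <- lapply(participants, `[[`, "truth")
  } else {
    inp <- read_input_cohort(config$input_dir)
    participants <- inp$participants
    reference <- inp$reference
    ages <- stats::setNames(vapply(participants, `[[`, 0, "age"),
                            names(participants))
    truth <- NULL
  }
  stage(sprintf("cohort ready: %d participants", length(participants)))

  # --- preprocess ---------------------------------------------------------
  tr <- if (!is.null(config$cohort)) config$cohort$tr_seconds else 2
  excluded <- character()
  z_raw <- list()   # negatives retained, for group averaging
  z_ind <- list()   # negatives removed, for participant-level PC
  for (id in names(participants)) {
    p <- participants[[id]]
    fd <- compute_fd(p$motion)
    res <- tryCatch(
      clean_rsfc(p$ts, friston24(p$motion), fd,
                 fd_threshold = config$fd_threshold,
                 min_frames = config$min_frames, tr_seconds = tr,
                 low_hz = config$band[1], high_hz = config$band[2]),
      netsel_exclusion = function(e) e)
    if (inherits(res, "netsel_exclusion")) {
      excluded <- c(excluded, id)
      next
    }
    z_raw[[id]] <- correlation_zmatrix(res, drop_negatives = FALSE)
    z_ind[[id]] <- correlation_zmatrix(res, drop_negatives = TRUE)
  }
  stage(sprintf("preprocessing done: %d kept, %d excluded",
                length(z_raw), length(excluded)))
  if (length(z_raw) == 0) {
    manifest <- list(config = manifest_config(config),
                     excluded = excluded, n_analyzable = 0)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
    return(invisible(list(consensus = NULL, topology = NULL, scores = NULL,
                          summary = NULL, ages = ages, excluded = excluded,
                          manifest = manifest)))
  }

  # --- consensus communities ----------------------------------------------
  consensus <- consensus_assignment(z_raw, config$densities, config$n_boot,
                                    reference, seed = sub_seeds[2],
                                    min_nodes = config$min_nodes)
  write_consensus_tsv(consensus, file.path(config$out_dir, "consensus.tsv"))
  stage("consensus assignment done")

  # --- group topology -----------------------------------------------------
  z_group <- mean_zmatrix(z_raw, drop_negatives = TRUE)
  topology <- node_topology(z_group, consensus, config$densities,
                            variant = config$pc_variant)
  write_table_tsv(topology, file.path(config$out_dir, "topology.tsv"))
  stage("group node topology done")

  # --- participant selectivity --------------------------------------------
  modal <- consensus_modal_system(consensus)
  scores <- list()
  for (id in names(z_ind)) {
    sp <- summed_pc(z_ind[[id]], consensus, config$densities,
                    variant = config$pc_variant)
    betas <- participants[[id]]$betas
    for (tk in unique(betas$task)) {
      b <- betas[betas$task == tk, ]
      all_sc <- selectivity_score(sp$pc_sum, b, modal,
                                  include_default = config$include_default_system)
      rows <- data.frame(participant = id, task = tk, scope = "all",
                         score = all_sc$score, n_nodes = all_sc$n_nodes,
                         stringsAsFactors = FALSE)
      by_type <- tryCatch(system_type_selectivity(sp$pc_sum, b, modal),
                          error = function(e) NULL)
      if (!is.null(by_type))
        rows <- rbind(rows, data.frame(participant = id, task = tk,
                                       scope = by_type$scope,
                                       score = by_type$score,
                                       n_nodes = by_type$n_nodes,
                                       stringsAsFactors = FALSE))
      scores[[paste(id, tk)]] <- rows
    }
  }
  scores <- do.call(rbind, scores)
  rownames(scores) <- NULL
  write_table_tsv(scores, file.path(config$out_dir, "scores.tsv"))
  stage("participant selectivity done")

  # --- cohort summary -----------------------------------------------------
  summary_df <- if (length(unique(scores$participant)) >= 4 &&
                    stats::sd(ages[unique(scores$participant)]) > 0)
    cohort_summary(scores, ages) else NULL
  if (!is.null(summary_df)) {
    sj <- summary_df; attr(sj, "trend") <- NULL
    jsonlite::write_json(sj, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  manifest <- list(config = manifest_config(config),
                   excluded = excluded,
                   n_analyzable = length(z_raw),
                   artifacts = c("consensus.tsv", "topology.tsv",
                                 "scores.tsv",
                                 if (!is.null(summary_df)) "summary.json"))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  stage("pipeline complete")
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))

  invisible(list(consensus = consensus, topology = topology, scores = scores,
                 summary = summary_df, ages = ages, excluded = excluded,
                 truth = truth, manifest = manifest))
}

# resolved configuration for the manifest (cohort spec flattened; task specs
# summarized by their scalar fields); filesystem paths are omitted so the
# manifest depends only on the scientific configuration and seed
manifest_config <- function(config) {
  out <- unclass(config)
  out$out_dir <- NULL
  out$input_dir <- NULL
  if (!is.null(out$cohort)) {
    sp <- unclass(out$cohort)
    sp$task_specs <- lapply(sp$task_specs, unclass)
    out$cohort <- sp
  }
  out
}
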