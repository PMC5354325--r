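# Tab-delimited and JSON readers/writers. All numeric output is serialized
# at 17 significant digits with '.' decimal so that round-tripping is exact.

fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    s <- formatC(v, digits = 17, format = "g")
    gsub(" ", "", s)
  }, character(1))
  out
}

#' Write a numeric matrix as TSV with row/column identifiers
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @param row_label header of the identifier column.
#' @export
write_matrix_tsv <- function(m, path, row_label = "node_id") {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(c(row_label, colnames(m)), collapse = "\t"), con)
  for (i in seq_len(nrow(m)))
    writeLines(paste(c(rownames(m)[i], fmt_num(m[i, ])), collapse = "\t"),
               con)
  invisible(path)
}

#' Read a matrix written by [write_matrix_tsv()]
#'
#' @param path input path.
#' @return Numeric matrix with dimnames restored.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1]]
  m
}

#' Write a frames-by-nodes time series (or realignment trace) as TSV
#'
#' Tab-delimited UTF-8 with a header row of node IDs / parameter names.
#'
#' @param ts numeric matrix with column names.
#' @param path output path.
#' @export
write_timeseries_tsv <- function(ts, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(colnames(ts), collapse = "\t"), con)
  for (i in seq_len(nrow(ts)))
    writeLines(paste(fmt_num(ts[i, ]), collapse = "\t"), con)
  invisible(path)
}

#' Read a TSV time series written by [write_timeseries_tsv()]
#' @param path input path.
#' @return Numeric matrix.
#' @export
read_timeseries_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, colClasses = "character")
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  rownames(m) <- NULL
  m
}

#' Write per-node task beta estimates as TSV (node_id, task, beta)
#' @param betas data.frame node_id, task, beta.
#' @param path output path.
#' @export
write_betas_tsv <- function(betas, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("node_id\ttask\tbeta", con)
  writeLines(paste(betas$node_id, betas$task, fmt_num(betas$beta),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a beta table written by [write_betas_tsv()]
#' @param path input path.
#' @return data.frame node_id, task, beta.
#' @export
read_betas_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = c("character", "character",
                                         "character"))
  df$beta <- as.numeric(df$beta)
  df
}

#' Write a reference/system partition as TSV
#' @param partition data.frame node_id, system, system_type.
#' @param path output path.
#' @export
write_partition_tsv <- function(partition, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("node_id\tsystem\tsystem_type", con)
  writeLines(paste(partition$node_id, partition$system,
                   ifelse(is.na(partition$system_type), "NA",
                          partition$system_type), sep = "\t"), con)
  invisible(path)
}

#' Read a partition TSV (node_id, system, system_type)
#' @param path input path.
#' @return data.frame.
#' @export
read_partition_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  df$system_type[df$system_type == "NA"] <- NA_character_
  df
}

#' Write planted truth as JSON
#' @param truth a `netsel_truth`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(age = truth$age,
              partition = truth$partition,
              roles = as.list(truth$roles),
              partner_system = as.list(truth$partner_system),
              planted_selectivity = as.list(truth$planted_selectivity))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a consensus assignment as long-format TSV
#' @param consensus a `netsel_consensus`.
#' @param path output path.
#' @export
write_consensus_tsv <- function(consensus, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("node_id\tdensity\tsystem\tagreement\ttied", con)
  for (d in seq_along(consensus$densities))
    writeLines(paste(consensus$node_id,
                     fmt_num(rep(consensus$densities[d],
                                 length(consensus$node_id))),
                     consensus$labels[, d],
                     fmt_num(consensus$agreement[, d]),
                     ifelse(consensus$tied[, d], "1", "0"),
                     sep = "\t"), con)
  invisible(path)
}

#' Write a generic data.frame as TSV with numeric columns at full precision
#' @param df data.frame.
#' @param path output path.
#' @export
write_table_tsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(names(df), collapse = "\t"), con)
  cols <- lapply(df, function(x) if (is.numeric(x)) fmt_num(x)
                 else as.character(x))
  writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}
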