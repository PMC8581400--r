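#' @importFrom utils write.table read.delim modifyList
NULL

#' Read and validate a pipeline run configuration
#'
#' Run configurations are YAML (or JSON) with the fields used by
#' [runSimulate()], [runCall()] and [runAnalyze()]:
#'
#' ```yaml
#' reference_fasta: refs.fa       # donor + acceptor switch regions
#' donor: Smu
#' output_dir: out
#' thresholds: {min_identity: 0.90, min_length: 40}
#' motif: {pattern: WRCY, strands: both}
#' primers: {forward: ACGT..., reverse: ...}   # optional, exact-match trim
#' simulate:                       # for runSimulate()
#'   n_reads: 1000
#'   error_rate: 0.005
#'   seed: 1
#'   ...                           # any simConfig() argument
#' groups:                         # label -> FASTQ/FASTA read files
#'   WT: [wt.fastq]
#'   AID: [aid.fastq]
#' analysis: {n_permutations: 100000, n_random: 4000, seed: 1}
#' ```
#'
#' @param path Path to a YAML/JSON configuration file.
#' @param seed_override Optional integer replacing every seed in the config.
#' @return The validated configuration list (class `RunConfig`).
#' @export
readRunConfig <- function(path, seed_override = NULL) {
  if (!file.exists(path))
    stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validateRunConfig(cfg, seed_override)
}

#' @rdname readRunConfig
#' @param config A configuration list.
#' @export
validateRunConfig <- function(config, seed_override = NULL) {
  if (is.null(config$reference_fasta))
    stop("config needs 'reference_fasta'", call. = FALSE)
  if (!file.exists(config$reference_fasta))
    stop(sprintf("reference FASTA not found: %s", config$reference_fasta),
         call. = FALSE)
  if (is.null(config$donor))
    stop("config needs 'donor' (name of the donor region)", call. = FALSE)
  if (is.null(config$output_dir))
    stop("config needs 'output_dir'", call. = FALSE)
  config$thresholds <- modifyList(list(min_identity = 0.90, min_length = 40L),
                                  config$thresholds %||% list())
  config$motif <- modifyList(list(pattern = "WRCY", strands = "both"),
                             config$motif %||% list())
  config$analysis <- modifyList(list(n_permutations = 100000L,
                                     n_random = 4000L, seed = 1L),
                                config$analysis %||% list())
  if (!is.null(seed_override)) {
    config$analysis$seed <- as.integer(seed_override)
    if (!is.null(config$simulate)) config$simulate$seed <-
        as.integer(seed_override)
  }
  if (!is.null(config$groups)) {
    if (is.null(names(config$groups)) || any(names(config$groups) == ""))
      stop("'groups' must map labels to read files", call. = FALSE)
  }
  class(config) <- c("RunConfig", class(config))
  config
}

.loadRegions <- function(config) {
  readSwitchRegions(config$reference_fasta, donor = config$donor,
                    min_length = config$thresholds$min_length)
}

.configHash <- function(config) rlang::hash(unclass(config))

.tsvHeader <- function(config, seed, extra = character()) {
  c("# switchJunctions output; coordinates: 0-based, half-open; breakpoints donor-maximal (1-based inclusive = value + 1)",
    sprintf("# config_hash: %s", .configHash(config)),
    sprintf("# seed: %s", paste(seed, collapse = ",")),
    extra)
}

.writeTSV <- function(df, path, header) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a junctions/clusters/truth TSV written by the pipeline
#'
#' @param path TSV path (comment lines starting with `#` are skipped).
#' @return A `data.frame`.
#' @export
readJunctionsTSV <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
             colClasses = NA)
}

#' Trim primer sequences from reads
#'
#' Exact-match trimming: a forward primer is removed when it is a literal
#' prefix of the read, a reverse primer when it is a literal suffix. Reads
#' without the primer are left unchanged (primers are metadata, not a
#' filter).
#'
#' @param reads A [Biostrings::DNAStringSet] or character vector.
#' @param forward,reverse Primer sequences (or `NULL`).
#' @return A `DNAStringSet`.
#' @export
trimPrimers <- function(reads, forward = NULL, reverse = NULL) {
  s <- as.character(reads)
  if (!is.null(forward) && nzchar(forward)) {
    fw <- toupper(forward)
    has <- startsWith(s, fw)
    s[has] <- substring(s[has], nchar(fw) + 1L)
  }
  if (!is.null(reverse) && nzchar(reverse)) {
    rv <- toupper(reverse)
    has <- endsWith(s, rv)
    s[has] <- substring(s[has], 1L, nchar(s[has]) - nchar(rv))
  }
  DNAStringSet(setNames(s, names(reads)))
}

# tolerant FASTQ/FASTA loading: malformed FASTQ records are skipped with a
# warning rather than aborting the sample
.readReads <- function(path) {
  if (!file.exists(path))
    stop(sprintf("read file not found: %s", path), call. = FALSE)
  if (file.size(path) == 0L)
    return(list(reads = DNAStringSet(), skipped = 0L))
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  res <- tryCatch(readDNAStringSet(path, format = fmt),
                  error = function(e) NULL)
  if (!is.null(res)) return(list(reads = res, skipped = 0L))
  if (fmt == "fasta")
    stop(sprintf("could not parse FASTA file %s", path), call. = FALSE)
  lines <- readLines(path)
  nrec <- length(lines) %/% 4L
  keep <- character()
  ids <- character()
  skipped <- 0L
  for (r in seq_len(nrec)) {
    block <- lines[(4L * (r - 1L) + 1L):(4L * r)]
    ok <- startsWith(block[1], "@") && startsWith(block[3], "+") &&
      nchar(block[2]) == nchar(block[4]) &&
      !grepl("[^ACGTNacgtn]", block[2])
    if (!ok) { skipped <- skipped + 1L; next }
    ids <- c(ids, sub("\\s.*$", "", substring(block[1], 2L)))
    keep <- c(keep, toupper(block[2]))
  }
  if (length(lines) %% 4L != 0L) skipped <- skipped + 1L
  warning(sprintf("%s: skipped %d malformed FASTQ record(s)", path, skipped),
          call. = FALSE)
  list(reads = DNAStringSet(setNames(keep, ids)), skipped = skipped)
}

#' Simulate reads as a pipeline step
#'
#' Config-driven wrapper around [simulateJunctionReads()]: validates the
#' configuration (nothing is written on a validation failure), simulates,
#' and writes `<label>.fastq`, `<label>.truth.tsv` and a
#' `<label>.manifest.json` embedding the config hash and seed to the output
#' directory.
#'
#' @param config A [readRunConfig()] configuration (or path to one).
#' @param label File-name prefix (default `"sim"`).
#' @return Invisibly, the written paths.
#' @export
runSimulate <- function(config, label = "sim") {
  if (is.character(config)) config <- readRunConfig(config)
  config <- validateRunConfig(config)
  regions <- .loadRegions(config)
  simargs <- config$simulate %||% list()
  if (!is.null(simargs$structure_mix))
    simargs$structure_mix <- unlist(simargs$structure_mix)
  cfg <- do.call(simConfig, simargs)
  mi <- scanMotif(regions, motif = config$motif$pattern,
                  strands = config$motif$strands)
  sim <- simulateJunctionReads(regions, cfg, motif_index = mi)

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  fq <- file.path(config$output_dir, paste0(label, ".fastq"))
  tt <- file.path(config$output_dir, paste0(label, ".truth.tsv"))
  mf <- file.path(config$output_dir, paste0(label, ".manifest.json"))
  writeXStringSet(sim$reads, fq, format = "fastq", qualities = sim$qualities)
  .writeTSV(sim$truth, tt, .tsvHeader(config, cfg$seed))
  jsonlite::write_json(list(command = "simulate", label = label,
                            config_hash = .configHash(config),
                            seed = cfg$seed,
                            n_reads = cfg$n_reads,
                            files = list(fastq = basename(fq),
                                         truth = basename(tt))),
                       mf, auto_unbox = TRUE, pretty = TRUE)
  message(sprintf("simulate[%s]: wrote %d reads (%d junction, %d germline)",
                  label, nrow(sim$truth), sum(!sim$truth$is_germline),
                  sum(sim$truth$is_germline)))
  invisible(c(fastq = fq, truth = tt, manifest = mf))
}

#' Call junctions as a pipeline step
#'
#' For every group in `config$groups`, reads the sample's FASTQ/FASTA
#' file(s), optionally trims configured primers, calls junctions with the
#' configured thresholds, clusters them, and writes
#' `<label>.junctions.tsv` and `<label>.clusters.tsv`. The log records, per
#' sample, the total read count, junction-positive count and cluster count.
#'
#' @param config A [readRunConfig()] configuration (or path to one).
#' @return Invisibly, a named list of `list(calls, clusters)` per group.
#' @export
runCall <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- validateRunConfig(config)
  if (is.null(config$groups))
    stop("config needs 'groups' (label -> read files) for the call stage",
         call. = FALSE)
  for (files in config$groups)
    for (f in files) if (!file.exists(f))
      stop(sprintf("read file not found: %s", f), call. = FALSE)
  regions <- .loadRegions(config)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)

  out <- list()
  for (lab in names(config$groups)) {
    reads <- DNAStringSet()
    nskip <- 0L
    for (f in config$groups[[lab]]) {
      got <- .readReads(f)
      reads <- c(reads, got$reads)
      nskip <- nskip + got$skipped
    }
    reads <- trimPrimers(reads, config$primers$forward,
                         config$primers$reverse)
    calls <- callJunctions(reads, regions,
                           min_identity = config$thresholds$min_identity,
                           min_length = config$thresholds$min_length)
    clusters <- clusterJunctions(calls)
    jt <- file.path(config$output_dir, paste0(lab, ".junctions.tsv"))
    ct <- file.path(config$output_dir, paste0(lab, ".clusters.tsv"))
    extra <- sprintf("# sample: %s; reads: %d; junction_reads: %d; clusters: %d; skipped_records: %d",
                     lab, length(reads), nrow(calls), nrow(clusters), nskip)
    .writeTSV(calls, jt, .tsvHeader(config, config$analysis$seed, extra))
    .writeTSV(clusters, ct, .tsvHeader(config, config$analysis$seed, extra))
    if (nrow(calls) == 0L)
      message(sprintf("call[%s]: %d reads, 0 junctions", lab, length(reads)))
    else
      message(sprintf(
        "call[%s]: %d reads, %d junction-positive, %d clusters%s", lab,
        length(reads), nrow(calls), nrow(clusters),
        if (nskip > 0L) sprintf(" (%d records skipped)", nskip) else ""))
    out[[lab]] <- list(calls = calls, clusters = clusters)
  }
  invisible(out)
}

#' Analyze called junctions as a pipeline step
#'
#' Reads the per-group junction tables written by [runCall()] from the
#' output directory (or from `config$analysis$junction_files`), builds the
#' [compareGroupsReport()], and writes it as `analysis.json`. Groups with
#' zero clusters are excluded from tests and noted in the report.
#'
#' @param config A [readRunConfig()] configuration (or path to one).
#' @return Invisibly, the report.
#' @export
runAnalyze <- function(config) {
  if (is.character(config)) config <- readRunConfig(config)
  config <- validateRunConfig(config)
  regions <- .loadRegions(config)
  files <- config$analysis$junction_files
  if (is.null(files)) {
    if (is.null(config$groups))
      stop("config needs 'groups' or 'analysis$junction_files'", call. = FALSE)
    files <- setNames(file.path(config$output_dir,
                                paste0(names(config$groups), ".junctions.tsv")),
                      names(config$groups))
  }
  for (f in files) if (!file.exists(f))
    stop(sprintf("junction table not found: %s (run the call stage first)", f),
         call. = FALSE)
  group_calls <- lapply(files, readJunctionsTSV)
  mi <- scanMotif(regions, motif = config$motif$pattern,
                  strands = config$motif$strands)
  rep_ <- compareGroupsReport(group_calls, regions, motif_index = mi,
                              n_random = config$analysis$n_random,
                              n_permutations = config$analysis$n_permutations,
                              seed = config$analysis$seed)
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- file.path(config$output_dir, "analysis.json")
  payload <- unclass(rep_)
  payload$config_hash <- .configHash(config)
  jsonlite::write_json(payload, out, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", force = TRUE)
  message(sprintf("analyze: report for %d group(s) -> %s",
                  length(group_calls), out))
  invisible(rep_)
}
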