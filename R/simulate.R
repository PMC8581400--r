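#' @importFrom stats rnorm runif rbinom
NULL

BASES <- c("A", "C", "G", "T")

# default length distributions: truncated geometric over 1..10 nt, matching
# the short (1-3 nt mean) microhomologies and insertions seen at CSR joints
.truncGeom <- function(p, kmax = 10L) {
  w <- p * (1 - p)^(seq_len(kmax) - 1L)
  w / sum(w)
}

#' Configuration for the junction-read simulator
#'
#' Validates and bundles the parameters of [simulateJunctionReads()]. The
#' defaults emulate the study conditions the pipeline targets: 200-bp
#' amplicon reads spanning an Smu donor / S-acceptor junction, a structure
#' mix of 0.3 blunt / 0.5 microhomology / 0.2 insertion, short (geometric,
#' 1-10 nt) microhomology and insertion lengths, and a 0.5% per-base
#' substitution sequencing-error rate.
#'
#' @param n_reads Number of reads to emit.
#' @param read_length Read length in nt (default 200). Must be at least
#'   twice the minimum alignment length so both junction sides can clear the
#'   length floor.
#' @param break_model `"uniform"` (breaks uniform over eligible donor
#'   positions) or `"motif_anchored"` (a motif-covered base plus a Gaussian
#'   offset with sd `decay_sd`, clamped to the eligible range).
#' @param decay_sd Gaussian sd (nt) for `motif_anchored` placement.
#' @param structure_mix Named probabilities over
#'   `c(blunt, microhomology, insertion)`; must sum to 1.
#' @param mh_length_probs Probabilities over microhomology lengths 1..K.
#' @param insertion_length_probs Probabilities over insertion lengths 1..K.
#' @param error_rate Per-base substitution probability, in \[0, 0.2\].
#' @param germline_fraction Fraction of junction-free donor-only control
#'   reads.
#' @param seed Integer RNG seed; identical configurations yield
#'   byte-identical reads and truth tables.
#' @param min_length Minimum alignment length the downstream caller will
#'   apply (used only for validity checks; default 40).
#' @return A validated list of class `SimConfig`.
#' @export
simConfig <- function(n_reads = 1000L,
                      read_length = 200L,
                      break_model = c("uniform", "motif_anchored"),
                      decay_sd = 1,
                      structure_mix = c(blunt = 0.3, microhomology = 0.5,
                                        insertion = 0.2),
                      mh_length_probs = .truncGeom(0.35),
                      insertion_length_probs = .truncGeom(0.40),
                      error_rate = 0.005,
                      germline_fraction = 0,
                      seed = 1L,
                      min_length = 40L) {
  break_model <- match.arg(break_model)
  cats <- c("blunt", "microhomology", "insertion")
  if (is.null(names(structure_mix)))
    names(structure_mix) <- cats
  structure_mix <- structure_mix[cats]
  if (anyNA(structure_mix) || any(structure_mix < 0))
    stop("structure_mix must give nonnegative probabilities for blunt, ",
         "microhomology and insertion", call. = FALSE)
  if (abs(sum(structure_mix) - 1) > 1e-9)
    stop("structure_mix must sum to 1", call. = FALSE)
  if (error_rate < 0 || error_rate > 0.2)
    stop("error_rate must lie in [0, 0.2]", call. = FALSE)
  if (read_length < 2L * min_length)
    stop(sprintf(
      "read_length %d is too short for the alignment thresholds (need >= %d)",
      read_length, 2L * min_length), call. = FALSE)
  if (germline_fraction < 0 || germline_fraction > 1)
    stop("germline_fraction must lie in [0, 1]", call. = FALSE)
  if (n_reads < 0L) stop("n_reads must be >= 0", call. = FALSE)
  if (decay_sd < 0) stop("decay_sd must be >= 0", call. = FALSE)
  stopifnot(all(mh_length_probs >= 0), sum(mh_length_probs) > 0,
            all(insertion_length_probs >= 0), sum(insertion_length_probs) > 0)
  structure(list(n_reads = as.integer(n_reads),
                 read_length = as.integer(read_length),
                 break_model = break_model,
                 decay_sd = decay_sd,
                 structure_mix = structure_mix,
                 mh_length_probs = mh_length_probs / sum(mh_length_probs),
                 insertion_length_probs =
                   insertion_length_probs / sum(insertion_length_probs),
                 error_rate = error_rate,
                 germline_fraction = germline_fraction,
                 seed = as.integer(seed),
                 min_length = as.integer(min_length)),
            class = "SimConfig")
}

#' @export
print.SimConfig <- function(x, ...) {
  cat(sprintf(
    paste0("SimConfig: %d reads of %d nt, break model %s%s,\n",
           "  mix blunt/mh/ins = %.2f/%.2f/%.2f, error rate %.3g, ",
           "germline fraction %.2f, seed %d\n"),
    x$n_reads, x$read_length, x$break_model,
    if (x$break_model == "motif_anchored")
      sprintf(" (sd %.1f nt)", x$decay_sd) else "",
    x$structure_mix[1], x$structure_mix[2], x$structure_mix[3],
    x$error_rate, x$germline_fraction, x$seed))
  invisible(x)
}

#' Sample donor break positions
#'
#' Draws 0-based break positions in a region, either uniformly over the
#' eligible range or anchored on degenerate-motif occurrences with a
#' Gaussian offset (`decay_sd = 0` places every break exactly on a
#' motif-covered base). Sampling uses the current RNG state unless `seed`
#' is given.
#'
#' @param region_length Length of the region in nt.
#' @param n Number of breaks.
#' @param model `"uniform"` or `"motif_anchored"`.
#' @param motif_index A [MotifIndex] (required for `motif_anchored`).
#' @param decay_sd Gaussian sd in nt.
#' @param eligible Integer `c(lo, hi)` 0-based inclusive eligible range
#'   (default the whole region).
#' @param seed Optional RNG seed.
#' @return Integer vector of 0-based positions.
#' @export
sampleBreakPositions <- function(region_length, n,
                                 model = c("uniform", "motif_anchored"),
                                 motif_index = NULL, decay_sd = 1,
                                 eligible = NULL, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(eligible)) eligible <- c(0L, region_length - 1L)
  lo <- eligible[1]; hi <- eligible[2]
  stopifnot(lo >= 0L, hi < region_length, lo <= hi)
  if (n <= 0L) stop("n must be positive", call. = FALSE)
  if (model == "uniform")
    return(lo + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L)
  if (is.null(motif_index))
    stop("motif_anchored break model needs a motif index", call. = FALSE)
  cov <- .coveredBases(motif_index)
  cov <- cov[cov >= lo & cov <= hi]
  if (length(cov) == 0L)
    stop("motif index has no occurrences in the eligible range", call. = FALSE)
  anchors <- cov[sample.int(length(cov), n, replace = TRUE)]
  pos <- anchors + as.integer(round(rnorm(n, 0, decay_sd)))
  pmin(pmax(pos, lo), hi)
}

# Short-window score guard on both joint diagonals: the emitted joint is
# locally unambiguous iff chance homology just beyond the normalized joint
# keeps a strictly negative +1/-2 running score within the window (the
# walk's value is congruent to its step count mod 3, so staying < 0 for the
# window bounds it away from 0 essentially forever). Without this a caller
# could legitimately extend a segment to or past the recorded breakpoint,
# making exact truth recovery ill-posed.
.jointClean <- function(rchars, dchars, achars, db, ab, Ld, g, mh, W = 15L) {
  L <- length(rchars)
  o_d <- db - (Ld - 1L)
  cum <- 0L; p <- Ld
  steps <- 0L
  while (steps < W && p < L && (p + o_d) < length(dchars)) {
    cum <- cum + if (rchars[p + 1L] == dchars[p + o_d + 1L]) 1L else -2L
    if (cum >= 0L) return(FALSE)
    p <- p + 1L; steps <- steps + 1L
  }
  p_fa <- Ld + g
  o_a <- ab - p_fa
  cum <- 0L; p <- p_fa - mh - 1L
  steps <- 0L
  while (steps < W && p >= 0L && (p + o_a) >= 0L) {
    cum <- cum + if (rchars[p + 1L] == achars[p + o_a + 1L]) 1L else -2L
    if (cum >= 0L) return(FALSE)
    p <- p - 1L; steps <- steps + 1L
  }
  TRUE
}

#' Simulate junction amplicon reads with a ground-truth table
#'
#' Emits reads spanning a donor->acceptor CSR junction plus (optionally)
#' junction-free germline control reads, with a truth table recording every
#' read's breakpoints and repair structure under the same donor-maximal
#' convention the caller reports.
#'
#' Each junction read is a donor suffix-context ending at `donor_break`,
#' then (for an insertion) untemplated bases, then acceptor context from
#' `acceptor_break`. A microhomology-k junction is placed only where a k-nt
#' block immediately left of the joint is genuinely identical in both
#' references (acceptor positions are searched for the donor's junction
#' k-mer; if none exists for a sampled k, k is resampled). Joints are
#' emitted only where they are locally unambiguous: blunt joints do not
#' extend into either reference, insertion bases match neither reference on
#' its local diagonal ("untemplated" in the strict sense), and a short
#' score-window guard excludes chance near-joint homology between the two
#' references beyond the recorded microhomology. Truth breakpoints are
#' therefore exactly the convention-normalized breakpoints of each read.
#'
#' Donor break positions follow `config$break_model`; acceptor break
#' positions are uniform over acceptor positions compatible with the
#' structure. Substitution errors are applied last at `config$error_rate`.
#' Quality strings are constant Q30 placeholders. The whole simulation is
#' reproducible from `config$seed`.
#'
#' @param regions A [SwitchRegionSet].
#' @param config A [simConfig()] object.
#' @param motif_index A [MotifIndex] on the donor (required for the
#'   `motif_anchored` break model).
#' @return A list of class `JunctionSimulation`: `reads` (named
#'   [Biostrings::DNAStringSet]), `qualities` ([Biostrings::BStringSet]),
#'   `truth` (`data.frame` with `read_id`, `donor_break`, `acceptor_name`,
#'   `acceptor_break`, `structure`, `mh_len`, `insertion_seq`,
#'   `is_germline`), and `config`.
#' @export
simulateJunctionReads <- function(regions, config = simConfig(),
                                  motif_index = NULL) {
  stopifnot(is(regions, "SwitchRegionSet"), inherits(config, "SimConfig"))
  if (config$break_model == "motif_anchored" && is.null(motif_index))
    motif_index <- scanMotif(regions)
  withr::local_seed(config$seed)

  L <- config$read_length
  Ld <- L %/% 2L
  dname <- donorName(regions)
  dchars <- strsplit(as.character(regions[[dname]]), "")[[1]]
  accs <- lapply(acceptorNames(regions),
                 function(a) strsplit(as.character(regions[[a]]), "")[[1]])
  names(accs) <- acceptorNames(regions)
  if (length(dchars) < L)
    stop("donor region shorter than the read length", call. = FALSE)
  if (any(vapply(accs, length, 1L) < L))
    stop("acceptor region(s) shorter than the read length", call. = FALSE)

  n <- config$n_reads
  ids <- sprintf("read_%05d", seq_len(n))
  out_reads <- character(n)
  truth <- data.frame(read_id = ids,
                      donor_break = rep(NA_integer_, n),
                      acceptor_name = rep(NA_character_, n),
                      acceptor_break = rep(NA_integer_, n),
                      structure = rep(NA_character_, n),
                      mh_len = rep(NA_integer_, n),
                      insertion_seq = rep("", n),
                      is_germline = rep(FALSE, n),
                      stringsAsFactors = FALSE)
  if (n == 0L) {
    return(structure(list(reads = DNAStringSet(), qualities = BStringSet(),
                          truth = truth, config = config),
                     class = "JunctionSimulation"))
  }

  is_germ <- runif(n) < config$germline_fraction
  elig <- c(Ld - 1L, length(dchars) - 1L)
  cats <- c("blunt", "microhomology", "insertion")
  structs <- sample(cats, n, replace = TRUE, prob = config$structure_mix)
  gmax <- L - Ld - (config$min_length + 1L)

  for (i in seq_len(n)) {
    if (is_germ[i]) {
      s <- sample.int(length(dchars) - L + 1L, 1L) - 1L
      out_reads[i] <- paste(dchars[(s + 1L):(s + L)], collapse = "")
      truth$is_germline[i] <- TRUE
      next
    }
    anm <- if (length(accs) == 1L) names(accs) else
      names(accs)[sample.int(length(accs), 1L)]
    achars <- accs[[anm]]
    db <- .sampleOneBreak(config, length(dchars), elig, motif_index)
    jr <- .placeJunction(structs[i], db, dchars, achars, config, L, Ld, gmax,
                         elig, motif_index)
    out_reads[i] <- jr$read
    truth$donor_break[i] <- jr$db
    truth$acceptor_name[i] <- anm
    truth$acceptor_break[i] <- jr$ab
    truth$structure[i] <- jr$structure
    truth$mh_len[i] <- jr$mh
    truth$insertion_seq[i] <- jr$ins
  }

  reads <- DNAStringSet(out_reads)
  names(reads) <- ids
  if (config$error_rate > 0)
    reads <- addSequencingErrors(reads, config$error_rate)
  quals <- BStringSet(rep(strrep("?", L), n))  # constant Q30
  names(quals) <- ids
  structure(list(reads = reads, qualities = quals, truth = truth,
                 config = config),
            class = "JunctionSimulation")
}

.sampleOneBreak <- function(config, dlen, elig, motif_index) {
  sampleBreakPositions(dlen, 1L, model = config$break_model,
                       motif_index = motif_index,
                       decay_sd = config$decay_sd, eligible = elig)
}

# place one junction of the requested structure at donor break db,
# resampling the acceptor side (and, for microhomology, k and db) until the
# joint is realizable and locally unambiguous
.placeJunction <- function(structure_, db, dchars, achars, config, L, Ld,
                           gmax, elig, motif_index) {
  for (try_ in seq_len(400L)) {
    res <- switch(structure_,
      blunt = .tryBlunt(db, dchars, achars, L, Ld),
      microhomology = .tryMH(db, dchars, achars, config, L, Ld),
      insertion = .tryInsertion(db, dchars, achars, config, L, Ld, gmax))
    if (!is.null(res)) return(res)
    # resample the donor break and retry
    db <- .sampleOneBreak(config, length(dchars), elig, motif_index)
  }
  stop(sprintf("could not place a %s junction after 400 attempts", structure_),
       call. = FALSE)
}

.tryBlunt <- function(db, dchars, achars, L, Ld) {
  La <- L - Ld
  abmax <- length(achars) - La
  for (t in seq_len(50L)) {
    ab <- sample.int(abmax + 1L, 1L) - 1L
    if (db + 1L < length(dchars) && achars[ab + 1L] == dchars[db + 2L]) next
    if (ab > 0L && achars[ab] == dchars[db + 1L]) next
    rchars <- c(dchars[(db - Ld + 2L):(db + 1L)],
                achars[(ab + 1L):(ab + La)])
    if (!.jointClean(rchars, dchars, achars, db, ab, Ld, 0L, 0L)) next
    return(list(read = paste(rchars, collapse = ""), db = db, ab = ab,
                structure = "blunt", mh = 0L, ins = ""))
  }
  NULL
}

.tryMH <- function(db, dchars, achars, config, L, Ld) {
  La <- L - Ld
  abmax <- length(achars) - La
  astr <- paste(achars, collapse = "")
  ks <- sample.int(length(config$mh_length_probs), 8L, replace = TRUE,
                   prob = config$mh_length_probs)
  for (k in ks) {
    if (db - k + 1L < db - Ld + 2L || db - k + 1L < 1L) next
    kmer <- paste(dchars[(db - k + 2L):(db + 1L)], collapse = "")
    hits <- gregexpr(kmer, astr, fixed = TRUE)[[1]]
    if (hits[1] == -1L) next
    ab_cand <- (hits - 1L) + k          # 0-based first base after the block
    ab_cand <- ab_cand[ab_cand >= k & ab_cand <= abmax]
    # maximality: the shared block must not extend on either side
    keep <- vapply(ab_cand, function(ab) {
      leftok <- (ab - k == 0L) || (db - k < 0L) ||
        achars[ab - k] != dchars[db - k + 1L]
      rightok <- (db + 1L >= length(dchars)) ||
        achars[ab + 1L] != dchars[db + 2L]
      leftok && rightok
    }, logical(1))
    ab_cand <- ab_cand[keep]
    if (length(ab_cand) == 0L) next
    for (ab in ab_cand[sample.int(length(ab_cand))]) {
      rchars <- c(dchars[(db - Ld + 2L):(db + 1L)],
                  achars[(ab + 1L):(ab + La)])
      if (!.jointClean(rchars, dchars, achars, db, ab, Ld, 0L, k)) next
      return(list(read = paste(rchars, collapse = ""), db = db, ab = ab,
                  structure = "microhomology", mh = k, ins = ""))
    }
  }
  NULL
}

.tryInsertion <- function(db, dchars, achars, config, L, Ld, gmax) {
  probs <- config$insertion_length_probs
  kmax <- min(length(probs), gmax)
  if (kmax < 1L) stop("read too short for insertions", call. = FALSE)
  g <- sample.int(kmax, 1L, prob = probs[seq_len(kmax)])
  La <- L - Ld - g
  abmax <- length(achars) - La
  for (t in seq_len(50L)) {
    ab <- sample.int(abmax + 1L, 1L) - 1L
    # untemplated in the strict sense: each inserted base differs from both
    # references at its position on their local diagonals
    ins <- character(g)
    ok <- TRUE
    for (j in seq_len(g)) {
      excl <- character()
      if (db + j < length(dchars)) excl <- c(excl, dchars[db + j + 1L])
      if (ab - g + j - 1L >= 0L) excl <- c(excl, achars[ab - g + j])
      choices <- setdiff(BASES, excl)
      if (length(choices) == 0L) { ok <- FALSE; break }
      ins[j] <- choices[sample.int(length(choices), 1L)]
    }
    if (!ok) next
    rchars <- c(dchars[(db - Ld + 2L):(db + 1L)], ins,
                achars[(ab + 1L):(ab + La)])
    if (!.jointClean(rchars, dchars, achars, db, ab, Ld, g, 0L)) next
    return(list(read = paste(rchars, collapse = ""), db = db, ab = ab,
                structure = "insertion", mh = 0L,
                ins = paste(ins, collapse = "")))
  }
  NULL
}

#' Apply per-base substitution sequencing errors
#'
#' Each base is independently substituted, with probability `rate`, by a
#' base drawn uniformly from the three alternatives. `N` bases are left
#' untouched. Deterministic under a fixed seed.
#'
#' @param reads A [Biostrings::DNAStringSet] (or character vector).
#' @param rate Substitution probability per base, in \[0, 1\].
#' @param seed Optional RNG seed; if `NULL` the current RNG state is used.
#' @return A `DNAStringSet` of mutated reads (names preserved).
#' @export
addSequencingErrors <- function(reads, rate, seed = NULL) {
  stopifnot(rate >= 0, rate <= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  seqs <- as.character(reads)
  nms <- names(seqs)
  if (rate == 0 || length(seqs) == 0L)
    return(DNAStringSet(setNames(seqs, nms)))
  chars <- strsplit(seqs, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- runif(length(flat)) < rate & flat %in% BASES
  if (any(hit)) {
    orig <- match(flat[hit], BASES)
    # uniformly one of the three other bases
    shift <- sample.int(3L, sum(hit), replace = TRUE)
    flat[hit] <- BASES[((orig - 1L + shift) %% 4L) + 1L]
  }
  out <- vapply(split(flat, rep(seq_along(lens), lens)),
                paste, character(1), collapse = "")
  DNAStringSet(setNames(unname(out), nms))
}

#' Reconstruct the error-free read implied by a truth record
#'
#' Concatenates the reference contexts recorded in a simulator truth row;
#' with `error_rate = 0` this reproduces the emitted read exactly.
#'
#' @param truth_row One row of a [simulateJunctionReads()] truth table.
#' @param regions The [SwitchRegionSet] used for the simulation.
#' @param read_length Read length of the simulation.
#' @return A character string.
#' @export
reconstructRead <- function(truth_row, regions, read_length) {
  L <- as.integer(read_length)
  Ld <- L %/% 2L
  stopifnot(nrow(truth_row) == 1L, !truth_row$is_germline)
  d <- as.character(donorRegion(regions))
  a <- as.character(regions[[truth_row$acceptor_name]])
  db <- truth_row$donor_break
  ab <- truth_row$acceptor_break
  ins <- truth_row$insertion_seq
  g <- nchar(ins)
  La <- L - Ld - g
  paste0(substr(d, db - Ld + 2L, db + 1L), ins,
         substr(a, ab + 1L, ab + La))
}

#' @export
print.JunctionSimulation <- function(x, ...) {
  cat(sprintf("JunctionSimulation: %d reads (%d junction, %d germline)\n",
              nrow(x$truth), sum(!x$truth$is_germline),
              sum(x$truth$is_germline)))
  print(x$config)
  invisible(x)
}

#' Write simulated reads and truth table to disk
#'
#' Writes a FASTQ of the reads and a TSV truth table whose comment header
#' records the configuration hash and seed.
#'
#' @param sim A [simulateJunctionReads()] result.
#' @param fastq,truth_tsv Output paths.
#' @return Invisibly, the two paths.
#' @export
writeSimulatedReads <- function(sim, fastq, truth_tsv) {
  writeXStringSet(sim$reads, fastq, format = "fastq",
                  qualities = sim$qualities)
  hdr <- c(sprintf("# switchJunctions truth table; coordinates: 0-based"),
           sprintf("# seed: %d", sim$config$seed),
           sprintf("# config_hash: %s", rlang::hash(sim$config)))
  con <- file(truth_tsv, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(sim$truth, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fastq = fastq, truth_tsv = truth_tsv))
}
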