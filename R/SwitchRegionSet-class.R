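#' @import methods
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#'   reverseComplement matchPattern DNAString BStringSet
#' @importFrom S4Vectors mcols mcols<-
NULL

#' A set of switch-region reference sequences
#'
#' `SwitchRegionSet` holds the donor switch region (conventionally Smu) and
#' one or more acceptor switch regions (Sgamma, Salpha, ...) used for
#' class-switch recombination (CSR) junction calling. It extends
#' [Biostrings::DNAStringSet], so all the usual sequence accessors
#' (`names()`, `width()`, `[[`, ...) apply. Acceptor order follows the input
#' order and is used downstream as a deterministic tie-break when several
#' acceptors align a read equally well.
#'
#' Coordinates throughout the package are 0-based with half-open intervals;
#' human-readable displays additionally show 1-based inclusive positions.
#'
#' @slot donor Name of the single donor region.
#' @export
setClass("SwitchRegionSet",
  contains = "DNAStringSet",
  representation(donor = "character")
)

setValidity("SwitchRegionSet", function(object) {
  msg <- character()
  nm <- names(object)
  if (is.null(nm) || anyNA(nm) || any(nm == ""))
    msg <- c(msg, "all regions must be named")
  if (anyDuplicated(nm))
    msg <- c(msg, sprintf("duplicate region name(s): %s",
                          paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  if (length(object@donor) != 1L || is.na(object@donor))
    msg <- c(msg, "exactly one donor region must be named")
  else if (!object@donor %in% nm)
    msg <- c(msg, sprintf("donor region '%s' not present", object@donor))
  if (length(object) < 2L)
    msg <- c(msg, "need a donor and at least one acceptor region")
  bad <- vapply(seq_along(object), function(i) {
    s <- as.character(object[[i]])
    grepl("[^ACGTN]", s)
  }, logical(1))
  if (any(bad))
    msg <- c(msg, sprintf("region(s) with letters outside {A,C,G,T,N}: %s",
                          paste(nm[bad], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a SwitchRegionSet
#'
#' @param regions A named [Biostrings::DNAStringSet] (or named character
#'   vector) of switch-region sequences. Lowercase letters are upcased.
#' @param donor Name of the donor region (must match one record).
#' @param min_length Minimum admissible region length in nucleotides.
#'   Regions shorter than the minimum alignment length cannot anchor an
#'   accepted alignment segment, so loading fails for them (default 40).
#' @return A `SwitchRegionSet`.
#' @export
#' @examples
#' SwitchRegionSet(c(Smu = strrep("ACGT", 20), Sg1 = strrep("TGCA", 20)),
#'                 donor = "Smu")
SwitchRegionSet <- function(regions, donor, min_length = 40L) {
  if (is.character(regions)) regions <- DNAStringSet(toupper(regions))
  else regions <- DNAStringSet(toupper(as.character(regions)))
  if (missing(donor) || is.null(donor))
    stop("a donor region name must be supplied", call. = FALSE)
  if (!donor %in% names(regions))
    stop(sprintf("donor region '%s' not found among records: %s", donor,
                 paste(names(regions), collapse = ", ")), call. = FALSE)
  short <- Biostrings::width(regions) < min_length
  if (any(short))
    stop(sprintf("region(s) shorter than the %d-nt minimum: %s", min_length,
                 paste(names(regions)[short], collapse = ", ")), call. = FALSE)
  hasN <- vapply(seq_along(regions),
                 function(i) grepl("N", as.character(regions[[i]]), fixed = TRUE),
                 logical(1))
  if (any(hasN))
    warning(sprintf(
      "region(s) contain N bases (never matched by motif scans): %s",
      paste(names(regions)[hasN], collapse = ", ")), call. = FALSE)
  new("SwitchRegionSet", regions, donor = donor)
}

#' Read switch-region references from a FASTA file
#'
#' Record identifiers are the first whitespace-delimited token of each FASTA
#' header. Acceptor order is preserved from file order.
#'
#' @param file Path to a multi-record FASTA file.
#' @inheritParams SwitchRegionSet
#' @return A [SwitchRegionSet].
#' @export
#' @examples
#' fa <- system.file("extdata", "synthetic_sregions.fa",
#'                   package = "switchJunctions")
#' readSwitchRegions(fa, donor = "Smu")
readSwitchRegions <- function(file, donor, min_length = 40L) {
  if (!file.exists(file))
    stop(sprintf("reference FASTA not found: %s", file), call. = FALSE)
  x <- readDNAStringSet(file, format = "fasta")
  if (length(x) == 0L)
    stop(sprintf("no FASTA records in %s", file), call. = FALSE)
  names(x) <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(names(x)))
    stop(sprintf("duplicate record name(s) in %s: %s", file,
                 paste(unique(names(x)[duplicated(names(x))]), collapse = ", ")),
         call. = FALSE)
  SwitchRegionSet(x, donor = donor, min_length = min_length)
}

#' @describeIn SwitchRegionSet-accessors Name of the donor region.
#' @export
donorName <- function(x) {
  stopifnot(is(x, "SwitchRegionSet"))
  x@donor
}

#' Accessors for SwitchRegionSet
#'
#' @param x A [SwitchRegionSet].
#' @return `donorName()` a character scalar; `donorRegion()` a
#'   [Biostrings::DNAString]; `acceptorNames()` a character vector in locus
#'   order; `acceptorRegions()` a [Biostrings::DNAStringSet].
#' @name SwitchRegionSet-accessors
NULL

#' @describeIn SwitchRegionSet-accessors The donor sequence.
#' @export
donorRegion <- function(x) x[[donorName(x)]]

#' @describeIn SwitchRegionSet-accessors Acceptor names, input order preserved.
#' @export
acceptorNames <- function(x) setdiff(names(x), donorName(x))

#' @describeIn SwitchRegionSet-accessors The acceptor sequences.
#' @export
acceptorRegions <- function(x) {
  DNAStringSet(x[acceptorNames(x)])
}

setMethod("show", "SwitchRegionSet", function(object) {
  cat(sprintf("SwitchRegionSet with %d regions (donor: %s)\n",
              length(object), object@donor))
  for (nm in names(object)) {
    role <- if (nm == object@donor) "donor   " else "acceptor"
    cat(sprintf("  %s %-10s %6d nt\n", role, nm, length(object[[nm]])))
  }
})

#' Simulate synthetic switch-region reference sequences
#'
#' Generates random G-rich sequences standing in for immunoglobulin
#' switch-region references. Real S regions are repetitive, G-rich on the
#' non-template strand and dense in AID hotspot (WRCY) motifs; these
#' synthetic regions reproduce the base composition (and hence a realistic
#' WRCY density of roughly one motif per 10-15 nt) but are *not* repetitive,
#' so alignments against them are unambiguous. They are test references,
#' not biological annotations.
#'
#' @param donor_length Length of the donor region in nt (default 600).
#' @param acceptor_lengths Named integer vector of acceptor lengths
#'   (default `c(Sg1 = 500)`).
#' @param donor_name Name given to the donor region (default `"Smu"`).
#' @param seed Integer RNG seed; the result is reproducible.
#' @param base_probs Sampling probabilities for A, C, G, T. The default
#'   mimics the G-richness of switch regions.
#' @return A [SwitchRegionSet].
#' @export
#' @examples
#' regions <- simulateSwitchRegions(seed = 1)
#' regions
simulateSwitchRegions <- function(donor_length = 600L,
                                  acceptor_lengths = c(Sg1 = 500L),
                                  donor_name = "Smu",
                                  seed = 1L,
                                  base_probs = c(A = 0.22, C = 0.18,
                                                 G = 0.34, T = 0.26)) {
  stopifnot(donor_length >= 40L, all(acceptor_lengths >= 40L),
            !is.null(names(acceptor_lengths)))
  withr::local_seed(seed)
  draw <- function(n) paste(sample(names(base_probs), n, replace = TRUE,
                                   prob = base_probs), collapse = "")
  seqs <- c(draw(donor_length),
            vapply(acceptor_lengths, draw, character(1)))
  names(seqs) <- c(donor_name, names(acceptor_lengths))
  SwitchRegionSet(seqs, donor = donor_name)
}
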