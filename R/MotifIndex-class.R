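#' @importFrom GenomicRanges GRanges start end strand seqnames
#' @importFrom IRanges IRanges
NULL

IUPAC_CODES <- c(A = "A", C = "C", G = "G", T = "T",
                 R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
                 B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Index of degenerate-motif occurrences in a switch region
#'
#' Holds all positions where a degenerate IUPAC pattern (default the AID
#' hotspot motif `WRCY`; W = A/T, R = A/G, Y = C/T) occurs in a reference
#' region, on the plus strand and optionally on the minus strand (a
#' minus-strand hit means the reverse complement of the window matches, i.e.
#' the plus strand reads the reverse-complement motif, `RGYW` for `WRCY`).
#' Used for nearest-distance queries from breakpoints to hotspots.
#'
#' @slot hits A [GenomicRanges::GRanges] of motif occurrences (1-based
#'   ranges, as customary for GRanges; exported BED and all package
#'   arithmetic are 0-based).
#' @slot motif The IUPAC pattern scanned.
#' @slot strands `"both"` or `"plus"`.
#' @slot region Name of the scanned region.
#' @slot region_length Length of the scanned region.
#' @export
setClass("MotifIndex", representation(
  hits = "GRanges",
  motif = "character",
  strands = "character",
  region = "character",
  region_length = "integer"
))

setValidity("MotifIndex", function(object) {
  msg <- character()
  if (!object@strands %in% c("both", "plus"))
    msg <- c(msg, "strands must be 'both' or 'plus'")
  if (length(object@hits) &&
      is.unsorted(GenomicRanges::start(object@hits)))
    msg <- c(msg, "hits must be sorted by start")
  if (length(object@hits) &&
      max(GenomicRanges::end(object@hits)) > object@region_length)
    msg <- c(msg, "hits extend beyond the region")
  if (length(msg)) msg else TRUE
})

#' Scan a region for a degenerate motif
#'
#' Finds all occurrences of an IUPAC-degenerate pattern in a switch region.
#' `N` bases in the reference never match any motif code, so degenerate
#' reference positions cannot create phantom hotspots. Rescanning the same
#' sequence is deterministic.
#'
#' @param region A [SwitchRegionSet] (scanned region chosen by `name`), a
#'   [Biostrings::DNAString], or a character sequence.
#' @param motif IUPAC-degenerate pattern (default `"WRCY"`).
#' @param strands `"both"` (default; AID attacks both strands, so the
#'   reverse-complement motif on the plus strand is also indexed) or
#'   `"plus"`.
#' @param name Region to scan when `region` is a [SwitchRegionSet]
#'   (default: the donor).
#' @return A [MotifIndex].
#' @export
#' @examples
#' scanMotif("AACTGGGG", motif = "WRCY", strands = "plus")
scanMotif <- function(region, motif = "WRCY", strands = c("both", "plus"),
                      name = NULL) {
  strands <- match.arg(strands)
  if (is(region, "SwitchRegionSet")) {
    if (is.null(name)) name <- donorName(region)
    seq <- region[[name]]
  } else {
    seq <- if (is.character(region)) DNAString(toupper(region)) else region
    if (is.null(name)) name <- "region"
  }
  if (!nzchar(motif) || is.na(motif))
    stop("motif must be a nonempty IUPAC pattern", call. = FALSE)
  letters_ <- strsplit(toupper(motif), "")[[1]]
  if (!all(letters_ %in% names(IUPAC_CODES)))
    stop(sprintf("invalid IUPAC code(s) in motif '%s': %s", motif,
                 paste(setdiff(letters_, names(IUPAC_CODES)), collapse = ", ")),
         call. = FALSE)
  plus <- matchPattern(toupper(motif), seq, fixed = "subject")
  mkgr <- function(m, str) {
    n <- length(Biostrings::start(m))
    GRanges(rep(name, n),
            IRanges(Biostrings::start(m), Biostrings::end(m)),
            strand = rep(str, n))
  }
  gr <- mkgr(plus, "+")
  if (strands == "both") {
    rcpat <- as.character(reverseComplement(DNAString(toupper(motif))))
    minus <- matchPattern(rcpat, seq, fixed = "subject")
    gr <- c(gr, mkgr(minus, "-"))
  }
  gr <- gr[order(GenomicRanges::start(gr), as.character(strand(gr)))]
  new("MotifIndex", hits = gr, motif = toupper(motif), strands = strands,
      region = name, region_length = length(seq))
}

#' @describeIn MotifIndex-accessors Motif occurrences as a
#'   `data.frame(start, end, strand)` with 0-based half-open coordinates.
#' @export
motifHits <- function(x) {
  stopifnot(is(x, "MotifIndex"))
  data.frame(start = GenomicRanges::start(x@hits) - 1L,
             end = GenomicRanges::end(x@hits),
             strand = as.character(strand(x@hits)))
}

#' Accessors for MotifIndex
#'
#' @param x A [MotifIndex].
#' @name MotifIndex-accessors
NULL

#' @describeIn MotifIndex-accessors Name of the indexed region.
#' @export
motifRegionName <- function(x) x@region

setMethod("length", "MotifIndex", function(x) length(x@hits))

setMethod("show", "MotifIndex", function(object) {
  cat(sprintf("MotifIndex: %d occurrences of %s (%s strand%s) in '%s' (%d nt)\n",
              length(object@hits), object@motif, object@strands,
              if (object@strands == "both") "s" else "",
              object@region, object@region_length))
})

# 0-based positions of all motif-covered bases, sorted and unique
.coveredBases <- function(index) {
  if (length(index@hits) == 0L) return(integer())
  st <- GenomicRanges::start(index@hits) - 1L
  en <- GenomicRanges::end(index@hits) - 1L
  sort(unique(unlist(mapply(seq.int, st, en, SIMPLIFY = FALSE))))
}

#' Distance from break positions to the nearest motif-covered base
#'
#' For each 0-based break position, the minimum over all motif-covered bases
#' m of `|break - m|`; 0 when the break base lies inside a motif occurrence.
#' The anchor is the nearest covered *base*, not the motif start, which makes
#' "inside a motif" exactly distance 0.
#'
#' @param breaks Integer vector of 0-based break positions within the region.
#' @param index A non-empty [MotifIndex].
#' @return Integer vector of distances in nucleotides.
#' @export
nearestMotifDistance <- function(breaks, index) {
  stopifnot(is(index, "MotifIndex"))
  cov <- .coveredBases(index)
  if (length(cov) == 0L)
    stop("motif index is empty: no occurrences to measure distance to",
         call. = FALSE)
  breaks <- as.integer(breaks)
  if (any(is.na(breaks)) || any(breaks < 0L) ||
      any(breaks >= index@region_length))
    stop("break positions must lie within [0, region length)", call. = FALSE)
  i <- findInterval(breaks, cov)
  dleft <- ifelse(i >= 1L, breaks - cov[pmax(i, 1L)], Inf)
  dright <- ifelse(i < length(cov), cov[pmin(i + 1L, length(cov))] - breaks, Inf)
  as.integer(pmin(dleft, dright))
}

#' Export a motif index as a BED file
#'
#' Writes motif occurrences as BED (0-based half-open, strand column).
#'
#' @param index A [MotifIndex].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
exportMotifBED <- function(index, file) {
  stopifnot(is(index, "MotifIndex"))
  gr <- index@hits
  mcols(gr)$name <- rep(index@motif, length(gr))
  mcols(gr)$score <- rep(0L, length(gr))
  rtracklayer::export(gr, file, format = "BED")
  invisible(file)
}
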