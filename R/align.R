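#' @importFrom Biostrings pairwiseAlignment nmatch score pattern subject
#'   alignedPattern alignedSubject nchar
NULL

# substitution matrix over {A,C,G,T,N}: match +1, mismatch -2, N never matches
.submat <- local({
  bases <- c("A", "C", "G", "T", "N")
  m <- matrix(-2, 5, 5, dimnames = list(bases, bases))
  diag(m) <- 1
  m["N", ] <- -2
  m[, "N"] <- -2
  m
})

GAP_OPEN <- 4
GAP_EXT <- 1

# vectorized exact local alignment of a read set against one reference
.alignBatch <- function(reads, ref) {
  pairwiseAlignment(reads, ref, type = "local", substitutionMatrix = .submat,
                    gapOpening = GAP_OPEN, gapExtension = GAP_EXT)
}

# thresholds are strict: identity > min_identity, aligned length > min_length;
# identity denominator includes gap columns
.batchAccept <- function(pa, min_identity, min_length) {
  alen <- Biostrings::end(pattern(pa)) - Biostrings::start(pattern(pa)) + 1L
  ident <- nmatch(pa) / nchar(pa)
  ident > min_identity & alen > min_length
}

# build a SegmentAlignment (list) from pre-extracted aligned strings and
# 1-based range scalars
.segmentFromStrings <- function(apstr, asstr, ps, pe, ss, se, ident, sc, nc,
                                strand, region_name) {
  pc <- strsplit(apstr, "", fixed = TRUE)[[1]]
  scv <- strsplit(asstr, "", fixed = TRUE)[[1]]
  rpos <- ps - 1L + cumsum(pc != "-") - 1L
  spos <- ss - 1L + cumsum(scv != "-") - 1L
  match_col <- pc != "-" & scv != "-" & pc == scv & pc != "N"
  structure(list(
    region_name = region_name,
    read_start = ps - 1L, read_end = pe,            # half-open
    ref_start = ss - 1L, ref_end = se,              # half-open
    strand = strand, identity = ident,
    aligned_length = pe - ps + 1L, score = sc, n_columns = nc,
    match_read_pos = rpos[match_col],
    match_ref_pos = spos[match_col]
  ), class = "SegmentAlignment")
}

# SegmentAlignments for every element of a PairwiseAlignments object.
# Gapless alignments (the overwhelming majority under substitution-only
# error) are reconstructed directly from the sequences, avoiding the costly
# alignedPattern() extraction, which is only used for gapped alignments.
.segmentsBatch <- function(pa, strand, region_name, rchars_list, refchars) {
  ps <- Biostrings::start(pattern(pa)); pe <- Biostrings::end(pattern(pa))
  ss <- Biostrings::start(subject(pa)); se <- Biostrings::end(subject(pa))
  nc <- nchar(pa); nm <- nmatch(pa); sc <- score(pa)
  gapless <- (pe - ps == se - ss) & (nc == pe - ps + 1L)
  need <- which(!gapless)
  ap <- as_ <- NULL
  if (length(need)) {
    sub <- pa[need]
    ap <- as.character(alignedPattern(sub))
    as_ <- as.character(alignedSubject(sub))
  }
  segs <- vector("list", length(pa))
  for (j in seq_along(segs)) {
    if (gapless[j]) {
      o <- ss[j] - ps[j]
      p <- (ps[j] - 1L):(pe[j] - 1L)
      rc <- rchars_list[[j]]
      b <- rc[p + 1L]
      mvec <- b == refchars[p + o + 1L] & b != "N"
      segs[[j]] <- structure(list(
        region_name = region_name,
        read_start = ps[j] - 1L, read_end = pe[j],
        ref_start = ss[j] - 1L, ref_end = se[j],
        strand = strand, identity = nm[j] / nc[j],
        aligned_length = pe[j] - ps[j] + 1L, score = sc[j],
        n_columns = nc[j],
        match_read_pos = p[mvec], match_ref_pos = p[mvec] + o
      ), class = "SegmentAlignment")
    } else {
      k <- match(j, need)
      segs[[j]] <- .segmentFromStrings(ap[k], as_[k], ps[j], pe[j], ss[j],
                                       se[j], nm[j] / nc[j], sc[j], nc[j],
                                       strand, region_name)
    }
  }
  segs
}

#' Local alignment of a read against a switch region
#'
#' Computes the exact (Smith-Waterman, affine-gap) highest-scoring local
#' alignment of a read against one reference region, with scoring match +1,
#' mismatch -2, gap open -4, gap extend -1, and accepts it only if it clears
#' both thresholds *strictly*: identity higher than `min_identity` and
#' aligned read length longer than `min_length` nucleotides. Identity is
#' matches divided by alignment columns, gap columns included. Both read
#' orientations are tried when `both_strands = TRUE` and the better-scoring
#' acceptable one is returned with its strand.
#'
#' @param read A character string, [Biostrings::DNAString], or length-1
#'   `DNAStringSet`.
#' @param region Reference sequence (same types accepted).
#' @param min_identity Identity floor, exclusive (default 0.90).
#' @param min_length Aligned-length floor in read nucleotides, exclusive
#'   (default 40).
#' @param both_strands Try the reverse complement of the read too.
#' @param region_name Name recorded in the result.
#' @return A `SegmentAlignment` (list with fields `region_name`,
#'   `read_start`/`read_end` and `ref_start`/`ref_end` (0-based half-open,
#'   read coordinates on the oriented read), `strand`, `identity`,
#'   `aligned_length`, `score`, and per-column bookkeeping used by the
#'   junction caller), or `NULL` if no alignment clears the thresholds.
#' @export
alignLocal <- function(read, region, min_identity = 0.90, min_length = 40L,
                       both_strands = TRUE, region_name = "region") {
  rd <- if (is(read, "DNAString")) read else DNAString(toupper(as.character(read)))
  rf <- if (is(region, "DNAString")) region else DNAString(toupper(as.character(region)))
  if (length(rd) == 0L) return(NULL)
  oris <- if (both_strands) c("+", "-") else "+"
  best <- NULL
  for (strand in oris) {
    r <- if (strand == "-") reverseComplement(rd) else rd
    pa <- .alignBatch(DNAStringSet(list(r)), rf)
    if (!.batchAccept(pa, min_identity, min_length)) next
    seg <- .segmentsBatch(pa, strand, region_name,
                          list(strsplit(as.character(r), "")[[1]]),
                          strsplit(as.character(rf), "")[[1]])[[1]]
    if (is.null(best) || seg$score > best$score) best <- seg
  }
  best
}

#' @export
print.SegmentAlignment <- function(x, ...) {
  cat(sprintf(
    paste0("SegmentAlignment to '%s' (%s): read [%d,%d), ref [%d,%d) ",
           "(1-based %d-%d), identity %.3f, %d nt, score %.0f\n"),
    x$region_name, x$strand, x$read_start, x$read_end, x$ref_start, x$ref_end,
    x$ref_start + 1L, x$ref_end, x$identity, x$aligned_length, x$score))
  invisible(x)
}

# majority (modal) diagonal ref_pos - read_pos over exact-match columns,
# plus the read positions of match columns lying on that diagonal
.majorityDiagonal <- function(seg) {
  d <- seg$match_ref_pos - seg$match_read_pos
  tab <- table(d)
  o <- as.integer(names(tab)[which.max(tab)])
  on_diag <- seg$match_read_pos[d == o]
  list(offset = o, match_read_pos = on_diag)
}
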