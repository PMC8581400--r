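#' @importFrom stats aggregate
NULL

# Forward score scan along a fixed diagonal. Starting from an exact-match
# anchor (0-based read position `anchor` paired with ref position
# `anchor + o`), walk right scoring +1 for an exact base match on the
# diagonal and -2 otherwise, and return the largest read position that is a
# match and attains at least the running maximum. Sequencing errors inside
# or at the edge of a segment are crossed when enough matches balance them;
# genuine chance homology beyond a clean joint stays strictly
# score-negative (the simulator's joint guard enforces the same bound), so
# on error-free reads the anchor never moves past the true joint.
.scanForward <- function(rchars, refchars, anchor, o) {
  best <- 0L; cum <- 0L; bestp <- anchor
  p <- anchor + 1L
  nread <- length(rchars); nref <- length(refchars)
  while (p < nread && (p + o) < nref && (p + o) >= 0L) {
    b <- rchars[p + 1L]
    m <- b != "N" && b == refchars[p + o + 1L]
    cum <- cum + if (m) 1L else -2L
    if (m && cum >= best) { best <- cum; bestp <- p }
    p <- p + 1L
  }
  bestp
}

.scanBackward <- function(rchars, refchars, anchor, o) {
  best <- 0L; cum <- 0L; bestp <- anchor
  p <- anchor - 1L
  nref <- length(refchars)
  while (p >= 0L && (p + o) >= 0L && (p + o) < nref) {
    b <- rchars[p + 1L]
    m <- b != "N" && b == refchars[p + o + 1L]
    cum <- cum + if (m) 1L else -2L
    if (m && cum >= best) { best <- cum; bestp <- p }
    p <- p - 1L
  }
  bestp
}

# core of classifyStructure on pre-split character vectors
.classifyCore <- function(rchars, donor_seg, acceptor_seg, dchars, achars) {
  dd <- .majorityDiagonal(donor_seg)
  da <- .majorityDiagonal(acceptor_seg)
  o_d <- dd$offset
  o_a <- da$offset
  p_d <- .scanForward(rchars, dchars, max(dd$match_read_pos), o_d)
  p_a <- .scanBackward(rchars, achars, min(da$match_read_pos), o_a)

  db <- p_d + o_d
  if (p_a > p_d + 1L) {                     # unassigned read bases: insertion
    ins <- paste(rchars[(p_d + 2L):p_a], collapse = "")
    return(list(structure = "insertion", mh_length = 0L, insertion_seq = ins,
                donor_break = db, acceptor_break = p_a + o_a,
                ambiguity_start = db, ambiguity_end = db))
  }
  # flush or microhomologous joint: maximal exact simultaneous match
  k <- 0L
  repeat {
    p <- p_d - k
    if (p < 0L || (p + o_d) < 0L || (p + o_a) < 0L ||
        (p + o_a) >= length(achars)) break
    b <- rchars[p + 1L]
    if (b == "N" || b != dchars[p + o_d + 1L] || b != achars[p + o_a + 1L])
      break
    k <- k + 1L
  }
  list(structure = if (k > 0L) "microhomology" else "blunt",
       mh_length = k, insertion_seq = "",
       donor_break = db, acceptor_break = p_d + 1L + o_a,
       ambiguity_start = db - k, ambiguity_end = db)
}

#' Resolve and classify the joint between a donor and an acceptor segment
#'
#' Given accepted donor and acceptor alignment segments of one read (read
#' coordinates for both segments on the same oriented read), refines the two
#' breakpoints and classifies the repair structure of the joint:
#'
#' * a gap of g > 0 read bases between the donor end and the acceptor start
#'   is an untemplated **insertion** (the g bases are reported);
#' * with no gap, the **microhomology** length is the largest k such that
#'   the k read bases ending at the donor break match both the donor
#'   reference there and the acceptor reference immediately before the
#'   acceptor break (exact matches only: a mismatch breaks the block);
#' * k = 0 with no gap is a **blunt** joint.
#'
#' Breakpoints follow the donor-maximal convention: a shared block is
#' assigned to the donor, `donor_break` is the donor position of the last
#' donor-assigned base and `acceptor_break` the acceptor position of the
#' first acceptor-assigned base (0-based). The half-open `ambiguity`
#' interval `[donor_break - mh_length, donor_break)` records the alternative
#' donor-break placements; together with `donor_break` itself it is the full
#' equivalence class of the call.
#'
#' @param read Character string of the oriented read.
#' @param donor_seg,acceptor_seg `SegmentAlignment`s (see [alignLocal()]),
#'   both in coordinates of `read`, acceptor downstream of donor.
#' @param donor_seq,acceptor_seq The reference sequences (character).
#' @return List with `structure`, `mh_length`, `insertion_seq`,
#'   `donor_break`, `acceptor_break`, `ambiguity_start`, `ambiguity_end`.
#' @export
classifyStructure <- function(read, donor_seg, acceptor_seg,
                              donor_seq, acceptor_seq) {
  if (acceptor_seg$read_end <= donor_seg$read_start)
    stop("internal consistency error: segments out of order on the read",
         call. = FALSE)
  .classifyCore(strsplit(toupper(read), "", fixed = TRUE)[[1]],
                donor_seg, acceptor_seg,
                strsplit(toupper(as.character(donor_seq)), "")[[1]],
                strsplit(toupper(as.character(acceptor_seq)), "")[[1]])
}

#' Call CSR junctions in a set of reads
#'
#' Implements sequential switch-region alignment: a read must carry an
#' accepted donor (Smu) segment (identity > `min_identity`, aligned length >
#' `min_length`, both strict), and the read portion beyond the donor segment
#' must carry an accepted segment on one of the acceptor regions in the same
#' orientation. Reads aligning to the donor only (germline reads) or to an
#' acceptor only yield no call and are absent from the result. When several
#' acceptors pass, the highest alignment score wins, ties broken by acceptor
#' order in the reference set (5'->3' locus order). Breakpoints are resolved
#' by [classifyStructure()] under the donor-maximal convention.
#'
#' @param reads A named [Biostrings::DNAStringSet] (or named character
#'   vector); names become `read_id`s.
#' @param regions A [SwitchRegionSet].
#' @param min_identity,min_length Acceptance thresholds, strict (defaults
#'   0.90 and 40).
#' @param both_strands Try the reverse complement of each read.
#' @return A `data.frame` with one row per junction-positive read and
#'   columns `read_id`, `donor_break`, `acceptor_name`, `acceptor_break`,
#'   `structure`, `mh_length`, `insertion_seq`, `ambiguity_start`,
#'   `ambiguity_end`, `strand`, `donor_identity`, `acceptor_identity`.
#'   All coordinates are 0-based (add 1 for 1-based inclusive positions).
#' @export
callJunctions <- function(reads, regions, min_identity = 0.90,
                          min_length = 40L, both_strands = TRUE) {
  stopifnot(is(regions, "SwitchRegionSet"))
  seqs <- toupper(as.character(reads))
  ids <- names(seqs)
  if (is.null(ids)) ids <- sprintf("read_%05d", seq_along(seqs))
  if (length(seqs) == 0L) return(.emptyCalls())
  rset <- DNAStringSet(seqs)
  dname <- donorName(regions)
  dstr <- regions[[dname]]
  dchars <- strsplit(as.character(dstr), "", fixed = TRUE)[[1]]
  anames <- acceptorNames(regions)
  achars_all <- lapply(anames, function(a)
    strsplit(as.character(regions[[a]]), "", fixed = TRUE)[[1]])
  names(achars_all) <- anames

  pa_p <- .alignBatch(rset, dstr)
  ok_p <- .batchAccept(pa_p, min_identity, min_length)
  sc_p <- score(pa_p)
  if (both_strands) {
    rset_rc <- reverseComplement(rset)
    pa_m <- .alignBatch(rset_rc, dstr)
    ok_m <- .batchAccept(pa_m, min_identity, min_length)
    sc_m <- score(pa_m)
  } else {
    ok_m <- rep(FALSE, length(seqs))
    sc_m <- rep(-Inf, length(seqs))
  }
  use_m <- ok_m & (!ok_p | sc_m > sc_p)
  use_p <- ok_p & !use_m
  keep <- which(use_p | use_m)
  if (length(keep) == 0L) return(.emptyCalls())

  # donor segments, oriented reads and their split characters
  dsegs <- vector("list", length(seqs))
  opseqs <- character(length(seqs))
  opchars <- vector("list", length(seqs))
  idxp <- which(use_p)
  if (length(idxp)) {
    opseqs[idxp] <- seqs[idxp]
    opchars[idxp] <- strsplit(seqs[idxp], "", fixed = TRUE)
    dsegs[idxp] <- .segmentsBatch(pa_p[idxp], "+", dname, opchars[idxp],
                                  dchars)
  }
  idxm <- which(use_m)
  if (length(idxm)) {
    rc <- as.character(rset_rc[idxm])
    opseqs[idxm] <- rc
    opchars[idxm] <- strsplit(rc, "", fixed = TRUE)
    dsegs[idxm] <- .segmentsBatch(pa_m[idxm], "-", dname, opchars[idxm],
                                  dchars)
  }

  # acceptor search on the read portion beyond the donor segment
  s0 <- vapply(keep, function(i) dsegs[[i]]$read_end, integer(1))
  suffixes <- substring(opseqs[keep], s0 + 1L)
  viable <- nchar(suffixes) > min_length
  cand <- keep[viable]
  if (length(cand) == 0L) return(.emptyCalls())
  sufset <- DNAStringSet(suffixes[viable])
  sufchars <- lapply(seq_along(cand), function(j) {
    ch <- opchars[[cand[j]]]
    ch[(s0[viable][j] + 1L):length(ch)]
  })

  best_idx <- rep(NA_integer_, length(cand))   # which acceptor
  best_score <- rep(-Inf, length(cand))
  pas <- list()
  for (ai in seq_along(anames)) {
    pa_a <- .alignBatch(sufset, regions[[anames[ai]]])
    pas[[ai]] <- pa_a
    ok_a <- .batchAccept(pa_a, min_identity, min_length)
    sc_a <- score(pa_a)
    better <- ok_a & sc_a > best_score      # strict: ties keep earlier region
    best_idx[better] <- ai
    best_score[better] <- sc_a[better]
  }
  hasacc <- which(!is.na(best_idx))
  if (length(hasacc) == 0L) return(.emptyCalls())

  rows <- vector("list", length(hasacc))
  # build acceptor segments per acceptor for the reads that chose it
  for (ai in unique(best_idx[hasacc])) {
    sel <- which(best_idx == ai)             # indices into cand/sufset
    asegs <- .segmentsBatch(pas[[ai]][sel], "+", anames[ai], sufchars[sel],
                            achars_all[[anames[ai]]])
    for (j in seq_along(sel)) {
      i <- cand[sel[j]]                      # read index
      aseg <- asegs[[j]]
      off <- dsegs[[i]]$read_end
      aseg$read_start <- aseg$read_start + off
      aseg$read_end <- aseg$read_end + off
      aseg$match_read_pos <- aseg$match_read_pos + off
      cl <- .classifyCore(opchars[[i]], dsegs[[i]], aseg, dchars,
                          achars_all[[anames[ai]]])
      rows[[match(sel[j], hasacc)]] <- data.frame(
        read_id = ids[i],
        donor_break = cl$donor_break,
        acceptor_name = anames[ai],
        acceptor_break = cl$acceptor_break,
        structure = cl$structure,
        mh_length = cl$mh_length,
        insertion_seq = cl$insertion_seq,
        ambiguity_start = cl$ambiguity_start,
        ambiguity_end = cl$ambiguity_end,
        strand = dsegs[[i]]$strand,
        donor_identity = dsegs[[i]]$identity,
        acceptor_identity = aseg$identity,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(match(out$read_id, ids)), ]
  rownames(out) <- NULL
  out
}

#' Call a CSR junction in a single read
#'
#' Single-read convenience wrapper around [callJunctions()].
#'
#' @param read Character string / `DNAString` of one read.
#' @inheritParams callJunctions
#' @param read_id Identifier recorded in the call.
#' @return A one-row `data.frame` (see [callJunctions()]) or `NULL` when
#'   the read contains no acceptable junction.
#' @export
callJunction <- function(read, regions, min_identity = 0.90,
                         min_length = 40L, both_strands = TRUE,
                         read_id = "read") {
  res <- callJunctions(setNames(as.character(read), read_id), regions,
                       min_identity, min_length, both_strands)
  if (nrow(res) == 0L) NULL else res
}

.emptyCalls <- function() {
  data.frame(read_id = character(), donor_break = integer(),
             acceptor_name = character(), acceptor_break = integer(),
             structure = character(), mh_length = integer(),
             insertion_seq = character(), ambiguity_start = integer(),
             ambiguity_end = integer(), strand = character(),
             donor_identity = numeric(), acceptor_identity = numeric(),
             stringsAsFactors = FALSE)
}

#' Assemble identical junctions into clusters
#'
#' Reads sharing the same breakpoint pair and inserted sequence are counted
#' as one recombination event (a cluster). The key is
#' `(donor_break, acceptor_name, acceptor_break, insertion_seq)`.
#'
#' @param calls A call table from [callJunctions()].
#' @return A `data.frame` with the key columns, `structure`, `mh_length`,
#'   `read_count` and `representative_read_id`, one row per cluster. The
#'   read counts sum to `nrow(calls)`.
#' @export
clusterJunctions <- function(calls) {
  empty <- data.frame(donor_break = integer(), acceptor_name = character(),
                      acceptor_break = integer(), insertion_seq = character(),
                      structure = character(), mh_length = integer(),
                      read_count = integer(),
                      representative_read_id = character(),
                      stringsAsFactors = FALSE)
  if (is.null(calls) || nrow(calls) == 0L) return(empty)
  key <- paste(calls$donor_break, calls$acceptor_name, calls$acceptor_break,
               calls$insertion_seq, sep = "\r")
  first <- !duplicated(key)
  out <- calls[first, c("donor_break", "acceptor_name", "acceptor_break",
                        "insertion_seq", "structure", "mh_length")]
  out$read_count <- as.integer(table(key)[key[first]])
  out$representative_read_id <- calls$read_id[first]
  out <- out[order(out$acceptor_name, out$donor_break, out$acceptor_break,
                   out$insertion_seq), ]
  rownames(out) <- NULL
  out
}

#' Summarize junction repair structures
#'
#' Counts and fractions of blunt / microhomology / insertion junctions, the
#' mean microhomology length among microhomology junctions and the mean
#' inserted length among insertion junctions. Means of empty categories are
#' reported as `NA`, not 0.
#'
#' @param calls A call (or cluster) table with `structure`, `mh_length` and
#'   `insertion_seq` columns.
#' @return A list of class `StructureSummary` with elements `n`, `counts`,
#'   `fractions`, `mean_mh_length`, `mean_insertion_length`.
#' @export
summarizeStructures <- function(calls) {
  cats <- c("blunt", "microhomology", "insertion")
  n <- if (is.null(calls)) 0L else nrow(calls)
  counts <- structure(integer(3), names = cats)
  if (n > 0L) {
    tab <- table(factor(calls$structure, levels = cats))
    counts[] <- as.integer(tab)
  }
  fractions <- if (n > 0L) counts / n else structure(rep(NA_real_, 3),
                                                     names = cats)
  mh <- if (counts["microhomology"] > 0L)
    mean(calls$mh_length[calls$structure == "microhomology"]) else NA_real_
  il <- if (counts["insertion"] > 0L)
    mean(nchar(calls$insertion_seq[calls$structure == "insertion"]))
  else NA_real_
  structure(list(n = n, counts = counts, fractions = fractions,
                 mean_mh_length = mh, mean_insertion_length = il),
            class = "StructureSummary")
}

#' @export
print.StructureSummary <- function(x, ...) {
  cat(sprintf("StructureSummary of %d junctions\n", x$n))
  for (cat_ in names(x$counts))
    cat(sprintf("  %-14s %5d  (%s)\n", cat_, x$counts[[cat_]],
                ifelse(is.na(x$fractions[[cat_]]), "-",
                       sprintf("%.1f%%", 100 * x$fractions[[cat_]]))))
  cat(sprintf("  mean microhomology length: %s nt\n",
              ifelse(is.na(x$mean_mh_length), "-",
                     sprintf("%.2f", x$mean_mh_length))))
  cat(sprintf("  mean insertion length:     %s nt\n",
              ifelse(is.na(x$mean_insertion_length), "-",
                     sprintf("%.2f", x$mean_insertion_length))))
  invisible(x)
}

#' Re-express calls under the acceptor-maximal breakpoint convention
#'
#' Package output assigns microhomology blocks to the donor (donor-maximal).
#' The acceptor-maximal convention assigns them to the acceptor instead:
#' for each microhomology call the donor gives up the shared block and the
#' acceptor claims it, so `donor_break` and `acceptor_break` both shift by
#' exactly `mh_length` (the donor segment shrinks while the acceptor segment
#' grows by the same amount - the two ends move in opposite directions along
#' the junction).
#'
#' @param calls A call table from [callJunctions()] (donor-maximal).
#' @param to `"acceptor-maximal"` or `"donor-maximal"` (identity).
#' @return The converted call table.
#' @export
convertBreakConvention <- function(calls,
                                   to = c("acceptor-maximal",
                                          "donor-maximal")) {
  to <- match.arg(to)
  if (to == "donor-maximal" || nrow(calls) == 0L) return(calls)
  mh <- calls$mh_length
  calls$donor_break <- calls$donor_break - mh
  calls$acceptor_break <- calls$acceptor_break - mh
  calls$ambiguity_start <- calls$donor_break
  calls$ambiguity_end <- calls$donor_break + mh
  calls
}
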