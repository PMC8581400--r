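# Shared fixtures and independent brute-force oracles. Every oracle here is
# deliberately written as naive loops, independent of the package's
# implementation paths.

testRegions <- function(seed = 42L, donor_length = 600L,
                        acceptor_lengths = c(Sg1 = 500L)) {
  simulateSwitchRegions(donor_length = donor_length,
                        acceptor_lengths = acceptor_lengths, seed = seed)
}

IUPAC <- list(A = "A", C = "C", G = "G", T = "T",
              R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"),
              W = c("A", "T"), K = c("G", "T"), M = c("A", "C"),
              B = c("C", "G", "T"), D = c("A", "G", "T"),
              H = c("A", "C", "T"), V = c("A", "C", "G"),
              N = c("A", "C", "G", "T"))

COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

# sliding-window degenerate matcher; N in the subject matches nothing
bruteMotifScan <- function(seq, motif, strands = "both") {
  s <- strsplit(toupper(seq), "")[[1]]
  m <- strsplit(toupper(motif), "")[[1]]
  w <- length(m)
  rcm <- rev(COMP[m])          # motif complement letters, reversed
  rc_allowed <- lapply(rev(m), function(x) COMP[IUPAC[[x]]])
  hits <- list()
  for (st in 0:(length(s) - w)) {
    win <- s[(st + 1):(st + w)]
    if (all(mapply(function(b, code) b %in% IUPAC[[code]] && b != "N",
                   win, m)))
      hits[[length(hits) + 1]] <- c(start = st, strand = "+")
    if (strands == "both" &&
        all(mapply(function(b, allowed) b %in% allowed && b != "N",
                   win, rc_allowed)))
      hits[[length(hits) + 1]] <- c(start = st, strand = "-")
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(), strand = character()))
  df <- data.frame(start = as.integer(vapply(hits, `[[`, "", "start")),
                   strand = vapply(hits, `[[`, "", "strand"))
  df[order(df$start, df$strand), , drop = FALSE]
}

# exhaustive min-over-motif-covered-bases distance
bruteNearest <- function(pos, hits_df, width) {
  covered <- integer()
  for (i in seq_len(nrow(hits_df)))
    covered <- c(covered, hits_df$start[i] + 0:(width - 1))
  covered <- unique(covered)
  vapply(pos, function(p) min(abs(p - covered)), integer(1))
}

# brute-force joint scanner: maximal k such that the k bases left of the
# joint are identical in donor (ending at db) and acceptor (ending at ab-1)
bruteMH <- function(dchars, achars, db, ab) {
  k <- 0L
  while (db - k >= 0L && ab - k - 1L >= 0L &&
         dchars[db - k + 1L] == achars[ab - k]) k <- k + 1L
  k
}

# exact permutation p-value by full enumeration of label assignments
exactPermP <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  obs <- abs(mean(a) - mean(b))
  idx <- utils::combn(length(pool), na)
  stats <- apply(idx, 2, function(ii)
    abs(mean(pool[ii]) - mean(pool[-ii])))
  mean(stats >= obs - 1e-12)
}

# direct-summation Pearson chi-square
bruteChisq <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

writeRegionsFasta <- function(regions, path) {
  Biostrings::writeXStringSet(as(regions, "DNAStringSet"), path)
  path
}
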