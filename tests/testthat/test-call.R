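# Engineered references with controlled joints: start from random regions,
# then edit bases around the joint so each constructed example has a known,
# independently verifiable truth.
makeJointFixture <- function() {
  withr::local_seed(101)
  d <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  a <- sample(c("A", "C", "G", "T"), 300, replace = TRUE)
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  # blunt / insertion joint at donor break 79 -> acceptor break 100:
  # forbid any shared or extending base at the joint
  a[101] <- rot[[d[81]]]                 # A[100] != D[80]   (0-based)
  a[100] <- rot[[d[80]]]                 # A[99]  != D[79]
  # keep the next few diagonal bases distinct so chance homology cannot
  # accumulate a non-negative score at the joint
  for (i in 2:12) a[100 + i] <- rot[[d[80 + i]]]
  for (i in 1:12) a[99 - i] <- rot[[d[79 - i]]]
  list(d = d, a = a,
       regions = SwitchRegionSet(c(Smu = paste(d, collapse = ""),
                                   Sg1 = paste(a, collapse = "")),
                                 donor = "Smu"))
}

fix <- makeJointFixture()

test_that("a constructed blunt joint is called with exact breakpoints", {
  read <- paste(c(fix$d[1:80], fix$a[101:180]), collapse = "")
  call <- callJunction(read, fix$regions)
  expect_identical(call$donor_break, 79L)
  expect_identical(call$acceptor_break, 100L)
  expect_identical(call$structure, "blunt")
  expect_identical(call$mh_length, 0L)
  expect_identical(call$ambiguity_end - call$ambiguity_start, 0L)
})

test_that("an engineered 4-nt shared block is called as microhomology", {
  d <- fix$d; a <- fix$a
  a[97:100] <- d[77:80]                  # A[96..99] == D[76..79]
  rot <- c(A = "C", C = "G", G = "T", T = "A")
  a[96] <- rot[[d[76]]]                  # block not extendable left
  regions <- SwitchRegionSet(c(Smu = paste(d, collapse = ""),
                               Sg1 = paste(a, collapse = "")), donor = "Smu")
  read <- paste(c(d[1:80], a[101:180]), collapse = "")
  call <- callJunction(read, regions)
  expect_identical(call$structure, "microhomology")
  expect_identical(call$mh_length, 4L)
  expect_identical(call$donor_break, 79L)          # donor-maximal
  expect_identical(call$acceptor_break, 100L)
  expect_identical(call$ambiguity_start, 75L)      # width = mh_length
  expect_identical(call$ambiguity_end, 79L)
  # brute-force joint scanner agrees
  expect_identical(bruteMH(d, a, call$donor_break, call$acceptor_break), 4L)
})

test_that("untemplated bases between the segments are called as insertion", {
  d <- fix$d; a <- fix$a
  # search the references for a joint where "TTA" is untemplated on both
  # local diagonals and the flanking diagonals carry no chance homology
  ins <- c("T", "T", "A")
  found <- NULL
  for (db in 80:200) {                     # 0-based donor break
    for (ab in 60:200) {                   # 0-based acceptor break
      ok <- all(d[db + 2:4] != ins) &&     # donor continuation
        all(a[ab - 2:0] != ins) &&         # acceptor diagonal before ab
        all(a[ab + 1:10] != d[db + 4 + 1:10]) &&   # beyond-insert, donor diag
        all(d[db + 1 - 0:9] != a[ab - 3 - 0:9])    # before-donor, acceptor diag
      if (ok) { found <- c(db, ab); break }
    }
    if (!is.null(found)) break
  }
  expect_false(is.null(found))
  db <- found[1]; ab <- found[2]
  read <- paste(c(d[(db - 79):(db + 1)], ins, a[(ab + 1):(ab + 77)]),
                collapse = "")
  call <- callJunction(read, fix$regions)
  expect_identical(call$structure, "insertion")
  expect_identical(call$insertion_seq, "TTA")
  expect_identical(call$mh_length, 0L)
  expect_identical(call$donor_break, db)
  expect_identical(call$acceptor_break, ab)
})

test_that("donor-only, acceptor-only and short-homology reads yield no call", {
  regions <- fix$regions
  germline <- paste(fix$d[1:180], collapse = "")
  expect_null(callJunction(germline, regions))
  acceptor_only <- paste(fix$a[1:180], collapse = "")
  expect_null(callJunction(acceptor_only, regions))
  # acceptor side shorter than the 40-nt floor: no junction
  short_acc <- paste(c(fix$d[1:80], fix$a[101:135]), collapse = "")
  expect_null(callJunction(short_acc, regions))
})

test_that("minus-strand reads are called with identical junctions", {
  regions <- testRegions()
  cfg <- simConfig(n_reads = 40, error_rate = 0, seed = 31)
  sim <- simulateJunctionReads(regions, cfg)
  fwd <- callJunctions(sim$reads, regions)
  rev <- callJunctions(Biostrings::reverseComplement(sim$reads), regions)
  expect_identical(fwd$donor_break, rev$donor_break)
  expect_identical(fwd$acceptor_break, rev$acceptor_break)
  expect_identical(fwd$structure, rev$structure)
  expect_true(all(fwd$strand == "+"))
  expect_true(all(rev$strand == "-"))
})

test_that("classifyStructure rejects out-of-order segments", {
  regions <- fix$regions
  read <- paste(c(fix$d[1:80], fix$a[101:180]), collapse = "")
  dseg <- alignLocal(read, paste(fix$d, collapse = ""), region_name = "Smu")
  aseg <- alignLocal(substring(read, 81), paste(fix$a, collapse = ""),
                     region_name = "Sg1")
  aseg$read_start <- aseg$read_start + 80L   # lift to read coordinates
  aseg$read_end <- aseg$read_end + 80L
  aseg$match_read_pos <- aseg$match_read_pos + 80L
  # acceptor passed in the donor slot: segments are out of order
  expect_error(classifyStructure(read, aseg, dseg,
                                 paste(fix$a, collapse = ""),
                                 paste(fix$d, collapse = "")),
               "out of order")
})

test_that("clustering merges identical junctions and conserves counts", {
  calls <- data.frame(
    read_id = sprintf("r%d", 1:5),
    donor_break = c(100L, 100L, 101L, 100L, 200L),
    acceptor_name = "Sg1",
    acceptor_break = c(50L, 50L, 50L, 50L, 60L),
    structure = c("blunt", "blunt", "blunt", "blunt", "insertion"),
    mh_length = 0L,
    insertion_seq = c("", "", "", "", "GG"),
    stringsAsFactors = FALSE)
  cl <- clusterJunctions(calls)
  expect_identical(nrow(cl), 3L)
  expect_identical(sum(cl$read_count), 5L)
  expect_identical(cl$read_count[cl$donor_break == 100L], 3L)
  expect_identical(nrow(clusterJunctions(calls[0, ])), 0L)
  # one-off breakpoints are distinct clusters
  expect_identical(nrow(clusterJunctions(calls[1:3, ])), 2L)
})

test_that("structure summaries report fractions and conditional means", {
  calls <- data.frame(
    structure = c(rep("blunt", 10), rep("microhomology", 10)),
    mh_length = c(rep(0L, 10), rep(2L, 10)),
    insertion_seq = "")
  s <- summarizeStructures(calls)
  expect_equal(unname(s$fractions), c(0.5, 0.5, 0))
  expect_identical(s$mean_mh_length, 2)
  expect_true(is.na(s$mean_insertion_length))   # absent, not 0
  allb <- summarizeStructures(data.frame(structure = rep("blunt", 4),
                                         mh_length = 0L, insertion_seq = ""))
  expect_equal(unname(allb$fractions), c(1, 0, 0))
  expect_output(print(s), "50.0%")
})

test_that("simulated structure mix is recovered within binomial error", {
  regions <- testRegions()
  cfg <- simConfig(n_reads = 2000, error_rate = 0, seed = 17,
                   structure_mix = c(blunt = 0.3, microhomology = 0.5,
                                     insertion = 0.2))
  sim <- simulateJunctionReads(regions, cfg)
  calls <- callJunctions(sim$reads, regions)
  s <- summarizeStructures(calls)
  for (i in seq_along(s$fractions)) {
    p <- c(0.3, 0.5, 0.2)[i]
    expect_lt(abs(s$fractions[[i]] - p), 3 * sqrt(p * (1 - p) / 2000))
  }
})

test_that("convention conversion shifts both breakpoints by mh_length", {
  regions <- testRegions()
  cfg <- simConfig(n_reads = 100, error_rate = 0, seed = 23)
  sim <- simulateJunctionReads(regions, cfg)
  calls <- callJunctions(sim$reads, regions)
  conv <- convertBreakConvention(calls, to = "acceptor-maximal")
  expect_identical(calls$donor_break - conv$donor_break, calls$mh_length)
  expect_identical(calls$acceptor_break - conv$acceptor_break,
                   calls$mh_length)
  # acceptor-maximal blocks remain genuine shared blocks
  d <- strsplit(as.character(donorRegion(regions)), "")[[1]]
  a <- strsplit(as.character(regions[["Sg1"]]), "")[[1]]
  mh <- conv[conv$structure == "microhomology", ]
  for (i in seq_len(nrow(mh))) {
    k <- mh$mh_length[i]
    expect_identical(
      paste(d[(mh$donor_break[i] + 2):(mh$donor_break[i] + 1 + k)],
            collapse = ""),
      paste(a[(mh$acceptor_break[i] + 1):(mh$acceptor_break[i] + k)],
            collapse = ""))
  }
  expect_identical(convertBreakConvention(calls, to = "donor-maximal"), calls)
})
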