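regions <- testRegions()

test_that("configuration invariants are enforced", {
  expect_error(simConfig(structure_mix = c(0.5, 0.5, 0.2)), "sum to 1")
  expect_error(simConfig(structure_mix = c(-0.1, 0.9, 0.2)), "nonnegative")
  expect_error(simConfig(error_rate = 0.5), "error_rate")
  expect_error(simConfig(read_length = 60), "too short")
  expect_error(simConfig(germline_fraction = 2), "germline_fraction")
  expect_s3_class(simConfig(), "SimConfig")
})

test_that("structure mix, germline fraction and break placement are honored", {
  cfg <- simConfig(n_reads = 100, structure_mix = c(1, 0, 0), error_rate = 0,
                   seed = 7)
  sim <- simulateJunctionReads(regions, cfg)
  expect_identical(nrow(sim$truth), 100L)
  expect_true(all(sim$truth$structure == "blunt"))
  expect_false(any(sim$truth$is_germline))

  cfgG <- simConfig(n_reads = 50, germline_fraction = 1, error_rate = 0,
                    seed = 3)
  simG <- simulateJunctionReads(regions, cfgG)
  expect_true(all(simG$truth$is_germline))
  d <- as.character(donorRegion(regions))
  expect_true(all(vapply(as.character(simG$reads), grepl, TRUE, x = d,
                         fixed = TRUE)))

  idx <- scanMotif(regions)
  cfgM <- simConfig(n_reads = 60, break_model = "motif_anchored",
                    decay_sd = 0, error_rate = 0, seed = 5)
  simM <- simulateJunctionReads(regions, cfgM, motif_index = idx)
  expect_true(all(nearestMotifDistance(simM$truth$donor_break, idx) == 0L))
})

test_that("truth records reconstruct the emitted error-free reads exactly", {
  cfg <- simConfig(n_reads = 150, error_rate = 0, seed = 9)
  sim <- simulateJunctionReads(regions, cfg)
  for (i in which(!sim$truth$is_germline)) {
    expect_identical(as.character(sim$reads[[i]]),
                     reconstructRead(sim$truth[i, ], regions, 200L))
  }
  # microhomology truth is realizable: the recorded block exists in both refs
  d <- strsplit(as.character(donorRegion(regions)), "")[[1]]
  a <- strsplit(as.character(regions[["Sg1"]]), "")[[1]]
  mh <- sim$truth[!is.na(sim$truth$structure) &
                    sim$truth$structure == "microhomology", ]
  for (i in seq_len(nrow(mh)))
    expect_identical(bruteMH(d, a, mh$donor_break[i], mh$acceptor_break[i]),
                     mh$mh_len[i])
})

test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simConfig(n_reads = 80, error_rate = 0.01, seed = 21)
  s1 <- simulateJunctionReads(regions, cfg)
  s2 <- simulateJunctionReads(regions, cfg)
  expect_identical(as.character(s1$reads), as.character(s2$reads))
  expect_identical(s1$truth, s2$truth)
  f1 <- tempfile(fileext = ".fastq"); t1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".fastq"); t2 <- tempfile(fileext = ".tsv")
  writeSimulatedReads(s1, f1, t1)
  writeSimulatedReads(s2, f2, t2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_identical(unname(tools::md5sum(t1)), unname(tools::md5sum(t2)))
})

test_that("substitution errors behave like the configured binomial process", {
  reads <- Biostrings::DNAStringSet(setNames(
    rep(strrep("ACGT", 50), 50), sprintf("r%02d", 1:50)))
  expect_identical(as.character(addSequencingErrors(reads, 0)),
                   as.character(reads))
  all_changed <- addSequencingErrors(reads, 1, seed = 2)
  orig <- strsplit(as.character(reads), "")
  mut <- strsplit(as.character(all_changed), "")
  expect_true(all(mapply(function(a, b) all(a != b), orig, mut)))
  # rate 0.01 over 10,000 bases: count within 3 binomial SD of 100
  mutated <- addSequencingErrors(reads, 0.01, seed = 4)
  ndiff <- sum(mapply(function(a, b) sum(a != b), orig,
                      strsplit(as.character(mutated), "")))
  expect_lt(abs(ndiff - 100), 3 * sqrt(10000 * 0.01 * 0.99))
  # deterministic under seed
  expect_identical(as.character(addSequencingErrors(reads, 0.05, seed = 6)),
                   as.character(addSequencingErrors(reads, 0.05, seed = 6)))
})

test_that("uniform break model gives uniform donor breaks over eligible range", {
  cfg <- simConfig(n_reads = 10000, error_rate = 0, seed = 13)
  sim <- simulateJunctionReads(regions, cfg)
  db <- sim$truth$donor_break
  lo <- 99L; hi <- 599L                     # eligible: [read_length/2 - 1, end]
  expect_true(all(db >= lo & db <= hi))
  gof <- suppressWarnings(
    stats::chisq.test(table(factor(db, levels = lo:hi))))
  expect_gt(gof$p.value, 0.01)
})

test_that("zero reads produce an empty but well-formed simulation", {
  sim <- simulateJunctionReads(regions, simConfig(n_reads = 0))
  expect_identical(length(sim$reads), 0L)
  expect_identical(nrow(sim$truth), 0L)
  expect_named(sim$truth, c("read_id", "donor_break", "acceptor_name",
                            "acceptor_break", "structure", "mh_len",
                            "insertion_seq", "is_germline"))
})
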