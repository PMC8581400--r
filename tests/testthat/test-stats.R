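regions <- testRegions()
midx <- scanMotif(regions)

test_that("distance profiles are per cluster and match simple cases", {
  # motif occupies bases 4..7; single junction at distance 3
  s <- paste0("GGGG", "AACT", strrep("G", 42))
  idx <- scanMotif(s, "WRCY", strands = "plus")
  calls <- data.frame(read_id = c("r1", "r2"), donor_break = c(10L, 10L),
                      acceptor_name = "Sg1", acceptor_break = 5L,
                      structure = "blunt", mh_length = 0L, insertion_seq = "",
                      stringsAsFactors = FALSE)
  dp <- distanceProfile(calls, idx, label = "x")
  expect_identical(dp$n, 1L)               # two reads, one cluster
  expect_identical(dp$mean, 3)
  expect_identical(distanceProfile(8L, idx)$mean, 1)
  expect_error(distanceProfile(integer(), idx), "no junctions")
})

test_that("uniform breaks give a mean distance near the exhaustive average", {
  L <- motifRegionName(midx)
  all_pos <- 0:(midx@region_length - 1L)
  exhaustive <- mean(nearestMotifDistance(all_pos, midx))
  withr::local_seed(19)
  br <- sample(all_pos, 10000, replace = TRUE)
  d <- nearestMotifDistance(br, midx)
  se <- stats::sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - exhaustive), 3 * se)
})

test_that("random break simulation is in-range, reproducible and uniform", {
  b <- simulateRandomBreaks(regions, n = 4000, seed = 8)
  expect_length(b, 4000L)
  expect_true(all(b >= 0 & b < length(donorRegion(regions))))
  expect_identical(b, simulateRandomBreaks(regions, n = 4000, seed = 8))
  expect_length(simulateRandomBreaks(regions, n = 1, seed = 1), 1L)
  expect_error(simulateRandomBreaks(regions, n = 0), "positive")
  big <- simulateRandomBreaks(500L, n = 100000, seed = 2)
  gof <- suppressWarnings(stats::chisq.test(table(factor(big, levels = 0:499))))
  expect_gt(gof$p.value, 0.01)
})

test_that("permutation test handles degenerate and exact cases", {
  r <- permutationTest(c(2, 2, 2), c(2, 2, 2), n_permutations = 500, seed = 1)
  expect_identical(r@statistic_observed, 0)
  expect_identical(r@p_value, 1)
  expect_gte(r@p_value, 1 / (r@n_permutations + 1))
  # p is deterministic under a fixed seed
  a <- c(0, 1, 5); b <- c(2, 6, 9)
  p1 <- permutationTest(a, b, 2000, seed = 3)@p_value
  p2 <- permutationTest(a, b, 2000, seed = 3)@p_value
  expect_identical(p1, p2)
})

test_that("approximate p matches full enumeration for two groups of three", {
  withr::local_seed(5)
  for (rep_ in 1:3) {
    a <- round(stats::rexp(3, 1 / 3), 2)
    b <- round(stats::rexp(3, 1 / 2), 2)
    pex <- exactPermP(a, b)
    pt <- permutationTest(a, b, n_permutations = 20000, seed = rep_)
    se <- sqrt(pex * (1 - pex) / 20000)
    expect_lt(abs(pt@p_value - pex), 3 * se + 1e-4)
  }
})

test_that("p-values are invariant to label swap and to location shifts", {
  a <- c(0, 1, 2, 4, 8); b <- c(1, 3, 3, 5, 9, 11)
  p_ab <- permutationTest(a, b, 2000, seed = 7)@p_value
  p_ba <- permutationTest(b, a, 2000, seed = 7)@p_value
  expect_identical(p_ab, p_ba)
  p_shift <- permutationTest(a + 100, b + 100, 2000, seed = 7)@p_value
  expect_identical(p_ab, p_shift)
  expect_error(permutationTest(numeric(), b), "nonempty")
})

test_that("chi-square matches the closed form and drops empty categories", {
  res <- structureChisq(matrix(c(30, 10, 10, 30), 2, byrow = TRUE))
  expect_equal(res$chi2, 20)               # n(ad-bc)^2 / row&col products
  expect_identical(res$df, 1L)
  res0 <- structureChisq(matrix(c(10, 10, 10, 10), 2, byrow = TRUE))
  expect_equal(res0$chi2, 0)
  expect_equal(res0$p, 1)
  # direct-summation oracle on random tables
  withr::local_seed(9)
  for (i in 1:5) {
    m <- matrix(rpois(6, 20) + 1L, 2, 3)
    expect_equal(structureChisq(m)$chi2, bruteChisq(m))
  }
  # all-zero column dropped with warning, df reduced
  m <- cbind(matrix(c(12, 5, 9, 14), 2), c(0, 0))
  colnames(m) <- c("blunt", "microhomology", "insertion")
  expect_warning(resz <- structureChisq(m), "insertion")
  expect_identical(resz$df, 1L)
  expect_error(structureChisq(matrix(1:3, 1)), "two groups")
  expect_error(suppressWarnings(structureChisq(matrix(c(1, 2, 0, 0), 2))),
               "surviving")
  expect_error(structureChisq(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "at least one junction")
})

test_that("group reports summarize, test pairwise and echo parameters", {
  cfgA <- simConfig(n_reads = 150, error_rate = 0, seed = 41,
                    break_model = "motif_anchored", decay_sd = 1)
  cfgB <- simConfig(n_reads = 150, error_rate = 0, seed = 43)
  simA <- simulateJunctionReads(regions, cfgA, motif_index = midx)
  simB <- simulateJunctionReads(regions, cfgB)
  calls <- list(WT = callJunctions(simA$reads, regions),
                AID = callJunctions(simB$reads, regions))
  rep_ <- compareGroupsReport(calls, regions, midx, n_random = 500,
                              n_permutations = 500, seed = 2)
  expect_s3_class(rep_, "csrGroupReport")
  expect_named(rep_$groups, c("WT", "AID"))
  labs <- c(rep_$distance_tests$group_a, rep_$distance_tests$group_b)
  expect_true("random" %in% labs)
  expect_identical(nrow(rep_$distance_tests), 3L)   # WT/AID/random pairwise
  expect_true(all(rep_$distance_tests$p_holm >= rep_$distance_tests$p))
  expect_identical(rep_$params$seed, 2L)
  expect_identical(nrow(rep_$structure_tests), 1L)
  expect_output(print(rep_), "permutation")
})

test_that("single-group reports are descriptive only", {
  cfg <- simConfig(n_reads = 60, error_rate = 0, seed = 47)
  sim <- simulateJunctionReads(regions, cfg)
  calls <- list(only = callJunctions(sim$reads, regions))
  rep_ <- compareGroupsReport(calls, regions, midx, n_random = 0,
                              n_permutations = 100, seed = 1)
  expect_null(rep_$distance_tests)
  expect_null(rep_$structure_tests)
  expect_identical(rep_$groups$only$n_junction_reads, 60L)
  # a group with zero clusters is excluded from tests but noted
  rep2 <- compareGroupsReport(c(calls, list(empty = calls$only[0, ])),
                              regions, midx, n_random = 0,
                              n_permutations = 100, seed = 1)
  expect_match(rep2$groups$empty$note, "excluded")
  expect_null(rep2$distance_tests)
})
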