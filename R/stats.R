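#' @importFrom stats chisq.test p.adjust setNames
NULL

#' Breakpoint-to-motif distance profile
#'
#' Scores, for each junction *cluster* (not each read, so PCR duplicates do
#' not dominate), the distance from its donor break to the nearest
#' motif-covered base. Raw break positions can be supplied directly as an
#' integer vector (used for the simulated random reference).
#'
#' @param x A call table from [callJunctions()] (clustered internally), a
#'   cluster table from [clusterJunctions()], or an integer vector of
#'   0-based break positions.
#' @param motif_index A non-empty [MotifIndex] over the donor region.
#' @param label Group label carried into downstream tests.
#' @return A list of class `DistanceSample` with `label`, `distances`,
#'   `mean`, `n`.
#' @export
distanceProfile <- function(x, motif_index, label = "sample") {
  if (is.data.frame(x)) {
    if (!"read_count" %in% names(x)) x <- clusterJunctions(x)
    breaks <- x$donor_break
  } else {
    breaks <- as.integer(x)
  }
  if (length(breaks) == 0L)
    stop("no junctions to profile", call. = FALSE)
  d <- nearestMotifDistance(breaks, motif_index)
  structure(list(label = label, distances = d, mean = mean(d),
                 n = length(d)),
            class = "DistanceSample")
}

#' @export
print.DistanceSample <- function(x, ...) {
  cat(sprintf("DistanceSample '%s': n = %d, mean = %.3f nt (range %d-%d)\n",
              x$label, x$n, x$mean, min(x$distances), max(x$distances)))
  invisible(x)
}

#' Simulate random DNA breaks in a region
#'
#' Draws `n` break positions uniformly with replacement over the bases of a
#' region (by default its whole extent), the in-silico reference
#' distribution against which observed break patterns are compared.
#'
#' @param region A [SwitchRegionSet] (the donor region is used), a
#'   [Biostrings::DNAString], or an integer region length.
#' @param n Number of breaks (default 4000).
#' @param seed Integer RNG seed.
#' @return Integer vector of `n` 0-based positions.
#' @export
simulateRandomBreaks <- function(region, n = 4000L, seed = 1L) {
  if (n <= 0L) stop("n must be a positive count", call. = FALSE)
  L <- if (is(region, "SwitchRegionSet")) length(donorRegion(region))
  else if (is.numeric(region)) as.integer(region)
  else length(region)
  withr::local_seed(seed)
  sample.int(L, n, replace = TRUE) - 1L
}

#' Result of an approximate permutation test
#'
#' @slot statistic_observed Observed `|mean(A) - mean(B)|`.
#' @slot p_value Add-one Monte-Carlo estimate
#'   `(1 + #{permuted >= observed}) / (1 + n_permutations)`; never below
#'   `1 / (n_permutations + 1)`.
#' @slot n_permutations Number of random label permutations.
#' @slot seed RNG seed used.
#' @slot group_sizes Sizes of the two groups.
#' @slot labels Group labels.
#' @export
setClass("PermutationResult", representation(
  statistic_observed = "numeric",
  p_value = "numeric",
  n_permutations = "integer",
  seed = "integer",
  group_sizes = "integer",
  labels = "character"
))

setValidity("PermutationResult", function(object) {
  msg <- character()
  if (object@p_value <= 0 || object@p_value > 1)
    msg <- c(msg, "p_value must lie in (0, 1]")
  if (object@p_value < 1 / (object@n_permutations + 1) - 1e-12)
    msg <- c(msg, "p_value below the add-one floor")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PermutationResult", function(object) {
  cat(sprintf(
    paste0("PermutationResult: |mean(%s) - mean(%s)| = %.4f\n",
           "  p = %.3g (%d permutations, group sizes %d/%d, seed %d)\n"),
    object@labels[1], object@labels[2], object@statistic_observed,
    object@p_value, object@n_permutations, object@group_sizes[1],
    object@group_sizes[2], object@seed))
})

.sampleValues <- function(x) {
  if (inherits(x, "DistanceSample")) x$distances else as.numeric(x)
}
.sampleLabel <- function(x, default) {
  if (inherits(x, "DistanceSample")) x$label else default
}

#' Approximate permutation test on the difference of group means
#'
#' Tests whether two samples (typically breakpoint-to-motif distance
#' profiles) share a mean, using the statistic `|mean(A) - mean(B)|` and an
#' approximate permutation distribution: group labels are shuffled over the
#' pooled values `n_permutations` times preserving group sizes, and the
#' p-value is the add-one estimator
#' `(1 + #{permuted statistic >= observed}) / (1 + n_permutations)`.
#'
#' Each permutation draws, with a shared canonical size (the smaller group),
#' so the p-value is exactly invariant to swapping the two group labels
#' under the same seed, and - because the statistic is a difference of
#' means - to adding a constant to all values.
#'
#' @param a,b `DistanceSample`s (see [distanceProfile()]) or numeric
#'   vectors; both must be nonempty.
#' @param n_permutations Number of permutations (default 100000).
#' @param seed Integer RNG seed.
#' @return A [PermutationResult-class] object.
#' @export
permutationTest <- function(a, b, n_permutations = 100000L, seed = 1L) {
  va <- .sampleValues(a); vb <- .sampleValues(b)
  la <- .sampleLabel(a, "A"); lb <- .sampleLabel(b, "B")
  na <- length(va); nb <- length(vb)
  if (na == 0L || nb == 0L)
    stop("both groups must be nonempty", call. = FALSE)
  n_permutations <- as.integer(n_permutations)
  obs <- abs(mean(va) - mean(vb))
  pool <- sort(c(va, vb))   # canonical order: p is label-swap invariant
  ntot <- na + nb
  m <- min(na, nb)
  tot <- sum(pool)
  tol <- 1e-12 * max(1, obs)
  withr::local_seed(seed)
  cnt <- 0L
  for (i in seq_len(n_permutations)) {
    s <- sum(pool[sample.int(ntot, m)])
    st <- abs(s / m - (tot - s) / (ntot - m))
    if (st >= obs - tol) cnt <- cnt + 1L
  }
  new("PermutationResult",
      statistic_observed = obs,
      p_value = (1 + cnt) / (1 + n_permutations),
      n_permutations = n_permutations,
      seed = as.integer(seed),
      group_sizes = c(na, nb),
      labels = c(la, lb))
}

#' Chi-square test of junction-structure composition
#'
#' Pearson chi-square test (no continuity correction) of homogeneity of a
#' groups x structure-categories count table. Columns whose expected counts
#' are all zero (i.e. all-zero columns) are dropped with a warning before
#' testing; degrees of freedom are `(rows - 1) * (surviving columns - 1)`.
#'
#' @param table Integer matrix of counts, rows = groups, columns =
#'   structure categories (e.g. blunt / microhomology / insertion).
#' @return A list with `chi2`, `df`, `p`, and the `table` actually tested.
#' @export
structureChisq <- function(table) {
  m <- as.matrix(table)
  if (any(m < 0) || any(m != round(m)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (nrow(m) < 2L)
    stop("need at least two groups", call. = FALSE)
  if (any(rowSums(m) == 0))
    stop("every tested group must have at least one junction", call. = FALSE)
  zero <- colSums(m) == 0
  if (any(zero)) {
    warning(sprintf("dropping all-zero column(s): %s",
                    paste(colnames(m)[zero] %||% which(zero), collapse = ", ")),
            call. = FALSE)
    m <- m[, !zero, drop = FALSE]
  }
  if (ncol(m) < 2L)
    stop("need at least two surviving categories", call. = FALSE)
  ct <- suppressWarnings(chisq.test(m, correct = FALSE))
  list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value), table = m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Group comparison report
#'
#' The inferential layer over called junctions: per-group read, cluster and
#' structure summaries; pairwise permutation tests on breakpoint-to-motif
#' distance profiles, including each group against a simulated random-break
#' reference within the donor region; and pairwise chi-square tests on
#' structure composition. Pairwise p-values are reported raw with a
#' Holm-adjusted column alongside. All seeds and parameters are echoed into
#' the report.
#'
#' @param group_calls Named list of call tables (one per group label).
#' @param regions The [SwitchRegionSet] used for calling.
#' @param motif_index A [MotifIndex] over the donor (default: WRCY scan of
#'   the donor, both strands).
#' @param n_random Size of the random-break reference (default 4000;
#'   `NULL`/0 disables it).
#' @param n_permutations Permutations per test (default 100000).
#' @param seed Integer master seed; per-test seeds are derived from it.
#' @return A list of class `csrGroupReport`.
#' @export
compareGroupsReport <- function(group_calls, regions, motif_index = NULL,
                                n_random = 4000L, n_permutations = 100000L,
                                seed = 1L) {
  stopifnot(length(group_calls) >= 1L, !is.null(names(group_calls)))
  if (is.null(motif_index)) motif_index <- scanMotif(regions)
  seed <- as.integer(seed)

  groups <- list()
  profiles <- list()
  tables <- list()
  for (lab in names(group_calls)) {
    calls <- group_calls[[lab]]
    cl <- clusterJunctions(calls)
    ss <- summarizeStructures(calls)
    groups[[lab]] <- list(
      n_junction_reads = nrow(calls),
      n_clusters = nrow(cl),
      structure = list(counts = as.list(ss$counts),
                       fractions = as.list(ss$fractions),
                       mean_mh_length = ss$mean_mh_length,
                       mean_insertion_length = ss$mean_insertion_length))
    if (nrow(cl) > 0L) {
      profiles[[lab]] <- distanceProfile(cl, motif_index, label = lab)
      groups[[lab]]$mean_motif_distance <- profiles[[lab]]$mean
      tables[[lab]] <- ss$counts
    } else {
      groups[[lab]]$note <- "no clusters; excluded from tests"
    }
  }
  if (!is.null(n_random) && n_random > 0L) {
    rb <- simulateRandomBreaks(regions, n = n_random, seed = seed)
    profiles[["random"]] <- distanceProfile(rb, motif_index, label = "random")
  }

  dist_tests <- NULL
  if (length(profiles) >= 2L) {
    labs <- names(profiles)
    prs <- utils::combn(labs, 2L)
    rows <- lapply(seq_len(ncol(prs)), function(j) {
      pt <- permutationTest(profiles[[prs[1, j]]], profiles[[prs[2, j]]],
                            n_permutations = n_permutations,
                            seed = seed + j)
      data.frame(group_a = prs[1, j], group_b = prs[2, j],
                 mean_a = profiles[[prs[1, j]]]$mean,
                 mean_b = profiles[[prs[2, j]]]$mean,
                 observed = pt@statistic_observed, p = pt@p_value,
                 n_permutations = n_permutations, seed = seed + j,
                 stringsAsFactors = FALSE)
    })
    dist_tests <- do.call(rbind, rows)
    dist_tests$p_holm <- p.adjust(dist_tests$p, method = "holm")
  }

  struct_tests <- NULL
  if (length(tables) >= 2L) {
    labs <- names(tables)
    prs <- utils::combn(labs, 2L)
    rows <- lapply(seq_len(ncol(prs)), function(j) {
      tab <- rbind(tables[[prs[1, j]]], tables[[prs[2, j]]])
      res <- tryCatch(suppressWarnings(structureChisq(tab)),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      data.frame(group_a = prs[1, j], group_b = prs[2, j],
                 chi2 = res$chi2, df = res$df, p = res$p,
                 stringsAsFactors = FALSE)
    })
    rows <- Filter(Negate(is.null), rows)
    if (length(rows)) {
      struct_tests <- do.call(rbind, rows)
      struct_tests$p_holm <- p.adjust(struct_tests$p, method = "holm")
    }
  }

  structure(list(
    params = list(seed = seed, n_permutations = n_permutations,
                  n_random = n_random, motif = motif_index@motif,
                  motif_strands = motif_index@strands,
                  coordinate_convention =
                    "0-based, half-open; donor-maximal breakpoints"),
    groups = groups,
    distance_tests = dist_tests,
    structure_tests = struct_tests),
    class = "csrGroupReport")
}

#' @export
print.csrGroupReport <- function(x, ...) {
  cat("CSR junction group report\n")
  for (lab in names(x$groups)) {
    g <- x$groups[[lab]]
    cat(sprintf("  %-12s %5d junction reads, %5d clusters%s\n", lab,
                g$n_junction_reads, g$n_clusters,
                if (!is.null(g$mean_motif_distance))
                  sprintf(", mean motif distance %.2f nt",
                          g$mean_motif_distance) else ""))
  }
  if (!is.null(x$distance_tests)) {
    cat("  distance permutation tests:\n")
    for (i in seq_len(nrow(x$distance_tests)))
      cat(sprintf("    %s vs %s: |d-mean| = %.3f, p = %.3g (holm %.3g)\n",
                  x$distance_tests$group_a[i], x$distance_tests$group_b[i],
                  x$distance_tests$observed[i], x$distance_tests$p[i],
                  x$distance_tests$p_holm[i]))
  }
  if (!is.null(x$structure_tests)) {
    cat("  structure chi-square tests:\n")
    for (i in seq_len(nrow(x$structure_tests)))
      cat(sprintf("    %s vs %s: chi2 = %.2f (df %d), p = %.3g (holm %.3g)\n",
                  x$structure_tests$group_a[i], x$structure_tests$group_b[i],
                  x$structure_tests$chi2[i], x$structure_tests$df[i],
                  x$structure_tests$p[i], x$structure_tests$p_holm[i]))
  }
  invisible(x)
}
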