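test_that("mismatch frequency is pooled over all don't-care positions", {
  one <- data.frame(mismatches = 0L, dontcareN = 60L)
  expect_equal(estimateP(one)$pRaw, 0)

  six <- data.frame(mismatches = 6L, dontcareN = 60L)
  expect_equal(estimateP(six)$pRaw, 0.1)

  two <- data.frame(mismatches = c(0L, 12L), dontcareN = c(60L, 60L))
  r <- estimateP(two)
  expect_equal(r$pRaw, 12 / 120)
  expect_equal(r$totalMismatch, 12)
  expect_equal(r$totalDontCare, 120)
  expect_equal(r$nMatches, 2L)

  none <- estimateP(two[0, ])
  expect_true(is.na(none$pRaw))
  expect_equal(none$nMatches, 0L)
})

test_that("error correction inverts the uniform sequencing channel", {
  # identity channel
  for (mode in c("genome_vs_genome", "genome_vs_reads", "reads_vs_reads"))
    expect_equal(correctError(0.3, mode, errorRate = 0), 0.3)
  # genome comparisons never correct
  expect_equal(correctError(0.3, "genome_vs_genome", 0.0024), 0.3)
  # pure sequencing error maps to zero divergence
  e <- 0.0024
  expect_equal(correctError(e, "genome_vs_reads", e), 0)
  eHat2 <- 2 * e - (4 / 3) * e^2
  expect_equal(correctError(eHat2, "reads_vs_reads", e), 0)
  # worked value
  expect_equal(correctError(0.1, "genome_vs_reads", 0.0024),
               (0.1 - 0.0024) / (1 - 0.0032), tolerance = 1e-12)
  expect_lt(abs(correctError(0.1, "genome_vs_reads", 0.0024) - 0.097913),
            1e-6)
  # clamped at zero below the error floor
  expect_equal(correctError(0.001, "genome_vs_reads", 0.0024), 0)
})

test_that("forward channel then correction is the identity", {
  forward <- function(p, eHat) p * (1 - (4 / 3) * eHat) + eHat
  for (mode in c("genome_vs_genome", "genome_vs_reads", "reads_vs_reads")) {
    e <- 0.0024
    eHat <- switch(mode, genome_vs_genome = 0, genome_vs_reads = e,
                   reads_vs_reads = 2 * e - (4 / 3) * e^2)
    p <- seq(0, 0.74, by = 0.01)
    expect_equal(correctError(forward(p, eHat), mode, e), p,
                 tolerance = 1e-12)
  }
})

test_that("Jukes-Cantor correction matches the closed form", {
  expect_equal(jukesCantor(0), 0)
  expect_equal(jukesCantor(0.1), -0.75 * log(1 - 0.4 / 3))
  expect_lt(abs(jukesCantor(0.1) - 0.107326), 1e-6)
  expect_true(is.na(jukesCantor(0.75)))
  expect_true(is.na(jukesCantor(0.9)))
  # strictly increasing on [0, 0.75)
  p <- seq(0, 0.74, by = 0.005)
  expect_true(all(diff(jukesCantor(p)) > 0))
  # exact inverse of the forward channel
  d <- seq(0, 3, by = 0.01)
  expect_equal(jukesCantor(pOfD(d)), d, tolerance = 1e-12)
})

test_that("error-free reads from the genome itself give distance zero", {
  g <- randomGenome(20000, seed = 301)
  r <- simulateReads(g, coverage = 1, errorRate = 0, seed = 302)
  est <- estimateDistance(g, r)
  expect_true(isDefined(est))
  expect_identical(est@mode, "genome_vs_reads")
  expect_lte(jcDistance(est), 0.001)
})

test_that("no retained matches yields an undefined estimate with a reason", {
  a <- randomGenome(300, seed = 303, taxon = "a")
  b <- randomGenome(300, seed = 304, taxon = "b")
  est <- estimateDistance(a, b)
  expect_false(isDefined(est))
  expect_true(is.na(jcDistance(est)))
  expect_identical(undefinedReason(est), "no spaced-word matches")
  expect_identical(est@mode, "genome_vs_genome")
})

test_that("genome-vs-genome distance is symmetric in its inputs", {
  # exact symmetry needs a reversal-symmetric pattern: reverse-strand
  # matches of d(B, A) correspond to those of d(A, B) under pattern
  # reversal, so a palindromic mask makes the correspondence exact
  pal <- spacedPattern("1010100101010010101")
  g <- randomGenome(40000, seed = 305, taxon = "a")
  e <- evolveGenome(g, dTrue = 0.08, seed = 306, taxon = "b")
  ab <- estimateDistance(g, e, pattern = pal)
  ba <- estimateDistance(e, g, pattern = pal)
  expect_true(isDefined(ab))
  expect_identical(jcDistance(ab), jcDistance(ba))
  expect_identical(nMatches(ab), nMatches(ba))
  # with the (asymmetric) default seed, symmetry holds for the
  # forward strand and approximately overall
  ab2 <- estimateDistance(g, e)
  ba2 <- estimateDistance(e, g)
  expect_equal(jcDistance(ab2), jcDistance(ba2), tolerance = 0.01)
})

test_that("comparison mode follows the input roles", {
  g <- randomGenome(20000, seed = 307)
  r1 <- simulateReads(g, coverage = 0.2, seed = 308, taxon = "r1")
  r2 <- simulateReads(g, coverage = 0.2, seed = 309, taxon = "r2")
  expect_identical(estimateDistance(r1, r2)@mode, "reads_vs_reads")
  expect_identical(estimateDistance(g, r1)@mode, "genome_vs_reads")
  expect_identical(estimateDistance(r1, g)@mode, "genome_vs_reads")
})

test_that("fragment bounds tile the genome with ell-1 overlaps", {
  ell <- 72L
  g <- randomDNA(10000)
  b <- fragmentBounds(g, 25L, ell)
  expect_equal(nrow(b), 25L)
  expect_equal(b$start[1L], 1L)
  expect_equal(b$end[25L], 10000L)
  # neighbouring fragments overlap by ell - 1
  expect_true(all(b$end[-25L] - b$start[-1L] + 1L == ell - 1L))
  expect_error(fragmentBounds(randomDNA(80), 25L, ell), "too short")
})

test_that("fragmented comparison of a genome with itself gives zero", {
  g <- randomGenome(30000, seed = 310)
  fe <- fragmentedDistance(g, g, nFragments = 20L)
  expect_s4_class(fe, "FragmentedEstimate")
  expect_true(isDefined(fe))
  expect_equal(fe@nUndefined, 0L)
  expect_equal(jcDistance(fe), 0)
  # the reported distance is the unweighted mean over defined fragments
  expect_equal(jcDistance(fe),
               mean(fe@perFragment$distance, na.rm = TRUE))
})
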