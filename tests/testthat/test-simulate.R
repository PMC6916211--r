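test_that("generators are reproducible and leave the caller's RNG alone", {
  g1 <- randomGenome(5000, seed = 8)
  g2 <- randomGenome(5000, seed = 8)
  g3 <- randomGenome(5000, seed = 9)
  expect_identical(as.character(sequences(g1)), as.character(sequences(g2)))
  expect_false(identical(as.character(sequences(g1)),
                         as.character(sequences(g3))))

  set.seed(123)
  before <- runif(1)
  set.seed(123)
  invisible(randomGenome(1000, seed = 4))
  invisible(evolveGenome(g1, 0.1, seed = 5))
  invisible(simulateReads(g1, coverage = 0.5, seed = 6))
  expect_identical(runif(1), before)

  e1 <- evolveGenome(g1, 0.2, seed = 77)
  e2 <- evolveGenome(g1, 0.2, seed = 77)
  expect_identical(as.character(sequences(e1)), as.character(sequences(e2)))
  r1 <- simulateReads(g1, coverage = 1, seed = 78)
  r2 <- simulateReads(g1, coverage = 1, seed = 78)
  expect_identical(as.character(sequences(r1)), as.character(sequences(r2)))
})

test_that("random genomes are uniform over A/C/G/T", {
  g <- randomGenome(1000000, seed = 21)
  expect_equal(totalLength(g), 1000000L)
  s <- as.character(sequences(g))[[1L]]
  freq <- table(strsplit(s, "", fixed = TRUE)[[1L]]) / nchar(s)
  expect_setequal(names(freq), c("A", "C", "G", "T"))
  expect_true(all(abs(freq - 0.25) < 0.002))
})

test_that("substitution channel hits the Jukes-Cantor mismatch fraction", {
  g <- randomGenome(1000000, seed = 22)
  ev <- evolveGenome(g, dTrue = 0.1, indelProb = 0, seed = 23)
  a <- strsplit(as.character(sequences(g))[[1L]], "", fixed = TRUE)[[1L]]
  b <- strsplit(as.character(sequences(ev))[[1L]], "", fixed = TRUE)[[1L]]
  expect_length(b, length(a))
  mismatch <- mean(a != b)
  expect_lt(abs(mismatch - pOfD(0.1)), 0.001)
  gt <- attr(ev, "groundTruth")
  # every substitution event changes the base, so counts agree exactly
  expect_equal(sum(a != b), gt$nSubstituted)

  # null channel
  same <- evolveGenome(g, dTrue = 0, indelProb = 0, seed = 24)
  expect_identical(as.character(sequences(same))[[1L]],
                   as.character(sequences(g))[[1L]])
})

test_that("indel events appear at 1% of positions with uniform lengths", {
  g <- randomGenome(1000000, seed = 25)
  ev <- evolveGenome(g, dTrue = 0, indelProb = 0.01, seed = 26)
  gt <- attr(ev, "groundTruth")
  k <- gt$nInsertions + gt$nDeletions
  # binomial(1e6, 0.01): 3 sigma is ~300 around 10000
  expect_gt(k, 10000 - 300)
  expect_lt(k, 10000 + 300)
  # insertion/deletion split is close to 50/50
  expect_gt(gt$nInsertions / k, 0.45)
  expect_lt(gt$nInsertions / k, 0.55)
})

test_that("indel lengths are uniform on 1..100", {
  # exercise the length distribution through many small genomes
  set.seed(27)
  lens <- integer(0)
  g <- randomGenome(200000, seed = 28)
  s <- as.character(sequences(g))[[1L]]
  for (i in 1:5) {
    ev <- evolveGenome(s, dTrue = 0, indelProb = 0.01,
                       insertionFraction = 1, seed = 28 + i)
    # with only insertions, total added length = sum of event lengths
    lensum <- totalLength(ev) - nchar(s)
    k <- attr(ev, "groundTruth")$nInsertions
    # mean event length ~ 50.5, sd ~ 28.9/sqrt(k)
    expect_equal(lensum / k, 50.5, tolerance = 4 * 28.9 / sqrt(k) / 50.5)
    lens <- c(lens, lensum)
  }
})

test_that("read counts, lengths and coverage follow the configuration", {
  g <- randomGenome(150000, seed = 30)
  r <- simulateReads(g, coverage = 1, readLength = 150, seed = 31)
  expect_equal(length(sequences(r)), 1000L)
  expect_true(all(Biostrings::width(sequences(r)) == 150L))
  expect_equal(totalLength(r), 150000L)
  expect_identical(seqRole(r), "reads")

  half <- simulateReads(g, coverage = 2^-4, readLength = 150, seed = 32)
  expect_equal(length(sequences(half)), round(150000 / 16 / 150))
  expect_error(simulateReads(randomGenome(100, seed = 1), coverage = 1),
               "shorter")
})

test_that("error-free reads are exact substrings of the genome or its rc", {
  g <- randomGenome(30000, seed = 33)
  s <- as.character(sequences(g))[[1L]]
  rc <- revComp(s)
  r <- simulateReads(g, coverage = 0.25, errorRate = 0, seed = 34)
  reads <- as.character(sequences(r))
  hit <- vapply(reads, function(x)
    grepl(x, s, fixed = TRUE) || grepl(x, rc, fixed = TRUE), TRUE)
  expect_true(all(hit))
})

test_that("the sequencing error rate is realised at 0.24% per base", {
  g <- randomGenome(1000000, seed = 35)
  clean <- simulateReads(g, coverage = 1, errorRate = 0, seed = 36)
  noisy <- simulateReads(g, coverage = 1, errorRate = 0.0024, seed = 36)
  a <- paste(as.character(sequences(clean)), collapse = "")
  b <- paste(as.character(sequences(noisy)), collapse = "")
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  rate <- mean(av != bv)
  expect_equal(rate, 0.0024, tolerance = 0.0003 / 0.0024)
})

test_that("evolution along a tree composes additively", {
  # zero-length star: leaves identical to the root
  star <- ape::read.tree(text = "(a:0,b:0,c:0);")
  root <- randomGenome(20000, seed = 40)
  leaves <- evolveAlongTree(root, star, seed = 41)
  expect_setequal(names(leaves), c("a", "b", "c"))
  for (l in leaves)
    expect_identical(as.character(sequences(l))[[1L]],
                     as.character(sequences(root))[[1L]])

  # two leaves at a + b apart: empirical JC distance ~ a + b
  two <- ape::read.tree(text = "(x:0.06,y:0.1);")
  root2 <- randomGenome(1000000, seed = 42)
  lv <- evolveAlongTree(root2, two, seed = 43)
  xa <- strsplit(as.character(sequences(lv$x))[[1L]], "", fixed = TRUE)[[1L]]
  ya <- strsplit(as.character(sequences(lv$y))[[1L]], "", fixed = TRUE)[[1L]]
  d <- jukesCantor(mean(xa != ya))
  expect_lt(abs(d - 0.16), 0.01)
})
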