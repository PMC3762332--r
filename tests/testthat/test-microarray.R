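test_that("spot tables parse, with format and value errors on bad input", {
  tf <- tempfile(fileext = ".tsv")
  tab <- data.frame(Block = 1, Row = c(1, 1, 2, 2), Column = c(1, 2, 1, 2),
                    Name = c("P1", "P1", "P2", "P2"),
                    F_Median = c(2000, 1000, 500, 500),
                    B_Median = c(500, 500, 500, 500), Flag = 0)
  write.table(tab, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  spots <- readSpotTable(tf, arrayId = "A")
  expect_equal(nrow(spots), 4)
  expect_equal(spots$F / spots$B, c(4, 2, 1, 1))
  expect_true(all(spots$flag == "ok"))

  write.table(tab[, setdiff(names(tab), "B_Median")], tf, sep = "\t",
              row.names = FALSE, quote = FALSE)
  expect_error(readSpotTable(tf), "B_Median")

  tab$B_Median[2] <- 0
  write.table(tab, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  expect_error(readSpotTable(tf), "row 2")

  # excluded rows are retained but marked, even with B = 0
  tab$Flag[2] <- -100
  write.table(tab, tf, sep = "\t", row.names = FALSE, quote = FALSE)
  spots <- readSpotTable(tf)
  expect_equal(spots$flag, c("ok", "excluded", "ok", "ok"))
})

test_that("raw intensity is F/B with excluded spots masked", {
  spots <- data.frame(protein_id = c("P1", "P1", "P2", "P2"),
                      row = c(1, 1, 2, 2), col = c(1, 2, 1, 2),
                      F = c(2000, 500, 100, 1), B = c(500, 500, 200, 2),
                      flag = c("ok", "ok", "ok", "excluded"))
  g <- computeRawIntensity(spots)
  expect_equal(gridValues(g)[1, 1], 4)
  expect_equal(gridValues(g)[1, 2], 1)
  expect_true(is.na(gridValues(g)[2, 2]))

  spots$row <- 1; spots$col <- 1
  expect_error(computeRawIntensity(spots), "duplicate")
})

test_that("local normalization matches identities and is median-robust", {
  const <- gridFromMatrix(matrix(4, 9, 9))
  expect_true(all(gridValues(localNormalize(const, 9)) == 1))

  spike <- matrix(1, 9, 9); spike[5, 5] <- 10
  norm <- localNormalize(gridFromMatrix(spike), 9)
  expect_equal(gridValues(norm)[5, 5], 10)
  expect_equal(gridValues(norm)[1, 1], 1)

  expect_error(localNormalize(const, 4), "odd")
})

test_that("window medians agree with a brute-force oracle, incl. edges and NAs", {
  set.seed(11)
  for (dims in list(c(5, 5), c(12, 7), c(3, 12))) {
    for (window in c(3, 5, 9)) {
      m <- matrix(exp(rnorm(prod(dims), 0, 0.3)), dims[1], dims[2])
      m[sample(length(m), length(m) %/% 10)] <- NA
      got <- gridValues(localNormalize(gridFromMatrix(m), window))
      expect_equal(got, bruteWindowNormalize(m, window))
    }
  }
})

test_that("mirrored-shadow noise model matches the hand-computed example", {
  nm <- estimateNoise(c(0.8, 0.9, 0.95, 1.3, 5.0), minShadow = 3)
  expect_equal(noiseMean(nm), 1, tolerance = 1e-12)
  expect_equal(noiseSd(nm), sqrt(2 * (0.04 + 0.01 + 0.0025) / 6),
               tolerance = 1e-12)
  expect_equal(nShadow(nm), 3L)
})

test_that("noise estimation fails on an empty shadow and recovers a known SD", {
  expect_error(estimateNoise(c(1.0, 1.2, 2, 3), minShadow = 2),
               "degenerate")
  set.seed(5)
  nm <- estimateNoise(rnorm(10000, 1, 0.1))
  expect_equal(noiseMean(nm), 1, tolerance = 1e-12)
  expect_lt(abs(noiseSd(nm) - 0.1) / 0.1, 0.03)
})

test_that("noise mean is 1 by construction for arbitrary inputs", {
  set.seed(21)
  for (i in 1:25) {
    x <- exp(rnorm(200, 0, runif(1, 0.05, 0.5)))
    nm <- estimateNoise(x)
    expect_equal(noiseMean(nm), 1, tolerance = 1e-12)
  }
})

test_that("Z-scores center, scale and propagate missingness", {
  nm <- estimateNoise(c(0.8, 0.9, 0.95, 1.3, 5.0), minShadow = 3)
  expect_equal(computeZScores(noiseMean(nm), nm), 0)
  expect_equal(computeZScores(noiseMean(nm) + 3 * noiseSd(nm), nm), 3)
  expect_equal(computeZScores(1.3969, nm), 3.0, tolerance = 1e-3)
  g <- gridFromMatrix(matrix(c(1, NA, 1.1323, 1), 2, 2))
  z <- computeZScores(g, nm)
  expect_true(is.na(gridValues(z)[2, 1]))
})

test_that("Z-scores are invariant to rescaling F and B by a common factor", {
  set.seed(31)
  spots <- genMicroarray(nProteins = 64, nBinders = 2, nRows = 8,
                         seed = 3)$arrayA
  run <- function(sp) {
    g <- localNormalize(computeRawIntensity(sp), 5)
    gridValues(computeZScores(g, estimateNoise(g)))
  }
  scaled <- spots
  scaled$F <- spots$F * 7.5
  scaled$B <- spots$B * 7.5
  expect_equal(run(scaled), run(spots), tolerance = 1e-12)
})

test_that("hit calling enforces the all-four-spots rule", {
  mkZ <- function(z) {
    m <- matrix(z, 1, 4)
    g1 <- new("ArrayGrid", arrayId = "A",
              values = matrix(z[1:2], 1, 2),
              spots = data.frame(protein_id = "P1", row = 1, col = 1:2,
                                 flag = "ok"), stage = "Z")
    g2 <- initialize(g1, arrayId = "B", values = matrix(z[3:4], 1, 2))
    callHits(g1, g2, "M1")
  }
  expect_true(isHit(mkZ(c(3.2, 4.0, 3.1, 5.0)))[["P1"]])
  expect_false(isHit(mkZ(c(3.2, 4.0, 2.9, 5.0)))[["P1"]])
  expect_true(isHit(mkZ(c(3, 3, 3, 3)))[["P1"]])   # inclusive cutoff
  expect_false(isHit(mkZ(c(3, 3, 3, NA)))[["P1"]]) # missing spot: never a hit

  empty <- new("ArrayGrid", arrayId = "A",
               values = matrix(numeric(), 0, 0),
               spots = data.frame(protein_id = character(),
                                  row = integer(), col = integer(),
                                  flag = character()), stage = "Z")
  ht <- callHits(empty, empty, "M1")
  expect_length(isHit(ht), 0)
})

test_that("hit calling rejects mismatched layouts and non-duplicate spots", {
  g1 <- new("ArrayGrid", arrayId = "A", values = matrix(5, 1, 2),
            spots = data.frame(protein_id = "P1", row = 1, col = 1:2,
                               flag = "ok"), stage = "Z")
  g3 <- initialize(g1, spots = data.frame(protein_id = "P2", row = 1,
                                          col = 1:2, flag = "ok"))
  expect_error(callHits(g1, g3), "mismatched")
  g4 <- new("ArrayGrid", arrayId = "A", values = matrix(5, 1, 3),
            spots = data.frame(protein_id = "P1", row = 1, col = 1:3,
                               flag = "ok"), stage = "Z")
  expect_error(callHits(g4, g4), "2 spots")
})

test_that("replicate correlation is 1 for identical/affine grids, ~0 for noise", {
  set.seed(41)
  m <- matrix(rnorm(100), 10, 10)
  a <- gridFromMatrix(m)
  expect_equal(replicateCorrelation(a, a), 1)
  expect_equal(replicateCorrelation(a, gridFromMatrix(2 * m + 1)), 1)
  n1 <- gridFromMatrix(matrix(rnorm(1000), 25, 40))
  n2 <- gridFromMatrix(matrix(rnorm(1000), 25, 40))
  expect_lt(abs(replicateCorrelation(n1, n2)), 0.1)
  tiny <- gridFromMatrix(matrix(c(1, NA, NA, NA), 2, 2))
  expect_error(replicateCorrelation(tiny, tiny), "fewer than 3")
})

test_that("planted binders are recovered with high recall and no false calls", {
  sim <- genMicroarray(nProteins = 256, nBinders = 5, nRows = 16, seed = 9)
  res <- analyzeArrayPair(sim$arrayA, sim$arrayB, "M1")
  found <- hitProteins(res$hits)
  expect_gte(length(intersect(found, sim$truth)), 4)
  expect_lte(length(setdiff(found, sim$truth)), 1)
})
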