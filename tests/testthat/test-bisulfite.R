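mkCalls <- function(mat, positions = seq_len(ncol(mat)),
                    prefix = "r") {
  dimnames(mat) <- list(paste0(prefix, seq_len(nrow(mat))), positions)
  mat
}

test_that("site methylation levels count informative calls only", {
  expect_equal(siteMethylationLevel(c(rep("M", 5), rep("U", 5)))$level, 0.5)
  expect_equal(siteMethylationLevel(rep("M", 10))$level, 1)
  s <- siteMethylationLevel(c("M", "U", "."))
  expect_equal(s$level, 0.5)
  expect_equal(s$n, 2)
  expect_true(is.na(siteMethylationLevel(c(".", "."))$level))
})

test_that("region profiles report per-site levels and the pooled mean", {
  allM <- mkCalls(matrix("M", 4, 3))
  expect_equal(regionMethylationProfile(allM)$region_mean, 1)
  allU <- mkCalls(matrix("U", 4, 3))
  expect_equal(regionMethylationProfile(allU)$region_mean, 0)
  mixed <- mkCalls(matrix(c("M", "M", "U", ".",
                            "M", "U", "U", "U"), 4, 2))
  prof <- regionMethylationProfile(mixed)
  expect_equal(prof$per_site$level, c(2 / 3, 1 / 4))
  expect_equal(prof$region_mean, 3 / 7)  # pooled, not mean of levels
})

test_that("call-matrix IO round-trips and validates", {
  m <- mkCalls(matrix(sample(c("M", "U", "."), 40, TRUE,
                             prob = c(.4, .4, .2)), 8, 5),
               positions = c(101, 120, 135, 160, 171))
  m[rowSums(m != ".") == 0, 1] <- "M"
  tf <- tempfile(fileext = ".tsv")
  writeCallMatrix(m, tf)
  expect_identical(readCallMatrix(tf), m)
  bad <- m; bad[2, ] <- "."
  writeCallMatrix(bad, tf)
  expect_error(readCallMatrix(tf), "non-missing")
})

test_that("ChIP vs input comparison uses the exact binomial upper tail", {
  # input level 0.5, chip 10/10: p = 0.5^10
  inp <- mkCalls(matrix(rep(c("M", "U"), 5), 10, 1), 7, "in_")
  chp <- mkCalls(matrix("M", 10, 1), 7, "ip_")
  cmp <- compareMethylation(inp, chp, consensusSites = 7)
  expect_equal(cmp$p, 0.5^10, tolerance = 1e-12)
  expect_true(cmp$in_consensus)
  expect_equal(cmp$delta, 0.5)

  # chip level equal to input level: no evidence of increase
  inp2 <- mkCalls(matrix(c(rep("M", 3), rep("U", 7)), 10, 1), 1, "in_")
  chp2 <- mkCalls(matrix(c(rep("M", 3), rep("U", 7)), 10, 1), 1, "ip_")
  expect_gte(compareMethylation(inp2, chp2)$p, 0.5)

  # input 0.3, chip 13/20 vs exhaustive enumeration
  inp3 <- mkCalls(matrix(c(rep("M", 3), rep("U", 7)), 10, 1), 1, "in_")
  chp3 <- mkCalls(matrix(c(rep("M", 13), rep("U", 7)), 20, 1), 1, "ip_")
  expect_equal(compareMethylation(inp3, chp3)$p,
               binomUpperTail(13, 20, 0.3), tolerance = 1e-12)
})

test_that("binomial tails match enumeration for all chip_n <= 50", {
  set.seed(47)
  for (i in 1:80) {
    n <- sample(1:50, 1)
    k <- sample(0:n, 1)
    p0 <- sample(1:19, 1) / 20
    expect_equal(pbinom(k - 1, n, p0, lower.tail = FALSE),
                 binomUpperTail(k, n, p0), tolerance = 1e-11)
  }
})

test_that("degenerate input levels are flagged with forced tails", {
  inp <- mkCalls(matrix("U", 5, 2), c(1, 2), "in_")
  chp <- mkCalls(matrix(c("M", "M", "U", "U", "U",
                          "U", "U", "U", "U", "U"), 5, 2), c(1, 2), "ip_")
  expect_message(cmp <- compareMethylation(inp, chp), "degenerate")
  expect_true(all(cmp$degenerate))
  # p0 = 0: any methylated chip read is impossible under the null
  expect_equal(cmp$p[cmp$position == 1], 0)
  expect_equal(cmp$p[cmp$position == 2], 1)
})

test_that("testing a decrease on the flipped fixture mirrors the tail", {
  set.seed(51)
  sim <- genBisulfite(runif(6, 0.2, 0.8), runif(6, 0.2, 0.8),
                      coverage = 15, seed = 12)
  fwd <- compareMethylation(sim$input, sim$chip, alternative = "greater")
  flip <- function(m) {
    out <- m
    out[m == "M"] <- "U"
    out[m == "U"] <- "M"
    out
  }
  rev <- compareMethylation(flip(sim$input), flip(sim$chip),
                            alternative = "less")
  expect_equal(rev$p, fwd$p, tolerance = 1e-12)
})

test_that("the exact test is valid under the null (type-I below alpha)", {
  set.seed(53)
  nSites <- 4000
  cov <- 20
  truth <- runif(nSites, 0.1, 0.9)
  sim <- genBisulfite(truth, truth, coverage = cov, seed = 77)
  p0 <- colMeans(sim$input == "M")
  # chip reads drawn at exactly the observed input level
  null <- genBisulfite(p0, p0, coverage = cov, seed = 78)
  cmp <- compareMethylation(sim$input, null$chip)
  rate <- mean(cmp$p < 0.05)
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / nSites))
})

test_that("a planted methylation increase is detected at consensus sites", {
  powered <- vapply(1:10, function(i) {
    sim <- genBisulfite(0.3, 0.65, coverage = 20, seed = 100 + i)
    compareMethylation(sim$input, sim$chip, consensusSites = 1)$p
  }, numeric(1))
  expect_gte(mean(powered < 0.05), 0.5)
})
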