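test_that("bin aggregation follows floor division and conserves totals", {
  # spots (0..19, 0..19) each with one A read all land in bin (0,0)
  spots <- expand.grid(x = 0:19, y = 0:19)
  spots$n_A <- 1L; spots$n_G <- 0L
  bins <- binAggregate(spots, binSize = 20, minReads = 180)
  expect_identical(nrow(bins), 1L)
  expect_identical(bins$n_A, 400L)
  expect_true(bins$valid)

  # floor convention: spot (20, 0) belongs to bin (1, 0)
  one <- data.frame(x = 20L, y = 0L, n_A = 1L, n_G = 0L)
  b1 <- binAggregate(one, binSize = 20, minReads = 1)
  expect_identical(c(b1$bx, b1$by), c(1L, 0L))

  # totals conserved for arbitrary bin sizes
  set.seed(40)
  spots2 <- expand.grid(x = 0:36, y = 0:23)
  spots2$n_A <- rpois(nrow(spots2), 3)
  spots2$n_G <- rpois(nrow(spots2), 2)
  for (bs in c(1, 7, 20)) {
    bb <- binAggregate(spots2, binSize = bs, minReads = 10)
    expect_identical(sum(bb$total), sum(spots2$n_A + spots2$n_G))
    expect_identical(sum(bb$n_A), sum(spots2$n_A))
  }
  expect_error(binAggregate(spots, binSize = 0), "at least 1")
})

test_that("the 180-read validity threshold is inclusive", {
  spots <- data.frame(x = c(0L, 1L), y = 0L, n_A = c(100L, 79L),
                      n_G = c(0L, 0L))
  expect_false(binAggregate(spots, 20, 180)$valid)  # 179 reads
  spots$n_G[2] <- 1L
  expect_true(binAggregate(spots, 20, 180)$valid)   # exactly 180
})

test_that("dominance calls use strict 95% and match the A/G > 19 ratio rule", {
  mk <- function(nA, nG) {
    data.frame(bx = 0L, by = 0L, n_A = nA, n_G = nG, total = nA + nG,
               frac_A = nA / (nA + nG), ratio_AG = nA / nG, valid = TRUE)
  }
  expect_identical(callBins(mk(100L, 100L))$call, "mixed")
  # 180/189 = 0.9524 > 0.95 and A/G = 20 > 19
  expect_identical(callBins(mk(180L, 9L))$call, "A-dominant")
  # frac_A exactly 0.95 stays mixed under the strict inequality
  expect_identical(callBins(mk(19L, 1L))$call, "mixed")
  expect_identical(callBins(mk(1L, 19L))$call, "mixed")
  expect_error(callBins(mk(1L, 1L), dominance = 0.5), "0.5")
  expect_error(callBins(mk(1L, 1L), dominance = 1), "0.5")

  # exhaustive boundary equivalence against the integer-arithmetic oracle
  grid <- expand.grid(nA = 0:500, nG = 0:500)
  grid <- grid[grid$nA + grid$nG >= 1 & grid$nA + grid$nG <= 500, ]
  bins <- data.frame(bx = seq_len(nrow(grid)), by = 0L,
                     n_A = grid$nA, n_G = grid$nG,
                     total = grid$nA + grid$nG, valid = TRUE)
  bins$frac_A <- bins$n_A / bins$total
  bins$ratio_AG <- bins$n_A / bins$n_G
  got <- callBins(bins)$call
  want <- mapply(bruteDominanceCall, grid$nA, grid$nG)
  expect_identical(got, unname(want))
  # and the oracle itself encodes the ratio rule
  aDom <- got == "A-dominant"
  expect_identical(aDom, grid$nA > 19 * grid$nG)
})

test_that("heterogeneity summaries tabulate fractions and adjacency", {
  mk <- function(bx, by, nA, nG, minReads = 1) {
    callBins(binAggregate(
      data.frame(x = bx, y = by, n_A = nA, n_G = nG),
      binSize = 1, minReads = minReads))
  }
  # two valid bins at frac_A 0.96 and 0.50
  bins <- mk(c(0L, 1L), c(0L, 0L), c(96L, 50L), c(4L, 50L))
  s <- summarizeBins(bins)
  expect_identical(s$nValidBins, 2L)
  expect_identical(unname(s$histogram[20]), 1L)  # [0.95, 1.00]
  expect_identical(unname(s$histogram[11]), 1L)  # [0.50, 0.55)
  expect_identical(sum(s$histogram), 2L)
  expect_equal(s$extremeFraction, 0.5)
  expect_equal(s$singlePhylotypeStrict, 0)
  expect_equal(s$singlePhylotypeDominance, 0.5)

  # all bins pure A: extreme share 1, no discordance
  pure <- mk(0:3, rep(0L, 4), rep(10L, 4), rep(0L, 4))
  sp <- summarizeBins(pure)
  expect_equal(sp$extremeFraction, 1)
  expect_equal(sp$neighborDiscordance, 0)
  expect_equal(sp$singlePhylotypeStrict, 1)

  # checkerboard of pure A and pure G bins: every adjacent pair discords
  cb <- expand.grid(x = 0:3, y = 0:3)
  isA <- (cb$x + cb$y) %% 2 == 0
  board <- mk(cb$x, cb$y, ifelse(isA, 10L, 0L), ifelse(isA, 0L, 10L))
  expect_equal(summarizeBins(board)$neighborDiscordance, 1)

  # zero valid bins is an error
  none <- mk(0L, 0L, 1L, 0L, minReads = 100)
  expect_error(summarizeBins(none), "no valid bins")
})
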