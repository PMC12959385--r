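test_that("classification requires the full 47-nt window with zero mismatches", {
  refs <- shortRefs()
  seqG <- as.character(refSeqG(refs))
  w <- refs@window  # 80..126

  # a 75-nt fragment of seqG covering the window is called G
  frag <- substr(seqG, 60, 134)
  expect_identical(classifyReads(frag, refs), "G")
  expect_identical(bruteClassify(frag, refs), "G")

  # one substitution at a non-diagnostic window position -> unclassified
  mut <- frag
  p <- w[1] - 60 + 1 + 3  # fourth window base, away from the diagnostic
  orig <- substr(mut, p, p)
  substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"), orig)[1]
  expect_identical(classifyReads(mut, refs), "unclassified")

  # fragment covering only 46 of the 47 window bases -> unclassified
  partial <- substr(seqG, w[1] + 1, w[1] + 75)
  expect_identical(classifyReads(partial, refs), "unclassified")

  # a substitution at the diagnostic base flips the call, A window <-> G
  fragA <- substr(as.character(refSeqA(refs)), 60, 134)
  flip <- fragA
  dp <- diagnosticPos(refs) - 60 + 1
  substr(flip, dp, dp) <- "G"
  expect_identical(classifyReads(fragA, refs), "A")
  expect_identical(classifyReads(flip, refs), "G")
})

test_that("classifier agrees with the brute-force substring oracle on 10^4 reads", {
  refs <- shortRefs()
  truth <- simulateField(20, 20, "well-mixed", mixingBeta = 1, seed = 20)
  set.seed(21)
  # half error-free, half with exactly one random substitution
  simClean <- simulateReads(truth, refs, meanReadsPerSpot = 14,
                            errorRate = 0, seed = 22)
  reads <- simClean$read2[seq_len(min(5000L, length(simClean$read2)))]
  oneErr <- vapply(reads, function(r) {
    p <- sample.int(75, 1)
    b <- substr(r, p, p)
    substr(r, p, p) <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
    r
  }, character(1), USE.NAMES = FALSE)
  all <- c(reads, oneErr)
  expect_gte(length(all), 1e4)
  got <- classifyReads(all, refs)
  want <- vapply(all, bruteClassify, character(1), refs = refs,
                 USE.NAMES = FALSE)
  expect_identical(got, want)
  # no read can match both windows; every A/G call is exclusive
  expect_true(all(got %in% c("A", "G", "unclassified")))
})

test_that("with no errors the classifier recovers every planted window-covering read", {
  refs <- shortRefs()
  truth <- simulateField(20, 20, "domain-mosaic", nDomains = 3, seed = 23)
  sim <- simulateReads(truth, refs, meanReadsPerSpot = 10, errorRate = 0,
                       seed = 24)
  calls <- classifyReads(sim$read2, refs)
  cw <- sim$labels$coversWindow
  expect_identical(calls[cw], sim$labels$phylotype[cw])
  expect_true(all(calls[!cw] == "unclassified"))
})

test_that("spot accumulation tallies, deduplicates and conserves reads", {
  cls <- data.frame(
    x = c(0L, 0L, 0L, 0L, 1L), y = c(0L, 0L, 0L, 0L, 2L),
    mid = c("M1", "M1", "M1", "M2", "M3"),
    call = c("A", "A", "A", "G", "unclassified"),
    stringsAsFactors = FALSE)
  plain <- accumulateCounts(cls)
  s00 <- plain[plain$x == 0 & plain$y == 0, ]
  expect_identical(s00$n_A, 3L)
  expect_identical(s00$n_G, 1L)
  dedup <- accumulateCounts(cls, dedupMid = TRUE)
  expect_identical(dedup[dedup$x == 0, ]$n_A, 1L)
  # conservation
  expect_identical(sum(plain$n_A + plain$n_G + plain$n_unclassified),
                   nrow(cls))
})

test_that("sample frequency and estimator concordance follow their definitions", {
  expect_equal(sampleFrequency(0, 10)$frac_G, 1)
  expect_equal(sampleFrequency(50, 50)$frac_G, 0.5)
  expect_equal(sampleFrequency(46, 54)$frac_G, 0.54)
  expect_error(sampleFrequency(0, 0), "positive")

  expect_equal(concordanceR2(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)), 1)
  # anti-correlated exact line: R2 is sign-blind
  expect_equal(concordanceR2(c(0, 0.5, 1), c(1, 0.5, 0)), 1)
  x <- c(0, 0.5, 1, 0.2, 0.8); y <- c(0, 1, 0.5, 0.2, 0.8)
  expect_equal(concordanceR2(x, y), bruteR2(x, y), tolerance = 1e-12)
  expect_error(concordanceR2(c(1, 1, 1), c(0, 1, 2)), "constant")
  expect_error(concordanceR2(c(1, 2), c(0, 1)), "at least 3")
})
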