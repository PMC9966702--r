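# Sequence reweighting, plmDCA fitting, and coupling-score summaries.

test_that("sequence weights count identity-threshold neighbourhoods", {
  # M identical rows -> every weight 1/M
  pa <- toyPaired(rep("AAKK", 4), lenA = 2)
  w <- sequenceWeights(pa, 0.8)
  expect_equal(weights(w), rep(0.25, 4))
  expect_equal(mEff(w), 1)

  # all rows dissimilar -> all weights 1
  pa2 <- toyPaired(c("AAAA", "CCCC", "GGGG"), lenA = 2)
  w2 <- sequenceWeights(pa2, 0.8)
  expect_equal(weights(w2), rep(1, 3))

  # two identical + one unrelated -> (0.5, 0.5, 1); brute-force check
  pa3 <- toyPaired(c("AAAAA", "AAAAA", "CCCCC"), lenA = 2)
  expect_equal(weights(sequenceWeights(pa3, 0.8)), c(0.5, 0.5, 1.0))
})

test_that("raising theta never decreases any weight (Meff monotonicity)", {
  set.seed(7)
  rows <- replicate(12, paste(sample(c("A", "C", "G", "T"), 10,
                                     replace = TRUE, prob = c(.6, .2, .1, .1)),
                              collapse = ""))
  pa <- toyPaired(rows, lenA = 5)
  thetas <- c(0.3, 0.5, 0.7, 0.9)
  W <- sapply(thetas, function(th) weights(sequenceWeights(pa, th)))
  for (k in seq_len(length(thetas) - 1))
    expect_true(all(W[, k + 1] >= W[, k] - 1e-12))
})

test_that("APC correction matches the row/column mean formula and kills rank-1 structure", {
  # constant off-diagonal matrix -> identically zero
  S <- matrix(3, 6, 6); diag(S) <- 0
  expect_equal(apcCorrect(S), matrix(0, 6, 6))

  # random symmetric matrix: equals the direct formula with clipping
  set.seed(11)
  S <- matrix(runif(36), 6, 6); S <- (S + t(S)) / 2; diag(S) <- 0
  L <- 6
  rowM <- sapply(seq_len(L), function(i) mean(S[i, -i]))
  grand <- mean(S[row(S) != col(S)])
  expected <- S - outer(rowM, rowM) / grand
  expected[expected < 0] <- 0
  diag(expected) <- 0
  expect_equal(apcCorrect(S), expected, tolerance = 1e-12)
})

test_that("inter-protein block slices the coupling matrix correctly", {
  set.seed(5)
  S <- matrix(runif(100), 10, 10); S <- (S + t(S)) / 2; diag(S) <- 0
  cm <- new("CouplingMatrix", scores = S, raw = S, apcApplied = FALSE,
            lenA = 4L, lenB = 6L)
  blk <- interProteinBlock(cm)
  expect_equal(dim(blk), c(4L, 6L))
  expect_equal(blk, S[1:4, 5:10])
  # symmetry: block equals the transpose of the mirrored block
  expect_equal(blk, t(S[5:10, 1:4]))
  expect_error(interProteinBlock(cm, lenA = 5L, lenB = 6L), "must equal")
})

test_that("a planted perfectly-correlated column pair dominates the couplings", {
  set.seed(21)
  M <- 400; lenA <- 4; lenB <- 4
  alpha <- c("A", "C", "G", "T")
  mat <- matrix(sample(alpha, M * (lenA + lenB), TRUE), M)
  mat[, lenA + 2] <- mat[, 2]           # column 2 of A copied into B
  pa <- toyPaired(apply(mat, 1, paste, collapse = ""), lenA = lenA)
  model <- fitPlm(pa, sequenceWeights(pa, 0.8))
  cm <- couplingScores(model, apc = FALSE)
  blk <- interProteinBlock(cm)
  peak <- which(blk == max(blk), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(2L, 2L))
  # and the planted pair stands far above an iid fit's maximum
  matNull <- matrix(sample(alpha, M * (lenA + lenB), TRUE), M)
  paNull <- toyPaired(apply(matNull, 1, paste, collapse = ""), lenA = lenA)
  cmNull <- couplingScores(fitPlm(paNull, sequenceWeights(paNull, 0.8)),
                           apc = FALSE)
  expect_gt(max(blk), 3 * max(interProteinBlock(cmNull)))
})

test_that("very strong coupling regularisation drives all couplings to zero", {
  set.seed(31)
  rows <- replicate(50, paste(sample(c("A", "C"), 6, TRUE), collapse = ""))
  pa <- toyPaired(rows, lenA = 3)
  model <- fitPlm(pa, sequenceWeights(pa, 0.8), regCouplings = 1e3)
  cm <- couplingScores(model, apc = FALSE)
  expect_lt(max(scoreMatrix(cm)), 1e-3)
})

test_that("coupling scores are invariant to per-column gauge shifts of J", {
  set.seed(41)
  q <- 3; L <- 4
  J <- array(rnorm(q * q * L * L, sd = 0.3), c(q, q, L, L))
  for (i in 1:(L - 1)) for (j in (i + 1):L) J[, , j, i] <- t(J[, , i, j])
  gaugeFix <- function(K) K - outer(rowMeans(K), rep(1, q)) -
    outer(rep(1, q), colMeans(K)) + mean(K)
  mkModel <- function(Jarr) {
    Jg <- Jarr
    for (i in 1:(L - 1)) for (j in (i + 1):L) {
      Jg[, , i, j] <- gaugeFix(Jarr[, , i, j]); Jg[, , j, i] <- t(Jg[, , i, j])
    }
    new("PottsModel", q = 3L, alphabet = c("A", "C", "G"),
        fields = matrix(0, L, q), couplings = Jg, regFields = 0.01,
        regCouplings = 0.01, meta = list(gauge = "zero-sum",
                                         lenA = 2L, lenB = 2L))
  }
  m1 <- mkModel(J)
  Jshift <- J
  for (i in 1:(L - 1)) for (j in (i + 1):L) {
    Jshift[, , i, j] <- Jshift[, , i, j] + matrix(rnorm(q), q, q)  # row const
    Jshift[, , j, i] <- t(Jshift[, , i, j])
  }
  m2 <- mkModel(Jshift)
  expect_equal(scoreMatrix(couplingScores(m1, apc = FALSE)),
               scoreMatrix(couplingScores(m2, apc = FALSE)),
               tolerance = 1e-8)
})

test_that("fitted pseudo-likelihood beats random parameter draws at tiny scale", {
  set.seed(51)
  rows <- c("AAA", "AAC", "ACA", "CAA", "CCC", "CCA")
  pa <- toyPaired(rows, lenA = 2)
  w <- sequenceWeights(pa, 0.8)
  model <- fitPlm(pa, w, regFields = 0.01, regCouplings = 0.01)
  fitted <- pseudoLogLik(model, pa, w)
  L <- 3; q <- model@q
  for (r in 1:100) {
    rnd <- model
    rnd@fields <- matrix(rnorm(L * q), L, q)
    rnd@couplings <- array(rnorm(q * q * L * L), c(q, q, L, L))
    for (i in 1:(L - 1)) for (j in (i + 1):L)
      rnd@couplings[, , j, i] <- t(rnd@couplings[, , i, j])
    expect_gte(fitted, pseudoLogLik(rnd, pa, w))
  }
})

test_that("plmDCA and mean-field DCA agree on the planted pair at small scale", {
  pm <- makePlantedModel(6, 6, q = 4, nPairs = 1, strength = 2.5, seed = 9)
  pa <- sampleMSA(pm$model, m = 1000, burnIn = 50, seed = 1009)
  blkPlm <- interProteinBlock(couplingScores(fitPlm(pa, sequenceWeights(pa))))
  Smf <- spdca:::meanFieldScores(pa)
  blkMf <- Smf[1:6, 7:12]
  truth <- plantedPairs(pm$truth)
  expect_equal(unname(which(blkPlm == max(blkPlm), arr.ind = TRUE)[1, ]),
               unname(truth[1, ]))
  expect_equal(unname(which(blkMf == max(blkMf), arr.ind = TRUE)[1, ]),
               unname(truth[1, ]))
})

test_that("fitted couplings satisfy the declared gauge and symmetry invariants", {
  set.seed(61)
  rows <- replicate(80, paste(sample(c("A", "C", "G"), 6, TRUE),
                              collapse = ""))
  pa <- toyPaired(rows, lenA = 3)
  model <- fitPlm(pa, sequenceWeights(pa, 0.8))
  q <- model@q
  for (i in 1:5) for (j in (i + 1):6) {
    K <- model@couplings[, , i, j]
    expect_equal(K, t(model@couplings[, , j, i]), tolerance = 1e-12)
    expect_lt(max(abs(rowSums(K))), 1e-8)
    expect_lt(max(abs(colSums(K))), 1e-8)
  }
})
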