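# RMSD, radius of gyration, contact maps and screened electrostatics.

test_that("PDB frames parse with MODEL splitting, HETATM and hydrogen rules", {
  f1 <- toyFrame(list("A", 1, "ALA", "N", 0, 0, 0),
                 list("A", 1, "ALA", "CA", 1.5, 0, 0),
                 list("A", 1, "ALA", "CB", 1.5, 1.5, 0))
  pdb <- withr::local_tempfile(fileext = ".pdb")
  writeToyPdb(pdb, list(f1))
  frames <- readFrames(pdb)
  expect_length(frames, 1L)
  expect_equal(nrow(atomTable(frames[[1]])), 3L)

  # multi-MODEL: one frame per MODEL, equal atom counts
  writeToyPdb(pdb, list(f1, rigidTransform(f1), rigidTransform(f1, 1.2)))
  frames3 <- readFrames(pdb)
  expect_length(frames3, 3L)
  expect_equal(unique(vapply(frames3, function(f) nrow(atomTable(f)),
                             integer(1))), 3L)

  # HETATM water excluded by default and counted
  writeToyPdb(pdb, list(f1), hetatm = TRUE)
  fh <- readFrames(pdb)
  expect_equal(nrow(atomTable(fh[[1]])), 3L)
  expect_equal(fh[[1]]@nExcluded, 1L)

  expect_error(readFrames("no/such/file.pdb"), "not found")
})

test_that("hydrogens are flagged non-heavy from atom names", {
  fr <- toyFrame(list("A", 1, "ALA", "N", 0, 0, 0),
                 list("A", 1, "ALA", "HA", 1, 0, 0),
                 list("A", 1, "ALA", "1HB", 2, 0, 0),
                 list("A", 1, "ALA", "CB", 3, 0, 0))
  expect_equal(atomTable(fr)$heavy, c(TRUE, FALSE, FALSE, TRUE))
})

test_that("Kabsch RMSD is zero on congruent frames and symmetric", {
  fr <- randomFrame(1, nResA = 3, nResB = 2)
  expect_equal(kabschRMSD(fr, fr), 0)
  moved <- rigidTransform(fr, angle = 1.1, axis = c(2, -1, 4),
                          shift = c(12, 5, -9))
  expect_lt(kabschRMSD(moved, fr), 1e-8)
  # metric symmetry
  set.seed(2)
  jig <- atomTable(fr)
  jig$x <- jig$x + rnorm(nrow(jig), sd = 0.4)
  jig$y <- jig$y + rnorm(nrow(jig), sd = 0.4)
  jigF <- structureFrame(jig)
  expect_equal(kabschRMSD(jigF, fr), kabschRMSD(fr, jigF),
               tolerance = 1e-8)
  expect_error(kabschRMSD(fr, fr, selection = 1:2), "at least 3")
})

test_that("Kabsch RMSD matches an exhaustive rotation-grid search on 4 atoms", {
  set.seed(14)
  X <- matrix(rnorm(12), 4, 3)
  Y <- matrix(rnorm(12), 4, 3)
  mk <- function(M) structureFrame(data.frame(
    chain = "A", resno = 1:4, resid = "ALA", elety = "CA",
    x = M[, 1], y = M[, 2], z = M[, 3]))
  got <- kabschRMSD(mk(X), mk(Y))
  # oracle: Euler-angle grid search refined by Nelder-Mead (no SVD)
  Xc <- sweep(X, 2, colMeans(X)); Yc <- sweep(Y, 2, colMeans(Y))
  euler <- function(v) {
    a <- v[1]; b <- v[2]; c <- v[3]
    Rz1 <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3,
                  byrow = TRUE)
    Rz1 %*% Ry %*% Rz2
  }
  obj <- function(v) sqrt(mean(rowSums((Yc - Xc %*% t(euler(v)))^2)))
  grid <- expand.grid(a = seq(0, 2 * pi, length.out = 13)[-13],
                      b = seq(0, pi, length.out = 9),
                      c = seq(0, 2 * pi, length.out = 13)[-13])
  vals <- apply(grid, 1, obj)
  start <- as.numeric(grid[which.min(vals), ])
  best <- optim(start, obj, method = "Nelder-Mead",
                control = list(maxit = 2000, reltol = 1e-14))$value
  expect_lt(abs(got - best), 1e-3)
  expect_lte(got, best + 1e-9)         # the oracle can only overestimate
})

test_that("RMSD agrees with the bio3d reference implementation", {
  fr <- randomFrame(5, nResA = 5, nResB = 3)
  set.seed(6)
  a2 <- atomTable(fr)
  a2$x <- a2$x + rnorm(nrow(a2), sd = 0.8)
  a2$z <- a2$z + rnorm(nrow(a2), sd = 0.8)
  fr2 <- structureFrame(a2)
  xyz1 <- as.vector(t(as.matrix(atomTable(fr)[, c("x", "y", "z")])))
  xyz2 <- as.vector(t(as.matrix(a2[, c("x", "y", "z")])))
  ref <- bio3d::rmsd(xyz1, xyz2, fit = TRUE)   # bio3d rounds to 3 decimals
  expect_equal(kabschRMSD(fr2, fr), ref, tolerance = 1e-3)
})

test_that("radius of gyration follows the closed form and rigid invariance", {
  one <- toyFrame(list("A", 1, "ALA", "CA", 3, 4, 5))
  expect_equal(radiusOfGyration(one), 0)
  two <- toyFrame(list("A", 1, "ALA", "CA", 0, 0, 0),
                  list("A", 1, "ALA", "CB", 1, 0, 0))
  expect_equal(radiusOfGyration(two), 0.5)
  # random cloud: direct formula
  fr <- randomFrame(9, nResA = 7, nResB = 0)
  X <- as.matrix(atomTable(fr)[, c("x", "y", "z")])
  com <- colMeans(X)
  expect_equal(radiusOfGyration(fr),
               sqrt(mean(rowSums(sweep(X, 2, com)^2))), tolerance = 1e-10)
  # rigid invariance
  expect_equal(radiusOfGyration(rigidTransform(fr)), radiusOfGyration(fr),
               tolerance = 1e-10)
  # mass weighting
  m <- c(2, 1)
  expect_equal(radiusOfGyration(two, masses = m),
               sqrt((2 * (1 / 3)^2 + (2 / 3)^2) / 3))
  expect_error(radiusOfGyration(one, selection = logical(1)), "empty")
})

test_that("the contact rule needs >= minAtomPairs heavy-atom pairs strictly under cutoff", {
  # two atom pairs at 4 A -> contact under the published rule
  fr <- toyFrame(list("A", 1, "ALA", "CA", 0, 0, 0),
                 list("A", 1, "ALA", "CB", 0, 1, 0),
                 list("B", 1, "ALA", "CA", 4, 0, 0),
                 list("B", 1, "ALA", "CB", 4, 1, 0))
  cm <- residueContactMap(fr, "A", "B", cutoff = 5, minAtomPairs = 2)
  expect_true(contactMatrix(cm)[1, 1])

  # exactly one close atom pair -> no contact (but minAtomPairs = 1 accepts)
  fr2 <- toyFrame(list("A", 1, "ALA", "CA", 0, 0, 0),
                  list("A", 1, "ALA", "CB", 0, 40, 0),
                  list("B", 1, "ALA", "CA", 4, 0, 0),
                  list("B", 1, "ALA", "CB", 40, 40, 40))
  expect_false(contactMatrix(residueContactMap(fr2, "A", "B"))[1, 1])
  expect_true(contactMatrix(residueContactMap(fr2, "A", "B",
                                              minAtomPairs = 1))[1, 1])

  # strict inequality at the cutoff
  fr3 <- toyFrame(list("A", 1, "ALA", "CA", 0, 0, 0),
                  list("A", 1, "ALA", "CB", 0, 1, 0),
                  list("B", 1, "ALA", "CA", 5, 0, 0),
                  list("B", 1, "ALA", "CB", 5, 1, 0))
  expect_false(contactMatrix(residueContactMap(fr3, "A", "B"))[1, 1])

  # hydrogens never count
  fr4 <- toyFrame(list("A", 1, "ALA", "HA", 0, 0, 0),
                  list("A", 1, "ALA", "HB", 0, 1, 0),
                  list("A", 1, "ALA", "CA", 0, 2, 0),
                  list("B", 1, "ALA", "CA", 1, 0, 0),
                  list("B", 1, "ALA", "CB", 1, 1, 0))
  cm4 <- residueContactMap(fr4, "A", "B")
  expect_equal(unname(cm4@counts[1, 1]), 2L)  # CA-CA and CA-CB only

  expect_error(residueContactMap(fr, "A", "Z"), "chain Z")
})

test_that("contact maps equal exhaustive enumeration and transpose symmetry", {
  for (seed in c(3, 4, 5)) {
    fr <- randomFrame(seed, nResA = 5, nResB = 5, atomsPerRes = 3,
                      spread = 8)
    cm <- residueContactMap(fr, "A", "B")
    expect_equal(unname(contactMatrix(cm)),
                 unname(bruteContacts(fr, "A", "B")))
    # (A,B) equals transpose of (B,A)
    expect_equal(unname(contactMatrix(residueContactMap(fr, "B", "A"))),
                 unname(t(contactMatrix(cm))))
  }
})

test_that("native-contact fractions are 1, 0 and 0.5 on constructed cases", {
  fr <- randomFrame(11, nResA = 4, nResB = 4, spread = 7)
  native <- residueContactMap(fr, "A", "B")
  expect_gt(sum(contactMatrix(native)), 0)
  expect_equal(nativeContactFraction(list(fr), native), 1)
  # chains pulled 100 A apart: nothing survives
  a <- atomTable(fr)
  a$x[a$chain == "B"] <- a$x[a$chain == "B"] + 100
  expect_equal(nativeContactFraction(list(structureFrame(a)), native), 0)
  # half-preserved by construction: two isolated contact pairs, one broken
  mkRes <- function(chain, resno, x)
    list(list(chain, resno, "ALA", "CA", x, 0, 0),
         list(chain, resno, "ALA", "CB", x, 1, 0))
  fr2 <- do.call(toyFrame, c(mkRes("A", 1, 0), mkRes("B", 1, 3),
                             mkRes("A", 2, 50), mkRes("B", 2, 53)))
  nat2 <- residueContactMap(fr2, "A", "B")
  expect_equal(sum(contactMatrix(nat2)), 2L)
  a2 <- atomTable(fr2)
  a2$x[a2$chain == "B" & a2$resno == 2] <- 80    # break one contact
  expect_equal(nativeContactFraction(list(structureFrame(a2)), nat2), 0.5)
})

test_that("Debye-Hueckel energies follow the screened-Coulomb closed form", {
  mkCharged <- function(...) toyFrame(...)
  # neutral system -> 0
  neutral <- mkCharged(list("A", 1, "ALA", "CB", 0, 0, 0),
                       list("B", 1, "SER", "CB", 10, 0, 0))
  expect_equal(debyeHuckelEnergy(neutral), 0)
  # one +1/+1 pair at r = lD = 10, epsR = 1: kElec * exp(-1) / 10
  pair <- mkCharged(list("A", 1, "LYS", "CB", 0, 0, 0),
                    list("B", 1, "ARG", "CB", 10, 0, 0))
  par1 <- electrostaticParams(epsR = 1, lD = 10)
  expect_equal(debyeHuckelEnergy(pair, par1), 332.24 * exp(-1) / 10,
               tolerance = 1e-12)
  # sign flips with one charge
  pairNeg <- mkCharged(list("A", 1, "LYS", "CB", 0, 0, 0),
                       list("B", 1, "GLU", "CB", 10, 0, 0))
  expect_equal(debyeHuckelEnergy(pairNeg, par1),
               -debyeHuckelEnergy(pair, par1))
  # three-charge additivity over the three pairs
  tri <- mkCharged(list("A", 1, "LYS", "CB", 0, 0, 0),
                   list("A", 2, "GLU", "CB", 7, 0, 0),
                   list("B", 1, "ARG", "CB", 0, 9, 0))
  pairE <- function(q1, q2, r) 332.24 * q1 * q2 * exp(-r / 10) / r
  expect_equal(debyeHuckelEnergy(tri, par1),
               pairE(1, -1, 7) + pairE(1, 1, 9) + pairE(-1, 1, sqrt(49 + 81)),
               tolerance = 1e-10)
  # linear in kElec; magnitude decays with r
  par2 <- electrostaticParams(epsR = 1, lD = 10, kElec = 664.48)
  expect_equal(debyeHuckelEnergy(pair, par2),
               2 * debyeHuckelEnergy(pair, par1))
  far <- mkCharged(list("A", 1, "LYS", "CB", 0, 0, 0),
                   list("B", 1, "ARG", "CB", 20, 0, 0))
  expect_lt(debyeHuckelEnergy(far, par1), debyeHuckelEnergy(pair, par1))
  # coincident beads are an error
  zero <- mkCharged(list("A", 1, "LYS", "CB", 0, 0, 0),
                    list("B", 1, "ARG", "CB", 0, 0, 0))
  expect_error(debyeHuckelEnergy(zero, par1), "r = 0")
  # inter-chain restriction drops the intra-chain pair
  expect_equal(debyeHuckelEnergy(tri, par1, interChainOnly = TRUE),
               pairE(1, 1, 9) + pairE(-1, 1, sqrt(130)), tolerance = 1e-10)
})

test_that("derived Debye lengths match the aqueous textbook value", {
  # water at 25 C, I = 0.1 M: l_D ~ 3.04 / sqrt(I) Angstrom
  expect_equal(debyeLength(298.15, 0.1, epsR = 78.5), 3.04 / sqrt(0.1),
               tolerance = 0.02)
  # scaling: l_D ~ 1/sqrt(I)
  expect_equal(debyeLength(300, 0.04) / debyeLength(300, 0.16), 2,
               tolerance = 1e-10)
})

test_that("trajectory summaries assemble all per-frame criteria", {
  fr <- randomFrame(21, nResA = 4, nResB = 4, spread = 7)
  fr2 <- rigidTransform(fr, 0.4)
  out <- trajectorySummary(list(fr, fr2), reference = fr,
                           chainA = "A", chainB = "B")
  expect_equal(names(out),
               c("frame", "rmsd", "rg", "nativeFraction", "dhEnergy"))
  expect_equal(out$rmsd[1], 0)
  expect_lt(out$rmsd[2], 1e-8)         # rigid motion
  expect_equal(out$nativeFraction, c(1, 1))
  expect_equal(out$rg[1], out$rg[2], tolerance = 1e-10)
})
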