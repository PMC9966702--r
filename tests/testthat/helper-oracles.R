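# Shared fixtures and independent oracles used across the test files.

# construct an Alignment directly from sequence strings
toyAlignment <- function(seqs, species = NULL, name = "toy") {
  if (is.null(species)) species <- paste0("sp", seq_along(seqs))
  mat <- do.call(rbind, strsplit(seqs, ""))
  new("Alignment", seqs = mat, species = species, name = name,
      nUnknown = 0L)
}

toyPaired <- function(seqs, lenA, species = NULL) {
  if (is.null(species)) species <- paste0("sp", seq_along(seqs))
  mat <- do.call(rbind, strsplit(seqs, ""))
  new("PairedAlignment", seqs = mat, species = species,
      lenA = as.integer(lenA), lenB = ncol(mat) - as.integer(lenA),
      nameA = "A", nameB = "B", nDropped = 0L)
}

writeFasta <- function(headers, seqs, path) {
  writeLines(as.vector(rbind(paste0(">", headers), seqs)), path)
  path
}

# brute-force quadruple-loop convolution oracle (independent of the
# banded-matrix implementation)
bruteConvolve <- function(P, a, b, l, wA = NULL, wB = NULL) {
  nA <- nrow(P); nB <- ncol(P)
  if (!is.null(wA)) P <- P * wA
  if (!is.null(wB)) P <- sweep(P, 2, wB, "*")
  Q <- matrix(0, nA, nB)
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    acc <- 0
    for (al in max(1, i - l):min(nA, i + l))
      for (be in max(1, j - l):min(nB, j + l))
        acc <- acc + P[al, be] * exp(-(a * (al - i)^2 + b * (be - j)^2))
    Q[i, j] <- acc
  }
  Q
}

# cumulative-sum (summed-area table) boxcar oracle for the a = b = 0 limit
boxcarSum <- function(P, l) {
  nA <- nrow(P); nB <- ncol(P)
  S <- matrix(0, nA + 1, nB + 1)
  S[-1, -1] <- apply(apply(P, 2, cumsum), 1, cumsum) |> t()
  Q <- matrix(0, nA, nB)
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    i1 <- max(1, i - l); i2 <- min(nA, i + l)
    j1 <- max(1, j - l); j2 <- min(nB, j + l)
    Q[i, j] <- S[i2 + 1, j2 + 1] - S[i1, j2 + 1] - S[i2 + 1, j1] +
      S[i1, j1]
  }
  Q
}

# toy structure frames --------------------------------------------------

# a frame from a compact spec: list of (chain, resno, resid, elety, xyz)
toyFrame <- function(...) {
  rows <- list(...)
  atoms <- do.call(rbind, lapply(rows, function(r)
    data.frame(chain = r[[1]], resno = as.integer(r[[2]]), resid = r[[3]],
               elety = r[[4]], x = r[[5]], y = r[[6]], z = r[[7]],
               stringsAsFactors = FALSE)))
  structureFrame(atoms)
}

# random two-chain cloud with several residues and atoms
randomFrame <- function(seed, nResA = 4, nResB = 4, atomsPerRes = 3,
                        spread = 6) {
  set.seed(seed)
  mk <- function(chain, nRes) {
    do.call(rbind, lapply(seq_len(nRes), function(r)
      data.frame(chain = chain, resno = r, resid = "ALA",
                 elety = c("N", "CA", "CB")[seq_len(atomsPerRes)],
                 x = runif(atomsPerRes, 0, spread),
                 y = runif(atomsPerRes, 0, spread),
                 z = runif(atomsPerRes, 0, spread),
                 stringsAsFactors = FALSE)))
  }
  structureFrame(rbind(mk("A", nResA), mk("B", nResB)))
}

# exhaustive contact-map oracle: loop over every heavy-atom pair
bruteContacts <- function(frame, chainA, chainB, cutoff = 5,
                          minAtomPairs = 2) {
  a <- atomTable(frame)
  A <- a[a$chain == chainA & a$heavy, ]
  B <- a[a$chain == chainB & a$heavy, ]
  resA <- sort(unique(A$resno)); resB <- sort(unique(B$resno))
  out <- matrix(FALSE, length(resA), length(resB),
                dimnames = list(resA, resB))
  for (ra in seq_along(resA)) for (rb in seq_along(resB)) {
    n <- 0L
    Aa <- A[A$resno == resA[ra], ]; Bb <- B[B$resno == resB[rb], ]
    for (i in seq_len(nrow(Aa))) for (j in seq_len(nrow(Bb))) {
      d <- sqrt((Aa$x[i] - Bb$x[j])^2 + (Aa$y[i] - Bb$y[j])^2 +
                  (Aa$z[i] - Bb$z[j])^2)
      if (d < cutoff) n <- n + 1L
    }
    out[ra, rb] <- n >= minAtomPairs
  }
  out
}

# rigid transform: rotation about an arbitrary axis + translation
rigidTransform <- function(frame, angle = 0.7, axis = c(1, 2, 3),
                           shift = c(5, -3, 2)) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -axis[3], axis[2], axis[3], 0, -axis[1],
                -axis[2], axis[1], 0), 3, 3, byrow = TRUE)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
  a <- atomTable(frame)
  xyz <- as.matrix(a[, c("x", "y", "z")]) %*% t(R)
  a$x <- xyz[, 1] + shift[1]
  a$y <- xyz[, 2] + shift[2]
  a$z <- xyz[, 3] + shift[3]
  structureFrame(a)
}

# minimal multi-MODEL PDB text for readFrames tests
writeToyPdb <- function(path, frames, hetatm = FALSE) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(frames)) {
    writeLines(sprintf("MODEL     %4d", f), con)
    a <- atomTable(frames[[f]])
    for (k in seq_len(nrow(a))) {
      writeLines(sprintf(
        "ATOM  %5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        k, a$elety[k], a$resid[k], a$chain[k], a$resno[k],
        a$x[k], a$y[k], a$z[k]), con)
    }
    if (hetatm)
      writeLines(sprintf(
        "HETATM%5d  %-3s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
        nrow(a) + 1L, "O", "HOH", "W", 999L, 99.0, 99.0, 99.0), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  path
}
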