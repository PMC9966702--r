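# Trajectory validation criteria: Kabsch RMSD, radius of gyration,
# heavy-atom residue contact maps, native-contact fractions, and
# Debye-Hueckel screened electrostatics.

newStructureFrame <- function(atoms, nExcluded = 0L) {
  rownames(atoms) <- NULL
  new("StructureFrame", atoms = atoms, nExcluded = as.integer(nExcluded))
}

# hydrogen flag from the element symbol, falling back to the atom name
# (digits stripped; names like "1HB" or "HG1" are hydrogens)
isHeavyAtom <- function(elety, elesy = NULL) {
  if (!is.null(elesy) && !all(is.na(elesy)) && any(nzchar(trimws(elesy)))) {
    el <- toupper(trimws(elesy))
    miss <- is.na(el) | el == ""
    if (any(miss)) el[miss] <- substr(gsub("[0-9]", "", toupper(
      trimws(elety[miss]))), 1, 1)
    return(el != "H" & el != "D")
  }
  first <- substr(gsub("[0-9]", "", toupper(trimws(elety))), 1, 1)
  first != "H"
}

#' Read one or more structure frames from a PDB file
#'
#' Parses a single- or multi-MODEL PDB (via \pkg{bio3d}) into one
#' \linkS4class{StructureFrame} per MODEL.  HETATM records (waters,
#' ligands) are excluded by default and counted in \code{@nExcluded};
#' hydrogens are kept but flagged non-heavy.
#'
#' @param path PDB file path.
#' @param keepHetatm keep HETATM records (default FALSE).
#' @return List of \linkS4class{StructureFrame} objects.
#' @export
readFrames <- function(path, keepHetatm = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e)
                    stop("failed to parse PDB '", path, "': ",
                         conditionMessage(e)))
  atoms <- pdb$atom
  nExcl <- 0L
  if (!keepHetatm) {
    het <- atoms$type == "HETATM"
    nExcl <- sum(het)
    keep <- !het
  } else keep <- rep(TRUE, nrow(atoms))
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nFrames <- nrow(xyz)
  heavy <- isHeavyAtom(atoms$elety, atoms$elesy)
  lapply(seq_len(nFrames), function(f) {
    co <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
    df <- data.frame(chain = atoms$chain, resno = atoms$resno,
                     resid = atoms$resid, elety = trimws(atoms$elety),
                     x = co[, 1], y = co[, 2], z = co[, 3],
                     heavy = heavy, stringsAsFactors = FALSE)[keep, ,
                                                             drop = FALSE]
    newStructureFrame(df, nExcl)
  })
}

#' Build a StructureFrame from an atom table
#'
#' For toy structures constructed in code.  Columns chain, resno, resid,
#' elety, x, y, z are required; \code{heavy} is inferred from the atom name
#' when absent.
#'
#' @param atoms data.frame of atoms.
#' @return A \linkS4class{StructureFrame}.
#' @export
structureFrame <- function(atoms) {
  if (is.null(atoms$heavy)) atoms$heavy <- isHeavyAtom(atoms$elety)
  if (is.null(atoms$resid)) atoms$resid <- "ALA"
  newStructureFrame(atoms)
}

selectAtoms <- function(frame, selection = NULL) {
  a <- atomTable(frame)
  idx <- if (is.null(selection)) seq_len(nrow(a))
  else if (is.function(selection)) which(selection(a))
  else if (is.logical(selection)) which(selection)
  else as.integer(selection)
  a[idx, , drop = FALSE]
}

coords <- function(atoms) as.matrix(atoms[, c("x", "y", "z")])

#' Minimal RMSD after optimal rigid superposition (Kabsch)
#'
#' Centres both selections, finds the optimal rotation by singular value
#' decomposition of the cross-covariance (with the reflection correction),
#' and returns the root-mean-square deviation in Angstrom.  Atoms
#' correspond by order within the selection.
#'
#' @param mobile,reference \linkS4class{StructureFrame} objects.
#' @param selection \code{NULL} (all atoms), a predicate
#'   \code{function(atoms)} returning a logical vector, a logical vector,
#'   or integer indices; applied to both frames.
#' @return RMSD in Angstrom.
#' @export
kabschRMSD <- function(mobile, reference, selection = NULL) {
  X <- coords(selectAtoms(mobile, selection))
  Y <- coords(selectAtoms(reference, selection))
  if (nrow(X) != nrow(Y))
    stop("selections differ in atom count (", nrow(X), " vs ", nrow(Y), ")")
  if (nrow(X) < 3L) stop("at least 3 atoms are required")
  Xc <- sweep(X, 2, colMeans(X))
  Yc <- sweep(Y, 2, colMeans(Y))
  s <- svd(crossprod(Xc, Yc))
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((Yc - Xc %*% t(R))^2)))
}

#' Radius of gyration
#'
#' \eqn{R_g = \sqrt{\sum_k m_k |r_k - r_{com}|^2 / \sum_k m_k}} with unit
#' masses by default.
#'
#' @param frame a \linkS4class{StructureFrame}.
#' @param selection as in \code{\link{kabschRMSD}}.
#' @param masses optional per-selected-atom masses (default: unit).
#' @return Radius of gyration in Angstrom.
#' @export
radiusOfGyration <- function(frame, selection = NULL, masses = NULL) {
  X <- coords(selectAtoms(frame, selection))
  if (nrow(X) == 0L) stop("empty selection")
  m <- if (is.null(masses)) rep(1, nrow(X)) else masses
  stopifnot(length(m) == nrow(X))
  com <- colSums(X * m) / sum(m)
  sqrt(sum(m * rowSums(sweep(X, 2, com)^2)) / sum(m))
}

#' Heavy-atom residue contact map between two chains
#'
#' A residue pair is in contact when at least \code{minAtomPairs}
#' heavy-atom pairs (one atom from each residue) are separated by a
#' distance strictly below \code{cutoff}; the published rule uses a 5
#' Angstrom cutoff and at least two heavy-atom pairs
#' (\code{minAtomPairs = 1} reproduces the laxer single-pair reading).
#'
#' @param frame a \linkS4class{StructureFrame}.
#' @param chainA,chainB chain identifiers present in the frame.
#' @param cutoff distance cutoff in Angstrom (default 5.0).
#' @param minAtomPairs minimum qualifying atom pairs (default 2).
#' @return A \linkS4class{ContactMap}.
#' @export
residueContactMap <- function(frame, chainA, chainB, cutoff = 5.0,
                              minAtomPairs = 2L) {
  a <- atomTable(frame)
  A <- a[a$chain == chainA & a$heavy, , drop = FALSE]
  B <- a[a$chain == chainB & a$heavy, , drop = FALSE]
  if (nrow(A) == 0L) stop("chain ", chainA, " not present (or no heavy atoms)")
  if (nrow(B) == 0L) stop("chain ", chainB, " not present (or no heavy atoms)")
  resA <- sort(unique(A$resno))
  resB <- sort(unique(B$resno))
  D <- outer(rowSums(coords(A)^2), rowSums(coords(B)^2), "+") -
    2 * coords(A) %*% t(coords(B))
  D[D < 0] <- 0
  close <- sqrt(D) < cutoff            # strict inequality
  counts <- matrix(0L, length(resA), length(resB),
                   dimnames = list(resA, resB))
  ia <- match(A$resno, resA)
  ib <- match(B$resno, resB)
  for (k in seq_len(nrow(A))) {
    tab <- tapply(close[k, ], ib, sum)
    counts[ia[k], as.integer(names(tab))] <-
      counts[ia[k], as.integer(names(tab))] + as.integer(tab)
  }
  new("ContactMap", contacts = counts >= minAtomPairs, counts = counts,
      chainA = chainA, chainB = chainB, cutoff = cutoff,
      minAtomPairs = as.integer(minAtomPairs))
}

#' Fraction of native contacts present in each frame
#'
#' Recomputes the contact map of every frame under the same chains, cutoff
#' and atom-pair rule as the native map and reports the fraction of native
#' contacts retained.
#'
#' @param frames list of \linkS4class{StructureFrame} objects.
#' @param native the reference \linkS4class{ContactMap} (nonempty).
#' @return Numeric vector, one fraction per frame.
#' @export
nativeContactFraction <- function(frames, native) {
  natIdx <- which(contactMatrix(native), arr.ind = TRUE)
  if (nrow(natIdx) == 0L) stop("native contact map is empty")
  natA <- as.integer(rownames(contactMatrix(native)))[natIdx[, 1]]
  natB <- as.integer(colnames(contactMatrix(native)))[natIdx[, 2]]
  vapply(frames, function(fr) {
    cmF <- residueContactMap(fr, native@chainA, native@chainB,
                             cutoff = native@cutoff,
                             minAtomPairs = native@minAtomPairs)
    M <- contactMatrix(cmF)
    ra <- match(natA, as.integer(rownames(M)))
    rb <- match(natB, as.integer(colnames(M)))
    present <- !is.na(ra) & !is.na(rb)
    present[present] <- M[cbind(ra[present], rb[present])]
    mean(present)
  }, numeric(1))
}

#' Default residue bead charges at pH 7
#'
#' Asp/Glu -1, Lys/Arg +1, His (and everything else) neutral.
#'
#' @return Named numeric vector over three-letter residue codes.
#' @export
defaultCharges <- function()
  c(ASP = -1, GLU = -1, LYS = 1, ARG = 1, HIS = 0)

#' Electrostatic parameters for the Debye-Hueckel energy
#'
#' @param epsR relative dielectric constant (default 80, aqueous).
#' @param lD Debye screening length in Angstrom (default 10; or derive
#'   from temperature and ionic strength with \code{\link{debyeLength}}).
#' @param kElec Coulomb constant, 332.24 kcal mol^-1 e^-2 Angstrom.
#' @param charges named charge table over residue codes.
#' @return An \linkS4class{ElectrostaticParams}.
#' @export
electrostaticParams <- function(epsR = 80, lD = 10, kElec = 332.24,
                                charges = defaultCharges())
  new("ElectrostaticParams", kElec = kElec, epsR = epsR, lD = lD,
      charges = charges)

#' Debye screening length from temperature and ionic strength
#'
#' \eqn{l_D = \sqrt{\epsilon_r \epsilon_0 k_B T / (2 N_A e^2 I)}} with the
#' ionic strength I in mol/L, returned in Angstrom.  For water at 25 C
#' (epsR ~ 78.5) this gives the textbook 3.04/sqrt(I) Angstrom.
#'
#' @param temperature in Kelvin.
#' @param ionicStrength in mol/L.
#' @param epsR relative dielectric constant.
#' @return Debye length in Angstrom.
#' @export
debyeLength <- function(temperature = 300, ionicStrength = 0.1,
                        epsR = 80) {
  eps0 <- 8.8541878128e-12             # F/m
  kB <- 1.380649e-23                   # J/K
  e <- 1.602176634e-19                 # C
  NA_ <- 6.02214076e23                 # 1/mol
  I <- ionicStrength * 1000 * NA_      # ions/m^3
  sqrt(epsR * eps0 * kB * temperature / (2 * e^2 * I)) * 1e10
}

#' Debye-Hueckel screened electrostatic energy
#'
#' \deqn{V = K_{Elec} \sum_{i<j} \frac{q_i q_j}{\epsilon_r r_{ij}}
#'   e^{-r_{ij}/l_D}}
#' over one charged bead per residue.  By default the bead is the CB atom
#' (CA for glycine) of each residue carrying a nonzero charge in the
#' charge table.
#'
#' @param frame a \linkS4class{StructureFrame}.
#' @param params an \linkS4class{ElectrostaticParams}.
#' @param beadSelection optional selection (as in \code{\link{kabschRMSD}})
#'   overriding the default CB-bead rule; charges are then looked up per
#'   selected atom's residue.
#' @param interChainOnly restrict the sum to pairs on different chains.
#' @return Energy in kcal/mol.
#' @export
debyeHuckelEnergy <- function(frame, params = electrostaticParams(),
                              beadSelection = NULL,
                              interChainOnly = FALSE) {
  a <- if (is.null(beadSelection)) {
    t <- atomTable(frame)
    beads <- t[t$elety == "CB" | (t$elety == "CA" & t$resid == "GLY"), ,
               drop = FALSE]
    beads[!duplicated(beads[, c("chain", "resno")]), , drop = FALSE]
  } else selectAtoms(frame, beadSelection)
  qch <- unname(params@charges[a$resid])
  qch[is.na(qch)] <- 0
  keep <- qch != 0
  a <- a[keep, , drop = FALSE]; qch <- qch[keep]
  n <- nrow(a)
  if (n < 2L) return(0)
  X <- coords(a)
  V <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (interChainOnly && a$chain[i] == a$chain[j]) next
    r <- sqrt(sum((X[i, ] - X[j, ])^2))
    if (r == 0) stop("coincident charged beads (r = 0) at residues ",
                     a$resno[i], " and ", a$resno[j])
    V <- V + qch[i] * qch[j] * exp(-r / params@lD) / r
  }
  params@kElec * V / params@epsR
}

#' Per-frame trajectory summary
#'
#' Convenience wrapper computing, for every frame: RMSD to the reference,
#' radius of gyration, native-contact fraction, and Debye-Hueckel energy.
#'
#' @param frames list of \linkS4class{StructureFrame} objects.
#' @param reference reference \linkS4class{StructureFrame} (default: first
#'   frame).
#' @param chainA,chainB chains defining the interface contact map.
#' @param cutoff,minAtomPairs contact rule (defaults 5.0 A, 2 pairs).
#' @param params \linkS4class{ElectrostaticParams} for the energy term.
#' @return data.frame with columns frame, rmsd, rg, nativeFraction,
#'   dhEnergy.
#' @export
trajectorySummary <- function(frames, reference = frames[[1]],
                              chainA, chainB, cutoff = 5.0,
                              minAtomPairs = 2L,
                              params = electrostaticParams()) {
  native <- residueContactMap(reference, chainA, chainB, cutoff,
                              minAtomPairs)
  data.frame(frame = seq_along(frames),
             rmsd = vapply(frames, kabschRMSD, numeric(1),
                           reference = reference),
             rg = vapply(frames, radiusOfGyration, numeric(1)),
             nativeFraction = nativeContactFraction(frames, native),
             dhEnergy = vapply(frames, debyeHuckelEnergy, numeric(1),
                               params = params))
}
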