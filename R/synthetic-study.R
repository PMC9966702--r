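# Canonical synthetic validation studies: planted-coupling recovery and
# end-to-end hot-spot recovery.  The generator settings below ARE the
# study conditions (see the methods vignette for the rationale); they are
# deliberately fixed rather than exposed as tuning knobs.

#' Planted-coupling recovery study (one replicate)
#'
#' Draws a two-protein Potts model (30 + 30 columns, q = 8) with five
#' planted inter-protein couplings of strength 2.0, samples 2000 paired
#' sequences by Gibbs sampling, runs the full inference path (reweighting
#' at theta = 0.8, plmDCA, APC-corrected scores) and evaluates
#' precision@5 of the inter-protein coupling ranking against the planted
#' pairs.
#'
#' @param seed replicate seed.
#' @param m alignment depth (default 2000).
#' @return list with precisionAtK, averagePrecision, truth and the ranked
#'   pair list.
#' @export
plantedCouplingStudy <- function(seed, m = 2000L) {
  pm <- makePlantedModel(lenA = 30L, lenB = 30L, q = 8L, nPairs = 5L,
                         strength = 2.0, seed = seed)
  pa <- sampleMSA(pm$model, m = m, burnIn = 50L, seed = seed + 1000L)
  w <- sequenceWeights(pa, theta = 0.8)
  model <- fitPlm(pa, w)
  cm <- couplingScores(model, apc = TRUE)
  ranked <- rankInterPairs(interProteinBlock(cm))
  c(evaluateRecovery(ranked, pm$truth, k = 5L),
    list(truth = pm$truth, ranked = ranked))
}

#' End-to-end hot-spot recovery study (one replicate)
#'
#' Plants one contiguous interacting peptide pair (7 residues on each
#' protein, matched couplings of strength 2.0) in a 30 + 30 column model
#' (q = 8), samples 2000 sequences, infers couplings, convolves the
#' inter-protein block with a kernel matched to the peptide scale
#' (half-window l = 3 residues, i.e. a 7-residue window, variances
#' a = b = 0.05) and extracts hot-spot rectangles (top 5\% of cells,
#' merge separation 3).  Reports the Jaccard overlap (on cells) between
#' the top-1 rectangle and the planted region.
#'
#' @param seed replicate seed.
#' @param m alignment depth (default 2000).
#' @return list with jaccard, the top rectangle, all rectangles and the
#'   planted region.
#' @export
plantedInterfaceStudy <- function(seed, m = 2000L) {
  regionA <- 9:15
  regionB <- 14:20
  pm <- plantedInterfaceModel(lenA = 30L, lenB = 30L,
                              regionA = regionA, regionB = regionB,
                              q = 8L, strength = 2.0, seed = seed)
  pa <- sampleMSA(pm$model, m = m, burnIn = 50L, seed = seed + 1000L)
  model <- fitPlm(pa, sequenceWeights(pa, theta = 0.8))
  cm <- couplingScores(model, apc = TRUE)
  conv <- convolveCouplings(interProteinBlock(cm),
                            priorParams(a = 0.05, b = 0.05, l = 3L))
  rects <- extractHotspots(conv, topFraction = 0.05, minSeparation = 3L)
  planted <- c(startA = min(regionA), endA = max(regionA),
               startB = min(regionB), endB = max(regionB))
  jac <- if (nrow(rects) == 0) 0 else
    rectangleJaccard(rects[1, ], planted)
  list(jaccard = jac,
       top = if (nrow(rects)) rects[1, ] else NULL,
       rects = rects, planted = planted)
}

#' Jaccard overlap of two peptide-pair rectangles
#'
#' Cell-set Jaccard index of two rectangles given as
#' (startA, endA, startB, endB).
#'
#' @param r1,r2 rectangles: data.frame rows or named vectors with
#'   startA/endA/startB/endB.
#' @return Jaccard index in [0, 1].
#' @export
rectangleJaccard <- function(r1, r2) {
  g <- function(r, f) as.numeric(if (is.data.frame(r)) r[[f]] else r[[f]])
  ovA <- max(0, min(g(r1, "endA"), g(r2, "endA")) -
               max(g(r1, "startA"), g(r2, "startA")) + 1)
  ovB <- max(0, min(g(r1, "endB"), g(r2, "endB")) -
               max(g(r1, "startB"), g(r2, "startB")) + 1)
  a1 <- (g(r1, "endA") - g(r1, "startA") + 1) *
    (g(r1, "endB") - g(r1, "startB") + 1)
  a2 <- (g(r2, "endA") - g(r2, "startA") + 1) *
    (g(r2, "endB") - g(r2, "startB") + 1)
  inter <- ovA * ovB
  inter / (a1 + a2 - inter)
}
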