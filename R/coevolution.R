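# Potts-model inference (plmDCA) and coupling-score summarisation.

encodeAlignment <- function(pa, alphabet = NULL) {
  seqs <- alnMatrix(pa)
  if (is.null(alphabet)) {
    present <- unique(as.vector(seqs))
    alphabet <- spdcaAlphabet()[spdcaAlphabet() %in% present]
  }
  X <- matrix(match(seqs, alphabet), nrow = nrow(seqs))
  if (anyNA(X)) stop("alignment contains symbols outside the alphabet")
  list(X = X, alphabet = alphabet, q = length(alphabet))
}

#' Identity-based sequence reweighting
#'
#' Standard DCA preprocessing: the weight of row r is 1 over the number of
#' rows (including itself) whose fractional identity to r is at least
#' \code{theta}.  The effective sequence number Meff is the sum of weights.
#'
#' @param pa a \linkS4class{PairedAlignment}.
#' @param theta identity threshold in (0, 1]; default 0.8.
#' @return A \linkS4class{SequenceWeights}.
#' @export
sequenceWeights <- function(pa, theta = 0.8) {
  stopifnot(theta > 0, theta <= 1)
  seqs <- alnMatrix(pa)
  M <- nrow(seqs); L <- ncol(seqs)
  enc <- matrix(match(seqs, unique(as.vector(seqs))), nrow = M)
  counts <- rep(1L, M)
  if (M > 1) {
    for (r in seq_len(M - 1)) {
      ids <- rowMeans(enc[(r + 1):M, , drop = FALSE] ==
                        matrix(enc[r, ], M - r, L, byrow = TRUE))
      hits <- which(ids >= theta)
      counts[r] <- counts[r] + length(hits)
      counts[r + hits] <- counts[r + hits] + 1L
    }
  }
  w <- 1 / counts
  new("SequenceWeights", weights = w, theta = theta, mEff = sum(w))
}

# per-pair zero-sum gauge: subtract row/column means, add grand mean
zeroSumGauge <- function(K) {
  K - outer(rowMeans(K), rep(1, ncol(K))) -
    outer(rep(1, nrow(K)), colMeans(K)) + mean(K)
}

#' Fit a Potts model by pseudo-likelihood maximisation (plmDCA)
#'
#' Maximises, per alignment column, the weighted L2-regularised conditional
#' likelihood of that column given all others (asymmetric plmDCA), using
#' L-BFGS-B with analytic gradients.  The two per-column estimates of each
#' coupling block are averaged and the result is put in the zero-sum gauge.
#' The fit is deterministic given the inputs and optimizer tolerances.
#'
#' @param pa a \linkS4class{PairedAlignment}.
#' @param w a \linkS4class{SequenceWeights} (default: computed at
#'   theta = 0.8).
#' @param regFields,regCouplings L2 penalties; defaults 0.01 and
#'   0.01 * (L - 1) following common plmDCA practice.
#' @param alphabet state symbols; default: the alphabet symbols present in
#'   the alignment (gap included when present).
#' @param maxit,pgtol L-BFGS-B iteration cap and projected-gradient
#'   tolerance.
#' @return A \linkS4class{PottsModel}.
#' @export
fitPlm <- function(pa, w = sequenceWeights(pa), regFields = 0.01,
                   regCouplings = NULL, alphabet = NULL,
                   maxit = 200L, pgtol = 1e-5) {
  enc <- encodeAlignment(pa, alphabet)
  X <- enc$X; q <- enc$q
  M <- nrow(X); L <- ncol(X)
  if (M == 0L) stop("empty alignment")
  if (is.null(regCouplings)) regCouplings <- 0.01 * (L - 1)
  stopifnot(regFields > 0, regCouplings > 0)
  wts <- weights(w)
  stopifnot(length(wts) == M)

  # asymmetric per-site fits
  fields <- matrix(0, L, q)
  Jhat <- array(0, dim = c(q, q, L, L))
  conv <- integer(L)
  Xt <- t(X)                           # K x M views are cache-friendly
  for (r in seq_len(L)) {
    Xr <- Xt[-r, , drop = FALSE]
    yr <- X[, r]
    npar <- q + q * q * (L - 1L)
    cache <- new.env(parent = emptyenv())
    evalSite <- function(theta, grad) {
      if (!is.null(cache$theta) && identical(cache$theta, theta) &&
          (!grad || !is.null(cache$grad)))
        return(cache)
      res <- plm_site(theta, Xr, yr, wts, q, regFields, regCouplings, grad)
      cache$theta <- theta
      cache$value <- res$value
      cache$grad <- res$grad
      cache
    }
    fit <- optim(rep(0, npar),
                 fn = function(th) evalSite(th, TRUE)$value,
                 gr = function(th) evalSite(th, TRUE)$grad,
                 method = "L-BFGS-B",
                 control = list(maxit = maxit, pgtol = pgtol))
    if (!fit$convergence %in% c(0L, 1L))
      stop("plmDCA optimizer failed at column ", r, ": ", fit$message)
    conv[r] <- fit$convergence
    fields[r, ] <- fit$par[seq_len(q)]
    Jr <- array(fit$par[-seq_len(q)], dim = c(q, q, L - 1L))
    others <- seq_len(L)[-r]
    for (k in seq_along(others)) Jhat[, , r, others[k]] <- Jr[, , k]
  }

  # symmetrise the two per-column estimates, then zero-sum gauge
  J <- array(0, dim = c(q, q, L, L))
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    K <- zeroSumGauge((Jhat[, , i, j] + t(Jhat[, , j, i])) / 2)
    J[, , i, j] <- K
    J[, , j, i] <- t(K)
  }
  fields <- fields - rowMeans(fields)

  new("PottsModel", q = as.integer(q), alphabet = enc$alphabet,
      fields = fields, couplings = J,
      regFields = regFields, regCouplings = regCouplings,
      meta = list(gauge = "zero-sum", mEff = mEff(w), M = M,
                  lenA = lenA(pa), lenB = lenB(pa),
                  convergence = conv, maxit = maxit, pgtol = pgtol))
}

#' Log-pseudolikelihood of a Potts model on an alignment
#'
#' Sum over columns of the weighted conditional log-likelihoods (no
#' regularisation term); the quantity plmDCA maximises up to the L2 penalty.
#'
#' @param model a \linkS4class{PottsModel}.
#' @param pa the \linkS4class{PairedAlignment} to score.
#' @param w optional \linkS4class{SequenceWeights}; default: unit weights.
#' @return A single number (higher is better).
#' @export
pseudoLogLik <- function(model, pa, w = NULL) {
  enc <- encodeAlignment(pa, model@alphabet)
  X <- enc$X; q <- model@q
  M <- nrow(X); L <- ncol(X)
  wts <- if (is.null(w)) rep(1, M) else weights(w)
  total <- 0
  for (r in seq_len(L)) {
    theta <- c(model@fields[r, ],
               as.vector(model@couplings[, , r, -r, drop = FALSE]))
    res <- plm_site(theta, t(X[, -r, drop = FALSE]), X[, r], wts, q, 0, 0,
                    FALSE)
    total <- total - res$value
  }
  total
}

#' Summarise couplings into residue-residue scores
#'
#' The score of a column pair is the Frobenius norm of its gauge-fixed
#' coupling block over non-gap states.  With \code{apc = TRUE} (default) the
#' average product correction is subtracted
#' (S_ij - mean_i(S) mean_j(S) / mean(S), means over off-diagonal entries)
#' and negative corrected values are clipped to zero.
#'
#' @param model a fitted \linkS4class{PottsModel}.
#' @param apc apply the average product correction.
#' @return A \linkS4class{CouplingMatrix}.
#' @export
couplingScores <- function(model, apc = TRUE) {
  q <- model@q
  ng <- which(model@alphabet != "-")     # exclude the gap state
  L <- nrow(model@fields)
  S <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    S[i, j] <- S[j, i] <- sqrt(sum(model@couplings[ng, ng, i, j]^2))
  }
  raw <- S
  if (apc) S <- apcCorrect(S)
  lenA <- model@meta$lenA %||% 0L
  lenB <- model@meta$lenB %||% (L - lenA)
  new("CouplingMatrix", scores = S, raw = raw, apcApplied = apc,
      lenA = as.integer(lenA), lenB = as.integer(lenB))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Average product correction of a symmetric score matrix
#'
#' Subtracts \code{mean_i(S) * mean_j(S) / mean(S)}, all means computed over
#' off-diagonal entries; negative corrected entries are clipped to 0 and the
#' diagonal stays 0.
#'
#' @param S symmetric nonnegative matrix with zero diagonal.
#' @return Corrected matrix.
#' @export
apcCorrect <- function(S) {
  L <- nrow(S)
  off <- !diag(TRUE, L)
  rowM <- rowSums(S * off) / (L - 1)
  grand <- sum(S * off) / (L * (L - 1))
  if (grand == 0) return(S * 0)
  corrected <- S - outer(rowM, rowM) / grand
  corrected[corrected < 0] <- 0
  diag(corrected) <- 0
  corrected
}

#' Extract the inter-protein block of a coupling matrix
#'
#' Returns the lenA x lenB submatrix whose rows are protein-A columns and
#' whose columns are protein-B columns (in protein-B coordinates);
#' intra-protein scores are discarded.  This is the evolutionary score
#' matrix P fed to the structure-prior convolution.
#'
#' @param cm a \linkS4class{CouplingMatrix}, or a plain square matrix with
#'   \code{lenA}/\code{lenB} given.
#' @param lenA,lenB block lengths (defaults: recorded in \code{cm}).
#' @return A lenA x lenB numeric matrix.
#' @export
interProteinBlock <- function(cm, lenA = NULL, lenB = NULL) {
  S <- if (is(cm, "CouplingMatrix")) scoreMatrix(cm) else as.matrix(cm)
  if (is.null(lenA)) lenA <- lenA(cm)
  if (is.null(lenB)) lenB <- lenB(cm)
  if (lenA + lenB != nrow(S))
    stop("lenA + lenB (", lenA + lenB, ") must equal the matrix dimension (",
         nrow(S), ")")
  S[seq_len(lenA), lenA + seq_len(lenB), drop = FALSE]
}

# Mean-field DCA cross-check (inverse regularised covariance of one-hot
# encodings); used as an independent oracle in tests, not as the default
# inference path.
meanFieldScores <- function(pa, pseudocount = 0.5) {
  enc <- encodeAlignment(pa)
  X <- enc$X; q <- enc$q
  M <- nrow(X); L <- ncol(X)
  qm <- q - 1L                           # drop the last state per column
  H <- matrix(0, M, L * qm)
  for (i in seq_len(L)) for (s in seq_len(qm))
    H[, (i - 1L) * qm + s] <- as.numeric(X[, i] == s)
  f <- (colSums(H) + pseudocount * M / q) / (M * (1 + pseudocount))
  C <- crossprod(H) / M / (1 + pseudocount) - outer(f, f)
  diag(C) <- diag(C) + pseudocount / q * (1 - 1 / q)
  Jfull <- -solve(C)
  S <- matrix(0, L, L)
  for (i in seq_len(L - 1L)) for (j in (i + 1L):L) {
    blk <- Jfull[(i - 1L) * qm + seq_len(qm), (j - 1L) * qm + seq_len(qm)]
    S[i, j] <- S[j, i] <- sqrt(sum(zeroSumGauge(blk)^2))
  }
  apcCorrect(S)
}
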