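# Synthetic paired alignments from a two-block Potts model with planted
# inter-protein couplings: the validation harness for coupling inference
# and interface prediction.

#' Build a two-protein Potts model with planted inter-protein couplings
#'
#' Single-site fields are drawn i.i.d. normal with standard deviation 0.5;
#' all couplings are zero except at the planted inter-protein column pairs,
#' where J(s, t) = strength for s = t and 0 otherwise (favouring
#' co-occurring states, which makes mutual-information oracles direct).
#' Deterministic given \code{seed}.
#'
#' @param lenA,lenB column counts of the two proteins.
#' @param q alphabet size (2..20; states are the first q amino-acid
#'   letters).
#' @param nPairs number of planted pairs (ignored when \code{pairs} given).
#' @param strength planted coupling magnitude.
#' @param seed RNG seed.
#' @param pairs optional integer matrix (colA, colB in protein
#'   coordinates) of planted pairs; default: drawn uniformly without
#'   replacement.
#' @return list with elements \code{model} (\linkS4class{PottsModel}) and
#'   \code{truth} (\linkS4class{PlantedTruth}).
#' @export
#' @examples
#' pm <- makePlantedModel(10, 10, q = 4, nPairs = 2, strength = 2, seed = 1)
#' pm$truth
makePlantedModel <- function(lenA, lenB, q = 8L, nPairs = 5L,
                             strength = 2.0, seed = 1L, pairs = NULL) {
  stopifnot(q >= 2L, q <= 20L)
  L <- lenA + lenB
  set.seed(seed)
  fields <- matrix(rnorm(L * q, sd = 0.5), L, q)
  if (is.null(pairs)) {
    stopifnot(nPairs <= lenA * lenB)
    idx <- sample.int(lenA * lenB, nPairs)
    pairs <- cbind(colA = (idx - 1L) %% lenA + 1L,
                   colB = (idx - 1L) %/% lenA + 1L)
  } else {
    pairs <- cbind(colA = as.integer(pairs[, 1]),
                   colB = as.integer(pairs[, 2]))
  }
  J <- array(0, dim = c(q, q, L, L))
  if (nrow(pairs) > 0 && strength != 0) {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs[k, 1]; j <- lenA + pairs[k, 2]
      J[, , i, j] <- diag(strength, q)
      J[, , j, i] <- diag(strength, q)
    }
  }
  alphabet <- spdcaAlphabet()[seq_len(q)]
  model <- new("PottsModel", q = as.integer(q), alphabet = alphabet,
               fields = fields, couplings = J,
               regFields = 0, regCouplings = 0,
               meta = list(gauge = "generator", lenA = as.integer(lenA),
                           lenB = as.integer(lenB), seed = as.integer(seed)))
  truth <- new("PlantedTruth", pairs = pairs, strength = strength,
               seed = as.integer(seed), lenA = as.integer(lenA),
               lenB = as.integer(lenB), q = as.integer(q))
  list(model = model, truth = truth)
}

#' Plant one contiguous interacting peptide-pair region
#'
#' Convenience wrapper around \code{\link{makePlantedModel}} that plants
#' matched (diagonal) couplings along two equal-length peptide regions, the
#' synthetic analogue of one interacting peptide pair.
#'
#' @param lenA,lenB protein lengths.
#' @param regionA,regionB integer ranges (same length) of the interacting
#'   peptides, e.g. \code{10:16}.
#' @inheritParams makePlantedModel
#' @return As \code{\link{makePlantedModel}}.
#' @export
plantedInterfaceModel <- function(lenA, lenB, regionA, regionB,
                                  q = 8L, strength = 2.0, seed = 1L) {
  stopifnot(length(regionA) == length(regionB))
  makePlantedModel(lenA, lenB, q = q, strength = strength, seed = seed,
                   pairs = cbind(regionA, regionB))
}

# sparse per-site coupling lists for the Gibbs sampler
couplingNeighbours <- function(model) {
  L <- nrow(model@fields)
  partners <- vector("list", L)
  jmats <- vector("list", L)
  for (i in seq_len(L)) {
    nz <- which(vapply(seq_len(L), function(j)
      j != i && any(model@couplings[, , i, j] != 0), logical(1)))
    partners[[i]] <- as.integer(nz)
    jmats[[i]] <- lapply(nz, function(j) model@couplings[, , i, j])
  }
  list(partners = partners, jmats = jmats)
}

#' Sample a paired alignment from a Potts model by Gibbs sampling
#'
#' Runs \code{chains} parallel single-site Gibbs chains (default: one chain
#' per requested row, each recording its state after \code{burnIn} full
#' sweeps).  With \code{chains < m}, each chain is additionally thinned:
#' rows are recorded every \code{thin} sweeps after burn-in.  All
#' randomness flows through R's RNG, so results are reproducible given
#' \code{seed}.  Rows are tagged with synthetic species ids
#' \code{sp0001...}.
#'
#' @param model a \linkS4class{PottsModel} from
#'   \code{\link{makePlantedModel}} (its \code{meta} must record lenA and
#'   lenB).
#' @param m number of rows to sample.
#' @param burnIn burn-in sweeps per chain (default 50).
#' @param thin sweeps between recorded rows within one chain (default 5;
#'   only used when \code{chains < m}).
#' @param seed RNG seed.
#' @param chains number of parallel chains (default \code{m}).
#' @return A \linkS4class{PairedAlignment}.
#' @export
sampleMSA <- function(model, m, burnIn = 50L, thin = 5L, seed = 1L,
                      chains = m) {
  stopifnot(m >= 1L, burnIn >= 0L, chains >= 1L, chains <= m)
  L <- nrow(model@fields); q <- model@q
  lenA <- model@meta$lenA
  lenB <- model@meta$lenB
  if (is.null(lenA) || is.null(lenB))
    stop("model must record lenA and lenB in meta")
  nb <- couplingNeighbours(model)
  set.seed(seed)
  # initialise chains from the field-only marginals
  state <- matrix(0L, chains, L)
  for (i in seq_len(L)) {
    p <- exp(model@fields[i, ] - max(model@fields[i, ]))
    state[, i] <- sample.int(q, chains, replace = TRUE, prob = p / sum(p))
  }
  gumbelNoise <- function()
    matrix(-log(-log(runif(chains * q * L))), chains, q * L)
  for (s in seq_len(burnIn))
    state <- gibbs_sweep(state, model@fields, nb$partners, nb$jmats,
                         gumbelNoise())
  rows <- matrix(0L, m, L)
  if (chains == m) {
    rows[] <- state
  } else {
    taken <- 0L
    rows[seq_len(chains), ] <- state
    taken <- chains
    while (taken < m) {
      for (s in seq_len(thin))
        state <- gibbs_sweep(state, model@fields, nb$partners, nb$jmats,
                             gumbelNoise())
      take <- min(chains, m - taken)
      rows[taken + seq_len(take), ] <- state[seq_len(take), , drop = FALSE]
      taken <- taken + take
    }
  }
  seqs <- matrix(model@alphabet[rows], m, L)
  new("PairedAlignment", seqs = seqs,
      species = sprintf("sp%04d", seq_len(m)),
      lenA = as.integer(lenA), lenB = as.integer(lenB),
      nameA = "synthA", nameB = "synthB", nDropped = 0L)
}

#' Write the planted truth as a TSV
#'
#' @param truth a \linkS4class{PlantedTruth}.
#' @param path output TSV path (columns col_a, col_b, strength, seed).
#' @return \code{path}, invisibly.
#' @export
writeTruth <- function(truth, path) {
  p <- plantedPairs(truth)
  write.table(data.frame(col_a = p[, 1], col_b = p[, 2],
                         strength = truth@strength, seed = truth@seed),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rank inter-protein cells of a score matrix
#'
#' @param P lenA x lenB inter-protein score matrix.
#' @return data.frame (colA, colB, score) sorted by decreasing score.
#' @export
rankInterPairs <- function(P) {
  idx <- which(!is.na(P), arr.ind = TRUE)
  out <- data.frame(colA = idx[, 1], colB = idx[, 2], score = P[idx])
  out <- out[order(-out$score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Precision of a ranked pair list against the planted truth
#'
#' @param predicted data.frame or matrix whose first two columns are
#'   (colA, colB), ranked best first (see \code{\link{rankInterPairs}}).
#' @param truth a \linkS4class{PlantedTruth}.
#' @param k evaluate precision at this depth (default: number of planted
#'   pairs).
#' @return list with precisionAtK and averagePrecision.
#' @export
evaluateRecovery <- function(predicted, truth, k = nrow(plantedPairs(truth))) {
  stopifnot(k >= 1L)
  pred <- as.matrix(predicted[, 1:2, drop = FALSE])
  tr <- plantedPairs(truth)
  key <- function(m) paste(m[, 1], m[, 2], sep = ":")
  hits <- key(pred) %in% key(tr)
  pAtK <- sum(hits[seq_len(min(k, length(hits)))]) / k
  cum <- cumsum(hits) / seq_along(hits)
  ap <- if (nrow(tr) == 0) NA_real_ else sum(cum[hits]) / nrow(tr)
  list(precisionAtK = pAtK, averagePrecision = ap)
}
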