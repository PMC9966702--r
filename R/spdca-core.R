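# The structure-prior Gaussian convolution of the inter-protein coupling
# map, and hot-spot rectangle extraction / domain labelling.

#' Prior parameters of the interface convolution
#'
#' @param a,b normalised kernel variances along proteins A and B
#'   (default 0.001).
#' @param l half-window in residues: the window over the first protein runs
#'   from i - l to i + l (default 21, the average length of the peptides
#'   involved in the interaction).
#' @return A \linkS4class{PriorParams}.
#' @export
priorParams <- function(a = 0.001, b = 0.001, l = 21L)
  new("PriorParams", a = a, b = b, l = as.integer(l))

#' Convolve an inter-protein coupling map with the structure-prior kernel
#'
#' Computes, for every residue pair (i, j) of the two proteins,
#' \deqn{Q_{ij} = \sum_{\alpha=i-l}^{i+l} \sum_{\beta=j-l}^{j+l}
#'   P'_{\alpha\beta} \exp[-(a(\alpha-i)^2 + b(\beta-j)^2)]}
#' where \eqn{P'_{\alpha\beta} = m_A[\alpha] m_B[\beta] P_{\alpha\beta}} is
#' the coupling map with the structure-prior column masks applied.  Window
#' terms falling outside the matrix contribute zero (boundary clipping; the
#' proteins are not periodic).  Implemented exactly, as two banded-kernel
#' matrix products.
#'
#' @param P lenA x lenB inter-protein score matrix (see
#'   \code{\link{interProteinBlock}}), all entries finite.
#' @param params a \linkS4class{PriorParams}.
#' @param maskA,maskB optional \linkS4class{PriorMask} (or numeric vectors)
#'   for the two proteins; all-ones when absent.
#' @return A \linkS4class{ConvolvedMap}.
#' @export
convolveCouplings <- function(P, params = priorParams(),
                              maskA = NULL, maskB = NULL) {
  P <- as.matrix(P)
  if (!all(is.finite(P))) stop("P contains non-finite entries")
  wA <- if (is.null(maskA)) rep(1, nrow(P)) else
    if (is(maskA, "PriorMask")) maskWeights(maskA) else as.numeric(maskA)
  wB <- if (is.null(maskB)) rep(1, ncol(P)) else
    if (is(maskB, "PriorMask")) maskWeights(maskB) else as.numeric(maskB)
  if (length(wA) != nrow(P) || length(wB) != ncol(P))
    stop("mask lengths must match the matrix dimensions")
  Pm <- P * outer(wA, wB)
  KA <- bandKernel(nrow(P), params@a, params@l)
  KB <- bandKernel(ncol(P), params@b, params@l)
  Q <- KA %*% Pm %*% KB                 # KB symmetric
  prov <- c(if (is.null(maskA)) "A:all-ones" else
              paste0("A:", if (is(maskA, "PriorMask")) maskA@provenance
                     else "numeric"),
            if (is.null(maskB)) "B:all-ones" else
              paste0("B:", if (is(maskB, "PriorMask")) maskB@provenance
                     else "numeric"))
  new("ConvolvedMap", qmap = Q, params = params, masks = prov)
}

# symmetric banded Gaussian kernel matrix: K[i, alpha] = exp(-v (alpha-i)^2)
# for |alpha - i| <= l, else 0
bandKernel <- function(n, v, l) {
  d <- abs(outer(seq_len(n), seq_len(n), "-"))
  K <- exp(-v * d^2)
  K[d > l] <- 0
  K
}

#' Extract hot-spot rectangles from a convolved map
#'
#' Cells with Q strictly above the (1 - topFraction) quantile are grouped
#' into 8-connected components; each component contributes its bounding
#' rectangle.  Components whose bounding boxes are closer than
#' \code{minSeparation} residues on both axes are merged.  Rectangles are
#' returned sorted by peak score, with peak and mean computed over the
#' component cells.  A constant map has no distinguishable hot-spot and
#' yields an empty result with a warning.
#'
#' @param cm a \linkS4class{ConvolvedMap} (or a plain matrix).
#' @param topFraction fraction of cells considered hot (default 0.01).
#' @param minSeparation merge distance in residues (default 10).
#' @return data.frame with columns startA, endA, startB, endB, peakScore,
#'   meanScore, labelA, labelB (labels NA until
#'   \code{\link{labelHotspots}}).
#' @export
extractHotspots <- function(cm, topFraction = 0.01, minSeparation = 10L) {
  stopifnot(topFraction > 0, topFraction <= 1)
  Q <- if (is(cm, "ConvolvedMap")) qMatrix(cm) else as.matrix(cm)
  emptyRes <- data.frame(startA = integer(), endA = integer(),
                         startB = integer(), endB = integer(),
                         peakScore = numeric(), meanScore = numeric(),
                         labelA = character(), labelB = character())
  thr <- quantile(Q, 1 - topFraction, names = FALSE)
  hot <- Q > thr
  if (!any(hot)) {
    warning("no cells above the threshold (constant map?)")
    return(emptyRes)
  }
  comp <- connectedComponents(hot)
  cells <- lapply(seq_len(max(comp[comp > 0])), function(k)
    which(comp == k, arr.ind = TRUE))
  # merge components whose bounding boxes are close on both axes
  repeat {
    merged <- FALSE
    k <- 1L
    while (k < length(cells)) {
      j <- k + 1L
      while (j <= length(cells)) {
        if (boxGap(cells[[k]], cells[[j]], 1) < minSeparation &&
            boxGap(cells[[k]], cells[[j]], 2) < minSeparation) {
          cells[[k]] <- rbind(cells[[k]], cells[[j]])
          cells[[j]] <- NULL
          merged <- TRUE
        } else j <- j + 1L
      }
      k <- k + 1L
    }
    if (!merged) break
  }
  res <- do.call(rbind, lapply(cells, function(cc) {
    v <- Q[cc]
    data.frame(startA = min(cc[, 1]), endA = max(cc[, 1]),
               startB = min(cc[, 2]), endB = max(cc[, 2]),
               peakScore = max(v), meanScore = mean(v),
               labelA = NA_character_, labelB = NA_character_)
  }))
  res <- res[order(-res$peakScore), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# gap between the bounding intervals of two cell sets along one axis
boxGap <- function(c1, c2, axis) {
  lo <- max(min(c1[, axis]), min(c2[, axis]))
  hi <- min(max(c1[, axis]), max(c2[, axis]))
  max(0L, lo - hi)
}

# label 8-connected components of a logical matrix (flood fill)
connectedComponents <- function(mask) {
  comp <- matrix(0L, nrow(mask), ncol(mask))
  lab <- 0L
  idx <- which(mask, arr.ind = TRUE)
  for (n in seq_len(nrow(idx))) {
    i0 <- idx[n, 1]; j0 <- idx[n, 2]
    if (comp[i0, j0] > 0L) next
    lab <- lab + 1L
    queue <- matrix(c(i0, j0), 1)
    comp[i0, j0] <- lab
    while (nrow(queue) > 0) {
      i <- queue[1, 1]; j <- queue[1, 2]
      queue <- queue[-1, , drop = FALSE]
      for (di in -1:1) for (dj in -1:1) {
        ii <- i + di; jj <- j + dj
        if (ii >= 1 && ii <= nrow(mask) && jj >= 1 && jj <= ncol(mask) &&
            mask[ii, jj] && comp[ii, jj] == 0L) {
          comp[ii, jj] <- lab
          queue <- rbind(queue, c(ii, jj))
        }
      }
    }
  }
  comp
}

#' Label hot-spot rectangles with topology domains
#'
#' Each rectangle is labelled, on each axis, with the label of the segment
#' containing the majority of its columns (ties broken by the lower-start
#' segment), giving interaction strings such as \code{"C-Ter/N-Ter"}.
#'
#' @param rects data.frame from \code{\link{extractHotspots}}.
#' @param dmA,dmB \linkS4class{DomainMap} of proteins A and B.
#' @return \code{rects} with labelA, labelB and an \code{interaction} column
#'   filled in.
#' @export
labelHotspots <- function(rects, dmA, dmB) {
  if (nrow(rects) == 0) {
    rects$interaction <- character(0)
    return(rects)
  }
  rects$labelA <- vapply(seq_len(nrow(rects)), function(k)
    majoritySegment(dmA, rects$startA[k], rects$endA[k]), "")
  rects$labelB <- vapply(seq_len(nrow(rects)), function(k)
    majoritySegment(dmB, rects$startB[k], rects$endB[k]), "")
  rects$interaction <- paste0(rects$labelA, "/", rects$labelB)
  rects
}

# label of the segment covering most of [start, end]; ties -> lower start
majoritySegment <- function(dm, start, end) {
  s <- domainSegments(dm)
  cover <- pmax(0L, pmin(s$end, end) - pmax(s$start, start) + 1L)
  s$label[which.max(cover)]            # which.max: first (lowest-start) max
}

#' Write a convolved map / hot-spot table to disk
#'
#' @param cm a \linkS4class{ConvolvedMap}.
#' @param path output path (dense CSV for maps, TSV for hot-spots).
#' @return \code{path}, invisibly.
#' @export
writeQMap <- function(cm, path) {
  write.table(qMatrix(cm), path, sep = ",", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeQMap
#' @param rects hot-spot data.frame from \code{\link{extractHotspots}}.
#' @export
writeHotspots <- function(rects, path) {
  write.table(rects, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a dense CSV map written by writeQMap
#'
#' @param path CSV path.
#' @param params optional \linkS4class{PriorParams} to attach.
#' @return A \linkS4class{ConvolvedMap}.
#' @export
readQMap <- function(path, params = priorParams()) {
  m <- as.matrix(read.table(path, sep = ","))
  dimnames(m) <- NULL
  new("ConvolvedMap", qmap = m, params = params, masks = "file")
}
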