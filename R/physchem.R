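# Sliding-window physicochemical property profiles and interface contrasts.

#' Canonical amino-acid property scales
#'
#' Loads the property scales shipped with the package
#' (\code{inst/extdata/property_scales.tsv}): Kyte-Doolittle hydrophobicity,
#' Hopp-Woods hydrophilicity, Grantham polarity, integer side-chain charge
#' at pH 7 (D, E = -1; K, R = +1; H = 0), Charton polarizability, residue
#' side-chain volume (A^3), Chou-Fasman alpha-helix propensity, and the
#' theoretical maximum solvent-accessible surface area per residue (A^2).
#' Any tab-separated file with a \code{residue} column and one numeric
#' column per scale can be substituted.
#'
#' @param path optional TSV path; default: the packaged scales.
#' @return Named list of named numeric vectors (20 values each).
#' @export
#' @examples
#' names(propertyScales())
#' propertyScales()$hydrophobicity["W"]
propertyScales <- function(path = system.file("extdata",
                                              "property_scales.tsv",
                                              package = "spdca")) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  stopifnot("residue" %in% names(d), nrow(d) == 20L)
  out <- lapply(names(d)[names(d) != "residue"], function(nm)
    setNames(d[[nm]], d$residue))
  names(out) <- names(d)[names(d) != "residue"]
  out
}

#' Sliding-window property profile of a sequence
#'
#' The value at position i is the mean of the scale values of the non-gap
#' residues in the window [i - (w-1)/2, i + (w-1)/2], clipped to the
#' sequence bounds.  Positions whose window holds only gaps are \code{NA}.
#'
#' @param seq sequence as a string or character vector (gaps \code{"-"}
#'   allowed).
#' @param scale a named numeric vector over the 20 amino acids (one element
#'   of \code{\link{propertyScales}}), or a scale name.
#' @param window odd window length in residues (default 9).
#' @return data.frame with columns position, residue, value.
#' @export
#' @examples
#' propertyProfile("ARNDC", "hydrophobicity", window = 3)
propertyProfile <- function(seq, scale, window = 9L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L)
    stop("window must be an odd positive integer")
  if (is.character(scale) && length(scale) == 1L)
    scale <- propertyScales()[[scale]] %||%
      stop("unknown scale name: ", scale)
  if (is.character(seq) && length(seq) == 1L)
    seq <- strsplit(toupper(seq), "")[[1]]
  n <- length(seq)
  vals <- unname(scale[seq])           # NA for gaps / unknowns
  half <- (window - 1L) %/% 2L
  prof <- vapply(seq_len(n), function(i) {
    win <- vals[max(1L, i - half):min(n, i + half)]
    if (all(is.na(win))) NA_real_ else mean(win, na.rm = TRUE)
  }, numeric(1))
  data.frame(position = seq_len(n), residue = seq, value = prof)
}

#' Contrast a property profile inside vs outside predicted hot-spots
#'
#' Compares the profile values at the hot-spot columns (union over the
#' rectangles on the chosen axis, no double counting) against all remaining
#' columns, with a Wilcoxon rank-sum statistic and a seeded permutation
#' p-value obtained by permuting column labels.
#'
#' @param profile data.frame from \code{\link{propertyProfile}}.
#' @param rects hot-spot data.frame (\code{\link{extractHotspots}}).
#' @param axis \code{"A"} (use startA/endA) or \code{"B"}.
#' @param nPerm number of label permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @return data.frame with meanInside, meanOutside, difference, the
#'   rank-sum statistic, pValue, nInside, nOutside, nPerm.
#' @export
interfaceContrast <- function(profile, rects, axis = c("A", "B"),
                              nPerm = 10000L, seed = 1L) {
  axis <- match.arg(axis)
  if (nrow(rects) == 0L) stop("empty hot-spot set")
  n <- nrow(profile)
  cols <- if (axis == "A") Map(`:`, rects$startA, rects$endA) else
    Map(`:`, rects$startB, rects$endB)
  inside <- sort(unique(unlist(cols)))
  if (any(inside < 1L | inside > n))
    stop("hot-spot rectangles outside the sequence bounds")
  isIn <- seq_len(n) %in% inside
  vals <- profile$value
  ok <- !is.na(vals)
  vals <- vals[ok]; isIn <- isIn[ok]
  nIn <- sum(isIn); nOut <- sum(!isIn)
  if (nIn == 0L || nOut == 0L)
    stop("both inside and outside sets must be non-empty")
  rk <- rank(vals)
  W <- sum(rk[isIn])                    # rank-sum of the inside group
  expW <- nIn * (length(vals) + 1) / 2
  withr_seed <- function(expr) {        # local, restorable RNG state
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
      globalenv()) else NULL
    set.seed(seed)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    expr
  }
  exceed <- withr_seed({
    sum(vapply(seq_len(nPerm), function(p) {
      Wp <- sum(rk[sample.int(length(vals), nIn)])
      abs(Wp - expW) >= abs(W - expW)
    }, logical(1)))
  })
  data.frame(meanInside = mean(vals[isIn]), meanOutside = mean(vals[!isIn]),
             difference = mean(vals[isIn]) - mean(vals[!isIn]),
             statistic = W, pValue = (1 + exceed) / (nPerm + 1),
             nInside = nIn, nOutside = nOut, nPerm = nPerm)
}
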