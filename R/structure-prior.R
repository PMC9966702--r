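# Topology annotation parsing and structure-prior column masks.

#' Parse a topology segment table into a DomainMap
#'
#' Accepts a data.frame or a TSV path with columns \code{label},
#' \code{category}, \code{start}, \code{end} (1-based, inclusive), in the
#' UniProt topology style (categories N-terminal, C-terminal, TM, ICL, ECL,
#' other).  Gaps between annotated segments are auto-filled with category
#' \code{"other"}.
#'
#' @param table data.frame or path to a tab-separated file with a header.
#' @param protein protein name.
#' @param protLength protein length; default \code{max(end)}.
#' @return A \linkS4class{DomainMap}.
#' @export
#' @examples
#' tab <- data.frame(label = c("ECL2", "C-Ter"),
#'                   category = c("ECL", "C-terminal"),
#'                   start = c(144, 291), end = c(173, 412))
#' parseTopology(tab, protein = "A2aR")
parseTopology <- function(table, protein = "protein", protLength = NULL) {
  if (is.character(table) && base::length(table) == 1L)
    table <- read.table(table, sep = "\t", header = TRUE,
                        stringsAsFactors = FALSE)
  s <- as.data.frame(table)[, c("label", "category", "start", "end")]
  s$start <- as.integer(s$start); s$end <- as.integer(s$end)
  if (any(bad <- s$end < s$start))
    stop("segment '", s$label[which(bad)[1]], "' has end < start")
  o <- order(s$start)
  s <- s[o, , drop = FALSE]
  if (nrow(s) > 1) {
    ov <- which(s$start[-1] <= s$end[-nrow(s)])
    if (length(ov))
      stop("overlapping segments '", s$label[ov[1]], "' and '",
           s$label[ov[1] + 1], "'")
  }
  if (is.null(protLength)) protLength <- max(s$end)
  # fill uncovered stretches with category "other"
  fill <- list()
  prev <- 0L
  for (k in seq_len(nrow(s))) {
    if (s$start[k] > prev + 1L)
      fill[[base::length(fill) + 1L]] <-
        data.frame(label = "other", category = "other",
                   start = prev + 1L, end = s$start[k] - 1L)
    prev <- s$end[k]
  }
  if (prev < protLength)
    fill[[base::length(fill) + 1L]] <-
      data.frame(label = "other", category = "other",
                 start = prev + 1L, end = as.integer(protLength))
  s <- rbind(s, do.call(rbind, fill))
  s <- s[order(s$start), , drop = FALSE]
  rownames(s) <- NULL
  new("DomainMap", protein = protein, length = as.integer(protLength),
      segments = s)
}

#' Write a DomainMap back to a TSV segment table
#'
#' Only the annotated (non-filler) segments are written, so parse/serialize
#' round-trips are stable.
#'
#' @param dm a \linkS4class{DomainMap}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeTopology <- function(dm, path) {
  s <- domainSegments(dm)
  write.table(s[s$label != "other" | s$category != "other", ],
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Category label of each protein column
#'
#' @param dm a \linkS4class{DomainMap}.
#' @return Character vector of length \code{dm@length}.
#' @export
columnCategories <- function(dm) {
  out <- rep("other", dm@length)
  s <- domainSegments(dm)
  for (k in seq_len(nrow(s))) out[s$start[k]:s$end[k]] <- s$category[k]
  out
}

#' Build a structure-prior column mask from a topology annotation
#'
#' Columns in the included categories get weight 1, all others 0.  The
#' default keeps the non-transmembrane categories (N-terminal, C-terminal,
#' ICL, ECL), reflecting that coevolutionary signal is least informative
#' inside the membrane-embedded helices.
#'
#' @param dm a \linkS4class{DomainMap}.
#' @param include categories to keep; subset of
#'   \code{c("N-terminal", "C-terminal", "TM", "ICL", "ECL", "other")}.
#' @return A \linkS4class{PriorMask}.
#' @export
buildPriorMask <- function(dm,
                           include = c("N-terminal", "C-terminal",
                                       "ICL", "ECL")) {
  if (!all(include %in% domainCategories()))
    stop("unknown category: ",
         paste(setdiff(include, domainCategories()), collapse = " "))
  w <- as.numeric(columnCategories(dm) %in% include)
  if (all(w == 0)) warning("prior mask is all zeros")
  new("PriorMask", weights = w,
      provenance = paste0("categories{", paste(include, collapse = ","), "}"))
}

#' An all-ones prior mask (no structural prior)
#'
#' @param n number of columns.
#' @return A \linkS4class{PriorMask} of ones.
#' @export
unitMask <- function(n)
  new("PriorMask", weights = rep(1, n), provenance = "all-ones")

#' Write / read a prior mask as TSV
#'
#' @param mask a \linkS4class{PriorMask}.
#' @param path TSV path (columns position, weight).
#' @return \code{path} (write) or a \linkS4class{PriorMask} (read).
#' @export
writeMask <- function(mask, path) {
  write.table(data.frame(position = seq_along(maskWeights(mask)),
                         weight = maskWeights(mask)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeMask
#' @export
readMask <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE)
  new("PriorMask", weights = d$weight[order(d$position)],
      provenance = paste0("file:", basename(path)))
}
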