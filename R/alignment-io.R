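# Reading, filtering and species-wise concatenation of ortholog alignments.

newAlignment <- function(seqs, species, name, nUnknown = 0L) {
  dimnames(seqs) <- NULL
  new("Alignment", seqs = seqs, species = as.character(species),
      name = name, nUnknown = as.integer(nUnknown))
}

#' Read an aligned FASTA file into an Alignment
#'
#' Symbols are uppercased; gaps are kept as \code{"-"}; any symbol outside
#' the 21-state alphabet (including \code{"."} and \code{"X"}) is mapped to
#' the gap and counted.  The species id is parsed from each header, by
#' default as the first whitespace-delimited token; supply
#' \code{speciesPattern} (a regex with one capture group) to override.
#'
#' @param path path to an aligned FASTA file.
#' @param name protein identifier (default: file name without extension).
#' @param speciesPattern optional regex with one capture group applied to the
#'   full header to extract the species id.
#' @return An \linkS4class{Alignment}.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">human", "MKV-A", ">mouse", "MKVQA"), fa)
#' readAlignment(fa, name = "demo")
readAlignment <- function(path, name = sub("\\.[^.]*$", "", basename(path)),
                          speciesPattern = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  widths <- Biostrings::width(set)
  if (length(unique(widths)) > 1L) {
    bad <- which(widths != widths[1])[1]
    stop("ragged alignment: record ", bad, " ('", names(set)[bad],
         "') has length ", widths[bad], ", expected ", widths[1])
  }
  chars <- toupper(as.character(set))
  seqs <- matrix(unlist(strsplit(chars, ""), use.names = FALSE),
                 nrow = length(set), byrow = TRUE)
  unknown <- !(seqs %in% spdcaAlphabet())
  if (any(unknown)) {
    warning(sum(unknown), " unknown symbol(s) mapped to gap")
    seqs[unknown] <- "-"
  }
  headers <- names(set)
  species <- if (is.null(speciesPattern)) {
    sub("\\s.*$", "", headers)
  } else {
    m <- regmatches(headers, regexec(speciesPattern, headers))
    vapply(m, function(g) if (length(g) >= 2) g[2] else NA_character_, "")
  }
  if (anyNA(species)) stop("species pattern failed on some headers")
  newAlignment(seqs, species, name, sum(unknown))
}

#' Write an Alignment (or PairedAlignment) as FASTA
#'
#' For a \linkS4class{PairedAlignment} a sidecar metadata file
#' (\code{<path>.meta.tsv}) records \code{len_a}, \code{len_b} and the
#' species list in tab-separated form.
#'
#' @param x an \linkS4class{Alignment} or \linkS4class{PairedAlignment}.
#' @param path output FASTA path.
#' @return \code{path}, invisibly.
#' @export
writeAlignment <- function(x, path) {
  seqs <- alnMatrix(x)
  set <- Biostrings::BStringSet(apply(seqs, 1, paste, collapse = ""))
  names(set) <- speciesIds(x)
  Biostrings::writeXStringSet(set, path)
  if (is(x, "PairedAlignment")) {
    meta <- rbind(c("len_a", x@lenA), c("len_b", x@lenB),
                  cbind("species", speciesIds(x)))
    write.table(meta, paste0(path, ".meta.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a paired alignment written by writeAlignment
#'
#' @param path FASTA path; the sidecar \code{<path>.meta.tsv} must exist.
#' @param nameA,nameB protein identifiers.
#' @return A \linkS4class{PairedAlignment}.
#' @export
readPairedAlignment <- function(path, nameA = "A", nameB = "B") {
  meta <- read.table(paste0(path, ".meta.tsv"), sep = "\t",
                     stringsAsFactors = FALSE)
  la <- as.integer(meta[meta[, 1] == "len_a", 2])
  lb <- as.integer(meta[meta[, 1] == "len_b", 2])
  aln <- readAlignment(path, name = nameA)
  new("PairedAlignment", seqs = alnMatrix(aln), species = speciesIds(aln),
      lenA = la, lenB = lb, nameA = nameA, nameB = nameB, nDropped = 0L)
}

# fractional identity over mutually ungapped columns; NA when none
fracIdentity <- function(row, ref) {
  ok <- row != "-" & ref != "-"
  if (!any(ok)) return(NA_real_)
  mean(row[ok] == ref[ok])
}

asRefVector <- function(reference, width) {
  if (is.character(reference) && length(reference) == 1L)
    reference <- strsplit(toupper(reference), "")[[1]]
  if (length(reference) != width)
    stop("reference length (", length(reference),
         ") must match the alignment width (", width, ")")
  reference
}

#' Filter alignment rows by fractional identity to a reference
#'
#' Identity is computed over columns where neither the row nor the reference
#' has a gap.  Rows whose identity lies in \code{[minFrac, maxFrac]} are
#' retained; the published ortholog filter keeps sequences with 70--90\%
#' similarity to the human protein.  All-gap rows (undefined identity) are
#' dropped with a warning.
#'
#' @param aln an \linkS4class{Alignment}.
#' @param reference aligned reference sequence (string or character vector,
#'   same width as the alignment).
#' @param minFrac,maxFrac inclusive identity bounds in [0, 1].
#' @return The filtered \linkS4class{Alignment} (possibly empty, with a
#'   warning).
#' @export
filterBySimilarity <- function(aln, reference, minFrac = 0.7, maxFrac = 0.9) {
  stopifnot(minFrac >= 0, maxFrac <= 1, minFrac <= maxFrac)
  seqs <- alnMatrix(aln)
  ref <- asRefVector(reference, ncol(seqs))
  ids <- apply(seqs, 1, fracIdentity, ref = ref)
  if (anyNA(ids))
    warning(sum(is.na(ids)), " all-gap row(s) dropped (undefined identity)")
  keep <- !is.na(ids) & ids >= minFrac & ids <= maxFrac
  if (!any(keep)) warning("no rows within the identity bounds")
  newAlignment(seqs[keep, , drop = FALSE], speciesIds(aln)[keep],
               aln@name, aln@nUnknown)
}

#' Keep the best isoform per species
#'
#' For species with several rows (isoforms), keep the row with maximal
#' fractional identity to the reference; ties are broken by first occurrence.
#'
#' @inheritParams filterBySimilarity
#' @return An \linkS4class{Alignment} with one row per species.
#' @export
selectBestIsoform <- function(aln, reference) {
  seqs <- alnMatrix(aln)
  ref <- asRefVector(reference, ncol(seqs))
  ids <- apply(seqs, 1, fracIdentity, ref = ref)
  ids[is.na(ids)] <- -Inf
  keep <- vapply(split(seq_len(nrow(seqs)), speciesIds(aln)), function(idx) {
    idx[which.max(ids[idx])]          # which.max takes the first maximum
  }, integer(1))
  keep <- sort(unname(keep))          # preserve file order
  newAlignment(seqs[keep, , drop = FALSE], speciesIds(aln)[keep],
               aln@name, aln@nUnknown)
}

#' Concatenate two alignments by species
#'
#' Builds the concatenated MSA (cMSA): for every species present in both
#' alignments the protein-A row is followed by the protein-B row.  Species
#' present in only one alignment are dropped and counted in
#' \code{@nDropped}.
#'
#' @param a,b \linkS4class{Alignment} objects with unique species ids.
#' @return A \linkS4class{PairedAlignment}.
#' @export
concatenateBySpecies <- function(a, b) {
  if (anyDuplicated(speciesIds(a)) || anyDuplicated(speciesIds(b)))
    stop("species ids must be unique; run selectBestIsoform first")
  shared <- intersect(speciesIds(a), speciesIds(b))
  if (length(shared) == 0L) stop("no species shared between the alignments")
  ia <- match(shared, speciesIds(a))
  ib <- match(shared, speciesIds(b))
  seqs <- cbind(alnMatrix(a)[ia, , drop = FALSE],
                alnMatrix(b)[ib, , drop = FALSE])
  dropped <- (nSequences(a) - length(shared)) + (nSequences(b) - length(shared))
  new("PairedAlignment", seqs = seqs, species = shared,
      lenA = alnLength(a), lenB = alnLength(b),
      nameA = a@name, nameB = b@name, nDropped = as.integer(dropped))
}
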