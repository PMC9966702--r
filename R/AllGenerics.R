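#' @name spdca-accessors
#' @title Accessors for spdca data objects
#' @description Slot accessors for the package's S4 containers.
#' @param x an spdca object.
#' @return The requested component.
NULL

#' @rdname spdca-accessors
#' @export
setGeneric("alnMatrix", function(x) standardGeneric("alnMatrix"))
#' @rdname spdca-accessors
#' @export
setGeneric("speciesIds", function(x) standardGeneric("speciesIds"))
#' @rdname spdca-accessors
#' @export
setGeneric("alnLength", function(x) standardGeneric("alnLength"))
#' @rdname spdca-accessors
#' @export
setGeneric("nSequences", function(x) standardGeneric("nSequences"))
#' @rdname spdca-accessors
#' @export
setGeneric("lenA", function(x) standardGeneric("lenA"))
#' @rdname spdca-accessors
#' @export
setGeneric("lenB", function(x) standardGeneric("lenB"))
#' @rdname spdca-accessors
#' @export
setGeneric("mEff", function(x) standardGeneric("mEff"))
#' @rdname spdca-accessors
#' @export
setGeneric("scoreMatrix", function(x) standardGeneric("scoreMatrix"))
#' @rdname spdca-accessors
#' @export
setGeneric("qMatrix", function(x) standardGeneric("qMatrix"))
#' @rdname spdca-accessors
#' @export
setGeneric("domainSegments", function(x) standardGeneric("domainSegments"))
#' @rdname spdca-accessors
#' @export
setGeneric("maskWeights", function(x) standardGeneric("maskWeights"))
#' @rdname spdca-accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname spdca-accessors
#' @export
setGeneric("contactMatrix", function(x) standardGeneric("contactMatrix"))
#' @rdname spdca-accessors
#' @export
setGeneric("plantedPairs", function(x) standardGeneric("plantedPairs"))

setMethod("alnMatrix", "Alignment", function(x) x@seqs)
setMethod("alnMatrix", "PairedAlignment", function(x) x@seqs)
setMethod("speciesIds", "Alignment", function(x) x@species)
setMethod("speciesIds", "PairedAlignment", function(x) x@species)
setMethod("alnLength", "Alignment", function(x) ncol(x@seqs))
setMethod("alnLength", "PairedAlignment", function(x) ncol(x@seqs))
setMethod("nSequences", "Alignment", function(x) nrow(x@seqs))
setMethod("nSequences", "PairedAlignment", function(x) nrow(x@seqs))
setMethod("lenA", "PairedAlignment", function(x) x@lenA)
setMethod("lenB", "PairedAlignment", function(x) x@lenB)
setMethod("lenA", "CouplingMatrix", function(x) x@lenA)
setMethod("lenB", "CouplingMatrix", function(x) x@lenB)
setMethod("mEff", "SequenceWeights", function(x) x@mEff)

#' @rdname spdca-accessors
#' @param object a \linkS4class{SequenceWeights} object.
#' @param ... ignored.
#' @importFrom stats weights
#' @export
setMethod("weights", "SequenceWeights", function(object, ...) object@weights)
setMethod("scoreMatrix", "CouplingMatrix", function(x) x@scores)
setMethod("qMatrix", "ConvolvedMap", function(x) x@qmap)
setMethod("domainSegments", "DomainMap", function(x) x@segments)
setMethod("maskWeights", "PriorMask", function(x) x@weights)
setMethod("atomTable", "StructureFrame", function(x) x@atoms)
setMethod("contactMatrix", "ContactMap", function(x) x@contacts)
setMethod("plantedPairs", "PlantedTruth", function(x) x@pairs)

# ---- show methods -----------------------------------------------------------

setMethod("show", "Alignment", function(object) {
  cat("Alignment '", object@name, "': ", nrow(object@seqs), " sequences x ",
      ncol(object@seqs), " columns", sep = "")
  if (object@nUnknown > 0L)
    cat(" (", object@nUnknown, " unknown symbols mapped to gap)", sep = "")
  cat("\n")
})

setMethod("show", "PairedAlignment", function(object) {
  cat("PairedAlignment ", object@nameA, "/", object@nameB, ": ",
      nrow(object@seqs), " species x (", object@lenA, " + ", object@lenB,
      ") columns\n", sep = "")
})

setMethod("show", "SequenceWeights", function(object) {
  cat("SequenceWeights: ", length(object@weights), " rows, theta = ",
      object@theta, ", Meff = ", signif(object@mEff, 5), "\n", sep = "")
})

setMethod("show", "PottsModel", function(object) {
  cat("PottsModel: L = ", nrow(object@fields), ", q = ", object@q,
      ", gauge = ", if (is.null(object@meta$gauge)) "raw" else object@meta$gauge,
      "\n", sep = "")
})

setMethod("show", "CouplingMatrix", function(object) {
  cat("CouplingMatrix: ", nrow(object@scores), " x ", ncol(object@scores),
      if (object@apcApplied) " (APC-corrected)" else " (raw)",
      ", inter-protein block ", object@lenA, " x ", object@lenB, "\n",
      sep = "")
})

setMethod("show", "DomainMap", function(object) {
  cat("DomainMap '", object@protein, "' (length ", object@length, "):\n",
      sep = "")
  print(object@segments, row.names = FALSE)
})

setMethod("show", "PriorMask", function(object) {
  cat("PriorMask over ", length(object@weights), " columns (",
      sum(object@weights > 0), " nonzero); rule: ", object@provenance, "\n",
      sep = "")
})

setMethod("show", "PriorParams", function(object) {
  cat("PriorParams: a = ", object@a, ", b = ", object@b, ", l = ",
      object@l, "\n", sep = "")
})

setMethod("show", "ConvolvedMap", function(object) {
  cat("ConvolvedMap: ", nrow(object@qmap), " x ", ncol(object@qmap),
      " (a = ", object@params@a, ", b = ", object@params@b, ", l = ",
      object@params@l, ")\n", sep = "")
})

setMethod("show", "StructureFrame", function(object) {
  cat("StructureFrame: ", nrow(object@atoms), " atoms (",
      sum(object@atoms$heavy), " heavy), chains ",
      paste(unique(object@atoms$chain), collapse = " "), "\n", sep = "")
})

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap ", object@chainA, " x ", object@chainB, ": ",
      sum(object@contacts), " contacts of ", length(object@contacts),
      " residue pairs (< ", object@cutoff, " A, >= ", object@minAtomPairs,
      " atom pairs)\n", sep = "")
})

setMethod("show", "PlantedTruth", function(object) {
  cat("PlantedTruth: ", nrow(object@pairs), " planted pairs, strength ",
      object@strength, ", seed ", object@seed, "\n", sep = "")
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: a = ", object@a, ", b = ", object@b, ", l = ", object@l,
      "; theta = ", object@theta, "; identity filter [", object@minId, ", ",
      object@maxId, "]; contact rule < ", object@cutoff, " A, >= ",
      object@minAtomPairs, " atom pairs; seed ", object@seed, "\n", sep = "")
})
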