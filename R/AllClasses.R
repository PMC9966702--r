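#' @import methods
#' @importFrom stats optim quantile rnorm runif sd setNames
#' @importFrom utils read.table write.table packageVersion
#' @useDynLib spdca, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Residue alphabet used throughout the package
#'
#' Twenty amino acids in one-letter code followed by the gap symbol.  The gap
#' is a full Potts state during model fitting but is excluded from coupling
#' scores.
#'
#' @return Character vector of 21 symbols.
#' @export
#' @examples
#' spdcaAlphabet()
spdcaAlphabet <- function() c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "-")

# ---- alignment containers ---------------------------------------------------

#' Alignment: a species-labelled multiple sequence alignment
#'
#' Holds an aligned block of residue symbols (rows = sequences, columns =
#' alignment positions) over the 21-state alphabet (20 amino acids + gap),
#' one species label per row.  Unknown symbols are mapped to the gap at
#' construction time and counted in \code{nUnknown}.
#'
#' @slot seqs character matrix of residue symbols.
#' @slot species one species id per row.
#' @slot name protein identifier.
#' @slot nUnknown number of symbols coerced to gap on input.
#' @export
setClass("Alignment",
  representation(seqs = "matrix", species = "character",
                 name = "character", nUnknown = "integer"))

setValidity("Alignment", function(object) {
  msg <- character()
  if (!is.character(object@seqs)) msg <- c(msg, "seqs must be a character matrix")
  if (nrow(object@seqs) != length(object@species))
    msg <- c(msg, "one species id is required per row")
  bad <- setdiff(unique(as.vector(object@seqs)), spdcaAlphabet())
  if (length(bad))
    msg <- c(msg, paste0("symbols outside the alphabet: ",
                         paste(bad, collapse = " ")))
  if (length(msg)) msg else TRUE
})

#' PairedAlignment: a species-concatenated alignment of two proteins
#'
#' Each row is the protein-A row of one species followed by its protein-B row
#' (the concatenated MSA, cMSA).  \code{lenA} and \code{lenB} record the two
#' column blocks.
#'
#' @slot seqs character matrix, \code{lenA + lenB} columns.
#' @slot species unique species ids.
#' @slot lenA,lenB column counts of the two blocks.
#' @slot nameA,nameB protein identifiers.
#' @slot nDropped species present in only one input alignment.
#' @export
setClass("PairedAlignment",
  representation(seqs = "matrix", species = "character",
                 lenA = "integer", lenB = "integer",
                 nameA = "character", nameB = "character",
                 nDropped = "integer"))

setValidity("PairedAlignment", function(object) {
  msg <- character()
  if (ncol(object@seqs) != object@lenA + object@lenB)
    msg <- c(msg, "row length must equal lenA + lenB")
  if (anyDuplicated(object@species))
    msg <- c(msg, "species ids must be unique")
  if (nrow(object@seqs) != length(object@species))
    msg <- c(msg, "one species id is required per row")
  if (length(msg)) msg else TRUE
})

# ---- coupling inference -----------------------------------------------------

#' SequenceWeights: identity-based sequence reweighting
#'
#' Weight of a row is one over the number of rows within fractional identity
#' \code{theta} of it (itself included); \code{mEff} is the effective number
#' of sequences (sum of weights).
#'
#' @slot weights one positive weight per alignment row.
#' @slot theta identity threshold used.
#' @slot mEff sum of weights.
#' @export
setClass("SequenceWeights",
  representation(weights = "numeric", theta = "numeric", mEff = "numeric"))

setValidity("SequenceWeights", function(object) {
  if (any(object@weights <= 0 | object@weights > 1))
    return("weights must lie in (0, 1]")
  if (object@mEff > length(object@weights) + 1e-8)
    return("mEff cannot exceed the number of rows")
  TRUE
})

#' PottsModel: fields and pairwise couplings over a residue alphabet
#'
#' Parameters of a q-state Potts model on L sites.  Couplings are stored as a
#' \code{q x q x L x L} array with \code{J[s, t, i, j] = J[t, s, j, i]} after
#' symmetrisation, and are in the zero-sum gauge when \code{meta$gauge} is
#' \code{"zero-sum"}.
#'
#' @slot q alphabet size.
#' @slot alphabet state symbols, length q.
#' @slot fields L x q matrix of single-site biases.
#' @slot couplings q x q x L x L array.
#' @slot regFields,regCouplings L2 regularisation strengths used in fitting.
#' @slot meta fit record (optimizer diagnostics, gauge, block lengths).
#' @export
setClass("PottsModel",
  representation(q = "integer", alphabet = "character", fields = "matrix",
                 couplings = "array", regFields = "numeric",
                 regCouplings = "numeric", meta = "list"))

setValidity("PottsModel", function(object) {
  d <- dim(object@couplings)
  L <- nrow(object@fields)
  if (length(d) != 4 || d[1] != object@q || d[2] != object@q ||
      d[3] != L || d[4] != L)
    return("couplings must be a q x q x L x L array")
  if (ncol(object@fields) != object@q)
    return("fields must have q columns")
  if (length(object@alphabet) != object@q)
    return("alphabet must have q symbols")
  TRUE
})

#' CouplingMatrix: summarised residue-residue coupling scores
#'
#' Symmetric nonnegative L x L matrix of Frobenius-norm coupling scores, with
#' or without the average product correction (APC).  The \code{lenA} x
#' \code{lenB} inter-protein block (rows = protein A columns, columns =
#' protein B columns) is the evolutionary score matrix consumed by the
#' structure-prior convolution.
#'
#' @slot scores L x L score matrix (APC-corrected if \code{apcApplied}).
#' @slot raw uncorrected Frobenius-norm scores.
#' @slot apcApplied logical flag.
#' @slot lenA,lenB block lengths of the paired alignment.
#' @export
setClass("CouplingMatrix",
  representation(scores = "matrix", raw = "matrix", apcApplied = "logical",
                 lenA = "integer", lenB = "integer"))

setValidity("CouplingMatrix", function(object) {
  S <- object@scores
  if (nrow(S) != ncol(S)) return("scores must be square")
  if (max(abs(S - t(S))) > 1e-8) return("scores must be symmetric")
  if (any(abs(diag(S)) > 1e-12)) return("diagonal must be zero")
  if (object@lenA + object@lenB != nrow(S))
    return("lenA + lenB must equal the matrix dimension")
  TRUE
})

# ---- structure prior and convolution ---------------------------------------

#' DomainMap: topology/secondary-structure annotation of one protein
#'
#' Non-overlapping 1-based inclusive segments in the UniProt topology style
#' (N-terminal, TM helices, intra/extracellular loops, C-terminal); positions
#' not covered by any annotated segment are auto-filled with category
#' \code{"other"}.
#'
#' @slot protein protein name.
#' @slot length protein length (columns).
#' @slot segments data.frame with columns label, category, start, end.
#' @export
setClass("DomainMap",
  representation(protein = "character", length = "integer",
                 segments = "data.frame"))

domainCategories <- function()
  c("N-terminal", "C-terminal", "TM", "ICL", "ECL", "other")

setValidity("DomainMap", function(object) {
  s <- object@segments
  need <- c("label", "category", "start", "end")
  if (!all(need %in% names(s))) return("segments need label/category/start/end")
  if (any(s$start > s$end)) return("segment end before start")
  if (any(s$start < 1L) || any(s$end > object@length))
    return("segments outside 1..length")
  if (!all(s$category %in% domainCategories()))
    return("unknown segment category")
  o <- order(s$start)
  if (nrow(s) > 1 && any(s$start[o][-1] <= s$end[o][-nrow(s)]))
    return("overlapping segments")
  TRUE
})

#' PriorMask: per-column structure-prior weights
#'
#' @slot weights numeric in [0, 1], one per protein column.
#' @slot provenance rule used to build the mask.
#' @export
setClass("PriorMask",
  representation(weights = "numeric", provenance = "character"))

setValidity("PriorMask", function(object) {
  if (any(object@weights < 0 | object@weights > 1))
    return("mask weights must lie in [0, 1]")
  TRUE
})

#' PriorParams: Gaussian-kernel parameters of the interface convolution
#'
#' \code{a} and \code{b} are the normalised variances of the kernel along the
#' two proteins and \code{l} the half-window (the average length of the
#' peptides involved in the interaction, in residues).
#'
#' @slot a,b nonnegative normalised variances.
#' @slot l nonnegative integer half-window.
#' @export
setClass("PriorParams",
  representation(a = "numeric", b = "numeric", l = "integer"))

setValidity("PriorParams", function(object) {
  if (object@a < 0 || object@b < 0) return("a and b must be nonnegative")
  if (object@l < 0L) return("l must be a nonnegative integer")
  TRUE
})

#' ConvolvedMap: the structure-prior convolved coupling map Q
#'
#' @slot qmap lenA x lenB matrix of convolved scores.
#' @slot params the \linkS4class{PriorParams} used.
#' @slot masks provenance of the column masks applied to P.
#' @export
setClass("ConvolvedMap",
  representation(qmap = "matrix", params = "PriorParams", masks = "character"))

# ---- structures and trajectories -------------------------------------------

#' StructureFrame: residue-indexed heavy-atom coordinates of one frame
#'
#' @slot atoms data.frame with columns chain, resno, resid, elety, x, y, z,
#'   heavy (logical; hydrogens are FALSE).
#' @slot nExcluded HETATM/water records excluded at read time.
#' @export
setClass("StructureFrame",
  representation(atoms = "data.frame", nExcluded = "integer"))

setValidity("StructureFrame", function(object) {
  a <- object@atoms
  need <- c("chain", "resno", "resid", "elety", "x", "y", "z", "heavy")
  if (!all(need %in% names(a))) return("atoms lack required columns")
  if (!all(is.finite(a$x) & is.finite(a$y) & is.finite(a$z)))
    return("coordinates must be finite")
  TRUE
})

#' ContactMap: boolean residue-residue contacts between two chains
#'
#' A residue pair is in contact when at least \code{minAtomPairs} heavy-atom
#' pairs (one atom from each residue) lie strictly closer than \code{cutoff}.
#'
#' @slot contacts logical matrix (chain A residues x chain B residues).
#' @slot counts number of qualifying heavy-atom pairs per residue pair.
#' @slot chainA,chainB chain identifiers.
#' @slot cutoff distance cutoff in Angstrom (default 5.0).
#' @slot minAtomPairs minimum qualifying atom pairs (default 2).
#' @export
setClass("ContactMap",
  representation(contacts = "matrix", counts = "matrix",
                 chainA = "character", chainB = "character",
                 cutoff = "numeric", minAtomPairs = "integer"))

#' ElectrostaticParams: Debye-Hueckel energy parameters
#'
#' \code{kElec} is the Coulomb constant 332.24 kcal mol^-1 e^-2 Angstrom;
#' \code{epsR} the relative dielectric of the medium; \code{lD} the Debye
#' screening length in Angstrom (give directly or derive with
#' \code{\link{debyeLength}}); \code{charges} maps three-letter residue names
#' to bead charges in elementary units.
#'
#' @slot kElec Coulomb constant, kcal mol^-1 e^-2 Angstrom.
#' @slot epsR relative dielectric (> 0).
#' @slot lD Debye screening length in Angstrom (> 0).
#' @slot charges named numeric, charge per residue type.
#' @export
setClass("ElectrostaticParams",
  representation(kElec = "numeric", epsR = "numeric", lD = "numeric",
                 charges = "numeric"))

setValidity("ElectrostaticParams", function(object) {
  if (object@epsR <= 0) return("epsR must be positive")
  if (object@lD <= 0) return("lD must be positive")
  TRUE
})

# ---- synthetic data ---------------------------------------------------------

#' PlantedTruth: ground truth of a synthetic paired-alignment model
#'
#' @slot pairs integer matrix with columns colA, colB of planted
#'   inter-protein couplings (colB in protein-B coordinates).
#' @slot strength planted coupling magnitude.
#' @slot seed RNG seed used to draw the model.
#' @slot lenA,lenB,q model dimensions.
#' @export
setClass("PlantedTruth",
  representation(pairs = "matrix", strength = "numeric", seed = "integer",
                 lenA = "integer", lenB = "integer", q = "integer"))

setValidity("PlantedTruth", function(object) {
  p <- object@pairs
  if (ncol(p) != 2) return("pairs must have two columns")
  if (anyDuplicated(p)) return("planted pairs must be unique")
  if (nrow(p) && (any(p[, 1] < 1 | p[, 1] > object@lenA) ||
                  any(p[, 2] < 1 | p[, 2] > object@lenB)))
    return("planted pairs outside the column bounds")
  TRUE
})

# ---- pipeline configuration -------------------------------------------------

#' RunConfig: reproducible configuration of a full interface-prediction run
#'
#' Defaults reproduce the method's published settings: kernel variances
#' a = b = 0.001 with half-window l = 21 residues, the 70--90\% ortholog
#' identity filter, and the residue-contact rule (cutoff 5.0 Angstrom, at
#' least 2 heavy-atom pairs).  Build with \code{\link{spdcaConfig}} or
#' \code{\link{readConfig}}.
#'
#' @slot inputs named character vector of file paths (msa_a, msa_b, ref_a,
#'   ref_b, topo_a, topo_b; NA where unused).
#' @slot minId,maxId ortholog identity filter bounds.
#' @slot theta sequence-reweighting identity threshold.
#' @slot regFields,regCouplings plmDCA L2 regularisation (NA regCouplings
#'   means 0.01 * (L - 1), resolved at fit time).
#' @slot apc apply the average product correction.
#' @slot a,b,l Gaussian prior parameters.
#' @slot includeCategories topology categories kept by the prior mask.
#' @slot topFraction,minSeparation hot-spot extraction parameters.
#' @slot window physicochemical profile window (odd).
#' @slot cutoff,minAtomPairs residue-contact rule.
#' @slot seed RNG seed for all stochastic steps of a run.
#' @export
setClass("RunConfig",
  representation(inputs = "character", minId = "numeric", maxId = "numeric",
                 theta = "numeric", regFields = "numeric",
                 regCouplings = "numeric", apc = "logical",
                 a = "numeric", b = "numeric", l = "integer",
                 includeCategories = "character",
                 topFraction = "numeric", minSeparation = "integer",
                 window = "integer", cutoff = "numeric",
                 minAtomPairs = "integer", seed = "integer"))
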