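# One-command orchestration: pair -> couple -> map -> hotspots -> profile,
# with a flat key=value configuration and a reproducibility manifest.

#' Build a run configuration
#'
#' Defaults reproduce the method's published settings: Gaussian prior
#' a = b = 0.001 with half-window l = 21, the 70--90\% ortholog identity
#' filter, reweighting threshold theta = 0.8, and the residue-contact rule
#' (< 5.0 Angstrom, >= 2 heavy-atom pairs).
#'
#' @param msa_a,msa_b,ref_a,ref_b,topo_a,topo_b input file paths (refs and
#'   topologies optional, NA when absent).
#' @param minId,maxId ortholog identity bounds (default 0.7, 0.9).
#' @param theta reweighting identity threshold (default 0.8).
#' @param regFields plmDCA field penalty (default 0.01).
#' @param regCouplings coupling penalty; NA means 0.01 * (L - 1) at fit
#'   time.
#' @param apc apply the average product correction (default TRUE).
#' @param a,b,l Gaussian prior parameters (defaults 0.001, 0.001, 21).
#' @param includeCategories prior-mask categories (default non-TM).
#' @param topFraction,minSeparation hot-spot extraction (defaults 0.01,
#'   10).
#' @param window property-profile window (default 9).
#' @param cutoff,minAtomPairs contact rule (defaults 5.0, 2).
#' @param seed run seed (default 1).
#' @return A \linkS4class{RunConfig}.
#' @export
#' @examples
#' spdcaConfig()
spdcaConfig <- function(msa_a = NA, msa_b = NA, ref_a = NA, ref_b = NA,
                        topo_a = NA, topo_b = NA,
                        minId = 0.7, maxId = 0.9, theta = 0.8,
                        regFields = 0.01, regCouplings = NA_real_,
                        apc = TRUE, a = 0.001, b = 0.001, l = 21L,
                        includeCategories = c("N-terminal", "C-terminal",
                                              "ICL", "ECL"),
                        topFraction = 0.01, minSeparation = 10L,
                        window = 9L, cutoff = 5.0, minAtomPairs = 2L,
                        seed = 1L) {
  new("RunConfig",
      inputs = c(msa_a = as.character(msa_a), msa_b = as.character(msa_b),
                 ref_a = as.character(ref_a), ref_b = as.character(ref_b),
                 topo_a = as.character(topo_a),
                 topo_b = as.character(topo_b)),
      minId = minId, maxId = maxId, theta = theta,
      regFields = regFields, regCouplings = as.numeric(regCouplings),
      apc = apc, a = a, b = b, l = as.integer(l),
      includeCategories = includeCategories,
      topFraction = topFraction, minSeparation = as.integer(minSeparation),
      window = as.integer(window), cutoff = cutoff,
      minAtomPairs = as.integer(minAtomPairs), seed = as.integer(seed))
}

#' Read a flat key=value configuration file
#'
#' Lines of the form \code{key = value} (\code{#} comments allowed); keys
#' are the arguments of \code{\link{spdcaConfig}};
#' \code{includeCategories} is comma-separated.
#'
#' @param path configuration file path.
#' @return A \linkS4class{RunConfig}.
#' @export
readConfig <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines)]
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  args <- as.list(vals)
  names(args) <- keys
  numKeys <- c("minId", "maxId", "theta", "regFields", "regCouplings",
               "a", "b", "topFraction", "cutoff")
  intKeys <- c("l", "minSeparation", "window", "minAtomPairs", "seed")
  for (k in intersect(names(args), numKeys)) args[[k]] <- as.numeric(args[[k]])
  for (k in intersect(names(args), intKeys)) args[[k]] <- as.integer(args[[k]])
  if ("apc" %in% names(args)) args$apc <- toupper(args$apc) %in%
      c("TRUE", "T", "1", "YES")
  if ("includeCategories" %in% names(args))
    args$includeCategories <- trimws(strsplit(args$includeCategories,
                                              ",")[[1]])
  do.call(spdcaConfig, args)
}

cfgInput <- function(cfg, key) {
  v <- cfg@inputs[[key]]
  if (is.na(v) || v == "" || v == "NA") NULL else v
}

#' Run the full interface-prediction workflow
#'
#' Executes pair (read, filter, best isoform, concatenate), couple
#' (reweight, plmDCA, scores), map (structure-prior convolution), hotspots
#' (extraction and domain labelling) and profile (property contrasts at
#' the predicted interface), writing every intermediate, a machine-readable
#' manifest (package version, parameters, output hashes) and a
#' human-readable summary (complex, cMSA depth, predicted interactions) to
#' \code{outDir}.  A single seeded RNG stream drives all stochastic steps,
#' so reruns with the same configuration are byte-identical.
#'
#' @param cfg a \linkS4class{RunConfig}; \code{msa_a} and \code{msa_b} are
#'   required.
#' @param outDir output directory (created if missing).
#' @return \code{outDir}, invisibly; see files pair.fasta, scores.tsv,
#'   qmap.csv, hotspots.tsv, profile_contrasts.tsv, summary.tsv,
#'   manifest.json.
#' @export
runPipeline <- function(cfg, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg@seed)
  stage <- function(name, expr)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))

  # -- pair -------------------------------------------------------------
  pa <- stage("pair", {
    alnA <- readAlignment(cfgInput(cfg, "msa_a") %||%
                            stop("msa_a is required"), name = "A")
    alnB <- readAlignment(cfgInput(cfg, "msa_b") %||%
                            stop("msa_b is required"), name = "B")
    refA <- cfgInput(cfg, "ref_a")
    refB <- cfgInput(cfg, "ref_b")
    if (!is.null(refA)) {
      ref <- alnMatrix(readAlignment(refA))[1, ]
      alnA <- selectBestIsoform(alnA, ref)
      alnA <- filterBySimilarity(alnA, ref, cfg@minId, cfg@maxId)
    }
    if (!is.null(refB)) {
      ref <- alnMatrix(readAlignment(refB))[1, ]
      alnB <- selectBestIsoform(alnB, ref)
      alnB <- filterBySimilarity(alnB, ref, cfg@minId, cfg@maxId)
    }
    pa <- concatenateBySpecies(alnA, alnB)
    writeAlignment(pa, file.path(outDir, "pair.fasta"))
    pa
  })

  # -- couple -----------------------------------------------------------
  cm <- stage("couple", {
    w <- sequenceWeights(pa, cfg@theta)
    reg <- if (is.na(cfg@regCouplings)) NULL else cfg@regCouplings
    model <- fitPlm(pa, w, regFields = cfg@regFields, regCouplings = reg)
    cm <- couplingScores(model, apc = cfg@apc)
    writeScores(cm, alnMatrix(pa)[1, ], file.path(outDir, "scores.tsv"))
    cm
  })

  # -- map --------------------------------------------------------------
  topoA <- cfgInput(cfg, "topo_a")
  topoB <- cfgInput(cfg, "topo_b")
  dmA <- if (!is.null(topoA))
    parseTopology(topoA, protein = "A", protLength = lenA(cm)) else NULL
  dmB <- if (!is.null(topoB))
    parseTopology(topoB, protein = "B", protLength = lenB(cm)) else NULL
  conv <- stage("map", {
    P <- interProteinBlock(cm)
    mA <- if (is.null(dmA)) NULL else
      buildPriorMask(dmA, cfg@includeCategories)
    mB <- if (is.null(dmB)) NULL else
      buildPriorMask(dmB, cfg@includeCategories)
    conv <- convolveCouplings(P, priorParams(cfg@a, cfg@b, cfg@l), mA, mB)
    writeQMap(conv, file.path(outDir, "qmap.csv"))
    conv
  })

  # -- hotspots ---------------------------------------------------------
  rects <- stage("hotspots", {
    rects <- extractHotspots(conv, cfg@topFraction, cfg@minSeparation)
    if (!is.null(dmA) && !is.null(dmB) && nrow(rects) > 0)
      rects <- labelHotspots(rects, dmA, dmB)
    writeHotspots(rects, file.path(outDir, "hotspots.tsv"))
    rects
  })

  # -- profile ----------------------------------------------------------
  stage("profile", {
    if (nrow(rects) > 0) {
      seqA <- alnMatrix(pa)[1, seq_len(lenA(pa))]
      scales <- propertyScales()
      contrasts <- do.call(rbind, lapply(names(scales), function(nm) {
        prof <- propertyProfile(seqA, scales[[nm]], cfg@window)
        cbind(scale = nm,
              interfaceContrast(prof, rects, axis = "A",
                                nPerm = 1000L, seed = cfg@seed))
      }))
      write.table(contrasts, file.path(outDir, "profile_contrasts.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    NULL
  })

  # -- summary and manifest ---------------------------------------------
  interactions <- if (nrow(rects) > 0 && "interaction" %in% names(rects))
    paste(unique(rects$interaction), collapse = "; ") else
      if (nrow(rects) > 0) paste(nrow(rects), "unlabelled rectangle(s)") else
        "none"
  summary <- data.frame(complex = paste0(pa@nameA, "/", pa@nameB),
                        cmsa_depth = nSequences(pa),
                        predicted_interactions = interactions)
  write.table(summary, file.path(outDir, "summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  outputs <- list.files(outDir, full.names = TRUE)
  outputs <- outputs[!basename(outputs) %in% "manifest.json"]
  manifest <- list(
    package = "spdca",
    version = as.character(packageVersion("spdca")),
    parameters = list(minId = cfg@minId, maxId = cfg@maxId,
                      theta = cfg@theta, regFields = cfg@regFields,
                      regCouplings = cfg@regCouplings, apc = cfg@apc,
                      a = cfg@a, b = cfg@b, l = cfg@l,
                      includeCategories = cfg@includeCategories,
                      topFraction = cfg@topFraction,
                      minSeparation = cfg@minSeparation,
                      window = cfg@window, seed = cfg@seed),
    inputs = as.list(cfg@inputs),
    outputs = as.list(setNames(unname(tools::md5sum(outputs)),
                               basename(outputs))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outDir)
}

#' Write coupling scores as a TSV
#'
#' Long format with 1-based indices: i, j, residue_a, residue_b,
#' raw_score, apc_score (upper triangle).
#'
#' @param cm a \linkS4class{CouplingMatrix}.
#' @param refRow representative sequence used for the residue columns.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeScores <- function(cm, refRow, path) {
  L <- nrow(scoreMatrix(cm))
  ut <- which(upper.tri(matrix(0, L, L)), arr.ind = TRUE)
  d <- data.frame(i = ut[, 1], j = ut[, 2],
                  residue_a = refRow[ut[, 1]], residue_b = refRow[ut[, 2]],
                  raw_score = cm@raw[ut],
                  apc_score = scoreMatrix(cm)[ut])
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
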