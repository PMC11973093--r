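## Batch construction of a reversed-template database from a directory of
## peptide-MHC class II PDB files.

#' Reversed-template identifier
#'
#' @param pdbId four-character PDB identifier.
#' @return the template id `<PDBID>_reversed` (upper-cased), e.g.
#'   `3WEX_reversed`.
#' @export
templateId <- function(pdbId) {
  id <- toupper(pdbId)
  if (!grepl("^[0-9][A-Za-z0-9]{3}$", id))
    .stopf("'%s' is not a valid PDB identifier", pdbId)
  paste0(id, "_reversed")
}

#' Build a reversed-template database
#'
#' Reads every `*.pdb` file in `inputDir`, preprocesses it (hydrogens
#' stripped, selenomethionines substituted), reverses the peptide, runs
#' the automated geometry gate ([validateGeometry()]) and, for templates
#' that pass, writes `<PDBID>_reversed.pdb` plus a JSON sidecar with the
#' template metadata to `outputDir`.  Templates failing the gate are
#' quarantined (logged, not emitted); a failure in one file never aborts
#' the batch.
#'
#' Anchor positions are not stored in PDB files, so they come from
#' `anchorsTable`: a named list (PDB ID to integer anchor positions) or a
#' YAML file mapping ids to positions, optionally with per-id `alleles`
#' and `peptide_chain` entries, e.g.
#' `3WEX: {anchors: [2, 5, 7, 10], alleles: ["DPA1*02:02/DPB1*05:01"]}`.
#'
#' @param inputDir directory of input PDB files.
#' @param outputDir output directory (created if needed).
#' @param anchorsTable named list or YAML path (see Details).
#' @param config a [RegularizerConfig-class] for the regularization stage.
#' @param bondTol,omegaTol geometry-gate tolerances.
#' @return list of [TemplateRecord-class] for the successful inputs, with
#'   attribute `failures` (data.frame file/stage/reason).
#' @export
buildReversedDB <- function(inputDir, outputDir, anchorsTable = list(),
                            config = regularizerConfig(),
                            bondTol = 0.1, omegaTol = 30) {
  files <- sort(list.files(inputDir, pattern = "\\.pdb$", full.names = TRUE,
                           ignore.case = TRUE))
  if (!length(files))
    .stopf("no PDB files found in '%s'", inputDir)
  if (is.character(anchorsTable) && length(anchorsTable) == 1L)
    anchorsTable <- yaml::read_yaml(anchorsTable)
  dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
  records <- list()
  failures <- list()
  fail <- function(f, stage, reason)
    failures[[length(failures) + 1L]] <<- data.frame(
      file = basename(f), stage = stage, reason = reason)
  for (f in files) {
    id <- toupper(tools::file_path_sans_ext(basename(f)))
    meta <- anchorsTable[[id]]
    if (is.null(meta)) meta <- anchorsTable[[tolower(id)]]
    anch <- if (is.list(meta)) meta$anchors else meta
    alleles <- if (is.list(meta) && !is.null(meta$alleles))
      as.character(meta$alleles) else character()
    pepChain <- if (is.list(meta)) meta$peptide_chain else NULL
    cx <- tryCatch(
      readPDB(f, peptideChain = pepChain,
              anchors = if (is.null(anch)) integer() else as.integer(anch)),
      error = function(e) { fail(f, "read", conditionMessage(e)); NULL })
    if (is.null(cx)) next
    rev <- tryCatch({
      cx <- substituteMSE(stripHydrogens(cx))
      suppressMessages(reversePeptide(cx, config = config))
    }, error = function(e) { fail(f, "reverse", conditionMessage(e)); NULL })
    if (is.null(rev)) next
    qc <- validateGeometry(rev$complex, bondTol = bondTol,
                           omegaTol = omegaTol)
    if (sum(qc@violations) > 0L) {
      fail(f, "qc", sprintf(
        "quarantined: %d chirality / %d bond / %d omega violation(s)",
        qc@violations[["chirality"]], qc@violations[["bond"]],
        qc@violations[["omega"]]))
      next
    }
    tid <- templateId(id)
    outPdb <- file.path(outputDir, paste0(tid, ".pdb"))
    writePDB(rev$complex, outPdb)
    rec <- new("TemplateRecord", templateId = tid, alleles = alleles,
               peptideSequence = pepSequence(rev$complex),
               anchors = anchors(rev$complex), path = outPdb)
    sidecar <- file.path(outputDir, paste0(tid, ".json"))
    jsonlite::write_json(list(
      template_id = tid, source_pdb = id, alleles = alleles,
      peptide_sequence = rec@peptideSequence,
      anchors = rec@anchors,
      chirality_fixed = rev$report@chiralityFixed,
      prolines_rebuilt = rev$report@prolinesRebuilt,
      regularization_backbone_rmsd = rev$report@regularizationRMSD),
      sidecar, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    records[[tid]] <- rec
  }
  failures <- if (length(failures)) do.call(rbind, failures) else
    data.frame(file = character(), stage = character(), reason = character())
  if (nrow(failures))
    message(sprintf("buildReversedDB: %d of %d input(s) failed (%s)",
                    nrow(failures), length(files),
                    paste(unique(failures$stage), collapse = ", ")))
  attr(records, "failures") <- failures
  records
}
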