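#' @include AllClasses.R
NULL

#' Accessors for structure objects
#'
#' `peptide()` returns the bound peptide chain of a complex, `receptor()`
#' its receptor atom table, `anchors()` the annotated anchor positions,
#' `sourceId()` the provenance label, `atoms()` the flat atom table of a
#' chain, `pepSequence()` the one-letter sequence in stored reading order
#' and `pepLength()` the residue count.
#'
#' @param x a [PMHCComplex-class] or [PeptideChain-class].
#' @return the corresponding slot value (see Details).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("peptide", function(x) standardGeneric("peptide"))
#' @rdname accessors
#' @export
setGeneric("receptor", function(x) standardGeneric("receptor"))
#' @rdname accessors
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))
#' @rdname accessors
#' @export
setGeneric("sourceId", function(x) standardGeneric("sourceId"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("pepSequence", function(x) standardGeneric("pepSequence"))
#' @rdname accessors
#' @export
setGeneric("pepLength", function(x) standardGeneric("pepLength"))

#' @rdname accessors
setMethod("peptide", "PMHCComplex", function(x) x@peptide)
#' @rdname accessors
setMethod("receptor", "PMHCComplex", function(x) x@receptor)
#' @rdname accessors
setMethod("anchors", "PMHCComplex", function(x) x@anchors)
#' @rdname accessors
setMethod("sourceId", "PMHCComplex", function(x) x@sourceId)
#' @rdname accessors
setMethod("atoms", "PeptideChain", function(x) x@atoms)
#' @rdname accessors
setMethod("atoms", "PMHCComplex",
          function(x) rbind(x@receptor, x@peptide@atoms))
#' @rdname accessors
setMethod("pepSequence", "PeptideChain",
          function(x) .chainSequence(x@atoms))
#' @rdname accessors
setMethod("pepSequence", "PMHCComplex",
          function(x) .chainSequence(x@peptide@atoms))
#' @rdname accessors
setMethod("pepLength", "PeptideChain",
          function(x) length(.resOrder(x@atoms)))
#' @rdname accessors
setMethod("pepLength", "PMHCComplex", function(x) pepLength(x@peptide))

setMethod("show", "PeptideChain", function(object) {
  cat(sprintf("PeptideChain '%s': %d residues, %d atoms\n  %s\n",
              object@chainId, pepLength(object), nrow(object@atoms),
              pepSequence(object)))
})

setMethod("show", "PMHCComplex", function(object) {
  rc <- unique(object@receptor$chain)
  cat(sprintf("PMHCComplex '%s'\n", object@sourceId))
  cat(sprintf("  receptor: %d chain(s) [%s], %d atoms\n",
              length(rc), paste(rc, collapse = ","), nrow(object@receptor)))
  cat(sprintf("  peptide : chain '%s', %d residues (%s)\n",
              object@peptide@chainId, pepLength(object),
              pepSequence(object)))
  cat(sprintf("  anchors : %s\n",
              if (length(object@anchors))
                paste(object@anchors, collapse = ", ") else "<none>"))
})

setMethod("show", "ReversalReport", function(object) {
  cat("ReversalReport\n")
  for (s in names(object@stepDisplacements))
    cat(sprintf("  %-18s max displacement %.3f A\n", s,
                object@stepDisplacements[[s]]))
  cat(sprintf("  chirality fixed at: %s\n",
              if (length(object@chiralityFixed))
                paste(object@chiralityFixed, collapse = ", ") else "<none>"))
  cat(sprintf("  prolines rebuilt at: %s\n",
              if (length(object@prolinesRebuilt))
                paste(object@prolinesRebuilt, collapse = ", ") else "<none>"))
  cat(sprintf("  regularization backbone RMSD: %s A\n",
              ifelse(is.na(object@regularizationRMSD), "skipped",
                     sprintf("%.3f", object@regularizationRMSD))))
})

setMethod("show", "GeometryReport", function(object) {
  v <- object@violations
  cat(sprintf(
    "GeometryReport: %d chirality / %d bond / %d omega violation(s)\n",
    v[["chirality"]], v[["bond"]], v[["omega"]]))
  cat(sprintf("  tolerances: bond %.2f A, omega %.0f deg\n",
              object@tolerances[["bond"]], object@tolerances[["omega"]]))
})

setMethod("show", "TemplateRecord", function(object) {
  cat(sprintf("TemplateRecord %s\n  peptide %s, anchors %s\n  %s\n",
              object@templateId, object@peptideSequence,
              paste(object@anchors, collapse = ","), object@path))
})
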