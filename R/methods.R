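## Generics, accessors and show() methods for the S4 containers.
## Slots are never touched directly outside the package.

#' @name accessors
#' @title Accessors for RDReanalysis containers
#' @description Small, read-only accessors; user code should never reach into
#'   slots directly.
#' @param x a package container object
#' @param ... unused
NULL

#' @describeIn accessors number of variant records in a [VariantSet-class]
#' @export
setGeneric("nVariants", function(x) standardGeneric("nVariants"))
#' @export
setMethod("nVariants", "VariantSet", function(x) nrow(x@meta))

#' @describeIn accessors sample (experiment) identifiers
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @export
setMethod("sampleIds", "VariantSet", function(x) colnames(x@geno))

#' @describeIn accessors the variant annotation table (contig, pos, ref, alt,
#'   gene, consequence, filter)
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @export
setMethod("variantInfo", "VariantSet", function(x) x@meta)

#' @describeIn accessors "contig:pos:ref:alt" keys, one per record
#' @export
setGeneric("variantKeys", function(x) standardGeneric("variantKeys"))
#' @export
setMethod("variantKeys", "VariantSet", function(x) {
  with(x@meta, variantKey(contig, pos, ref, alt))
})

#' @describeIn accessors alt-allele dosage matrix (`NA` = uncalled)
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @export
setMethod("genotypes", "VariantSet", function(x) x@geno)

#' @describeIn accessors per-cell ploidy matrix
#' @export
setGeneric("ploidies", function(x) standardGeneric("ploidies"))
#' @export
setMethod("ploidies", "VariantSet", function(x) x@ploidy)

#' @describeIn accessors alt-read fraction matrix (`NA` = not available)
#' @export
setGeneric("allelicFractions", function(x) standardGeneric("allelicFractions"))
#' @export
setMethod("allelicFractions", "VariantSet", function(x) x@afrac)

#' Subset a VariantSet by record index
#' @param x a [VariantSet-class]
#' @param i record indices (logical or integer)
#' @param j,...,drop ignored
#' @export
setMethod("[", "VariantSet", function(x, i, j, ..., drop = FALSE) {
  initialize(x,
    meta = {
      m <- x@meta[i, , drop = FALSE]; rownames(m) <- NULL; m
    },
    geno = x@geno[i, , drop = FALSE],
    ploidy = x@ploidy[i, , drop = FALSE],
    afrac = x@afrac[i, , drop = FALSE]
  )
})

setMethod("show", "VariantSet", function(object) {
  cat(sprintf("VariantSet: %d record(s) x %d sample(s)\n",
              nVariants(object), length(sampleIds(object))))
  cat("  samples:", paste(sampleIds(object), collapse = ", "), "\n")
  if (nVariants(object) > 0) {
    cat("  contigs:", paste(unique(object@meta$contig), collapse = ", "), "\n")
  }
})

#' @describeIn accessors experiment id of the index case
#' @export
setGeneric("indexId", function(x) standardGeneric("indexId"))
#' @export
setMethod("indexId", "FamilyPedigree", function(x) {
  x@members$experiment_id[x@members$is_index]
})
#' @export
setMethod("indexId", "CaseBundle", function(x) indexId(x@pedigree))

#' @describeIn accessors family identifier
#' @export
setGeneric("familyId", function(x) standardGeneric("familyId"))
#' @export
setMethod("familyId", "FamilyPedigree", function(x) x@family_id)
#' @export
setMethod("familyId", "CaseBundle", function(x) x@pedigree@family_id)

#' @describeIn accessors family structure class (trio/singleton/other)
#' @export
setGeneric("structureClass", function(x) standardGeneric("structureClass"))
#' @export
setMethod("structureClass", "FamilyPedigree", function(x) x@structure_class)

#' @describeIn accessors pedigree member table
#' @export
setGeneric("pedMembers", function(x) standardGeneric("pedMembers"))
#' @export
setMethod("pedMembers", "FamilyPedigree", function(x) x@members)

setMethod("show", "FamilyPedigree", function(object) {
  cat(sprintf("FamilyPedigree %s (%s): %d member(s), index %s\n",
              object@family_id, object@structure_class,
              nrow(object@members), indexId(object)))
})

#' @describeIn accessors gene symbols of a [GenePanel-class]
#' @export
setGeneric("panelGenes", function(x) standardGeneric("panelGenes"))
#' @export
setMethod("panelGenes", "GenePanel", function(x) x@genes)

#' @describeIn accessors panel identifier
#' @export
setGeneric("panelId", function(x) standardGeneric("panelId"))
#' @export
setMethod("panelId", "GenePanel", function(x) x@panel_id)

setMethod("show", "GenePanel", function(object) {
  cat(sprintf("GenePanel %s (%s): %d gene(s)\n",
              object@panel_id, object@source, length(object@genes)))
})

#' @describeIn accessors all term ids of an [HpoOntology-class]
#' @export
setGeneric("ontologyTerms", function(x) standardGeneric("ontologyTerms"))
#' @export
setMethod("ontologyTerms", "HpoOntology", function(x) x@terms)

setMethod("show", "HpoOntology", function(object) {
  cat(sprintf("HpoOntology: %d term(s), root %s\n",
              length(object@terms), object@root))
})

setMethod("show", "KnowledgeBase", function(object) {
  cat("KnowledgeBase\n")
  cat(sprintf("  assertions:   %d variant key(s)\n", nrow(object@assertions)))
  cat(sprintf("  frequencies:  %d variant key(s)\n", length(object@frequencies)))
  cat(sprintf("  gene2disease: %d association(s)\n", nrow(object@gene2disease)))
  cat(sprintf("  constraint:   %d gene(s)\n", nrow(object@constraint)))
  cat(sprintf("  acmg:         %d variant key(s)\n", nrow(object@acmg)))
  if (length(object@versions)) {
    cat("  versions:", paste(names(object@versions), object@versions,
                             sep = "=", collapse = ", "), "\n")
  }
})

setMethod("show", "FilterConfig", function(object) {
  cat("FilterConfig\n")
  cat(sprintf("  af_external < %g, af_internal < %g\n",
              object@af_external_max, object@af_internal_max))
  cat(sprintf("  panel: %s\n",
              if (is.null(object@panel)) "on-the-fly (per case)" else object@panel@panel_id))
  cat(sprintf("  require P/LP: %s (%s)\n", object@require_plp, object@plp_aggregation))
  cat(sprintf("  region restriction: %s\n", object@region_restriction))
  cat(sprintf("  segregation models: %s\n",
              paste(object@segregation_models, collapse = ", ")))
})

setMethod("show", "CaseBundle", function(object) {
  cat(sprintf("CaseBundle %s: index %s (%s), %d variant record(s)\n",
              familyId(object), indexId(object),
              structureClass(object@pedigree), nVariants(object@variants)))
})
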