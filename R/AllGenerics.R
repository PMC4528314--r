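#' Animal identifiers
#' @param x a GenotypeData, Pedigree, TraitRecords or RelationshipMatrix.
#' @return character vector of animal ids.
#' @export
setGeneric("animalIds", function(x) standardGeneric("animalIds"))

#' SNP identifiers
#' @param x a GenotypeData.
#' @return character vector of SNP ids.
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' Allele dosage matrix, animals in rows and SNPs in columns
#' @param x a GenotypeData.
#' @return numeric matrix with `NA` for missing calls.
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))

#' Line labels per animal
#' @param x a GenotypeData, Pedigree or TraitRecords.
#' @return named character vector, names are animal ids.
#' @export
setGeneric("lineOf", function(x) standardGeneric("lineOf"))

#' SNP metadata (chromosome and position)
#' @param x a GenotypeData.
#' @return data.frame with columns `id`, `chrom`, `pos`.
#' @export
setGeneric("snpInfo", function(x) standardGeneric("snpInfo"))

#' Kind of a relationship matrix
#' @param x a RelationshipMatrix.
#' @return `"pedigree"`, `"genomic_within"` or `"genomic_across"`.
#' @export
setGeneric("kinshipKind", function(x) standardGeneric("kinshipKind"))

#' Trait records as a data.frame
#' @param x a TraitRecords object.
#' @return the underlying per-animal table.
#' @export
setGeneric("traitRecords", function(x) standardGeneric("traitRecords"))

#' Pedigree as a data.frame
#' @param x a Pedigree object.
#' @return data.frame with columns `id`, `sire`, `dam`, `line`, in
#'   topological order.
#' @export
setGeneric("pedigreeTable", function(x) standardGeneric("pedigreeTable"))

#' @describeIn GenotypeData animal ids
#' @param x a GenotypeData object.
#' @export
setMethod("animalIds", "GenotypeData", function(x) colnames(x))

#' @describeIn GenotypeData SNP ids
#' @export
setMethod("snpIds", "GenotypeData", function(x) rownames(x))

#' @describeIn GenotypeData dosage matrix (animals x SNPs)
#' @export
setMethod("dosages", "GenotypeData",
          function(x) t(SummarizedExperiment::assay(x, "dosage")))

#' @describeIn GenotypeData line label per animal
#' @export
setMethod("lineOf", "GenotypeData", function(x)
  setNames(as.character(SummarizedExperiment::colData(x)$line), colnames(x)))

#' @describeIn GenotypeData SNP chromosome/position metadata
#' @export
setMethod("snpInfo", "GenotypeData", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  data.frame(id = rownames(x), chrom = as.character(rd$chrom),
             pos = as.integer(rd$pos), row.names = NULL)
})

#' @describeIn Pedigree animal ids in topological order
#' @param x a Pedigree object.
#' @export
setMethod("animalIds", "Pedigree", function(x) x@id)

#' @describeIn Pedigree line label per animal
#' @export
setMethod("lineOf", "Pedigree", function(x) setNames(x@line, x@id))

#' @describeIn Pedigree records as a data.frame
#' @export
setMethod("pedigreeTable", "Pedigree", function(x)
  data.frame(id = x@id, sire = x@sire, dam = x@dam, line = x@line,
             row.names = NULL))

setMethod("show", "Pedigree", function(object) {
  cat("Pedigree with", length(object@id), "animals in",
      length(unique(object@line)), "line(s);",
      sum(is.na(object@sire) & is.na(object@dam)), "founders\n")
})

#' @describeIn TraitRecords animal ids
#' @param x a TraitRecords object.
#' @export
setMethod("animalIds", "TraitRecords", function(x) x@records$id)

#' @describeIn TraitRecords line label per animal
#' @export
setMethod("lineOf", "TraitRecords", function(x)
  setNames(x@records$line, x@records$id))

#' @describeIn TraitRecords the per-animal table
#' @export
setMethod("traitRecords", "TraitRecords", function(x) x@records)

setMethod("show", "TraitRecords", function(object) {
  r <- object@records
  cat("TraitRecords:", nrow(r), "animals,",
      if ("debv" %in% names(r)) "deregressed" else "not deregressed", "\n")
  cat("  mean r2:", round(mean(r$r2), 3), "\n")
})

#' @describeIn RelationshipMatrix animal ids
#' @param x a RelationshipMatrix object.
#' @export
setMethod("animalIds", "RelationshipMatrix", function(x) rownames(x@values))

#' @describeIn RelationshipMatrix matrix kind
#' @export
setMethod("kinshipKind", "RelationshipMatrix", function(x) x@kind)

#' @describeIn RelationshipMatrix the plain symmetric matrix
#' @export
setMethod("as.matrix", "RelationshipMatrix", function(x, ...) x@values)

setMethod("show", "RelationshipMatrix", function(object) {
  v <- object@values
  cat("RelationshipMatrix (", object@kind, "): ", nrow(v), " animals, ",
      "mean diagonal ", round(mean(diag(v)), 4), "\n", sep = "")
})

setMethod("show", "PopulationSpec", function(object) {
  cat("PopulationSpec:", paste(object@lines, collapse = "+"),
      sprintf("(%d/line) + %d F1, %d SNPs (%d QTL), h2=%.2f, rhoPbCb=%.2f\n",
              object@nPerLine, object@nF1, object@nSnps, object@nQtl,
              object@h2, object@rhoPbCb))
})

setMethod("show", "ScenarioResult", function(object) {
  s <- object@summary
  cat(sprintf("Scenario %s [%s, %s]: accuracy %.3f%s, slope %.3f (%d replicate%s)\n",
              object@id, object@model, object@matrixKind, s$meanAccuracy,
              if (is.na(s$sdAccuracy)) "" else sprintf(" (SD %.3f)", s$sdAccuracy),
              s$meanSlope, nrow(object@replicates),
              if (nrow(object@replicates) == 1) "" else "s"))
})
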