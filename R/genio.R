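# Readers and writers for the standard interchange formats: VCF (GT only),
# a PLINK-raw-style text dosage table, and CSV pedigree/trait tables.

gtToDosage <- function(gt, where) {
  gt <- gsub("\\|", "/", gt)
  d <- rep(NA_real_, length(gt))
  d[gt == "0/0"] <- 0
  d[gt %in% c("0/1", "1/0")] <- 1
  d[gt == "1/1"] <- 2
  bad <- !(gt %in% c("0/0", "0/1", "1/0", "1/1", "./.", ".")) & !is.na(gt)
  if (any(bad))
    stop("malformed GT field '", gt[which(bad)[1]], "' at ", where,
         " record ", which(bad)[1])
  d
}

#' Read SNP genotypes from VCF or a raw text dosage table
#'
#' VCF input (v4.x, GT field only, biallelic) is parsed with \pkg{vcfR};
#' dosages count the alternate allele and `./.` maps to missing. The raw
#' text dialect is a whitespace-separated table whose first two columns are
#' `IID` and `LINE` followed by one column per SNP (dosage of the A1
#' allele, `NA` for missing). Animal and SNP identifiers must be unique.
#'
#' @param path input file.
#' @param format `"vcf"`, `"raw"`, or `"auto"` (by file extension).
#' @param lines optional named line labels for VCF input, which carries no
#'   line column (default label `"unknown"`).
#' @return a [GenotypeData-class].
#' @export
readGenotypes <- function(path, format = c("auto", "vcf", "raw"),
                          lines = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "raw"
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- vcfR::getFIX(v)
    if (any(grepl(",", fix[, "ALT"])))
      stop("multi-allelic site at record ",
           which(grepl(",", fix[, "ALT"]))[1], "; only biallelic supported")
    snp <- fix[, "ID"]
    snp[is.na(snp) | snp == "."] <-
      paste0(fix[, "CHROM"], "_", fix[, "POS"])[is.na(snp) | snp == "."]
    if (anyDuplicated(snp))
      stop("duplicate SNP id: ", snp[duplicated(snp)][1])
    gt <- vcfR::extract.gt(v, element = "GT")
    anm <- colnames(gt)
    if (anyDuplicated(anm))
      stop("duplicate animal id: ", anm[duplicated(anm)][1])
    d <- apply(gt, 2, gtToDosage, where = basename(path))
    d <- matrix(d, nrow = nrow(gt),
                dimnames = list(snp, anm))
    lin <- if (is.null(lines)) rep("unknown", length(anm)) else lines[anm]
    GenotypeData(t(d), line = lin, chrom = fix[, "CHROM"],
                 pos = as.integer(fix[, "POS"]))
  } else {
    tab <- read.table(path, header = TRUE, check.names = FALSE,
                      stringsAsFactors = FALSE)
    if (!all(c("IID", "LINE") == names(tab)[1:2]))
      stop("raw dosage table must start with IID and LINE columns")
    if (anyDuplicated(tab$IID))
      stop("duplicate animal id: ", tab$IID[duplicated(tab$IID)][1])
    sn <- names(tab)[-(1:2)]
    if (anyDuplicated(sn)) stop("duplicate SNP id: ", sn[duplicated(sn)][1])
    d <- as.matrix(tab[, -(1:2), drop = FALSE])
    if (!is.numeric(d)) stop("non-numeric dosage entries in ", path)
    rownames(d) <- tab$IID
    GenotypeData(d, line = tab$LINE)
  }
}

#' Write SNP genotypes to VCF or the raw text dosage table
#'
#' VCF output encodes integer dosages as GT (`0/0`, `0/1`, `1/1`, `./.`)
#' with placeholder REF/ALT alleles `A`/`B`; real-valued (imputed) dosages
#' cannot be represented as genotypes and are rejected for VCF. The raw
#' dialect writes the `IID`/`LINE` + per-SNP table with `NA` for missing
#' and accepts real-valued dosages.
#'
#' @param g a [GenotypeData-class].
#' @param path output file.
#' @param format `"vcf"` or `"raw"`.
#' @return `path`, invisibly.
#' @export
writeGenotypes <- function(g, path, format = c("vcf", "raw")) {
  format <- match.arg(format)
  d <- dosages(g)
  if (format == "vcf") {
    if (any(abs(d - round(d)) > 1e-9, na.rm = TRUE))
      stop("VCF output requires integer dosages; use format = 'raw'")
    info <- snpInfo(g)
    gtCode <- c("0/0", "0/1", "1/1")
    body <- vapply(seq_len(ncol(d)), function(j) {
      gts <- ifelse(is.na(d[, j]), "./.", gtCode[round(d[, j]) + 1L])
      paste(c(info$chrom[j], info$pos[j], info$id[j], "A", "B", ".",
              "PASS", ".", "GT", gts), collapse = "\t")
    }, character(1))
    writeLines(c("##fileformat=VCFv4.2",
                 "##source=crossblup",
                 paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                        "Description=\"Genotype\">"),
                 paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                         "FILTER", "INFO", "FORMAT", rownames(d)),
                       collapse = "\t"),
                 body), path)
  } else {
    tab <- data.frame(IID = rownames(d), LINE = lineOf(g),
                      check.names = FALSE)
    tab <- cbind(tab, as.data.frame(d, check.names = FALSE))
    write.table(tab, path, quote = FALSE, row.names = FALSE, sep = "\t")
  }
  invisible(path)
}

#' Read a pedigree CSV
#'
#' Expects a header with columns `id` (or `animal`), `sire`, `dam`, `line`.
#' Unknown parents may be empty, `NA` or `0`. Rows are topologically sorted
#' on load; a cyclic pedigree is an error listing the cycle.
#'
#' @param path CSV file.
#' @return a [Pedigree-class].
#' @export
readPedigree <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("animal" %in% names(tab) && !"id" %in% names(tab))
    names(tab)[names(tab) == "animal"] <- "id"
  Pedigree(tab)
}

#' Write a pedigree CSV
#' @param ped a [Pedigree-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(ped, path) {
  utils::write.csv(pedigreeTable(ped), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a trait table CSV
#'
#' Columns `id` (or `animal`), `line`, `ebv`, `r2` and optionally `debv`
#' and `weight`. Reliabilities outside (0, 1] are rejected.
#'
#' @param path CSV file.
#' @return a [TraitRecords-class].
#' @export
readTraits <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("animal" %in% names(tab) && !"id" %in% names(tab))
    names(tab)[names(tab) == "animal"] <- "id"
  if (any(tab$r2 <= 0 | tab$r2 > 1))
    stop("reliability out of (0, 1] for animal ",
         tab$id[which(tab$r2 <= 0 | tab$r2 > 1)[1]])
  TraitRecords(tab)
}

#' Write a trait table CSV
#' @param traits a [TraitRecords-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTraits <- function(traits, path) {
  utils::write.csv(traitRecords(traits), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Intersect genotype, pedigree and trait data into a working set
#'
#' The working set is the intersection of genotyped animals and trait
#' records (the pedigree is kept whole, as ungenotyped ancestors still
#' contribute relationships). The report counts animals dropped from each
#' source.
#'
#' @param g a [GenotypeData-class].
#' @param ped a [Pedigree-class].
#' @param traits a [TraitRecords-class].
#' @return list with `genotypes`, `traits` (both restricted to the working
#'   set, genotype order), `pedigree`, and `report` (counts
#'   `nKept`, `nGenotypeOnly`, `nTraitOnly`, `nNotInPedigree`).
#' @export
alignDatasets <- function(g, ped, traits) {
  gid <- animalIds(g)
  tid <- animalIds(traits)
  keep <- intersect(gid, tid)
  if (!length(keep))
    stop("no animal has both genotypes and trait records")
  r <- traitRecords(traits)
  r <- r[match(keep, r$id), , drop = FALSE]
  list(genotypes = g[, keep],
       traits = TraitRecords(r),
       pedigree = ped,
       report = list(nKept = length(keep),
                     nGenotypeOnly = length(setdiff(gid, tid)),
                     nTraitOnly = length(setdiff(tid, gid)),
                     nNotInPedigree = length(setdiff(keep, animalIds(ped)))))
}
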