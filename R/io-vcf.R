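as_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(genome)
  if (!methods::is(genome, "DNAStringSet")) {
    stop_bad("genome must be a named character vector or DNAStringSet")
  }
  if (is.null(names(genome))) stop_bad("genome sequences must be named")
  genome
}

#' Read a minimal VCF for spectrum/TMB analysis
#'
#' Parses a VCF v4.x with `VariantAnnotation::readVcf`, splits multi-allelic
#' records, validates every position against the supplied genome (the REF
#' field must match the reference base(s)), and classifies records as
#' `SNV`, `insertion`, `deletion` or `other`. Only SNVs are eligible for the
#' SBS96 spectrum; indels are flagged and passed through so TMB counting can
#' include them.
#'
#' @param path VCF file path.
#' @param genome Named character vector or `Biostrings::DNAStringSet` holding
#'   every contig named in the VCF.
#' @return `data.frame` with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `class`.
#' @export
read_vcf_minimal <- function(path, genome) {
  genome <- as_genome(genome)
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path))
  vcf <- VariantAnnotation::expand(vcf)
  rr <- SummarizedExperiment::rowRanges(vcf)
  chrom <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  alt <- as.character(rr$ALT)
  missing_contig <- !(chrom %in% names(genome))
  if (any(missing_contig)) {
    stop_bad("contig absent from genome: ", chrom[which(missing_contig)[1]])
  }
  for (i in seq_along(chrom)) {
    expected <- as.character(Biostrings::subseq(
      genome[[chrom[i]]], pos[i], pos[i] + nchar(ref[i]) - 1L))
    if (!identical(expected, ref[i])) {
      stop_bad("REF mismatch at ", chrom[i], ":", pos[i],
               " (VCF says ", ref[i], ", genome says ", expected, ")")
    }
  }
  class <- ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV",
           ifelse(nchar(alt) > nchar(ref), "insertion",
           ifelse(nchar(alt) < nchar(ref), "deletion", "other")))
  class[class == "SNV" & ref == alt] <- "other"
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, class = class,
             stringsAsFactors = FALSE)
}

#' Write a minimal VCF v4.2
#'
#' Emits the eight fixed columns plus contig header lines; used by the
#' synthetic-data generator. Records are sorted by contig and position.
#'
#' @param variants `data.frame` with `chrom`, `pos`, `ref`, `alt`.
#' @param path Output file path.
#' @param genome Genome the records refer to (for contig header lines).
#' @return `path`, invisibly.
#' @export
write_vcf_minimal <- function(variants, path, genome) {
  genome <- as_genome(genome)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=dmmrkit",
    paste0("##contig=<ID=", names(genome), ",length=",
           Biostrings::width(genome), ">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(variants)) {
    ord <- order(variants$chrom, variants$pos)
    v <- variants[ord, ]
    writeLines(paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
                     sep = "\t"), con)
  }
  invisible(path)
}
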