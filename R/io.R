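# Readers/writers for the standard interchange formats: FASTA genomes,
# GFF3/BED exon annotation, CSV tables. Coordinates are 1-based inclusive
# throughout the package; BED input (0-based half-open) is converted on
# read.

#' Read a genome from FASTA
#' @param path FASTA file.
#' @return `DNAStringSet` (names truncated at the first whitespace).
#' @export
read_genome_fasta <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write a genome to FASTA
#' @param genome named character vector or `DNAStringSet`.
#' @param path output file.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(as_genome(genome), path)
  invisible(path)
}

#' Read exon annotation from GFF3 or BED
#'
#' GFF3 exon features are read with rtracklayer; BED (0-based half-open,
#' gene id in the name column) is converted to the package's 1-based
#' inclusive convention.
#'
#' @param path annotation file.
#' @param format `"gff3"` or `"bed"` (default from the file extension).
#' @return data.frame `contig`, `start`, `end` (1-based inclusive),
#'   `gene_id`.
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  if (format == "gff3") {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[tolower(as.character(gr$type)) %in% c("exon", "gene")]
    data.frame(contig = as.character(GenomicRanges::seqnames(gr)),
               start = BiocGenerics::start(gr), end = BiocGenerics::end(gr),
               gene_id = as.character(gr$gene_id), stringsAsFactors = FALSE)
  } else {
    bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
    data.frame(contig = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]],
               gene_id = bed[[4]], stringsAsFactors = FALSE)
  }
}

#' Write exon annotation as GFF3
#' @param annotation data.frame `contig`, `start`, `end`, `gene_id`
#'   (1-based inclusive).
#' @param path output file.
#' @export
write_annotation_gff3 <- function(annotation, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tscreenaudit\texon\t%d\t%d\t.\t+\t.\tgene_id=%s;ID=exon_%d",
                     annotation$contig, annotation$start, annotation$end,
                     annotation$gene_id, seq_len(nrow(annotation))))
  writeLines(lines, path)
  invisible(path)
}

#' Convert 0-based half-open BED intervals to 1-based inclusive
#' @param bed data.frame with columns chrom, chromStart, chromEnd, name.
#' @return data.frame `contig`, `start`, `end`, `gene_id`.
#' @export
bed_to_annotation <- function(bed) {
  data.frame(contig = bed[[1]], start = bed[[2]] + 1L, end = bed[[3]],
             gene_id = bed[[4]], stringsAsFactors = FALSE)
}

#' Write all inputs of a synthetic screen to a directory
#'
#' Writes genome FASTA, GFF3 exon annotation, and CSV tables (guides, LFC,
#' expression, copy number, SNPs, genotypes, paralog pairs) consumable by
#' the audit functions and external tools.
#'
#' @param screen a `synthetic_screen`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_screen_inputs <- function(screen, dir) {
  stopifnot(inherits(screen, "synthetic_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- screen$design
  write_genome_fasta(d$genome, file.path(dir, "genome.fa"))
  write_annotation_gff3(d$annotation, file.path(dir, "annotation.gff3"))
  utils::write.csv(d$guides, file.path(dir, "guides.csv"), row.names = FALSE)
  utils::write.csv(screen$lfc, file.path(dir, "lfc.csv"))
  utils::write.csv(screen$expression, file.path(dir, "expression.csv"))
  utils::write.csv(screen$cn, file.path(dir, "copy_number.csv"))
  if (nrow(d$paralog_pairs) > 0L)
    utils::write.csv(d$paralog_pairs, file.path(dir, "paralog_pairs.csv"),
                     row.names = FALSE)
  if (nrow(d$snps) > 0L) {
    utils::write.csv(d$snps, file.path(dir, "snps.csv"), row.names = FALSE)
    utils::write.csv(screen$genotypes, file.path(dir, "genotypes.csv"))
  }
  invisible(dir)
}
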