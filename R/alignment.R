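#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet reverseComplement matchPattern
NULL

# normalize a genome to an uppercase DNAStringSet with unique names
as_genome <- function(genome) {
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  if (!methods::is(genome, "DNAStringSet"))
    stop("'genome' must be a named character vector or DNAStringSet")
  if (is.null(names(genome)) || anyDuplicated(names(genome)))
    stop("genome contigs must have unique names")
  genome
}

.check_spacer <- function(spacer) {
  if (!is.character(spacer) || length(spacer) != 1L)
    stop("'spacer' must be a single string")
  spacer <- toupper(spacer)
  if (nchar(spacer) != 20L) stop("spacer must be exactly 20 nt")
  if (grepl("[^ACGT]", spacer)) stop("spacer alphabet must be A/C/G/T")
  spacer
}

.empty_alignments <- function() {
  data.frame(guide_id = character(0), contig = character(0),
             start = integer(0), strand = character(0),
             n_mismatches = integer(0), mismatch_positions = character(0),
             substitutions = character(0), pam_seq = character(0),
             protospacer = character(0), stringsAsFactors = FALSE)
}

#' Find genomic alignments of a spacer with mismatch tolerance
#'
#' Scans both strands of a genome for 20-nt windows matching the spacer at
#' up to `max_mm` substitutions and whose adjacent 3-nt PAM (3' of the
#' protospacer, in spacer orientation) matches canonical NGG. Windows or
#' PAMs containing ambiguous bases (N) are excluded. For minus-strand hits
#' the reported `start` is the forward-strand coordinate of the 5' end of
#' the 20-nt window; the protospacer is reported in spacer orientation.
#' Mismatch positions are PAM-relative (position 1 adjacent to the PAM).
#'
#' @param genome named character vector or `DNAStringSet` of contigs.
#' @param spacer 20-nt guide spacer (A/C/G/T).
#' @param max_mm maximum number of spacer-protospacer mismatches (0-2).
#' @param guide_id identifier recorded in the output.
#' @param warn_above warn if the number of alignments exceeds this cap.
#' @return data.frame with one row per alignment: `guide_id`, `contig`,
#'   `start` (1-based), `strand`, `n_mismatches`, `mismatch_positions`
#'   (comma-separated PAM-relative positions, increasing),
#'   `substitutions` (reference>spacer, same order), `pam_seq`,
#'   `protospacer`; rows ordered by (contig, start, strand).
#' @export
find_alignments <- function(genome, spacer, max_mm = 2L, guide_id = NA_character_,
                            warn_above = 10000L) {
  genome <- as_genome(genome)
  spacer <- .check_spacer(spacer)
  if (!is.numeric(max_mm) || max_mm < 0 || max_mm > 2)
    stop("'max_mm' must be 0, 1 or 2")
  max_mm <- as.integer(max_mm)

  sp <- Biostrings::DNAString(spacer)
  sp_rc <- Biostrings::reverseComplement(sp)
  rows <- list()

  for (ctg in names(genome)) {
    subject <- genome[[ctg]]
    len <- length(subject)
    if (len < 23L) next

    # plus strand: protospacer at [s, s+19], PAM at [s+20, s+22]
    hits <- Biostrings::matchPattern(sp, subject, max.mismatch = max_mm,
                                     with.indels = FALSE)
    for (s in BiocGenerics::start(hits)) {
      if (s + 22L > len) next
      window <- as.character(Biostrings::subseq(subject, s, s + 19L))
      pam <- as.character(Biostrings::subseq(subject, s + 20L, s + 22L))
      if (grepl("[^ACGT]", window) || grepl("[^ACGT]", pam)) next
      if (substr(pam, 2L, 3L) != "GG") next
      mm <- mismatch_profile(spacer, window)
      if (length(mm$positions) > max_mm) next
      rows[[length(rows) + 1L]] <- data.frame(
        guide_id = guide_id, contig = ctg, start = s, strand = "+",
        n_mismatches = length(mm$positions),
        mismatch_positions = paste(mm$positions, collapse = ","),
        substitutions = paste(mm$substitutions, collapse = ","),
        pam_seq = pam, protospacer = window, stringsAsFactors = FALSE)
    }

    # minus strand: reverse complement of spacer at forward [s, s+19];
    # PAM (spacer orientation) is the reverse complement of forward
    # [s-3, s-1], so the forward sequence there must match CCN
    hits <- Biostrings::matchPattern(sp_rc, subject, max.mismatch = max_mm,
                                     with.indels = FALSE)
    for (s in BiocGenerics::start(hits)) {
      if (s - 3L < 1L || s + 19L > len) next
      window_fwd <- Biostrings::subseq(subject, s, s + 19L)
      pam_fwd <- Biostrings::subseq(subject, s - 3L, s - 1L)
      wf <- as.character(window_fwd)
      pf <- as.character(pam_fwd)
      if (grepl("[^ACGT]", wf) || grepl("[^ACGT]", pf)) next
      if (substr(pf, 1L, 2L) != "CC") next
      proto <- as.character(Biostrings::reverseComplement(window_fwd))
      pam <- as.character(Biostrings::reverseComplement(pam_fwd))
      mm <- mismatch_profile(spacer, proto)
      if (length(mm$positions) > max_mm) next
      rows[[length(rows) + 1L]] <- data.frame(
        guide_id = guide_id, contig = ctg, start = s, strand = "-",
        n_mismatches = length(mm$positions),
        mismatch_positions = paste(mm$positions, collapse = ","),
        substitutions = paste(mm$substitutions, collapse = ","),
        pam_seq = pam, protospacer = proto, stringsAsFactors = FALSE)
    }
  }

  if (length(rows) == 0L) return(.empty_alignments())
  out <- do.call(rbind, rows)
  out <- out[order(out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) > warn_above)
    warning(sprintf("guide %s has %d alignments (> %d)", guide_id,
                    nrow(out), warn_above))
  out
}

#' Align a guide library to a genome
#'
#' Applies [find_alignments()] to every guide in a library table.
#'
#' @param genome named character vector or `DNAStringSet`.
#' @param guides data.frame with columns `guide_id`, `spacer` and
#'   optionally `intended_gene` (NA for non-targeting controls).
#' @param max_mm maximum mismatches (0-2).
#' @return data.frame of alignments across all guides (possibly 0 rows per
#'   guide; guides with no alignments contribute no rows).
#' @export
align_library <- function(genome, guides, max_mm = 2L) {
  stopifnot(all(c("guide_id", "spacer") %in% names(guides)))
  genome <- as_genome(genome)
  res <- lapply(seq_len(nrow(guides)), function(i) {
    find_alignments(genome, guides$spacer[i], max_mm = max_mm,
                    guide_id = guides$guide_id[i])
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' PAM-relative mismatch profile between a spacer and a protospacer
#'
#' Compares two 20-nt sequences (spacer orientation) and reports mismatch
#' positions counted from the PAM: position 1 is the nucleotide adjacent to
#' the PAM (the 3'-most spacer base), position 20 the 5'-most. Substitutions
#' are reported as reference>spacer.
#'
#' @param spacer,protospacer 20-nt strings.
#' @return list with `positions` (increasing PAM-relative integers) and
#'   `substitutions` (character, `"ref>spacer"`, same order).
#' @export
mismatch_profile <- function(spacer, protospacer) {
  spacer <- toupper(spacer); protospacer <- toupper(protospacer)
  if (nchar(spacer) != 20L || nchar(protospacer) != 20L)
    stop("both sequences must be 20 nt")
  s <- strsplit(spacer, "")[[1]]
  p <- strsplit(protospacer, "")[[1]]
  diff_idx <- which(s != p)               # 1-based 5' index
  if (length(diff_idx) == 0L)
    return(list(positions = integer(0), substitutions = character(0)))
  pos <- 21L - diff_idx                   # PAM-relative
  ord <- order(pos)
  list(positions = as.integer(pos[ord]),
       substitutions = paste0(p[diff_idx][ord], ">", s[diff_idx][ord]))
}

#' Annotate alignments against exon intervals
#'
#' Marks each alignment exonic if its 20-nt protospacer interval overlaps
#' any exon by at least 1 bp; all overlapping genes are recorded. With empty
#' annotation every alignment is intergenic.
#'
#' @param alignments data.frame from [find_alignments()].
#' @param annotation data.frame with columns `contig`, `start`, `end`
#'   (1-based inclusive) and `gene_id`.
#' @return `alignments` with columns `region` (`"exonic"`/`"intergenic"`)
#'   and `region_genes` (comma-separated gene ids, `""` if intergenic).
#' @export
annotate_alignments <- function(alignments, annotation) {
  if (nrow(alignments) == 0L) {
    alignments$region <- character(0)
    alignments$region_genes <- character(0)
    return(alignments)
  }
  region <- rep("intergenic", nrow(alignments))
  region_genes <- rep("", nrow(alignments))
  if (!is.null(annotation) && nrow(annotation) > 0L) {
    a_end <- alignments$start + 19L
    for (i in seq_len(nrow(alignments))) {
      hit <- annotation$contig == alignments$contig[i] &
        annotation$start <= a_end[i] &
        annotation$end >= alignments$start[i]
      if (any(hit)) {
        region[i] <- "exonic"
        region_genes[i] <- paste(sort(unique(annotation$gene_id[hit])),
                                 collapse = ",")
      }
    }
  }
  alignments$region <- region
  alignments$region_genes <- region_genes
  alignments
}

#' Summarize alignments of a single guide
#'
#' Tallies perfect, single-mismatch and double-mismatch alignments for one
#' guide, the genes hit at each level, and the guide class label.
#'
#' @param alignments alignments of exactly one guide (0 rows allowed when
#'   `guide_id` is given); annotated columns are used when present.
#' @param guide_id guide identifier, required when `alignments` is empty.
#' @param clean_level `"1mm"` (clean = one perfect alignment and no
#'   single-mismatch alignments) or `"2mm"` (additionally no
#'   double-mismatch alignments).
#' @return one-row data.frame: `guide_id`, `n_perfect`, `n_1mm`, `n_2mm`,
#'   `n_exonic_1mm`, `genes_hit_perfect`, `genes_hit_1mm`, `class`,
#'   `is_clean`, `is_double_target`.
#' @export
summarize_guide <- function(alignments, guide_id = NULL,
                            clean_level = c("1mm", "2mm")) {
  clean_level <- match.arg(clean_level)
  if (nrow(alignments) > 0L) {
    ids <- unique(alignments$guide_id)
    if (length(ids) != 1L) stop("alignments must belong to a single guide")
    guide_id <- ids
  } else if (is.null(guide_id)) {
    stop("'guide_id' required for a guide with no alignments")
  }
  n_perfect <- sum(alignments$n_mismatches == 0L)
  n_1mm <- sum(alignments$n_mismatches == 1L)
  n_2mm <- sum(alignments$n_mismatches == 2L)
  has_region <- "region" %in% names(alignments)
  n_exonic_1mm <- if (has_region)
    sum(alignments$n_mismatches == 1L & alignments$region == "exonic") else NA_integer_
  genes_at <- function(k) {
    if (!has_region) return("")
    g <- alignments$region_genes[alignments$n_mismatches == k]
    g <- unlist(strsplit(g[g != ""], ","))
    paste(sort(unique(g)), collapse = ",")
  }
  out <- data.frame(
    guide_id = guide_id, n_perfect = n_perfect, n_1mm = n_1mm, n_2mm = n_2mm,
    n_exonic_1mm = n_exonic_1mm,
    genes_hit_perfect = genes_at(0L), genes_hit_1mm = genes_at(1L),
    stringsAsFactors = FALSE)
  out$class <- classify_guide(out, clean_level)
  out$is_clean <- n_perfect == 1L && n_1mm == 0L &&
    (clean_level == "1mm" || n_2mm == 0L)
  out$is_double_target <- n_perfect == 2L
  out
}

#' Summarize alignments for a whole library
#'
#' @param alignments alignment table across guides.
#' @param guide_ids all library guide ids (guides without alignments get a
#'   zero-count row, the "no genomic target" class).
#' @param clean_level see [summarize_guide()].
#' @return data.frame with one row per guide.
#' @export
summarize_guides <- function(alignments, guide_ids = NULL,
                             clean_level = c("1mm", "2mm")) {
  clean_level <- match.arg(clean_level)
  if (is.null(guide_ids)) guide_ids <- unique(alignments$guide_id)
  by_guide <- split(seq_len(nrow(alignments)), alignments$guide_id)
  rows <- lapply(guide_ids, function(g) {
    idx <- by_guide[[g]]
    aln <- if (is.null(idx)) alignments[0, , drop = FALSE] else alignments[idx, , drop = FALSE]
    summarize_guide(aln, guide_id = g, clean_level = clean_level)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a guide from its alignment summary
#'
#' Deterministic label from alignment counts. A clean single-target guide
#' has one perfect alignment and no single-mismatch alignments (level
#' `"1mm"`), additionally no double-mismatch alignments at level `"2mm"`.
#'
#' @param summary one-row summary (columns `n_perfect`, `n_1mm`, `n_2mm`).
#' @param clean_level `"1mm"` or `"2mm"`.
#' @return one of `"no_target"`, `"clean_single"`, `"single_mm_offtarget"`,
#'   `"double_mm_only"`, `"double_target"`, `"multi_target"`,
#'   `"multi_target_with_offtargets"`.
#' @export
classify_guide <- function(summary, clean_level = c("1mm", "2mm")) {
  clean_level <- match.arg(clean_level)
  np <- summary$n_perfect; n1 <- summary$n_1mm; n2 <- summary$n_2mm
  if (np == 0L) return("no_target")
  if (np == 1L) {
    if (n1 > 0L) return("single_mm_offtarget")
    if (clean_level == "2mm" && n2 > 0L) return("double_mm_only")
    return("clean_single")
  }
  if (n1 > 0L) return("multi_target_with_offtargets")
  if (np == 2L) return("double_target")
  "multi_target"
}

#' Gene-level target summary table
#'
#' Aggregates per-guide alignment summaries by intended gene and flags
#' genes whose guides are all multi-target (no clean guide at the chosen
#' level) -- genes whose essentiality scores rest entirely on promiscuous
#' reagents.
#'
#' @param summaries per-guide summary table (from [summarize_guides()]).
#' @param guide_map data.frame with `guide_id`, `intended_gene` (NA rows,
#'   i.e. non-targeting controls, are dropped).
#' @param clean_level `"1mm"` or `"2mm"` used to (re)derive cleanliness.
#' @return data.frame: `gene_id`, `n_guides`, `n_clean_guides`,
#'   `all_guides_multitarget`.
#' @export
gene_summary_table <- function(summaries, guide_map,
                               clean_level = c("1mm", "2mm")) {
  clean_level <- match.arg(clean_level)
  stopifnot(all(c("guide_id", "intended_gene") %in% names(guide_map)))
  if (anyDuplicated(guide_map$guide_id))
    stop("each guide must map to at most one intended gene")
  m <- merge(summaries, guide_map, by = "guide_id")
  m <- m[!is.na(m$intended_gene), , drop = FALSE]
  clean <- m$n_perfect == 1L & m$n_1mm == 0L &
    (clean_level == "1mm" | m$n_2mm == 0L)
  agg <- data.frame(
    gene_id = sort(unique(m$intended_gene)), stringsAsFactors = FALSE)
  agg$n_guides <- as.integer(table(m$intended_gene)[agg$gene_id])
  nc <- tapply(clean, m$intended_gene, sum)
  agg$n_clean_guides <- as.integer(nc[agg$gene_id])
  agg$all_guides_multitarget <- agg$n_clean_guides == 0L
  rownames(agg) <- NULL
  agg
}

#' Genotype-aware alignment of a guide library
#'
#' Substitutes a cell line's SNP alleles into the genome and realigns the
#' library, so that mismatch counts and PAM validity reflect that genome.
#' Homozygous-minor genotypes substitute the alternate base on both
#' haplotypes; heterozygous sites are evaluated on both haplotypes and each
#' alignment is reported at its fewest-mismatch haplotype, flagged
#' `heterozygous` when the two haplotypes disagree.
#'
#' @param genome reference genome.
#' @param guides guide library table (`guide_id`, `spacer`).
#' @param snp_table data.frame `snp_id`, `contig`, `position` (1-based),
#'   `ref`, `alt`; `ref` must equal the genome base at `position`.
#' @param genotype integer vector (0/1/2 minor-allele copies) aligned with
#'   `snp_table` rows; NA treated as 0 (reference).
#' @param max_mm maximum mismatches.
#' @return alignment table with an extra logical column `heterozygous`.
#' @export
apply_genotype <- function(genome, guides, snp_table, genotype, max_mm = 2L) {
  genome <- as_genome(genome)
  stopifnot(nrow(snp_table) == length(genotype))
  genotype[is.na(genotype)] <- 0L

  seqs <- as.character(genome)
  # validate reference alleles
  for (i in seq_len(nrow(snp_table))) {
    base <- substr(seqs[[snp_table$contig[i]]], snp_table$position[i],
                   snp_table$position[i])
    if (base != toupper(snp_table$ref[i]))
      stop(sprintf("SNP %s: reference allele %s disagrees with genome base %s",
                   snp_table$snp_id[i], snp_table$ref[i], base))
  }
  substitute_alleles <- function(which_alt) {
    s <- seqs
    for (i in which(which_alt)) {
      ctg <- snp_table$contig[i]
      substr(s[[ctg]], snp_table$position[i], snp_table$position[i]) <-
        toupper(snp_table$alt[i])
    }
    s
  }
  hap1 <- substitute_alleles(genotype == 2L)               # hom-alt only
  hap2 <- substitute_alleles(genotype >= 1L)               # het + hom-alt

  key <- function(a) paste(a$guide_id, a$contig, a$start, a$strand)
  a1 <- align_library(hap1, guides, max_mm = max_mm)
  if (all(genotype != 1L)) {
    a1$heterozygous <- FALSE
    return(a1)
  }
  a2 <- align_library(hap2, guides, max_mm = max_mm)
  k1 <- key(a1); k2 <- key(a2)
  all_keys <- union(k1, k2)
  rows <- lapply(all_keys, function(k) {
    r1 <- a1[match(k, k1), , drop = FALSE]
    r2 <- a2[match(k, k2), , drop = FALSE]
    in1 <- !is.na(r1$guide_id[1]); in2 <- !is.na(r2$guide_id[1])
    if (in1 && in2) {
      best <- if (r1$n_mismatches[1] <= r2$n_mismatches[1]) r1 else r2
      best$heterozygous <- r1$n_mismatches[1] != r2$n_mismatches[1]
    } else {
      best <- if (in1) r1 else r2
      best$heterozygous <- TRUE
    }
    best
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$guide_id, out$contig, out$start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}
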