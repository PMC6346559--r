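# Effects of SNPs in protospacer / PAM sequences on guide activity:
# intersection of SNPs with guide target sites, effect-category
# classification, and genotype-LFC association with permutation nulls.

.complement <- c(A = "T", C = "G", G = "C", T = "A")

#' Intersect SNPs with guide target sites
#'
#' Finds SNPs falling inside the 20-nt protospacer or the 3-nt PAM of each
#' alignment and computes the SNP position class PAM-relatively:
#' `protospacer_proximal` (positions 1-10), `protospacer_distal` (11-20),
#' `PAM_N`, `PAM_G2`, `PAM_G3`.
#'
#' @param alignments alignment table (from [find_alignments()] /
#'   [align_library()]).
#' @param snp_table data.frame `snp_id`, `contig`, `position` (1-based),
#'   `ref`, `alt` (forward-strand alleles).
#' @return data.frame of SNP-guide pairs: `snp_id`, `guide_id`, `contig`,
#'   `start`, `strand`, `site_role` (`"on_target"` / `"off_target_1mm"` /
#'   `"off_target_2mm"`), `position_class`, `pam_relative_pos` (1-20 within
#'   the protospacer, NA in the PAM), `snp_in_pam`, plus the protospacer
#'   strand alleles `ref_ps`, `alt_ps`.
#' @export
intersect_snps_with_targets <- function(alignments, snp_table) {
  empty <- data.frame(snp_id = character(0), guide_id = character(0),
                      contig = character(0), start = integer(0),
                      strand = character(0), site_role = character(0),
                      position_class = character(0),
                      pam_relative_pos = integer(0), snp_in_pam = logical(0),
                      ref_ps = character(0), alt_ps = character(0),
                      stringsAsFactors = FALSE)
  if (nrow(alignments) == 0L || nrow(snp_table) == 0L) return(empty)
  rows <- list()
  for (i in seq_len(nrow(alignments))) {
    a <- alignments[i, ]
    if (a$strand == "+") {
      ps_span <- c(a$start, a$start + 19L)
      pam_span <- c(a$start + 20L, a$start + 22L)
    } else {
      ps_span <- c(a$start, a$start + 19L)
      pam_span <- c(a$start - 3L, a$start - 1L)
    }
    snps <- snp_table[snp_table$contig == a$contig &
                        ((snp_table$position >= ps_span[1] &
                            snp_table$position <= ps_span[2]) |
                           (snp_table$position >= pam_span[1] &
                              snp_table$position <= pam_span[2])), ,
                      drop = FALSE]
    if (nrow(snps) == 0L) next
    for (k in seq_len(nrow(snps))) {
      g <- snps$position[k]
      in_pam <- g >= pam_span[1] && g <= pam_span[2]
      if (in_pam) {
        # PAM base index 1..3 (N, G, G) in spacer orientation
        pam_idx <- if (a$strand == "+") g - a$start - 19L else a$start - g
        pos_class <- c("PAM_N", "PAM_G2", "PAM_G3")[pam_idx]
        pam_rel <- NA_integer_
      } else {
        pam_rel <- if (a$strand == "+") 21L - (g - a$start + 1L)
                   else g - a$start + 1L
        pos_class <- if (pam_rel <= 10L) "protospacer_proximal"
                     else "protospacer_distal"
      }
      # alleles on the protospacer strand
      ref_ps <- toupper(snps$ref[k]); alt_ps <- toupper(snps$alt[k])
      if (a$strand == "-") {
        ref_ps <- .complement[[ref_ps]]
        alt_ps <- .complement[[alt_ps]]
      }
      role <- switch(as.character(a$n_mismatches),
                     "0" = "on_target", "1" = "off_target_1mm",
                     "off_target_2mm")
      rows[[length(rows) + 1L]] <- data.frame(
        snp_id = snps$snp_id[k], guide_id = a$guide_id, contig = a$contig,
        start = a$start, strand = a$strand, site_role = role,
        position_class = pos_class, pam_relative_pos = pam_rel,
        snp_in_pam = in_pam, ref_ps = ref_ps, alt_ps = alt_ps,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify the effect of a SNP on a guide target site
#'
#' Deterministic case analysis on one SNP-guide pair:
#' \itemize{
#'   \item SNP at PAM position 2 or 3 (a required G): the minor allele
#'     breaks the canonical NGG motif -- `"pam_destroying"`.
#'   \item SNP at PAM position 1 (the N): any base keeps NGG valid --
#'     `"pam_neutral"`.
#'   \item SNP inside the protospacer of a single-mismatch off-target: if it
#'     overlaps the mismatch position and the minor allele (protospacer
#'     strand) equals the spacer base, the off-target gains perfect
#'     complementarity in minor-allele homozygotes --
#'     `"offtarget_to_ontarget"`; otherwise the site gains a mismatch --
#'     `"mm1_to_mm2"`.
#'   \item SNP inside an on-target protospacer: the minor allele creates a
#'     mismatch and reduces cutting -- `"efficiency_loss"`.
#' }
#'
#' @param pair one row of [intersect_snps_with_targets()] output.
#' @param alignment the matching alignment row (for mismatch positions and
#'   the spacer base at the SNP).
#' @param spacer the guide's 20-nt spacer.
#' @return category string.
#' @export
classify_snp_effect <- function(pair, alignment, spacer) {
  if (pair$snp_in_pam) {
    if (pair$position_class %in% c("PAM_G2", "PAM_G3")) return("pam_destroying")
    return("pam_neutral")
  }
  if (pair$site_role == "on_target") return("efficiency_loss")
  mm_pos <- as.integer(strsplit(alignment$mismatch_positions, ",")[[1]])
  spacer_base <- substr(spacer, 21L - pair$pam_relative_pos,
                        21L - pair$pam_relative_pos)
  if (pair$pam_relative_pos %in% mm_pos && pair$alt_ps == spacer_base)
    return("offtarget_to_ontarget")
  "mm1_to_mm2"
}

#' Classify all SNP-guide pairs
#'
#' Vectorized wrapper of [classify_snp_effect()] over an intersection table.
#'
#' @param pairs output of [intersect_snps_with_targets()].
#' @param alignments the alignment table the pairs were derived from.
#' @param guides guide library (`guide_id`, `spacer`).
#' @return `pairs` with an `effect_category` column.
#' @export
classify_snp_effects <- function(pairs, alignments, guides) {
  if (nrow(pairs) == 0L) {
    pairs$effect_category <- character(0)
    return(pairs)
  }
  akey <- paste(alignments$guide_id, alignments$contig, alignments$start,
                alignments$strand)
  pkey <- paste(pairs$guide_id, pairs$contig, pairs$start, pairs$strand)
  idx <- match(pkey, akey)
  if (anyNA(idx)) stop("pair without matching alignment row")
  pairs$effect_category <- vapply(seq_len(nrow(pairs)), function(i) {
    classify_snp_effect(pairs[i, ], alignments[idx[i], ],
                        guides$spacer[match(pairs$guide_id[i], guides$guide_id)])
  }, character(1))
  pairs
}

#' Genotype-LFC Pearson correlation
#'
#' Correlation between a guide's LFC and the SNP genotype dose (0 = AA,
#' 1 = AB, 2 = BB) across cell lines, on complete pairs. A positive
#' correlation means minor-allele carriers deplete less (lost cutting); a
#' negative one means they deplete more (gained cutting).
#'
#' @param lfc numeric vector across cell lines.
#' @param genotype integer vector (0/1/2), same cells; NA dropped pairwise.
#' @return Pearson r.
#' @export
genotype_lfc_correlation <- function(lfc, genotype) {
  ok <- stats::complete.cases(lfc, genotype)
  lfc <- lfc[ok]; genotype <- genotype[ok]
  if (length(lfc) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(genotype) == 0)
    stop("no allele variation across cell lines")
  if (stats::sd(lfc) == 0) stop("constant LFC")
  stats::cor(lfc, genotype)
}

#' Permutation null for a genotype-LFC correlation
#'
#' Permutes genotype labels across cell lines B times (seeded) and reports
#' the null correlations, an empirical two-sided p-value with the +1
#' correction, p = (1 + #\{|r_null| >= |r_obs|\}) / (B + 1), and tail calls
#' at a configurable null quantile.
#'
#' @param lfc,genotype as in [genotype_lfc_correlation()].
#' @param B number of permutations (default 100).
#' @param seed integer seed for reproducibility.
#' @param quantile_level null quantile for the tail calls (default 0.95).
#' @return list with `r_obs`, `r_null` (length B), `p_empirical`
#'   (two-sided), `call_positive` (r_obs above the upper one-sided null
#'   quantile), `call_negative` (below the lower), `quantile_level`.
#' @export
permutation_null <- function(lfc, genotype, B = 100L, seed = 1L,
                             quantile_level = 0.95) {
  ok <- stats::complete.cases(lfc, genotype)
  lfc <- lfc[ok]; genotype <- genotype[ok]
  r_obs <- genotype_lfc_correlation(lfc, genotype)
  if (B < 1L) stop("B must be >= 1")
  set.seed(seed)
  n <- length(lfc)
  perm <- matrix(0, nrow = n, ncol = B)
  for (b in seq_len(B)) perm[, b] <- genotype[sample.int(n)]
  r_null <- suppressWarnings(as.numeric(stats::cor(lfc, perm)))
  r_null[is.na(r_null)] <- 0
  p_emp <- (1 + sum(abs(r_null) >= abs(r_obs))) / (B + 1)
  hi <- stats::quantile(r_null, quantile_level, names = FALSE)
  lo <- stats::quantile(r_null, 1 - quantile_level, names = FALSE)
  list(r_obs = r_obs, r_null = r_null, p_empirical = p_emp,
       call_positive = r_obs > hi, call_negative = r_obs < lo,
       quantile_level = quantile_level)
}

#' Compare genotype-LFC correlations between PAM-proximal and distal SNPs
#'
#' Wilcoxon rank-sum comparison of the genotype-LFC correlations of
#' SNP-guide pairs with the SNP in the PAM-proximal protospacer region
#' (positions 1-10) against pairs with the SNP PAM-distal (11-20).
#' Proximal mismatches are poorly tolerated, so proximal correlations are
#' expected to be higher.
#'
#' @param pairs data.frame with columns `position_class` and `r`
#'   (genotype-LFC correlation per pair).
#' @return list with `proximal` and `distal` summaries (n, mean, median),
#'   `p_value` (one-sided, proximal greater), and the `wilcox` htest object;
#'   NA p when a stratum has fewer than 2 pairs.
#' @export
position_stratified_correlations <- function(pairs) {
  prox <- pairs$r[pairs$position_class == "protospacer_proximal"]
  dist <- pairs$r[pairs$position_class == "protospacer_distal"]
  summ <- function(v) list(n = length(v), mean = mean(v),
                           median = stats::median(v))
  if (length(prox) < 2L || length(dist) < 2L) {
    return(list(proximal = summ(prox), distal = summ(dist),
                p_value = NA_real_, wilcox = NULL))
  }
  wt <- stats::wilcox.test(prox, dist, alternative = "greater",
                           exact = length(prox) + length(dist) <= 20)
  list(proximal = summ(prox), distal = summ(dist),
       p_value = wt$p.value, wilcox = wt)
}
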