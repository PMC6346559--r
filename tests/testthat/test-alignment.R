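# Mismatch-tolerant alignment with NGG PAM filtering, annotation and
# guide/gene summaries.

SOX9_PROTO <- "GCACCTGGCTGACCGCCTCG"   # perfect-match target of guide A3
SOX10_PROTO <- "GCACCTGGCTGACGGCCTCG"  # its single-mismatch counterpart
B4_SPACER <- "GCTGGTACTTGTAGTCCGGG"
SOX8_PROTO <- "GCTGGTACTTGTAGTCGGGG"   # differs at PAM-relative position 4

test_that("a uniquely planted protospacer yields exactly one alignment", {
  set.seed(1)
  g <- random_seq(1000)
  proto <- random_seq(20)
  g <- plant_protospacer(g, proto, 301)
  aln <- find_alignments(c(chr1 = g), proto, max_mm = 0)
  expect_equal(nrow(aln), 1L)
  expect_equal(aln$start, 301L)
  expect_equal(aln$n_mismatches, 0L)
  expect_equal(aln$strand, "+")
  expect_match(aln$pam_seq, "^[ACGT]GG$")
})

test_that("paralog-pair mini-genome gives one perfect and one 1-mm hit", {
  set.seed(2)
  g <- random_seq(600)
  g <- plant_protospacer(g, SOX9_PROTO, 101)
  g <- plant_protospacer(g, SOX10_PROTO, 401)
  aln <- find_alignments(c(chr1 = g), SOX9_PROTO, max_mm = 2)
  expect_equal(sum(aln$n_mismatches == 0), 1L)
  expect_equal(sum(aln$n_mismatches == 1), 1L)
  mm <- aln[aln$n_mismatches == 1, ]
  expect_equal(mm$mismatch_positions, "7")
  expect_equal(mm$substitutions, "G>C")   # reference G, spacer C
})

test_that("mismatch_profile reports PAM-relative positions and substitutions", {
  expect_equal(mismatch_profile(SOX9_PROTO, SOX9_PROTO),
               list(positions = integer(0), substitutions = character(0)))
  prof <- mismatch_profile(SOX9_PROTO, SOX10_PROTO)
  expect_equal(prof$positions, 7L)
  expect_equal(prof$substitutions, "G>C")
  prof <- mismatch_profile(B4_SPACER, SOX8_PROTO)
  expect_equal(prof$positions, 4L)
  expect_equal(prof$substitutions, "G>C")
  # positions strictly increasing for multiple mismatches
  two <- mutate_pam_rel(SOX9_PROTO, c(18, 3))
  prof <- mismatch_profile(SOX9_PROTO, two)
  expect_equal(prof$positions, c(3L, 18L))
  expect_error(mismatch_profile("ACGT", SOX9_PROTO), "20 nt")
})

test_that("mismatch profile is invariant under joint reverse complement", {
  set.seed(8)
  for (rep in 1:10) {
    sp <- random_seq(20)
    pr <- mutate_pam_rel(sp, sample(1:20, sample(0:2, 1)))
    a <- mismatch_profile(sp, pr)
    b <- mismatch_profile(revcomp(sp), revcomp(pr))
    # reverse complement flips 5' indices i -> 21 - i, i.e. PAM-relative
    # positions p -> 21 - p
    expect_equal(sort(21L - a$positions), sort(b$positions))
    expect_equal(length(a$substitutions), length(b$substitutions))
  }
})

test_that("aligner equals the exhaustive window oracle on random genomes", {
  set.seed(99)
  for (rep in 1:8) {
    L <- sample(500:2000, 1)
    g <- random_seq(L)
    # plant a target and mutated variants so non-trivial hits exist
    proto <- random_seq(20)
    g <- plant_protospacer(g, proto, 51)
    g <- plant_protospacer(g, mutate_pam_rel(proto, 5), 151)
    g <- plant_protospacer(g, mutate_pam_rel(proto, c(4, 17)), 251)
    genome <- c(chrA = g, chrB = random_seq(400))
    for (mm in 0:2) {
      got <- find_alignments(genome, proto, max_mm = mm)
      want <- brute_force_align(genome, proto, mm)
      expect_equal(alignment_key(got), alignment_key(want))
    }
    # and for a fully random spacer (usually no hits)
    sp2 <- random_seq(20)
    got <- find_alignments(genome, sp2, max_mm = 2)
    want <- brute_force_align(genome, sp2, 2)
    expect_equal(alignment_key(got), alignment_key(want))
  }
})

test_that("minus-strand hits are found and reverse complement remaps them", {
  set.seed(12)
  proto <- random_seq(20)
  g <- random_seq(300)
  # embed the reverse complement: CCN + rc(proto) puts the site on -
  rc_site <- paste0("CCT", revcomp(proto))
  substr(g, 101, 123) <- rc_site
  aln <- find_alignments(c(chr1 = g), proto, max_mm = 0)
  expect_equal(aln$strand, "-")
  expect_equal(aln$start, 104L)
  expect_equal(aln$protospacer, proto)

  # reverse complementing the genome flips strands and remaps coordinates
  g2 <- revcomp(g)
  aln2 <- find_alignments(c(chr1 = g2), proto, max_mm = 0)
  L <- nchar(g)
  expect_equal(aln2$strand, "+")
  expect_equal(aln2$start, L - (aln$start + 19L) + 1L)
})

test_that("windows or PAMs containing N are excluded", {
  set.seed(13)
  proto <- random_seq(20)
  g <- plant_protospacer(random_seq(200), proto, 51)
  gN <- g
  substr(gN, 60, 60) <- "N"     # N inside the window
  expect_equal(nrow(find_alignments(c(c1 = gN), proto, max_mm = 2)), 0L)
  gP <- g
  substr(gP, 71, 71) <- "N"     # N in the PAM
  expect_equal(nrow(find_alignments(c(c1 = gP), proto, max_mm = 2)), 0L)
  expect_error(find_alignments(c(c1 = g), "ACGT"), "20 nt")
  expect_error(find_alignments(c(c1 = g), paste(rep("N", 20), collapse = "")),
               "A/C/G/T")
})

test_that("annotation marks >= 1 bp exon overlap as exonic", {
  aln <- data.frame(guide_id = "g", contig = "chr1", start = 100L,
                    strand = "+", n_mismatches = 0L, mismatch_positions = "",
                    substitutions = "", pam_seq = "AGG",
                    protospacer = strrep("A", 20), stringsAsFactors = FALSE)
  ann <- data.frame(contig = "chr1", start = c(50L, 119L, 200L),
                    end = c(90L, 130L, 300L),
                    gene_id = c("up", "boundary", "down"))
  out <- annotate_alignments(aln, ann)
  expect_equal(out$region, "exonic")       # 1 bp overlap at position 119
  expect_equal(out$region_genes, "boundary")
  out <- annotate_alignments(aln, ann[c(1, 3), ])
  expect_equal(out$region, "intergenic")
  # empty annotation: everything intergenic
  out <- annotate_alignments(aln, ann[0, ])
  expect_equal(out$region, "intergenic")
})

test_that("annotation agrees with a naive all-pairs interval oracle", {
  set.seed(21)
  aln <- data.frame(guide_id = "g", contig = "chr1",
                    start = sample(1:2000, 100), strand = "+",
                    n_mismatches = 0L, mismatch_positions = "",
                    substitutions = "", pam_seq = "AGG",
                    protospacer = strrep("A", 20), stringsAsFactors = FALSE)
  ann <- data.frame(contig = "chr1", start = sample(1:2000, 20))
  ann$end <- ann$start + sample(10:100, 20, replace = TRUE)
  ann$gene_id <- paste0("gene", 1:20)
  out <- annotate_alignments(aln, ann)
  for (i in seq_len(nrow(aln))) {
    hits <- ann$gene_id[ann$start <= aln$start[i] + 19L &
                          ann$end >= aln$start[i]]
    expect_equal(out$region[i],
                 if (length(hits) > 0) "exonic" else "intergenic")
    expect_equal(out$region_genes[i],
                 paste(sort(unique(hits)), collapse = ","))
  }
})

test_that("guide summaries count alignments and classify correctly", {
  mk <- function(n0, n1, n2) {
    k <- n0 + n1 + n2
    data.frame(guide_id = "g", contig = "chr1", start = seq_len(k) * 100L,
               strand = "+", n_mismatches = rep(c(0L, 1L, 2L), c(n0, n1, n2)),
               mismatch_positions = "", substitutions = "", pam_seq = "AGG",
               protospacer = strrep("A", 20), region = "intergenic",
               region_genes = "", stringsAsFactors = FALSE)
  }
  # no alignments at all: the "did not align anywhere" class
  s <- summarize_guide(mk(1, 0, 0)[0, ], guide_id = "lost")
  expect_equal(s$n_perfect, 0L)
  expect_equal(s$class, "no_target")

  s <- summarize_guide(mk(1, 0, 0))
  expect_true(s$is_clean)
  expect_equal(s$class, "clean_single")
  expect_true(summarize_guide(mk(1, 0, 0), clean_level = "2mm")$is_clean)

  s <- summarize_guide(mk(2, 3, 0))
  expect_equal(c(s$n_perfect, s$n_1mm, s$n_2mm), c(2L, 3L, 0L))
  expect_equal(s$class, "multi_target_with_offtargets")

  expect_equal(summarize_guide(mk(2, 0, 0))$class, "double_target")
  expect_true(summarize_guide(mk(2, 0, 0))$is_double_target)
  expect_equal(summarize_guide(mk(4, 0, 0))$class, "multi_target")
  expect_equal(summarize_guide(mk(1, 2, 0))$class, "single_mm_offtarget")
  expect_equal(summarize_guide(mk(1, 0, 3))$class, "clean_single")
  expect_equal(summarize_guide(mk(1, 0, 3), clean_level = "2mm")$class,
               "double_mm_only")

  mixed <- rbind(mk(1, 0, 0), within(mk(1, 0, 0), guide_id <- "other"))
  expect_error(summarize_guide(mixed), "single guide")
})

test_that("summaries are order-independent pure functions of the alignments", {
  set.seed(31)
  aln <- data.frame(guide_id = "g", contig = "chr1", start = 1:6 * 50L,
                    strand = "+", n_mismatches = c(0L, 1L, 2L, 0L, 1L, 1L),
                    mismatch_positions = "", substitutions = "",
                    pam_seq = "AGG", protospacer = strrep("A", 20),
                    region = "intergenic", region_genes = "",
                    stringsAsFactors = FALSE)
  s1 <- summarize_guide(aln)
  s2 <- summarize_guide(aln[sample(nrow(aln)), ])
  expect_equal(s1, s2)
})

test_that("gene_summary_table flags genes with no clean guides", {
  summaries <- data.frame(
    guide_id = c("a1", "a2", "a3", "a4", "b1", "b2"),
    n_perfect = c(1L, 1L, 1L, 1L, 2L, 2L),
    n_1mm = 0L, n_2mm = 0L, n_exonic_1mm = 0L,
    genes_hit_perfect = "", genes_hit_1mm = "",
    class = "x", is_clean = c(rep(TRUE, 4), FALSE, FALSE),
    is_double_target = FALSE, stringsAsFactors = FALSE)
  map <- data.frame(guide_id = c("a1", "a2", "a3", "a4", "b1", "b2"),
                    intended_gene = c(rep("GENE_A", 4), rep("GENE_B", 2)))
  tab <- gene_summary_table(summaries, map)
  expect_equal(tab$n_clean_guides[tab$gene_id == "GENE_A"], 4L)
  expect_false(tab$all_guides_multitarget[tab$gene_id == "GENE_A"])
  expect_equal(tab$n_clean_guides[tab$gene_id == "GENE_B"], 0L)
  expect_true(tab$all_guides_multitarget[tab$gene_id == "GENE_B"])
  expect_error(gene_summary_table(summaries, rbind(map, map[1, ])),
               "at most one")
})

test_that("gene flags equal recomputation from raw alignments", {
  set.seed(41)
  scr <- make_fixture("myl12_like", seed = 17, n_cells = 5)
  aln <- annotate_alignments(
    align_library(scr$design$genome, scr$design$guides),
    scr$design$annotation)
  summ <- summarize_guides(aln, guide_ids = scr$design$guides$guide_id)
  tab <- gene_summary_table(summ, scr$design$guides)
  for (g in tab$gene_id) {
    gids <- scr$design$guides$guide_id[
      !is.na(scr$design$guides$intended_gene) &
        scr$design$guides$intended_gene == g]
    clean <- vapply(gids, function(id) {
      a <- aln[aln$guide_id == id, ]
      sum(a$n_mismatches == 0) == 1 && sum(a$n_mismatches == 1) == 0
    }, TRUE)
    expect_equal(tab$all_guides_multitarget[tab$gene_id == g], !any(clean))
  }
})

test_that("apply_genotype substitutes alleles and recomputes alignments", {
  set.seed(51)
  proto <- random_seq(20)
  offtarget <- mutate_pam_rel(proto, 7)     # 1-mm off-target at position 7
  g <- random_seq(600)
  g <- plant_protospacer(g, proto, 101)
  g <- plant_protospacer(g, offtarget, 301)
  genome <- c(chr1 = g)
  guides <- data.frame(guide_id = "gd", spacer = proto,
                       intended_gene = "X", stringsAsFactors = FALSE)

  # SNP at the off-target's mismatch position; minor allele = spacer base
  pos_mm <- 301L + 20L - 7L
  ref <- substr(g, pos_mm, pos_mm)
  alt <- substr(proto, 21L - 7L, 21L - 7L)
  snp_mm <- data.frame(snp_id = "s1", contig = "chr1", position = pos_mm,
                       ref = ref, alt = alt, stringsAsFactors = FALSE)
  # reference genotype everywhere: unchanged
  a0 <- apply_genotype(genome, guides, snp_mm, 0L)
  base <- align_library(genome, guides)
  expect_equal(alignment_key(a0), alignment_key(base))
  # homozygous minor: the off-target becomes a perfect on-target
  a2 <- apply_genotype(genome, guides, snp_mm, 2L)
  expect_equal(sort(a2$n_mismatches), c(0L, 0L))

  # SNP destroying PAM position 2 of the primary site removes it
  pam2 <- 101L + 21L
  snp_pam <- data.frame(snp_id = "s2", contig = "chr1", position = pam2,
                        ref = substr(g, pam2, pam2), alt = "A",
                        stringsAsFactors = FALSE)
  a2 <- apply_genotype(genome, guides, snp_pam, 2L)
  expect_false(101L %in% a2$start)
  # heterozygous: best haplotype keeps the site, flagged heterozygous
  a1 <- apply_genotype(genome, guides, snp_pam, 1L)
  expect_true(101L %in% a1$start)
  expect_true(a1$heterozygous[a1$start == 101L])

  bad <- within(snp_pam, ref <- "N")
  expect_error(apply_genotype(genome, guides, bad, 2L), "disagrees")
})
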