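# Named fixtures: small synthetic screens reproducing the structures that
# drive each bias analysis, plus direct scenario generators for the
# statistical operations.

#' Build a named synthetic-screen fixture
#'
#' Each fixture is a deterministic input bundle (design + simulated screen)
#' with a documented planted structure:
#' \describe{
#'   \item{myl12_like}{Two non-essential paralogs PARA_A/PARA_B sharing two
#'     double-target guides; two of PARA_B's own guides also hit pseudogene
#'     copies. A redundancy partner (gene G01) is expressed in 60\% of
#'     cells; the digenic A+B knockout is lethal (interaction -1) exactly
#'     where the partner is not expressed -- context-dependent synthetic
#'     lethality that an additive model cannot capture.}
#'   \item{sox9_sox10_like}{Genes CONF_X and DEP_Y are each essential
#'     exactly where expressed, in disjoint cell subsets. Three of CONF_X's
#'     four guides carry a well-tolerated PAM-distal (position 20)
#'     single-mismatch off-target in DEP_Y's exon, so CONF_X additionally
#'     looks essential in the DEP_Y-expressing "lineage" subset where
#'     CONF_X itself is silent -- a spurious lineage dependency.}
#'   \item{tmed7_ticam2_like}{A readthrough locus RT1_A / RT1_B / RT1_FUS
#'     with the guide incidence of a fusion transcript: A-guides cut A and
#'     the fusion, three B-guides cut B and the fusion, one B-guide cuts B
#'     only. Knockout effects are additive with planted per-gene scores.}
#'   \item{snp_pam_like}{Essential genes carrying planted SNPs: one guide
#'     with a PAM-G2-destroying SNP (minor-allele homozygotes lose
#'     cutting), one guide whose intolerant single-mismatch off-target in
#'     an essential gene's exon gains perfect complementarity on the minor
#'     allele, and protospacer SNPs in PAM-proximal and PAM-distal
#'     positions of on-targets.}
#'   \item{double_mm_like}{Guides with five tolerated double-mismatch
#'     off-targets (mismatches at positions 19 and 20) next to clean guides
#'     for the same genes, over a background of clean-guide-only genes for
#'     the null delta band.}
#' }
#'
#' @param name fixture name.
#' @param seed integer seed (default 1).
#' @param n_cells number of cell lines (default 100).
#' @return `synthetic_screen` (with `$design` inside).
#' @export
make_fixture <- function(name = c("myl12_like", "sox9_sox10_like",
                                  "tmed7_ticam2_like", "snp_pam_like",
                                  "double_mm_like"),
                         seed = 1L, n_cells = 100L) {
  name <- match.arg(name)
  switch(name,
         myl12_like = .fixture_myl12(seed, n_cells),
         sox9_sox10_like = .fixture_sox(seed, n_cells),
         tmed7_ticam2_like = .fixture_readthrough(seed, n_cells),
         snp_pam_like = .fixture_snp(seed, n_cells),
         double_mm_like = .fixture_double_mm(seed, n_cells))
}

.fixture_myl12 <- function(seed, n_cells) {
  cfg <- sim_config(
    seed = seed, n_cells = n_cells,
    genome = genome_spec(
      background_genes = 10L,
      paralog_families = list(
        list(genes = c("PARA_A", "PARA_B"), cross_guides = 2L,
             mismatch_positions = list(integer(0), integer(0)))),
      extra_copies = data.frame(gene_id = "PARA_B", guide_num = c(1L, 2L),
                                n_extra = c(1L, 2L), coding = TRUE),
      n_ntc = 5L))
  design <- generate_genome(cfg)
  genes <- design$genes$gene_id
  cells <- paste0("cell", seq_len(n_cells))

  set.seed(seed + 100L)
  expression <- matrix(pmax(0, stats::rnorm(length(genes) * n_cells, 6, 1)),
                       length(genes), n_cells,
                       dimnames = list(genes, cells))
  expression[!design$genes$functional, ] <- 0
  # background gene G01 plays the redundancy partner: silent in 40% of cells
  red_off <- sample(cells, round(0.4 * n_cells))
  expression["G01", red_off] <- 0

  essentiality <- matrix(0, length(genes), n_cells,
                         dimnames = list(genes, cells))
  ess <- c("G02", "G03")                    # reference essentials
  essentiality[ess, ] <- -1

  interactions <- data.frame(gene_a = "PARA_A", gene_b = "PARA_B",
                             strength = -1, condition_gene = "G01",
                             condition_threshold = 1,
                             stringsAsFactors = FALSE)
  simulate_screen(design, expression = expression,
                  essentiality = essentiality, interactions = interactions)
}

.fixture_sox <- function(seed, n_cells) {
  cfg <- sim_config(
    seed = seed, n_cells = n_cells,
    genome = genome_spec(
      background_genes = 12L,
      paralog_families = list(
        list(genes = c("CONF_X", "DEP_Y"), cross_guides = 3L,
             mismatch_positions = list(20L, 20L, 20L))),
      n_ntc = 5L))
  design <- generate_genome(cfg)
  genes <- design$genes$gene_id
  cells <- paste0("cell", seq_len(n_cells))

  set.seed(seed + 100L)
  expression <- matrix(pmax(0, stats::rnorm(length(genes) * n_cells, 6, 1)),
                       length(genes), n_cells,
                       dimnames = list(genes, cells))
  lineage <- sample(cells, round(0.3 * n_cells))   # DEP_Y-expressing subset
  other <- setdiff(cells, lineage)
  x_on <- sample(other, round(0.4 * n_cells))      # CONF_X expressed here
  expression["DEP_Y", ] <- 0; expression["DEP_Y", lineage] <- 8
  expression["CONF_X", ] <- 0; expression["CONF_X", x_on] <- 8

  essentiality <- matrix(0, length(genes), n_cells,
                         dimnames = list(genes, cells))
  ess <- paste0("G", sprintf("%02d", 1:3))
  essentiality[ess, ] <- -1                        # reference essentials
  essentiality["DEP_Y", lineage] <- -1             # essential where expressed
  essentiality["CONF_X", x_on] <- -1               # essential where expressed

  scr <- simulate_screen(design, expression = expression,
                         essentiality = essentiality)
  scr$lineage_cells <- lineage
  scr
}

.fixture_readthrough <- function(seed, n_cells) {
  cfg <- sim_config(seed = seed, n_cells = n_cells,
                    genome = genome_spec(background_genes = 8L,
                                         readthroughs = 1L, n_ntc = 5L))
  design <- generate_genome(cfg)
  genes <- design$genes$gene_id
  cells <- paste0("cell", seq_len(n_cells))
  set.seed(seed + 100L)
  essentiality <- matrix(0, length(genes), n_cells,
                         dimnames = list(genes, cells))
  essentiality[c("G01", "G02"), ] <- -1
  # planted additive per-cell scores for the readthrough triplet
  for (g in c("RT1_A", "RT1_B", "RT1_FUS"))
    essentiality[g, ] <- stats::rnorm(n_cells, -0.4, 0.2)
  simulate_screen(design, essentiality = essentiality)
}

.fixture_snp <- function(seed, n_cells) {
  cfg <- sim_config(
    seed = seed, n_cells = n_cells,
    genome = genome_spec(
      background_genes = 24L,
      paralog_families = list(
        # intolerant (position 5) single-mismatch off-target of SNP_HOST_g4
        list(genes = c("SNP_HOST", "SNP_OFF"), cross_guides = 1L,
             mismatch_positions = list(5L))),
      n_ntc = 5L))
  design <- generate_genome(cfg)
  # SNPs: PAM-G2 destroyer on an essential gene's guide; off-target gains
  # an on-target (mm_match); protospacer SNPs proximal (pos 3) and distal
  # (pos 18) on essential genes' on-targets
  spec <- data.frame(
    guide_id = c("G01_g1", "SNP_HOST_g4",
                 paste0("G", sprintf("%02d", 2:9), "_g1"),
                 paste0("G", sprintf("%02d", 10:17), "_g1")),
    site_index = c(1L, 2L, rep(1L, 16L)),
    class = c("pam_g2", "mm_match", rep("protospacer", 16L)),
    pam_rel_pos = c(NA, NA, rep(3L, 8L), rep(18L, 8L)),
    stringsAsFactors = FALSE)
  design <- plant_snps(design, spec)

  genes <- design$genes$gene_id
  cells <- paste0("cell", seq_len(n_cells))
  essentiality <- matrix(0, length(genes), n_cells,
                         dimnames = list(genes, cells))
  essentiality[paste0("G", sprintf("%02d", 1:17)), ] <- -1
  essentiality["SNP_OFF", ] <- -1   # the gained on-target cuts an essential
  simulate_screen(design, essentiality = essentiality)
}

.fixture_double_mm <- function(seed, n_cells) {
  # five genes with one problematic guide each (5 double-mismatch
  # off-targets at positions 19+20 in separate host genes) + clean-guide
  # background for the null band
  fams <- lapply(1:5, function(i)
    list(genes = c(sprintf("DMM_%d", i), sprintf("DMMHOST_%d", i)),
         cross_guides = 1L,
         mismatch_positions = list(c(19L, 20L))))
  cfg <- sim_config(seed = seed, n_cells = n_cells,
                    genome = genome_spec(background_genes = 30L,
                                         gene_length = 1000L,
                                         paralog_families = fams,
                                         n_ntc = 5L))
  design <- generate_genome(cfg)
  # add 4 more double-mismatch copies for each problematic guide
  # (unannotated DNA: pure cleavage toxicity)
  seqs <- as.character(design$genome)
  extra_sites <- list()
  segs <- character(0)
  cursor <- nchar(seqs[["chr1"]])
  set.seed(design$config$seed + 7L)
  for (i in 1:5) {
    gid <- sprintf("DMM_%d_g%d", i, design$config$genome$guides_per_gene)
    srows <- design$sites[design$sites$guide_id == gid, ]
    copy <- srows$protospacer[srows$n_mismatches == 2L][1]
    for (j in 1:4) {
      region <- .plant_site(random_dna(83L), 31L, copy)
      segs[[length(segs) + 1L]] <- region$body
      extra_sites[[length(extra_sites) + 1L]] <- data.frame(
        guide_id = gid, contig = "chr1", start = cursor + 31L,
        strand = "+", protospacer = copy, pam_seq = "TGG",
        mismatch_positions = "19,20", n_mismatches = 2L,
        stringsAsFactors = FALSE)
      cursor <- cursor + 83L
    }
  }
  genome <- Biostrings::DNAStringSet(paste(c(seqs[["chr1"]], segs),
                                           collapse = ""))
  names(genome) <- "chr1"
  design$genome <- genome
  design$sites <- rbind(design$sites, do.call(rbind, extra_sites))
  simulate_screen(design)
}

#' Simulate guide-of-interest vs clean-guide LFCs (delta-model scenario)
#'
#' Generates the data structure the delta coefficient is fit on: per-cell
#' gene knockout effects shared by all guides, Gaussian noise, and a
#' planted offset on the guide of interest.
#'
#' @param n_cells number of cell lines.
#' @param n_clean number of clean guides.
#' @param effect planted offset of the guide of interest (default -0.5, a
#'   substantial off-target effect).
#' @param cell_mean,cell_sd distribution of per-cell knockout effects.
#' @param sigma noise sd.
#' @param seed integer seed.
#' @return matrix n_cells x (1 + n_clean); column 1 is the guide of
#'   interest. Attribute `"effect"` records the planted offset.
#' @export
simulate_delta_scenario <- function(n_cells = 100L, n_clean = 3L,
                                    effect = -0.5, cell_mean = -0.3,
                                    cell_sd = 0.3, sigma = 0.1, seed = 1L) {
  set.seed(seed)
  b <- stats::rnorm(n_cells, cell_mean, cell_sd)
  y <- matrix(stats::rnorm(n_cells * (n_clean + 1L), 0, sigma),
              n_cells, n_clean + 1L) + b
  y[, 1L] <- y[, 1L] + effect
  colnames(y) <- c("guide_of_interest", paste0("clean", seq_len(n_clean)))
  attr(y, "effect") <- effect
  y
}

#' Simulate pooled LFCs for a digenic additivity scenario
#'
#' Three guide classes (A-only, B-only, double-target AB) with additive
#' class means plus an optional synthetic-lethal interaction applied in a
#' fraction of cells, and iid Gaussian noise.
#'
#' @param n_cells number of cell lines.
#' @param guides_per_class guides per class.
#' @param beta_A,beta_B single-knockout effects.
#' @param interaction interaction effect added to the AB class (default 0 =
#'   additive null).
#' @param interaction_fraction fraction of cells in which the interaction
#'   is active (default 0.4, cells lacking the redundant partner).
#' @param sigma noise sd.
#' @param seed integer seed.
#' @return list `y_A`, `y_B`, `y_AB` (pooled guide x cell observations) and
#'   `cluster` (list of cell ids per observation).
#' @export
simulate_paralog_knockout <- function(n_cells = 100L, guides_per_class = 2L,
                                      beta_A = 0, beta_B = 0,
                                      interaction = 0,
                                      interaction_fraction = 0.4,
                                      sigma = 0.1, seed = 1L) {
  set.seed(seed)
  g <- guides_per_class
  cells <- rep(seq_len(n_cells), each = g)
  i_c <- rep(0, n_cells)
  if (interaction != 0) {
    n_int <- round(interaction_fraction * n_cells)
    i_c[sample.int(n_cells, n_int)] <- interaction
  }
  noise <- function() stats::rnorm(n_cells * g, 0, sigma)
  list(y_A = beta_A + noise(),
       y_B = beta_B + noise(),
       y_AB = beta_A + beta_B + i_c[cells] + noise(),
       cluster = list(A = cells, B = cells, AB = cells))
}

#' Simulate a multi-target toxicity screen
#'
#' Guides targeting non-essential loci with 1..`n_max` alignments; LFC =
#' a_c * tau(n) + noise, where tau is the quadratic cleavage-toxicity
#' curve and a_c the per-cell Cas9 activity. For
#' `kind = "off_target_1mm"` every guide has one perfect alignment and the
#' count varies in the single-mismatch alignments, whose per-cut toxicity
#' is discounted by the mean PAM-distal tolerance weight.
#'
#' @param n_guides,n_cells problem size.
#' @param n_max maximum alignment count.
#' @param kind `"on_target"` or `"off_target_1mm"`.
#' @param t1,t2 toxicity coefficients.
#' @param cas9_range per-cell activity range.
#' @param sigma noise sd.
#' @param seed integer seed.
#' @return list with `lfc` (guides x cells), `summaries` (per-guide
#'   alignment summary), `a_c`, and `implied_coef(cell)` -- a function
#'   returning the true (intercept, linear, quadratic) polynomial
#'   coefficients of mean LFC on alignment count for a cell line.
#' @export
simulate_toxicity_screen <- function(n_guides = 2000L, n_cells = 10L,
                                     n_max = 8L,
                                     kind = c("on_target", "off_target_1mm"),
                                     t1 = -0.05, t2 = -0.01,
                                     cas9_range = c(0.2, 1), sigma = 0.1,
                                     seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  probs <- 0.55^(seq_len(n_max) - 1L)
  n <- sample(seq_len(n_max), n_guides, replace = TRUE,
              prob = probs / sum(probs))
  a_c <- stats::runif(n_cells, cas9_range[1], cas9_range[2])
  cells <- paste0("cell", seq_len(n_cells))
  names(a_c) <- cells
  disc <- if (kind == "on_target") 1 else 0.5   # tolerance discount per cut
  cuts <- if (kind == "on_target") n else 1 + disc * (n - 1L)
  tau <- function(N) t1 * pmax(N - 1, 0) + t2 * pmax(N - 1, 0)^2
  lfc <- outer(tau(cuts), a_c) +
    matrix(stats::rnorm(n_guides * n_cells, 0, sigma), n_guides, n_cells)
  gid <- sprintf("guide%04d", seq_len(n_guides))
  dimnames(lfc) <- list(gid, cells)
  summaries <- data.frame(
    guide_id = gid,
    n_perfect = if (kind == "on_target") n else 1L,
    n_1mm = if (kind == "on_target") 0L else n - 1L,
    n_2mm = 0L, stringsAsFactors = FALSE)
  implied_coef <- function(cell) {
    a <- a_c[cell]
    if (kind == "on_target") {
      # a * tau(n) expanded in n
      c(a * (t2 - t1), a * (t1 - 2 * t2), a * t2)
    } else {
      # a * tau(1 + disc*(m)) expanded in m = n_1mm
      c(0, a * t1 * disc, a * t2 * disc^2)
    }
  }
  list(lfc = lfc, summaries = summaries, a_c = a_c,
       implied_coef = implied_coef)
}
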