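# Synthetic pooled CRISPR screens with planted ground truth.
#
# The generator builds a small genome in which every guide target site is
# planted explicitly (random 20-mers followed by a TGG PAM), so the true
# on/off-target structure of every guide is known. The screen model is
#
#   y_gc = a_c * tau(N_gc) + sum_G d_Gc * e_Gc + sum_(A,B) d_A d_B i_ABc
#          + gamma_c * (CN_gc - 1) + eps,
#
# with per-site cutting efficiency eta = prod of position-specific mismatch
# tolerance weights w(pos) (1 for a perfect site, 0 when the PAM is broken),
# N_gc the guide's expected cut count, knockout dosage
# d_Gc = 1 - prod_(sites of g cutting G) (1 - eta), and cleavage toxicity
# tau(N) = t1 * max(N - 1, 0) + t2 * max(N - 1, 0)^2 (no cuts, no toxicity).
# Non-targeting controls receive noise only.

.BASES <- c("A", "C", "G", "T")
.CYCLE <- c(A = "C", C = "G", G = "T", T = "A")

random_dna <- function(n) paste(sample(.BASES, n, replace = TRUE), collapse = "")

#' Default position-specific mismatch tolerance weights
#'
#' Tolerance of a single spacer-protospacer mismatch by PAM-relative
#' position: low (0.05) in the PAM-proximal seed (positions 1-10), ramping
#' from 0.2 to 0.8 over positions 11-19, and maximal (0.9) at position 20.
#' Double mismatches multiply their two weights.
#'
#' @return numeric vector of length 20.
#' @export
default_tolerance_weights <- function() {
  c(rep(0.05, 10), seq(0.2, 0.8, length.out = 9), 0.9)
}

#' Simulation configuration
#'
#' Bundles the effect parameters, noise level and genome specification of a
#' synthetic screen. Defaults encode the study conditions used throughout
#' the package's analyses: 100 cell lines, Gaussian LFC noise sd 0.1,
#' toxicity coefficients t1 = -0.05 and t2 = -0.01, cell-specific Cas9
#' activity uniform on [0.2, 1], essential-gene knockout effect -1 on a
#' fifth of the functional genes.
#'
#' @param seed mandatory integer seed.
#' @param n_cells number of cell lines.
#' @param sigma LFC noise standard deviation.
#' @param t1,t2 linear and quadratic toxicity coefficients.
#' @param w mismatch tolerance weights by PAM-relative position (length 20).
#' @param cas9_range range of per-cell Cas9 activity a_c.
#' @param cn_slope_range range of the per-cell copy-number effect slope.
#' @param essential_fraction fraction of functional genes that are
#'   broadly essential.
#' @param essential_effect knockout effect of an essential gene.
#' @param expression_mean,expression_sd log2(rpkm+1)-scale expression of
#'   expressed genes.
#' @param maf default minor allele frequency for planted SNPs.
#' @param genome genome specification from [genome_spec()].
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed, n_cells = 100L, sigma = 0.1,
                       t1 = -0.05, t2 = -0.01,
                       w = default_tolerance_weights(),
                       cas9_range = c(0.2, 1),
                       cn_slope_range = c(-0.5, -0.1),
                       essential_fraction = 0.2, essential_effect = -1,
                       expression_mean = 6, expression_sd = 1,
                       maf = 0.3, genome = genome_spec()) {
  if (missing(seed)) stop("'seed' is mandatory")
  stopifnot(length(w) == 20L, all(w >= 0 & w <= 1),
            essential_fraction >= 0, essential_fraction <= 1,
            sigma >= 0, n_cells >= 2)
  structure(list(seed = as.integer(seed), n_cells = as.integer(n_cells),
                 sigma = sigma, t1 = t1, t2 = t2, w = w,
                 cas9_range = cas9_range, cn_slope_range = cn_slope_range,
                 essential_fraction = essential_fraction,
                 essential_effect = essential_effect,
                 expression_mean = expression_mean,
                 expression_sd = expression_sd,
                 maf = maf, genome = genome),
            class = "sim_config")
}

#' Genome specification for the synthetic generator
#'
#' @param background_genes number of ordinary single-exon genes, each with
#'   `guides_per_gene` clean guides.
#' @param gene_length gene body length (bp); must accommodate all planted
#'   sites.
#' @param guides_per_gene guides designed per gene (default 4, the Avana
#'   design density).
#' @param gap intergenic gap (bp).
#' @param paralog_families list; each element
#'   `list(genes = c(a, b), cross_guides = k, mismatch_positions = list(...))`
#'   copies the last `k` guide sites of gene `a` into gene `b`'s body with
#'   substitutions at the given PAM-relative positions (an empty integer
#'   vector plants a perfect copy, i.e. a double-target guide).
#' @param extra_copies data.frame (`gene_id`, `guide_num`, `n_extra`,
#'   `coding`) planting extra perfect copies of a guide's site, in a
#'   pseudogene exon (`coding = TRUE`) or unannotated DNA.
#' @param readthroughs number of readthrough constructs; each adds genes
#'   `RT<i>_A`, `RT<i>_B` and `RT<i>_FUS`, with the fusion annotation
#'   covering all of A and all but the last guide site of B.
#' @param n_ntc number of non-targeting control guides.
#' @return list of class `genome_spec`.
#' @export
genome_spec <- function(background_genes = 20L, gene_length = 800L,
                        guides_per_gene = 4L, gap = 200L,
                        paralog_families = list(),
                        extra_copies = NULL,
                        readthroughs = 0L, n_ntc = 10L) {
  structure(list(background_genes = as.integer(background_genes),
                 gene_length = as.integer(gene_length),
                 guides_per_gene = as.integer(guides_per_gene),
                 gap = as.integer(gap),
                 paralog_families = paralog_families,
                 extra_copies = extra_copies,
                 readthroughs = as.integer(readthroughs),
                 n_ntc = as.integer(n_ntc)),
            class = "genome_spec")
}

# plant a 23-mer (20-nt protospacer + TGG PAM) at a relative offset in a
# gene body; returns the updated body and the protospacer string
.plant_site <- function(body, offset, protospacer = NULL) {
  if (is.null(protospacer))
    protospacer <- random_dna(20L)
  stopifnot(offset + 22L <= nchar(body))
  substr(body, offset, offset + 19L) <- protospacer
  substr(body, offset + 20L, offset + 22L) <- "TGG"
  list(body = body, protospacer = protospacer)
}

# substitute bases of a protospacer at PAM-relative positions
.mutate_at <- function(protospacer, pam_rel_pos) {
  for (p in pam_rel_pos) {
    i <- 21L - p
    substr(protospacer, i, i) <- .CYCLE[[substr(protospacer, i, i)]]
  }
  protospacer
}

#' Generate a synthetic genome, guide library and annotation
#'
#' Builds a single-contig genome with planted guide target sites according
#' to the genome specification in `config`, together with the guide
#' library, exon annotation, gene table (with functional flags;
#' pseudogenes are non-functional), paralog pair list and the planted site
#' table (the alignment ground truth).
#'
#' @param config a [sim_config()].
#' @return list of class `screen_design` with elements `genome`
#'   (DNAStringSet), `annotation` (exon data.frame), `genes`, `guides`,
#'   `sites`, `paralog_pairs`, `snps` (empty; see [plant_snps()]) and
#'   `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gs <- config$genome
  set.seed(config$seed)
  gpg <- gs$guides_per_gene
  site_pitch <- 80L
  # cross sites (paralog copies) live after a gene's own sites
  max_cross <- if (length(gs$paralog_families) > 0L)
    max(vapply(gs$paralog_families, function(f) f$cross_guides, 1L)) else 0L
  need <- 60L + (gpg + max_cross) * site_pitch + 40L
  if (gs$gene_length < need)
    stop(sprintf("gene_length %d too short for planted sites (need >= %d)",
                 gs$gene_length, need))

  genes <- list(); guides <- list(); sites <- list(); annotation <- list()
  segments <- character(0)
  cursor <- 0L  # last written forward coordinate

  add_segment <- function(seq) {
    segments[[length(segments) + 1L]] <<- seq
    start <- cursor + 1L
    cursor <<- cursor + nchar(seq)
    start
  }
  site_offset <- function(i) 60L + (i - 1L) * site_pitch

  add_gene <- function(gene_id, n_guides = gpg, functional = TRUE,
                       annotate = TRUE) {
    body <- random_dna(gs$gene_length)
    protos <- character(n_guides)
    for (i in seq_len(n_guides)) {
      planted <- .plant_site(body, site_offset(i))
      body <- planted$body
      protos[i] <- planted$protospacer
    }
    add_segment(random_dna(gs$gap))
    start <- add_segment(body)
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = gene_id, start = start, end = start + gs$gene_length - 1L,
      functional = functional, stringsAsFactors = FALSE)
    if (annotate)
      annotation[[length(annotation) + 1L]] <<- data.frame(
        contig = "chr1", start = start, end = start + gs$gene_length - 1L,
        gene_id = gene_id, stringsAsFactors = FALSE)
    for (i in seq_len(n_guides)) {
      gid <- sprintf("%s_g%d", gene_id, i)
      guides[[length(guides) + 1L]] <<- data.frame(
        guide_id = gid, spacer = protos[i], intended_gene = gene_id,
        stringsAsFactors = FALSE)
      sites[[length(sites) + 1L]] <<- data.frame(
        guide_id = gid, contig = "chr1",
        start = start + site_offset(i) - 1L, strand = "+",
        protospacer = protos[i], pam_seq = "TGG",
        mismatch_positions = "", n_mismatches = 0L,
        stringsAsFactors = FALSE)
    }
    start
  }

  for (i in seq_len(gs$background_genes))
    add_gene(sprintf("G%02d", i))

  # paralog families: member a's last cross_guides guides get a (possibly
  # mismatched) site copy planted into member b's body
  paralog_pairs <- list()
  for (fam in gs$paralog_families) {
    a <- fam$genes[1]; b <- fam$genes[2]
    add_gene(a)
    add_gene(b)
    paralog_pairs[[length(paralog_pairs) + 1L]] <-
      data.frame(gene_a = a, gene_b = b, stringsAsFactors = FALSE)
    b_start <- genes[[length(genes)]]$start
    for (k in seq_len(fam$cross_guides)) {
      guide_num <- gpg - fam$cross_guides + k
      gid <- sprintf("%s_g%d", a, guide_num)
      srow <- which(vapply(sites, function(s) s$guide_id, "") == gid)
      proto <- sites[[srow]]$protospacer
      mmpos <- sort(fam$mismatch_positions[[k]])
      copy <- .mutate_at(proto, mmpos)
      off <- site_offset(gpg + k)
      # overwrite the reserved area of b's body in the assembled segment
      seg_idx <- length(segments)
      planted <- .plant_site(segments[[seg_idx]], off, copy)
      segments[[seg_idx]] <- planted$body
      sites[[length(sites) + 1L]] <- data.frame(
        guide_id = gid, contig = "chr1", start = b_start + off - 1L,
        strand = "+", protospacer = copy, pam_seq = "TGG",
        mismatch_positions = paste(mmpos, collapse = ","),
        n_mismatches = length(mmpos), stringsAsFactors = FALSE)
    }
  }

  # readthrough constructs: fusion annotation covers A and all but the
  # last guide site of B
  for (r in seq_len(gs$readthroughs)) {
    a <- sprintf("RT%d_A", r); b <- sprintf("RT%d_B", r)
    fus <- sprintf("RT%d_FUS", r)
    a_start <- add_gene(a)
    b_start <- add_gene(b)
    fus_end <- b_start + site_offset(gpg) - 2L  # before B's last site
    genes[[length(genes) + 1L]] <- data.frame(
      gene_id = fus, start = a_start, end = fus_end, functional = TRUE,
      stringsAsFactors = FALSE)
    annotation[[length(annotation) + 1L]] <- data.frame(
      contig = "chr1", start = a_start, end = fus_end, gene_id = fus,
      stringsAsFactors = FALSE)
  }

  # extra perfect copies (pseudogene exons or unannotated DNA)
  ec <- gs$extra_copies
  if (!is.null(ec)) {
    for (i in seq_len(nrow(ec))) {
      gid <- sprintf("%s_g%d", ec$gene_id[i], ec$guide_num[i])
      srow <- which(vapply(sites, function(s) s$guide_id[1], "") == gid)[1]
      proto <- sites[[srow]]$protospacer
      for (j in seq_len(ec$n_extra[i])) {
        region <- .plant_site(random_dna(83L), 31L, proto)
        start <- add_segment(random_dna(gs$gap))
        start <- add_segment(region$body)
        if (isTRUE(ec$coding[i])) {
          psg <- sprintf("PSG_%s_%d", gid, j)
          genes[[length(genes) + 1L]] <- data.frame(
            gene_id = psg, start = start, end = start + 82L,
            functional = FALSE, stringsAsFactors = FALSE)
          annotation[[length(annotation) + 1L]] <- data.frame(
            contig = "chr1", start = start, end = start + 82L,
            gene_id = psg, stringsAsFactors = FALSE)
        }
        sites[[length(sites) + 1L]] <- data.frame(
          guide_id = gid, contig = "chr1", start = start + 30L,
          strand = "+", protospacer = proto, pam_seq = "TGG",
          mismatch_positions = "", n_mismatches = 0L,
          stringsAsFactors = FALSE)
      }
    }
  }

  add_segment(random_dna(gs$gap))
  for (i in seq_len(gs$n_ntc)) {
    guides[[length(guides) + 1L]] <- data.frame(
      guide_id = sprintf("NTC_%02d", i), spacer = random_dna(20L),
      intended_gene = NA_character_, stringsAsFactors = FALSE)
  }

  genome <- Biostrings::DNAStringSet(paste(segments, collapse = ""))
  names(genome) <- "chr1"
  structure(list(genome = genome,
                 annotation = do.call(rbind, annotation),
                 genes = do.call(rbind, genes),
                 guides = do.call(rbind, guides),
                 sites = do.call(rbind, sites),
                 paralog_pairs = if (length(paralog_pairs) > 0L)
                   do.call(rbind, paralog_pairs) else
                     data.frame(gene_a = character(0), gene_b = character(0)),
                 snps = data.frame(),
                 config = config),
            class = "screen_design")
}

#' Plant SNPs at guide target sites
#'
#' Adds biallelic SNPs to a screen design at specified positions of planted
#' sites (all planted sites are on the plus strand, so forward-strand and
#' protospacer-strand alleles coincide).
#'
#' @param design a `screen_design`.
#' @param spec data.frame with columns `guide_id`, `site_index` (which of
#'   the guide's sites, 1 = primary), `class` (one of `"protospacer"`,
#'   `"pam_n"`, `"pam_g2"`, `"pam_g3"`, `"mm_match"` -- the last places the
#'   SNP at the site's first mismatch position with the minor allele equal
#'   to the spacer base, turning the off-target into an on-target), and for
#'   `class = "protospacer"` a `pam_rel_pos` column; optional `maf`.
#' @return the design with rows appended to `design$snps` (`snp_id`,
#'   `contig`, `position`, `ref`, `alt`, `maf`, `class`, `guide_id`).
#' @export
plant_snps <- function(design, spec) {
  stopifnot(inherits(design, "screen_design"))
  seqs <- as.character(design$genome)
  rows <- list()
  for (i in seq_len(nrow(spec))) {
    gid <- spec$guide_id[i]
    ssub <- design$sites[design$sites$guide_id == gid, , drop = FALSE]
    site <- ssub[spec$site_index[i], ]
    spacer <- design$guides$spacer[design$guides$guide_id == gid]
    cls <- spec$class[i]
    if (cls == "protospacer" || cls == "mm_match") {
      p <- if (cls == "mm_match") {
        as.integer(strsplit(site$mismatch_positions, ",")[[1]])[1]
      } else spec$pam_rel_pos[i]
      pos <- site$start + 20L - p
      ref <- substr(seqs[[site$contig]], pos, pos)
      alt <- if (cls == "mm_match") substr(spacer, 21L - p, 21L - p)
             else .CYCLE[[ref]]
    } else {
      j <- match(cls, c("pam_n", "pam_g2", "pam_g3"))
      pos <- site$start + 19L + j
      ref <- substr(seqs[[site$contig]], pos, pos)
      alt <- if (cls == "pam_n") .CYCLE[[ref]] else "A"
    }
    rows[[length(rows) + 1L]] <- data.frame(
      snp_id = sprintf("snp_%s_%s", gid, cls), contig = site$contig,
      position = pos, ref = ref, alt = alt,
      maf = if ("maf" %in% names(spec)) spec$maf[i] else design$config$maf,
      class = cls, guide_id = gid, stringsAsFactors = FALSE)
  }
  new <- do.call(rbind, rows)
  design$snps <- if (nrow(design$snps) == 0L) new else rbind(design$snps, new)
  design
}

#' Sample Hardy-Weinberg genotypes for planted SNPs
#'
#' @param snps SNP table with a `maf` column.
#' @param n_cells number of cell lines.
#' @return integer matrix SNPs x cells with values 0/1/2 (minor-allele
#'   copies), rownames = snp ids.
#' @export
sample_genotypes <- function(snps, n_cells) {
  g <- t(vapply(snps$maf, function(q) {
    sample(0:2, n_cells, replace = TRUE,
           prob = c((1 - q)^2, 2 * q * (1 - q), q^2))
  }, integer(n_cells)))
  rownames(g) <- snps$snp_id
  colnames(g) <- paste0("cell", seq_len(n_cells))
  g
}

# cutting efficiency of one site given spacer/protospacer/pam characters
.site_eta <- function(sp, ps, pam, w) {
  if (pam[2] != "G" || pam[3] != "G") return(0)
  mm <- 21L - which(sp != ps)
  if (length(mm) == 0L) return(1)
  prod(w[mm])
}

#' Simulate a pooled CRISPR knockout screen
#'
#' Draws per-cell Cas9 activities and copy-number slopes, builds (or takes)
#' expression, essentiality, copy-number and genotype matrices, and
#' computes guide x cell LFCs under the model documented at the top of this
#' file. SNP alleles modify per-site cutting efficiency per cell:
#' homozygous minor substitutes the alternate base (possibly breaking the
#' PAM or changing the mismatch structure); heterozygotes get the mean of
#' the two haplotype efficiencies.
#'
#' @param design a `screen_design` from [generate_genome()] (optionally
#'   with planted SNPs).
#' @param expression optional genes x cells matrix; default: functional
#'   genes expressed everywhere at N(mean, sd), pseudogenes 0.
#' @param essentiality optional genes x cells knockout-effect matrix;
#'   default: a random `essential_fraction` of functional genes at
#'   `essential_effect`, others 0.
#' @param cn optional genes x cells relative copy-number matrix (default 1).
#' @param genotypes optional SNPs x cells 0/1/2 matrix (default sampled
#'   under Hardy-Weinberg when SNPs are planted).
#' @param interactions optional data.frame (`gene_a`, `gene_b`, `strength`,
#'   `condition_gene`, `condition_threshold`): the pairwise interaction is
#'   `strength` in cells where the condition gene's expression is below the
#'   threshold (everywhere when `condition_gene` is NA).
#' @return list of class `synthetic_screen`: `lfc` (guides x cells),
#'   `expression`, `cn`, `genotypes`, `design`, and `truth` (planted
#'   parameters: `a_c`, `gamma_c`, `t1`, `t2`, `w`, `essentiality`,
#'   `interactions`, `N` expected cut counts, `eta` site efficiencies).
#' @export
simulate_screen <- function(design, expression = NULL, essentiality = NULL,
                            cn = NULL, genotypes = NULL, interactions = NULL) {
  stopifnot(inherits(design, "screen_design"))
  config <- design$config
  set.seed(config$seed + 1L)
  n <- config$n_cells
  cells <- paste0("cell", seq_len(n))
  genes <- design$genes
  guides <- design$guides
  sites <- design$sites
  w <- config$w

  a_c <- stats::runif(n, config$cas9_range[1], config$cas9_range[2])
  gamma_c <- stats::runif(n, config$cn_slope_range[1], config$cn_slope_range[2])
  names(a_c) <- names(gamma_c) <- cells

  if (is.null(expression)) {
    expression <- matrix(0, nrow(genes), n,
                         dimnames = list(genes$gene_id, cells))
    fn <- genes$functional
    expression[fn, ] <- pmax(0, stats::rnorm(sum(fn) * n,
                                             config$expression_mean,
                                             config$expression_sd))
  }
  if (is.null(essentiality)) {
    essentiality <- matrix(0, nrow(genes), n,
                           dimnames = list(genes$gene_id, cells))
    fg <- genes$gene_id[genes$functional]
    n_ess <- round(config$essential_fraction * length(fg))
    ess <- sample(fg, n_ess)
    essentiality[ess, ] <- config$essential_effect
  }
  if (is.null(cn)) {
    cn <- matrix(1, nrow(genes), n, dimnames = list(genes$gene_id, cells))
  }
  if (is.null(genotypes) && nrow(design$snps) > 0L)
    genotypes <- sample_genotypes(design$snps, n)

  # per-site gene overlap (all genes, functional or not, for CN; knockout
  # restricted to functional genes)
  site_genes <- lapply(seq_len(nrow(sites)), function(i) {
    s_end <- sites$start[i] + 19L
    hit <- design$annotation$contig == sites$contig[i] &
      design$annotation$start <= s_end &
      design$annotation$end >= sites$start[i]
    design$annotation$gene_id[hit]
  })

  # per-site efficiency across cells
  spacer_of <- stats::setNames(guides$spacer, guides$guide_id)
  eta <- matrix(0, nrow(sites), n)
  site_snps <- if (nrow(design$snps) > 0L) {
    lapply(seq_len(nrow(sites)), function(i) {
      span_lo <- sites$start[i]; span_hi <- sites$start[i] + 22L
      which(design$snps$contig == sites$contig[i] &
              design$snps$position >= span_lo &
              design$snps$position <= span_hi)
    })
  } else rep(list(integer(0)), nrow(sites))

  for (i in seq_len(nrow(sites))) {
    sp <- strsplit(spacer_of[[sites$guide_id[i]]], "")[[1]]
    ps0 <- strsplit(sites$protospacer[i], "")[[1]]
    pam0 <- strsplit(sites$pam_seq[i], "")[[1]]
    snp_idx <- site_snps[[i]]
    if (length(snp_idx) == 0L) {
      eta[i, ] <- .site_eta(sp, ps0, pam0, w)
      next
    }
    apply_alts <- function(which_alt) {
      ps <- ps0; pam <- pam0
      for (k in snp_idx[which_alt]) {
        pos <- design$snps$position[k]
        rel <- pos - sites$start[i] + 1L
        if (rel <= 20L) ps[rel] <- design$snps$alt[k]
        else pam[rel - 20L] <- design$snps$alt[k]
      }
      .site_eta(sp, ps, pam, w)
    }
    gt <- genotypes[design$snps$snp_id[snp_idx], , drop = FALSE]
    for (c_i in seq_len(n)) {
      g_c <- gt[, c_i]
      hap1 <- apply_alts(g_c == 2L)
      hap2 <- apply_alts(g_c >= 1L)
      eta[i, c_i] <- (hap1 + hap2) / 2
    }
  }

  functional_genes <- genes$gene_id[genes$functional]
  sites_by_guide <- split(seq_len(nrow(sites)), sites$guide_id)
  tau <- function(N) {
    x <- pmax(N - 1, 0)
    config$t1 * x + config$t2 * x^2
  }
  ia <- interactions
  lfc <- matrix(stats::rnorm(nrow(guides) * n, 0, config$sigma),
                nrow(guides), n, dimnames = list(guides$guide_id, cells))
  N_mat <- matrix(0, nrow(guides), n, dimnames = list(guides$guide_id, cells))

  for (g_i in seq_len(nrow(guides))) {
    gid <- guides$guide_id[g_i]
    s_idx <- sites_by_guide[[gid]]
    if (is.null(s_idx)) next                      # NTC: noise only
    eta_g <- eta[s_idx, , drop = FALSE]
    Ng <- colSums(eta_g)
    N_mat[g_i, ] <- Ng
    y <- a_c * tau(Ng)
    # knockout dosage per functional gene cut by this guide
    cut_lists <- site_genes[s_idx]
    cut_genes <- intersect(unique(unlist(cut_lists)), functional_genes)
    dosage <- matrix(0, length(cut_genes), n,
                     dimnames = list(cut_genes, NULL))
    for (cg in cut_genes) {
      rows <- which(vapply(cut_lists, function(v) cg %in% v, TRUE))
      dosage[cg, ] <- 1 - apply(1 - eta_g[rows, , drop = FALSE], 2, prod)
      y <- y + dosage[cg, ] * essentiality[cg, ]
    }
    if (!is.null(ia) && length(cut_genes) >= 2L) {
      for (r in seq_len(nrow(ia))) {
        if (ia$gene_a[r] %in% cut_genes && ia$gene_b[r] %in% cut_genes) {
          i_c <- rep(ia$strength[r], n)
          if (!is.na(ia$condition_gene[r]))
            i_c <- i_c * (expression[ia$condition_gene[r], ] <
                            ia$condition_threshold[r])
          y <- y + dosage[ia$gene_a[r], ] * dosage[ia$gene_b[r], ] * i_c
        }
      }
    }
    # copy-number effect at perfectly matched loci
    perfect <- sites$n_mismatches[s_idx] == 0L
    cn_genes <- intersect(unique(unlist(cut_lists[perfect])), genes$gene_id)
    if (length(cn_genes) > 0L) {
      cn_g <- apply(cn[cn_genes, , drop = FALSE], 2, max)
      y <- y + gamma_c * (cn_g - 1)
    }
    lfc[g_i, ] <- lfc[g_i, ] + y
  }

  structure(list(lfc = lfc, expression = expression, cn = cn,
                 genotypes = genotypes, design = design,
                 truth = list(a_c = a_c, gamma_c = gamma_c,
                              t1 = config$t1, t2 = config$t2, w = w,
                              essentiality = essentiality,
                              interactions = interactions,
                              N = N_mat, eta = eta)),
            class = "synthetic_screen")
}

#' Sample read counts from simulated LFCs
#'
#' Counts are drawn per sample as negative binomial around
#' plasmid * 2^LFC, with gamma-style overdispersion.
#'
#' @param lfc LFC matrix.
#' @param plasmid_reads expected plasmid representation per guide.
#' @param dispersion negative-binomial dispersion (default 0.1).
#' @param seed integer seed.
#' @return integer matrix with a `plasmid` column followed by the samples.
#' @export
simulate_counts <- function(lfc, plasmid_reads = 500, dispersion = 0.1,
                            seed = 1L) {
  set.seed(seed)
  size <- 1 / dispersion
  plasmid <- stats::rnbinom(nrow(lfc), mu = plasmid_reads, size = size)
  counts <- cbind(plasmid,
                  matrix(stats::rnbinom(length(lfc),
                                        mu = plasmid * 2^as.numeric(lfc),
                                        size = size),
                         nrow(lfc), ncol(lfc)))
  dimnames(counts) <- list(rownames(lfc), c("plasmid", colnames(lfc)))
  counts
}
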