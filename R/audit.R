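# End-to-end audit of a screen: alignment -> summaries -> toxicity ->
# gene scores -> self-expression confounding screen -> delta coefficients
# -> SNP effects.

#' Audit a CRISPR screen for multi-target and off-target biases
#'
#' Runs the full pipeline on a screen bundle: aligns the library to the
#' genome (up to 2 mismatches, NGG PAM), annotates and summarizes
#' alignments, fits per-cell-line cleavage-toxicity curves where the design
#' supports it, computes gene scores (per-gene mean guide LFC), screens for
#' genes whose score anti-correlates with their own expression (flagging
#' those with exonic single-mismatch off-targets), estimates off-target
#' delta coefficients for single-mismatch guides, and analyzes planted SNP
#' effects when genotypes are available.
#'
#' @param screen a `synthetic_screen` (from [simulate_screen()] /
#'   [make_fixture()]) or a list with elements `genome`, `annotation`,
#'   `guides`, `lfc`, and optionally `expression`, `snps`, `genotypes`.
#' @param guide_subset optional guide ids restricting the library (e.g. to
#'   re-audit after removing mismatch-tolerant guides).
#' @param max_mm alignment mismatch tolerance.
#' @param clean_level clean-guide definition (see [summarize_guide()]).
#' @param flag_r_cutoff a gene is flagged when its score-vs-self-expression
#'   correlation is at or below this and it has an exonic single-mismatch
#'   off-target (default -0.3).
#' @param delta_threshold delta coefficients below this are marked
#'   substantial off-target activity (default -0.25).
#' @param B_permutations permutations for SNP genotype-LFC nulls.
#' @param seed seed for the permutation stage.
#' @param stages character vector of stages to run (subset of
#'   `"toxicity"`, `"scores"`, `"self_expression"`, `"delta"`, `"snp"`;
#'   alignment always runs).
#' @param out_dir optional directory for CSV reports.
#' @return list with `alignments`, `summaries`, `gene_table`, `curves`,
#'   `lfc_adjusted`, `scores`, `self_expression`, `flagged_genes`,
#'   `delta_table`, `snp_table`, `trend`, `log`.
#' @export
run_audit <- function(screen, guide_subset = NULL, max_mm = 2L,
                      clean_level = "1mm", flag_r_cutoff = -0.3,
                      delta_threshold = -0.25, B_permutations = 100L,
                      seed = 1L,
                      stages = c("toxicity", "scores", "self_expression",
                                 "delta", "snp"),
                      out_dir = NULL) {
  if (inherits(screen, "synthetic_screen")) {
    bundle <- list(genome = screen$design$genome,
                   annotation = screen$design$annotation,
                   guides = screen$design$guides, lfc = screen$lfc,
                   expression = screen$expression,
                   snps = screen$design$snps, genotypes = screen$genotypes)
  } else bundle <- screen
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  guides <- bundle$guides
  if (!is.null(guide_subset)) {
    guides <- guides[guides$guide_id %in% guide_subset, , drop = FALSE]
    note("library restricted to %d guides", nrow(guides))
  }
  lfc <- bundle$lfc[rownames(bundle$lfc) %in% guides$guide_id, , drop = FALSE]
  guide_map <- guides[, c("guide_id", "intended_gene")]

  alignments <- align_library(bundle$genome, guides, max_mm = max_mm)
  alignments <- annotate_alignments(alignments, bundle$annotation)
  summaries <- summarize_guides(alignments, guide_ids = guides$guide_id,
                                clean_level = clean_level)
  gene_table <- gene_summary_table(summaries, guide_map,
                                   clean_level = clean_level)
  note("aligned %d guides: %d alignments", nrow(guides), nrow(alignments))

  out <- list(alignments = alignments, summaries = summaries,
              gene_table = gene_table, curves = NULL, lfc_adjusted = NULL,
              scores = NULL, self_expression = NULL, flagged_genes = NULL,
              delta_table = NULL, snp_table = NULL, trend = NULL)

  mean_lfc <- rowMeans(lfc)
  out$trend <- tryCatch(
    trend_over_alignment_count(mean_lfc, summaries, kind = "on_target"),
    error = function(e) { note("trend skipped: %s", conditionMessage(e)); NULL })

  if ("toxicity" %in% stages) {
    curves <- lapply(colnames(lfc), function(cl) {
      tryCatch(fit_toxicity_curve(stats::setNames(lfc[, cl], rownames(lfc)),
                                  summaries, target_kind = "on_target",
                                  cell_line = cl),
               error = function(e) NULL)
    })
    names(curves) <- colnames(lfc)
    if (all(!vapply(curves, is.null, TRUE))) {
      out$curves <- curves
      out$lfc_adjusted <- suppressWarnings(
        adjust_for_toxicity(lfc, summaries, curves))
      note("toxicity curves fitted for %d cell lines", length(curves))
    } else note("toxicity stage skipped: insufficient multi-target support")
  }

  if ("scores" %in% stages) {
    targeted <- guide_map[!is.na(guide_map$intended_gene), , drop = FALSE]
    gene_ids <- sort(unique(targeted$intended_gene))
    scores <- t(vapply(gene_ids, function(g) {
      gs <- targeted$guide_id[targeted$intended_gene == g]
      colMeans(lfc[rownames(lfc) %in% gs, , drop = FALSE])
    }, numeric(ncol(lfc))))
    out$scores <- scores
    note("gene scores computed for %d genes", nrow(scores))
  }

  if ("self_expression" %in% stages && !is.null(out$scores) &&
      !is.null(bundle$expression)) {
    se <- self_expression_screen(out$scores, bundle$expression, alignments,
                                 guide_map)
    out$self_expression <- se
    flagged <- se[!is.na(se$r) & se$r <= flag_r_cutoff &
                    se$has_exonic_1mm_offtarget, , drop = FALSE]
    out$flagged_genes <- flagged
    note("self-expression screen: %d gene(s) flagged", nrow(flagged))
  }

  if ("delta" %in% stages) {
    out$delta_table <- .delta_table(lfc, summaries, guide_map,
                                    delta_threshold)
    note("delta coefficients for %d single-mismatch guide(s)",
         if (is.null(out$delta_table)) 0L else nrow(out$delta_table))
  }

  if ("snp" %in% stages && !is.null(bundle$snps) &&
      nrow(bundle$snps) > 0L && !is.null(bundle$genotypes)) {
    out$snp_table <- .snp_table(alignments, bundle$snps, bundle$genotypes,
                                lfc, guides, B_permutations, seed)
    note("SNP analysis: %d SNP-guide pair(s)", nrow(out$snp_table))
  }

  out$log <- log
  if (!is.null(out_dir)) .write_audit(out, out_dir)
  out
}

# delta coefficients of single-mismatch guides vs clean guides of the same
# intended gene
.delta_table <- function(lfc, summaries, guide_map, delta_threshold) {
  m <- merge(summaries, guide_map, by = "guide_id")
  # strictly clean comparators: no single- or double-mismatch alignments
  strict <- m$n_perfect == 1L & m$n_1mm == 0L & m$n_2mm == 0L
  clean_by_gene <- split(m$guide_id[strict], m$intended_gene[strict])
  cand <- m[m$class == "single_mm_offtarget" & !is.na(m$intended_gene), ,
            drop = FALSE]
  rows <- list()
  for (i in seq_len(nrow(cand))) {
    g <- cand$intended_gene[i]
    clean <- setdiff(clean_by_gene[[g]], cand$guide_id[i])
    if (length(clean) < 1L) next
    y <- t(lfc[c(cand$guide_id[i], clean), , drop = FALSE])
    fit <- delta_coefficient(y)
    rows[[length(rows) + 1L]] <- data.frame(
      guide_id = cand$guide_id[i], gene_id = g, n_clean = length(clean),
      delta = fit$delta, se = fit$se, p_value = fit$p_value,
      substantial = fit$delta < delta_threshold, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(NULL)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# genotype-LFC correlations + permutation calls per SNP-guide pair
.snp_table <- function(alignments, snps, genotypes, lfc, guides,
                       B, seed) {
  pairs <- intersect_snps_with_targets(alignments, snps)
  if (nrow(pairs) == 0L) return(pairs)
  pairs <- classify_snp_effects(pairs, alignments, guides)
  pairs$r <- NA_real_
  pairs$p_empirical <- NA_real_
  pairs$call_positive <- NA
  pairs$call_negative <- NA
  for (i in seq_len(nrow(pairs))) {
    y <- lfc[pairs$guide_id[i], ]
    gt <- genotypes[pairs$snp_id[i], colnames(lfc)]
    res <- tryCatch(permutation_null(y, gt, B = B, seed = seed + i),
                    error = function(e) NULL)
    if (is.null(res)) next
    pairs$r[i] <- res$r_obs
    pairs$p_empirical[i] <- res$p_empirical
    pairs$call_positive[i] <- res$call_positive
    pairs$call_negative[i] <- res$call_negative
  }
  pairs
}

.write_audit <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) if (!is.null(x) && is.data.frame(x))
    utils::write.csv(x, file.path(out_dir, paste0(name, ".csv")),
                     row.names = FALSE)
  wr(out$alignments, "alignments")
  wr(out$summaries, "guide_summaries")
  wr(out$gene_table, "gene_summaries")
  wr(out$self_expression, "self_expression")
  wr(out$flagged_genes, "flagged_genes")
  wr(out$delta_table, "delta_coefficients")
  wr(out$snp_table, "snp_pairs")
  if (!is.null(out$scores))
    utils::write.csv(out$scores, file.path(out_dir, "gene_scores.csv"))
  writeLines(out$log, file.path(out_dir, "audit_log.txt"))
  invisible(out_dir)
}

#' Select problematic double-mismatch guides and compare to a null band
#'
#' Selects guides with one unique on-target alignment, no single-mismatch
#' alignments and at least `min_2mm` double-mismatch alignments whose most
#' PAM-distal mismatch sits at position `first_mm_at`, restricted to genes
#' with at least one clean guide. Estimates the off-target delta
#' coefficient for each, and a 95\% null band of delta coefficients from
#' random genes targeted by clean guides only (one clean guide played
#' against the gene's remaining clean guides per draw).
#'
#' @param lfc LFC matrix (guides x cell lines).
#' @param summaries per-guide summary table.
#' @param alignments alignment table (mismatch positions of the 2-mm
#'   alignments).
#' @param guide_map data.frame `guide_id`, `intended_gene`.
#' @param min_2mm minimum qualifying double-mismatch alignments (default 5).
#' @param first_mm_at required most PAM-distal mismatch position (default
#'   20).
#' @param n_null null draws (default 1000).
#' @param seed seed for the null draws.
#' @return list with `table` (guide, gene, delta, se, below/above band),
#'   `null_band` (2.5\% and 97.5\% quantiles) and `null_deltas`.
#' @export
select_problematic_double_mm <- function(lfc, summaries, alignments,
                                         guide_map, min_2mm = 5L,
                                         first_mm_at = 20L, n_null = 1000L,
                                         seed = 1L) {
  m <- merge(summaries, guide_map, by = "guide_id")
  # strictly clean: one perfect alignment, no mismatch alignments at all
  strict <- m$n_perfect == 1L & m$n_1mm == 0L & m$n_2mm == 0L
  clean_by_gene <- split(m$guide_id[strict], m$intended_gene[strict])
  n_guides_gene <- table(m$intended_gene)

  # qualifying 2-mm alignments: most PAM-distal mismatch at first_mm_at
  a2 <- alignments[alignments$n_mismatches == 2L, , drop = FALSE]
  if (nrow(a2) > 0L) {
    distal_ok <- vapply(strsplit(a2$mismatch_positions, ","), function(p)
      max(as.integer(p)) == first_mm_at, TRUE)
    n_qual <- table(a2$guide_id[distal_ok])
  } else n_qual <- table(character(0))

  cand <- m[m$n_perfect == 1L & m$n_1mm == 0L & !is.na(m$intended_gene), ,
            drop = FALSE]
  cand$n_qual_2mm <- as.integer(n_qual[cand$guide_id])
  cand$n_qual_2mm[is.na(cand$n_qual_2mm)] <- 0L
  cand <- cand[cand$n_qual_2mm >= min_2mm, , drop = FALSE]

  rows <- list()
  for (i in seq_len(nrow(cand))) {
    clean <- setdiff(clean_by_gene[[cand$intended_gene[i]]],
                     cand$guide_id[i])
    if (length(clean) < 1L) next
    fit <- delta_coefficient(t(lfc[c(cand$guide_id[i], clean), ,
                                   drop = FALSE]))
    rows[[length(rows) + 1L]] <- data.frame(
      guide_id = cand$guide_id[i], gene_id = cand$intended_gene[i],
      n_qual_2mm = cand$n_qual_2mm[i], delta = fit$delta, se = fit$se,
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(guide_id = character(0), gene_id = character(0),
               n_qual_2mm = integer(0), delta = numeric(0), se = numeric(0))

  # null band from genes targeted by clean guides only (>= 2 of them)
  set.seed(seed)
  n_clean_gene <- vapply(clean_by_gene, length, 1L)
  eligible <- names(clean_by_gene)[n_clean_gene >= 2L &
                                     n_clean_gene ==
                                       as.integer(n_guides_gene[names(clean_by_gene)])]
  if (length(eligible) == 0L) stop("no genes with >= 2 clean guides")
  null_deltas <- vapply(seq_len(n_null), function(k) {
    g <- sample(eligible, 1L)
    cg <- clean_by_gene[[g]]
    goi <- sample(cg, 1L)
    delta_coefficient(t(lfc[c(goi, setdiff(cg, goi)), , drop = FALSE]))$delta
  }, numeric(1))
  band <- stats::quantile(null_deltas, c(0.025, 0.975), names = FALSE)
  if (nrow(tab) > 0L) {
    tab$below_band <- tab$delta < band[1]
    tab$above_band <- tab$delta > band[2]
  } else {
    tab$below_band <- logical(0); tab$above_band <- logical(0)
  }
  rownames(tab) <- NULL
  list(table = tab, null_band = band, null_deltas = null_deltas)
}
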