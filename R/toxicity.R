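# Cleavage toxicity: gene-independent loss of viability scaling with the
# number of Cas9 cut sites. Modeled per cell line as a second-degree
# polynomial of guide LFC on alignment count.

#' Fit a cell line's cleavage-toxicity curve
#'
#' Least-squares quadratic of guide LFC on alignment count. For
#' `target_kind = "on_target"` the count is the number of perfect
#' alignments and guides with any single-mismatch alignment are excluded
#' (to prevent off-target confounding). For `target_kind = "off_target_1mm"`
#' the count is the number of single-mismatch alignments and the fit is
#' restricted to guides with exactly one perfect alignment (controls for
#' on-target count).
#'
#' @param lfc numeric vector of one cell line's guide LFCs, names = guide ids.
#' @param summaries per-guide alignment summary table.
#' @param target_kind `"on_target"` or `"off_target_1mm"`.
#' @param n_max counts above `n_max` are pooled at `n_max` before fitting
#'   (default 8; large-count bins are sparse).
#' @param cell_line label stored in the result.
#' @return object of class `toxicity_curve`: list with `coefficients`
#'   (intercept, linear, quadratic in the alignment count), `target_kind`,
#'   `cell_line`, `n_guides`, `domain` (observed count range) and `fit`.
#' @export
fit_toxicity_curve <- function(lfc, summaries,
                               target_kind = c("on_target", "off_target_1mm"),
                               n_max = 8L, cell_line = NA_character_) {
  target_kind <- match.arg(target_kind)
  s <- summaries[match(names(lfc), summaries$guide_id), , drop = FALSE]
  if (anyNA(s$guide_id)) stop("all guides in 'lfc' need a summary row")
  if (target_kind == "on_target") {
    keep <- s$n_1mm == 0L & s$n_perfect >= 1L
    n <- s$n_perfect
  } else {
    keep <- s$n_perfect == 1L
    n <- s$n_1mm
  }
  keep <- keep & is.finite(lfc)
  n <- pmin(n, n_max)
  x <- n[keep]; y <- lfc[keep]
  if (length(unique(x)) < 3L)
    stop("need at least 3 distinct alignment-count values after exclusions")
  fit <- stats::lm(y ~ x + I(x^2))
  structure(list(coefficients = unname(stats::coef(fit)),
                 target_kind = target_kind, cell_line = cell_line,
                 n_guides = length(y), domain = range(x), fit = fit),
            class = "toxicity_curve")
}

#' Evaluate a toxicity curve at alignment counts
#'
#' Counts outside the fit domain are clamped to the domain boundary with a
#' warning.
#'
#' @param curve `toxicity_curve`.
#' @param n alignment counts.
#' @return fitted mean LFC at each count.
#' @export
predict_toxicity <- function(curve, n) {
  lo <- curve$domain[1]; hi <- curve$domain[2]
  if (any(n < lo | n > hi, na.rm = TRUE)) {
    warning("alignment counts outside fit domain clamped to the boundary")
    n <- pmin(pmax(n, lo), hi)
  }
  b <- curve$coefficients
  b[1] + b[2] * n + b[3] * n^2
}

#' Adjust LFCs for multi-target cleavage toxicity
#'
#' Subtracts from each guide's LFC the cell line's fitted toxicity at the
#' guide's perfect-alignment count, relative to the single-target baseline:
#' y' = y - (f_c(n) - f_c(1)). Guides with one perfect alignment are
#' unchanged.
#'
#' @param lfc LFC matrix (guides x cell lines).
#' @param summaries per-guide summary table.
#' @param curves named list of `toxicity_curve` objects, one per cell line
#'   (names matching `colnames(lfc)`).
#' @return adjusted LFC matrix (stage `"toxicity_adjusted"`).
#' @export
adjust_for_toxicity <- function(lfc, summaries, curves) {
  lfc <- as.matrix(lfc)
  missing <- setdiff(colnames(lfc), names(curves))
  if (length(missing) > 0L)
    stop("no toxicity curve for cell line(s): ", paste(missing, collapse = ", "))
  n <- summaries$n_perfect[match(rownames(lfc), summaries$guide_id)]
  if (anyNA(n)) stop("all guides in 'lfc' need a summary row")
  out <- lfc
  for (cl in colnames(lfc)) {
    cv <- curves[[cl]]
    eff <- predict_toxicity(cv, n) -
      predict_toxicity(cv, min(max(1, cv$domain[1]), cv$domain[2]))
    eff[n <= 1L] <- 0
    out[, cl] <- lfc[, cl] - eff
  }
  .set_stage(out, "toxicity_adjusted")
}

#' Cell line toxicity metrics at four alignments
#'
#' Mean LFC of guides with four perfect alignments (on-target toxicity) and
#' of single-target guides with four single-mismatch alignments (off-target
#' toxicity); both summarize a cell line's susceptibility to cleavage
#' toxicity.
#'
#' @param lfc one cell line's guide LFCs (named vector).
#' @param summaries per-guide summary table.
#' @param at alignment count defining the metric bin (default 4).
#' @param min_guides minimum guides required in a bin (default 5); below
#'   that the metric is NA.
#' @return list `on_target_at`, `off_target_at`, `n_on`, `n_off`.
#' @export
toxicity_metric <- function(lfc, summaries, at = 4L, min_guides = 5L) {
  s <- summaries[match(names(lfc), summaries$guide_id), , drop = FALSE]
  on_idx <- s$n_perfect == at & s$n_1mm == 0L & is.finite(lfc)
  off_idx <- s$n_perfect == 1L & s$n_1mm == at & is.finite(lfc)
  list(
    on_target_at = if (sum(on_idx) >= min_guides) mean(lfc[on_idx]) else NA_real_,
    off_target_at = if (sum(off_idx) >= min_guides) mean(lfc[off_idx]) else NA_real_,
    n_on = sum(on_idx), n_off = sum(off_idx))
}

#' Median LFC stratified by mismatch structure and PAM region
#'
#' For single-target guides (one perfect alignment), groups LFCs by the
#' number of single-mismatch alignments and by where the mismatches fall:
#' PAM-proximal (all mismatch positions 1-10) or PAM-distal (all positions
#' 11-20); guides with mismatches on both sides are reported as `"mixed"`.
#' Attaches Welch two-sample t-tests between the proximal and distal strata
#' at each mismatch count.
#'
#' @param lfc guide LFCs averaged across cell lines (named vector).
#' @param alignments annotated alignment table (used for mismatch positions).
#' @param summaries per-guide summary table.
#' @param max_n1mm pool single-mismatch counts above this value (default 4).
#' @return list with `table` (stratum, n_1mm, n, median LFC) and `tests`
#'   (proximal vs distal per mismatch count).
#' @export
stratified_mismatch_table <- function(lfc, alignments, summaries, max_n1mm = 4L) {
  s <- summaries[match(names(lfc), summaries$guide_id), , drop = FALSE]
  keep <- s$n_perfect == 1L & is.finite(lfc)
  guides <- names(lfc)[keep]

  mm1 <- alignments[alignments$n_mismatches == 1L &
                      alignments$guide_id %in% guides, , drop = FALSE]
  pos_by_guide <- split(as.integer(mm1$mismatch_positions), mm1$guide_id)
  stratum <- vapply(guides, function(g) {
    p <- pos_by_guide[[g]]
    if (is.null(p)) return("none")
    if (all(p <= 10L)) return("proximal")
    if (all(p >= 11L)) return("distal")
    "mixed"
  }, character(1))
  n1 <- pmin(s$n_1mm[keep], max_n1mm)
  y <- lfc[keep]

  df <- data.frame(guide_id = guides, n_1mm = n1, stratum = stratum, lfc = y,
                   stringsAsFactors = FALSE)
  tab <- stats::aggregate(lfc ~ stratum + n_1mm, data = df,
                          FUN = stats::median)
  cnt <- stats::aggregate(lfc ~ stratum + n_1mm, data = df, FUN = length)
  names(tab)[3] <- "median_lfc"
  tab$n <- cnt$lfc
  tests <- lapply(sort(unique(n1[n1 > 0])), function(k) {
    a <- df$lfc[df$n_1mm == k & df$stratum == "proximal"]
    b <- df$lfc[df$n_1mm == k & df$stratum == "distal"]
    if (length(a) < 2L || length(b) < 2L)
      return(data.frame(n_1mm = k, p_value = NA_real_,
                        n_proximal = length(a), n_distal = length(b)))
    tt <- stats::t.test(a, b)
    data.frame(n_1mm = k, p_value = tt$p.value,
               n_proximal = length(a), n_distal = length(b))
  })
  list(table = tab, tests = do.call(rbind, tests))
}

#' Trend of LFC over alignment count
#'
#' Jonckheere trend test of guide LFCs across ordered alignment-count
#' groups (default: decreasing LFC with more alignments, the cleavage
#' toxicity direction).
#'
#' @param lfc guide LFCs averaged across cell lines (named vector).
#' @param summaries per-guide summary table.
#' @param kind `"on_target"` (groups by perfect-alignment count, excluding
#'   guides with single-mismatch alignments) or `"off_target_1mm"` (groups
#'   single-target guides by single-mismatch count).
#' @param n_max pool counts above this value.
#' @param alternative trend direction (default `"decreasing"`).
#' @return `jonckheere_result`.
#' @export
trend_over_alignment_count <- function(lfc, summaries,
                                       kind = c("on_target", "off_target_1mm"),
                                       n_max = 8L,
                                       alternative = "decreasing") {
  kind <- match.arg(kind)
  s <- summaries[match(names(lfc), summaries$guide_id), , drop = FALSE]
  if (kind == "on_target") {
    keep <- s$n_1mm == 0L & s$n_perfect >= 1L & is.finite(lfc)
    n <- pmin(s$n_perfect, n_max)
  } else {
    keep <- s$n_perfect == 1L & is.finite(lfc)
    n <- pmin(s$n_1mm, n_max)
  }
  groups <- split(lfc[keep], n[keep])
  if (length(groups) < 3L) stop("need at least 3 ordered alignment-count groups")
  jonckheere(groups, alternative = alternative, method = "normal")
}
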