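# LFC matrices are numeric matrices (guides x samples or guides x cell
# lines) carrying a "stage" attribute that records provenance:
# raw -> normalized -> scaled -> averaged -> cn_corrected -> toxicity_adjusted

.set_stage <- function(x, stage) { attr(x, "stage") <- stage; x }

#' Stage flag of an LFC matrix
#' @param lfc LFC matrix.
#' @return character stage label (or NULL).
#' @export
lfc_stage <- function(lfc) attr(lfc, "stage")

#' Compute raw log-fold changes from read counts
#'
#' Drops guides with insufficient plasmid representation, then computes
#' per-sample LFC = log2(sample + pseudocount) - log2(plasmid + pseudocount).
#'
#' @param counts non-negative integer matrix, guides x samples, rownames =
#'   guide ids.
#' @param plasmid_col name or index of the plasmid (pDNA) column.
#' @param min_plasmid_reads guides with fewer plasmid reads are dropped
#'   (default 30).
#' @param pseudocount added before the log transform (default 1).
#' @return LFC matrix (stage `"raw"`) over the non-plasmid columns.
#' @export
compute_raw_lfc <- function(counts, plasmid_col = "plasmid",
                            min_plasmid_reads = 30, pseudocount = 1) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.character(plasmid_col)) {
    if (!plasmid_col %in% colnames(counts)) stop("plasmid column not found")
    plasmid_col <- match(plasmid_col, colnames(counts))
  }
  plasmid <- counts[, plasmid_col]
  keep <- plasmid >= min_plasmid_reads
  if (!any(keep)) stop("all guides fail the plasmid read filter")
  samples <- counts[keep, -plasmid_col, drop = FALSE]
  lfc <- log2(samples + pseudocount) - log2(plasmid[keep] + pseudocount)
  .set_stage(lfc, "raw")
}

#' Median/MAD normalization per replicate column
#'
#' Centers each column at its median and divides by its median absolute
#' deviation, so that each replicate has median 0 and MAD 1. Optionally the
#' centering median is computed over a reference guide set only (e.g.
#' guides targeting non-essential genes).
#'
#' @param lfc LFC matrix (guides x replicate columns).
#' @param center `"column"` (whole-column median, default) or
#'   `"reference"` (median over `reference_guides` rows).
#' @param reference_guides guide ids used when `center = "reference"`.
#' @param scale divide by the column MAD (default TRUE).
#' @return normalized LFC matrix (stage `"normalized"`).
#' @export
normalize_median_mad <- function(lfc, center = c("column", "reference"),
                                 reference_guides = NULL, scale = TRUE) {
  center <- match.arg(center)
  lfc <- as.matrix(lfc)
  out <- lfc
  for (j in seq_len(ncol(lfc))) {
    v <- lfc[, j]
    if (sum(is.finite(v)) < 2L)
      stop(sprintf("replicate '%s': fewer than 2 finite values",
                   colnames(lfc)[j]))
    med <- if (center == "reference") {
      if (is.null(reference_guides)) stop("'reference_guides' required")
      stats::median(v[rownames(lfc) %in% reference_guides], na.rm = TRUE)
    } else stats::median(v, na.rm = TRUE)
    v <- v - med
    if (scale) {
      s <- stats::mad(lfc[, j], na.rm = TRUE)
      if (!is.finite(s) || s == 0)
        stop(sprintf("replicate '%s': zero MAD", colnames(lfc)[j]))
      v <- v / s
    }
    out[, j] <- v
  }
  .set_stage(out, "normalized")
}

#' Scale LFCs by the depletion of essential-gene guides
#'
#' Divides the matrix by a positive scale statistic computed over guides
#' targeting reference essential genes, so that essential-guide LFCs center
#' near -1. `"mean_abs"` uses the absolute value of the mean essential-guide
#' LFC across the whole matrix; `"median"` uses the absolute median.
#'
#' @param lfc LFC matrix, rownames = guide ids.
#' @param essential_genes character vector of essential reference genes.
#' @param guide_map data.frame `guide_id`, `intended_gene`.
#' @param statistic `"mean_abs"` or `"median"`.
#' @return scaled LFC matrix (stage `"scaled"`).
#' @export
scale_by_essentials <- function(lfc, essential_genes, guide_map,
                                statistic = c("mean_abs", "median")) {
  statistic <- match.arg(statistic)
  ess_guides <- guide_map$guide_id[guide_map$intended_gene %in% essential_genes]
  rows <- rownames(lfc) %in% ess_guides
  if (!any(rows)) stop("no guides target the essential reference set")
  vals <- as.numeric(lfc[rows, , drop = FALSE])
  s <- switch(statistic,
              mean_abs = abs(mean(vals, na.rm = TRUE)),
              median = abs(stats::median(vals, na.rm = TRUE)))
  if (!is.finite(s) || s < 1e-12) stop("essential-guide scale statistic is ~0")
  .set_stage(lfc / s, "scaled")
}

#' Average replicate columns per cell line
#'
#' @param lfc LFC matrix (guides x replicate columns).
#' @param sample_map data.frame `sample` (column name), `cell_line`.
#' @return LFC matrix with one column per cell line (arithmetic mean over
#'   replicates, NAs removed); stage `"averaged"`.
#' @export
average_replicates <- function(lfc, sample_map) {
  stopifnot(all(c("sample", "cell_line") %in% names(sample_map)))
  missing <- setdiff(colnames(lfc), sample_map$sample)
  if (length(missing) > 0L)
    stop("samples not in map: ", paste(missing, collapse = ", "))
  cells <- unique(sample_map$cell_line)
  out <- sapply(cells, function(cl) {
    cols <- sample_map$sample[sample_map$cell_line == cl]
    rowMeans(lfc[, cols, drop = FALSE], na.rm = TRUE)
  })
  out <- matrix(out, nrow = nrow(lfc),
                dimnames = list(rownames(lfc), cells))
  .set_stage(out, "averaged")
}

#' Correct one cell line's LFCs for copy-number effects
#'
#' Fits a continuous piecewise-linear spline of LFC on relative copy number
#' (knots at interior CN quantiles) and subtracts the fitted effect relative
#' to its value at CN = 1, so that guides at normal diploid copy number are
#' unchanged up to fit error. With fewer than 10 distinct CN values the fit
#' falls back to a straight line with a warning. Guides with missing CN are
#' passed through untouched.
#'
#' @param lfc numeric vector of one cell line's guide LFCs.
#' @param cn relative copy number per guide (1 = diploid-normal); NA allowed.
#' @param knots number of interior knots (default 4, at CN quantiles
#'   0.2/0.4/0.6/0.8).
#' @return list with `corrected` (numeric vector), `fit` (the `lm` object)
#'   and `effect` (fitted CN effect relative to CN = 1, NA where CN is NA).
#' @export
correct_copy_number <- function(lfc, cn, knots = 4L) {
  stopifnot(length(lfc) == length(cn))
  ok <- is.finite(lfc) & is.finite(cn)
  if (any(cn[is.finite(cn)] <= 0)) stop("relative copy numbers must be positive")
  n_distinct <- length(unique(cn[ok]))
  corrected <- lfc
  if (n_distinct < 2L) {
    return(list(corrected = lfc, fit = NULL, effect = rep(0, length(lfc))))
  }
  if (n_distinct < 10L) {
    warning("fewer than 10 distinct CN values; falling back to a linear fit")
    fit <- stats::lm(lfc[ok] ~ cn[ok])
    beta <- stats::coef(fit)
    pred <- function(x) as.numeric(cbind(1, x) %*% beta)
    eff <- rep(NA_real_, length(lfc))
    eff[ok] <- pred(cn[ok]) - pred(1)
  } else {
    probs <- seq_len(knots) / (knots + 1)
    kn <- unique(stats::quantile(cn[ok], probs = probs, names = FALSE))
    rng <- range(c(cn[ok], 1))
    kn <- kn[kn > rng[1] & kn < rng[2]]
    basis <- function(x) splines::bs(x, knots = kn, degree = 1L,
                                     Boundary.knots = rng)
    X <- cbind(1, basis(cn[ok]))
    fit <- stats::lm.fit(X, lfc[ok])
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0
    pred <- function(x) as.numeric(cbind(1, basis(x)) %*% beta)
    eff <- rep(NA_real_, length(lfc))
    eff[ok] <- pred(cn[ok]) - pred(1)
  }
  corrected[ok] <- lfc[ok] - eff[ok]
  list(corrected = corrected, fit = fit, effect = eff)
}

#' Copy-number correct an LFC matrix, cell line by cell line
#'
#' Applies [correct_copy_number()] to each column. Multi-target guides
#' should carry the maximum CN across their perfectly matched loci.
#'
#' @param lfc LFC matrix (guides x cell lines).
#' @param cn_matrix matrix of the same shape (or a vector recycled across
#'   columns) of relative copy number per guide and cell line.
#' @param knots interior knot count.
#' @return LFC matrix (stage `"cn_corrected"`).
#' @export
correct_copy_number_matrix <- function(lfc, cn_matrix, knots = 4L) {
  lfc <- as.matrix(lfc)
  if (is.vector(cn_matrix))
    cn_matrix <- matrix(cn_matrix, nrow = nrow(lfc), ncol = ncol(lfc))
  stopifnot(all(dim(cn_matrix) == dim(lfc)))
  out <- lfc
  for (j in seq_len(ncol(lfc))) {
    out[, j] <- correct_copy_number(lfc[, j], cn_matrix[, j], knots = knots)$corrected
  }
  .set_stage(out, "cn_corrected")
}
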