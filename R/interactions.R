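# OLS machinery for quantifying guide-level discrepancies and genetic
# interactions: the delta coefficient (guide-of-interest vs clean guides),
# the digenic additivity test, and the guide-design system solver.

#' Delta coefficient: discrepancy of a guide against clean guides
#'
#' Fits the fixed-effects model y_ij = alpha + beta_i + delta * 1(j = 1) +
#' r_ij over cell lines i and guides j, where guide 1 is the guide of
#' interest and guides 2..n_g are clean guides targeting the same gene, with
#' a sum-to-zero constraint on the cell effects beta_i. The delta
#' coefficient is the average LFC change of the guide of interest relative
#' to the clean guides; a large negative value indicates excess activity
#' (e.g. off-target cutting). With a balanced design the OLS estimate has
#' the closed form mean_i(y_i1 - mean of clean guides in cell i), which this
#' implementation uses, with the classical residual-variance SE.
#'
#' @param y numeric matrix, n cells x n_g guides; column 1 is the guide of
#'   interest, remaining columns are clean guides.
#' @return object of class `delta_fit`: list with `delta`, `se`,
#'   `t`, `p_value` (two-sided), `alpha`, `cell_effects` (sum-to-zero),
#'   `n_cells`, `n_guides`, `df`, `residuals` (n x n_g matrix).
#' @export
delta_coefficient <- function(y) {
  y <- as.matrix(y)
  n <- nrow(y); n_g <- ncol(y)
  if (n < 2L) stop("need at least 2 cell lines")
  if (n_g < 2L) stop("need at least one clean guide (n_g >= 2)")
  if (anyNA(y)) stop("'y' must be complete; subset to cells with all guides")

  clean_mean_i <- rowMeans(y[, -1L, drop = FALSE])
  delta <- mean(y[, 1L] - clean_mean_i)
  alpha <- mean(clean_mean_i)
  # cell effects under the sum-to-zero constraint: block mean adjusted for
  # the guide-of-interest offset share
  m_i <- rowMeans(y)
  beta_i <- (m_i - delta / n_g) - mean(m_i - delta / n_g)

  fitted <- outer(beta_i + alpha, rep(1, n_g))
  fitted[, 1L] <- fitted[, 1L] + delta
  res <- y - fitted
  df <- n * n_g - n - 1L
  sigma2 <- sum(res^2) / df
  se <- sqrt(sigma2 * n_g / (n * (n_g - 1L)))
  t <- delta / se
  p <- 2 * stats::pt(abs(t), df = df, lower.tail = FALSE)
  structure(list(delta = delta, se = se, t = t, p_value = p, alpha = alpha,
                 cell_effects = beta_i, n_cells = n, n_guides = n_g,
                 df = df, residuals = res),
            class = "delta_fit")
}

#' Test additivity of a digenic knockout
#'
#' Three-group means model over pooled guide x cell observations: LFCs of
#' guides targeting gene A only, gene B only, and both (double-target
#' guides). Fits beta_A, beta_B, beta_AB by OLS and t-tests the linear
#' contrast beta_A + beta_B - beta_AB = 0 (two-sided). A significantly
#' positive contrast (equivalently, beta_AB below beta_A + beta_B) means the
#' double knockout is more lethal than the sum of the single knockouts
#' (synergy / synthetic lethality).
#'
#' @param y_A,y_B,y_AB numeric vectors of pooled LFC observations for the
#'   three guide classes (each non-empty).
#' @param cluster optional list of three integer/character vectors giving
#'   the cell line of each observation; when supplied, CR1
#'   cluster-robust standard errors by cell line are used for the contrast.
#' @return object of class `additivity_fit`: list with `beta_A`, `beta_B`,
#'   `beta_AB` (each with `estimate`, `se`, `p_value`), `contrast`
#'   (estimate, se, t, df, p_value), `sigma2`, `n`.
#' @export
additivity_test <- function(y_A, y_B, y_AB, cluster = NULL) {
  if (length(y_A) == 0L || length(y_B) == 0L || length(y_AB) == 0L)
    stop("all three guide classes must be non-empty")
  y <- c(y_A, y_B, y_AB)
  if (anyNA(y)) stop("observations must be complete")
  nA <- length(y_A); nB <- length(y_B); nAB <- length(y_AB)
  N <- nA + nB + nAB
  bA <- mean(y_A); bB <- mean(y_B); bAB <- mean(y_AB)
  df <- N - 3L
  if (df < 1L) stop("not enough observations")
  sigma2 <- (sum((y_A - bA)^2) + sum((y_B - bB)^2) + sum((y_AB - bAB)^2)) / df

  # degenerate noiseless data: exact group means, p from the point null
  p_of <- function(est, se) {
    if (se == 0) return(if (abs(est) < 1e-10) 1 else 0)
    2 * stats::pt(abs(est / se), df = df, lower.tail = FALSE)
  }
  coef_row <- function(b, n) {
    se <- sqrt(sigma2 / n)
    list(estimate = b, se = se, p_value = p_of(b, se))
  }
  est <- bA + bB - bAB
  if (is.null(cluster)) {
    se_c <- sqrt(sigma2 * (1 / nA + 1 / nB + 1 / nAB))
  } else {
    se_c <- .cluster_se_contrast(y_A, y_B, y_AB, cluster)
  }
  t_c <- if (se_c == 0) 0 else est / se_c
  p_c <- p_of(est, se_c)
  structure(list(beta_A = coef_row(bA, nA), beta_B = coef_row(bB, nB),
                 beta_AB = coef_row(bAB, nAB),
                 contrast = list(estimate = est, se = se_c, t = t_c,
                                 df = df, p_value = p_c),
                 sigma2 = sigma2, n = c(A = nA, B = nB, AB = nAB)),
            class = "additivity_fit")
}

# CR1 cluster-robust SE (clustered by cell line) for the contrast
# l'beta with l = (1, 1, -1) on the three-group-means design
.cluster_se_contrast <- function(y_A, y_B, y_AB, cluster) {
  stopifnot(is.list(cluster), length(cluster) == 3L)
  g <- factor(rep(c("A", "B", "AB"), c(length(y_A), length(y_B), length(y_AB))),
              levels = c("A", "B", "AB"))
  y <- c(y_A, y_B, y_AB)
  cl <- factor(unlist(cluster))
  X <- stats::model.matrix(~ g - 1)
  XtX_inv <- solve(crossprod(X))
  res <- y - c(mean(y_A), mean(y_B), mean(y_AB))[as.integer(g)]
  meat <- matrix(0, 3, 3)
  for (lev in levels(cl)) {
    idx <- cl == lev
    u <- crossprod(X[idx, , drop = FALSE], res[idx])
    meat <- meat + tcrossprod(u)
  }
  G <- nlevels(cl)
  V <- XtX_inv %*% meat %*% XtX_inv * G / (G - 1)
  l <- c(1, 1, -1)
  sqrt(drop(t(l) %*% V %*% l))
}

#' Minimum expected LFC of a digenic knockout under additivity
#'
#' The most lethal LFC expected for a double knockout without genetic
#' interaction: min(y_A, y_B, y_A + y_B).
#'
#' @param y_A,y_B single-knockout LFCs.
#' @return numeric.
#' @export
expected_min_lfc <- function(y_A, y_B) {
  if (!all(is.finite(c(y_A, y_B)))) stop("inputs must be finite")
  pmin(y_A, y_B, y_A + y_B)
}

#' Solve an additive guide-design system by OLS
#'
#' Given a guides x genes incidence matrix (1 when a guide cuts the gene's
#' locus set) and observed guide LFCs, estimates per-gene knockout scores by
#' least squares and reports the score covariance matrix, which exposes the
#' design-induced correlation structure between gene scores. Rank-deficient
#' designs return NA for non-estimable genes together with a null-space
#' report.
#'
#' @param incidence numeric matrix guides x genes (colnames = gene ids).
#' @param y numeric vector of guide LFCs (length = nrow(incidence)).
#' @return object of class `design_fit`: list with `scores` (named vector,
#'   NA where non-estimable), `covariance` (p x p, NA rows/cols where
#'   non-estimable), `sigma2`, `rank`, `null_space` (NULL if full rank),
#'   `residuals`.
#' @export
solve_design_ols <- function(incidence, y) {
  X <- as.matrix(incidence)
  if (is.null(colnames(X))) colnames(X) <- paste0("gene", seq_len(ncol(X)))
  y <- as.numeric(y)
  stopifnot(nrow(X) == length(y))
  p <- ncol(X)
  qr_x <- qr(X)
  full_rank <- qr_x$rank == p
  beta <- qr.coef(qr_x, y)
  fitted <- as.numeric(X %*% ifelse(is.na(beta), 0, beta))
  res <- y - fitted
  df <- length(y) - qr_x$rank
  sigma2 <- if (df > 0) sum(res^2) / df else NA_real_
  covariance <- matrix(NA_real_, p, p, dimnames = list(colnames(X), colnames(X)))
  null_space <- NULL
  if (full_rank) {
    xtx_inv <- chol2inv(chol(crossprod(X)))
    covariance <- xtx_inv * sigma2
    dimnames(covariance) <- list(colnames(X), colnames(X))
  } else {
    sv <- svd(X, nu = 0)
    null_idx <- which(sv$d < max(sv$d) * 1e-8)
    null_space <- sv$v[, null_idx, drop = FALSE]
    rownames(null_space) <- colnames(X)
  }
  structure(list(scores = stats::setNames(beta, colnames(X)),
                 covariance = covariance, sigma2 = sigma2,
                 rank = qr_x$rank, null_space = null_space,
                 residuals = res),
            class = "design_fit")
}

#' Coessentiality edges from gene score profiles
#'
#' Draws an undirected edge between two genes when the Pearson correlation
#' of their score profiles across cell lines reaches the cutoff. Constant
#' gene rows are excluded with a warning.
#'
#' @param scores numeric matrix genes x cell lines (rownames = gene ids).
#' @param r_cutoff correlation cutoff (default 0.35).
#' @return data.frame `gene_a`, `gene_b`, `r` (one row per edge, a < b).
#' @export
coessentiality_edges <- function(scores, r_cutoff = 0.35) {
  scores <- as.matrix(scores)
  if (ncol(scores) < 3L) stop("need at least 3 cell lines")
  sds <- apply(scores, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding constant gene rows: ",
            paste(rownames(scores)[sds == 0], collapse = ", "))
    scores <- scores[sds > 0, , drop = FALSE]
  }
  g <- rownames(scores)
  if (length(g) < 2L)
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      r = numeric(0)))
  cm <- stats::cor(t(scores))
  idx <- which(upper.tri(cm) & cm >= r_cutoff, arr.ind = TRUE)
  out <- data.frame(gene_a = g[idx[, 1]], gene_b = g[idx[, 2]],
                    r = cm[idx], stringsAsFactors = FALSE)
  out[order(out$gene_a, out$gene_b), , drop = FALSE]
}

#' Screen for genes whose score anti-correlates with their own expression
#'
#' For each gene, correlates its essentiality score profile with its own
#' expression across cell lines and ranks genes by ascending correlation.
#' Genes at the top of this list (most negative r) are essential precisely
#' where they are NOT expressed -- the signature of mismatch-tolerant
#' off-target confounding. Each gene is annotated with whether any of its
#' guides carries a single-mismatch alignment in another gene's exon, and
#' with those off-target gene ids.
#'
#' @param scores genes x cell lines score matrix.
#' @param expression genes x cell lines expression matrix (e.g.
#'   log2(rpkm+1)); cell lines are matched by column name.
#' @param alignments annotated alignment table for the library.
#' @param guide_map data.frame `guide_id`, `intended_gene`.
#' @return data.frame ranked by ascending `r`: `gene_id`, `r`, `p_value`,
#'   `q_value` (Benjamini-Hochberg), `has_exonic_1mm_offtarget`,
#'   `offtarget_genes`.
#' @export
self_expression_screen <- function(scores, expression, alignments, guide_map) {
  cells <- intersect(colnames(scores), colnames(expression))
  if (length(cells) < 3L) stop("need at least 3 matched cell lines")
  genes <- rownames(scores)
  dropped <- setdiff(genes, rownames(expression))
  if (length(dropped) > 0L) {
    message("dropping ", length(dropped), " gene(s) absent from expression")
    genes <- setdiff(genes, dropped)
  }
  # exonic 1-mm off-targets per intended gene
  mm1 <- alignments[alignments$n_mismatches == 1L &
                      alignments$region == "exonic", , drop = FALSE]
  mm1$intended <- guide_map$intended_gene[match(mm1$guide_id, guide_map$guide_id)]
  offtargets_of <- function(gene) {
    rows <- mm1[!is.na(mm1$intended) & mm1$intended == gene, , drop = FALSE]
    hits <- setdiff(unlist(strsplit(rows$region_genes, ",")), gene)
    sort(unique(hits))
  }
  res <- lapply(genes, function(g) {
    sc <- scores[g, cells]; ex <- expression[g, cells]
    if (stats::sd(sc) == 0 || stats::sd(ex) == 0)
      return(data.frame(gene_id = g, r = NA_real_, p_value = NA_real_,
                        stringsAsFactors = FALSE))
    ct <- pearson_with_p(sc, ex)
    data.frame(gene_id = g, r = ct$r, p_value = ct$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  ot <- lapply(out$gene_id, offtargets_of)
  out$has_exonic_1mm_offtarget <- vapply(ot, length, 1L) > 0L
  out$offtarget_genes <- vapply(ot, paste, character(1), collapse = ",")
  out <- out[order(out$r), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.delta_fit <- function(x, ...) {
  cat("Delta coefficient:", format(round(x$delta, 4)),
      "(SE", format(round(x$se, 4)), ", p =", format(x$p_value), ")\n",
      x$n_cells, "cells,", x$n_guides - 1L, "clean guides\n")
  invisible(x)
}

#' @export
print.additivity_fit <- function(x, ...) {
  cat("Additivity test: beta_A =", format(round(x$beta_A$estimate, 4)),
      ", beta_B =", format(round(x$beta_B$estimate, 4)),
      ", beta_AB =", format(round(x$beta_AB$estimate, 4)), "\n",
      "contrast (A + B - AB) =", format(round(x$contrast$estimate, 4)),
      ", p =", format(x$contrast$p_value), "\n")
  invisible(x)
}
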