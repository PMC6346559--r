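# Cell-line-specific cleavage-toxicity curves, LFC adjustment, mismatch
# stratification and the alignment-count trend.

make_summaries <- function(n_perfect, n_1mm = 0L, n_2mm = 0L) {
  data.frame(guide_id = sprintf("g%04d", seq_along(n_perfect)),
             n_perfect = n_perfect,
             n_1mm = rep_len(n_1mm, length(n_perfect)),
             n_2mm = rep_len(n_2mm, length(n_perfect)),
             stringsAsFactors = FALSE)
}

test_that("a noiseless quadratic is recovered essentially exactly", {
  n <- rep(1:6, each = 10)
  y <- -0.05 * (n - 1) - 0.01 * (n - 1)^2
  s <- make_summaries(n)
  cv <- fit_toxicity_curve(setNames(y, s$guide_id), s, "on_target")
  # tau(n) expanded in n: (t2 - t1) + (t1 - 2 t2) n + t2 n^2
  expect_equal(cv$coefficients, c(0.04, -0.03, -0.01), tolerance = 1e-9)
  expect_equal(cv$domain, c(1, 6))
})

test_that("the quadratic fit equals the closed-form normal equations", {
  set.seed(3)
  n <- sample(1:8, 300, replace = TRUE)
  y <- rnorm(300, -0.04 * (n - 1), 0.1)
  s <- make_summaries(n)
  cv <- fit_toxicity_curve(setNames(y, s$guide_id), s, "on_target")
  X <- cbind(1, n, n^2)
  beta <- solve(crossprod(X), crossprod(X, y))
  expect_equal(cv$coefficients, as.numeric(beta), tolerance = 1e-10)
})

test_that("exclusion rules separate on- and off-target fits", {
  # guides with 1-mm alignments must not enter the on-target fit
  n <- rep(1:4, each = 20)
  n1 <- rep(c(0L, 2L), 40)
  y <- ifelse(n1 > 0, -5, -0.05 * (n - 1))   # contaminated values are wild
  s <- make_summaries(n, n1)
  cv <- fit_toxicity_curve(setNames(y, s$guide_id), s, "on_target")
  expect_equal(cv$n_guides, sum(n1 == 0))
  expect_lt(abs(cv$coefficients[3]), 1e-9)
  # off-target fit restricted to single-target guides
  s2 <- make_summaries(rep(c(1L, 2L), 30), n_1mm = rep(0:5, 10))
  y2 <- rnorm(60)
  cv2 <- fit_toxicity_curve(setNames(y2, s2$guide_id), s2, "off_target_1mm")
  expect_equal(cv2$n_guides, sum(s2$n_perfect == 1))
  expect_error(fit_toxicity_curve(setNames(y[1:5], s$guide_id[1:5]),
                                  make_summaries(rep(1L, 5)), "on_target"),
               "3 distinct")
})

test_that("toxicity recovery from the simulator is within 3 SE per cell", {
  ts <- simulate_toxicity_screen(n_guides = 2000, n_cells = 3, seed = 11)
  for (cl in colnames(ts$lfc)) {
    cv <- fit_toxicity_curve(setNames(ts$lfc[, cl], rownames(ts$lfc)),
                             ts$summaries, "on_target", cell_line = cl)
    se <- sqrt(diag(vcov(cv$fit)))
    z <- (cv$coefficients - ts$implied_coef(cl)) / se
    expect_true(all(abs(z) < 3))
  }
})

test_that("adjust_for_toxicity leaves single-target guides unchanged", {
  ts <- simulate_toxicity_screen(n_guides = 1500, n_cells = 4, seed = 12)
  curves <- lapply(colnames(ts$lfc), function(cl)
    fit_toxicity_curve(setNames(ts$lfc[, cl], rownames(ts$lfc)),
                       ts$summaries, "on_target", cell_line = cl))
  names(curves) <- colnames(ts$lfc)
  adj <- adjust_for_toxicity(ts$lfc, ts$summaries, curves)
  single <- ts$summaries$n_perfect == 1
  expect_equal(adj[single, ], ts$lfc[single, ])
  expect_equal(lfc_stage(adj), "toxicity_adjusted")
  # adjustment removes the alignment-count trend in non-essential guides
  bin_means <- tapply(rowMeans(adj), ts$summaries$n_perfect, mean)
  expect_lt(max(abs(bin_means)), 0.05)
  # the adjustment is a fixed offset: shifting the input shifts the output
  adj2 <- adjust_for_toxicity(ts$lfc + 1, ts$summaries, curves)
  expect_equal(adj2, adj + 1, ignore_attr = TRUE)
})

test_that("counts outside the fit domain are clamped with a warning", {
  n <- rep(1:5, each = 10)
  y <- -0.05 * (n - 1)
  s <- make_summaries(n)
  cv <- fit_toxicity_curve(setNames(y, s$guide_id), s, "on_target")
  expect_warning(p <- predict_toxicity(cv, 9), "clamped")
  expect_equal(p, suppressWarnings(predict_toxicity(cv, 5)))
  # an outlier guide beyond the domain is adjusted at the boundary value
  s_out <- make_summaries(c(n, 12L))
  lfc <- matrix(c(y, -1), ncol = 1,
                dimnames = list(s_out$guide_id, "c1"))
  expect_warning(adj <- adjust_for_toxicity(lfc, s_out, list(c1 = cv)),
                 "clamped")
  eff5 <- suppressWarnings(predict_toxicity(cv, 5) - predict_toxicity(cv, 1))
  expect_equal(adj[nrow(adj), 1], -1 - eff5)
})

test_that("fitted toxicity metrics track planted Cas9 activity", {
  ts <- simulate_toxicity_screen(n_guides = 2000, n_cells = 100, seed = 13)
  metric <- vapply(colnames(ts$lfc), function(cl)
    toxicity_metric(setNames(ts$lfc[, cl], rownames(ts$lfc)),
                    ts$summaries)$on_target_at, numeric(1))
  # more active Cas9 -> more toxic (more negative mean LFC at 4 targets)
  expect_gt(cor(ts$a_c, -metric, method = "spearman"), 0.8)
  # off-target counterpart
  to <- simulate_toxicity_screen(n_guides = 2000, n_cells = 50,
                                 kind = "off_target_1mm", seed = 14)
  m_off <- vapply(colnames(to$lfc), function(cl)
    toxicity_metric(setNames(to$lfc[, cl], rownames(to$lfc)),
                    to$summaries)$off_target_at, numeric(1))
  expect_gt(cor(to$a_c, -m_off, method = "spearman"), 0.8)
  # sparse bins yield NA
  s <- make_summaries(rep(1L, 10))
  expect_true(is.na(toxicity_metric(setNames(rnorm(10), s$guide_id),
                                    s)$on_target_at))
})

test_that("stratified mismatch table groups by count and PAM region", {
  # construct single-target guides with planted strata medians
  n_per <- 30
  guides <- sprintf("g%03d", 1:(3 * n_per))
  s <- data.frame(guide_id = guides, n_perfect = 1L,
                  n_1mm = rep(c(0L, 1L, 1L), each = n_per), n_2mm = 0L,
                  stringsAsFactors = FALSE)
  mm_pos <- rep(c(NA, 4L, 18L), each = n_per)   # proximal vs distal
  aln <- data.frame(guide_id = guides[!is.na(mm_pos)], contig = "chr1",
                    start = 1L, strand = "+", n_mismatches = 1L,
                    mismatch_positions = as.character(mm_pos[!is.na(mm_pos)]),
                    substitutions = "A>C", pam_seq = "AGG",
                    protospacer = strrep("A", 20), stringsAsFactors = FALSE)
  set.seed(15)
  lfc <- setNames(c(rnorm(n_per, 0, 0.02),        # no off-targets
                    rnorm(n_per, -0.02, 0.02),    # proximal: tolerated badly
                    rnorm(n_per, -0.4, 0.02)),    # distal: cuts, toxic
                  guides)
  res <- stratified_mismatch_table(lfc, aln, s)
  tab <- res$table
  med_prox <- tab$median_lfc[tab$stratum == "proximal" & tab$n_1mm == 1]
  med_dist <- tab$median_lfc[tab$stratum == "distal" & tab$n_1mm == 1]
  expect_lt(med_dist, med_prox)
  expect_equal(med_prox, median(lfc[(n_per + 1):(2 * n_per)]))
  expect_equal(med_dist, median(lfc[(2 * n_per + 1):(3 * n_per)]))
  expect_lt(res$tests$p_value[res$tests$n_1mm == 1], 0.001)
  # identical LFCs in both strata: test non-significant
  flat <- setNames(c(rnorm(n_per, 0, 0.05), rep(-0.1, 2 * n_per) +
                       rnorm(2 * n_per, 0, 0.05)), guides)
  res2 <- stratified_mismatch_table(flat, aln, s)
  expect_gt(res2$tests$p_value[res2$tests$n_1mm == 1], 0.05)
})

test_that("the LFC trend over alignment count uses the Jonckheere test", {
  ts <- simulate_toxicity_screen(n_guides = 1000, n_cells = 5, seed = 16)
  res <- trend_over_alignment_count(rowMeans(ts$lfc), ts$summaries,
                                    kind = "on_target")
  expect_s3_class(res, "jonckheere_result")
  expect_lt(res$p_value, 1e-10)
  few <- make_summaries(rep(1L, 10))
  expect_error(trend_over_alignment_count(setNames(rnorm(10), few$guide_id),
                                          few, "on_target"), "3 ordered")
})
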