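# Delta coefficient, digenic additivity test, design-system OLS,
# coessentiality edges and the self-expression screen.

test_that("delta is zero when the guide of interest matches clean guides", {
  set.seed(1)
  clean <- matrix(rnorm(40), 10, 4)
  y <- cbind(rowMeans(clean), clean)
  fit <- delta_coefficient(y)
  expect_equal(fit$delta, 0, tolerance = 1e-12)
})

test_that("delta equals the closed form and the dummy-coded lm oracle", {
  set.seed(2)
  for (rep in 1:20) {
    n <- sample(3:30, 1); n_g <- sample(2:6, 1)
    y <- matrix(rnorm(n * n_g, -0.3, 0.5), n, n_g)
    fit <- delta_coefficient(y)
    closed <- mean(y[, 1] - rowMeans(y[, -1, drop = FALSE]))
    expect_equal(fit$delta, closed, tolerance = 1e-10)
    oracle <- oracle_delta_lm(y)
    expect_equal(fit$delta, oracle$delta, tolerance = 1e-10)
    expect_equal(fit$se, oracle$se, tolerance = 1e-10)
    # sum-to-zero cell effects; residuals orthogonal to the design
    expect_equal(sum(fit$cell_effects), 0, tolerance = 1e-10)
    expect_equal(sum(fit$residuals), 0, tolerance = 1e-8)
  }
  expect_error(delta_coefficient(matrix(rnorm(10), 10, 1)), "clean guide")
  expect_error(delta_coefficient(matrix(rnorm(4), 1, 4)), "2 cell")
})

test_that("a planted off-target delta of -0.5 is recovered within 3 SE", {
  y <- simulate_delta_scenario(n_cells = 100, effect = -0.5, seed = 5)
  fit <- delta_coefficient(y)
  expect_lt(abs(fit$delta - attr(y, "effect")) / fit$se, 3)
  expect_true(fit$delta < -0.25)   # flagged substantial off-target activity
  expect_lt(fit$p_value, 1e-10)
})

test_that("additivity test: exact additivity gives contrast 0 and p 1", {
  fit <- additivity_test(rep(0.2, 4), rep(-0.3, 4), rep(-0.1, 4))
  expect_equal(fit$contrast$estimate, 0)
  expect_equal(fit$contrast$p_value, 1)
  expect_equal(fit$beta_AB$estimate,
               fit$beta_A$estimate + fit$beta_B$estimate)
  expect_error(additivity_test(numeric(0), 1, 1), "non-empty")
})

test_that("additivity estimates equal a generic linear-model oracle", {
  set.seed(6)
  for (rep in 1:10) {
    nA <- sample(3:10, 1); nB <- sample(3:10, 1); nAB <- sample(3:10, 1)
    y_A <- rnorm(nA); y_B <- rnorm(nB); y_AB <- rnorm(nAB)
    fit <- additivity_test(y_A, y_B, y_AB)
    g <- factor(rep(c("A", "B", "AB"), c(nA, nB, nAB)),
                levels = c("A", "B", "AB"))
    lmf <- lm(c(y_A, y_B, y_AB) ~ g - 1)
    expect_equal(fit$beta_A$estimate, unname(coef(lmf)["gA"]))
    expect_equal(fit$beta_AB$se, unname(sqrt(diag(vcov(lmf))["gAB"])),
                 tolerance = 1e-12)
    l <- c(1, 1, -1)
    est <- sum(l * coef(lmf))
    se <- sqrt(drop(t(l) %*% vcov(lmf) %*% l))
    expect_equal(fit$contrast$estimate, est, tolerance = 1e-12)
    expect_equal(fit$contrast$se, se, tolerance = 1e-12)
    expect_equal(fit$contrast$p_value,
                 2 * pt(abs(est / se), df = nA + nB + nAB - 3,
                        lower.tail = FALSE), tolerance = 1e-12)
  }
})

test_that("planted synthetic lethality is detected with high power", {
  set.seed(7)
  hits <- 0L
  for (rep in 1:50) {
    sim <- simulate_paralog_knockout(n_cells = 100, interaction = -1,
                                     sigma = 0.1, seed = 7000 + rep)
    fit <- additivity_test(sim$y_A, sim$y_B, sim$y_AB)
    if (fit$contrast$p_value < 0.05 &&
        fit$beta_AB$estimate < fit$beta_A$estimate + fit$beta_B$estimate)
      hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.9)
})

test_that("additivity p-values are uniform under the additive null", {
  pvals <- vapply(1:200, function(rep) {
    sim <- simulate_paralog_knockout(n_cells = 40, beta_A = -0.2,
                                     beta_B = 0.1, interaction = 0,
                                     sigma = 0.1, seed = 100 + rep)
    additivity_test(sim$y_A, sim$y_B, sim$y_AB)$contrast$p_value
  }, numeric(1))
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("expected_min_lfc takes the most lethal additive branch", {
  expect_equal(expected_min_lfc(0, 0), 0)
  expect_equal(expected_min_lfc(-1, 0.5), -1)
  expect_equal(expected_min_lfc(-0.4, -0.3), -0.7)
  expect_error(expected_min_lfc(NA, 1), "finite")
})

test_that("solve_design_ols reproduces the readthrough closed forms", {
  # guides 1-4: gene A + fusion; 5-7: gene B + fusion; 8: gene B only
  inc <- cbind(A = c(1, 1, 1, 1, 0, 0, 0, 0),
               B = c(0, 0, 0, 0, 1, 1, 1, 1),
               FUS = c(1, 1, 1, 1, 1, 1, 1, 0))
  y <- c(rep(-0.8, 4), rep(-0.6, 3), -0.3)
  fit <- solve_design_ols(inc, y)
  expect_equal(unname(fit$scores["B"]), -0.3)
  expect_equal(unname(fit$scores["FUS"]), mean(y[5:7]) - (-0.3))
  expect_equal(unname(fit$scores["A"]), mean(y[1:4]) - unname(fit$scores["FUS"]))
  # the same closed forms hold for arbitrary observations
  set.seed(8)
  for (rep in 1:20) {
    y <- rnorm(8)
    fit <- solve_design_ols(inc, y)
    b_B <- y[8]
    b_F <- mean(y[5:7]) - b_B
    b_A <- mean(y[1:4]) - b_F
    expect_equal(unname(fit$scores), c(b_A, b_B, b_F), tolerance = 1e-10)
  }
  # design-induced negative correlation between the A and fusion scores
  expect_lt(cov2cor(fit$covariance)["A", "FUS"], 0)
})

test_that("solve_design_ols equals normal equations and handles identity", {
  set.seed(9)
  for (rep in 1:10) {
    X <- matrix(rbinom(40, 1, 0.5), 10, 4)
    X[, 1] <- 1   # guarantee full column rank more often
    if (qr(X)$rank < 4) next
    y <- rnorm(10)
    fit <- solve_design_ols(X, y)
    beta <- solve(crossprod(X), crossprod(X, y))
    expect_equal(unname(fit$scores), as.numeric(beta), tolerance = 1e-9)
    s2 <- sum((y - X %*% beta)^2) / (10 - 4)
    expect_equal(unname(fit$covariance),
                 unname(s2 * solve(crossprod(X))), tolerance = 1e-8)
  }
  I4 <- diag(4); colnames(I4) <- paste0("g", 1:4)
  y <- rnorm(4)
  expect_equal(unname(solve_design_ols(I4, y)$scores), y)
})

test_that("rank-deficient designs yield NA scores and a null-space report", {
  X <- cbind(a = c(1, 1, 0, 0), b = c(0, 0, 1, 1), ab = c(1, 1, 1, 1))
  fit <- solve_design_ols(X, rnorm(4))
  expect_equal(fit$rank, 2L)
  expect_true(any(is.na(fit$scores)))
  expect_false(is.null(fit$null_space))
  # the null space really annihilates the design
  expect_lt(max(abs(X %*% fit$null_space)), 1e-8)
})

test_that("coessentiality edges equal the brute-force pairwise oracle", {
  set.seed(10)
  m <- matrix(rnorm(60), 6, 10,
              dimnames = list(paste0("gene", 1:6), paste0("c", 1:10)))
  m[2, ] <- m[1, ]                       # a duplicated profile: r = 1
  edges <- coessentiality_edges(m, 0.35)
  expect_true(any(edges$gene_a == "gene1" & edges$gene_b == "gene2"))
  cm <- cor(t(m))
  want <- sum(cm[upper.tri(cm)] >= 0.35)
  expect_equal(nrow(edges), want)
  # independent noise at many cells: no spurious edges
  big <- matrix(rnorm(5 * 500), 5, 500,
                dimnames = list(paste0("g", 1:5), NULL))
  expect_equal(nrow(coessentiality_edges(big, 0.35)), 0L)
  m[3, ] <- 2
  expect_warning(coessentiality_edges(m, 0.35), "constant")
})

test_that("self-expression screen ranks and flags a planted confounder", {
  scr <- make_fixture("sox9_sox10_like", seed = 23, n_cells = 50)
  aln <- annotate_alignments(align_library(scr$design$genome,
                                           scr$design$guides),
                             scr$design$annotation)
  map <- scr$design$guides[, c("guide_id", "intended_gene")]
  targeted <- map[!is.na(map$intended_gene), ]
  genes <- sort(unique(targeted$intended_gene))
  scores <- t(vapply(genes, function(g)
    colMeans(scr$lfc[targeted$guide_id[targeted$intended_gene == g], ,
                     drop = FALSE]), numeric(ncol(scr$lfc))))
  tab <- self_expression_screen(scores, scr$expression, aln, map)
  conf <- tab[tab$gene_id == "CONF_X", ]
  expect_lt(conf$r, -0.3)
  expect_true(conf$has_exonic_1mm_offtarget)
  expect_equal(conf$offtarget_genes, "DEP_Y")
  expect_lte(which(tab$gene_id == "CONF_X"),
             ceiling(nrow(tab) / 10))      # top decile of the ranking
  # a gene with no 1-mm alignments is never flagged
  g01 <- tab[tab$gene_id == "G01", ]
  expect_false(g01$has_exonic_1mm_offtarget)
  # constant-expression genes: independence means small |r| for essentials
  expect_gt(min(tab$r[tab$gene_id %in% paste0("G", sprintf("%02d", 4:9))]),
            -0.5)
})
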