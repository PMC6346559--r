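# Independent oracles and small generators used across the test files.

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

random_seq <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

revcomp <- function(s) paste(rev(COMP[strsplit(s, "")[[1]]]), collapse = "")

# exhaustive sliding-window aligner: every 20-nt window on both strands with
# <= max_mm mismatches and a canonical NGG PAM, N excluded
brute_force_align <- function(genome, spacer, max_mm) {
  sp <- strsplit(spacer, "")[[1]]
  sp_rc <- strsplit(revcomp(spacer), "")[[1]]
  out <- list()
  for (ctg in names(genome)) {
    g <- strsplit(genome[[ctg]], "")[[1]]
    L <- length(g)
    if (L >= 23) {                          # plus strand
      starts <- seq_len(L - 22L)
      mm <- integer(length(starts)); bad <- logical(length(starts))
      for (k in 0:19) {
        b <- g[starts + k]
        mm <- mm + (b != sp[k + 1])
        bad <- bad | !(b %in% BASES)
      }
      p1 <- g[starts + 20L]; p2 <- g[starts + 21L]; p3 <- g[starts + 22L]
      ok <- mm <= max_mm & !bad & p1 %in% BASES & p2 == "G" & p3 == "G"
      if (any(ok))
        out[[length(out) + 1L]] <- data.frame(
          contig = ctg, start = starts[ok], strand = "+",
          n_mismatches = mm[ok], stringsAsFactors = FALSE)
    }
    if (L >= 23) {                          # minus strand
      starts <- 4:(L - 19L)
      mm <- integer(length(starts)); bad <- logical(length(starts))
      for (k in 0:19) {
        b <- g[starts + k]
        mm <- mm + (b != sp_rc[k + 1])
        bad <- bad | !(b %in% BASES)
      }
      q1 <- g[starts - 3L]; q2 <- g[starts - 2L]; q3 <- g[starts - 1L]
      ok <- mm <= max_mm & !bad & q1 == "C" & q2 == "C" & q3 %in% BASES
      if (any(ok))
        out[[length(out) + 1L]] <- data.frame(
          contig = ctg, start = starts[ok], strand = "-",
          n_mismatches = mm[ok], stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(contig = character(0), start = integer(0),
                      strand = character(0), n_mismatches = integer(0)))
  res <- do.call(rbind, out)
  res[order(res$contig, res$start, res$strand), , drop = FALSE]
}

alignment_key <- function(df) {
  if (nrow(df) == 0L) return(character(0))
  sort(paste(df$contig, df$start, df$strand, df$n_mismatches))
}

# plant a protospacer + AGG PAM at a position of a plus-strand genome string
plant_protospacer <- function(genome_str, protospacer, at) {
  substr(genome_str, at, at + 19L) <- protospacer
  substr(genome_str, at + 20L, at + 22L) <- "AGG"
  genome_str
}

# mutate a 20-mer at given PAM-relative positions (pos 1 adjacent to PAM)
mutate_pam_rel <- function(seq20, positions) {
  cyc <- c(A = "C", C = "G", G = "T", T = "A")
  for (p in positions) {
    i <- 21L - p
    substr(seq20, i, i) <- cyc[[substr(seq20, i, i)]]
  }
  seq20
}

# independent Jonckheere statistic + exact one-sided p by enumeration of all
# distinct assignments of the pooled sample to the observed group sizes
oracle_jonckheere_J <- function(groups) {
  k <- length(groups); J <- 0
  for (i in seq_len(k - 1)) for (j in (i + 1):k)
    for (a in groups[[i]]) for (b in groups[[j]])
      J <- J + (b > a) + 0.5 * (b == a)
  J
}

oracle_jonckheere_exact_p <- function(groups, alternative = "increasing") {
  if (alternative == "decreasing") groups <- lapply(groups, function(g) -g)
  x <- unlist(groups); n_i <- lengths(groups)
  J_obs <- oracle_jonckheere_J(groups)
  total <- 0; ge <- 0
  # enumerate index partitions
  parts <- list()
  gen <- function(remaining, g, acc) {
    if (g > length(n_i)) { parts[[length(parts) + 1L]] <<- acc; return() }
    for (p in utils::combn(remaining, n_i[g], simplify = FALSE))
      gen(setdiff(remaining, p), g + 1L, c(acc, list(p)))
  }
  gen(seq_along(x), 1L, list())
  for (pt in parts) {
    gl <- lapply(pt, function(idx) x[idx])
    total <- total + 1
    if (oracle_jonckheere_J(gl) >= J_obs - 1e-9) ge <- ge + 1
  }
  ge / total
}

# exact one-sided rank-sum p (P(W_x >= observed)) by enumeration, no ties
oracle_ranksum_exact_p <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  W_obs <- sum(r[seq_along(x)])
  combos <- utils::combn(length(pooled), length(x))
  W_all <- apply(combos, 2, function(idx) sum(r[idx]))
  mean(W_all >= W_obs - 1e-9)
}

# delta-model oracle: dummy-coded lm fit
oracle_delta_lm <- function(y) {
  n <- nrow(y); n_g <- ncol(y)
  df <- data.frame(y = as.numeric(y),
                   cell = factor(rep(seq_len(n), n_g)),
                   goi = rep(c(1, rep(0, n_g - 1)), each = n))
  fit <- stats::lm(y ~ goi + cell, data = df)
  list(delta = unname(stats::coef(fit)["goi"]),
       se = unname(sqrt(diag(stats::vcov(fit))["goi"])))
}
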