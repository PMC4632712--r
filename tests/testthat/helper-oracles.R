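# Independent oracles used across the suite.  These deliberately avoid the
# package's implementation paths: the scanner oracle slides every pattern
# literally, the Fisher oracle enumerates the hypergeometric support with
# choose(), and the rank-test oracles enumerate permutations explicitly.

.oracle_core_offset <- c("6mer" = 0L, "7mer-A1" = 0L, "7mer-m8" = 1L,
                         "8mer-1a" = 1L)
.oracle_priority <- c("6mer" = 1L, "7mer-A1" = 2L, "7mer-m8" = 3L,
                      "8mer-1a" = 4L)

# Brute-force site scan: slide each seed_match_site pattern over every
# offset, collect literal matches, then apply the per-(miRNA, core-locus)
# priority rule and the (start, mirna) ordering.
oracle_scan <- function(window, catalog, counted_types = NULL) {
  counted <- if (is.null(counted_types)) catalog$counted_types else
    counted_types
  rows <- list()
  for (i in seq_len(nrow(catalog$records))) {
    nm <- catalog$records$name[i]
    pats <- seed_match_site(catalog$records$mature_seq[i])
    for (t in intersect(names(pats), counted)) {
      pat <- pats[[t]]
      L <- nchar(pat)
      W <- nchar(window)
      if (W < L) next
      starts <- 0:(W - L)
      hit <- substring(window, starts + 1, starts + L) == pat
      for (s in starts[hit]) {
        rows[[length(rows) + 1L]] <- data.frame(
          mirna = nm, site_type = t, start = s, end = s + L,
          core = s + .oracle_core_offset[[t]],
          priority = .oracle_priority[[t]], stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mirna = character(), site_type = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE))
  }
  h <- do.call(rbind, rows)
  keep <- rep(TRUE, nrow(h))
  for (j in seq_len(nrow(h))) {
    same <- h$mirna == h$mirna[j] & h$core == h$core[j]
    if (any(h$priority[same] > h$priority[j])) keep[j] <- FALSE
  }
  h <- h[keep, , drop = FALSE]
  h <- h[order(h$start, h$mirna), , drop = FALSE]
  rownames(h) <- NULL
  h[, c("mirna", "site_type", "start", "end")]
}

# Full hypergeometric enumeration of the 2x2 Fisher test.
oracle_fisher <- function(a, b, c, d, alternative = "two.sided") {
  m <- a + b
  n <- c + d
  k <- a + c
  xs <- max(0, k - n):min(k, m)
  p <- exp(lchoose(m, xs) + lchoose(n, k - xs) - lchoose(m + n, k))
  pobs <- p[xs == a]
  switch(alternative,
         two.sided = sum(p[p <= pobs * (1 + 1e-7)]),
         greater = sum(p[xs >= a]),
         less = sum(p[xs <= a]))
}

# All permutations of 1..n (rows), independent of the package's generator.
oracle_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- oracle_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, matrix((seq_len(n)[-k])[sub], nrow(sub), n - 1L))
  }))
}

# Exhaustive two-sided permutation p for Spearman's rho, via cor() on every
# permutation of one variable.
oracle_spearman_p <- function(x, y) {
  pm <- oracle_perms(length(y))
  obs <- abs(cor(rank(x), rank(y)))
  rr <- apply(pm, 1L, function(ix) cor(rank(x), rank(y[ix])))
  mean(abs(rr) >= obs - 1e-9)
}

# Exhaustive two-sided rank-sum p over all assignments of the pooled ranks
# to the first sample (distance-from-mean convention; the null is symmetric
# so this matches the doubled-tail convention of the exact test).
oracle_wilcoxon_p <- function(x, y) {
  pooled <- rank(c(x, y))
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  sums <- colSums(matrix(pooled[idx], nrow = n1))
  obs <- sum(pooled[seq_len(n1)])
  es <- mean(sums)
  mean(abs(sums - es) >= abs(obs - es) - 1e-9)
}

# Random scan instances shared by the oracle-equivalence tests.
random_window <- function(max_len = 60L, with_n = TRUE) {
  len <- sample(6:max_len, 1L)
  alpha <- c("A", "C", "G", "T", if (with_n) "N")
  prob <- c(rep(0.24, 4), if (with_n) 0.04)
  paste(sample(alpha, len, replace = TRUE, prob = prob), collapse = "")
}

random_catalog <- function(max_mirnas = 20L) {
  n <- sample(1:max_mirnas, 1L)
  lens <- sample(8:24, n, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
  }, "")
  types <- c("6mer", "7mer-A1", "7mer-m8", "8mer-1a")
  counted <- sample(types, sample(1:4, 1L))
  seed_catalog(sprintf("m%02d", seq_len(n)), seqs, counted_types = counted)
}

# Random SNP tables for the allele-swap property tests; low-complexity
# windows raise the chance of real seed matches.
random_snp_table <- function(n, alphabet_bias = TRUE) {
  mk <- function(len) {
    vapply(seq_len(n), function(i) {
      p <- if (alphabet_bias) c(0.4, 0.1, 0.4, 0.1) else rep(0.25, 4)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p),
            collapse = "")
    }, "")
  }
  a <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  b <- vapply(a, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L),
              "", USE.NAMES = FALSE)
  snp_table(data.frame(
    snp_id = sprintf("s%04d", seq_len(n)), left_flank = mk(15L),
    allele_a = a, allele_b = b, right_flank = mk(15L),
    snp_class = sample(c("synonymous", "nonsynonymous"), n, replace = TRUE),
    stringsAsFactors = FALSE))
}
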