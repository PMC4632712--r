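#' Spearman association of genotype with expression
#'
#' Rank correlation of per-sample genotype dosages (0/1/2 alternate-allele
#' counts) with expression values.  Missing pairs are dropped.  Ties take
#' average ranks.  The two-sided p-value uses the t approximation for
#' n >= 10 and exhaustive permutation of the rank assignment for smaller n.
#' Monomorphic genotypes are not testable and are flagged rather than
#' tested.
#'
#' @param genotype numeric vector of dosages (`NA` = missing).
#' @param expression numeric vector, same samples as `genotype`.
#' @return list with `rho`, `p_value`, `n_used`, `testable`.
#' @export
spearman_assoc <- function(genotype, expression) {
  if (length(genotype) != length(expression)) {
    stop("genotype and expression must cover the same samples")
  }
  keep <- !is.na(genotype) & !is.na(expression)
  g <- as.numeric(genotype[keep])
  e <- as.numeric(expression[keep])
  n <- length(g)
  if (n < 3L) stop("insufficient data: fewer than 3 complete sample pairs")
  if (length(unique(g)) < 2L) {
    return(list(rho = NA_real_, p_value = NA_real_, n_used = n,
                testable = FALSE))
  }
  rg <- rank(g)
  re <- rank(e)
  rho <- stats::cor(rg, re)
  if (n >= 10L) {
    # t approximation on the rank correlation
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  } else {
    # exhaustive permutation of one rank vector; with fixed rank multisets
    # rho is a monotone function of sum(rg * re[perm]), so the two-sided
    # permutation p on |rho| is computed on that sum's distance from its
    # permutation mean
    pm <- all_permutations(n)
    s_obs <- sum(rg * re)
    es <- sum(rg) * sum(re) / n
    s_perm <- as.vector(matrix(re[pm], nrow(pm), n) %*% rg)
    p <- mean(abs(s_perm - es) >= abs(s_obs - es) - 1e-9)
  }
  list(rho = rho, p_value = min(1, p), n_used = n, testable = TRUE)
}

# All permutations of 1..n as a matrix (n! rows), built recursively.
all_permutations <- function(n) {
  if (n > 9L) stop("exhaustive permutation limited to n <= 9")
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Associate every mapped SNP-gene pair
#'
#' Runs [spearman_assoc()] for each SNP against the expression of its host
#' gene over the shared samples.
#'
#' @param genotypes numeric matrix, rows = SNPs, columns = samples,
#'   values 0/1/2/NA.
#' @param expression numeric matrix, rows = genes, columns = samples.
#' @param snp_to_gene data.frame with columns `snp_id`, `gene_id`.
#' @return data.frame `snp_id`, `gene_id`, `rho`, `p_value`, `n_used`,
#'   `testable`.
#' @export
assoc_table <- function(genotypes, expression, snp_to_gene) {
  stopifnot(is.matrix(genotypes), is.matrix(expression))
  samples <- intersect(colnames(genotypes), colnames(expression))
  if (length(samples) < 3L) stop("fewer than 3 shared samples")
  miss <- setdiff(snp_to_gene$snp_id, rownames(genotypes))
  if (length(miss)) {
    stop("missing genotypes for mapped SNPs: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  miss <- setdiff(snp_to_gene$gene_id, rownames(expression))
  if (length(miss)) {
    stop("missing expression for mapped genes: ",
         paste(utils::head(miss, 5L), collapse = ", "))
  }
  res <- lapply(seq_len(nrow(snp_to_gene)), function(i) {
    a <- spearman_assoc(genotypes[snp_to_gene$snp_id[i], samples],
                        expression[snp_to_gene$gene_id[i], samples])
    data.frame(snp_id = snp_to_gene$snp_id[i],
               gene_id = snp_to_gene$gene_id[i],
               rho = a$rho, p_value = a$p_value, n_used = a$n_used,
               testable = a$testable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Gene-level enrichment of expression association in changing-SNP genes
#'
#' Partitions genes into those hosting at least one regulation-changing SNP
#' and those not; a gene is "significant" if any of its testable SNP
#' associations has `p <= alpha`.  The resulting 2x2 table is tested by
#' Fisher's exact test with the sample odds ratio.  The any-SNP aggregation
#' at a nominal alpha with no multiplicity adjustment is deliberately simple
#' and anti-conservative; interpret the odds ratio, not the raw counts.
#'
#' @param assoc data.frame from [assoc_table()].
#' @param changes a `mirsnp_classification` or named logical changed flags.
#' @param snp_to_gene data.frame `snp_id`, `gene_id` covering every SNP in
#'   `assoc` and `changes`.
#' @param alpha per-association significance level, default 0.05.
#' @param alternative sidedness for [fisher_exact()].
#' @return an `enrichment_result` with `mode = "expression"`.
#' @export
gene_level_enrichment <- function(assoc, changes, snp_to_gene, alpha = 0.05,
                                  alternative = c("two.sided", "greater",
                                                  "less")) {
  alternative <- match.arg(alternative)
  ch <- if (is.vector(changes) || is.logical(changes)) changes else
    changed_flags(changes)
  map <- stats::setNames(as.character(snp_to_gene$gene_id),
                         snp_to_gene$snp_id)
  unmapped <- setdiff(c(assoc$snp_id, names(ch)), names(map))
  if (length(unmapped)) {
    stop("missing SNP-to-gene mapping for: ",
         paste(utils::head(unmapped, 10L), collapse = ", "))
  }
  genes <- unique(unname(map))
  hosts_changing <- genes %in% map[names(ch)[as.logical(ch)]]
  sig_assoc <- assoc$testable & !is.na(assoc$p_value) &
    assoc$p_value <= alpha
  sig_genes <- unique(assoc$gene_id[sig_assoc])
  significant <- genes %in% sig_genes
  tab <- contingency_2x2(sum(hosts_changing & significant),
                         sum(hosts_changing & !significant),
                         sum(!hosts_changing & significant),
                         sum(!hosts_changing & !significant))
  res <- list(table = tab, odds_ratio = odds_ratio(tab),
              p_value = fisher_exact(tab, alternative),
              method = "fisher", mode = "expression",
              alternative = alternative, population = NULL,
              alpha = alpha)
  class(res) <- "enrichment_result"
  res
}
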