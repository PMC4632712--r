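#' Permutation null for the overlap of changed and annotated SNP sets
#'
#' Empirical randomization test for "how many regulation-changing SNPs fall
#' in an annotated set": each permutation redraws `|changed_set|` SNP ids
#' uniformly without replacement from the universe and counts the overlap
#' with the annotated set.  Only set sizes are preserved (no matching on
#' allele frequency or gene length), so the null counts follow the
#' hypergeometric distribution with the corresponding parameters.
#'
#' The empirical p carries the +1 correction,
#' `p = (#\{null >= observed\} + 1) / (n_perm + 1)` for the default upper
#' tail; `"less"` uses the lower tail and `"two.sided"` doubles the smaller
#' tail (capped at 1).
#'
#' @param universe character vector of all SNP ids.
#' @param changed_set subset of `universe`: the regulation-changing SNPs.
#' @param annotated_set subset of `universe`: the annotated SNPs.
#' @param n_perm number of permutations (>= 100), default 10000.
#' @param seed integer seed; the draw is deterministic given the seed.
#' @param alternative `"greater"` (default, enrichment), `"less"` or
#'   `"two.sided"`.
#' @return object of class `permutation_result`: `observed`, `expected`
#'   (mean of null counts), `null_counts`, `p_value`, `n_perm`, `seed`,
#'   `alternative`.
#' @export
permute_overlap <- function(universe, changed_set, annotated_set,
                            n_perm = 10000L, seed = 1L,
                            alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  universe <- unique(as.character(universe))
  changed_set <- unique(as.character(changed_set))
  annotated_set <- unique(as.character(annotated_set))
  if (!all(changed_set %in% universe)) {
    stop("inconsistent input: changed_set is not a subset of the universe")
  }
  if (!all(annotated_set %in% universe)) {
    stop("inconsistent input: annotated_set is not a subset of the universe")
  }
  if (n_perm < 100L) stop("n_perm must be >= 100")

  observed <- length(intersect(changed_set, annotated_set))
  ann <- universe %in% annotated_set
  m <- length(changed_set)
  N <- length(universe)

  null_counts <- local_seed(seed, {
    vapply(seq_len(n_perm),
           function(i) sum(ann[sample.int(N, m)]), integer(1))
  })

  p_up <- (sum(null_counts >= observed) + 1) / (n_perm + 1)
  p_lo <- (sum(null_counts <= observed) + 1) / (n_perm + 1)
  p <- switch(alternative,
              greater = p_up, less = p_lo,
              two.sided = min(1, 2 * min(p_up, p_lo)))
  structure(list(observed = observed, expected = mean(null_counts),
                 null_counts = null_counts, p_value = p,
                 n_perm = as.integer(n_perm), seed = as.integer(seed),
                 alternative = alternative),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat("Randomization test (", x$n_perm, " permutations, seed ", x$seed,
      ")\n", sep = "")
  cat(sprintf("  observed overlap = %d, expected = %.2f\n",
              x$observed, x$expected))
  cat(sprintf("  p (%s) = %.4g\n", x$alternative, x$p_value))
  invisible(x)
}

#' Null-count histogram of a permutation result
#'
#' Tabulates the null overlap counts (the curve behind the empirical null
#' distribution figure).
#'
#' @param x a `permutation_result`.
#' @param path optional TSV path; when given, the histogram is written there.
#' @return data.frame with columns `count`, `n_perms`, `frequency`.
#' @export
null_histogram <- function(x, path = NULL) {
  stopifnot(inherits(x, "permutation_result"))
  tb <- table(x$null_counts)
  h <- data.frame(count = as.integer(names(tb)),
                  n_perms = as.integer(tb),
                  frequency = as.integer(tb) / x$n_perm)
  if (!is.null(path)) {
    utils::write.table(h, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  h
}

# Evaluate an expression under a fixed RNG state, restoring the caller's
# state afterwards.
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}
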