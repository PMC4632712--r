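#' Run the full analysis pipeline
#'
#' Binds the stages end to end: allele-swap classification of every SNP,
#' per-population |iHS| selection screens (Fisher 2x2 plus Wilcoxon
#' rank-sum on the score distributions), binary-track disease enrichments,
#' randomization tests of the changed/annotated overlaps, and the
#' genotype-expression association stage with its gene-level enrichment.
#' All tables, odds ratios, p-values, thresholds and seeds appear in the
#' returned summary, so every result can be re-derived from it.
#'
#' @param snps a [snp_table()].
#' @param catalog a [seed_catalog()].
#' @param ihs_tracks named list of scalar [annotation_track()]s (one per
#'   population), or `NULL` to skip the selection stage.
#' @param binary_tracks named list of binary tracks (e.g. `disease`,
#'   `deleterious`), or `NULL`.
#' @param expression_data list with `genotypes`, `expression`,
#'   `snp_to_gene` (see [simulate_expression()] / [read_matrices()]), or
#'   `NULL`.
#' @param ihs_threshold |iHS| cutoff for strong selection, default 2.5.
#' @param alpha per-association significance level for the expression
#'   stage, default 0.05.
#' @param n_perm permutations for the randomization tests, default 10000.
#' @param seed integer seed for the randomization stage.
#' @param snp_class restrict enrichments to one class (`"synonymous"` /
#'   `"nonsynonymous"`), or `NULL` for all SNPs.
#' @return object of class `mirsnp_pipeline`: list with `classification`,
#'   `selection`, `wilcoxon`, `disease`, `randomization`, `association`,
#'   `expression_enrichment`, and `settings`.
#' @export
run_pipeline <- function(snps, catalog, ihs_tracks = NULL,
                         binary_tracks = NULL, expression_data = NULL,
                         ihs_threshold = 2.5, alpha = 0.05,
                         n_perm = 10000L, seed = 1L, snp_class = NULL) {
  cl <- classify_all(snps, catalog)
  flags <- changed_flags(cl, snp_class = snp_class)
  changed_ids <- names(flags)[flags]

  selection <- wilcoxon <- NULL
  if (!is.null(ihs_tracks)) {
    selection <- lapply(ihs_tracks, function(tr) {
      run_enrichment(flags, tr, mode = "selection",
                     threshold = ihs_threshold)
    })
    wilcoxon <- lapply(ihs_tracks, function(tr) {
      v <- tr[!is.na(tr)]
      ids <- intersect(names(v), names(flags))
      wilcoxon_rank_sum(abs(v[ids[flags[ids]]]), abs(v[ids[!flags[ids]]]))
    })
  }

  disease <- randomization <- NULL
  if (!is.null(binary_tracks)) {
    disease <- lapply(binary_tracks, function(tr) {
      run_enrichment(flags, tr, mode = "disease")
    })
    randomization <- lapply(binary_tracks, function(tr) {
      ids <- intersect(names(tr), names(flags))
      permute_overlap(ids, intersect(changed_ids, ids),
                      ids[tr[ids] == 1], n_perm = n_perm, seed = seed)
    })
  }

  association <- expression_enrichment <- NULL
  if (!is.null(expression_data)) {
    association <- assoc_table(expression_data$genotypes,
                               expression_data$expression,
                               expression_data$snp_to_gene)
    expression_enrichment <- gene_level_enrichment(
      association, flags, expression_data$snp_to_gene, alpha = alpha)
  }

  out <- list(classification = cl, selection = selection,
              wilcoxon = wilcoxon, disease = disease,
              randomization = randomization, association = association,
              expression_enrichment = expression_enrichment,
              settings = list(
                counted_types = catalog$counted_types,
                ihs_threshold = ihs_threshold, alpha = alpha,
                n_perm = as.integer(n_perm), seed = as.integer(seed),
                snp_class = snp_class,
                package_version = as.character(
                  utils::packageVersion("mirsnp"))))
  class(out) <- "mirsnp_pipeline"
  out
}

#' @export
print.mirsnp_pipeline <- function(x, ...) {
  cat("miRNA-regulation SNP analysis pipeline\n")
  cat("  counted site types:",
      paste(x$settings$counted_types, collapse = ", "), "\n")
  print(x$classification)
  if (!is.null(x$selection)) {
    cat("Selection screens (|iHS| >=", x$settings$ihs_threshold, "):\n")
    for (pop in names(x$selection)) {
      r <- x$selection[[pop]]
      cat(sprintf("  %-4s OR = %.3g, Fisher p = %.3g, Wilcoxon p = %.3g\n",
                  pop, r$odds_ratio, r$p_value, x$wilcoxon[[pop]]))
    }
  }
  if (!is.null(x$disease)) {
    for (nm in names(x$disease)) {
      r <- x$disease[[nm]]
      cat(sprintf("Disease track '%s': OR = %.3g, Fisher p = %.3g", nm,
                  r$odds_ratio, r$p_value))
      pr <- x$randomization[[nm]]
      cat(sprintf(", randomization p = %.3g (obs %d, exp %.1f)\n",
                  pr$p_value, pr$observed, pr$expected))
    }
  }
  if (!is.null(x$expression_enrichment)) {
    r <- x$expression_enrichment
    cat(sprintf(
      "Expression stage: %d associations, gene-level OR = %.3g, p = %.3g\n",
      nrow(x$association), r$odds_ratio, r$p_value))
  }
  invisible(x)
}

#' Machine-readable pipeline summary
#'
#' Flattens a pipeline result into plain lists (written as JSON when `path`
#' is given): per-class change counts, every 2x2 table with its odds ratio
#' and p-value, Wilcoxon and randomization p-values, expression-stage
#' counts, thresholds and seeds.
#'
#' @param x a `mirsnp_pipeline`.
#' @param path optional JSON output path.
#' @return the summary list, invisibly when writing.
#' @export
pipeline_summary <- function(x, path = NULL) {
  stopifnot(inherits(x, "mirsnp_pipeline"))
  enr <- function(r) {
    if (is.null(r)) return(NULL)
    m <- unclass(r$table)
    list(a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2],
         odds_ratio = r$odds_ratio, p_value = r$p_value,
         alternative = r$alternative)
  }
  s <- list(
    classification = x$classification$summary,
    selection = lapply(x$selection, enr),
    wilcoxon = x$wilcoxon,
    disease = lapply(x$disease, enr),
    randomization = lapply(x$randomization, function(r) {
      list(observed = r$observed, expected = r$expected,
           p_value = r$p_value, n_perm = r$n_perm, seed = r$seed)
    }),
    expression_enrichment = enr(x$expression_enrichment),
    n_associations = if (is.null(x$association)) NULL else
      nrow(x$association),
    settings = x$settings)
  if (!is.null(path)) {
    jsonlite::write_json(s, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, dataframe = "rows")
    return(invisible(s))
  }
  s
}
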