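#' Annotation track
#'
#' A per-SNP annotation: either a scalar track (e.g. iHS selection scores,
#' possibly covering only part of the SNP universe) or a binary track
#' (disease association, deleterious label).
#'
#' @param snp_id character vector of SNP identifiers (unique).
#' @param value numeric values; binary tracks must be 0/1.
#' @param kind `"scalar"` or `"binary"`.
#' @param population optional population label (e.g. `"ASI"`).
#' @return named numeric vector of class `annotation_track` with attributes
#'   `kind` and `population`.
#' @export
annotation_track <- function(snp_id, value, kind = c("scalar", "binary"),
                             population = NULL) {
  kind <- match.arg(kind)
  if (anyDuplicated(snp_id)) stop("duplicate snp_id in annotation track")
  value <- as.numeric(value)
  if (kind == "binary" && !all(value %in% c(0, 1))) {
    stop("binary track values must be 0/1")
  }
  structure(stats::setNames(value, as.character(snp_id)),
            kind = kind, population = population,
            class = "annotation_track")
}

#' @export
print.annotation_track <- function(x, ...) {
  cat(sprintf("Annotation track (%s%s): %d SNP(s)\n", attr(x, "kind"),
              if (!is.null(attr(x, "population")))
                paste0(", ", attr(x, "population")) else "",
              length(x)))
  invisible(x)
}

#' Flag SNPs under strong recent positive selection
#'
#' Thresholds the absolute value of a scalar selection-score track
#' (integrated haplotype score, iHS): flag 1 iff `|value| >= threshold`.
#' SNPs without a score are excluded from the output, not flagged 0 — the
#' selection universe is only the scored SNPs.
#'
#' @param track named numeric vector (e.g. an `annotation_track`) of scores;
#'   `NA` entries are dropped.
#' @param threshold positive threshold, default 2.5.
#' @return named integer 0/1 vector over SNPs having a score.
#' @export
strong_selection_flags <- function(track, threshold = 2.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("invalid threshold: must be a single positive number")
  }
  v <- track[!is.na(track)]
  nm <- names(v)
  if (is.null(nm)) nm <- character(length(v))
  stats::setNames(as.integer(abs(as.numeric(v)) >= threshold), nm)
}

#' 2x2 contingency table of change status vs annotation
#'
#' Rows are (changed, not changed), columns (annotated, not annotated):
#' `a` = changed & annotated, `b` = changed & not, `c` = not changed &
#' annotated, `d` = neither.
#'
#' @param a,b,c,d non-negative integer counts.
#' @return 2x2 integer matrix of class `contingency_2x2`.
#' @export
contingency_2x2 <- function(a, b, c, d) {
  x <- c(a, b, c, d)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x))) {
    stop("counts must be non-negative integers")
  }
  if (sum(x) == 0) stop("empty table: total count is zero")
  m <- matrix(as.integer(round(x)), nrow = 2L, byrow = TRUE,
              dimnames = list(changed = c("yes", "no"),
                              annotated = c("yes", "no")))
  class(m) <- c("contingency_2x2", class(m))
  m
}

#' Cross-tabulate changed and annotated flags
#'
#' Both flag vectors are named by SNP id; the table is built over the
#' intersection of the two universes (a size mismatch is reported).
#'
#' @param changed named logical/0-1 vector of change status.
#' @param annotated named logical/0-1 vector of annotation status.
#' @return a [contingency_2x2()].
#' @export
make_table <- function(changed, annotated) {
  ids <- intersect(names(changed), names(annotated))
  if (!length(ids)) stop("empty universe: no SNP ids shared between flags")
  if (length(ids) < length(changed) || length(ids) < length(annotated)) {
    message(sprintf(
      "make_table: universes differ (%d changed, %d annotated, %d shared)",
      length(changed), length(annotated), length(ids)))
  }
  ch <- as.logical(changed[ids])
  an <- as.logical(annotated[ids])
  contingency_2x2(sum(ch & an), sum(ch & !an), sum(!ch & an), sum(!ch & !an))
}

#' Fisher exact p-value for a 2x2 table
#'
#' Exact hypergeometric test of independence.  The two-sided p uses the
#' probability-mass convention (sum of all margin-preserving tables whose
#' point probability does not exceed the observed one), matching R's
#' `fisher.test`.  One-sided alternatives test enrichment (`"greater"`) or
#' depletion (`"less"`) of cell `a`.
#'
#' @param table a [contingency_2x2()] (or any 2x2 matrix of counts).
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return p-value in (0, 1]; a table with a zero margin returns 1 with
#'   attribute `degenerate = TRUE`.
#' @export
fisher_exact <- function(table,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  m <- unclass(table)
  stopifnot(is.matrix(m), all(dim(m) == 2L))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    return(structure(1, degenerate = TRUE))
  }
  stats::fisher.test(m, alternative = alternative)$p.value
}

#' Sample odds ratio of a 2x2 table
#'
#' The sample estimator `a*d / (b*c)` (not the conditional MLE).  Returns
#' `Inf` when `b*c == 0` with `a*d > 0`, and `NaN` when both products are 0
#' (undefined).
#'
#' @param table a [contingency_2x2()] (or any 2x2 matrix of counts).
#' @return positive real, `Inf`, or `NaN`.
#' @export
odds_ratio <- function(table) {
  m <- unclass(table)
  stopifnot(is.matrix(m), all(dim(m) == 2L))
  ad <- as.numeric(m[1, 1]) * as.numeric(m[2, 2])
  bc <- as.numeric(m[1, 2]) * as.numeric(m[2, 1])
  if (bc == 0) {
    if (ad == 0) return(NaN)
    return(Inf)
  }
  ad / bc
}

#' Wilcoxon rank-sum test (two-sided)
#'
#' Compares two score distributions (e.g. |iHS| of changing vs non-changing
#' SNPs).  Uses the exact rank-sum distribution for small tie-free samples
#' (both n <= 50) and the normal approximation with continuity and tie
#' correction otherwise.
#'
#' @param xs,ys numeric samples (non-empty).
#' @return two-sided p-value.
#' @export
wilcoxon_rank_sum <- function(xs, ys) {
  xs <- xs[!is.na(xs)]; ys <- ys[!is.na(ys)]
  if (!length(xs) || !length(ys)) stop("empty sample in rank-sum test")
  exact <- length(xs) <= 50L && length(ys) <= 50L
  suppressWarnings(
    stats::wilcox.test(xs, ys, alternative = "two.sided", exact = exact,
                       correct = TRUE)$p.value
  )
}

#' Enrichment of changing SNPs in an annotation
#'
#' Composes the full 2x2 enrichment: in `selection` mode the scalar track is
#' first thresholded by [strong_selection_flags()] (universe = scored SNPs
#' only); in `disease` mode the binary track is used directly.  Then
#' [make_table()], [fisher_exact()] and [odds_ratio()].
#'
#' @param changes a `mirsnp_classification`, its `changes` data.frame, or a
#'   named logical vector of changed flags.
#' @param track an [annotation_track()] (or named numeric vector).
#' @param mode `"selection"` or `"disease"`.
#' @param threshold |iHS| threshold for selection mode, default 2.5.
#' @param alternative sidedness passed to [fisher_exact()].
#' @param snp_class optional restriction of the change flags by class.
#' @return object of class `enrichment_result`: list with `table`,
#'   `odds_ratio`, `p_value`, `method`, `mode`, `alternative`, `population`.
#' @export
run_enrichment <- function(changes, track, mode = c("selection", "disease"),
                           threshold = 2.5,
                           alternative = c("two.sided", "greater", "less"),
                           snp_class = NULL) {
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  ch <- if (is.vector(changes) || is.logical(changes)) changes else
    changed_flags(changes, snp_class = snp_class)
  ann <- if (mode == "selection") strong_selection_flags(track, threshold)
         else track[!is.na(track)]
  tab <- make_table(ch, ann)
  res <- list(table = tab, odds_ratio = odds_ratio(tab),
              p_value = fisher_exact(tab, alternative),
              method = "fisher", mode = mode, alternative = alternative,
              population = attr(track, "population"))
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("Enrichment (%s%s, Fisher %s)\n", x$mode,
              if (!is.null(x$population)) paste0(" ", x$population) else "",
              x$alternative))
  m <- unclass(x$table)
  cat(sprintf("  changed:     %6d annotated / %6d not\n", m[1, 1], m[1, 2]))
  cat(sprintf("  not changed: %6d annotated / %6d not\n", m[2, 1], m[2, 2]))
  cat(sprintf("  OR = %.3g, p = %.3g\n", x$odds_ratio, x$p_value))
  invisible(x)
}

#' Write enrichment results to TSV
#'
#' @param results an `enrichment_result` or list of them.
#' @param path output path.
#' @export
write_enrichment <- function(results, path) {
  if (inherits(results, "enrichment_result")) results <- list(results)
  rows <- lapply(results, function(r) {
    m <- unclass(r$table)
    data.frame(a = m[1, 1], b = m[1, 2], c = m[2, 1], d = m[2, 2],
               odds_ratio = r$odds_ratio, p_value = r$p_value,
               method = r$method, mode = r$mode,
               alternative = r$alternative,
               population = if (is.null(r$population)) NA else r$population,
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
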