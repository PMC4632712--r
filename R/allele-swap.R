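#' Validate a SNP table
#'
#' A SNP table is a data.frame with one coding-region SNP per row: columns
#' `snp_id`, `left_flank`, `allele_a`, `allele_b`, `right_flank`,
#' `snp_class`.  Flanks target 15 nt each side (a 31-nt window); shorter
#' flanks are permitted near transcript ends and flagged downstream rather
#' than dropped.  `snp_class` is `"synonymous"`, `"nonsynonymous"` or `NA`
#' when the input carries no annotation.
#'
#' @param snps data.frame of SNP records.
#' @return the validated, normalized data.frame (invisibly classed
#'   `snp_table`).
#' @export
snp_table <- function(snps) {
  need <- c("snp_id", "left_flank", "allele_a", "allele_b", "right_flank",
            "snp_class")
  miss <- setdiff(need, names(snps))
  if (length(miss)) stop("missing SNP columns: ", paste(miss, collapse = ", "))
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  if (anyDuplicated(snps$snp_id)) {
    stop("duplicate snp_id: ",
         paste(unique(snps$snp_id[duplicated(snps$snp_id)]), collapse = ", "))
  }
  snps$left_flank <- normalize_sequence(as.character(snps$left_flank))
  snps$right_flank <- normalize_sequence(as.character(snps$right_flank))
  snps$allele_a <- normalize_sequence(as.character(snps$allele_a))
  snps$allele_b <- normalize_sequence(as.character(snps$allele_b))
  if (nrow(snps)) {
    ok1 <- nchar(snps$allele_a) == 1L & snps$allele_a %in% c("A", "C", "G", "T")
    ok2 <- nchar(snps$allele_b) == 1L & snps$allele_b %in% c("A", "C", "G", "T")
    if (!all(ok1 & ok2)) {
      stop("alleles must be single A/C/G/T bases: ",
           paste(snps$snp_id[!(ok1 & ok2)], collapse = ", "))
    }
    if (any(snps$allele_a == snps$allele_b)) {
      stop("allele_a equals allele_b for: ",
           paste(snps$snp_id[snps$allele_a == snps$allele_b], collapse = ", "))
    }
    if (any(nchar(snps$left_flank) > 15L | nchar(snps$right_flank) > 15L)) {
      stop("flanks longer than 15 nt for: ",
           paste(snps$snp_id[nchar(snps$left_flank) > 15L |
                             nchar(snps$right_flank) > 15L], collapse = ", "))
    }
    bad <- !(is.na(snps$snp_class) |
             snps$snp_class %in% c("synonymous", "nonsynonymous"))
    if (any(bad)) {
      stop("snp_class must be synonymous/nonsynonymous/NA: ",
           paste(snps$snp_id[bad], collapse = ", "))
    }
  }
  class(snps) <- c("snp_table", "data.frame")
  snps
}

#' Build the allele-centered window for one allele
#'
#' Concatenates `left_flank + allele + right_flank` on the mRNA sense
#' strand.  With full 15-nt flanks the window is 31 nt and the allele sits at
#' 0-based offset 15; truncated flanks near transcript ends shift the allele
#' offset accordingly (`nchar(left_flank)`).
#'
#' @param snps a [snp_table()] (or any data.frame with its columns).
#' @param which_allele `"a"` or `"b"`.
#' @return character vector of windows, one per SNP.
#' @export
build_allele_window <- function(snps, which_allele = c("a", "b")) {
  which_allele <- match.arg(which_allele)
  al <- if (which_allele == "a") snps$allele_a else snps$allele_b
  w <- paste0(snps$left_flank, al, snps$right_flank)
  short <- nchar(w) < 8L
  if (any(short)) {
    stop("window shorter than 8 nt (flanks too short) for: ",
         paste(snps$snp_id[short], collapse = ", "))
  }
  w
}

#' Classify one SNP as changing miRNA regulation
#'
#' Builds both allele windows, scans each against the catalog, and reports
#' the miRNAs gained (bind the b-allele window only) and lost (bind the
#' a-allele window only).  A SNP changes regulation iff it gains or loses at
#' least one miRNA; a SNP that merely moves a site for a miRNA that still
#' binds both windows is not a change.
#'
#' @param snp a single-row [snp_table()].
#' @param catalog a [seed_catalog()].
#' @return list of class `regulation_change` with elements `snp_id`,
#'   `gained`, `lost` (character vectors) and `changed` (logical).
#' @export
classify_snp <- function(snp, catalog) {
  snp <- snp_table(snp)
  if (nrow(snp) != 1L) stop("classify_snp expects a single SNP")
  ga <- binding_mirnas(build_allele_window(snp, "a"), catalog)
  gb <- binding_mirnas(build_allele_window(snp, "b"), catalog)
  res <- list(snp_id = snp$snp_id, gained = setdiff(gb, ga),
              lost = setdiff(ga, gb))
  res$changed <- length(res$gained) + length(res$lost) > 0L
  class(res) <- "regulation_change"
  res
}

#' @export
print.regulation_change <- function(x, ...) {
  cat(sprintf("SNP %s: %s\n", x$snp_id,
              if (x$changed) "changes miRNA regulation" else "no change"))
  if (length(x$gained)) cat("  gained:", paste(x$gained, collapse = ", "), "\n")
  if (length(x$lost)) cat("  lost:  ", paste(x$lost, collapse = ", "), "\n")
  invisible(x)
}

#' Classify every SNP in a table
#'
#' Vectorized allele-swap classification: both windows of every SNP are
#' scanned in one pass, per-SNP gained/lost miRNA sets are derived by set
#' difference, and per-class changed fractions are summarized.
#'
#' @param snps a [snp_table()].
#' @param catalog a [seed_catalog()].
#' @return object of class `mirsnp_classification`: list with
#'   * `changes`: data.frame `snp_id`, `snp_class`, `changed`, `gained`,
#'     `lost` (list columns of miRNA names), `short_flank`;
#'   * `summary`: data.frame `snp_class`, `n`, `n_changed`, `fraction`
#'     (fraction is `NA` for empty strata).
#' @export
classify_all <- function(snps, catalog) {
  snps <- snp_table(snps)
  n <- nrow(snps)
  if (n == 0L) {
    changes <- data.frame(snp_id = character(), snp_class = character(),
                          changed = logical(), short_flank = logical(),
                          stringsAsFactors = FALSE)
    changes$gained <- list()
    changes$lost <- list()
    out <- list(changes = changes,
                summary = data.frame(snp_class = character(), n = integer(),
                                     n_changed = integer(),
                                     fraction = numeric()))
    class(out) <- "mirsnp_classification"
    return(out)
  }
  wa <- build_allele_window(snps, "a")
  wb <- build_allele_window(snps, "b")
  hits <- scan_windows(c(wa, wb), catalog)
  key <- paste(hits$window, hits$mirna, sep = "\r")
  hm <- hits$mirna[!duplicated(key)]
  hw <- hits$window[!duplicated(key)]
  sets_a <- split(hm[hw <= n], factor(hw[hw <= n], levels = seq_len(n)))
  sets_b <- split(hm[hw > n], factor(hw[hw > n] - n, levels = seq_len(n)))
  gained <- Map(setdiff, sets_b, sets_a)
  lost <- Map(setdiff, sets_a, sets_b)
  gained <- lapply(gained, sort)
  lost <- lapply(lost, sort)
  changed <- lengths(gained) + lengths(lost) > 0L

  changes <- data.frame(snp_id = snps$snp_id, snp_class = snps$snp_class,
                        changed = unname(changed),
                        short_flank = nchar(snps$left_flank) < 15L |
                                      nchar(snps$right_flank) < 15L,
                        stringsAsFactors = FALSE)
  changes$gained <- unname(gained)
  changes$lost <- unname(lost)

  cls <- ifelse(is.na(changes$snp_class), "unannotated", changes$snp_class)
  tot <- tapply(changes$changed, cls, length)
  chg <- tapply(changes$changed, cls, sum)
  summary <- data.frame(snp_class = names(tot), n = as.integer(tot),
                        n_changed = as.integer(chg),
                        fraction = as.numeric(chg) / as.numeric(tot),
                        row.names = NULL, stringsAsFactors = FALSE)
  out <- list(changes = changes, summary = summary)
  class(out) <- "mirsnp_classification"
  out
}

#' @export
print.mirsnp_classification <- function(x, ...) {
  cat("miRNA-regulation change classification\n")
  cat(sprintf("  %d SNP(s), %d changing regulation\n",
              nrow(x$changes), sum(x$changes$changed)))
  if (nrow(x$summary)) {
    for (i in seq_len(nrow(x$summary))) {
      cat(sprintf("  %-14s %6d / %-6d changed (%.1f%%)\n",
                  x$summary$snp_class[i], x$summary$n_changed[i],
                  x$summary$n[i], 100 * x$summary$fraction[i]))
    }
  }
  invisible(x)
}

#' Changed-status flags from a classification
#'
#' @param x a `mirsnp_classification` (or its `changes` data.frame).
#' @param snp_class optional filter (`"synonymous"`/`"nonsynonymous"`).
#' @return named logical vector keyed by `snp_id`.
#' @export
changed_flags <- function(x, snp_class = NULL) {
  ch <- if (inherits(x, "mirsnp_classification")) x$changes else x
  if (!is.null(snp_class)) {
    ch <- ch[!is.na(ch$snp_class) & ch$snp_class %in% snp_class, ,
             drop = FALSE]
  }
  stats::setNames(ch$changed, ch$snp_id)
}
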