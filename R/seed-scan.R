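SITE_TYPES <- c("6mer", "7mer-A1", "7mer-m8", "8mer-1a")

# Priority used when nested site variants co-occur at one seed-complement
# locus: only the strongest canonical class is reported.
SITE_PRIORITY <- c("6mer" = 1L, "7mer-A1" = 2L, "7mer-m8" = 3L, "8mer-1a" = 4L)

# Offset of the 6-nt seed-complement core within each site pattern.  Patterns
# that include the match to miRNA position 8 carry one extra 5'-most base.
CORE_OFFSET <- c("6mer" = 0L, "7mer-A1" = 0L, "7mer-m8" = 1L, "8mer-1a" = 1L)

#' Normalize a nucleotide sequence
#'
#' Uppercases, maps RNA U to DNA T and validates the alphabet.  All internal
#' code works on the normalized DNA alphabet `A/C/G/T/N`.
#'
#' @param seq character vector of nucleotide sequences.
#' @return character vector of the same length, normalized.
#' @examples
#' normalize_sequence("augcu")  # "ATGCT"
#' @export
normalize_sequence <- function(seq) {
  if (!is.character(seq)) stop("sequence must be a character vector")
  out <- chartr("U", "T", toupper(seq))
  bad <- regexpr("[^ACGTN]", out)
  hit <- which(bad > 0L)
  if (length(hit)) {
    i <- hit[1L]
    stop(sprintf(
      "malformed sequence: invalid character '%s' at position %d%s",
      substr(out[i], bad[i], bad[i]), bad[i],
      if (length(seq) > 1L) sprintf(" (element %d)", i) else ""
    ))
  }
  out
}

.revcomp <- function(x) {
  # DNA reverse complement of normalized sequences
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Target-strand match patterns for a mature miRNA
#'
#' Derives, for each canonical site class, the exact subsequence on the mRNA
#' sense strand that constitutes a match to the miRNA seed (positions 2-8 of
#' the mature sequence).  `6mer` is the reverse complement of seed positions
#' 2-7; `7mer-m8` extends the perfect match to position 8; `7mer-A1` and
#' `8mer-1a` additionally require an `A` on the target opposite miRNA
#' position 1.
#'
#' @param mature_seq a single mature miRNA sequence (RNA or DNA, length >= 8).
#' @return named character vector with elements `6mer`, `7mer-A1`, `7mer-m8`,
#'   `8mer-1a`.
#' @examples
#' seed_match_site("UGGAGUGUGACAAUGGUGUUUG")[["7mer-m8"]]  # "ACACTCC"
#' @export
seed_match_site <- function(mature_seq) {
  s <- normalize_sequence(mature_seq)
  if (length(s) != 1L) stop("mature_seq must be a single sequence")
  if (nchar(s) < 8L) {
    stop(sprintf("invalid miRNA: mature sequence has %d nt, need >= 8", nchar(s)))
  }
  if (grepl("N", substr(s, 2L, 8L), fixed = TRUE)) {
    stop("invalid miRNA: ambiguous base (N) inside the seed region")
  }
  rc6 <- .revcomp(substr(s, 2L, 7L))
  rc7 <- .revcomp(substr(s, 2L, 8L))
  c("6mer" = rc6, "7mer-A1" = paste0(rc6, "A"),
    "7mer-m8" = rc7, "8mer-1a" = paste0(rc7, "A"))
}

#' Build a seed catalog
#'
#' A seed catalog holds a set of uniquely named mature miRNAs plus the site
#' classes counted as "miRNA regulation".  The default counts `8mer-1a`,
#' `7mer-m8` and `7mer-A1`; marginal `6mer` sites can be enabled via
#' `counted_types`.
#'
#' @param name character vector of unique miRNA identifiers.
#' @param mature_seq character vector of mature sequences (RNA or DNA,
#'   length >= 8 each).
#' @param counted_types site classes that qualify as regulation.
#' @return an object of class `seed_catalog`.
#' @export
seed_catalog <- function(name, mature_seq,
                         counted_types = c("8mer-1a", "7mer-m8", "7mer-A1")) {
  name <- as.character(name)
  if (length(name) != length(mature_seq)) {
    stop("name and mature_seq must have equal length")
  }
  if (anyDuplicated(name)) {
    stop("duplicate miRNA names: ",
         paste(unique(name[duplicated(name)]), collapse = ", "))
  }
  counted_types <- match.arg(counted_types, SITE_TYPES, several.ok = TRUE)
  if (!length(counted_types)) stop("counted_types must be non-empty")
  mature_seq <- normalize_sequence(as.character(mature_seq))
  if (length(name) && any(nchar(mature_seq) < 8L)) {
    stop("invalid miRNA: mature sequence shorter than 8 nt for ",
         paste(name[nchar(mature_seq) < 8L], collapse = ", "))
  }
  pats <- if (length(name)) {
    do.call(rbind, lapply(seq_along(name), function(i) {
      p <- seed_match_site(mature_seq[i])
      data.frame(mirna = name[i], site_type = names(p), pattern = unname(p),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(mirna = character(), site_type = character(),
               pattern = character(), stringsAsFactors = FALSE)
  }
  pats$len <- nchar(pats$pattern)
  pats$priority <- SITE_PRIORITY[pats$site_type]
  pats$core_offset <- CORE_OFFSET[pats$site_type]
  structure(
    list(records = data.frame(name = name, mature_seq = mature_seq,
                              stringsAsFactors = FALSE),
         counted_types = counted_types,
         patterns = pats),
    class = "seed_catalog"
  )
}

#' @export
print.seed_catalog <- function(x, ...) {
  cat("Seed catalog:", nrow(x$records), "miRNA(s)\n")
  cat("Counted site types:", paste(x$counted_types, collapse = ", "), "\n")
  if (nrow(x$records)) {
    show <- utils::head(x$records, 5L)
    cat(paste0("  ", show$name, "  seed(2-8) ",
               substr(show$mature_seq, 2L, 8L), collapse = "\n"), "\n")
    if (nrow(x$records) > 5L) cat("  ...\n")
  }
  invisible(x)
}

# Vectorized scan of many windows against a catalog.  Returns one row per
# reported site: window (index into `windows`), mirna, site_type, start, end
# (0-based half-open window offsets).  Matching is literal on the mRNA sense
# strand; windows containing N never match at positions covering the N
# because patterns are N-free.  Nested variants at one seed-complement locus
# are collapsed to the highest-priority class per (window, miRNA, locus).
scan_windows <- function(windows, catalog, counted_types = NULL) {
  stopifnot(inherits(catalog, "seed_catalog"))
  counted <- if (is.null(counted_types)) catalog$counted_types else
    match.arg(counted_types, SITE_TYPES, several.ok = TRUE)
  pats <- catalog$patterns[catalog$patterns$site_type %in% counted, ,
                           drop = FALSE]
  empty <- data.frame(window = integer(), mirna = character(),
                      site_type = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
  if (!length(windows) || !nrow(pats)) return(empty)
  nw <- nchar(windows)

  hits <- list()
  for (k in sort(unique(pats$len))) {
    pk <- pats[pats$len == k, , drop = FALSE]
    wi <- which(nw >= k)
    if (!length(wi)) next
    nk <- nw[wi] - k + 1L
    win <- rep(wi, nk)
    pos <- sequence(nk) - 1L                       # 0-based start
    kmer <- substring(windows[win], pos + 1L, pos + k)
    # multi-match join: one pattern string may serve several miRNAs
    upat <- unique(pk$pattern)
    m <- match(kmer, upat)
    keep <- !is.na(m)
    if (!any(keep)) next
    rows_by_pat <- split(seq_len(nrow(pk)), factor(pk$pattern, levels = upat))
    npp <- lengths(rows_by_pat)
    mk <- m[keep]
    prow <- unlist(rows_by_pat[mk], use.names = FALSE)
    hits[[length(hits) + 1L]] <- data.frame(
      window = rep(win[keep], npp[mk]),
      start = rep(pos[keep], npp[mk]),
      mirna = pk$mirna[prow],
      site_type = pk$site_type[prow],
      priority = pk$priority[prow],
      core = rep(pos[keep], npp[mk]) + pk$core_offset[prow],
      end = rep(pos[keep], npp[mk]) + k,
      stringsAsFactors = FALSE
    )
  }
  if (!length(hits)) return(empty)
  h <- do.call(rbind, hits)
  # per (window, miRNA, core locus) keep the highest-priority site class
  h <- h[order(h$window, h$mirna, h$core, -h$priority), , drop = FALSE]
  h <- h[!duplicated(paste(h$window, h$mirna, h$core, sep = "\r")), ,
         drop = FALSE]
  h <- h[order(h$window, h$start, h$mirna), , drop = FALSE]
  rownames(h) <- NULL
  h[, c("window", "mirna", "site_type", "start", "end")]
}

#' Scan one window for canonical seed-match sites
#'
#' Reports every occurrence of every counted site class for every catalog
#' miRNA that lies fully inside the window.  When an `8mer-1a` site and its
#' nested 7mer variants co-occur at one locus, only the highest-priority
#' class (`8mer-1a` > `7mer-m8` > `7mer-A1` > `6mer`) is reported for that
#' (miRNA, locus).  Positions containing `N` never match.
#'
#' @param window a single normalized nucleotide window (length >= 6).
#' @param catalog a [seed_catalog()].
#' @param counted_types optional override of the catalog's counted types.
#' @return data.frame with columns `mirna`, `site_type`, `start`, `end`
#'   (0-based half-open), ordered by (`start`, `mirna`).
#' @export
scan_sites <- function(window, catalog, counted_types = NULL) {
  window <- normalize_sequence(window)
  if (length(window) != 1L) stop("window must be a single sequence")
  if (nchar(window) < 6L) stop("window shorter than 6 nt")
  h <- scan_windows(window, catalog, counted_types)
  h$window <- NULL
  h
}

#' miRNAs binding a window
#'
#' Set semantics over [scan_sites()]: the distinct miRNA names with at least
#' one counted site in the window.
#'
#' @inheritParams scan_sites
#' @return sorted character vector of miRNA names.
#' @export
binding_mirnas <- function(window, catalog, counted_types = NULL) {
  sort(unique(scan_sites(window, catalog, counted_types)$mirna))
}

#' Write a site report
#'
#' @param sites data.frame from [scan_sites()] with an added `window_id`
#'   column, or a list of such frames named by window id.
#' @param path output TSV path.
#' @export
write_site_report <- function(sites, path) {
  if (is.list(sites) && !is.data.frame(sites)) {
    sites <- do.call(rbind, lapply(names(sites), function(id) {
      s <- sites[[id]]
      if (!nrow(s)) return(NULL)
      cbind(window_id = id, s, stringsAsFactors = FALSE)
    }))
    if (is.null(sites)) {
      sites <- data.frame(window_id = character(), mirna = character(),
                          site_type = character(), start = integer(),
                          end = integer())
    }
  }
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
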