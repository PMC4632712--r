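#' Read a miRNA catalog
#'
#' Accepts mature-miRNA FASTA (record id = miRNA name) or a two-column TSV
#' (`name`, `mature_seq`); both accept U or T.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"tsv"`.
#' @param counted_types site classes counted as regulation (see
#'   [seed_catalog()]).
#' @return a [seed_catalog()].
#' @export
read_mirna_catalog <- function(path, format = c("auto", "fasta", "tsv"),
                               counted_types = c("8mer-1a", "7mer-m8",
                                                 "7mer-A1")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fa|fasta|fna)$", path, ignore.case = TRUE))
      "fasta" else "tsv"
  }
  if (format == "fasta") {
    ss <- Biostrings::readBStringSet(path)
    nm <- sub("\\s.*$", "", names(ss))
    seed_catalog(nm, as.character(ss), counted_types)
  } else {
    tb <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
    if (ncol(tb) < 2L) stop("catalog TSV needs columns name, mature_seq")
    seed_catalog(tb[[1L]], tb[[2L]], counted_types)
  }
}

#' Write a miRNA catalog to TSV
#' @param catalog a [seed_catalog()].
#' @param path output path.
#' @export
write_mirna_catalog <- function(catalog, path) {
  utils::write.table(
    data.frame(name = catalog$records$name,
               mature_seq = catalog$records$mature_seq),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read SNP records
#'
#' Dialect A (`"tsv"`) is self-contained: columns `snp_id`, `left_flank`,
#' `ref`, `alt`, `right_flank`, `snp_class` (ref/alt become
#' allele_a/allele_b).  Dialect B (`"vcf"`) is a minimal VCF (CHROM, POS,
#' ID, REF, ALT) plus a reference FASTA and a CDS BED with strand: flanks
#' are the 15 bases each side on the mRNA sense strand, i.e. minus-strand
#' records are reverse-complemented during extraction so downstream modules
#' always see mRNA sense.  Multi-allelic VCF rows are split into biallelic
#' records (suffix `_1`, `_2`, ...) or rejected, per `multiallelic`.
#'
#' @param path SNP file.
#' @param dialect `"tsv"` or `"vcf"`.
#' @param ref_fasta reference FASTA (dialect B).
#' @param cds_bed BED of CDS intervals with strand (dialect B).
#' @param multiallelic `"split"` (default) or `"error"`.
#' @param class_map optional named vector snp_id -> class (dialect B, which
#'   carries no class column; unmapped ids get `NA`).
#' @return a [snp_table()].
#' @export
read_snps <- function(path, dialect = c("tsv", "vcf"), ref_fasta = NULL,
                      cds_bed = NULL, multiallelic = c("split", "error"),
                      class_map = NULL) {
  dialect <- match.arg(dialect)
  multiallelic <- match.arg(multiallelic)
  if (dialect == "tsv") {
    tb <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                            na.strings = c("NA", ""))
    need <- c("snp_id", "left_flank", "ref", "alt", "right_flank",
              "snp_class")
    miss <- setdiff(need, names(tb))
    if (length(miss)) {
      stop("SNP TSV missing columns: ", paste(miss, collapse = ", "))
    }
    tb$left_flank[is.na(tb$left_flank)] <- ""
    tb$right_flank[is.na(tb$right_flank)] <- ""
    return(snp_table(data.frame(
      snp_id = tb$snp_id, left_flank = tb$left_flank, allele_a = tb$ref,
      allele_b = tb$alt, right_flank = tb$right_flank,
      snp_class = tb$snp_class, stringsAsFactors = FALSE)))
  }
  read_snps_vcf(path, ref_fasta, cds_bed, multiallelic, class_map)
}

read_snps_vcf <- function(path, ref_fasta, cds_bed, multiallelic,
                          class_map) {
  for (pkg in c("vcfR", "rtracklayer", "GenomicRanges", "IRanges")) {
    if (!requireNamespace(pkg, quietly = TRUE)) {
      stop("dialect 'vcf' needs the ", pkg, " package")
    }
  }
  if (is.null(ref_fasta) || is.null(cds_bed)) {
    stop("dialect 'vcf' needs ref_fasta and cds_bed")
  }
  fx <- vcfR::getFIX(vcfR::read.vcfR(path, verbose = FALSE))
  if (is.null(dim(fx))) fx <- t(fx)  # single-record VCFs drop to a vector
  fix <- as.data.frame(fx, stringsAsFactors = FALSE)
  genome <- Biostrings::readDNAStringSet(ref_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  cds <- rtracklayer::import(cds_bed, format = "BED")

  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  if (multiallelic == "error" && any(lengths(alts) > 1L)) {
    stop("non-biallelic VCF records: ",
         paste(fix$ID[lengths(alts) > 1L], collapse = ", "))
  }
  k <- lengths(alts)
  rows <- rep(seq_len(nrow(fix)), k)
  df <- data.frame(chrom = fix$CHROM[rows],
                   pos = as.integer(fix$POS[rows]),
                   snp_id = ifelse(k[rows] > 1L,
                                   paste0(fix$ID[rows], "_",
                                          sequence(k)),
                                   fix$ID[rows]),
                   ref = fix$REF[rows],
                   alt = unlist(alts, use.names = FALSE),
                   stringsAsFactors = FALSE)
  snv <- nchar(df$ref) == 1L & nchar(df$alt) == 1L
  if (any(!snv)) {
    message("read_snps: dropping ", sum(!snv), " non-SNV record(s)")
    df <- df[snv, , drop = FALSE]
  }

  gr <- GenomicRanges::GRanges(df$chrom,
                               IRanges::IRanges(df$pos, df$pos))
  hit <- GenomicRanges::findOverlaps(gr, cds, select = "first")
  if (anyNA(hit)) {
    message("read_snps: dropping ", sum(is.na(hit)),
            " SNP(s) outside CDS intervals")
    df <- df[!is.na(hit), , drop = FALSE]
    hit <- hit[!is.na(hit)]
  }
  strand <- as.character(GenomicRanges::strand(cds))[hit]

  out <- lapply(seq_len(nrow(df)), function(i) {
    chr <- genome[[df$chrom[i]]]
    pos <- df$pos[i]
    lo <- max(1L, pos - 15L)
    hi <- min(length(chr), pos + 15L)
    win <- as.character(Biostrings::subseq(chr, lo, hi))
    cpos <- pos - lo + 1L
    if (substr(win, cpos, cpos) != toupper(df$ref[i])) {
      stop(sprintf("REF mismatch for %s at %s:%d (genome %s, VCF %s)",
                   df$snp_id[i], df$chrom[i], pos,
                   substr(win, cpos, cpos), df$ref[i]))
    }
    left <- substr(win, 1L, cpos - 1L)
    right <- substr(win, cpos + 1L, nchar(win))
    a <- toupper(df$ref[i]); b <- toupper(df$alt[i])
    if (strand[i] == "-") {
      tmp <- .revcomp(left); left <- .revcomp(right); right <- tmp
      a <- .revcomp(a); b <- .revcomp(b)
    }
    data.frame(snp_id = df$snp_id[i], left_flank = left, allele_a = a,
               allele_b = b, right_flank = right,
               snp_class = NA_character_, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (!is.null(class_map)) {
    res$snp_class <- unname(class_map[res$snp_id])
  }
  snp_table(res)
}

#' Write a SNP table (dialect A TSV)
#' @param snps a [snp_table()].
#' @param path output path.
#' @export
write_snps <- function(snps, path) {
  utils::write.table(
    data.frame(snp_id = snps$snp_id, left_flank = snps$left_flank,
               ref = snps$allele_a, alt = snps$allele_b,
               right_flank = snps$right_flank, snp_class = snps$snp_class),
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read an annotation track
#'
#' TSV with columns `snp_id`, `value` and optional `population`.  With a
#' `population` column, one track per population is returned (named list).
#'
#' @param path input TSV.
#' @param kind `"auto"` (binary iff all values are 0/1), `"scalar"` or
#'   `"binary"`.
#' @return an [annotation_track()] or named list of them.
#' @export
read_track <- function(path, kind = c("auto", "scalar", "binary")) {
  kind <- match.arg(kind)
  tb <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "value") %in% names(tb))) {
    stop("track TSV needs columns snp_id, value")
  }
  one <- function(d, pop) {
    k <- if (kind != "auto") kind else
      if (all(d$value %in% c(0, 1))) "binary" else "scalar"
    annotation_track(d$snp_id, d$value, kind = k, population = pop)
  }
  if ("population" %in% names(tb)) {
    pops <- split(tb, tb$population)
    lapply(stats::setNames(names(pops), names(pops)),
           function(p) one(pops[[p]], p))
  } else {
    one(tb, NULL)
  }
}

#' Write an annotation track to TSV
#' @param track an [annotation_track()] or list of them.
#' @param path output path.
#' @export
write_track <- function(track, path) {
  if (inherits(track, "annotation_track")) track <- list(track)
  rows <- do.call(rbind, lapply(track, function(t) {
    d <- data.frame(snp_id = names(t), value = as.numeric(t),
                    stringsAsFactors = FALSE)
    if (!is.null(attr(t, "population"))) d$population <- attr(t, "population")
    d
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read genotype and expression matrices
#'
#' Genotype TSV: rows = SNPs, columns = samples, values 0/1/2/NA.
#' Expression TSV: rows = genes, columns = samples.
#'
#' @param genotype_path,expression_path input TSVs (first column = row ids).
#' @return list with `genotypes` and `expression` numeric matrices.
#' @export
read_matrices <- function(genotype_path, expression_path) {
  rd <- function(p) {
    tb <- utils::read.delim(p, header = TRUE, row.names = 1L,
                            check.names = FALSE)
    as.matrix(tb)
  }
  g <- rd(genotype_path)
  if (!all(g %in% c(0, 1, 2) | is.na(g))) {
    stop("genotype matrix values must be 0/1/2/NA")
  }
  list(genotypes = g, expression = rd(expression_path))
}

#' Read a SNP-to-gene mapping TSV (`snp_id`, `gene_id`)
#' @param path input TSV.
#' @return data.frame `snp_id`, `gene_id`.
#' @export
read_snp_gene_map <- function(path) {
  tb <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (!all(c("snp_id", "gene_id") %in% names(tb))) {
    stop("mapping TSV needs columns snp_id, gene_id")
  }
  tb[, c("snp_id", "gene_id")]
}

#' Write per-SNP regulation changes to TSV
#'
#' Columns: `snp_id`, `snp_class`, `changed` (0/1), `gained`, `lost`
#' (comma-separated miRNA lists), `short_flank`.
#'
#' @param classification a `mirsnp_classification` from [classify_all()].
#' @param path output path.
#' @export
write_changes <- function(classification, path) {
  ch <- classification$changes
  utils::write.table(
    data.frame(snp_id = ch$snp_id, snp_class = ch$snp_class,
               changed = as.integer(ch$changed),
               gained = vapply(ch$gained, paste, "", collapse = ","),
               lost = vapply(ch$lost, paste, "", collapse = ","),
               short_flank = as.integer(ch$short_flank)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Write a full synthetic input bundle to a directory
#'
#' Emits catalog, SNP table, truth labels, annotation tracks, genotype and
#' expression matrices and the SNP-to-gene map as TSV files.
#'
#' @param bundle output of [simulate_bundle()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_mirna_catalog(bundle$catalog, fp("mirna_catalog.tsv"))
  write_snps(bundle$snps, fp("snps.tsv"))
  utils::write.table(bundle$truth, fp("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_track(bundle$annotations$ihs, fp("ihs.tsv"))
  write_track(bundle$annotations$disease, fp("disease.tsv"))
  write_track(bundle$annotations$deleterious, fp("deleterious.tsv"))
  ex <- bundle$expression_data
  utils::write.table(cbind(snp_id = rownames(ex$genotypes), ex$genotypes),
                     fp("genotypes.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(cbind(gene_id = rownames(ex$expression),
                           format(ex$expression, digits = 10)),
                     fp("expression.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(ex$snp_to_gene, fp("snp_to_gene.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
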