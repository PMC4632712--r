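#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator.  Defaults emulate
#' the genome-scale study conditions at desk scale: a 45.9% regulation-change
#' rate among coding SNPs, standard-normal iHS baselines (so that about 1.2%
#' of scores exceed |iHS| = 2.5), sparse GWAS-like disease annotation
#' (0.2% baseline) with a planted odds ratio of 1.6, an 18% deleterious
#' rate among non-synonymous SNPs with no association to change status, and
#' a 60-sample expression panel with unit-scale eQTL effects on 10% of the
#' genes hosting changing SNPs.
#'
#' @param n_snps number of SNPs.
#' @param n_mirnas catalog size.
#' @param change_rate_target probability a SNP is planted to change
#'   regulation.
#' @param frac_synonymous fraction of SNPs labelled synonymous.
#' @param planted_or_disease odds ratio of disease annotation for changing
#'   vs non-changing SNPs.
#' @param disease_baseline disease-annotation rate among non-changing SNPs.
#' @param deleterious_rate deleterious-label rate among non-synonymous SNPs
#'   (independent of change status).
#' @param planted_ihs_shift location shift added to |iHS| of changing SNPs.
#' @param ihs_tail_frac baseline fraction of scores with |iHS| >= 2.5
#'   (implemented as a variance scale of the normal baseline).
#' @param ihs_coverage fraction of SNPs having an iHS score at all.
#' @param n_samples expression/genotype panel size.
#' @param maf_range minor-allele-frequency range (uniform).
#' @param eqtl_effect_sd standard deviation of planted eQTL effect sizes.
#' @param eqtl_frac fraction of changing-SNP genes receiving an eQTL effect.
#' @param seed integer seed; every generator is a pure function of
#'   (config, seed).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_snps = 2000L, n_mirnas = 50L,
                       change_rate_target = 0.459, frac_synonymous = 0.5,
                       planted_or_disease = 1.6, disease_baseline = 0.002,
                       deleterious_rate = 0.18,
                       planted_ihs_shift = 0.1,
                       ihs_tail_frac = 2 * stats::pnorm(-2.5),
                       ihs_coverage = 0.15,
                       n_samples = 60L, maf_range = c(0.05, 0.5),
                       eqtl_effect_sd = 1, eqtl_frac = 0.1, seed = 1L) {
  cfg <- list(n_snps = as.integer(n_snps), n_mirnas = as.integer(n_mirnas),
              change_rate_target = change_rate_target,
              frac_synonymous = frac_synonymous,
              planted_or_disease = planted_or_disease,
              disease_baseline = disease_baseline,
              deleterious_rate = deleterious_rate,
              planted_ihs_shift = planted_ihs_shift,
              ihs_tail_frac = ihs_tail_frac,
              ihs_coverage = ihs_coverage,
              n_samples = as.integer(n_samples), maf_range = maf_range,
              eqtl_effect_sd = eqtl_effect_sd, eqtl_frac = eqtl_frac,
              seed = as.integer(seed))
  rates <- c(change_rate_target = cfg$change_rate_target,
             frac_synonymous = cfg$frac_synonymous,
             disease_baseline = cfg$disease_baseline,
             deleterious_rate = cfg$deleterious_rate,
             ihs_tail_frac = cfg$ihs_tail_frac,
             ihs_coverage = cfg$ihs_coverage,
             eqtl_frac = cfg$eqtl_frac)
  if (any(rates < 0 | rates > 1)) {
    stop("rates must lie in [0, 1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  }
  if (cfg$n_snps < 0L || cfg$n_mirnas < 0L || cfg$n_samples < 1L) {
    stop("sizes must be positive")
  }
  if (cfg$planted_or_disease <= 0) stop("planted_or_disease must be > 0")
  class(cfg) <- "sim_config"
  cfg
}

.BASES <- c("A", "C", "G", "T")

.random_seq <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(.BASES, n * len, replace = TRUE), n, len)
  apply(m, 1L, paste, collapse = "")
}

#' Simulate a miRNA catalog
#'
#' Draws `n_mirnas` mature sequences of length 22 with uniform bases.  Seed
#' heptamers (positions 2-8) are forced unique by bounded redraw, so every
#' catalog entry defines a distinct target-site family and planted
#' gain/loss labels stay unambiguous.
#'
#' @param n_mirnas catalog size (or a [sim_config()]).
#' @param seed integer seed.
#' @return a [seed_catalog()].
#' @export
simulate_catalog <- function(n_mirnas, seed = 1L) {
  if (inherits(n_mirnas, "sim_config")) {
    seed <- n_mirnas$seed + 1L
    n_mirnas <- n_mirnas$n_mirnas
  }
  if (n_mirnas > 4^7) stop("more miRNAs than distinct seed heptamers")
  local_seed(seed, {
    seqs <- .random_seq(n_mirnas, 22L)
    for (i in seq_len(1000L)) {
      dup <- duplicated(substr(seqs, 2L, 8L))
      if (!any(dup)) break
      seqs[dup] <- .random_seq(sum(dup), 22L)
    }
    if (anyDuplicated(substr(seqs, 2L, 8L))) {
      stop("generator exhausted: could not draw unique seed heptamers")
    }
    seed_catalog(sprintf("miR-sim-%04d", seq_len(n_mirnas)), seqs)
  })
}

# Plant one counted seed-match site overlapping the window center.  Returns
# 31-nt windows (character vector) whose center base is inside the 6-nt
# seed-complement core of a randomly chosen catalog pattern.
.plant_windows <- function(n, catalog) {
  pats <- catalog$patterns[catalog$patterns$site_type %in%
                             catalog$counted_types, , drop = FALSE]
  w <- .random_seq(n, 31L)
  pick <- sample.int(nrow(pats), n, replace = TRUE)
  for (i in seq_len(n)) {
    p <- pats[pick[i], ]
    co <- p$core_offset
    lo <- max(0L, 15L - co - 5L)
    hi <- min(15L - co, 31L - p$len)
    s <- if (lo == hi) lo else sample(lo:hi, 1L)
    substr(w[i], s + 1L, s + p$len) <- p$pattern
  }
  w
}

#' Simulate SNP records with known change-truth labels
#'
#' Constructive planting: a `change_rate_target` fraction of SNPs gets one
#' allele's window edited to contain a counted seed-match site whose 6-nt
#' seed-complement core covers the central base, which the other allele
#' destroys; the remaining SNPs get windows verified by the scanner to bind
#' identical miRNA sets under both alleles.  Every candidate is verified by
#' [classify_all()] in-loop, so the returned truth labels agree with the
#' classifier exactly by construction.
#'
#' @param config a [sim_config()].
#' @param catalog a [seed_catalog()] (non-empty).
#' @return list with `snps` (a [snp_table()]) and `truth` (data.frame
#'   `snp_id`, `changed`, `snp_class`).
#' @export
simulate_snps <- function(config, catalog) {
  stopifnot(inherits(config, "sim_config"), inherits(catalog, "seed_catalog"))
  if (!nrow(catalog$records)) stop("catalog must be non-empty")
  n <- config$n_snps
  local_seed(config$seed + 2L, {
    changed <- stats::runif(n) < config$change_rate_target
    snp_class <- ifelse(stats::runif(n) < config$frac_synonymous,
                        "synonymous", "nonsynonymous")
    left <- right <- allele_a <- allele_b <- character(n)
    pending <- seq_len(n)
    for (round in seq_len(100L)) {
      if (!length(pending)) break
      is_ch <- changed[pending]
      w <- character(length(pending))
      w[is_ch] <- .plant_windows(sum(is_ch), catalog)
      w[!is_ch] <- .random_seq(sum(!is_ch), 31L)
      a <- substr(w, 16L, 16L)
      b <- vapply(a, function(x) sample(setdiff(.BASES, x), 1L), "",
                  USE.NAMES = FALSE)
      cand <- data.frame(snp_id = sprintf("cand%06d", seq_along(pending)),
                         left_flank = substr(w, 1L, 15L), allele_a = a,
                         allele_b = b, right_flank = substr(w, 17L, 31L),
                         snp_class = snp_class[pending],
                         stringsAsFactors = FALSE)
      verdict <- classify_all(cand, catalog)$changes$changed
      ok <- verdict == is_ch
      acc <- pending[ok]
      left[acc] <- cand$left_flank[ok]
      right[acc] <- cand$right_flank[ok]
      allele_a[acc] <- cand$allele_a[ok]
      allele_b[acc] <- cand$allele_b[ok]
      pending <- pending[!ok]
    }
    if (length(pending)) {
      stop("generator exhausted: could not construct ", length(pending),
           " SNP(s) matching their truth label")
    }
    ids <- sprintf("snp%06d", seq_len(n))
    list(snps = snp_table(data.frame(
           snp_id = ids, left_flank = left, allele_a = allele_a,
           allele_b = allele_b, right_flank = right, snp_class = snp_class,
           stringsAsFactors = FALSE)),
         truth = data.frame(snp_id = ids, changed = changed,
                            snp_class = snp_class, stringsAsFactors = FALSE))
  })
}

#' Simulate annotation tracks with planted structure
#'
#' Per population (ASI, CEU, YRI), an iHS track covering an `ihs_coverage`
#' subset of SNPs: baseline scores are normal with variance scaled so the
#' two-sided tail beyond 2.5 equals `ihs_tail_frac`; changing SNPs get
#' `planted_ihs_shift` added to |iHS| (sign preserved).  A binary
#' GWAS-like disease track is drawn with log-odds offset
#' `log(planted_or_disease)` for changing SNPs over the `disease_baseline`
#' rate.  A deleterious track labels non-synonymous SNPs at
#' `deleterious_rate`, independent of change status.
#'
#' @param config a [sim_config()].
#' @param truth truth data.frame from [simulate_snps()] (`snp_id`,
#'   `changed`, `snp_class`).
#' @return list with `ihs` (list of three scalar tracks), `disease` and
#'   `deleterious` (binary tracks).
#' @export
simulate_annotations <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(truth)
  sdev <- 2.5 / stats::qnorm(1 - config$ihs_tail_frac / 2)
  local_seed(config$seed + 3L, {
    ihs <- lapply(c(ASI = "ASI", CEU = "CEU", YRI = "YRI"), function(pop) {
      cov <- which(stats::runif(n) < config$ihs_coverage)
      x <- stats::rnorm(length(cov), 0, sdev)
      ch <- truth$changed[cov]
      x[ch] <- sign(x[ch]) * (abs(x[ch]) + config$planted_ihs_shift)
      annotation_track(truth$snp_id[cov], x, kind = "scalar",
                       population = pop)
    })
    p0 <- config$disease_baseline
    p1 <- stats::plogis(stats::qlogis(p0) + log(config$planted_or_disease))
    disease <- annotation_track(
      truth$snp_id,
      stats::rbinom(n, 1L, ifelse(truth$changed, p1, p0)),
      kind = "binary")
    ns <- which(truth$snp_class == "nonsynonymous")
    deleterious <- annotation_track(
      truth$snp_id[ns],
      stats::rbinom(length(ns), 1L, config$deleterious_rate),
      kind = "binary")
    list(ihs = ihs, disease = disease, deleterious = deleterious)
  })
}

#' Simulate genotype and expression matrices with planted eQTLs
#'
#' Genotypes are Hardy-Weinberg draws `Binomial(2, maf)` with
#' `maf ~ Uniform(maf_range)`.  Expression of a gene hosting a changing SNP
#' receives, with probability `eqtl_frac`, a genotype effect
#' `beta ~ Normal(0, eqtl_effect_sd)` on top of unit normal noise; all
#' other genes are pure noise.
#'
#' @param config a [sim_config()].
#' @param truth truth data.frame from [simulate_snps()].
#' @param snp_to_gene data.frame `snp_id`, `gene_id`; default maps each SNP
#'   to its own gene.
#' @return list with `genotypes` (SNP x sample matrix), `expression`
#'   (gene x sample matrix), `snp_to_gene`, and `effects` (data.frame
#'   `gene_id`, `beta`).
#' @export
simulate_expression <- function(config, truth, snp_to_gene = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(truth)
  if (is.null(snp_to_gene)) {
    snp_to_gene <- data.frame(snp_id = truth$snp_id,
                              gene_id = sub("^snp", "gene", truth$snp_id),
                              stringsAsFactors = FALSE)
  }
  samples <- sprintf("S%03d", seq_len(config$n_samples))
  local_seed(config$seed + 4L, {
    maf <- stats::runif(n, config$maf_range[1], config$maf_range[2])
    geno <- matrix(stats::rbinom(n * config$n_samples, 2L, rep(maf, each =
                     config$n_samples)),
                   nrow = n, byrow = TRUE,
                   dimnames = list(truth$snp_id, samples))
    genes <- unique(snp_to_gene$gene_id)
    changed_ids <- truth$snp_id[truth$changed]
    # first changing SNP of a gene drives its planted effect
    first_snp <- vapply(genes, function(g) {
      s <- snp_to_gene$snp_id[snp_to_gene$gene_id == g]
      sc <- s[s %in% changed_ids]
      if (length(sc)) sc[1L] else s[1L]
    }, "")
    hosts_changing <- first_snp %in% changed_ids
    beta <- numeric(length(genes))
    planted <- hosts_changing & stats::runif(length(genes)) < config$eqtl_frac
    beta[planted] <- stats::rnorm(sum(planted), 0, config$eqtl_effect_sd)
    expr <- matrix(stats::rnorm(length(genes) * config$n_samples),
                   nrow = length(genes),
                   dimnames = list(genes, samples))
    expr <- expr + beta * geno[first_snp, , drop = FALSE]
    list(genotypes = geno, expression = expr, snp_to_gene = snp_to_gene,
         effects = data.frame(gene_id = genes, beta = beta,
                              stringsAsFactors = FALSE))
  })
}

#' Simulate a complete input bundle
#'
#' Runs every generator under sub-seeds derived from `config$seed` and
#' returns catalog, SNPs with truth labels, annotation tracks, and the
#' genotype/expression matrices with their SNP-to-gene mapping.
#'
#' @param config a [sim_config()].
#' @return list with `config`, `catalog`, `snps`, `truth`, `annotations`,
#'   `expression_data`.
#' @export
simulate_bundle <- function(config = sim_config()) {
  catalog <- simulate_catalog(config)
  sn <- simulate_snps(config, catalog)
  ann <- simulate_annotations(config, sn$truth)
  ex <- simulate_expression(config, sn$truth)
  list(config = config, catalog = catalog, snps = sn$snps,
       truth = sn$truth, annotations = ann, expression_data = ex)
}
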