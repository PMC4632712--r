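mk_snp <- function(id = "rs1", left = strrep("A", 15), a = "G", b = "C",
                   right = strrep("A", 15), cls = "synonymous") {
  data.frame(snp_id = id, left_flank = left, allele_a = a, allele_b = b,
             right_flank = right, snp_class = cls, stringsAsFactors = FALSE)
}

test_that("allele windows are 31 nt with the allele at the center", {
  s <- snp_table(mk_snp())
  w <- build_allele_window(s, "a")
  expect_equal(nchar(w), 31L)
  expect_identical(w, paste0(strrep("A", 15), "G", strrep("A", 15)))
  expect_identical(substr(w, 16, 16), "G")  # 0-based offset 15

  # truncated left flank near a transcript end: allele at offset 0
  s0 <- snp_table(mk_snp(left = "", a = "C", b = "G"))
  w0 <- build_allele_window(s0, "a")
  expect_equal(nchar(w0), 16L)
  expect_identical(substr(w0, 1, 1), "C")

  # the two allele windows differ at exactly one position
  set.seed(11)
  snps <- random_snp_table(20)
  wa <- build_allele_window(snps, "a")
  wb <- build_allele_window(snps, "b")
  diffs <- mapply(function(x, y) {
    sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }, wa, wb)
  expect_true(all(diffs == 1L))

  expect_error(build_allele_window(snp_table(mk_snp(left = "", right = "AC"))),
               "shorter than 8")
})

test_that("SNP table validation rejects malformed records", {
  expect_error(snp_table(rbind(mk_snp("x"), mk_snp("x"))), "duplicate")
  expect_error(snp_table(mk_snp(a = "G", b = "G")), "allele_a equals")
  expect_error(snp_table(mk_snp(a = "GG")), "single")
  expect_error(snp_table(mk_snp(left = strrep("A", 16))), "longer than 15")
  expect_error(snp_table(mk_snp(cls = "weird")), "snp_class")
})

test_that("an allele destroying the only counted site marks the miRNA as lost", {
  ctl <- seed_catalog("miR-x", "UGGAGUGUGACAAUGGUGUUUG")  # 7mer-m8 ACACTCC
  # a-allele window carries ACACTCC with its core over the center;
  # swapping the central C for G destroys it
  s <- snp_table(mk_snp(left = paste0(strrep("G", 11), "ACAC"), a = "T",
                        b = "G", right = paste0("CC", strrep("G", 13))))
  expect_identical(substr(build_allele_window(s, "a"), 12, 18), "ACACTCC")
  rc <- classify_snp(s, ctl)
  expect_true(rc$changed)
  expect_identical(rc$lost, "miR-x")
  expect_identical(rc$gained, character(0))

  # no catalog miRNA matching either allele: no change
  none <- classify_snp(snp_table(mk_snp()), ctl)
  expect_false(none$changed)
  expect_identical(none$gained, character(0))
  expect_identical(none$lost, character(0))
})

test_that("classification equals independent two-scan set differences", {
  set.seed(21)
  for (i in 1:20) {
    ctl <- random_catalog(8)
    s <- random_snp_table(1)
    rc <- classify_snp(s, ctl)
    ga <- sort(unique(oracle_scan(build_allele_window(s, "a"), ctl)$mirna))
    gb <- sort(unique(oracle_scan(build_allele_window(s, "b"), ctl)$mirna))
    expect_identical(rc$gained, sort(setdiff(gb, ga)))
    expect_identical(rc$lost, sort(setdiff(ga, gb)))
    expect_identical(rc$changed, !setequal(ga, gb))
  }
})

test_that("swapping the alleles swaps gained and lost exactly", {
  set.seed(31)
  ctl <- random_catalog(10)
  snps <- random_snp_table(30)
  swapped <- snps
  swapped$allele_a <- snps$allele_b
  swapped$allele_b <- snps$allele_a
  a <- classify_all(snps, ctl)$changes
  b <- classify_all(swapped, ctl)$changes
  expect_identical(a$gained, b$lost)
  expect_identical(a$lost, b$gained)
  expect_identical(a$changed, b$changed)
})

test_that("every gained or lost miRNA has a site overlapping the SNP position", {
  set.seed(41)
  found <- 0L
  for (i in 1:40) {
    ctl <- random_catalog(10)
    snps <- random_snp_table(5)
    cl <- classify_all(snps, ctl)$changes
    for (j in which(cl$changed)) {
      center <- nchar(snps$left_flank[j])  # 0-based allele offset
      for (m in cl$lost[[j]]) {
        hits <- scan_sites(build_allele_window(snps[j, ], "a"), ctl)
        hm <- hits[hits$mirna == m, , drop = FALSE]
        expect_true(any(hm$start <= center & center < hm$end))
        found <- found + 1L
      }
      for (m in cl$gained[[j]]) {
        hits <- scan_sites(build_allele_window(snps[j, ], "b"), ctl)
        hm <- hits[hits$mirna == m, , drop = FALSE]
        expect_true(any(hm$start <= center & center < hm$end))
        found <- found + 1L
      }
    }
  }
  expect_gt(found, 0L)  # the property must actually have been exercised
})

test_that("classify_all counts, preserves order and is deterministic", {
  ctl <- seed_catalog("miR-x", "UGGAGUGUGACAAUGGUGUUUG")
  planted <- snp_table(mk_snp("p1", left = paste0(strrep("G", 11), "ACAC"),
                              a = "T", b = "G",
                              right = paste0("CC", strrep("G", 13))))
  boring <- lapply(sprintf("b%d", 1:9), function(id) mk_snp(id))
  snps <- snp_table(do.call(rbind, c(list(planted), boring)))
  out <- classify_all(snps, ctl)
  expect_identical(out$changes$snp_id, snps$snp_id)
  expect_equal(sum(out$changes$changed), 1L)
  syn <- out$summary[out$summary$snp_class == "synonymous", ]
  expect_equal(syn$fraction, 0.1)
  expect_identical(classify_all(snps, ctl)$changes, out$changes)

  empty <- classify_all(snps[0, ], ctl)
  expect_equal(nrow(empty$changes), 0L)
  expect_equal(nrow(empty$summary), 0L)
})

test_that("changed_flags filters by class and keys by snp_id", {
  ctl <- seed_catalog("miR-x", "UGGAGUGUGACAAUGGUGUUUG")
  snps <- snp_table(rbind(mk_snp("a1", cls = "synonymous"),
                          mk_snp("a2", cls = "nonsynonymous")))
  cl <- classify_all(snps, ctl)
  f <- changed_flags(cl, snp_class = "synonymous")
  expect_identical(names(f), "a1")
  expect_identical(unname(changed_flags(cl)), cl$changes$changed)
})
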