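test_that("sequence normalization uppercases, maps U to T and rejects bad bases", {
  expect_identical(normalize_sequence("augcu"), "ATGCT")
  expect_identical(normalize_sequence(""), "")
  expect_identical(normalize_sequence(c("acg", "uuu")), c("ACG", "TTT"))
  expect_error(normalize_sequence("ACGX"), "position 4")
  expect_error(normalize_sequence("AC-G"), "position 3")
})

test_that("seed-match patterns are the reverse complements of the seed region", {
  p <- seed_match_site("UGGAGUGUGACAAUGGUGUUUG")  # seed 2-8 = GGAGUGU
  expect_identical(p[["7mer-m8"]], "ACACTCC")
  expect_identical(p[["6mer"]], "CACTCC")
  expect_identical(p[["6mer"]], substr(p[["7mer-m8"]], 2, 7))
  expect_identical(p[["7mer-A1"]], paste0(p[["6mer"]], "A"))
  expect_identical(p[["8mer-1a"]], paste0(p[["7mer-m8"]], "A"))

  h <- seed_match_site("AAAAAAAA")
  expect_identical(h[["6mer"]], "TTTTTT")
  expect_identical(h[["8mer-1a"]], "TTTTTTTA")

  expect_error(seed_match_site("UGGAGUG"), "invalid miRNA")
  expect_error(seed_match_site("ANNNNNNNAA"), "seed region")
})

test_that("scan_sites finds counted sites at the right offsets", {
  ctl <- seed_catalog("m1", "UGGAGUGUGACAAUGGUGUUUG",
                      counted_types = "7mer-m8")
  hits <- scan_sites("GGGACACTCCAGGG", ctl)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 3L)
  expect_equal(hits$end, 10L)
  expect_equal(hits$site_type, "7mer-m8")

  expect_equal(nrow(scan_sites("TTTTTTTTTT", ctl)), 0L)
  expect_identical(binding_mirnas("TTTTTTTTTT", ctl), character(0))
})

test_that("positions containing N never match", {
  ctl <- seed_catalog("m1", "UGGAGUGUGACAAUGGUGUUUG",
                      counted_types = "7mer-m8")
  clean <- scan_sites("GGGACACTCCAGG", ctl)
  expect_equal(nrow(clean), 1L)
  withN <- scan_sites("GGGACNCTCCAGG", ctl)  # N at offset 5
  expect_false(any(withN$start <= 5 & withN$end > 5))
  expect_equal(nrow(withN), 0L)
})

test_that("nested site variants collapse to the highest-priority class", {
  ctl <- seed_catalog("m1", "UGGAGUGUGACAAUGGUGUUUG",
                      counted_types = c("6mer", "7mer-A1", "7mer-m8",
                                        "8mer-1a"))
  # window embeds the full 8mer-1a pattern ACACTCCA; the nested 7mer-m8,
  # 7mer-A1 and 6mer matches share its seed-complement core
  hits <- scan_sites("GGACACTCCAGG", ctl)
  expect_equal(hits$site_type, "8mer-1a")
  expect_equal(hits$start, 2L)

  # without the 8mer counted, the 7mer-m8 wins at the same locus
  hits7 <- scan_sites("GGACACTCCAGG", ctl,
                      counted_types = c("6mer", "7mer-A1", "7mer-m8"))
  expect_equal(hits7$site_type, "7mer-m8")
})

test_that("scanner equals the brute-force sliding oracle on random instances", {
  set.seed(101)
  for (i in 1:80) {
    ctl <- random_catalog()
    w <- random_window()
    got <- scan_sites(w, ctl)
    want <- oracle_scan(w, ctl)
    expect_equal(got, want, info = sprintf("instance %d window %s", i, w))
  }
})

test_that("scanning is deterministic and binding_mirnas is the name projection", {
  set.seed(202)
  for (i in 1:25) {
    ctl <- random_catalog()
    w <- random_window()
    s1 <- scan_sites(w, ctl)
    s2 <- scan_sites(w, ctl)
    expect_identical(s1, s2)
    expect_identical(binding_mirnas(w, ctl), sort(unique(s1$mirna)))
  }
})

test_that("reported sites imply a literal seed-complement occurrence", {
  set.seed(303)
  checked <- 0L
  for (i in 1:25) {
    w <- random_window(40, with_n = FALSE)
    ctl <- random_catalog(10)
    if (i %% 2 == 0 && nchar(w) >= 10) {
      # plant a miRNA whose 7mer-m8 pattern is a substring of the window,
      # so the property is guaranteed to be exercised
      core <- substr(w, 3, 9)
      mat <- paste0("A", as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(core))), strrep("A", 14))
      ctl <- seed_catalog(c(ctl$records$name, "planted"),
                          c(ctl$records$mature_seq, mat),
                          counted_types = ctl$counted_types)
    }
    hits <- scan_sites(w, ctl)
    for (j in seq_len(nrow(hits))) {
      pats <- seed_match_site(
        ctl$records$mature_seq[ctl$records$name == hits$mirna[j]])
      expect_identical(substr(w, hits$start[j] + 1, hits$end[j]),
                       pats[[hits$site_type[j]]])
      checked <- checked + 1L
    }
  }
  expect_gt(checked, 0L)
})

test_that("enlarging counted_types never shrinks the binding miRNA set", {
  set.seed(404)
  for (i in 1:25) {
    ctl <- random_catalog()
    w <- random_window()
    small <- sample(c("6mer", "7mer-A1", "7mer-m8", "8mer-1a"), 2)
    b_small <- binding_mirnas(w, ctl, counted_types = small)
    b_all <- binding_mirnas(w, ctl,
                            counted_types = c("6mer", "7mer-A1", "7mer-m8",
                                              "8mer-1a"))
    expect_true(all(b_small %in% b_all))
  }
})

test_that("catalog construction validates names and sequences", {
  expect_error(seed_catalog(c("a", "a"), c("ACGTACGT", "ACGTACGA")),
               "duplicate")
  expect_error(seed_catalog("a", "ACGTAC"), "shorter than 8")
  expect_error(seed_catalog("a", "ACGTACGT", counted_types = character(0)))
  ctl <- seed_catalog(character(0), character(0))
  expect_equal(nrow(scan_sites("ACGTACGTAC", ctl)), 0L)
})
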