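test_that("cai matches its definition on hand-built cases", {
  tab <- tiny_table() # w: AAA=1, AAG=1/3, AAT=1, AAC=1
  expect_equal(cai("AAAAATAAC", tab), 1.0)
  expect_equal(cai("AAG", tab), 1 / 3)
  # two codons with w = {1, 1/3}: geometric mean = sqrt(1/3)
  expect_equal(cai("AAAAAG", tab), sqrt(1 / 3))
  expect_error(cai("TAA", tab), "zero sense codons")
})

test_that("log-space cai equals the direct product oracle on random sequences", {
  corp <- make_corpus(8, c(80, 200), bias = random_bias(0.8, 21), seed = 22)
  tab <- codon_usage_table(corp$sequences)
  for (seed in 1:10) {
    n <- sample(c(5, 50, 500, 1000), 1)
    cds <- random_cds(n, seed)
    expect_equal(cai(cds, tab), oracle_cai(cds, tab), tolerance = 1e-12)
  }
})

test_that("replacing a codon by a higher-w synonym never decreases cai", {
  corp <- make_corpus(6, c(80, 150), bias = random_bias(1, 31), seed = 32)
  tab <- codon_usage_table(corp$sequences)
  code <- tab$code
  set.seed(33)
  for (rep in 1:20) {
    cds <- random_cds(40, 100 + rep)
    cod <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
    i <- sample(length(cod), 1)
    fam <- code$families[[code$table[[cod[i]]]]]
    higher <- fam[tab$w[fam] >= tab$w[[cod[i]]]]
    cod2 <- cod
    cod2[i] <- sample(higher, 1)
    expect_gte(
      cai(paste(cod2, collapse = ""), tab),
      cai(paste(cod, collapse = ""), tab) - 1e-12
    )
  }
})

test_that("gc_content is the plain percent of G and C", {
  expect_equal(gc_content("ATGC"), 50)
  expect_equal(gc_content("GGCC"), 100)
  expect_equal(gc_content("atgc"), 50)
  expect_error(gc_content(""), "empty")
  expect_error(gc_content("ATGN"), "non-ACGT")
})

test_that("positional GC matches hand counts and averages to overall GC", {
  pg <- positional_gc("ATGGCA")
  expect_equal(unname(pg$gc), c(50, 50, 50))
  expect_equal(unname(positional_gc("GGGGGG")$gc), c(100, 100, 100))
  expect_equal(unname(pg$at), 100 - unname(pg$gc))
  for (seed in 1:25) {
    cds <- random_cds(sample(1:200, 1), 400 + seed)
    expect_equal(mean(positional_gc(cds)$gc), gc_content(cds), tolerance = 1e-9)
  }
})

test_that("icu is zero against a table built from the sequence itself and negative otherwise", {
  cds <- random_cds(120, 7)
  self_tab <- codon_usage_table(setNames(cds, "x"))
  expect_equal(icu(cds, self_tab), 0, tolerance = 1e-12)
  # one two-codon family, host splits 0.5/0.5, sequence uses one codon
  host <- codon_usage_table(c(g = "AAAAAG"))
  expect_equal(icu("AAAAAA", host), -1.0)
  corp <- make_corpus(5, c(50, 100), bias = random_bias(1, 8), seed = 9)
  tab <- codon_usage_table(corp$sequences)
  expect_lt(icu("AAAAAAAAA", tab), 0)
})

test_that("icu is codon-order invariant and bounded by -2 per family present", {
  corp <- make_corpus(5, c(50, 100), bias = random_bias(1, 18), seed = 19)
  tab <- codon_usage_table(corp$sequences)
  code <- tab$code
  for (seed in 1:10) {
    cds <- random_cds(60, 700 + seed)
    cod <- substring(cds, seq(1, nchar(cds) - 2, 3), seq(3, nchar(cds), 3))
    set.seed(seed)
    shuffled <- paste(sample(cod), collapse = "")
    expect_equal(icu(cds, tab), icu(shuffled, tab), tolerance = 1e-12)
    n_fam <- length(unique(code$table[cod]))
    expect_gte(icu(cds, tab), -2 * n_fam)
  }
})

test_that("cc is zero on self, matches the hand-built two-pair case, and ignores pair multiplicity scaling", {
  cds <- random_cds(100, 41)
  self_pt <- codon_pair_table(setNames(cds, "x"))
  expect_equal(cc(cds, self_pt), 0, tolerance = 1e-12)
  # host uses pairs AAAAAG and AAAAAA equally within aa-pair KK; a sequence
  # using only one of them is at distance |1-0.5| + |0-0.5| = 1
  host <- codon_pair_table(c(a = "AAAAAG", b = "AAAAAA"))
  expect_equal(cc("AAAAAA", host), -1.0)
  # duplicating the pair multiset (here: every host sequence) leaves the
  # normalized frequencies, and hence cc, unchanged
  corp <- make_corpus(4, c(40, 80), bias = random_bias(1, 42), seed = 43)
  seqs <- as.character(unclass(corp$sequences))
  doubled <- setNames(c(seqs, seqs), paste0("s", seq_len(2 * length(seqs))))
  pt <- codon_pair_table(corp$sequences)
  pt2 <- codon_pair_table(doubled)
  cds2 <- random_cds(30, 44)
  expect_equal(cc(cds2, pt), cc(cds2, pt2), tolerance = 1e-12)
  expect_error(cc("ATG", pt), "at least 2")
})

test_that("cpb is the arithmetic mean of host pair scores", {
  # host where all cps = 0 (one codon per family)
  b <- bias_spec(default = "gc3")
  corp <- lapply(1:4, function(i) as.character(sample_cds(length = 50, bias = b, seed = i)))
  names(corp) <- paste0("s", 1:4)
  pt <- codon_pair_table(corp)
  cds <- as.character(sample_cds(length = 30, bias = b, seed = 9))
  expect_equal(as.numeric(cpb(cds, pt)), 0, tolerance = 1e-12)
  # general host: mean of per-pair scores, hand-assembled
  corp2 <- make_corpus(5, c(60, 120), bias = random_bias(1, 51), seed = 52)
  pt2 <- codon_pair_table(corp2$sequences)
  cds2 <- as.character(corp2$sequences[[1]])
  cod <- sapply(seq(1, nchar(cds2) - 5, 3), function(i) substr(cds2, i, i + 5))
  cod <- cod[!grepl("TAA$|TAG$|TGA$", cod)]
  expected <- mean(pt2$cps[cod[cod %in% names(pt2$cps)]])
  expect_equal(as.numeric(cpb(cds2, pt2)), expected, tolerance = 1e-12)
})

test_that("cpb handles host-unseen pairs per the missing policy", {
  pt <- codon_pair_table(c(g = "ATGAAAGGG"))
  # sequence with a pair the host never saw
  expect_error(cpb("ATGCCC", pt, missing = "error"), "absent")
  res <- cpb("ATGAAACCC", pt, missing = "skip")
  expect_equal(attr(res, "n_unscored"), 1L)
  expect_error(cpb("CCCGGGTTT", pt), "no codon pair")
})

test_that("restriction site scan reports 0-based overlapping hits", {
  hits <- find_restriction_sites("AAGAATTCAA")
  expect_equal(hits$enzyme, "EcoRI")
  expect_equal(hits$position, 2L)
  expect_equal(find_restriction_sites("GGGGCCCC")$position, 1L)
  expect_equal(nrow(find_restriction_sites("ATATATATAT")), 0L)
  # overlapping occurrences are all reported
  hits2 <- find_restriction_sites("CCATGG", c(X = "CAT"))
  expect_equal(hits2$position, 1L)
  hits3 <- find_restriction_sites("AAAA", c(X = "AA"))
  expect_equal(hits3$position, c(0L, 1L, 2L))
  expect_error(find_restriction_sites("ACGT", c(X = "")), "empty motif")
})

test_that("reverse-complement scanning is available but off by default", {
  # GAATTC is palindromic; use an asymmetric motif
  s <- "AAACCCGGG" # contains revcomp of CCCGGG? use motif TTTGGG -> rc CCCAAA
  hits <- find_restriction_sites("ACCCAAA", c(X = "TTTGGG"))
  expect_equal(nrow(hits), 0L)
  hits_rc <- find_restriction_sites("ACCCAAA", c(X = "TTTGGG"), both_strands = TRUE)
  expect_equal(hits_rc$enzyme, "X_rc")
  expect_equal(hits_rc$position, 1L)
})

test_that("score_sequence aggregates the suite consistently", {
  corp <- make_corpus(6, c(60, 120), bias = random_bias(1, 61), seed = 62)
  tab <- codon_usage_table(corp$sequences)
  pt <- codon_pair_table(corp$sequences)
  cds <- as.character(corp$sequences[[2]])
  rep <- score_sequence(cds, tab, pair_table = pt, id = "g2")
  expect_s3_class(rep, "metrics_report")
  expect_equal(rep$cai, cai(cds, tab))
  expect_equal(rep$gc_percent, gc_content(cds))
  expect_equal(mean(c(rep$gc1, rep$gc2, rep$gc3)), rep$gc_percent, tolerance = 1e-9)
  expect_equal(rep$icu, icu(cds, tab))
  expect_equal(rep$cc, cc(cds, pt))
  expect_true(is.na(score_sequence(cds, tab)$cc))
  df <- as_report_frame(rep)
  expect_equal(nrow(df), 1L)
  # minimal 2-codon CDS still gets cc and cpb
  small <- score_sequence("ATGAAA", codon_usage_table(c(g = "ATGAAA")),
    pair_table = codon_pair_table(c(g = "ATGAAA"))
  )
  expect_false(is.na(small$cc))
  expect_false(is.na(small$cpb))
})

test_that("report serialization produces one row per sequence in TSV and JSON", {
  tab <- tiny_table()
  reps <- lapply(c(a = "ATGAAA", b = "ATGAATAAC"), function(s) {
    score_sequence(s, tab, id = s)
  })
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  write_report(reps, tsv, "tsv")
  write_report(reps, js, "json")
  expect_equal(nrow(read.delim(tsv)), 2L)
  expect_length(jsonlite::read_json(js), 2L)
})
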