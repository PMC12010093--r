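test_that("single-family corpus gives the hand-computed counts, p and w", {
  tab <- codon_usage_table(c(g = "ATGAAAAAATAA"))
  expect_equal(tab$counts[["AAA"]], 2L)
  expect_equal(tab$aa_totals[["K"]], 2L)
  expect_equal(tab$p[["AAA"]], 1.0)
  expect_equal(tab$w[["AAA"]], 1.0)
  # zero-count synonym: pseudocount 0.5 over family max 2
  expect_equal(tab$w[["AAG"]], 0.25)
})

test_that("counts are additive over duplicated sequences while p and w are invariant", {
  one <- codon_usage_table(c(g = "ATGAAAAAGAATTAA"))
  two <- codon_usage_table(c(g1 = "ATGAAAAAGAATTAA", g2 = "ATGAAAAAGAATTAA"))
  expect_equal(two$counts, one$counts * 2L)
  expect_equal(two$p, one$p)
  # w is count-scale invariant wherever the codon was observed; zero-count
  # codons keep the fixed pseudocount, so their w shrinks as counts grow
  seen <- one$counts > 0
  expect_equal(two$w[seen], one$w[seen])
  expect_true(all(two$w[!seen] <= one$w[!seen]))
})

test_that("family normalization and w-max invariants hold on random corpora", {
  for (seed in 1:8) {
    corp <- make_corpus(5, c(30, 120), bias = random_bias(0.7, seed), seed = seed)
    tab <- codon_usage_table(corp$sequences)
    code <- tab$code
    for (aa in names(code$families)) {
      fam <- code$families[[aa]]
      if (tab$aa_totals[[aa]] > 0) {
        expect_equal(sum(tab$p[fam]), 1, tolerance = 1e-9)
        expect_equal(max(tab$w[fam]), 1, tolerance = 1e-12)
        expect_equal(sum(tab$counts[fam]), tab$aa_totals[[aa]])
      }
    }
    expect_true(all(tab$w > 0 & tab$w <= 1))
  }
})

test_that("stop codons never enter usage or pair statistics", {
  tab <- codon_usage_table(c(g = "ATGAAATAA"))
  expect_equal(sum(tab$counts), 2L) # ATG + AAA only
  pt <- codon_pair_table(c(g = "ATGAAAGGGTGA"))
  expect_false(any(grepl("TGA$|TAA$|TAG$", names(pt$pair_counts)) &
    !grepl("^ATG|^AAA|^GGG", names(pt$pair_counts))))
  expect_equal(sum(pt$pair_counts), 2L)
})

test_that("pair table counts adjacent in-frame pairs within sequences only", {
  pt <- codon_pair_table(c(g = "ATGAAATAA"))
  expect_equal(names(pt$pair_counts), "ATGAAA")
  expect_equal(unname(pt$q[["ATGAAA"]]), 1.0)
  # 3-codon CDS -> 2 pairs; two sequences never chain across the boundary
  pt3 <- codon_pair_table(c(a = "ATGAAAGGG", b = "ATGCCCTTT"))
  expect_equal(sum(pt3$pair_counts), 4L)
  expect_false("GGGATG" %in% names(pt3$pair_counts))
})

test_that("q normalizes within amino-acid pair families", {
  corp <- make_corpus(6, c(40, 90), bias = random_bias(1, 3), seed = 5)
  pt <- codon_pair_table(corp$sequences)
  code <- pt$code
  aapair <- paste0(
    code$table[substr(names(pt$q), 1, 3)],
    code$table[substr(names(pt$q), 4, 6)]
  )
  sums <- tapply(pt$q, aapair, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("one-codon-per-family corpora have cps identically zero", {
  # with one codon per amino acid, observed pair counts equal the
  # independence expectation exactly, so every log-ratio is 0
  b <- bias_spec(default = "gc3")
  corp <- lapply(1:5, function(i) {
    as.character(sample_cds(length = 60, bias = b, seed = i))
  })
  names(corp) <- paste0("s", 1:5)
  pt <- codon_pair_table(corp)
  expect_true(all(abs(pt$cps) < 1e-12))
})

test_that("highly expressed selection keeps the top quantile with tie expansion", {
  seqs <- setNames(
    replicate(10, "ATGAAATAA"), sprintf("g%02d", 1:10)
  )
  expr <- data.frame(gene_id = names(seqs), expression = 1:10)
  top1 <- select_highly_expressed(seqs, expr, fraction = 0.1, quiet = TRUE)
  expect_equal(names(top1), "g10")
  all_of_them <- select_highly_expressed(seqs, expr, fraction = 1, quiet = TRUE)
  expect_setequal(names(all_of_them), names(seqs))
  # tie at the threshold: both tied genes kept
  expr$expression[9] <- 10
  tied <- select_highly_expressed(seqs, expr, fraction = 0.1, quiet = TRUE)
  expect_setequal(names(tied), c("g09", "g10"))
  expect_error(select_highly_expressed(seqs, expr, fraction = 0), "fraction")
  expect_error(
    select_highly_expressed(seqs, expr[0, ], fraction = 0.5, quiet = TRUE)
  )
})

test_that("ids missing from the expression table are dropped with a message", {
  seqs <- c(a = "ATGAAATAA", b = "ATGGGGTAA", z = "ATGCCCTAA")
  expr <- data.frame(gene_id = c("a", "b"), expression = c(5, 1))
  expect_message(
    out <- select_highly_expressed(seqs, expr, fraction = 0.5),
    "missing"
  )
  expect_equal(names(out), "a")
})

test_that("usage table serialization round-trips field by field", {
  corp <- make_corpus(4, c(30, 60), bias = random_bias(1, 2), seed = 9)
  tab <- codon_usage_table(corp$sequences, pseudocount = 0.5, source_label = "HE")
  f <- tempfile(fileext = ".tsv")
  write_usage_table(tab, f)
  back <- read_usage_table(f)
  expect_equal(back$counts, tab$counts)
  expect_equal(back$p, tab$p)
  expect_equal(back$w, tab$w)
  expect_equal(back$pseudocount, tab$pseudocount)
  expect_equal(back$source_label, tab$source_label)
})

test_that("usage table loading rejects incomplete codon sets and wrong formats", {
  tab <- tiny_table()
  f <- tempfile(fileext = ".tsv")
  write_usage_table(tab, f)
  lines <- readLines(f)
  writeLines(lines[-4], f) # drop one codon row
  expect_error(read_usage_table(f), "codon set")
  f2 <- tempfile(fileext = ".tsv")
  writeLines(c("# something else", lines[-1]), f2)
  expect_error(read_usage_table(f2), "not a codonkit")
})

test_that("usage table loading accepts newer minor versions of the format", {
  tab <- tiny_table()
  f <- tempfile(fileext = ".tsv")
  write_usage_table(tab, f)
  lines <- readLines(f)
  lines[1] <- "# codonkit usage_table v1.7"
  writeLines(lines, f)
  expect_equal(read_usage_table(f)$counts, tab$counts)
})

test_that("pair table serialization round-trips with zero rows omitted", {
  corp <- make_corpus(4, c(30, 60), bias = random_bias(1, 5), seed = 11)
  pt <- codon_pair_table(corp$sequences)
  f <- tempfile(fileext = ".tsv")
  write_pair_table(pt, f)
  back <- read_pair_table(f)
  expect_equal(back$pair_counts, pt$pair_counts)
  expect_equal(back$q, pt$q)
  expect_equal(back$cps, pt$cps)
  expect_equal(back$counts, pt$counts)
})

test_that("expression table reader accepts files with and without a header", {
  f1 <- tempfile(); f2 <- tempfile()
  writeLines(c("gene_id\texpression", "a\t1.5", "b\t2"), f1)
  writeLines(c("a\t1.5", "b\t2"), f2)
  expect_equal(read_expression_table(f1), read_expression_table(f2))
  f3 <- tempfile()
  writeLines(c("a\t-1"), f3)
  expect_error(read_expression_table(f3), "non-negative")
})

test_that("empty corpora are rejected", {
  expect_error(codon_usage_table(character(0)), "empty corpus")
  expect_error(codon_pair_table(list()), "empty corpus")
  expect_error(codon_pair_table(c(g = "ATGTAA")), "at least 2")
})
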