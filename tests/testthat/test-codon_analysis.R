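test_that("background frequencies match hand counts", {
  bg <- background_frequencies(make_orfs("ATGGCTTAA"))
  expect_equal(bg$freq[bg$nucleotide == "A"], 3 / 9)
  expect_equal(bg$freq[bg$nucleotide == "U"], 3 / 9)
  expect_equal(bg$freq[bg$nucleotide == "G"], 2 / 9)
  expect_equal(bg$freq[bg$nucleotide == "C"], 1 / 9)

  bg2 <- background_frequencies(make_orfs(c("AAA", "AAAAAA")))
  expect_equal(bg2$freq[bg2$nucleotide == "A"], 1)
  expect_equal(sum(bg2$freq), 1)

  expect_error(background_frequencies(make_orfs(character(0))), "empty")
})

test_that("codon classification partitions the 64 codons correctly", {
  tab <- codon_class_table()
  expect_equal(nrow(tab), 64L)
  expect_equal(as.integer(table(tab$wobble)), rep(16L, 4))
  expect_equal(sum(tab$t34 == "none"), 3L)
  expect_true(all(tab$amino_acid[tab$t34 == "none"] == "STOP"))
  # every NNU/NNC codon carries a G34 or I34 anticodon label
  uc <- tab[tab$wobble %in% c("U", "C"), ]
  expect_equal(nrow(uc), 32L)
  expect_true(all(uc$t34 %in% c("G34", "I34")))

  gcu <- classify_codon("GCU")
  expect_equal(gcu$amino_acid, "A")
  expect_equal(gcu$wobble, "U")
  expect_equal(gcu$t34, "I34")

  uuu <- classify_codon("UUU")  # UUA codes Leu, not Phe -> G34
  expect_equal(uuu$t34, "G34")

  cga <- classify_codon("CGA")
  expect_true(cga$i34_exclusive)
  expect_equal(cga$t34, "I34")
  expect_equal(sum(tab$i34_exclusive), 1L)

  expect_equal(classify_codon("UAA")$t34, "none")
  # Gly is the fixed eukaryote exception: G34 although GGA codes Gly
  expect_equal(classify_codon(c("GGU", "GGC"))$t34, c("G34", "G34"))
  # T- and U-alphabet inputs agree
  expect_identical(classify_codon("GCT"), classify_codon("GCU"))
  expect_error(classify_codon("GXA"), "invalid codon")

  prok <- codon_class_table("prokaryote")
  expect_false(any(prok$t34 == "I34"))
})

test_that("PWM equals an independent brute-force tally on small ORF sets", {
  withr::local_seed(42)
  seqs <- vapply(1:5, function(i) {
    paste(sample(c("A", "C", "G", "T"), 3 * sample(4:9, 1), replace = TRUE),
      collapse = ""
    )
  }, character(1))
  orfs <- make_orfs(seqs)

  pwm <- codon_pwm(orfs)
  oracle <- oracle_pwm(seqs)
  expect_equal(unname(pwm$f_obs), unname(oracle$f_obs))
  expect_equal(unname(pwm$f_exp), unname(oracle$f_exp))
  expect_equal(unname(pwm$weights), unname(oracle$weights))
  expect_equal(pwm$n_codons, oracle$n)

  adj <- adjacency_pwm(orfs, "NNU")
  oracle_adj <- oracle_pwm(seqs, function(codon, prev, i) {
    !is.na(prev) && substr(prev, 3, 3) == "T"
  })
  expect_equal(unname(adj$weights), unname(oracle_adj$weights))
  expect_equal(adj$n_codons, oracle_adj$n)

  # per-position observed frequencies always sum to 1
  expect_equal(unname(rowSums(pwm$f_obs)), rep(1, 3))
})

test_that("PWM weights obey the log-ratio definition and the zero guard", {
  # single ORF "ATGGAT": bg A=1/3, G=1/3, T=1/3, C=0
  pwm <- codon_pwm(make_orfs("ATGGAT"))
  expect_equal(pwm$weights["1", "G"], log2(0.5 / (1 / 3)))
  expect_true(all(is.nan(pwm$weights[, "C"])))  # f_exp = 0 -> sentinel

  # composition where observed equals expected at every position -> weight 0
  pwm0 <- codon_pwm(make_orfs("AAACCCGGGTTT"))
  expect_equal(unname(pwm0$weights), matrix(0, 3, 4))

  # near-zero weights for uniform random composition at scale
  withr::local_seed(7)
  seqs <- vapply(1:100, function(i) {
    paste(sample(c("A", "C", "G", "T"), 900, replace = TRUE), collapse = "")
  }, character(1))
  pwm_u <- codon_pwm(make_orfs(seqs))
  expect_lt(max(abs(pwm_u$weights)), 0.05)

  expect_error(
    adjacency_pwm(make_orfs("ATGGCTTAA"), function(x) rep(FALSE, length(x))),
    "zero codons"
  )
})

test_that("expression stratification ranks, rounds up and breaks ties by id", {
  orfs <- make_orfs(rep("ATGGCTTAA", 10), ids = sprintf("g%02d", 1:10))
  expr <- tibble::tibble(gene_id = sprintf("g%02d", 1:10), value = 1:10)
  s <- stratify_by_expression(orfs, expr, fraction = 0.2)
  expect_setequal(s$top$gene_id, c("g10", "g09"))
  expect_setequal(s$bottom$gene_id, c("g01", "g02"))
  expect_s3_class(s$top, "orf_set")

  # ceiling convention
  s2 <- stratify_by_expression(orfs, expr, fraction = 0.25)
  expect_equal(nrow(s2$top), 3L)

  # all-equal values: deterministic by gene_id order
  expr_eq <- tibble::tibble(gene_id = sprintf("g%02d", 1:10), value = rep(1, 10))
  s3 <- stratify_by_expression(orfs, expr_eq, fraction = 0.2)
  expect_equal(s3$top$gene_id, c("g01", "g02"))
  expect_equal(s3$bottom$gene_id, c("g01", "g02"))

  expect_warning(
    stratify_by_expression(
      orfs, dplyr::bind_rows(expr, tibble::tibble(gene_id = "gX", value = 5))
    ),
    "absent from the ORF set"
  )
  expect_error(
    suppressWarnings(stratify_by_expression(orfs, tibble::tibble(gene_id = "gX", value = 5))),
    "no overlap"
  )
})
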