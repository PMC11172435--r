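test_that("A-site offsets are recovered from start-proximal metagene signal", {
  for (true_off in c(15L, 14L)) {
    cfg <- sim_preset("null",
      n_genes = 60, seed = 31, length_codons = c(100L, 200L),
      rfp_classes = "28nt",
      true_offsets = stats::setNames(rep(true_off, 7), c(20:22, 27:30))
    )
    go <- gen_orfs(cfg)
    gp <- gen_profiles(go$orfs, cfg)
    ot <- calibrate_offsets(gp$counts, go$orfs, "28nt")
    expect_equal(ot$offset, rep(true_off, 4))
    expect_true(all(ot$calibrated))
  }

  empty <- footprint_counts(tibble::tibble(
    gene_id = character(), pos5 = integer(), read_length = integer(), count = integer()
  ))
  expect_error(calibrate_offsets(empty, make_orfs("ATGGCTTAA"), "28nt"), "no footprints")

  # too little signal falls back to the default with a warning
  tiny <- footprint_counts(tibble::tibble(
    gene_id = "g01", pos5 = c(-12L, -9L), read_length = 28L, count = c(2L, 3L)
  ))
  w <- testthat::capture_warnings(
    ot <- calibrate_offsets(tiny, make_orfs(strrep("ATGGCTGAA", 23)), "28nt")
  )
  expect_true(any(grepl("insufficient", w)))
  expect_equal(unique(ot$offset), 15L)
  expect_false(any(ot$calibrated))
})

test_that("codon densities sum major and flanking minor peaks and conserve counts", {
  # 30-nt ORF; counts at A-site positions 11, 12, 13 (codon 4 +/- 1 nt)
  orfs <- make_orfs(paste0("ATG", strrep("GCT", 8), "TAA"))
  counts <- footprint_counts(tibble::tibble(
    gene_id = "g01",
    pos5 = c(11L, 12L, 13L) - 15L,
    read_length = 28L,
    count = c(2L, 10L, 3L)
  ))
  dens <- codon_densities(counts, orfs, default_offsets("28nt"), "28nt")
  expect_equal(attr(dens, "major_frame"), 0L)
  expect_equal(dens$density[dens$codon_index == 4], 15)
  expect_equal(sum(dens$density), 15)
  expect_equal(nrow(dens), 10L)  # vector covers all codons incl. stop

  # all-zero gene stays an all-zero vector
  orfs2 <- make_orfs(c(orfs$seq, "ATGCCTTAA"), ids = c("g01", "g02"))
  dens2 <- codon_densities(counts, orfs2, default_offsets("28nt"), "28nt")
  expect_true(all(dens2$density[dens2$gene_id == "g02"] == 0))

  expect_error(
    codon_densities(
      footprint_counts(tibble::tibble(gene_id = "g01", pos5 = 0L, read_length = 31L, count = 1L)),
      orfs, tibble::tibble(read_length = 28L, offset = 15L), "28nt"
    ),
    NA
  )  # length 31 is outside the class and ignored
  expect_error(
    codon_densities(
      footprint_counts(tibble::tibble(gene_id = "g01", pos5 = 0L, read_length = 27L, count = 1L)),
      orfs, tibble::tibble(read_length = 28L, offset = 15L), "28nt"
    ),
    "missing from offset table"
  )

  # partition property on simulated data: per-gene sums equal the shifted
  # counts landing strictly inside [0, 3K-1) of each ORF
  sim <- quick_sim("null", n_genes = 20, seed = 8, length_codons = c(80L, 150L))
  dens3 <- codon_densities(sim$counts, sim$orfs, default_offsets("28nt"), "28nt")
  shifted <- sim$counts %>%
    dplyr::filter(.data$read_length %in% 27:30) %>%
    dplyr::mutate(
      p = .data$pos5 + 15L,
      len = nchar(sim$orfs$seq)[match(.data$gene_id, sim$orfs$gene_id)]
    ) %>%
    dplyr::filter(.data$p >= 0, .data$p < .data$len - 1L) %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(total = sum(.data$count))
  per_gene <- dens3 %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(total = sum(.data$density)) %>%
    dplyr::filter(.data$total > 0)
  expect_equal(
    per_gene$total[match(shifted$gene_id, per_gene$gene_id)],
    as.numeric(shifted$total)
  )
})

test_that("gene filters apply the strict length and density thresholds", {
  orfs <- make_orfs(
    c(strrep("AAA", 66), strrep("AAA", 100), strrep("AAA", 67)),
    ids = c("len198", "dens10", "keep")
  )
  counts <- footprint_counts(tibble::tibble(
    gene_id = c("len198", "dens10", "keep"),
    pos5 = 0L, read_length = 28L,
    count = c(1000L, 30L, 41L)
  ))
  rep <- filter_genes(counts, orfs, "28nt")
  expect_false(rep$retained[rep$gene_id == "len198"])  # 198 nt: not > 198
  expect_false(rep$retained[rep$gene_id == "dens10"])  # exactly 1/10 nt: not above
  expect_true(rep$retained[rep$gene_id == "keep"])     # 201 nt, 41 footprints
  s <- attr(rep, "summary")
  expect_equal(s$n_input, 3L)
  expect_equal(s$n_pass_length, 2L)
  expect_equal(s$n_pass_density, 1L)
  expect_lte(s$n_pass_density, s$n_pass_length)
})

test_that("normalization divides by the per-gene mean", {
  dens <- tibble::tibble(
    gene_id = rep(c("a", "b", "c"), each = 3),
    codon_index = rep(0:2, 3),
    density = c(2, 4, 6, 5, 5, 5, 0, 3, 3)
  )
  norm <- normalize_densities(dens)
  expect_equal(norm$density[norm$gene_id == "a"], c(0.5, 1, 1.5))
  expect_equal(norm$density[norm$gene_id == "b"], c(1, 1, 1))
  expect_equal(norm$density[norm$gene_id == "c"], c(0, 1.5, 1.5))
  means <- tapply(norm$density, norm$gene_id, mean)
  expect_equal(as.numeric(means), rep(1, 3), tolerance = 1e-9)

  dens$density[1:3] <- 0
  expect_error(normalize_densities(dens), "zero-total")
})

test_that("context annotation flags +1 GNN and stop-next instances", {
  orfs <- make_orfs("ATGGCTGAATAA")
  dens <- normalize_densities(tibble::tibble(
    gene_id = "g01", codon_index = 0:3, density = c(1, 2, 3, 2)
  ))
  ann <- annotate_contexts(dens, orfs)
  expect_equal(ann$asite_codon, c("AUG", "GCU", "GAA"))
  expect_equal(ann$plus1_codon, c("GCU", "GAA", "UAA"))
  # gnn_flag is TRUE exactly when the +1 codon starts with G (GCU, GAA)
  expect_equal(ann$gnn_flag, c(TRUE, TRUE, FALSE))
  expect_equal(ann$stop_next, c(FALSE, FALSE, TRUE))

  # stop codons never appear as A-site rows; 2 sense codons + stop -> 2 rows
  orfs2 <- make_orfs("ATGGAATAA")
  dens2 <- normalize_densities(tibble::tibble(
    gene_id = "g01", codon_index = 0:2, density = c(1, 2, 3)
  ))
  expect_equal(nrow(annotate_contexts(dens2, orfs2)), 2L)

  # edge exclusion trims the first codon; stop-next rows can be dropped
  expect_equal(annotate_contexts(dens, orfs, exclude_edge = 1)$asite_codon, c("GCU", "GAA"))
  expect_false(any(annotate_contexts(dens, orfs, stop_next_action = "drop")$stop_next))

  expect_error(
    annotate_contexts(dens[1:3, ], orfs),
    "does not match"
  )

  # gnn_flag totals equal the generator's planted adjacency count
  sim <- quick_sim("adjacency", n_genes = 25, seed = 13, length_codons = c(60L, 120L))
  dall <- tibble::tibble(
    gene_id = rep(sim$orfs$gene_id, nchar(sim$orfs$seq) %/% 3),
    codon_index = sequence(nchar(sim$orfs$seq) %/% 3) - 1L,
    density = 1
  )
  ann_all <- annotate_contexts(dall, sim$orfs)
  planted <- sim$orf_truth$adjacency_pairs
  expect_equal(
    sum(ann_all$gnn_flag[codon_matches(ann_all$asite_codon, "NNU")]),
    planted
  )
})
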