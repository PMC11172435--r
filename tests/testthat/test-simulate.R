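test_that("generation is deterministic given the seed", {
  cfg <- sim_preset("paper_effect", n_genes = 15, seed = 5, length_codons = c(60L, 90L))
  o1 <- gen_orfs(cfg)
  o2 <- gen_orfs(cfg)
  expect_identical(o1$orfs, o2$orfs)
  p1 <- gen_profiles(o1$orfs, cfg)
  p2 <- gen_profiles(o1$orfs, cfg)
  expect_identical(p1$counts, p2$counts)
  e1 <- gen_expression(o1$orfs, cfg)
  expect_identical(e1, gen_expression(o1$orfs, cfg))
  expect_false(identical(o1$orfs, gen_orfs(cfg, seed = 6)$orfs))

  # sigma = 0 gives all-equal expression values
  cfg0 <- sim_preset("null", n_genes = 10, seed = 1, expr_sigma = 0)
  e0 <- gen_expression(gen_orfs(cfg0, seed = 1)$orfs, cfg0)
  expect_equal(length(unique(e0$value)), 1L)
  expect_equal(nrow(e0), 10L)
})

test_that("generated ORFs respect start/stop structure and codon model", {
  cfg <- sim_preset("null", n_genes = 30, seed = 9, length_codons = c(30L, 60L))
  orfs <- gen_orfs(cfg)$orfs
  expect_true(all(substr(orfs$seq, 1, 3) == "ATG"))
  last <- substr(orfs$seq, nchar(orfs$seq) - 2, nchar(orfs$seq))
  expect_true(all(last %in% c("TAA", "TAG", "TGA")))
  inst <- orf_codons(orfs)
  interior <- inst$codon[inst$codon_index > 0 & inst$codon_index < inst$n_codons - 1]
  expect_false(any(interior %in% c("TAA", "TAG", "TGA")))
  expect_true(all(nchar(orfs$seq) %% 3 == 0))
  expect_true(all(nchar(orfs$seq) >= 90 & nchar(orfs$seq) <= 180))
})

test_that("adjacency bias shifts conditional G1 frequency as configured", {
  # null: conditional G1 frequency after NNU matches the unconditional one
  cfg <- sim_config(n_genes = 350, length_codons = c(300L, 300L), seed = 41)
  orfs <- gen_orfs(cfg)$orfs  # ~1e5 codons
  inst <- orf_codons(orfs)
  g1 <- substr(inst$codon, 1, 1) == "G"
  after_nnu <- !is.na(inst$prev_codon) & codon_matches(inst$prev_codon, "NNU")
  expect_lt(abs(mean(g1[after_nnu]) - mean(g1)), 0.01)

  # biased generation elevates it by the configured odds
  cfgb <- sim_config(
    n_genes = 350, length_codons = c(300L, 300L),
    adjacency_bias = 1.3, seed = 41
  )
  orfs_b <- gen_orfs(cfgb)$orfs
  inst_b <- orf_codons(orfs_b)
  g1_b <- substr(inst_b$codon, 1, 1) == "G"
  after_b <- !is.na(inst_b$prev_codon) & codon_matches(inst_b$prev_codon, "NNU")
  p_base <- 16 / 61
  p_expected <- 1.3 * p_base / (1.3 * p_base + (1 - p_base))
  expect_equal(mean(g1_b[after_b & inst_b$codon_index < inst_b$n_codons - 1]),
    p_expected,
    tolerance = 0.02
  )
})

test_that("profile counts match closed-form expectations", {
  cfg <- sim_preset("null",
    n_genes = 40, seed = 55, length_codons = c(150L, 250L),
    rfp_classes = "28nt", depth_sigma = 0
  )
  go <- gen_orfs(cfg)
  gp <- gen_profiles(go$orfs, cfg)
  totals <- gp$counts %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(n = sum(.data$count))
  lens <- nchar(go$orfs$seq)
  depth <- gp$truth$depth[go$orfs$gene_id]
  expected <- depth * lens
  # each gene total is a Poisson sum (edge clipping loses < 1 expected read)
  z <- (totals$n[match(go$orfs$gene_id, totals$gene_id)] - expected) / sqrt(expected)
  expect_true(all(abs(z) < 4))
  expect_lt(abs(mean(z)), 0.6)

  # only configured read lengths, all within the ORF-interior A-site model
  expect_true(all(gp$counts$read_length %in% 27:30))
  p <- gp$counts$pos5 + 15L
  expect_true(all(p >= 0 & p < lens[match(gp$counts$gene_id, go$orfs$gene_id)]))
})

test_that("flat dwell with a single frame yields near-constant normalized densities", {
  cfg <- sim_preset("null",
    n_genes = 10, seed = 77, length_codons = c(150L, 150L),
    rfp_classes = "28nt", frame_weights = c(1, 0, 0),
    depth_median = 20, depth_sigma = 0
  )
  go <- gen_orfs(cfg)
  gp <- gen_profiles(go$orfs, cfg)
  dens <- normalize_densities(
    codon_densities(gp$counts, go$orfs, default_offsets("28nt"), "28nt")
  )
  expect_lt(sd(dens$density), 0.2)  # Poisson(60) scaled: sd ~ 1/sqrt(60)
  expect_equal(mean(dens$density), 1, tolerance = 1e-9)
})

test_that("simulated datasets round-trip through the file readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset("paper_effect", out_dir = dir, seed = 3, n_genes = 12,
                          length_codons = c(60L, 90L))
  expect_true(all(file.exists(unlist(sim$paths))))
  orfs <- read_orf_fasta(sim$paths$fasta, quiet = TRUE)
  expect_equal(orfs$gene_id, sim$orfs$gene_id)
  expect_equal(orfs$seq, sim$orfs$seq)
  counts <- read_footprint_table(sim$paths$counts)
  expect_equal(counts$pos5, sim$counts$pos5)
  expect_equal(counts$count, sim$counts$count)
  expect_equal(counts$read_length, sim$counts$read_length)
  expr <- read_expression_table(sim$paths$expression)
  expect_equal(expr$value, sim$expression$value)
  truth <- jsonlite::read_json(sim$paths$truth)
  expect_equal(truth$preset, "paper_effect")
  expect_equal(truth$adjacency_pairs, sim$truth$adjacency_pairs)
})

test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 10), "seed is mandatory")
  expect_error(sim_config(frame_weights = c(0.5, 0.3, 0.1), seed = 1))
  expect_error(sim_config(adjacency_bias = 0, seed = 1))
  expect_error(
    sim_config(dwell_rules = list(list(asite = "NNU", plus1 = "GNN", multiplier = 0)), seed = 1)
  )
})
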