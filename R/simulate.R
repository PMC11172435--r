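SENSE_CODONS <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Simulation configuration
#'
#' Defines the generative model for synthetic ORF sets and footprint
#' profiles: codon-by-codon sequence sampling with an optional
#' adjacency bias (the odds of every G-starting codon are multiplied by
#' `adjacency_bias` immediately after an NNU codon), a multiplicative
#' dwell model keyed by (A-site pattern, +1 pattern) rules, a
#' three-nucleotide periodic frame profile, per-gene lognormal sequencing
#' depth, and per-class read-length mixtures with known true A-site
#' offsets.
#'
#' @param n_genes Number of genes.
#' @param length_codons Integer range (min, max) of ORF lengths in codons,
#'   start and stop included; lengths are drawn uniformly.
#' @param codon_weights Optional named weight vector over the 61 sense
#'   codons (DNA or RNA names); default uniform.
#' @param adjacency_bias Multiplicative odds applied to G-starting codons
#'   directly after an NNU codon (1 = no adjacency structure).
#' @param dwell_rules List of `list(asite=, plus1=, multiplier=)` rules;
#'   a codon's dwell is the product of the multipliers of all rules whose
#'   patterns match its A-site codon and defined +1 codon (base dwell 1).
#' @param frame_weights Probabilities of the major peak and its 5'/3'
#'   minor peaks (must sum to 1).
#' @param depth_median,depth_sigma Median (reads/nt) and lognormal sigma
#'   of per-gene depth.
#' @param read_length_mix Named list per footprint class of read-length
#'   probability vectors.
#' @param true_offsets Named integer vector: read length -> A-site offset.
#' @param major_frame Frame (0/1/2) carrying the major peak.
#' @param rfp_classes Footprint classes to generate reads for.
#' @param expr_median,expr_sigma Lognormal parameters for
#'   [gen_expression()].
#' @param overdispersion Negative-binomial overdispersion (0 = Poisson).
#' @param seed Mandatory integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200L,
                       length_codons = c(300L, 600L),
                       codon_weights = NULL,
                       adjacency_bias = 1,
                       dwell_rules = list(),
                       frame_weights = c(0.70, 0.15, 0.15),
                       depth_median = 1,
                       depth_sigma = 0.5,
                       read_length_mix = list(
                         "28nt" = c("27" = 0.15, "28" = 0.55, "29" = 0.20, "30" = 0.10),
                         "21nt" = c("20" = 0.20, "21" = 0.60, "22" = 0.20)
                       ),
                       true_offsets = stats::setNames(rep(15L, 7), c(20:22, 27:30)),
                       major_frame = 0L,
                       rfp_classes = c("28nt", "21nt"),
                       expr_median = 1,
                       expr_sigma = 1,
                       overdispersion = 0,
                       seed) {
  if (missing(seed)) stop("seed is mandatory in sim_config()")
  stopifnot(
    n_genes >= 1,
    length(length_codons) == 2, length_codons[1] >= 3,
    length_codons[2] >= length_codons[1],
    adjacency_bias > 0,
    abs(sum(frame_weights) - 1) < 1e-9, length(frame_weights) == 3,
    depth_median > 0, depth_sigma >= 0,
    major_frame %in% 0:2,
    overdispersion >= 0
  )
  if (!is.null(codon_weights)) {
    names(codon_weights) <- to_dna(names(codon_weights))
    stopifnot(setequal(names(codon_weights), SENSE_CODONS), all(codon_weights > 0))
    codon_weights <- codon_weights[SENSE_CODONS]
  }
  for (r in dwell_rules) {
    stopifnot(is.list(r), !is.null(r$asite), !is.null(r$plus1), r$multiplier > 0)
  }
  for (cl in rfp_classes) {
    mix <- read_length_mix[[cl]]
    stopifnot(!is.null(mix), abs(sum(mix) - 1) < 1e-9)
    stopifnot(all(names(mix) %in% names(true_offsets)))
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      length_codons = as.integer(length_codons),
      codon_weights = codon_weights,
      adjacency_bias = adjacency_bias,
      dwell_rules = dwell_rules,
      frame_weights = frame_weights,
      depth_median = depth_median,
      depth_sigma = depth_sigma,
      read_length_mix = read_length_mix,
      true_offsets = true_offsets,
      major_frame = as.integer(major_frame),
      rfp_classes = rfp_classes,
      expr_median = expr_median,
      expr_sigma = expr_sigma,
      overdispersion = overdispersion,
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Named simulation presets
#'
#' `"null"`: no adjacency bias, all dwell multipliers 1 (used for
#' calibration). `"paper_effect"`: dwell multiplier 1.4 for A-site NNU
#' codons followed by +1 GNN, everything else 1 - the documented headline
#' effect size all recovery tests refer to. `"adjacency"`: G-starting
#' codon odds multiplied by 1.3 after NNU codons, no dwell effect.
#'
#' @param preset Preset name.
#' @param ... Overrides passed to [sim_config()] (`seed` is required).
#' @return A `sim_config`.
#' @export
sim_preset <- function(preset = c("null", "paper_effect", "adjacency"), ...) {
  preset <- match.arg(preset)
  args <- list(...)
  if (preset == "paper_effect") {
    args$dwell_rules <- list(list(asite = "NNU", plus1 = "GNN", multiplier = 1.4))
  } else if (preset == "adjacency") {
    args$adjacency_bias <- 1.3
  }
  do.call(sim_config, args)
}

#' Generate a synthetic ORF set
#'
#' Sequences are drawn codon by codon: AUG start, uniformly chosen stop at
#' the end, interior codons from the configured sense-codon weights; after
#' an NNU codon the probability of every G-starting codon is multiplied by
#' `adjacency_bias` and renormalized. No internal stops are produced.
#'
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed`).
#' @return List with `orfs` (an [orf_set]) and `truth` (planted adjacency
#'   counts and the echoed configuration).
#' @export
gen_orfs <- function(config, seed = config$seed) {
  withr::local_seed(seed)
  n <- config$n_genes
  len_range <- seq(config$length_codons[1], config$length_codons[2])
  k <- len_range[sample.int(length(len_range), n, replace = TRUE)]
  w <- config$codon_weights
  if (is.null(w)) w <- stats::setNames(rep(1, 61), SENSE_CODONS)
  w <- w / sum(w)
  g_start <- substr(SENSE_CODONS, 1, 1) == "G"
  w_bias <- w * ifelse(g_start, config$adjacency_bias, 1)
  w_bias <- w_bias / sum(w_bias)
  is_nnu <- substr(SENSE_CODONS, 3, 3) == "T"
  n_int <- k - 2L
  max_int <- max(n_int)
  cod <- matrix(NA_integer_, n, max_int)
  if (config$adjacency_bias == 1) {
    draws <- sample.int(61L, sum(n_int), replace = TRUE, prob = w)
    cod[cbind(
      rep(seq_len(n), n_int),
      sequence(n_int)
    )] <- draws
  } else {
    prev_nnu <- rep(FALSE, n)
    for (j in seq_len(max_int)) {
      act <- n_int >= j
      a1 <- which(act & !prev_nnu)
      a2 <- which(act & prev_nnu)
      if (length(a1)) cod[cbind(a1, j)] <- sample.int(61L, length(a1), replace = TRUE, prob = w)
      if (length(a2)) cod[cbind(a2, j)] <- sample.int(61L, length(a2), replace = TRUE, prob = w_bias)
      drawn <- cod[cbind(which(act), j)]
      prev_nnu[act] <- is_nnu[drawn]
    }
  }
  stops <- sample(STOP_CODONS, n, replace = TRUE)
  seqs <- vapply(seq_len(n), function(g) {
    paste0("ATG", paste(SENSE_CODONS[cod[g, seq_len(n_int[g])]], collapse = ""), stops[g])
  }, character(1))
  orfs <- orf_set(sprintf("gene_%04d", seq_len(n)), seqs, quiet = TRUE)
  inst <- orf_codons(orfs)
  after_nnu <- !is.na(inst$prev_codon) & codon_matches(inst$prev_codon, "NNU")
  truth <- list(
    adjacency_pairs = sum(after_nnu & codon_matches(inst$codon, "GNN")),
    after_nnu_codons = sum(after_nnu),
    seed = seed,
    config = config
  )
  list(orfs = orfs, truth = truth)
}

#' Generate synthetic footprint counts for an ORF set
#'
#' For gene g, codon i and frame component f, the expected count is
#' `depth_g * 3 * dwell(g,i) * frame_weights[f] / mean_dwell_g`, realized
#' as Poisson (or negative binomial when overdispersed). Each count is
#' placed at the A-site nucleotide `3*i + major_frame + delta_f` (delta =
#' 0/-1/+1; positions confined to the ORF) and converted to a 5'-end
#' position by subtracting the true offset of a read length drawn from the
#' class mixture, so 5' ends of start-proximal reads may be negative
#' (in the 5' UTR). Expected total reads per gene and class equal
#' `depth_g * ORF length`.
#'
#' @param orfs An [orf_set].
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed + 1`).
#' @return List with `counts` (a `footprint_counts` tibble covering the
#'   configured classes) and `truth` (per-gene dwell vectors, depths,
#'   mean dwell, echoed config).
#' @export
gen_profiles <- function(orfs, config, seed = config$seed + 1L) {
  withr::local_seed(seed)
  inst <- orf_codons(orfs)
  dwell <- rep(1, nrow(inst))
  for (r in config$dwell_rules) {
    m <- codon_matches(inst$codon, r$asite) &
      !is.na(inst$next_codon) & codon_matches(inst$next_codon, r$plus1)
    dwell[m] <- dwell[m] * r$multiplier
  }
  gene_f <- factor(inst$gene_id, levels = orfs$gene_id)
  mean_dwell <- as.numeric(tapply(dwell, gene_f, mean))
  depth <- stats::rlnorm(nrow(orfs), log(config$depth_median), config$depth_sigma)
  gi <- as.integer(gene_f)
  lam_codon <- 3 * depth[gi] * dwell / mean_dwell[gi]
  orf_len <- nchar(orfs$seq)[gi]
  deltas <- c(0L, -1L, 1L)
  acc_gene <- list(); acc_pos <- list(); acc_len <- list(); acc_cnt <- list()
  for (cl in config$rfp_classes) {
    mix <- config$read_length_mix[[cl]]
    for (f in 1:3) {
      p <- 3L * inst$codon_index + config$major_frame + deltas[f]
      valid <- p >= 0L & p < orf_len
      for (l in names(mix)) {
        len <- as.integer(l)
        lam <- lam_codon * config$frame_weights[f] * mix[[l]]
        lam[!valid] <- 0
        cnt <- if (config$overdispersion > 0) {
          stats::rnbinom(length(lam), mu = lam, size = 1 / config$overdispersion)
        } else {
          stats::rpois(length(lam), lam)
        }
        nz <- which(cnt > 0L)
        if (length(nz)) {
          i <- length(acc_gene) + 1L
          acc_gene[[i]] <- inst$gene_id[nz]
          acc_pos[[i]] <- p[nz] - config$true_offsets[[l]]
          acc_len[[i]] <- rep(len, length(nz))
          acc_cnt[[i]] <- cnt[nz]
        }
      }
    }
  }
  counts <- footprint_counts(tibble::tibble(
    gene_id = unlist(acc_gene, use.names = FALSE),
    pos5 = unlist(acc_pos, use.names = FALSE),
    read_length = unlist(acc_len, use.names = FALSE),
    count = unlist(acc_cnt, use.names = FALSE)
  ))
  truth <- list(
    dwell = split(dwell, gene_f),
    mean_dwell = stats::setNames(mean_dwell, orfs$gene_id),
    depth = stats::setNames(depth, orfs$gene_id),
    seed = seed,
    config = config
  )
  list(counts = counts, truth = truth)
}

#' Generate a synthetic expression table
#'
#' Lognormal expression values, one per gene, seeded.
#'
#' @param orfs An [orf_set].
#' @param config A [sim_config()].
#' @param seed Seed (defaults to `config$seed + 2`).
#' @return Tibble with columns `gene_id`, `value`.
#' @export
gen_expression <- function(orfs, config, seed = config$seed + 2L) {
  withr::local_seed(seed)
  tibble::tibble(
    gene_id = orfs$gene_id,
    value = stats::rlnorm(nrow(orfs), log(config$expr_median), config$expr_sigma)
  )
}

#' Simulate a complete dataset and write it to disk
#'
#' Generates ORFs, footprint counts and expression values from a preset
#' and writes `orfs.fasta`, `counts.tsv`, `expression.tsv` and
#' `truth.json` into `out_dir`, in the formats consumed by the io readers.
#'
#' @param preset See [sim_preset()].
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param ... Further [sim_config()] overrides (e.g. `n_genes`).
#' @return Invisibly, a list with the file paths, the in-memory objects
#'   and the ground truth.
#' @export
simulate_dataset <- function(preset = "null", out_dir, seed, ...) {
  config <- sim_preset(preset, seed = seed, ...)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  go <- gen_orfs(config)
  gp <- gen_profiles(go$orfs, config)
  expr <- gen_expression(go$orfs, config)
  paths <- list(
    fasta = file.path(out_dir, "orfs.fasta"),
    counts = file.path(out_dir, "counts.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_orf_fasta(go$orfs, paths$fasta)
  write_footprint_table(gp$counts, paths$counts)
  readr::write_tsv(expr, paths$expression, progress = FALSE)
  truth <- list(
    preset = preset,
    adjacency_pairs = go$truth$adjacency_pairs,
    after_nnu_codons = go$truth$after_nnu_codons,
    depth = gp$truth$depth,
    mean_dwell = gp$truth$mean_dwell,
    config = config[setdiff(names(config), "codon_weights")]
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(
    paths = paths, config = config, orfs = go$orfs,
    counts = gp$counts, expression = expr,
    truth = c(go$truth[c("adjacency_pairs", "after_nnu_codons")], gp$truth[c("dwell", "mean_dwell", "depth")])
  ))
}
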