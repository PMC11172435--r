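NUCS_DNA <- c("A", "C", "G", "T")
NUCS_RNA <- c("A", "C", "G", "U")

to_rna <- function(x) chartr("T", "U", x)
to_dna <- function(x) chartr("U", "T", toupper(x))

#' Match codons against an N-wildcard pattern
#'
#' Patterns are 3-letter strings over A/C/G/T/U/N where N matches any
#' nucleotide, e.g. `"NNU"` (any codon with wobble U), `"GNN"` (any codon
#' starting with G).
#'
#' @param codons Character vector of 3-mers (T or U alphabet).
#' @param pattern A single 3-letter pattern.
#' @return Logical vector.
#' @export
codon_matches <- function(codons, pattern) {
  stopifnot(nchar(pattern) == 3L)
  pat <- to_dna(pattern)
  rx <- paste0("^", gsub("N", "[ACGT]", pat), "$")
  grepl(rx, to_dna(codons))
}

#' Per-codon instance table of an ORF set
#'
#' Expands an ORF set into one row per codon with its 0-based index and its
#' 5' (previous) and 3' (next, "+1") neighbours within the same ORF; both
#' neighbours are `NA` at ORF boundaries (codon context never crosses genes).
#'
#' @param orfs An [orf_set].
#' @return Tibble with columns `gene_id`, `codon_index`, `codon`,
#'   `prev_codon`, `next_codon`, `n_codons` (DNA alphabet).
#' @export
orf_codons <- function(orfs) {
  k <- nchar(orfs$seq) %/% 3L
  gene <- rep(orfs$gene_id, k)
  seqs <- rep(orfs$seq, k)
  idx <- sequence(k) - 1L
  nk <- rep(k, k)
  codon <- substring(seqs, 3L * idx + 1L, 3L * idx + 3L)
  prev <- ifelse(idx > 0L, substring(seqs, 3L * idx - 2L, 3L * idx), NA_character_)
  nxt <- ifelse(idx < nk - 1L, substring(seqs, 3L * idx + 4L, 3L * idx + 6L), NA_character_)
  tibble::tibble(
    gene_id = gene, codon_index = idx, codon = codon,
    prev_codon = prev, next_codon = nxt, n_codons = nk
  )
}

#' Background nucleotide frequencies of an ORF set
#'
#' Pooled single-nucleotide frequencies over all sequences, irrespective of
#' codon position. These are the expected frequencies against which
#' position-specific observed frequencies are weighted in [codon_pwm()].
#'
#' @param orfs An [orf_set].
#' @return Tibble with columns `nucleotide` (A/C/G/U), `count`, `freq`.
#' @export
background_frequencies <- function(orfs) {
  if (nrow(orfs) == 0L) stop("empty ORF set")
  counts <- vapply(
    NUCS_DNA,
    function(n) sum(stringr::str_count(orfs$seq, stringr::fixed(n))),
    numeric(1)
  )
  tibble::tibble(
    nucleotide = NUCS_RNA,
    count = unname(counts),
    freq = unname(counts / sum(counts))
  )
}

## Decoding classification: each NNU/NNC codon pair shares a tRNA whose
## anticodon nt 34 is either G (G34) or, in eukaryotes, inosine (I34).
## I34 is assigned when the NNA codon of the same family codes for the same
## amino acid (inosine also wobble-pairs with A); Gly is a known eukaryote
## exception and is kept G34 even though GGA codes Gly. CGA is the single
## NNA codon decoded exclusively by an I34 anticodon.
build_codon_class_table <- function(mode = c("eukaryote", "prokaryote")) {
  mode <- match.arg(mode)
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)
  aa <- unname(gc)
  wobble <- substr(codons, 3, 3)
  first2 <- substr(codons, 1, 2)
  t34 <- rep("other", 64)
  t34[aa == "*"] <- "none"
  uc <- wobble %in% c("T", "C") & aa != "*"
  aa_of_a <- unname(gc[paste0(first2, "A")])
  i34 <- uc & aa_of_a == aa & first2 != "GG"
  t34[uc] <- "G34"
  t34[i34] <- "I34"
  i34_exclusive <- codons == "CGA"
  t34[codons == "CGA"] <- "I34"
  if (mode == "prokaryote") {
    t34[t34 == "I34"] <- "G34"
    i34_exclusive[] <- FALSE
  }
  tibble::tibble(
    codon = to_rna(codons),
    codon_dna = codons,
    amino_acid = ifelse(aa == "*", "STOP", aa),
    wobble = to_rna(wobble),
    t34 = t34,
    i34_exclusive = i34_exclusive
  )
}

#' Full 64-codon decoding classification table
#'
#' @param mode `"eukaryote"` (default; I34 anticodons assigned per the
#'   inosine wobble rule) or `"prokaryote"` (all I34 entries relabelled G34).
#' @return Tibble with columns `codon` (RNA), `codon_dna`, `amino_acid`,
#'   `wobble`, `t34` (G34/I34/other/none), `i34_exclusive`.
#' @export
codon_class_table <- function(mode = c("eukaryote", "prokaryote")) {
  build_codon_class_table(match.arg(mode))
}

#' Classify codons by wobble nucleotide and anticodon nt-34 identity
#'
#' @param codon Character vector of 3-mers (T or U alphabet).
#' @param mode See [codon_class_table()].
#' @return Tibble, one row per input codon, columns as in
#'   [codon_class_table()].
#' @export
classify_codon <- function(codon, mode = c("eukaryote", "prokaryote")) {
  key <- to_dna(codon)
  if (any(nchar(key) != 3L | grepl("[^ACGT]", key))) {
    stop("invalid codon(s): ", paste(codon[nchar(key) != 3L | grepl("[^ACGT]", key)], collapse = ", "))
  }
  tab <- codon_class_table(mode)
  tab[match(key, tab$codon_dna), ]
}

#' Position weight matrix of codon nucleotide preferences
#'
#' For a selected set of codon instances, computes per-position observed
#' nucleotide frequencies and weights them against the background
#' frequencies of the whole ORF set:
#' `weight = log2(f_observed / f_expected)`. When an observed or expected
#' frequency is zero the weight is reported as `NaN` and excluded from
#' comparisons; no pseudocounts are added.
#'
#' @param orfs An [orf_set].
#' @param selector `NULL` (all codons) or a function taking the
#'   [orf_codons()] instance table and returning a logical inclusion vector.
#' @param description Label stored with the result.
#' @return An object of class `codon_pwm`: list with `weights` and `f_obs`
#'   (3 x 4 matrices, positions x A/C/G/U), `f_exp` (named length-4 vector),
#'   `n_codons`, `selector_description`. Use [generics::tidy()] for a long
#'   tibble.
#' @export
codon_pwm <- function(orfs, selector = NULL, description = "all codons") {
  inst <- orf_codons(orfs)
  keep <- if (is.null(selector)) rep(TRUE, nrow(inst)) else selector(inst)
  stopifnot(is.logical(keep), length(keep) == nrow(inst))
  keep[is.na(keep)] <- FALSE
  sel <- inst$codon[keep]
  if (length(sel) == 0L) stop("selector matched zero codons")
  f_obs <- t(vapply(1:3, function(p) {
    tab <- table(factor(substr(sel, p, p), levels = NUCS_DNA))
    as.numeric(tab) / length(sel)
  }, numeric(4)))
  dimnames(f_obs) <- list(position = 1:3, nucleotide = NUCS_RNA)
  bg <- background_frequencies(orfs)
  f_exp <- stats::setNames(bg$freq, bg$nucleotide)
  w <- log2(sweep(f_obs, 2, f_exp, "/"))
  w[f_obs == 0 | rep(f_exp == 0, each = 3)] <- NaN
  structure(
    list(
      weights = w, f_obs = f_obs, f_exp = f_exp,
      n_codons = length(sel), selector_description = description
    ),
    class = "codon_pwm"
  )
}

#' @export
print.codon_pwm <- function(x, ...) {
  cat("<codon_pwm> ", x$selector_description, " (n = ", x$n_codons, " codons)\n", sep = "")
  cat("log2(f_obs/f_exp) weights:\n")
  print(round(x$weights, 3))
  invisible(x)
}

#' @rdname codon_pwm
#' @param x A `codon_pwm`.
#' @param ... Unused.
#' @export
tidy.codon_pwm <- function(x, ...) {
  tibble::tibble(
    position = rep(1:3, each = 4),
    nucleotide = rep(NUCS_RNA, 3),
    f_obs = as.vector(t(x$f_obs)),
    f_exp = rep(unname(x$f_exp), 3),
    weight = as.vector(t(x$weights))
  )
}

#' @rdname codon_pwm
#' @export
glance.codon_pwm <- function(x, ...) {
  tibble::tibble(
    n_codons = x$n_codons,
    selector_description = x$selector_description
  )
}

#' PWM of codons 3'-adjacent to a reference codon class
#'
#' Conditional position weight matrix over codons whose 5' neighbour (the
#' codon at index i-1 in the same ORF) matches a reference class, e.g. the
#' +1 codons following NNU. Context never crosses ORF boundaries.
#'
#' @param orfs An [orf_set].
#' @param reference_class A 3-letter N-wildcard pattern (e.g. `"NNU"`) or a
#'   predicate function over codon 3-mers.
#' @return A `codon_pwm`.
#' @export
adjacency_pwm <- function(orfs, reference_class = "NNU") {
  pred <- if (is.function(reference_class)) {
    reference_class
  } else {
    function(x) codon_matches(x, reference_class)
  }
  desc <- if (is.function(reference_class)) {
    "codons 3'-adjacent to reference class"
  } else {
    paste0("codons 3'-adjacent to ", to_rna(reference_class))
  }
  sel <- function(inst) !is.na(inst$prev_codon) & pred(inst$prev_codon)
  codon_pwm(orfs, sel, description = desc)
}

## n_genes x n_boot matrix of resampling multiplicities: drawing n genes
## uniformly with replacement is exactly multinomial(n, 1/n).
boot_multiplicities <- function(n_genes, n_boot) {
  stats::rmultinom(n_boot, n_genes, rep(1 / n_genes, n_genes))
}

## Small-sample-safe two-tailed bootstrap p:
## 2 * min[(1 + #{boot <= ref})/(B+1), (1 + #{boot >= ref})/(B+1)], capped at 1.
p_two_tailed <- function(boot, ref) {
  boot <- boot[is.finite(boot)]
  B <- length(boot)
  if (B == 0L) return(1)
  p <- 2 * min(
    (1 + sum(boot <= ref)) / (B + 1),
    (1 + sum(boot >= ref)) / (B + 1)
  )
  min(p, 1)
}

new_codon_bootstrap <- function(statistic, observed, boot, p, n_boot, seed,
                                method, conf_level, degenerate = FALSE) {
  boot <- boot[is.finite(boot)]
  a <- (1 - conf_level) / 2
  structure(
    list(
      statistic = statistic,
      observed = observed,
      boot_mean = if (length(boot)) mean(boot) else NA_real_,
      boot_sd = if (length(boot) > 1) stats::sd(boot) else NA_real_,
      conf_level = conf_level,
      lower = if (length(boot)) unname(stats::quantile(boot, a)) else NA_real_,
      upper = if (length(boot)) unname(stats::quantile(boot, 1 - a)) else NA_real_,
      p_two_tailed = p,
      n_boot = n_boot,
      seed = seed,
      method = method,
      degenerate = degenerate
    ),
    class = "codon_bootstrap"
  )
}

#' @export
print.codon_bootstrap <- function(x, ...) {
  cat("<codon_bootstrap> ", x$statistic, "\n", sep = "")
  cat(sprintf(
    "  observed = %.4g, boot mean = %.4g (sd %.4g), p (two-tailed) = %.4g\n",
    x$observed, x$boot_mean, x$boot_sd, x$p_two_tailed
  ))
  cat(sprintf(
    "  n_boot = %d, seed = %d, method = %s%s\n",
    x$n_boot, x$seed, x$method, if (x$degenerate) " [degenerate input]" else ""
  ))
  invisible(x)
}

#' @rdname g1_weight_bootstrap
#' @param x A `codon_bootstrap`.
#' @param ... Unused.
#' @export
tidy.codon_bootstrap <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic,
    observed = x$observed,
    boot_mean = x$boot_mean,
    boot_sd = x$boot_sd,
    conf_level = x$conf_level,
    lower = x$lower,
    upper = x$upper,
    p_two_tailed = x$p_two_tailed,
    n_boot = x$n_boot,
    seed = x$seed,
    method = x$method,
    degenerate = x$degenerate
  )
}

#' @rdname g1_weight_bootstrap
#' @export
glance.codon_bootstrap <- function(x, ...) tidy(x)

## Per-gene sufficient statistics for G1-weight bootstraps: nucleotide
## counts, position-1 codon nucleotide counts, and the same restricted to
## codons following the reference class.
g1_gene_stats <- function(orfs, reference_class) {
  pred <- if (is.function(reference_class)) {
    reference_class
  } else {
    function(x) codon_matches(x, reference_class)
  }
  inst <- orf_codons(orfs)
  after <- !is.na(inst$prev_codon) & pred(inst$prev_codon)
  p1 <- substr(inst$codon, 1, 1)
  gene <- factor(inst$gene_id, levels = orfs$gene_id)
  nt_g <- vapply(
    NUCS_DNA,
    function(n) stringr::str_count(orfs$seq, stringr::fixed(n)),
    numeric(nrow(orfs))
  )
  if (is.null(dim(nt_g))) {
    nt_g <- matrix(nt_g, nrow = 1, dimnames = list(NULL, NUCS_DNA))
  }
  list(
    nt_g = nt_g,
    g1 = as.numeric(tapply(p1 == "G", gene, sum, default = 0)),
    tot = as.numeric(tapply(rep(1, nrow(inst)), gene, sum, default = 0)),
    g1_after = as.numeric(tapply((p1 == "G") & after, gene, sum, default = 0)),
    tot_after = as.numeric(tapply(after, gene, sum, default = 0))
  )
}

g1_weight <- function(num, den, g_nt, tot_nt) {
  log2((num / den) / (g_nt / tot_nt))
}

#' Gene-bootstrap test of the conditional G1 weight
#'
#' Tests whether the position-1 G weight of codons following a reference
#' class (e.g. NNU) differs from the unconditional position-1 G weight of
#' all codons, resampling genes with replacement and recomputing pooled
#' weights (gene multiplicity honoured).
#'
#' Two methods are available. `"difference"` (default) bootstraps the
#' difference between the conditional and unconditional G1 weights and
#' locates 0 two-tailed in that distribution - a calibrated percentile-CI
#' inversion. `"threshold"` locates the observed conditional weight in the
#' bootstrap distribution of the unconditional weight; it ignores the
#' sampling variance of the conditional weight (computed from the smaller
#' codon subset) and is anti-conservative under the null - it is provided
#' for comparability and is not the default. See the package vignette.
#'
#' @param orfs An [orf_set].
#' @param reference_class Pattern or predicate, as in [adjacency_pwm()].
#' @param n_boot Number of gene resamples (>= 100).
#' @param seed Integer seed; the result is reproducible given the seed.
#' @param method `"difference"` or `"threshold"`.
#' @param conf_level Level for the two-tailed bootstrap quantile thresholds.
#' @return A `codon_bootstrap` object.
#' @export
g1_weight_bootstrap <- function(orfs, reference_class = "NNU", n_boot = 1000,
                                seed = 1L,
                                method = c("difference", "threshold"),
                                conf_level = 0.99) {
  method <- match.arg(method)
  stopifnot(n_boot >= 100)
  st <- g1_gene_stats(orfs, reference_class)
  g_nt <- sum(st$nt_g[, "G"])
  tot_nt <- sum(st$nt_g)
  obs_cond <- g1_weight(sum(st$g1_after), sum(st$tot_after), g_nt, tot_nt)
  obs_unc <- g1_weight(sum(st$g1), sum(st$tot), g_nt, tot_nt)
  stat_name <- "G1 weight, conditional vs unconditional"
  n <- nrow(orfs)
  if (n < 2L) {
    warning("degenerate ORF set (< 2 genes): p set to 1")
    return(new_codon_bootstrap(
      stat_name, if (method == "difference") obs_cond - obs_unc else obs_cond,
      numeric(0), 1, n_boot, seed, method, conf_level,
      degenerate = TRUE
    ))
  }
  withr::local_seed(seed)
  W <- boot_multiplicities(n, n_boot)
  sums <- crossprod(W, cbind(
    g_nt = st$nt_g[, "G"], tot_nt = rowSums(st$nt_g),
    g1 = st$g1, tot = st$tot,
    g1_after = st$g1_after, tot_after = st$tot_after
  ))
  boot_unc <- g1_weight(sums[, "g1"], sums[, "tot"], sums[, "g_nt"], sums[, "tot_nt"])
  if (method == "threshold") {
    p <- p_two_tailed(boot_unc, obs_cond)
    new_codon_bootstrap(stat_name, obs_cond, boot_unc, p, n_boot, seed, method, conf_level)
  } else {
    boot_cond <- g1_weight(
      sums[, "g1_after"], sums[, "tot_after"],
      sums[, "g_nt"], sums[, "tot_nt"]
    )
    d <- boot_cond - boot_unc
    p <- p_two_tailed(d, 0)
    new_codon_bootstrap(stat_name, obs_cond - obs_unc, d, p, n_boot, seed, method, conf_level)
  }
}

#' Gene-bootstrap test of NNU versus NNC codon abundance
#'
#' Statistic: (count of NNU codons - count of NNC codons) / total codons,
#' pooled over genes. Genes are resampled with replacement and the pooled
#' statistic recomputed; the two-tailed p locates 0 in the bootstrap
#' distribution.
#'
#' @inheritParams g1_weight_bootstrap
#' @return A `codon_bootstrap` object.
#' @export
nnu_nnc_abundance_test <- function(orfs, n_boot = 1000, seed = 1L,
                                   conf_level = 0.99) {
  stopifnot(n_boot >= 100)
  inst <- orf_codons(orfs)
  gene <- factor(inst$gene_id, levels = orfs$gene_id)
  nnu <- as.numeric(tapply(codon_matches(inst$codon, "NNU"), gene, sum, default = 0))
  nnc <- as.numeric(tapply(codon_matches(inst$codon, "NNC"), gene, sum, default = 0))
  tot <- as.numeric(tapply(rep(1, nrow(inst)), gene, sum, default = 0))
  obs <- (sum(nnu) - sum(nnc)) / sum(tot)
  stat_name <- "(NNU - NNC) / total codons"
  n <- nrow(orfs)
  if (n < 2L) {
    warning("degenerate ORF set (< 2 genes): p set to 1")
    return(new_codon_bootstrap(
      stat_name, obs, numeric(0), 1, n_boot, seed,
      "difference", conf_level,
      degenerate = TRUE
    ))
  }
  withr::local_seed(seed)
  W <- boot_multiplicities(n, n_boot)
  sums <- crossprod(W, cbind(nnu = nnu, nnc = nnc, tot = tot))
  boot <- (sums[, "nnu"] - sums[, "nnc"]) / sums[, "tot"]
  p <- p_two_tailed(boot, 0)
  new_codon_bootstrap(stat_name, obs, boot, p, n_boot, seed, "difference", conf_level)
}

#' Split an ORF set by expression into top and bottom fractions
#'
#' Genes with expression values are ranked by value; the top and bottom
#' `ceiling(fraction * n)` genes are returned as ORF sets (ties broken by
#' lexicographic gene_id). Expression entries for genes absent from the ORF
#' set are ignored with a warning.
#'
#' @param orfs An [orf_set].
#' @param expr Tibble with columns `gene_id`, `value`
#'   (see [read_expression_table()]).
#' @param fraction Fraction in (0, 0.5].
#' @return List with elements `top` and `bottom`, each an [orf_set] in the
#'   original ORF-set order.
#' @export
stratify_by_expression <- function(orfs, expr, fraction = 0.1) {
  stopifnot(fraction > 0, fraction <= 0.5)
  missing <- setdiff(expr$gene_id, orfs$gene_id)
  if (length(missing) > 0) {
    warning(length(missing), " expression gene(s) absent from the ORF set; ignored")
  }
  common <- expr[expr$gene_id %in% orfs$gene_id, ]
  if (nrow(common) == 0L) stop("no overlap between expression table and ORF set")
  k <- ceiling(fraction * nrow(common))
  ord_desc <- order(-common$value, common$gene_id)
  ord_asc <- order(common$value, common$gene_id)
  top_ids <- common$gene_id[ord_desc][seq_len(k)]
  bot_ids <- common$gene_id[ord_asc][seq_len(k)]
  subset_orfs <- function(ids) {
    out <- orfs[orfs$gene_id %in% ids, ]
    class(out) <- c("orf_set", setdiff(class(out), "orf_set"))
    out
  }
  list(top = subset_orfs(top_ids), bottom = subset_orfs(bot_ids))
}
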