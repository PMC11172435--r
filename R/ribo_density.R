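#' Read lengths belonging to each footprint class
#'
#' The 28-nt class covers 27-30 nt footprints (ribosomes with A- and P-site
#' tRNAs); the 21-nt class covers 20-22 nt footprints (pre-accommodation
#' ribosomes). Other lengths are retained in count tables but ignored by
#' the default analyses.
#'
#' @param rfp_class `"28nt"` or `"21nt"`.
#' @return Integer vector of read lengths.
#' @export
rfp_class_lengths <- function(rfp_class = c("28nt", "21nt")) {
  switch(match.arg(rfp_class), "28nt" = 27:30, "21nt" = 20:22)
}

#' Default A-site offset table
#'
#' Used when calibration is not run: every analyzed read length maps to a
#' 15-nt offset from the footprint 5' end to the first nucleotide of the
#' A-site codon (the canonical yeast value). Prefer [calibrate_offsets()]
#' when start-proximal signal is available.
#'
#' @param rfp_class `"28nt"` or `"21nt"`.
#' @param offset Offset in nt, applied to every length of the class.
#' @return Tibble with columns `read_length`, `offset`.
#' @export
default_offsets <- function(rfp_class = c("28nt", "21nt"), offset = 15L) {
  stopifnot(offset >= 10, offset <= 20)
  tibble::tibble(
    read_length = rfp_class_lengths(rfp_class),
    offset = as.integer(offset)
  )
}

#' Calibrate A-site offsets from start-codon metagene signal
#'
#' For each read length of the class, candidate offsets are scored by the
#' number of reads whose shifted position (`pos5 + offset`) lands on the
#' first nucleotide of codons 1-5 (frame 0), i.e. the early-elongation A
#' sites downstream of the start codon. This pins the offset's frame; under
#' uniform elongation coverage, candidates one codon apart score alike, so
#' among near-maximal candidates the one most consistent with the 5'-most
#' observed read end (whose A site sits at the start of the ORF) is chosen.
#' When a length has fewer than `min_reads` reads supporting the chosen
#' candidate, the default 15-nt offset is used with a warning.
#'
#' @param counts A `footprint_counts` tibble.
#' @param orfs An [orf_set] (restricts to known genes).
#' @param rfp_class `"28nt"` or `"21nt"`.
#' @param candidates Candidate offsets (nt).
#' @param min_reads Minimum supporting reads for a calibrated offset.
#' @return Tibble with columns `read_length`, `offset`, `support`
#'   (reads at the chosen offset), `calibrated` (FALSE where the default
#'   was used).
#' @export
calibrate_offsets <- function(counts, orfs, rfp_class = c("28nt", "21nt"),
                              candidates = 10:20, min_reads = 50L) {
  rfp_class <- match.arg(rfp_class)
  lens <- rfp_class_lengths(rfp_class)
  cc <- counts[counts$read_length %in% lens & counts$gene_id %in% orfs$gene_id, ]
  if (nrow(cc) == 0L) stop("no footprints of class ", rfp_class, " for calibration")
  targets <- 3L * (1:5)
  purrr::map_dfr(lens, function(len) {
    cl <- cc[cc$read_length == len, ]
    score <- vapply(
      candidates,
      function(o) sum(cl$count[(cl$pos5 + o) %in% targets]),
      numeric(1)
    )
    best <- which.max(score)
    if (nrow(cl) > 0L && score[best] > 0) {
      near <- which(score >= 0.5 * score[best])
      boundary <- -min(cl$pos5)
      best <- near[which.min(abs(candidates[near] - boundary))]
    }
    if (nrow(cl) == 0L || score[best] < min_reads) {
      warning(
        "insufficient start-proximal signal for read length ", len,
        "; using default offset 15"
      )
      tibble::tibble(
        read_length = len, offset = 15L,
        support = if (nrow(cl)) score[best] else 0, calibrated = FALSE
      )
    } else {
      tibble::tibble(
        read_length = len, offset = as.integer(candidates[best]),
        support = score[best], calibrated = TRUE
      )
    }
  })
}

#' Filter genes by ORF length and footprint density
#'
#' Retains genes whose ORF is strictly longer than `min_len_nt` and whose
#' raw footprint total for the class, divided by ORF length, is strictly
#' above `min_density` (the defaults reproduce "ORFs > 198 nt" and "above
#' 1 footprint per 10 nt"). The density filter uses raw class totals before
#' any offsetting.
#'
#' @param counts A `footprint_counts` tibble.
#' @param orfs An [orf_set].
#' @param rfp_class `"28nt"` or `"21nt"`.
#' @param min_len_nt Minimum ORF length (exclusive), nt.
#' @param min_density Minimum footprints per nt (exclusive).
#' @return Tibble with one row per ORF-set gene: `gene_id`, `orf_length`,
#'   `n_footprints`, `density`, `pass_length`, `pass_density`, `retained`;
#'   attribute `"summary"` holds `n_input`, `n_pass_length`,
#'   `n_pass_density`.
#' @export
filter_genes <- function(counts, orfs, rfp_class = c("28nt", "21nt"),
                         min_len_nt = 198, min_density = 0.1) {
  rfp_class <- match.arg(rfp_class)
  lens <- rfp_class_lengths(rfp_class)
  totals <- counts[counts$read_length %in% lens, ] %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::summarise(n_footprints = sum(.data$count), .groups = "drop")
  rep <- tibble::tibble(gene_id = orfs$gene_id, orf_length = nchar(orfs$seq)) %>%
    dplyr::left_join(totals, by = "gene_id") %>%
    dplyr::mutate(
      n_footprints = dplyr::coalesce(.data$n_footprints, 0L),
      density = .data$n_footprints / .data$orf_length,
      pass_length = .data$orf_length > min_len_nt,
      pass_density = .data$pass_length & .data$density > min_density,
      retained = .data$pass_density
    )
  attr(rep, "summary") <- list(
    n_input = nrow(rep),
    n_pass_length = sum(rep$pass_length),
    n_pass_density = sum(rep$pass_density),
    rfp_class = rfp_class
  )
  rep
}

#' Raw per-codon ribosome densities from footprint counts
#'
#' Each read contributes its count at the A-site nucleotide position
#' `pos5 + offset(read_length)`. The dataset-wide major frame m is the
#' frame (0/1/2) with the largest total shifted count; codon i's density is
#' the sum of shifted counts at nucleotides 3i+m-1, 3i+m and 3i+m+1 (the
#' major peak plus the two adjacent minor peaks), so every interior
#' position contributes to exactly one codon. The first codon uses only
#' positions >= 0 and the last only positions inside the ORF.
#'
#' @param counts A `footprint_counts` tibble.
#' @param orfs An [orf_set].
#' @param offsets Offset table with columns `read_length`, `offset`
#'   (see [default_offsets()] / [calibrate_offsets()]); must cover every
#'   read length of the class present in `counts`.
#' @param rfp_class `"28nt"` or `"21nt"`.
#' @param genes Optional character vector restricting output genes
#'   (e.g. the retained set from [filter_genes()]); default all ORF genes.
#' @return Tibble of class `codon_density` with one row per (gene, codon):
#'   `gene_id`, `codon_index`, `density` (raw summed counts); attributes
#'   `"major_frame"` and `"rfp_class"`.
#' @export
codon_densities <- function(counts, orfs, offsets = default_offsets(rfp_class),
                            rfp_class = c("28nt", "21nt"), genes = NULL) {
  rfp_class <- match.arg(rfp_class)
  lens <- rfp_class_lengths(rfp_class)
  if (is.null(genes)) genes <- orfs$gene_id
  orfs_use <- orfs[orfs$gene_id %in% genes, ]
  cc <- counts[counts$read_length %in% lens & counts$gene_id %in% orfs_use$gene_id, ]
  missing_len <- setdiff(unique(cc$read_length), offsets$read_length)
  if (length(missing_len) > 0) {
    stop("read length(s) missing from offset table: ", paste(missing_len, collapse = ", "))
  }
  off <- offsets$offset[match(cc$read_length, offsets$read_length)]
  p <- cc$pos5 + off
  orf_len <- nchar(orfs_use$seq)[match(cc$gene_id, orfs_use$gene_id)]
  inside <- p >= 0L & p < orf_len
  p <- p[inside]
  gene <- cc$gene_id[inside]
  cnt <- cc$count[inside]
  orf_len <- orf_len[inside]
  frame_tot <- vapply(0:2, function(f) sum(cnt[p %% 3L == f]), numeric(1))
  m <- if (length(cnt) > 0) which.max(frame_tot) - 1L else 0L
  idx <- (p - m + 1L) %/% 3L
  k <- orf_len %/% 3L
  ok <- idx >= 0L & idx < k
  k_gene <- nchar(orfs_use$seq) %/% 3L
  max_k <- max(k_gene, 1L)
  gi <- match(gene[ok], orfs_use$gene_id)
  key <- (gi - 1) * max_k + idx[ok]
  dens <- numeric(sum(k_gene))
  offset0 <- c(0L, cumsum(k_gene))[seq_along(k_gene)]
  if (length(key)) {
    agg <- rowsum(as.numeric(cnt[ok]), key)
    akey <- as.numeric(rownames(agg))
    a_gi <- akey %/% max_k + 1
    a_idx <- akey %% max_k
    dens[offset0[a_gi] + a_idx + 1] <- agg[, 1]
  }
  out <- tibble::tibble(
    gene_id = rep(orfs_use$gene_id, k_gene),
    codon_index = sequence(k_gene) - 1L,
    density = dens
  )
  class(out) <- c("codon_density", class(out))
  attr(out, "major_frame") <- m
  attr(out, "rfp_class") <- rfp_class
  out
}

#' Normalize per-codon densities to each gene's mean
#'
#' Divides every gene's density vector by its own mean so that the per-gene
#' mean normalized density is exactly 1, making codon instances comparable
#' across genes of different coverage. A gene with zero total density is an
#' error (the density filter should have removed it).
#'
#' @param dens A `codon_density` tibble (raw densities).
#' @return A `codon_density` tibble with `density` normalized and an added
#'   `raw_total` column (per-gene raw totals retained).
#' @export
normalize_densities <- function(dens) {
  out <- dens %>%
    dplyr::group_by(.data$gene_id) %>%
    dplyr::mutate(
      raw_total = sum(.data$density),
      density = .data$density / (.data$raw_total / dplyr::n())
    ) %>%
    dplyr::ungroup()
  if (any(!is.finite(out$density))) {
    bad <- unique(out$gene_id[!is.finite(out$density)])
    stop(
      "zero-total gene(s) reached normalization: ",
      paste(utils::head(bad, 5), collapse = ", ")
    )
  }
  for (a in c("major_frame", "rfp_class")) attr(out, a) <- attr(dens, a)
  class(out) <- unique(c("codon_density", class(out)))
  out
}

#' Annotate codon instances with their A-site and +1 codon context
#'
#' Produces one row per sense A-site codon that has a defined +1 codon
#' within the same ORF. `gnn_flag` marks instances whose +1 codon starts
#' with G; `stop_next` marks instances whose +1 codon is a stop codon
#' (retained in the without-GNN group by default, or dropped with
#' `stop_next_action = "drop"`). Stop codons never appear as A-site rows.
#' `exclude_edge` trims that many codons from each ORF end (the pipeline
#' default is 1, removing initiation/termination pile-up positions).
#'
#' @param dens A normalized `codon_density` tibble.
#' @param orfs An [orf_set].
#' @param exclude_edge Codons trimmed from each ORF end.
#' @param stop_next_action `"without"` (keep, flagged, in the without-GNN
#'   group) or `"drop"`.
#' @return Tibble with columns `gene_id`, `codon_index`, `asite_codon`,
#'   `plus1_codon` (RNA alphabet), `gnn_flag`, `stop_next`, `density`.
#' @export
annotate_contexts <- function(dens, orfs, exclude_edge = 0L,
                              stop_next_action = c("without", "drop")) {
  stop_next_action <- match.arg(stop_next_action)
  inst <- orf_codons(orfs[orfs$gene_id %in% unique(dens$gene_id), ])
  bad <- dens %>%
    dplyr::count(.data$gene_id, name = "n_dens") %>%
    dplyr::left_join(dplyr::count(inst, .data$gene_id, name = "n_orf"), by = "gene_id") %>%
    dplyr::filter(is.na(.data$n_orf) | .data$n_dens != .data$n_orf)
  if (nrow(bad) > 0) {
    stop(
      "density vector length does not match ORF codons for: ",
      paste(utils::head(bad$gene_id, 5), collapse = ", ")
    )
  }
  stops <- c("TAA", "TAG", "TGA")
  out <- inst %>%
    dplyr::inner_join(dens, by = c("gene_id", "codon_index")) %>%
    dplyr::filter(
      !(.data$codon %in% stops),
      !is.na(.data$next_codon),
      .data$codon_index >= exclude_edge,
      .data$codon_index < .data$n_codons - exclude_edge
    ) %>%
    dplyr::mutate(
      stop_next = .data$next_codon %in% stops,
      gnn_flag = substr(.data$next_codon, 1, 1) == "G" & !.data$stop_next,
      asite_codon = to_rna(.data$codon),
      plus1_codon = to_rna(.data$next_codon)
    )
  if (stop_next_action == "drop") out <- dplyr::filter(out, !.data$stop_next)
  dplyr::select(
    out, "gene_id", "codon_index", "asite_codon", "plus1_codon",
    "gnn_flag", "stop_next", "density"
  )
}

#' Compare A-site codon densities with versus without a +1 GNN codon
#'
#' For each A-site codon type, pools normalized densities over codon
#' instances (each instance weight 1) and compares the mean density of
#' instances followed by +1 GNN with the mean of those not followed by GNN.
#' Inference resamples genes with replacement (`n_boot` times, multiplicity
#' honoured). With `method = "difference"` (default) the with-minus-without
#' mean difference is recomputed per resample and the two-tailed p locates
#' 0 in that distribution; `method = "without_null"` locates the observed
#' with-GNN mean in the bootstrap distribution of the without-GNN mean
#' (anti-conservative; see the vignette). Types with fewer than 2 genes
#' contributing both groups get p = 1 and `degenerate = TRUE`.
#'
#' @param instances Output of [annotate_contexts()].
#' @param codon_types Character vector of A-site codon types (RNA or DNA
#'   alphabet), default all types present.
#' @param rfp_class Label recorded in the output.
#' @param n_boot Number of gene resamples.
#' @param seed Integer seed (one RNG stream per call).
#' @param method `"difference"` or `"without_null"`.
#' @return Tibble of class `context_comparison`, one row per codon type:
#'   `asite_codon`, `label2` (first two nucleotides), `rfp_class`,
#'   `n_with`, `n_without`, `mean_with`, `mean_without`, `ratio`,
#'   `percent_elevation`, `p_two_tailed`, `n_boot`, `seed`, `method`,
#'   `degenerate`.
#' @export
context_comparison <- function(instances, codon_types = NULL,
                               rfp_class = "28nt", n_boot = 10000, seed = 1L,
                               method = c("difference", "without_null")) {
  method <- match.arg(method)
  if (is.null(codon_types)) {
    codon_types <- sort(unique(instances$asite_codon))
  }
  codon_types <- to_rna(to_dna(codon_types))
  withr::local_seed(seed)
  per_gene_all <- instances %>%
    dplyr::filter(.data$asite_codon %in% codon_types) %>%
    dplyr::group_by(.data$asite_codon, .data$gene_id) %>%
    dplyr::summarise(
      n_w = sum(.data$gnn_flag),
      s_w = sum(.data$density[.data$gnn_flag]),
      n_wo = sum(!.data$gnn_flag),
      s_wo = sum(.data$density[!.data$gnn_flag]),
      .groups = "drop"
    )
  rows <- purrr::map_dfr(codon_types, function(ct) {
    pg <- per_gene_all[per_gene_all$asite_codon == ct, ]
    n_with <- sum(pg$n_w)
    n_without <- sum(pg$n_wo)
    mean_with <- if (n_with > 0) sum(pg$s_w) / n_with else NA_real_
    mean_without <- if (n_without > 0) sum(pg$s_wo) / n_without else NA_real_
    ratio <- if (!is.na(mean_without) && mean_without > 0) mean_with / mean_without else NA_real_
    base <- tibble::tibble(
      asite_codon = ct,
      label2 = substr(ct, 1, 2),
      rfp_class = rfp_class,
      n_with = n_with, n_without = n_without,
      mean_with = mean_with, mean_without = mean_without,
      ratio = ratio,
      percent_elevation = 100 * (ratio - 1),
      p_two_tailed = 1,
      n_boot = n_boot, seed = seed, method = method,
      degenerate = TRUE
    )
    n_both <- sum(pg$n_w > 0 & pg$n_wo > 0)
    if (n_both < 2L || nrow(pg) < 2L || is.na(ratio)) {
      return(base)
    }
    W <- boot_multiplicities(nrow(pg), n_boot)
    sums <- crossprod(W, cbind(n_w = pg$n_w, s_w = pg$s_w, n_wo = pg$n_wo, s_wo = pg$s_wo))
    m_wo <- ifelse(sums[, "n_wo"] > 0, sums[, "s_wo"] / sums[, "n_wo"], NA_real_)
    if (method == "without_null") {
      p <- p_two_tailed(m_wo, mean_with)
    } else {
      m_w <- ifelse(sums[, "n_w"] > 0, sums[, "s_w"] / sums[, "n_w"], NA_real_)
      p <- p_two_tailed(m_w - m_wo, 0)
    }
    base$p_two_tailed <- p
    base$degenerate <- FALSE
    base
  })
  if (nrow(rows) == 0L) {
    rows <- tibble::tibble(
      asite_codon = character(), label2 = character(), rfp_class = character(),
      n_with = integer(), n_without = integer(),
      mean_with = numeric(), mean_without = numeric(), ratio = numeric(),
      percent_elevation = numeric(), p_two_tailed = numeric(),
      n_boot = numeric(), seed = integer(), method = character(),
      degenerate = logical()
    )
  }
  class(rows) <- c("context_comparison", class(rows))
  rows
}

#' Summarize +1 GNN density elevation by codon class
#'
#' Groups per-codon-type comparisons into {NNU(G34), NNU(I34), NNC, NNA,
#' NNG} using the decoding classification, summarizes the distribution of
#' percent elevation per group and footprint class, and, where both the
#' 21-nt and 28-nt classes are present, compares them per group with a
#' two-tailed Welch t-test.
#'
#' @param comparisons A `context_comparison` tibble, typically covering
#'   both footprint classes.
#' @param min_types Minimum codon types per (group, class); fewer is an
#'   error.
#' @return List of class `rfp_class_summary` with tibbles `groups`
#'   (per group x class: n_types, mean, sd, quartiles of percent
#'   elevation) and `tests` (per group: t statistic, p for 21nt vs 28nt;
#'   empty when only one class is present).
#' @export
class_summary <- function(comparisons, min_types = 2L) {
  cls <- classify_codon(comparisons$asite_codon)
  grp <- dplyr::case_when(
    cls$wobble == "U" ~ paste0("NNU(", cls$t34, ")"),
    cls$wobble == "C" ~ "NNC",
    cls$wobble == "A" ~ "NNA",
    cls$wobble == "G" ~ "NNG"
  )
  dat <- comparisons %>%
    dplyr::mutate(group = grp) %>%
    dplyr::filter(!is.na(.data$percent_elevation))
  groups <- dat %>%
    dplyr::group_by(.data$group, .data$rfp_class) %>%
    dplyr::summarise(
      n_types = dplyr::n(),
      mean = mean(.data$percent_elevation),
      sd = stats::sd(.data$percent_elevation),
      q25 = unname(stats::quantile(.data$percent_elevation, 0.25)),
      median = stats::median(.data$percent_elevation),
      q75 = unname(stats::quantile(.data$percent_elevation, 0.75)),
      .groups = "drop"
    )
  if (any(groups$n_types < min_types)) {
    bad <- groups$group[groups$n_types < min_types]
    stop(
      "group(s) with fewer than ", min_types, " codon types: ",
      paste(unique(bad), collapse = ", ")
    )
  }
  classes <- unique(dat$rfp_class)
  tests <- if (length(classes) >= 2) {
    purrr::map_dfr(unique(dat$group), function(g) {
      x <- dat$percent_elevation[dat$group == g & dat$rfp_class == classes[1]]
      y <- dat$percent_elevation[dat$group == g & dat$rfp_class == classes[2]]
      if (length(x) < 2 || length(y) < 2) {
        return(tibble::tibble(
          group = g, class_a = classes[1], class_b = classes[2],
          t_statistic = NA_real_, df = NA_real_, p_value = NA_real_
        ))
      }
      tt <- stats::t.test(x, y)
      tibble::tibble(
        group = g, class_a = classes[1], class_b = classes[2],
        t_statistic = unname(tt$statistic), df = unname(tt$parameter),
        p_value = tt$p.value
      )
    })
  } else {
    tibble::tibble(
      group = character(), class_a = character(), class_b = character(),
      t_statistic = numeric(), df = numeric(), p_value = numeric()
    )
  }
  structure(list(groups = groups, tests = tests), class = "rfp_class_summary")
}

#' @export
print.rfp_class_summary <- function(x, ...) {
  cat("<rfp_class_summary>\n")
  print(x$groups)
  if (nrow(x$tests) > 0) {
    cat("Welch t-tests between footprint classes:\n")
    print(x$tests)
  }
  invisible(x)
}

#' @rdname class_summary
#' @param x An `rfp_class_summary`.
#' @param ... Unused.
#' @export
tidy.rfp_class_summary <- function(x, ...) x$groups

#' @rdname class_summary
#' @export
glance.rfp_class_summary <- function(x, ...) x$tests
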