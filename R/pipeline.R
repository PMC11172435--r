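#' Density pipeline for one footprint class
#'
#' Runs the footprint-to-comparison pipeline in memory: gene filtering,
#' A-site offsetting (default table or start-codon calibration), raw
#' per-codon densities with dataset-wide frame assignment, per-gene mean
#' normalization, +1 context annotation, and the per-codon-type gene
#' bootstrap comparison.
#'
#' @param orfs An [orf_set].
#' @param counts A `footprint_counts` tibble.
#' @param rfp_class `"28nt"` or `"21nt"`.
#' @param offsets `"default"`, `"auto"` (calibrate), or an offset tibble.
#' @param n_boot,seed,method Passed to [context_comparison()].
#' @param min_len_nt,min_density Passed to [filter_genes()].
#' @param exclude_edge,stop_next_action Passed to [annotate_contexts()].
#' @param codon_types Optional restriction of compared A-site codon types.
#' @return List of class `density_analysis`: `filter`, `offsets`,
#'   `densities` (normalized), `instances`, `comparisons`, `major_frame`,
#'   `rfp_class`.
#' @export
analyze_density <- function(orfs, counts, rfp_class = c("28nt", "21nt"),
                            offsets = "default", n_boot = 10000, seed = 1L,
                            method = c("difference", "without_null"),
                            min_len_nt = 198, min_density = 0.1,
                            exclude_edge = 1L,
                            stop_next_action = "without",
                            codon_types = NULL) {
  rfp_class <- match.arg(rfp_class)
  method <- match.arg(method)
  filt <- filter_genes(counts, orfs, rfp_class, min_len_nt, min_density)
  retained <- filt$gene_id[filt$retained]
  if (length(retained) == 0L) {
    stop("no genes pass the length/density filters for class ", rfp_class)
  }
  off <- if (is.data.frame(offsets)) {
    offsets
  } else if (identical(offsets, "auto")) {
    calibrate_offsets(counts, orfs, rfp_class)
  } else {
    default_offsets(rfp_class)
  }
  raw <- codon_densities(counts, orfs, off, rfp_class, genes = retained)
  norm <- normalize_densities(raw)
  inst <- annotate_contexts(norm, orfs, exclude_edge = exclude_edge,
                            stop_next_action = stop_next_action)
  comp <- context_comparison(inst, codon_types = codon_types,
                             rfp_class = rfp_class, n_boot = n_boot,
                             seed = seed, method = method)
  structure(
    list(
      filter = filt, offsets = off, densities = norm, instances = inst,
      comparisons = comp, major_frame = attr(raw, "major_frame"),
      rfp_class = rfp_class
    ),
    class = "density_analysis"
  )
}

#' @export
print.density_analysis <- function(x, ...) {
  s <- attr(x$filter, "summary")
  cat("<density_analysis> class ", x$rfp_class, "\n", sep = "")
  cat(sprintf(
    "  genes: %d input, %d pass length, %d retained; major frame %d\n",
    s$n_input, s$n_pass_length, s$n_pass_density, x$major_frame
  ))
  cat("  comparisons for", nrow(x$comparisons), "A-site codon types\n")
  invisible(x)
}

#' Run configuration for an end-to-end analysis
#'
#' @param fasta Path to the ORF FASTA.
#' @param counts Path to the footprint count TSV.
#' @param out_dir Output directory.
#' @param expression Optional path to an expression TSV.
#' @param rfp_classes Footprint classes to analyze.
#' @param n_boot Bootstrap resamples for all tests.
#' @param seed Integer seed.
#' @param offsets `"default"`, `"auto"`, or a path to an offset TSV.
#' @param min_len_nt,min_density,exclude_edge,stop_next_action,method
#'   Pipeline options, see [analyze_density()].
#' @param reference_class Reference codon class for the adjacency PWM and
#'   G1-weight bootstrap.
#' @return List of class `run_config`.
#' @export
run_config <- function(fasta, counts, out_dir,
                       expression = NULL,
                       rfp_classes = c("28nt", "21nt"),
                       n_boot = 1000, seed = 1L,
                       offsets = "default",
                       min_len_nt = 198, min_density = 0.1,
                       exclude_edge = 1L,
                       stop_next_action = "without",
                       method = "difference",
                       reference_class = "NNU") {
  structure(
    list(
      fasta = fasta, counts = counts, out_dir = out_dir,
      expression = expression, rfp_classes = rfp_classes,
      n_boot = n_boot, seed = as.integer(seed), offsets = offsets,
      min_len_nt = min_len_nt, min_density = min_density,
      exclude_edge = exclude_edge, stop_next_action = stop_next_action,
      method = method, reference_class = reference_class
    ),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full analysis end to end
#'
#' Reads the inputs, computes codon statistics (background frequencies,
#' unconditional and adjacency PWMs, G1-weight and NNU/NNC bootstraps),
#' runs the density pipeline for every requested footprint class, and
#' writes deterministic TSV outputs plus the resolved configuration
#' (`config.yaml`) and a checksum manifest (`manifest.json`) into the
#' output directory. Stage errors propagate with the stage name.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with the result objects and output paths.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  orfs <- stage("io", read_orf_fasta(config$fasta, quiet = TRUE))
  counts <- stage("io", read_footprint_table(config$counts))
  expr <- if (!is.null(config$expression)) {
    stage("io", read_expression_table(config$expression))
  }
  out <- function(f) file.path(config$out_dir, f)

  cs <- stage("codon_stats", {
    bg <- background_frequencies(orfs)
    pwm_all <- codon_pwm(orfs)
    pwm_adj <- adjacency_pwm(orfs, config$reference_class)
    g1 <- g1_weight_bootstrap(
      orfs, config$reference_class,
      n_boot = max(config$n_boot, 100), seed = config$seed + 11L,
      method = if (config$method == "without_null") "threshold" else "difference"
    )
    ab <- nnu_nnc_abundance_test(
      orfs,
      n_boot = max(config$n_boot, 100),
      seed = config$seed + 12L
    )
    list(bg = bg, pwm_all = pwm_all, pwm_adj = pwm_adj, g1 = g1, abundance = ab)
  })
  write_tsv_report(cs$bg, out("background_frequencies.tsv"))
  write_tsv_report(cs$pwm_all, out("pwm_all.tsv"))
  write_tsv_report(cs$pwm_adj, out("pwm_adjacent.tsv"))
  write_tsv_report(
    dplyr::bind_rows(generics::tidy(cs$g1), generics::tidy(cs$abundance)),
    out("bootstrap.tsv")
  )

  analyses <- list()
  for (cl in config$rfp_classes) {
    an <- stage(paste0("density_", cl), analyze_density(
      orfs, counts, cl,
      offsets = if (is.character(config$offsets) &&
                    !config$offsets %in% c("default", "auto")) {
        readr::read_tsv(config$offsets, show_col_types = FALSE, progress = FALSE)
      } else {
        config$offsets
      },
      n_boot = config$n_boot, seed = config$seed,
      method = config$method,
      min_len_nt = config$min_len_nt, min_density = config$min_density,
      exclude_edge = config$exclude_edge,
      stop_next_action = config$stop_next_action
    ))
    analyses[[cl]] <- an
    write_tsv_report(an$filter, out(paste0("gene_filter_", cl, ".tsv")))
    write_tsv_report(an$offsets, out(paste0("offsets_", cl, ".tsv")))
    write_tsv_report(an$densities, out(paste0("densities_", cl, ".tsv")))
    write_tsv_report(an$instances, out(paste0("contexts_", cl, ".tsv")))
    s <- attr(an$filter, "summary")
    message(sprintf(
      "[%s] genes: %d input, %d pass length, %d retained; major frame %d",
      cl, s$n_input, s$n_pass_length, s$n_pass_density, an$major_frame
    ))
  }
  comparisons <- dplyr::bind_rows(lapply(analyses, function(a) a$comparisons))
  write_tsv_report(comparisons, out("comparisons.tsv"))

  summ <- stage("class_summary", tryCatch(
    class_summary(comparisons),
    error = function(e) {
      warning("class summary skipped: ", conditionMessage(e))
      NULL
    }
  ))
  if (!is.null(summ)) {
    write_tsv_report(summ$groups, out("class_summary.tsv"))
    write_tsv_report(summ$tests, out("class_tests.tsv"))
  }

  cfg <- unclass(config)
  cfg$offsets <- if (is.data.frame(cfg$offsets)) "table" else cfg$offsets
  yaml::write_yaml(cfg, out("config.yaml"))
  files <- sort(setdiff(list.files(config$out_dir), "manifest.json"))
  manifest <- list(files = lapply(files, function(f) {
    list(name = f, md5 = unname(tools::md5sum(out(f))))
  }))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE)

  invisible(list(
    orfs = orfs, counts = counts, expression = expr,
    codon_stats = cs, analyses = analyses, comparisons = comparisons,
    class_summary = summ, out_dir = config$out_dir
  ))
}

#' Render summary figures from a run directory
#'
#' Reads the TSV outputs of [run_all()] and writes static figures: a PWM
#' weight chart, a per-codon with/without +1 GNN bar chart, and a grouped
#' percent-elevation box plot. Plotting failures warn and never touch the
#' TSV outputs.
#'
#' @param out_dir A [run_all()] output directory.
#' @param format Image format (`"png"` or `"pdf"`).
#' @return Invisibly, the paths of the figures written.
#' @export
render_figures <- function(out_dir, format = "png") {
  written <- character(0)
  save_fig <- function(plot, name, width = 7, height = 4.5) {
    path <- file.path(out_dir, paste0(name, ".", format))
    tryCatch(
      {
        ggplot2::ggsave(path, plot, width = width, height = height, dpi = 150)
        written <<- c(written, path)
      },
      error = function(e) warning("figure ", name, " skipped: ", conditionMessage(e))
    )
    invisible(NULL)
  }
  pwm_path <- file.path(out_dir, "pwm_all.tsv")
  if (file.exists(pwm_path)) {
    pw <- readr::read_tsv(pwm_path, show_col_types = FALSE, progress = FALSE)
    save_fig(plot_pwm(pw, title = "All codons"), "pwm_all")
  }
  adj_path <- file.path(out_dir, "pwm_adjacent.tsv")
  if (file.exists(adj_path)) {
    pw <- readr::read_tsv(adj_path, show_col_types = FALSE, progress = FALSE)
    save_fig(plot_pwm(pw, title = "Codons 3'-adjacent to reference class"), "pwm_adjacent")
  }
  comp_path <- file.path(out_dir, "comparisons.tsv")
  comp <- NULL
  if (file.exists(comp_path)) {
    comp <- readr::read_tsv(comp_path, show_col_types = FALSE, progress = FALSE)
    if (nrow(comp) > 0) {
      save_fig(plot_context_comparison(comp), "comparisons", width = 9)
      save_fig(plot_class_summary(comp), "class_summary")
    } else {
      warning("comparisons.tsv is empty; no comparison figure written")
    }
  }
  invisible(written)
}
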