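#' @importFrom rlang .data
#' @importFrom dplyr %>%
NULL

#' Construct an ORF set from gene ids and sequences
#'
#' An ORF set is a tibble with columns `gene_id` and `seq`, one row per
#' coding sequence, in a stable (insertion) order. Sequences are
#' canonicalized to the DNA alphabet (U is treated as identical to T and
#' stored as T); every retained sequence is a positive multiple of 3 in
#' length and contains no characters outside A/C/G/T. Records violating
#' either rule are dropped with a message reporting the count.
#'
#' @param gene_id Character vector of unique gene identifiers.
#' @param seq Character vector of nucleotide sequences (ACGT or ACGU,
#'   case-insensitive).
#' @param quiet Suppress the dropped-record message.
#' @return A tibble of class `orf_set` with columns `gene_id`, `seq`.
#' @export
orf_set <- function(gene_id, seq, quiet = FALSE) {
  stopifnot(length(gene_id) == length(seq))
  gene_id <- unname(gene_id)
  seq <- toupper(chartr("u", "t", tolower(unname(seq))))
  dup <- duplicated(gene_id)
  if (any(dup)) {
    warning(sum(dup), " duplicate gene_id(s) dropped (first occurrence kept)")
    gene_id <- gene_id[!dup]
    seq <- seq[!dup]
  }
  ok_len <- nchar(seq) > 0L & nchar(seq) %% 3L == 0L
  ok_chr <- !stringr::str_detect(seq, "[^ACGT]")
  keep <- ok_len & ok_chr
  n_drop <- sum(!keep)
  if (n_drop > 0 && !quiet) {
    message(
      n_drop, " record(s) dropped: ",
      sum(!ok_len), " with length not a positive multiple of 3, ",
      sum(ok_len & !ok_chr), " with ambiguous/invalid characters"
    )
  }
  out <- tibble::tibble(gene_id = as.character(gene_id[keep]), seq = seq[keep])
  class(out) <- c("orf_set", class(out))
  attr(out, "n_dropped") <- n_drop
  out
}

#' Read an ORF set from a FASTA file
#'
#' Record names are taken up to the first whitespace. Records whose length is
#' not a positive multiple of 3, or that contain characters outside
#' A/C/G/T/U, are dropped and counted. U and T alphabets are canonicalized
#' to a single internal alphabet, so a FASTA written with U yields the same
#' ORF set as the equivalent written with T.
#'
#' @param path Path to a FASTA file.
#' @param quiet Suppress the dropped-record message.
#' @return An [orf_set] tibble.
#' @export
read_orf_fasta <- function(path, quiet = FALSE) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  recs <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(recs))
  out <- orf_set(ids, as.character(recs), quiet = quiet)
  if (nrow(out) == 0L) stop("no valid ORF records in ", path)
  out
}

#' Write an ORF set to a FASTA file
#'
#' @param orfs An [orf_set].
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_orf_fasta <- function(orfs, path, width = 60L) {
  x <- Biostrings::DNAStringSet(orfs$seq)
  names(x) <- orfs$gene_id
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a footprint 5'-end count table
#'
#' The table is a TSV with header columns `gene_id`, `pos5`, `read_length`,
#' `count`. `pos5` is the 0-based offset of the read 5' end relative to the
#' first nucleotide of the start codon and may be negative (5' ends in the
#' 5' UTR). Duplicate (gene, position, length) rows are summed. A negative
#' count or a malformed row is a hard error naming the offending line.
#'
#' @param path Path to the TSV.
#' @return A tibble of class `footprint_counts` with integer columns
#'   `pos5`, `read_length`, `count`.
#' @export
read_footprint_table <- function(path) {
  if (!file.exists(path)) stop("footprint table not found: ", path)
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      pos5 = readr::col_double(),
      read_length = readr::col_double(),
      count = readr::col_double()
    ),
    progress = FALSE
  )
  prob <- readr::problems(raw)
  if (nrow(prob) > 0) {
    stop("malformed footprint table row at line ", prob$row[1] + 1L, " of ", path)
  }
  bad <- which(!stats::complete.cases(raw))
  if (length(bad) > 0) {
    stop("malformed footprint table row at line ", bad[1] + 1L, " of ", path)
  }
  neg <- which(raw$count < 0)
  if (length(neg) > 0) {
    stop("negative count at line ", neg[1] + 1L, " of ", path)
  }
  footprint_counts(raw)
}

#' Construct a footprint count table
#'
#' @param x A data frame with columns `gene_id`, `pos5`, `read_length`,
#'   `count`. Duplicate keys are summed; zero-count rows are dropped.
#' @return A `footprint_counts` tibble.
#' @export
footprint_counts <- function(x) {
  stopifnot(all(c("gene_id", "pos5", "read_length", "count") %in% names(x)))
  if (any(x$count < 0)) stop("negative footprint count")
  gene <- as.character(x$gene_id)
  pos5 <- as.integer(x$pos5)
  len <- as.integer(x$read_length)
  cnt <- as.integer(round(x$count))
  nz <- cnt > 0L
  gene <- gene[nz]; pos5 <- pos5[nz]; len <- len[nz]; cnt <- cnt[nz]
  ord <- order(gene, pos5, len, method = "radix")
  gene <- gene[ord]; pos5 <- pos5[ord]; len <- len[ord]; cnt <- cnt[ord]
  n <- length(cnt)
  if (n > 1L) {
    new_key <- c(TRUE, gene[-1] != gene[-n] | pos5[-1] != pos5[-n] | len[-1] != len[-n])
    if (!all(new_key)) {
      grp <- cumsum(new_key)
      cnt <- as.integer(rowsum(cnt, grp)[, 1])
      gene <- gene[new_key]; pos5 <- pos5[new_key]; len <- len[new_key]
    }
  }
  out <- tibble::tibble(gene_id = gene, pos5 = pos5, read_length = len, count = cnt)
  class(out) <- c("footprint_counts", class(out))
  out
}

#' Write a footprint count table
#'
#' @param counts A `footprint_counts` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_footprint_table <- function(counts, path) {
  readr::write_tsv(counts, path, progress = FALSE)
  invisible(path)
}

#' Read a gene expression table
#'
#' TSV with header `gene_id`, `value`. Values must be numeric and finite.
#' Genes absent from an ORF set are retained here and warned about at use
#' time (see [stratify_by_expression()]).
#'
#' @param path Path to the TSV.
#' @return A tibble with columns `gene_id`, `value`.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  raw <- readr::read_tsv(
    path,
    col_types = readr::cols(
      gene_id = readr::col_character(),
      value = readr::col_double()
    ),
    progress = FALSE
  )
  if (nrow(raw) == 0) stop("empty expression table: ", path)
  if (nrow(readr::problems(raw)) > 0 || any(!is.finite(raw$value))) {
    stop("non-numeric or non-finite expression value in ", path)
  }
  raw
}

## Fixed 6-significant-digit decimal formatting so that repeated writes of
## the same object are byte-identical and round-trip through read_tsv.
format_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
}

#' Write a result object as a deterministic TSV report
#'
#' Writes any of the package's tabular result objects (a tidied PWM, a
#' context-comparison table, a bootstrap result, or any plain data frame)
#' with a fixed column order and floating-point values at 6 significant
#' digits, so that the same object always produces byte-identical files and
#' values round-trip through [readr::read_tsv()].
#'
#' @param x A data frame, or an object with a [generics::tidy()] method
#'   (`codon_pwm`, `codon_bootstrap`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_report <- function(x, path) {
  if (!is.data.frame(x)) x <- generics::tidy(x)
  out <- dplyr::mutate(x, dplyr::across(dplyr::where(is.double), format_num))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
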