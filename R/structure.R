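#' Collect gene-structure records from gene models or a metadata table
#'
#' Accepts either a gene-model data.frame from [read_annotation()] (exon
#' counts and lengths derived from the annotation: gene length is the genomic
#' span, transcript length the sum of exon widths, translation length the CDS
#' length / 3 minus the stop codon) or a metadata TSV/data.frame with columns
#' \code{gene_id}, \code{species}, \code{n_exons}, \code{gene_length},
#' \code{transcript_length}, \code{translation_length} as recorded from a
#' public annotation browser.
#'
#' Single-exon records with a gene length below \code{partial_max_length} are
#' flagged \code{partial}; such short one-exon orthologs are typically
#' incomplete sequences rather than true intronless genes.
#'
#' @param x Gene-model data.frame, metadata data.frame, or path to a TSV.
#' @param species Species label applied when \code{x} carries none.
#' @param partial_max_length Length threshold for the partial flag (default
#'   600 bp).
#' @return data.frame with columns \code{gene_id}, \code{species},
#'   \code{n_exons}, \code{n_introns}, \code{gene_length},
#'   \code{transcript_length}, \code{translation_length}, \code{partial}.
#' @export
collect_structures <- function(x, species = NA_character_,
                               partial_max_length = 600L) {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.delim(x, comment.char = "#", stringsAsFactors = FALSE)
  }
  stopifnot(is.data.frame(x))
  if (!is.null(x$exon_start)) {      # gene models from read_annotation()
    n_exons <- vapply(x$exon_start, length, integer(1))
    tr_len <- vapply(seq_len(nrow(x)), function(i) {
      sum(x$exon_end[[i]] - x$exon_start[[i]] + 1L)
    }, integer(1))
    aa <- ifelse(!is.null(x$cds_length) & x$cds_length %% 3L == 0L,
                 x$cds_length %/% 3L - 1L, NA_integer_)
    out <- data.frame(gene_id = x$gene_id,
                      species = if (is.null(x$species)) species else x$species,
                      n_exons = n_exons, n_introns = n_exons - 1L,
                      gene_length = x$gene_end - x$gene_start + 1L,
                      transcript_length = tr_len,
                      translation_length = aa, stringsAsFactors = FALSE)
  } else {
    need <- c("gene_id", "n_exons", "gene_length", "transcript_length",
              "translation_length")
    miss <- setdiff(need, names(x))
    if (length(miss) > 0L) {
      stop("metadata table lacks column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    out <- data.frame(gene_id = x$gene_id,
                      species = if (is.null(x$species)) species else x$species,
                      n_exons = as.integer(x$n_exons),
                      n_introns = if (is.null(x$n_introns))
                        as.integer(x$n_exons) - 1L else as.integer(x$n_introns),
                      gene_length = x$gene_length,
                      transcript_length = x$transcript_length,
                      translation_length = x$translation_length,
                      stringsAsFactors = FALSE)
  }
  bad <- out$n_introns != out$n_exons - 1L
  out$consistent <- !bad
  if (any(bad)) {
    warning(sum(bad), " record(s) with inconsistent exon/intron counts ",
            "flagged and excluded from summaries")
  }
  out$partial <- out$n_exons == 1L & out$gene_length < partial_max_length
  rownames(out) <- NULL
  out
}

#' Summarize intron-exon architecture and length statistics of a cohort
#'
#' Reports the exon-count frequency table, the modal exon class and its fold
#' enrichment over the runner-up class, medians of gene, transcript and
#' translation length, and a skew direction per measure operationalized as
#' \code{sign(mean - median)} (+1 means the tail points to larger values).
#' Records flagged inconsistent are excluded; flagged partial records are
#' included unless \code{exclude_partial = TRUE}.
#'
#' @param records data.frame from [collect_structures()].
#' @param exclude_partial Drop partial (short single-exon) records from all
#'   summaries (default FALSE).
#' @return List of class \code{structure_summary}: \code{exon_table},
#'   \code{modal_exons}, \code{modal_fold}, \code{medians}, \code{means},
#'   \code{skew}, \code{n}.
#' @export
summarize_structures <- function(records, exclude_partial = FALSE) {
  keep <- if (is.null(records$consistent)) rep(TRUE, nrow(records)) else
    records$consistent
  if (exclude_partial) keep <- keep & !records$partial
  r <- records[keep, , drop = FALSE]
  if (nrow(r) == 0L) stop("no valid records to summarize", call. = FALSE)
  tab <- sort(table(r$n_exons), decreasing = TRUE)
  modal <- as.integer(names(tab)[1L])
  fold <- if (length(tab) > 1L) unname(tab[1L] / tab[2L]) else Inf
  measures <- c("gene_length", "transcript_length", "translation_length")
  med <- vapply(measures, function(m) stats::median(r[[m]], na.rm = TRUE),
                numeric(1))
  mn <- vapply(measures, function(m) mean(r[[m]], na.rm = TRUE), numeric(1))
  structure(list(exon_table = tab, modal_exons = modal, modal_fold = fold,
                 medians = med, means = mn, skew = sign(mn - med),
                 n = nrow(r)),
            class = "structure_summary")
}

#' @export
print.structure_summary <- function(x, ...) {
  cat(sprintf("<structure_summary> n=%d  modal exon count=%d (%.2g-fold over runner-up)\n",
              x$n, x$modal_exons, x$modal_fold))
  cat("exon-count table:\n"); print(x$exon_table)
  cat("medians:\n"); print(round(x$medians, 2))
  cat("skew (sign of mean - median):\n"); print(x$skew)
  invisible(x)
}

#' Write a structure summary as TSV
#'
#' @param summary \code{structure_summary}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_structure_summary <- function(summary, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# structure_summary n=%d", summary$n), con)
  writeLines("key\tvalue", con)
  for (nm in names(summary$exon_table)) {
    writeLines(sprintf("n_exons_%s\t%d", nm, summary$exon_table[[nm]]), con)
  }
  writeLines(sprintf("modal_exons\t%d", summary$modal_exons), con)
  writeLines(sprintf("modal_fold\t%g", summary$modal_fold), con)
  for (nm in names(summary$medians)) {
    writeLines(sprintf("median_%s\t%g", nm, summary$medians[[nm]]), con)
    writeLines(sprintf("skew_%s\t%d", nm, summary$skew[[nm]]), con)
  }
  invisible(path)
}
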