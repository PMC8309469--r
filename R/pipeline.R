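write_tsv <- function(tab, path, config) {
  cfg <- paste(sprintf("%s=%s", names(config), vapply(config, function(x)
    paste(format(x), collapse = ","), character(1))), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# promoterscan %s",
                     as.character(utils::packageVersion("promoterscan"))), con)
  writeLines(sprintf("# config %s", cfg), con)
  flat <- tab
  for (nm in names(flat)) if (is.list(flat[[nm]])) flat[[nm]] <- NULL
  utils::write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scan stage: promoters and genome fragments of one genome
#'
#' Reads a genome and annotation, extracts promoters, scans promoters and
#' 2000-bp fragments for the motif registry, and writes promoter FASTA/BED,
#' the per-promoter count matrix, the hit table and the fragment GC table,
#' all as TSV with '#' header lines carrying the package version and config.
#'
#' @param genome_fa Genome FASTA path.
#' @param annotation_gff GFF3 path.
#' @param out_dir Output directory.
#' @param motifs Motif registry (default [default_motifs()]).
#' @param promoter_length Promoter length in bp (default 2000).
#' @param strands Strand policy (default \code{"both"}).
#' @return Invisibly, a list with the in-memory tables.
#' @export
run_scan <- function(genome_fa, annotation_gff, out_dir,
                     motifs = default_motifs(), promoter_length = 2000L,
                     strands = "both") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(stage = "scan", genome = basename(genome_fa),
                 annotation = basename(annotation_gff),
                 promoter_length = promoter_length, strands = strands)
  genome <- read_genome(genome_fa)
  genes <- read_annotation(annotation_gff)
  promoters <- extract_promoters(genome, genes, length = promoter_length)
  write_promoters(promoters, fasta = file.path(out_dir, "promoters.fa"),
                  bed = file.path(out_dir, "promoters.bed"))
  ann <- annotate_promoter_set(promoters, motifs, strands)
  write_tsv(ann$counts, file.path(out_dir, "promoter_counts.tsv"), config)
  write_tsv(ann$hits, file.path(out_dir, "promoter_hits.tsv"), config)
  write_annotation_bed(ann, file.path(out_dir, "promoter_hits.bed"))
  fragments <- fragment_genome(genome, window = promoter_length)
  write_tsv(fragments, file.path(out_dir, "fragments.tsv"), config)
  invisible(list(promoters = promoters, annotation = ann,
                 fragments = fragments))
}

#' Null-model stage: composition models and expected-count report
#'
#' Estimates a whole-genome composition model and, when a focal GC is given,
#' a GC-stratified model from matching fragments; writes both models and an
#' observed-versus-expected report over the genome fragments.
#'
#' @param genome_fa Genome FASTA path.
#' @param out_dir Output directory.
#' @param motifs Motif registry.
#' @param window Fragment width (default 2000).
#' @param gc_center Optional focal GC fraction for stratification.
#' @param gc_tolerance GC tolerance (default 0.02).
#' @param strands Strand policy (default \code{"both"}).
#' @return Invisibly, a list with models, reports and fragment tables.
#' @export
run_null <- function(genome_fa, out_dir, motifs = default_motifs(),
                     window = 2000L, gc_center = NULL, gc_tolerance = 0.02,
                     strands = "both") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(stage = "null", genome = basename(genome_fa),
                 window = window,
                 gc_center = if (is.null(gc_center)) "none" else gc_center,
                 gc_tolerance = gc_tolerance, strands = strands)
  genome <- read_genome(genome_fa)
  fragments <- fragment_genome(genome, window = window)
  frag_seqs <- fragment_seqs(genome, fragments)
  whole <- estimate_composition(genome, source = "whole-genome")
  write_composition_model(whole, file.path(out_dir, "model_whole_genome.tsv"))
  report <- observed_vs_expected_report(frag_seqs, motifs, whole, strands)
  out <- list(whole_model = whole, whole_report = report,
              fragments = fragments)
  if (!is.null(gc_center)) {
    strat_frags <- filter_fragments_by_gc(fragments, gc_center, gc_tolerance)
    if (nrow(strat_frags) > 0L) {
      strat_seqs <- fragment_seqs(genome, strat_frags)
      strat <- estimate_composition(strat_seqs, source = "GC-stratified")
      write_composition_model(strat,
                              file.path(out_dir, "model_gc_stratified.tsv"))
      strat_report <- observed_vs_expected_report(strat_seqs, motifs, strat,
                                                  strands)
      report <- rbind(report, strat_report)
      out$stratified_model <- strat
      out$stratified_report <- strat_report
      out$stratified_fragments <- strat_frags
    } else {
      warning("no fragments within the GC window; stratified model skipped")
    }
  }
  write_tsv(report, file.path(out_dir, "expected_vs_observed.tsv"), config)
  out$report <- report
  invisible(out)
}

#' Atlas stage: family track tables and count distributions
#'
#' @param promoter_fa Promoter FASTA (records named \code{species|gene} or
#'   \code{gene}).
#' @param out_dir Output directory.
#' @param family_file Optional two-column TSV (family_id, record_id).
#' @param motifs Motif registry.
#' @param strands Strand policy.
#' @return Invisibly, list with annotation, tracks and distributions.
#' @export
run_atlas <- function(promoter_fa, out_dir, family_file = NULL,
                      motifs = default_motifs(), strands = "both") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(stage = "atlas", promoters = basename(promoter_fa),
                 families = if (is.null(family_file)) "none" else
                   basename(family_file), strands = strands)
  promoters <- read_genome(promoter_fa)
  ann <- annotate_promoter_set(promoters, motifs, strands)
  families <- NULL
  if (!is.null(family_file)) {
    families <- utils::read.delim(family_file, comment.char = "#",
                                  stringsAsFactors = FALSE)
    names(families)[1:2] <- c("family_id", "record_id")
  }
  tt <- family_track_table(ann, families)
  write_tsv(tt$tracks, file.path(out_dir, "family_tracks.tsv"), config)
  write_tsv(tt$shared, file.path(out_dir, "family_shared.tsv"), config)
  write_annotation_bed(ann, file.path(out_dir, "promoter_hits.bed"))
  dists <- lapply(ann$motifs, function(m) {
    d <- count_distribution(ann, m$name, include_truncated = TRUE)
    data.frame(motif = m$name, d$histogram, mean = d$mean,
               n_promoters = d$n_promoters, stringsAsFactors = FALSE)
  })
  write_tsv(do.call(rbind, dists), file.path(out_dir, "distributions.tsv"),
            config)
  invisible(list(annotation = ann, tracks = tt))
}

#' Structures stage: cohort intron-exon summary
#'
#' @param input GFF3 path or metadata TSV path.
#' @param out_dir Output directory.
#' @param exclude_partial Exclude short single-exon (partial) records.
#' @return Invisibly, list with records and summary.
#' @export
run_structures <- function(input, out_dir, exclude_partial = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  config <- list(stage = "structures", input = basename(input),
                 exclude_partial = exclude_partial)
  records <- if (grepl("\\.gff3?$", input, ignore.case = TRUE)) {
    collect_structures(read_annotation(input))
  } else {
    collect_structures(input)
  }
  summary <- summarize_structures(records, exclude_partial = exclude_partial)
  write_tsv(records, file.path(out_dir, "structure_records.tsv"), config)
  write_structure_summary(summary, file.path(out_dir, "structure_summary.tsv"))
  invisible(list(records = records, summary = summary))
}

#' Simulate stage: write a seeded toy genome + annotation fixture
#'
#' @param out_dir Output directory.
#' @param n_genes Number of genes.
#' @param gc Background GC fraction.
#' @param seed Integer seed.
#' @return Invisibly, the [make_fixture()] result.
#' @export
run_simulate <- function(out_dir, n_genes = 3L, gc = 0.36, seed = 1L) {
  invisible(make_fixture(out_dir, n_genes = n_genes, gc = gc, seed = seed))
}

#' Command-line entry point
#'
#' Dispatches the subcommands \code{scan}, \code{null}, \code{atlas},
#' \code{structures} and \code{simulate}; see the Rscript wrapper installed
#' at \code{system.file("exec", "promoterscan", package = "promoterscan")}.
#' Exit status: 0 on success, 2 on usage errors, 1 on data errors.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit status (invisibly).
#' @export
promoterscan_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: promoterscan <scan|null|atlas|structures|simulate> [options]",
    "  scan       --genome FA --annotation GFF3 --out DIR [--length 2000] [--strands both]",
    "  null       --genome FA --out DIR [--window 2000] [--gc-center GC] [--gc-tolerance 0.02]",
    "  atlas      --promoters FA --out DIR [--families TSV]",
    "  structures --input GFF3|TSV --out DIR [--exclude-partial]",
    "  simulate   --out DIR [--n-genes 3] [--gc 0.36] [--seed 1]",
    sep = "\n")
  if (length(args) < 1L) { message(usage); return(invisible(2L)) }
  cmd <- args[[1L]]
  opts <- list()
  rest <- args[-1L]
  i <- 1L
  while (i <= length(rest)) {
    key <- sub("^--", "", rest[[i]])
    if (!startsWith(rest[[i]], "--")) { message(usage); return(invisible(2L)) }
    if (key == "exclude-partial") { opts[[key]] <- TRUE; i <- i + 1L }
    else if (i + 1L > length(rest)) { message(usage); return(invisible(2L)) }
    else { opts[[key]] <- rest[[i + 1L]]; i <- i + 2L }
  }
  need <- function(k) {
    if (is.null(opts[[k]])) stop("missing required option --", k, call. = FALSE)
    opts[[k]]
  }
  status <- tryCatch({
    switch(cmd,
      scan = run_scan(need("genome"), need("annotation"), need("out"),
                      promoter_length = as.integer(opts[["length"]] %||% 2000L),
                      strands = opts[["strands"]] %||% "both"),
      null = run_null(need("genome"), need("out"),
                      window = as.integer(opts[["window"]] %||% 2000L),
                      gc_center = if (is.null(opts[["gc-center"]])) NULL else
                        as.numeric(opts[["gc-center"]]),
                      gc_tolerance = as.numeric(opts[["gc-tolerance"]] %||%
                                                  0.02)),
      atlas = run_atlas(need("promoters"), need("out"),
                        family_file = opts[["families"]]),
      structures = run_structures(need("input"), need("out"),
                                  exclude_partial =
                                    isTRUE(opts[["exclude-partial"]])),
      simulate = run_simulate(need("out"),
                              n_genes = as.integer(opts[["n-genes"]] %||% 3L),
                              gc = as.numeric(opts[["gc"]] %||% 0.36),
                              seed = as.integer(opts[["seed"]] %||% 1L)),
      { message(usage); return(invisible(2L)) })
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    if (grepl("missing required option", conditionMessage(e))) 2L else 1L
  })
  invisible(status)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
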