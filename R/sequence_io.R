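#' Read a genome FASTA
#'
#' Sequences are upper-cased and record order is preserved. Record names are
#' truncated at the first whitespace, matching common annotation conventions.
#'
#' @param path Path to a FASTA file.
#' @return \link[Biostrings]{DNAStringSet}, one element per record.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  dss <- tryCatch(Biostrings::readDNAStringSet(path),
                  error = function(e) {
                    stop("malformed FASTA '", path, "': ", conditionMessage(e),
                         call. = FALSE)
                  })
  if (length(dss) == 0L) warning("FASTA file '", path, "' contains no records")
  names(dss) <- sub("\\s.*$", "", names(dss))
  toupper_dss(dss)
}

toupper_dss <- function(dss) {
  out <- Biostrings::DNAStringSet(toupper(as.character(dss)))
  names(out) <- names(dss)
  out
}

#' Read gene models from a GFF3 annotation
#'
#' Builds one gene model per protein-coding gene (genes whose transcripts carry
#' CDS features). When a gene has several transcripts the first-listed one is
#' used. \code{cds_start} is the strand-aware genomic coordinate of the first
#' base of the start codon: the minimum CDS start on \code{+} genes, the
#' maximum CDS end on \code{-} genes.
#'
#' @param path Path to a GFF3 file with gene/mRNA/exon/CDS features.
#' @return data.frame with columns \code{gene_id}, \code{contig_id},
#'   \code{strand}, \code{cds_start} (1-based), \code{gene_start},
#'   \code{gene_end}, \code{cds_length}, and list-columns \code{exon_start},
#'   \code{exon_end} (1-based inclusive, ordered 5' to 3' on the gene strand).
#' @export
read_annotation <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  genes <- gr[typ == "gene"]
  tx <- gr[typ %in% c("mRNA", "transcript")]
  exons <- gr[typ == "exon"]
  cds <- gr[typ == "CDS"]
  first_parent <- function(x) {
    vapply(x, function(p) if (length(p) > 0L) p[[1L]] else NA_character_,
           character(1))
  }
  tx_parent <- first_parent(tx$Parent)
  exon_parent <- first_parent(exons$Parent)
  cds_parent <- first_parent(cds$Parent)

  rows <- lapply(seq_along(genes), function(i) {
    g <- genes[i]
    gid <- g$ID
    gtx <- which(tx_parent == gid)
    if (length(gtx) == 0L) {
      warning("gene '", gid, "' has no transcript; skipped")
      return(NULL)
    }
    tid <- tx$ID[gtx[1L]]   # first-listed transcript
    ecs <- cds[cds_parent == tid]
    if (length(ecs) == 0L) {
      warning("gene '", gid, "' has no CDS; skipped")
      return(NULL)
    }
    ex <- exons[exon_parent == tid]
    if (length(ex) == 0L) ex <- ecs
    strand <- as.character(GenomicRanges::strand(g))
    ord <- order(GenomicRanges::start(ex),
                 decreasing = identical(strand, "-"))
    ex <- ex[ord]
    cds_start <- if (identical(strand, "-")) {
      max(GenomicRanges::end(ecs))
    } else {
      min(GenomicRanges::start(ecs))
    }
    data.frame(
      gene_id = gid,
      contig_id = as.character(GenomicRanges::seqnames(g)),
      strand = strand,
      cds_start = cds_start,
      gene_start = GenomicRanges::start(g),
      gene_end = GenomicRanges::end(g),
      cds_length = sum(GenomicRanges::width(ecs)),
      exon_start = I(list(GenomicRanges::start(ex))),
      exon_end = I(list(GenomicRanges::end(ex))),
      stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    stop("annotation '", path, "' yielded no protein-coding gene models",
         call. = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Extract the upstream promoter region of one gene
#'
#' Takes the \code{length} bases immediately 5' of the annotated CDS start
#' codon (so promoters include the 5'UTR): on \code{+} genes the genomic
#' interval \code{[cds_start-1-length, cds_start-1)} (0-based half-open); on
#' \code{-} genes \code{[cds_start, cds_start+length)} reverse-complemented.
#' Intervals are clipped at contig boundaries and flagged \code{truncated}.
#'
#' @param genome \link[Biostrings]{DNAStringSet} (from [read_genome()]).
#' @param gene One-row gene model data.frame (from [read_annotation()]) or a
#'   list with \code{gene_id}, \code{contig_id}, \code{strand},
#'   \code{cds_start}.
#' @param length Requested promoter length in bp (default 2000).
#' @return One-row data.frame: \code{gene_id}, \code{sequence} (5' to 3' in
#'   gene orientation), \code{requested_length}, \code{actual_length},
#'   \code{contig_id}, \code{start}, \code{end} (0-based half-open genomic
#'   interval), \code{strand}, \code{truncated}.
#' @export
extract_promoter <- function(genome, gene, length = 2000L) {
  contig <- gene$contig_id[[1L]]
  if (!contig %in% names(genome)) {
    stop("contig '", contig, "' not present in genome", call. = FALSE)
  }
  clen <- Biostrings::width(genome)[match(contig, names(genome))]
  cds_start <- as.integer(gene$cds_start[[1L]])
  strand <- gene$strand[[1L]]
  if (identical(strand, "+")) {
    s0 <- max(0L, cds_start - 1L - length)
    e0 <- cds_start - 1L
  } else {
    s0 <- cds_start
    e0 <- min(clen, cds_start + length)
  }
  e0 <- max(e0, s0)
  actual <- e0 - s0
  if (actual == 0L) {
    warning("gene '", gene$gene_id[[1L]], "' has no upstream bases; ",
            "empty promoter returned")
    seq_chr <- ""
  } else {
    sq <- Biostrings::subseq(genome[[contig]], start = s0 + 1L, end = e0)
    if (identical(strand, "-")) sq <- Biostrings::reverseComplement(sq)
    seq_chr <- as.character(sq)
  }
  data.frame(gene_id = gene$gene_id[[1L]], sequence = seq_chr,
             requested_length = as.integer(length), actual_length = actual,
             contig_id = contig, start = s0, end = e0, strand = strand,
             truncated = actual < length, stringsAsFactors = FALSE)
}

#' Extract promoters for a whole gene-model table
#'
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param genes Gene-model data.frame from [read_annotation()].
#' @param length Promoter length in bp (default 2000).
#' @return data.frame with one row per gene (see [extract_promoter()]).
#' @export
extract_promoters <- function(genome, genes, length = 2000L) {
  out <- do.call(rbind, lapply(seq_len(nrow(genes)), function(i) {
    extract_promoter(genome, genes[i, , drop = FALSE], length = length)
  }))
  rownames(out) <- NULL
  out
}

#' Promoter table to DNAStringSet
#'
#' @param promoters data.frame from [extract_promoters()].
#' @return Named \link[Biostrings]{DNAStringSet} (names are gene ids).
#' @export
promoter_seqs <- function(promoters) {
  dss <- Biostrings::DNAStringSet(promoters$sequence)
  names(dss) <- promoters$gene_id
  dss
}

#' Split contigs into fixed-width non-overlapping fragments
#'
#' Fragmentation starts at offset 0 on each contig; a trailing remainder
#' shorter than \code{window} is discarded so that all fragments are
#' directly comparable. GC content is computed per fragment with \code{N}
#' excluded from numerator and denominator.
#'
#' @param genome \link[Biostrings]{DNAStringSet} or single
#'   \link[Biostrings]{DNAString}/character string.
#' @param window Fragment width in bp (default 2000).
#' @return data.frame with \code{contig_id}, \code{start}, \code{end}
#'   (0-based half-open), \code{gc}, \code{n_frac} (fraction of N bases).
#' @export
fragment_genome <- function(genome, window = 2000L) {
  stopifnot(window >= 1L)
  if (is(genome, "DNAString")) genome <- Biostrings::DNAStringSet(genome)
  if (is.character(genome)) genome <- Biostrings::DNAStringSet(toupper(genome))
  if (is.null(names(genome))) names(genome) <- as.character(seq_along(genome))
  res <- lapply(seq_along(genome), function(i) {
    L <- Biostrings::width(genome)[i]
    n <- L %/% window
    if (n == 0L) return(NULL)
    starts0 <- (seq_len(n) - 1L) * window
    v <- Biostrings::Views(genome[[i]], start = starts0 + 1L,
                           width = window)
    freq <- Biostrings::letterFrequency(v, c("A", "C", "G", "T", "N"))
    denom <- rowSums(freq[, c("A", "C", "G", "T"), drop = FALSE])
    gc <- ifelse(denom > 0,
                 rowSums(freq[, c("C", "G"), drop = FALSE]) / denom, NA_real_)
    data.frame(contig_id = names(genome)[i], start = starts0,
               end = starts0 + window, gc = gc,
               n_frac = freq[, "N"] / window, stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) {
    return(data.frame(contig_id = character(0), start = integer(0),
                      end = integer(0), gc = numeric(0), n_frac = numeric(0)))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' GC content of a sequence
#'
#' \code{(G + C) / (A + C + G + T)}; \code{N} and other ambiguity codes are
#' excluded from both numerator and denominator.
#'
#' @param sequence Character string or \link[Biostrings]{DNAString}.
#' @return Fraction in \code{[0, 1]}.
#' @examples
#' gc_content("ATGC")  # 0.5
#' @export
gc_content <- function(sequence) {
  s <- if (is(sequence, "DNAString")) sequence else
    Biostrings::DNAString(toupper(as.character(sequence)))
  if (length(s) == 0L) stop("gc_content of an empty sequence is undefined",
                            call. = FALSE)
  f <- Biostrings::letterFrequency(s, c("A", "C", "G", "T"))
  if (sum(f) == 0) {
    stop("gc_content undefined: sequence contains no unambiguous bases",
         call. = FALSE)
  }
  unname((f[["C"]] + f[["G"]]) / sum(f))
}

#' Retain fragments whose GC content matches a focal value
#'
#' Boundaries are inclusive: with center 0.284 and tolerance 0.02 the retained
#' range is \code{[0.264, 0.304]}, i.e. GC content 26.4\% to 30.4\%. Fragments
#' with more than \code{max_n_frac} N bases are dropped so assembly gaps do
#' not bias background composition estimates.
#'
#' @param fragments data.frame from [fragment_genome()].
#' @param center Focal GC fraction (e.g. a promoter's GC content).
#' @param tolerance Allowed absolute deviation (default 0.02).
#' @param max_n_frac Maximum tolerated N fraction per fragment (default 0.1).
#' @return Filtered fragment data.frame.
#' @export
filter_fragments_by_gc <- function(fragments, center, tolerance = 0.02,
                                   max_n_frac = 0.1) {
  stopifnot(center >= 0, center <= 1, tolerance >= 0)
  keep <- !is.na(fragments$gc) &
    fragments$gc >= center - tolerance &
    fragments$gc <= center + tolerance &
    fragments$n_frac <= max_n_frac
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fragment sequences as a DNAStringSet
#'
#' @param genome \link[Biostrings]{DNAStringSet}.
#' @param fragments data.frame from [fragment_genome()] (possibly filtered).
#' @return \link[Biostrings]{DNAStringSet} named \code{contig:start-end}.
#' @export
fragment_seqs <- function(genome, fragments) {
  if (nrow(fragments) == 0L) return(Biostrings::DNAStringSet())
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(fragments)), function(i) {
    as.character(Biostrings::subseq(genome[[fragments$contig_id[i]]],
                                    start = fragments$start[i] + 1L,
                                    end = fragments$end[i]))
  }, character(1)))
  names(out) <- sprintf("%s:%d-%d", fragments$contig_id,
                        fragments$start, fragments$end)
  out
}

#' Write promoters as FASTA and BED6
#'
#' @param promoters data.frame from [extract_promoters()].
#' @param fasta,bed Output paths (either may be NULL to skip).
#' @return Invisibly, the promoter table.
#' @export
write_promoters <- function(promoters, fasta = NULL, bed = NULL) {
  if (!is.null(fasta)) {
    keep <- promoters$actual_length > 0L
    Biostrings::writeXStringSet(promoter_seqs(promoters[keep, , drop = FALSE]),
                                fasta)
  }
  if (!is.null(bed)) {
    keep <- promoters$actual_length > 0L
    p <- promoters[keep, , drop = FALSE]
    gr <- GenomicRanges::GRanges(
      seqnames = p$contig_id,
      ranges = IRanges::IRanges(start = p$start + 1L, end = p$end),
      strand = p$strand, name = p$gene_id, score = 0L)
    rtracklayer::export.bed(gr, bed)
  }
  invisible(promoters)
}
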