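with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# deterministic substream seeds so fixtures are stable under contig addition;
# kept below 2^31 - 1 (R integers are 32-bit)
substream_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 48271 + index * 16807) %% 2147483629)
}

#' Generate an i.i.d. random genome at a target GC content
#'
#' Bases are drawn independently with \code{p_G = p_C = gc/2} and
#' \code{p_A = p_T = (1 - gc)/2}; reproducible per seed.
#'
#' @param gc Target GC fraction, strictly between 0 and 1.
#' @param length Sequence length in bp.
#' @param seed Integer seed.
#' @return \link[Biostrings]{DNAString}.
#' @export
generate_iid_genome <- function(gc = 0.36, length, seed) {
  if (!(gc > 0 && gc < 1)) {
    stop("gc must be strictly between 0 and 1", call. = FALSE)
  }
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(seed, {
    Biostrings::DNAString(paste0(
      sample(BASES, length, replace = TRUE, prob = probs), collapse = ""))
  })
}

#' A fixed plant-genome-like composition model
#'
#' A first-order transition matrix with the qualitative features of an
#' AT-rich plant nuclear genome: CpG depletion, mild TpA avoidance and
#' same-base (AA/TT) enrichment, with stationary GC close to 0.36. The
#' mononucleotide vector is the stationary distribution of the matrix, so
#' long generated chains have stable composition from the first base.
#'
#' @return \code{composition_model} with source \code{"synthetic-plant-like"}.
#' @export
plantlike_composition <- function() {
  trans <- rbind(
    A = c(A = 0.35, C = 0.17, G = 0.19, T = 0.29),
    C = c(A = 0.32, C = 0.21, G = 0.07, T = 0.40),
    G = c(A = 0.28, C = 0.20, G = 0.20, T = 0.32),
    T = c(A = 0.23, C = 0.17, G = 0.20, T = 0.40))
  ev <- eigen(t(trans))
  i <- which.min(abs(ev$values - 1))
  mono <- Re(ev$vectors[, i]); mono <- mono / sum(mono)
  names(mono) <- BASES
  composition_model(mono, trans, source = "synthetic-plant-like")
}

markov_states <- function(n, mono, cum, u) {
  s <- integer(n)
  cm <- cumsum(mono)
  s[1L] <- 1L + (u[1L] > cm[1L]) + (u[1L] > cm[2L]) + (u[1L] > cm[3L])
  if (n > 1L) {
    c1 <- cum[, 1L]; c2 <- cum[, 2L]; c3 <- cum[, 3L]
    for (i in 2:n) {
      p <- s[i - 1L]
      ui <- u[i]
      s[i] <- if (ui <= c1[p]) 1L else if (ui <= c2[p]) 2L
              else if (ui <= c3[p]) 3L else 4L
    }
  }
  s
}

#' Generate a first-order Markov genome from a composition model
#'
#' The first base is drawn from the mononucleotide probabilities; each
#' subsequent base from the transition row of its predecessor.
#'
#' @param model \code{composition_model}.
#' @param length Sequence length in bp.
#' @param seed Integer seed.
#' @return \link[Biostrings]{DNAString}.
#' @export
generate_markov_genome <- function(model, length, seed) {
  stopifnot(inherits(model, "composition_model"), length >= 1L)
  cum <- t(apply(model$trans, 1L, cumsum))
  with_seed(seed, {
    u <- stats::runif(length)
    s <- markov_states(length, model$mono, cum, u)
    Biostrings::DNAString(paste0(BASES[s], collapse = ""))
  })
}

#' Overwrite exact motif words at fixed positions
#'
#' Plants exact words (reverse-complemented for reverse-strand plants) over
#' the background sequence; all other bases are untouched, so coordinates
#' stay stable. Plants must be in range and non-overlapping.
#'
#' @param sequence \link[Biostrings]{DNAString} or character string.
#' @param plants data.frame with columns \code{word} (exact variant),
#'   \code{position} (0-based start) and \code{strand}
#'   (\code{"forward"}/\code{"reverse"}).
#' @return \link[Biostrings]{DNAString} with the words written in.
#' @export
plant_motifs <- function(sequence, plants) {
  s <- if (is(sequence, "DNAString")) sequence else
    Biostrings::DNAString(toupper(as.character(sequence)))
  if (nrow(plants) == 0L) return(s)
  w <- nchar(plants$word)
  starts <- as.integer(plants$position)
  if (any(starts < 0L) || any(starts + w > length(s))) {
    stop("planted motif out of sequence range", call. = FALSE)
  }
  ir <- IRanges::IRanges(start = starts + 1L, width = w)
  if (!identical(IRanges::reduce(ir), IRanges::reduce(IRanges::disjoin(ir))) ||
      sum(IRanges::width(IRanges::reduce(ir))) != sum(w)) {
    stop("planted motifs overlap", call. = FALSE)
  }
  chars <- strsplit(as.character(s), "")[[1]]
  for (i in seq_len(nrow(plants))) {
    word <- plants$word[i]
    if (identical(plants$strand[i], "reverse")) {
      word <- as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(word)))
    }
    chars[(starts[i] + 1L):(starts[i] + w[i])] <- strsplit(word, "")[[1]]
  }
  Biostrings::DNAString(paste0(chars, collapse = ""))
}

#' Remove accidental motif occurrences from a background sequence
#'
#' Random backgrounds occasionally contain chance occurrences of the very
#' motifs an experiment plants, which would break exact planted-count
#' fixtures. This mutates one base of every non-protected hit (to a random
#' different base) and rescans, until no unprotected occurrence remains.
#'
#' @param sequence \link[Biostrings]{DNAString} or character string.
#' @param motifs List of \code{motif_def} to scrub (default
#'   [default_motifs()]).
#' @param protect Optional \link[IRanges]{IRanges} of 1-based intervals that
#'   must not be mutated (e.g. planted words).
#' @param seed Integer seed for the replacement bases.
#' @param max_iter Safety bound on scrub passes (default 50).
#' @return \link[Biostrings]{DNAString} free of unprotected occurrences.
#' @export
scrub_motifs <- function(sequence, motifs = default_motifs(), protect = NULL,
                         seed = 0L, max_iter = 50L) {
  s <- if (is(sequence, "DNAString")) sequence else
    Biostrings::DNAString(toupper(as.character(sequence)))
  with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      hits <- do.call(rbind, lapply(motifs, function(m) {
        h <- scan_motif(s, m, "both")
        if (nrow(h) > 0L) h$k <- m$k
        h
      }))
      if (is.null(hits) || nrow(hits) == 0L) return(s)
      chars <- strsplit(as.character(s), "")[[1]]
      protected_pos <- if (is.null(protect)) integer(0) else
        unlist(lapply(seq_along(protect), function(i) {
          IRanges::start(protect)[i]:IRanges::end(protect)[i]
        }))
      changed <- FALSE
      for (i in seq_len(nrow(hits))) {
        span <- (hits$position[i] + 1L):(hits$position[i] + hits$k[i])
        if (all(span %in% protected_pos)) next   # a planted word: keep
        free <- setdiff(span, protected_pos)
        if (length(free) == 0L) next
        j <- free[ceiling(length(free) / 2)]
        chars[j] <- sample(setdiff(BASES, chars[j]), 1L)
        changed <- TRUE
      }
      if (!changed) return(s)   # everything left is protected
      s <- Biostrings::DNAString(paste0(chars, collapse = ""))
    }
    stop("scrub_motifs did not converge in ", max_iter, " passes",
         call. = FALSE)
  })
}

#' Build a promoter with an AtSAG12-like motif configuration
#'
#' A 2000-bp i.i.d. background at promoter-like GC (default 0.284), scrubbed
#' of all registry motifs, then planted with five A-boxes in the ATG-proximal
#' kilobase (-1000..0) and two forward plus one reverse W-box further
#' upstream. Scanning the result recovers exactly the planted annotation.
#'
#' @param seed Integer seed.
#' @param gc Background GC fraction (default 0.284).
#' @param length Promoter length (default 2000).
#' @return List with \code{sequence} (\link[Biostrings]{DNAString}) and
#'   \code{plants} (the planted-motif table with \code{motif}, \code{word},
#'   \code{position}, \code{atg_position}, \code{strand}).
#' @export
make_sag12_like_promoter <- function(seed, gc = 0.284, length = 2000L) {
  plants <- data.frame(
    motif = c(rep("A-box", 5L), rep("W-box", 3L)),
    word = c(rep("TACGTA", 5L), "TTGACT", "CTGACC", "TTGACC"),
    atg_position = c(-950L, -800L, -650L, -500L, -200L, -1950L, -1750L, -1550L),
    strand = c(rep("forward", 7L), "reverse"),
    stringsAsFactors = FALSE)
  plants$position <- plants$atg_position + length
  bg <- generate_iid_genome(gc, length, substream_seed(seed, 1L))
  bg <- scrub_motifs(bg, seed = substream_seed(seed, 2L))
  s <- plant_motifs(bg, plants)
  prot <- IRanges::IRanges(start = plants$position + 1L,
                           width = nchar(plants$word))
  s <- scrub_motifs(s, protect = prot, seed = substream_seed(seed, 3L))
  list(sequence = s, plants = plants)
}

#' Write a toy genome + annotation fixture for end-to-end runs
#'
#' Generates \code{n_genes} genes on one contig, each in its own 5000-bp
#' slot with at least 2000 bp of upstream sequence, and writes a FASTA and a
#' GFF3 (gene/mRNA/exon/CDS features; three exons per gene). Regenerating
#' from the same seed gives byte-identical files.
#'
#' @param dir Output directory (created if needed).
#' @param n_genes Number of genes (default 3).
#' @param strands Strand per gene, recycled (default \code{c("+", "-")}).
#' @param gc Background GC fraction (default 0.36).
#' @param seed Integer seed.
#' @param contig_id Contig name (default \code{"chr1"}).
#' @return List with \code{fasta}, \code{gff3} paths, \code{genes} (the gene
#'   table: gene_id, strand, cds_start) and \code{upstream} (named character
#'   vector of each gene's true 2000-bp upstream sequence in gene
#'   orientation, for round-trip checks).
#' @export
make_fixture <- function(dir, n_genes = 3L, strands = c("+", "-"), gc = 0.36,
                         seed = 1L, contig_id = "chr1") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  slot <- 5000L
  clen <- n_genes * slot + 2000L
  genome <- generate_iid_genome(gc, clen, substream_seed(seed, 1L))
  strands <- rep_len(strands, n_genes)

  genes <- data.frame(gene_id = sprintf("gene%02d", seq_len(n_genes)),
                      contig_id = contig_id, strand = strands,
                      cds_start = NA_integer_, stringsAsFactors = FALSE)
  chars <- strsplit(as.character(genome), "")[[1]]
  feat <- list()
  upstream <- character(n_genes)

  for (i in seq_len(n_genes)) {
    base <- (i - 1L) * slot            # 0-based slot start
    if (strands[i] == "+") {
      cds_start <- base + 2501L        # 1-based
      # exons relative to cds_start: CDS split 300/300/300 with 150-bp introns
      ex_s <- cds_start + c(0L, 450L, 900L)
      ex_e <- ex_s + 299L
      chars[cds_start:(cds_start + 2L)] <- c("A", "T", "G")
      up <- paste0(chars[(cds_start - 2000L):(cds_start - 1L)], collapse = "")
    } else {
      cds_start <- base + 2500L
      ex_e <- cds_start - c(0L, 450L, 900L)
      ex_s <- ex_e - 299L
      ex_s <- rev(ex_s); ex_e <- rev(ex_e)     # genomic order
      chars[cds_start:(cds_start - 2L)] <- c("T", "A", "C")  # revcomp ATG
      up <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(
        paste0(chars[(cds_start + 1L):(cds_start + 2000L)], collapse = ""))))
    }
    genes$cds_start[i] <- cds_start
    upstream[i] <- up
    gid <- genes$gene_id[i]
    tid <- paste0(gid, ".1")
    feat[[length(feat) + 1L]] <- data.frame(
      type = c("gene", "mRNA", rep("exon", 3L), rep("CDS", 3L)),
      start = c(min(ex_s), min(ex_s), ex_s, ex_s),
      end = c(max(ex_e), max(ex_e), ex_e, ex_e),
      strand = strands[i],
      ID = c(gid, tid, paste0(tid, ".exon", 1:3), paste0(tid, ".cds", 1:3)),
      Parent = c(NA, gid, rep(tid, 6L)), stringsAsFactors = FALSE)
  }
  names(upstream) <- genes$gene_id
  genome <- Biostrings::DNAString(paste0(chars, collapse = ""))

  fasta <- file.path(dir, "genome.fa")
  dss <- Biostrings::DNAStringSet(genome); names(dss) <- contig_id
  Biostrings::writeXStringSet(dss, fasta)

  ftab <- do.call(rbind, feat)
  gr <- GenomicRanges::GRanges(
    seqnames = contig_id,
    ranges = IRanges::IRanges(start = ftab$start, end = ftab$end),
    strand = ftab$strand)
  S4Vectors::mcols(gr)$type <- ftab$type
  S4Vectors::mcols(gr)$ID <- ftab$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(ftab$Parent, function(p) if (is.na(p)) character(0) else p))
  S4Vectors::mcols(gr)$phase <- ifelse(ftab$type == "CDS", 0L, NA_integer_)
  gff3 <- file.path(dir, "genes.gff3")
  rtracklayer::export.gff3(gr, gff3)

  list(fasta = fasta, gff3 = gff3, genes = genes, upstream = upstream,
       contig_id = contig_id, contig_length = clen)
}
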