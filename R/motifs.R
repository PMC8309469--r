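#' Compile a degenerate hexamer motif
#'
#' Expands an IUPAC-style degenerate pattern (subset \code{A,C,G,T,Y,R}) into
#' its exact-word variants and detects palindromy (the variant set equals its
#' own reverse-complement set). Palindromic boxes such as the A-box
#' (\code{TACGTA}) and T-box (\code{AACGTT}) match identically on both strands,
#' so scanning and probability calculations count them once per position.
#'
#' @param name Motif name, e.g. \code{"W-box"}.
#' @param pattern Degenerate pattern string over \code{A,C,G,T,Y,R}.
#' @return An object of class \code{motif_def} with fields \code{name},
#'   \code{pattern}, \code{variants}, \code{k} and \code{palindromic}.
#' @examples
#' compile_motif("W-box", "YTGACY")
#' @export
compile_motif <- function(name, pattern) {
  stopifnot(is.character(name), length(name) == 1L,
            is.character(pattern), length(pattern) == 1L, nzchar(pattern))
  pattern <- toupper(pattern)
  letters <- strsplit(pattern, "")[[1]]
  expand <- list(A = "A", C = "C", G = "G", T = "T",
                 Y = c("C", "T"), R = c("A", "G"))
  bad <- setdiff(letters, names(expand))
  if (length(bad) > 0L) {
    stop("unsupported pattern symbol(s) in '", pattern, "': ",
         paste(unique(bad), collapse = ", "),
         " (allowed: A, C, G, T, Y, R)", call. = FALSE)
  }
  grid <- expand.grid(lapply(letters, function(x) expand[[x]]),
                      stringsAsFactors = FALSE)
  variants <- sort(apply(grid, 1L, paste0, collapse = ""))
  rc <- sort(as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(variants))))
  structure(
    list(name = name, pattern = pattern, variants = variants,
         k = nchar(pattern), palindromic = identical(variants, rc)),
    class = "motif_def")
}

#' @export
print.motif_def <- function(x, ...) {
  cat(sprintf("<motif_def> %s  pattern=%s  k=%d  variants=%d  palindromic=%s\n",
              x$name, x$pattern, x$k, length(x$variants), x$palindromic))
  invisible(x)
}

#' The default motif registry: the five promoter boxes
#'
#' W-box \code{YTGACY} (WRKY binding site), and the four bZIP-class ACGT-core
#' boxes: A-box \code{TACGTA}, T-box \code{AACGTT}, C-box \code{GACGTA},
#' G-box \code{CACGTA}. A- and T-boxes are reverse-complement palindromes.
#'
#' @return Named list of \code{motif_def} objects.
#' @export
default_motifs <- function() {
  specs <- c("W-box" = "YTGACY", "A-box" = "TACGTA", "T-box" = "AACGTT",
             "C-box" = "GACGTA", "G-box" = "CACGTA")
  out <- lapply(names(specs), function(nm) compile_motif(nm, specs[[nm]]))
  names(out) <- names(specs)
  out
}

#' Read a motif configuration file
#'
#' Plain-text TSV with columns \code{name} and \code{pattern}; lines starting
#' with \code{#} are ignored. Used to extend or replace the default registry.
#'
#' @param path Path to the TSV file.
#' @return Named list of \code{motif_def} objects.
#' @export
read_motif_config <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("name", "pattern") %in% names(tab))) {
    stop("motif config must have columns 'name' and 'pattern'", call. = FALSE)
  }
  out <- lapply(seq_len(nrow(tab)),
                function(i) compile_motif(tab$name[i], tab$pattern[i]))
  names(out) <- tab$name
  out
}

empty_hits <- function() {
  data.frame(motif = character(0), position = integer(0),
             strand = character(0), matched_word = character(0),
             stringsAsFactors = FALSE)
}

#' Scan a sequence for a motif on one or both strands
#'
#' Tests every start position \code{0..L-k} (0-based); overlapping occurrences
#' are all reported. Reverse-orientation hits are found by matching the
#' reverse complement of the pattern on the given strand, so reported positions
#' always refer to the scanned sequence. Palindromic motifs are reported once
#' per position with strand \code{"forward"} to avoid double counting.
#' Windows containing \code{N} never match.
#'
#' @param sequence A single character string or \link[Biostrings]{DNAString}.
#' @param motif A \code{motif_def} from [compile_motif()].
#' @param strands \code{"both"} (default) or \code{"forward_only"}.
#' @return data.frame with columns \code{motif}, \code{position} (0-based
#'   start), \code{strand} (\code{"forward"}/\code{"reverse"}) and
#'   \code{matched_word} (the hexamer as it appears on the scanned strand),
#'   ordered by position then strand.
#' @examples
#' m <- compile_motif("W-box", "YTGACY")
#' scan_motif("AGTCAA", m)          # one reverse hit at 0
#' @export
scan_motif <- function(sequence, motif, strands = c("both", "forward_only")) {
  strands <- match.arg(strands)
  stopifnot(inherits(motif, "motif_def"))
  subj <- if (is(sequence, "DNAString")) sequence else
    Biostrings::DNAString(toupper(as.character(sequence)))
  if (length(subj) < motif$k) return(empty_hits())

  hit_rows <- function(pattern, strand) {
    m <- Biostrings::matchPattern(pattern, subj, fixed = "subject")
    if (length(m) == 0L) return(empty_hits())
    data.frame(motif = motif$name, position = Biostrings::start(m) - 1L,
               strand = strand, matched_word = as.character(m),
               stringsAsFactors = FALSE)
  }

  out <- hit_rows(motif$pattern, "forward")
  if (strands == "both" && !motif$palindromic) {
    rc_pat <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(motif$pattern)))
    out <- rbind(out, hit_rows(rc_pat, "reverse"))
  }
  out[order(out$position, out$strand), , drop = FALSE]
}

#' Count motif occurrences in a region, optionally within sub-windows
#'
#' Sub-windows are given in ATG-relative coordinates for promoter sequences:
#' the base immediately 5' of the A of ATG is position -1, so a 2000-bp
#' promoter spans -2000..-1 and a window \code{c(-1000, 0)} (half-open
#' \code{[from, to)}) covers its 3' kilobase. A hit is counted in a window iff
#' the whole hexamer lies inside it.
#'
#' @inheritParams scan_motif
#' @param windows Optional list of \code{c(from, to)} ATG-relative half-open
#'   intervals.
#' @return List with \code{total}, \code{forward}, \code{reverse} counts,
#'   \code{hits} (the hit table with an added \code{atg_position} column) and,
#'   when \code{windows} is given, \code{window_counts} (one total per window).
#' @export
count_in_region <- function(sequence, motif, strands = c("both", "forward_only"),
                            windows = NULL) {
  strands <- match.arg(strands)
  hits <- scan_motif(sequence, motif, strands)
  L <- if (is(sequence, "DNAString")) length(sequence) else nchar(sequence)
  hits$atg_position <- hits$position - L
  out <- list(total = nrow(hits),
              forward = sum(hits$strand == "forward"),
              reverse = sum(hits$strand == "reverse"),
              hits = hits)
  if (!is.null(windows)) {
    out$window_counts <- vapply(windows, function(w) {
      sum(hits$atg_position >= w[1] & hits$atg_position + motif$k <= w[2])
    }, integer(1))
  }
  out
}

#' Scan a set of sequences for a set of motifs
#'
#' @param sequences \link[Biostrings]{DNAStringSet} or named character vector.
#' @param motifs List of \code{motif_def} objects (default [default_motifs()]).
#' @param strands \code{"both"} or \code{"forward_only"}.
#' @return data.frame of hits with a leading \code{seq_id} column.
#' @export
scan_set <- function(sequences, motifs = default_motifs(),
                     strands = c("both", "forward_only")) {
  strands <- match.arg(strands)
  if (!is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(toupper(sequences))
  }
  ids <- names(sequences)
  if (is.null(ids)) ids <- as.character(seq_along(sequences))
  res <- lapply(seq_along(sequences), function(i) {
    per_motif <- lapply(motifs, function(m) {
      scan_motif(sequences[[i]], m, strands)
    })
    tab <- do.call(rbind, per_motif)
    if (nrow(tab) > 0L) tab <- cbind(seq_id = ids[i], tab)
    tab
  })
  res <- res[vapply(res, function(x) !is.null(x) && nrow(x) > 0L, logical(1))]
  if (length(res) == 0L) {
    return(cbind(seq_id = character(0), empty_hits()))
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
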