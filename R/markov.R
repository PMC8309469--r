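BASES <- c("A", "C", "G", "T")

#' Build a composition model from explicit probabilities
#'
#' @param mono Named numeric of length 4 (A, C, G, T), summing to 1.
#' @param trans 4x4 matrix of conditional probabilities p(column | row),
#'   rows summing to 1; dimnames A,C,G,T.
#' @param source Provenance label, e.g. \code{"whole-genome"},
#'   \code{"GC-stratified"} or \code{"custom"}.
#' @param n_sites Number of bases the estimates are based on (NA if synthetic).
#' @return Object of class \code{composition_model}.
#' @export
composition_model <- function(mono, trans, source = "custom", n_sites = NA_real_) {
  mono <- mono[BASES]
  trans <- trans[BASES, BASES]
  stopifnot(all(!is.na(mono)), all(!is.na(trans)),
            all(mono >= 0), all(trans >= 0),
            abs(sum(mono) - 1) < 1e-9)
  rs <- rowSums(trans)
  if (any(abs(rs - 1) > 1e-9)) {
    stop("each transition row must sum to 1 (rows: ",
         paste(sprintf("%s=%.6f", BASES, rs), collapse = ", "), ")",
         call. = FALSE)
  }
  structure(list(mono = mono, trans = trans, source = source,
                 n_sites = n_sites,
                 exhausted = any(mono == 0) || any(trans == 0)),
            class = "composition_model")
}

#' @export
print.composition_model <- function(x, ...) {
  cat(sprintf("<composition_model> source=%s  n_sites=%s  GC=%.4f\n",
              x$source, format(x$n_sites), x$mono[["G"]] + x$mono[["C"]]))
  cat("mono:\n"); print(round(x$mono, 4))
  cat("trans p(col|row):\n"); print(round(x$trans, 4))
  invisible(x)
}

#' Estimate mono- and dinucleotide composition from sequences
#'
#' Mononucleotide probabilities come from single-base counts and transition
#' probabilities from adjacent-pair counts; pairs never span sequence or
#' fragment boundaries, and windows containing \code{N} are excluded from the
#' counts. A base that is never observed keeps probability zero and the model
#' is flagged (\code{exhausted = TRUE}).
#'
#' @param sequences \link[Biostrings]{DNAStringSet}, character vector,
#'   \link[Biostrings]{DNAString}, or a single string.
#' @param source Provenance label stored in the model.
#' @return \code{composition_model}.
#' @examples
#' m <- estimate_composition("ACACAC")
#' m$trans["A", "C"]  # 1
#' @export
estimate_composition <- function(sequences, source = "custom") {
  if (is(sequences, "DNAString")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  if (!is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(toupper(as.character(sequences)))
  }
  c1 <- colSums(Biostrings::oligonucleotideFrequency(sequences, 1L))[BASES]
  c2 <- colSums(Biostrings::oligonucleotideFrequency(sequences, 2L))
  n <- sum(c1)
  if (n < 2) stop("need at least 2 usable bases to estimate composition",
                  call. = FALSE)
  pair <- matrix(c2[paste0(rep(BASES, each = 4L), rep(BASES, 4L))],
                 nrow = 4L, byrow = TRUE, dimnames = list(BASES, BASES))
  rs <- rowSums(pair)
  trans <- pair / ifelse(rs > 0, rs, 1)
  # a base with no observed outgoing pair gets a uniform row so rows sum to 1;
  # the exhausted flag records that its probabilities are unsupported by data
  trans[rs == 0, ] <- 0.25
  mono <- c1 / n
  m <- composition_model(mono, trans, source = source, n_sites = n)
  m$exhausted <- any(c1 == 0) || any(rs == 0)
  m
}

chain_prob_word <- function(word, model) {
  idx <- match(strsplit(word, "")[[1]], BASES)
  p <- model$mono[[idx[1L]]]
  if (length(idx) > 1L) {
    for (i in seq_len(length(idx) - 1L)) {
      p <- p * model$trans[idx[i], idx[i + 1L]]
    }
  }
  p
}

#' First-order Markov chain probability of a motif per start position
#'
#' The first base of a word is treated as an independent event drawn from the
#' mononucleotide probabilities; every subsequent base is conditioned on its
#' predecessor through the dinucleotide transition probabilities. For the
#' A-box \code{TACGTA} this is pT x p(A|T) x p(C|A) x p(G|C) x p(T|G) x
#' p(A|T). The motif probability is the sum over all exact variants; with
#' \code{strands = "both"} the reverse-complement variants are added, except
#' for palindromic motifs whose variant set is its own reverse complement.
#'
#' @param motif \code{motif_def} from [compile_motif()].
#' @param model \code{composition_model}.
#' @param strands \code{"both"} (default) or \code{"forward_only"}.
#' @return Probability that a given start position begins a motif occurrence.
#' @export
motif_probability <- function(motif, model, strands = c("both", "forward_only")) {
  strands <- match.arg(strands)
  stopifnot(inherits(motif, "motif_def"),
            inherits(model, "composition_model"))
  words <- motif$variants
  if (strands == "both" && !motif$palindromic) {
    rc <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(motif$variants)))
    words <- c(words, rc)
  }
  sum(vapply(words, chain_prob_word, numeric(1), model = model))
}

#' Expected motif count in a window
#'
#' A window of \code{L} bp holds \code{L - k + 1} possible start positions for
#' a \code{k}-mer, so the expected number of occurrences is
#' \code{p_motif * (L - k + 1)}; by linearity of expectation this is exact
#' even though neighbouring windows overlap.
#'
#' @param p_motif Per-start-position occurrence probability.
#' @param L Window length in bp.
#' @param k Motif length in bp (default 6).
#' @return Expected occurrence count.
#' @examples
#' expected_count(0.00105, 2000)  # 2.0948 random W-boxes per 2000-bp fragment
#' @export
expected_count <- function(p_motif, L, k = 6L) {
  stopifnot(p_motif >= 0, p_motif <= 1)
  if (L < k) stop("window length L (", L, ") must be >= motif length k (",
                  k, ")", call. = FALSE)
  p_motif * (L - k + 1)
}

#' Enrichment fold of an observed count over an expectation
#'
#' @param observed Observed count.
#' @param expected Expected (or background-average) count; must be > 0.
#' @return \code{observed / expected}.
#' @examples
#' enrichment(5, 0.349)  # ~14.3-fold, the AtSAG12-style A-box excess
#' @export
enrichment <- function(observed, expected) {
  stopifnot(observed >= 0)
  if (!is.finite(expected) || expected <= 0) {
    stop("enrichment undefined: expected count must be positive", call. = FALSE)
  }
  observed / expected
}

#' Observed-versus-expected motif report for a region set
#'
#' Scans each region for each motif with the given strand policy, and compares
#' the mean observed count per region with the first-order Markov expectation
#' from the supplied composition model. Observation and expectation use the
#' same strand policy (palindromes counted once per position), so the two are
#' commensurable. Regions of unequal length contribute expectations at their
#' own length; the reported \code{L} is the mean region length.
#'
#' @param regions \link[Biostrings]{DNAStringSet} (fragments or promoters).
#' @param motifs List of \code{motif_def} (default [default_motifs()]).
#' @param model \code{composition_model}.
#' @param strands \code{"both"} or \code{"forward_only"}.
#' @return data.frame with one row per motif: \code{motif},
#'   \code{model_source}, \code{p_motif}, \code{L}, \code{positions},
#'   \code{expected}, \code{observed_mean}, \code{n_regions},
#'   \code{enrichment_fold}.
#' @export
observed_vs_expected_report <- function(regions, motifs = default_motifs(),
                                        model,
                                        strands = c("both", "forward_only")) {
  strands <- match.arg(strands)
  if (!is(regions, "DNAStringSet")) {
    regions <- Biostrings::DNAStringSet(toupper(regions))
  }
  widths <- Biostrings::width(regions)
  n <- length(regions)
  rows <- lapply(motifs, function(m) {
    p <- motif_probability(m, model, strands)
    hits <- vapply(seq_len(n), function(i) {
      nrow(scan_motif(regions[[i]], m, strands))
    }, numeric(1))
    exp_per_region <- vapply(widths, function(L) {
      if (L >= m$k) expected_count(p, L, m$k) else 0
    }, numeric(1))
    expected <- mean(exp_per_region)
    obs <- mean(hits)
    data.frame(motif = m$name, model_source = model$source, p_motif = p,
               L = mean(widths), positions = mean(pmax(widths - m$k + 1L, 0L)),
               expected = expected, observed_mean = obs, n_regions = n,
               enrichment_fold = if (expected > 0) obs / expected else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize / read a composition model as plain text
#'
#' Writes a TSV of the 4 mononucleotide and 16 transition probabilities with a
#' provenance header.
#'
#' @param model \code{composition_model}.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_composition_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# composition_model source=%s n_sites=%s",
                     model$source, format(model$n_sites)), con)
  writeLines("term\tvalue", con)
  for (b in BASES) {
    writeLines(sprintf("p%s\t%.17g", b, model$mono[[b]]), con)
  }
  for (b1 in BASES) for (b2 in BASES) {
    writeLines(sprintf("p%s%s\t%.17g", b1, b2, model$trans[b1, b2]), con)
  }
  invisible(path)
}

#' @rdname write_composition_model
#' @export
read_composition_model <- function(path) {
  hdr <- readLines(path, n = 1L)
  source <- sub(".*source=(\\S+).*", "\\1", hdr)
  n_sites <- suppressWarnings(as.numeric(sub(".*n_sites=(\\S+).*", "\\1", hdr)))
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  vals <- stats::setNames(tab$value, tab$term)
  mono <- stats::setNames(vals[paste0("p", BASES)], BASES)
  trans <- matrix(vals[paste0("p", rep(BASES, each = 4L), rep(BASES, 4L))],
                  nrow = 4L, byrow = TRUE, dimnames = list(BASES, BASES))
  composition_model(mono, trans, source = source, n_sites = n_sites)
}
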