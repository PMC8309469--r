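# Independent oracles and small fixture builders used across the suite.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Naive scanner: test every window against every expanded variant.
# Deliberately independent of scan_motif()'s matchPattern-based path.
naive_scan <- function(sequence, motif, strands = "both") {
  s <- toupper(as.character(sequence))
  L <- nchar(s)
  k <- motif$k
  if (L < k) {
    return(data.frame(position = integer(0), strand = character(0)))
  }
  rows <- list()
  for (p in 0:(L - k)) {
    w <- substr(s, p + 1, p + k)
    if (w %in% motif$variants) {
      rows[[length(rows) + 1]] <- data.frame(position = p, strand = "forward")
    }
    if (strands == "both" && !motif$palindromic &&
        revcomp(w) %in% motif$variants && !grepl("N", w)) {
      rows[[length(rows) + 1]] <- data.frame(position = p, strand = "reverse")
    }
  }
  out <- if (length(rows) == 0) {
    data.frame(position = integer(0), strand = character(0))
  } else {
    do.call(rbind, rows)
  }
  out[order(out$position, out$strand), , drop = FALSE]
}

all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
  apply(g, 1, paste0, collapse = "")
}

# Exhaustive chain probability of a single word under a composition model.
enum_word_prob <- function(word, model) {
  ch <- strsplit(word, "")[[1]]
  p <- model$mono[[ch[1]]]
  for (i in seq_len(length(ch) - 1)) p <- p * model$trans[ch[i], ch[i + 1]]
  p
}

# Brute-force motif probability: sum chain probabilities over all 4096
# hexamers that belong to the (variant union revcomp-variant) word set.
enum_motif_prob <- function(motif, model, strands = "both") {
  words <- motif$variants
  if (strands == "both" && !motif$palindromic) {
    words <- union(words, vapply(motif$variants, revcomp, character(1)))
  }
  hex <- all_hexamers()
  sum(vapply(hex[hex %in% words], enum_word_prob, numeric(1), model = model))
}

random_composition <- function(seed) {
  set.seed(seed)
  b <- c("A", "C", "G", "T")
  mono <- stats::runif(4, 0.05, 1)
  mono <- stats::setNames(mono / sum(mono), b)
  trans <- t(vapply(1:4, function(i) {
    r <- stats::runif(4, 0.05, 1)
    r / sum(r)
  }, numeric(4)))
  dimnames(trans) <- list(b, b)
  composition_model(mono, trans)
}

write_toy_gff <- function(path, lines) {
  writeLines(c("##gff-version 3", lines), path)
  path
}

random_dna <- function(n, gc = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE,
                prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
         collapse = "")
}
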