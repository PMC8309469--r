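parse_record_ids <- function(ids) {
  has_sp <- grepl("|", ids, fixed = TRUE)
  species <- ifelse(has_sp, sub("\\|.*$", "", ids), NA_character_)
  gene <- ifelse(has_sp, sub("^[^|]*\\|", "", ids), ids)
  data.frame(record_id = ids, species = species, gene_id = gene,
             stringsAsFactors = FALSE)
}

#' Annotate a promoter set with motif hits in ATG-relative coordinates
#'
#' Each promoter is scanned for every motif on the requested strands; hit
#' positions are reported relative to the ATG start codon (position -1 is the
#' base immediately 5' of the A, so a full-length 2000-bp promoter yields hit
#' starts in \code{[-2000, -k]}). Record names of the form
#' \code{species|gene_id} are split; otherwise the whole name is the gene id.
#' Records shorter than the motif length get zero hits and are flagged.
#'
#' @param promoters \link[Biostrings]{DNAStringSet}, named character vector,
#'   or promoter data.frame from [extract_promoters()] (in which case
#'   truncation flags are carried over).
#' @param motifs List of \code{motif_def} (default [default_motifs()]).
#' @param strands \code{"both"} or \code{"forward_only"}.
#' @return List of class \code{promoter_annotation} with elements
#'   \code{hits} (data.frame: species, gene_id, motif, atg_position, position,
#'   strand, matched_word), \code{counts} (data.frame: species, gene_id,
#'   length, truncated, then one count column per motif and per-strand
#'   \code{<motif>_fwd}/\code{_rev} columns) and \code{motifs}.
#' @export
annotate_promoter_set <- function(promoters, motifs = default_motifs(),
                                  strands = c("both", "forward_only")) {
  strands <- match.arg(strands)
  truncated <- NULL
  if (is.data.frame(promoters)) {
    truncated <- stats::setNames(promoters$truncated, promoters$gene_id)
    promoters <- promoter_seqs(promoters)
  }
  if (!is(promoters, "DNAStringSet")) {
    promoters <- Biostrings::DNAStringSet(toupper(promoters))
  }
  if (is.null(names(promoters))) {
    names(promoters) <- as.character(seq_along(promoters))
  }
  meta <- parse_record_ids(names(promoters))
  ord <- order(meta$species, meta$gene_id, method = "radix")
  promoters <- promoters[ord]
  meta <- meta[ord, , drop = FALSE]
  widths <- Biostrings::width(promoters)

  hit_rows <- vector("list", length(promoters))
  counts <- data.frame(species = meta$species, gene_id = meta$gene_id,
                       length = widths,
                       truncated = if (is.null(truncated)) FALSE else
                         unname(truncated[meta$gene_id]),
                       stringsAsFactors = FALSE)
  for (m in motifs) {
    counts[[m$name]] <- 0L
    counts[[paste0(m$name, "_fwd")]] <- 0L
    counts[[paste0(m$name, "_rev")]] <- 0L
  }
  counts$too_short <- widths < min(vapply(motifs, `[[`, numeric(1), "k"))

  for (i in seq_along(promoters)) {
    per <- lapply(motifs, function(m) scan_motif(promoters[[i]], m, strands))
    tab <- do.call(rbind, per)
    for (j in seq_along(motifs)) {
      m <- motifs[[j]]
      h <- per[[j]]
      counts[[m$name]][i] <- nrow(h)
      counts[[paste0(m$name, "_fwd")]][i] <- sum(h$strand == "forward")
      counts[[paste0(m$name, "_rev")]][i] <- sum(h$strand == "reverse")
    }
    if (nrow(tab) > 0L) {
      hit_rows[[i]] <- data.frame(
        species = meta$species[i], gene_id = meta$gene_id[i],
        motif = tab$motif, atg_position = tab$position - widths[i],
        position = tab$position, strand = tab$strand,
        matched_word = tab$matched_word, stringsAsFactors = FALSE)
    }
  }
  hits <- do.call(rbind, hit_rows[!vapply(hit_rows, is.null, logical(1))])
  if (is.null(hits)) {
    hits <- data.frame(species = character(0), gene_id = character(0),
                       motif = character(0), atg_position = integer(0),
                       position = integer(0), strand = character(0),
                       matched_word = character(0), stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  structure(list(hits = hits, counts = counts, motifs = motifs,
                 strands = strands),
            class = "promoter_annotation")
}

#' @export
print.promoter_annotation <- function(x, ...) {
  cat(sprintf("<promoter_annotation> %d promoters, %d hits, motifs: %s\n",
              nrow(x$counts), nrow(x$hits),
              paste(vapply(x$motifs, `[[`, character(1), "name"),
                    collapse = ", ")))
  invisible(x)
}

#' Per-promoter count distribution for one motif
#'
#' Truncated promoters are excluded by default: their counts are not
#' comparable with full-length promoters at a fixed window length.
#'
#' @param annotations \code{promoter_annotation} from
#'   [annotate_promoter_set()].
#' @param motif_name Name of a motif present in the annotation.
#' @param focal_gene Optional gene id whose count is marked against the
#'   distribution (e.g. a focal promoter versus the genome-wide histogram).
#' @param include_truncated Include truncated promoters (default FALSE).
#' @return List of class \code{count_distribution}: \code{motif},
#'   \code{histogram} (data.frame count / n_promoters), \code{mean},
#'   \code{n_promoters}, and optional \code{focal_gene}/\code{focal_count}.
#' @export
count_distribution <- function(annotations, motif_name, focal_gene = NULL,
                               include_truncated = FALSE) {
  stopifnot(inherits(annotations, "promoter_annotation"))
  cts <- annotations$counts
  if (!motif_name %in% names(cts)) {
    stop("unknown motif '", motif_name, "'", call. = FALSE)
  }
  keep <- if (include_truncated) rep(TRUE, nrow(cts)) else !cts$truncated
  if (!any(keep)) stop("no promoters left after truncation filter",
                       call. = FALSE)
  x <- cts[[motif_name]][keep]
  tab <- table(x)
  hist <- data.frame(count = as.integer(names(tab)),
                     n_promoters = as.integer(tab))
  out <- list(motif = motif_name, histogram = hist, mean = mean(x),
              n_promoters = length(x))
  if (!is.null(focal_gene)) {
    i <- match(focal_gene, cts$gene_id)
    if (is.na(i)) stop("focal gene '", focal_gene, "' not in annotation",
                       call. = FALSE)
    out$focal_gene <- focal_gene
    out$focal_count <- cts[[motif_name]][i]
  }
  structure(out, class = "count_distribution")
}

#' @export
print.count_distribution <- function(x, ...) {
  cat(sprintf("<count_distribution> %s: mean %.3f over %d promoters\n",
              x$motif, x$mean, x$n_promoters))
  print(x$histogram, row.names = FALSE)
  if (!is.null(x$focal_gene)) {
    cat(sprintf("focal %s: %d\n", x$focal_gene, x$focal_count))
  }
  invisible(x)
}

#' Side-by-side motif track table for promoter families
#'
#' Produces one row per (promoter, hit) with family id, ordered for
#' side-by-side comparison of ortholog-family promoters; promoters with no
#' hits are retained as a single empty row. Motifs present (any strand) in at
#' least \code{shared_fraction} of a family's members are flagged in the
#' \code{shared} summary.
#'
#' @param annotations \code{promoter_annotation}.
#' @param families data.frame with columns \code{family_id} and
#'   \code{record_id} (gene id or \code{species|gene} record name), or NULL to
#'   treat all promoters as one family.
#' @param shared_fraction Sharing threshold, default 0.5.
#' @return List with \code{tracks} (data.frame: family_id, species, gene_id,
#'   truncated, motif, atg_position, strand) and \code{shared} (data.frame:
#'   family_id, motif, n_with, n_members, fraction, shared).
#' @export
family_track_table <- function(annotations, families = NULL,
                               shared_fraction = 0.5) {
  stopifnot(inherits(annotations, "promoter_annotation"))
  cts <- annotations$counts
  gene_key <- ifelse(is.na(cts$species), cts$gene_id,
                     paste(cts$species, cts$gene_id, sep = "|"))
  if (is.null(families)) {
    families <- data.frame(family_id = "all", record_id = gene_key,
                           stringsAsFactors = FALSE)
  }
  fam_of <- stats::setNames(families$family_id, families$record_id)
  fam <- fam_of[gene_key]
  missing <- is.na(fam) & gene_key %in% cts$gene_id
  fam[is.na(fam)] <- fam_of[cts$gene_id][is.na(fam)]

  rows <- lapply(seq_len(nrow(cts)), function(i) {
    if (is.na(fam[i])) return(NULL)
    h <- annotations$hits[annotations$hits$gene_id == cts$gene_id[i] &
                            (is.na(cts$species[i]) |
                               annotations$hits$species %in% cts$species[i]), ,
                          drop = FALSE]
    if (nrow(h) == 0L) {
      return(data.frame(family_id = fam[[i]], species = cts$species[i],
                        gene_id = cts$gene_id[i], truncated = cts$truncated[i],
                        motif = NA_character_, atg_position = NA_integer_,
                        strand = NA_character_, stringsAsFactors = FALSE))
    }
    data.frame(family_id = fam[[i]], species = cts$species[i],
               gene_id = cts$gene_id[i], truncated = cts$truncated[i],
               motif = h$motif, atg_position = h$atg_position,
               strand = h$strand, stringsAsFactors = FALSE)
  })
  tracks <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(tracks) <- NULL

  motif_names <- vapply(annotations$motifs, `[[`, character(1), "name")
  shared <- do.call(rbind, lapply(unique(tracks$family_id), function(f) {
    members <- unique(tracks$gene_id[tracks$family_id == f])
    do.call(rbind, lapply(motif_names, function(mn) {
      with_m <- vapply(members, function(g) {
        any(tracks$family_id == f & tracks$gene_id == g &
              !is.na(tracks$motif) & tracks$motif == mn)
      }, logical(1))
      data.frame(family_id = f, motif = mn, n_with = sum(with_m),
                 n_members = length(members),
                 fraction = sum(with_m) / length(members),
                 shared = sum(with_m) / length(members) >= shared_fraction,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(shared) <- NULL
  list(tracks = tracks, shared = shared)
}

#' Export promoter-annotation hits as BED6
#'
#' Coordinates are promoter-local (0-based start on the promoter sequence);
#' the name field is the motif, the score the ATG-relative start.
#'
#' @param annotations \code{promoter_annotation}.
#' @param path Output BED path.
#' @return Invisibly, \code{path}.
#' @export
write_annotation_bed <- function(annotations, path) {
  h <- annotations$hits
  k <- vapply(annotations$motifs, `[[`, numeric(1), "k")
  kk <- k[match(h$motif, names(k))]
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t%s",
                   ifelse(is.na(h$species), h$gene_id,
                          paste(h$species, h$gene_id, sep = "|")),
                   h$position, h$position + kk, h$motif, h$atg_position,
                   ifelse(h$strand == "forward", "+", "-"))
  writeLines(lines, path)
  invisible(path)
}
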