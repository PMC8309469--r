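planted_family <- function() {
  # three promoters with known planted boxes on clean (scrubbed) backgrounds
  mk <- function(seed, plants) {
    bg <- scrub_motifs(generate_iid_genome(0.3, 2000, seed), seed = seed + 100)
    plant_motifs(bg, plants)
  }
  p1 <- mk(1, data.frame(word = c("TTGACT", "TACGTA"),
                         position = c(600, 1500), strand = "forward"))
  p2 <- mk(2, data.frame(word = "TTGACT", position = c(600),
                         strand = "reverse"))
  p3 <- mk(3, data.frame(word = character(0), position = integer(0),
                         strand = character(0)))
  dss <- Biostrings::DNAStringSet(c(as.character(p1), as.character(p2),
                                    as.character(p3)))
  names(dss) <- c("ath|geneA", "aly|geneB", "aly|geneC")
  dss
}

test_that("annotate_promoter_set recovers planted hits in ATG-relative coordinates", {
  dss <- planted_family()
  ann <- annotate_promoter_set(dss)
  expect_s3_class(ann, "promoter_annotation")
  # deterministic ordering: species then gene_id
  expect_equal(ann$counts$gene_id, c("geneB", "geneC", "geneA"))

  hA <- ann$hits[ann$hits$gene_id == "geneA", ]
  expect_setequal(hA$motif, c("W-box", "A-box"))
  expect_equal(sort(hA$atg_position), c(-1400L, -500L))
  expect_equal(hA$position, hA$atg_position + 2000L)

  hB <- ann$hits[ann$hits$gene_id == "geneB", ]
  expect_equal(hB$strand, "reverse")
  expect_equal(hB$atg_position, -1400L)

  expect_equal(sum(ann$hits$gene_id == "geneC"), 0L)
  cts <- ann$counts
  expect_equal(cts[cts$gene_id == "geneB", "W-box_rev"], 1L)
  expect_equal(cts[cts$gene_id == "geneA", "A-box"], 1L)
})

test_that("annotation is invariant under record reordering", {
  dss <- planted_family()
  a1 <- annotate_promoter_set(dss)
  a2 <- annotate_promoter_set(rev(dss))
  expect_equal(a1$counts, a2$counts)
  expect_equal(a1$hits, a2$hits)
})

test_that("a single planted A-box in a poly-A promoter lands at its planted position", {
  s <- plant_motifs(strrep("A", 2000),
                    data.frame(word = "TACGTA", position = 700,
                               strand = "forward"))
  dss <- Biostrings::DNAStringSet(as.character(s))
  names(dss) <- "toy"
  ann <- annotate_promoter_set(dss)
  expect_equal(nrow(ann$hits), 1L)
  expect_equal(ann$hits$atg_position, -1300L)
})

test_that("count_distribution histogram, mean and focal marking are exact", {
  counts <- c(0L, 0L, 1L, 3L)
  dss <- Biostrings::DNAStringSet(vapply(counts, function(n) {
    plants <- if (n == 0) {
      data.frame(word = character(0), position = integer(0),
                 strand = character(0))
    } else {
      data.frame(word = "TACGTA", position = seq(100, by = 300,
                                                 length.out = n),
                 strand = "forward")
    }
    as.character(plant_motifs(strrep("A", 2000), plants))
  }, character(1)))
  names(dss) <- paste0("g", 1:4)
  ann <- annotate_promoter_set(dss)
  d <- count_distribution(ann, "A-box", focal_gene = "g4")
  expect_equal(d$mean, 1.0)
  expect_equal(d$n_promoters, 4L)
  expect_equal(d$histogram,
               data.frame(count = c(0L, 1L, 3L), n_promoters = c(2L, 1L, 1L)))
  expect_equal(sum(d$histogram$n_promoters), d$n_promoters)
  expect_equal(d$focal_count, 3L)
  # mean equals total hits / n_promoters exactly
  expect_equal(d$mean, sum(ann$counts[["A-box"]]) / nrow(ann$counts))
  # all-zero distribution
  expect_equal(count_distribution(ann, "G-box")$mean, 0)
  expect_error(count_distribution(ann, "Z-box"), "unknown motif")
})

test_that("truncated promoters are excluded from distributions by default", {
  pr <- data.frame(gene_id = c("a", "b"),
                   sequence = c(strrep("A", 2000),
                                as.character(plant_motifs(
                                  strrep("A", 1000),
                                  data.frame(word = "TACGTA", position = 10,
                                             strand = "forward")))),
                   requested_length = 2000L, actual_length = c(2000L, 1000L),
                   contig_id = "c", start = 0L, end = c(2000L, 1000L),
                   strand = "+", truncated = c(FALSE, TRUE),
                   stringsAsFactors = FALSE)
  ann <- annotate_promoter_set(pr)
  expect_equal(count_distribution(ann, "A-box")$n_promoters, 1L)
  expect_equal(count_distribution(ann, "A-box")$mean, 0)
  expect_equal(count_distribution(ann, "A-box",
                                  include_truncated = TRUE)$mean, 0.5)
})

test_that("family tracks report shared planted motifs and keep empty promoters", {
  mk <- function(seed) {
    bg <- scrub_motifs(generate_iid_genome(0.3, 2000, seed), seed = seed + 10)
    plant_motifs(bg, data.frame(word = "CTGACC", position = 600,
                                strand = "forward"))
  }
  dss <- Biostrings::DNAStringSet(c(as.character(mk(4)), as.character(mk(5)),
                                    as.character(scrub_motifs(
                                      generate_iid_genome(0.3, 2000, 6),
                                      seed = 16))))
  names(dss) <- c("f1_m1", "f1_m2", "f1_m3")
  ann <- annotate_promoter_set(dss)
  fam <- data.frame(family_id = "fam1", record_id = names(dss))
  tt <- family_track_table(ann, fam)

  wrows <- tt$tracks[!is.na(tt$tracks$motif) & tt$tracks$motif == "W-box", ]
  expect_equal(wrows$gene_id, c("f1_m1", "f1_m2"))
  expect_equal(wrows$atg_position, c(-1400L, -1400L))
  # hit-free promoter retained as an empty row
  expect_true("f1_m3" %in% tt$tracks$gene_id)
  expect_true(all(is.na(tt$tracks$motif[tt$tracks$gene_id == "f1_m3"])))

  sh <- tt$shared
  expect_equal(sh$n_members, rep(3L, 5))
  expect_true(sh$shared[sh$motif == "W-box"])     # 2/3 >= 0.5
  expect_false(sh$shared[sh$motif == "A-box"])    # 0/3
  # threshold is configurable
  tt90 <- family_track_table(ann, fam, shared_fraction = 0.9)
  expect_false(tt90$shared$shared[tt90$shared$motif == "W-box"])
})

test_that("annotation BED export writes one line per hit", {
  dss <- planted_family()
  ann <- annotate_promoter_set(dss)
  bed <- tempfile(fileext = ".bed")
  write_annotation_bed(ann, bed)
  lines <- readLines(bed)
  expect_length(lines, nrow(ann$hits))
  f <- strsplit(lines[1], "\t")[[1]]
  expect_length(f, 6L)
  expect_equal(as.integer(f[3]) - as.integer(f[2]), 6L)
})
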