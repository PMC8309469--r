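test_that("read_genome preserves order, upper-cases, and warns on empty files", {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">c1 some description", "ACGTACGTAC",
               ">c2", "acgtacgtacgtacgtacgt"), fa)
  g <- read_genome(fa)
  expect_equal(names(g), c("c1", "c2"))
  expect_equal(unname(Biostrings::width(g)), c(10L, 20L))
  expect_equal(as.character(g[["c2"]]), strrep("ACGT", 5))

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_warning(read_genome(empty), "no records")
  expect_error(read_genome(tempfile()), "not found")
})

test_that("read_annotation derives strand-aware CDS starts and picks the first transcript", {
  gff <- write_toy_gff(tempfile(fileext = ".gff3"), c(
    "chr1\tt\tgene\t101\t400\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t101\t400\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tt\texon\t101\t400\t.\t+\t.\tID=g1.e1;Parent=g1.t1",
    "chr1\tt\tCDS\t101\t400\t.\t+\t0\tID=g1.c1;Parent=g1.t1",
    "chr1\tt\tgene\t101\t400\t.\t-\t.\tID=g2",
    "chr1\tt\tmRNA\t101\t400\t.\t-\t.\tID=g2.t1;Parent=g2",
    "chr1\tt\texon\t101\t400\t.\t-\t.\tID=g2.e1;Parent=g2.t1",
    "chr1\tt\tCDS\t101\t400\t.\t-\t0\tID=g2.c1;Parent=g2.t1",
    "chr1\tt\tgene\t501\t800\t.\t+\t.\tID=g3",
    "chr1\tt\tmRNA\t501\t800\t.\t+\t.\tID=g3.t1;Parent=g3",
    "chr1\tt\texon\t501\t600\t.\t+\t.\tID=g3.t1e1;Parent=g3.t1",
    "chr1\tt\texon\t701\t800\t.\t+\t.\tID=g3.t1e2;Parent=g3.t1",
    "chr1\tt\tCDS\t501\t600\t.\t+\t0\tID=g3.t1c1;Parent=g3.t1",
    "chr1\tt\tCDS\t701\t800\t.\t+\t0\tID=g3.t1c2;Parent=g3.t1",
    "chr1\tt\tmRNA\t501\t800\t.\t+\t.\tID=g3.t2;Parent=g3",
    "chr1\tt\texon\t501\t800\t.\t+\t.\tID=g3.t2e1;Parent=g3.t2",
    "chr1\tt\tCDS\t501\t800\t.\t+\t0\tID=g3.t2c1;Parent=g3.t2"))
  ann <- read_annotation(gff)
  expect_equal(ann$cds_start[ann$gene_id == "g1"], 101)
  expect_equal(ann$cds_start[ann$gene_id == "g2"], 400)
  # two transcripts: first-listed wins, so g3 keeps the two-exon structure
  expect_length(ann$exon_start[ann$gene_id == "g3"][[1]], 2L)

  # a gene without CDS is skipped with a warning
  gff2 <- write_toy_gff(tempfile(fileext = ".gff3"), c(
    "chr1\tt\tgene\t101\t400\t.\t+\t.\tID=g1",
    "chr1\tt\tmRNA\t101\t400\t.\t+\t.\tID=g1.t1;Parent=g1",
    "chr1\tt\texon\t101\t400\t.\t+\t.\tID=g1.e1;Parent=g1.t1",
    "chr1\tt\tCDS\t101\t400\t.\t+\t0\tID=g1.c1;Parent=g1.t1",
    "chr1\tt\tgene\t501\t800\t.\t+\t.\tID=g4",
    "chr1\tt\tmRNA\t501\t800\t.\t+\t.\tID=g4.t1;Parent=g4",
    "chr1\tt\texon\t501\t800\t.\t+\t.\tID=g4.e1;Parent=g4.t1"))
  expect_warning(ann2 <- read_annotation(gff2), "no CDS")
  expect_equal(ann2$gene_id, "g1")
})

test_that("extract_promoter takes the upstream window, strand-aware, with clipping", {
  set.seed(5)
  contig <- random_dna(6000, gc = 0.4)
  genome <- Biostrings::DNAStringSet(contig)
  names(genome) <- "chr1"

  plus <- list(gene_id = "gp", contig_id = "chr1", strand = "+",
               cds_start = 3001)
  p <- extract_promoter(genome, plus)
  expect_equal(c(p$start, p$end), c(1000, 3000))
  expect_equal(p$actual_length, 2000L)
  expect_false(p$truncated)
  expect_equal(p$sequence, substr(contig, 1001, 3000))

  minus <- list(gene_id = "gm", contig_id = "chr1", strand = "-",
                cds_start = 3000)
  m <- extract_promoter(genome, minus)
  expect_equal(c(m$start, m$end), c(3000, 5000))
  expect_equal(m$sequence, revcomp(substr(contig, 3001, 5000)))

  short <- list(gene_id = "gs", contig_id = "chr1", strand = "+",
                cds_start = 501)
  s <- extract_promoter(genome, short)
  expect_equal(s$actual_length, 500L)
  expect_true(s$truncated)
  expect_equal(s$sequence, substr(contig, 1, 500))

  edge <- list(gene_id = "ge", contig_id = "chr1", strand = "+",
               cds_start = 1)
  expect_warning(e <- extract_promoter(genome, edge), "no upstream")
  expect_equal(e$actual_length, 0L)
  expect_true(e$truncated)
})

test_that("promoter extraction round-trips planted upstream sequence on both strands", {
  fx <- make_fixture(tempfile("fx"), n_genes = 4, strands = c("+", "-"),
                     seed = 21)
  genome <- read_genome(fx$fasta)
  ann <- read_annotation(fx$gff3)
  pr <- extract_promoters(genome, ann)
  expect_equal(unname(pr$sequence), unname(fx$upstream[pr$gene_id]))
  expect_false(any(pr$truncated))
  expect_equal(unique(pr$actual_length), 2000L)
})

test_that("fragment_genome makes adjacent fixed-width windows and drops remainders", {
  g6 <- Biostrings::DNAStringSet(random_dna(6000, seed = 1))
  expect_equal(nrow(fragment_genome(g6)), 3L)
  g5 <- Biostrings::DNAStringSet(random_dna(5000, seed = 2))
  fr <- fragment_genome(g5)
  expect_equal(nrow(fr), 2L)
  expect_equal(fr$start, c(0L, 2000L))
  expect_equal(fr$end, c(2000L, 4000L))
  # coverage: window * floor(L / window)
  expect_equal(sum(fr$end - fr$start), 2000 * (5000 %/% 2000))
  # sub-window contigs yield nothing
  expect_equal(nrow(fragment_genome(Biostrings::DNAStringSet("ACGT"))), 0L)
})

test_that("gc_content matches its definition and ignores N", {
  expect_equal(gc_content("ATGC"), 0.5)
  expect_equal(gc_content("GGCC"), 1.0)
  expect_equal(gc_content("GCNNAT"), 0.5)
  expect_error(gc_content("NNN"), "undefined")
  expect_error(gc_content(""), "undefined")
  for (seed in 1:5) {
    s <- random_dna(200, gc = 0.3, seed = seed)
    expect_equal(gc_content(s), gc_content(revcomp(s)))
  }
})

test_that("GC filter keeps the closed interval and is idempotent", {
  # gc exactly at the printed boundaries 0.264 and 0.304
  mk <- function(n_gc) paste0(strrep("G", n_gc), strrep("A", 2000 - n_gc))
  g <- Biostrings::DNAStringSet(c(mk(528), mk(608), mk(609), mk(527)))
  fr <- fragment_genome(g)
  expect_equal(fr$gc, c(0.264, 0.304, 0.3045, 0.2635))
  kept <- filter_fragments_by_gc(fr, center = 0.284, tolerance = 0.02)
  expect_equal(kept$gc, c(0.264, 0.304))   # boundaries inclusive
  expect_identical(filter_fragments_by_gc(kept, 0.284, 0.02), kept)
  # zero tolerance keeps exact matches only
  expect_equal(nrow(filter_fragments_by_gc(fr, 0.264, 0)), 1L)
  # N-rich fragments are dropped from background sets
  frN <- fr
  frN$n_frac <- c(0, 0.5, 0, 0)
  expect_equal(filter_fragments_by_gc(frN, 0.284, 0.02)$gc, 0.264)
})
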