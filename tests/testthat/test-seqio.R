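test_that("FASTA reading preserves records and round-trips", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a desc", "ACGT", ">b", "GGGTTT", "AAA"), f)
  seqs <- read_fasta(f)
  expect_equal(as.character(seqs), c("ACGT", "GGGTTTAAA"))
  expect_equal(names(seqs), c("a", "b"))
  expect_equal(attr(seqs, "alphabet"), "dna")

  f2 <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f2)
  back <- read_fasta(f2)
  expect_equal(as.character(back), as.character(seqs))
  expect_equal(names(back), names(seqs))

  fe <- withr::local_tempfile(fileext = ".fa")
  file.create(fe)
  expect_warning(empty <- read_fasta(fe), "empty")
  expect_length(empty, 0L)
})

test_that("long sequences are wrapped at 60 columns on write", {
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(c(x = strrep("ACGT", 40)), f)
  lines <- readLines(f)
  expect_true(all(nchar(lines[-1]) <= 60L))
  expect_equal(paste(lines[-1], collapse = ""), strrep("ACGT", 40))
})

test_that("gene models validate exon structure", {
  expect_error(gene_model("g", "c", "+", matrix(numeric(0), ncol = 2)),
               "at least one exon")
  expect_error(gene_model("g", "c", "+", rbind(c(10, 5))), "half-open")
  expect_error(gene_model("g", "c", "+", rbind(c(0, 10), c(5, 20))),
               "overlap")
  expect_error(gene_model("g", "c", "*", rbind(c(0, 10))), "strand")
  g <- gene_model("g", "c", "+", rbind(c(99, 172), c(0, 30)))
  expect_equal(g$exons[, 1], c(0L, 99L))  # sorted on construction
})

test_that("GFF3 I/O converts coordinates and preserves them exactly", {
  g1 <- gene_model("gene1", "c1", "+", rbind(c(0, 30), c(99, 172)),
                   tag = "MAT1-1-1")
  g2 <- gene_model("gene2", "c1", "-", rbind(c(300, 420)), tag = "ste2")
  f <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(list(g1, g2), f)
  raw <- readLines(f)
  expect_equal(raw[1], "##gff-version 3")
  ## 1-based inclusive on disk: CDS 1..30 and 100..172
  cds <- read.table(text = raw[grepl("\tCDS\t", raw)], sep = "\t")
  expect_equal(cds$V4, c(1L, 100L, 301L))
  expect_equal(cds$V5, c(30L, 172L, 420L))

  back <- read_gff3(f)
  expect_equal(back$gene1$exons, g1$exons)
  expect_equal(back$gene2$exons, g2$exons)
  expect_equal(back$gene1$tag, "MAT1-1-1")
  expect_equal(back$gene2$strand, "-")

  expect_error(read_gff3(f, contigs = "other_ctg"), "unknown contig")
})

test_that("CDS extraction translates with strand symmetry", {
  expect_equal(as.character(extract_cds_and_translate(
    c(c1 = "ATGGCTTAA"),
    gene_model("g", "c1", "+", rbind(c(0, 9))))), "MA")
  expect_equal(as.character(extract_cds_and_translate(
    c(c1 = revcomp("ATGGCTTAA")),
    gene_model("g", "c1", "-", rbind(c(0, 9))))), "MA")
})

test_that("a 330-bp two-exon gene with a 57-bp intron yields 90 aa", {
  set.seed(41)
  prot <- matmine:::rand_protein(90)
  cds <- paste0(reverse_translate(prot), "TAA")        # 273 nt
  sp <- matmine:::insert_intron(cds, len = 57L)
  expect_equal(nchar(sp$dna), 330L)
  gm <- gene_model("m13", "c1", "+", sp$exons, tag = "MAT1-1-13")
  p <- extract_cds_and_translate(c(c1 = sp$dna), gm)
  expect_equal(nchar(p), 90L)
  expect_equal(as.character(p), prot)
  expect_false(attr(p, "internal_stop"))
})

test_that("internal stops and phase errors are flagged", {
  p <- extract_cds_and_translate(
    c(c1 = "ATGTAAGCTTAA"),
    gene_model("g", "c1", "+", rbind(c(0, 12))))
  expect_true(attr(p, "internal_stop"))
  expect_warning(
    p2 <- extract_cds_and_translate(
      c(c1 = "ATGGCTT"), gene_model("g", "c1", "+", rbind(c(0, 7)))),
    "divisible")
  expect_true(attr(p2, "phase_error"))
})

test_that("six-frame translation maps back to contig coordinates", {
  expect_equal(six_frame_translate("ATGGCT")$aa[1], "MA")
  expect_equal(six_frame_translate("AGCCAT")$aa[4], "MA")  # frame -1
  set.seed(11)
  dna <- matmine:::rand_dna(100)
  fr <- six_frame_translate(dna)
  expect_equal(nchar(fr$aa), (100L - fr$offset) %/% 3L)
  ## coordinate map: re-translating the mapped DNA interval reproduces
  ## each frame's residue
  for (i in c(1, 5)) {
    o <- fr$offset[i]
    p <- 3L
    d <- if (fr$strand[i] == "+")
      substr(dna, o + 3 * p + 1, o + 3 * p + 3) else
      revcomp(substr(dna, 100 - o - 3 * p - 2, 100 - o - 3 * p))
    expect_equal(matmine:::translate_dna(d),
                 substr(fr$aa[i], p + 1, p + 1))
  }
})

test_that("ambiguous codons translate to X", {
  expect_equal(matmine:::translate_dna("ATGNCTGCN"), "MXX")
})
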