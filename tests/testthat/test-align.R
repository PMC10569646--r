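test_that("local alignment reproduces known substitution sums", {
  h <- local_align("CTVM", "CTVM")
  expect_equal(h$score, 23)          # BLOSUM62 diagonal 9+5+4+5
  expect_equal(local_align("A", "A")$score, 4)
  expect_equal(h$identity, 1)
  ## unrelated composition scores 0 with no meaningful interval
  expect_lt(local_align("WWWW", "DDDD")$score, 5)
})

test_that("local alignment score is symmetric", {
  set.seed(51)
  for (i in 1:20) {
    a <- matmine:::rand_protein(sample(3:12, 1))
    b <- matmine:::rand_protein(sample(3:12, 1))
    expect_equal(local_align(a, b)$score, local_align(b, a)$score)
  }
})

test_that("local alignment equals the independent Gotoh oracle", {
  M <- matmine:::blosum62()
  set.seed(52)
  for (i in 1:60) {
    a <- matmine:::rand_protein(sample(1:8, 1))
    b <- matmine:::rand_protein(sample(1:8, 1))
    expect_equal(local_align(a, b)$score, sw_oracle(a, b, M),
                 info = paste(a, b))
  }
})

test_that("genome search recovers planted ORFs on both strands", {
  set.seed(53)
  prot <- matmine:::rand_protein(60)
  insert <- paste0(reverse_translate(prot), "TAA")
  contig <- paste0(matmine:::rand_dna(4000), insert,
                   matmine:::rand_dna(4000))
  h <- search_genome(prot, c(ctg = contig))
  expect_gt(nrow(h), 0L)
  expect_equal(h$target_id[1], "ctg")
  ## >= 99% overlap with the planted interval
  ov <- min(h$target_end[1], 4000 + 180) - max(h$target_start[1], 4000)
  expect_gte(ov / 180, 0.99)
  expect_lte(h$evalue[1], 0.05)

  hm <- search_genome(prot, c(ctg = revcomp(contig)))
  expect_equal(hm$score[1], h$score[1])
  expect_equal(hm$strand[1], "-")

  expect_equal(nrow(search_genome(prot,
                                  c(ctg = matmine:::rand_dna(8000)))),
               0L)
})

test_that("a prebuilt genome index gives identical hits", {
  set.seed(54)
  prot <- matmine:::rand_protein(40)
  genome <- c(ctg = paste0(matmine:::rand_dna(1000),
                           reverse_translate(prot), "TAA",
                           matmine:::rand_dna(1000)))
  idx <- genome_index(genome)
  expect_equal(search_genome(prot, idx), search_genome(prot, genome))
})

test_that("microsynteny windows are orientation-normalized intervals", {
  a <- data.frame(target_id = "c1", target_start = 1000L,
                  target_end = 2000L)
  b <- data.frame(target_id = "c1", target_start = 9000L,
                  target_end = 10000L)
  w <- microsynteny_window(a, b)
  expect_equal(c(w$start, w$end), c(2000L, 9000L))
  expect_false(w$split)
  w2 <- microsynteny_window(b, a)          # order-independent
  expect_equal(c(w2$start, w2$end), c(2000L, 9000L))

  b$target_id <- "c2"
  expect_true(microsynteny_window(a, b)$split)

  c_ <- data.frame(target_id = "c1", target_start = 1500L,
                   target_end = 2500L)
  expect_warning(w3 <- microsynteny_window(a, c_), "overlap")
  expect_equal(w3$start, w3$end)
})

test_that("conservation counts planted occurrences across genomes", {
  set.seed(55)
  prot <- matmine:::rand_protein(50)
  make <- function(planted)
    c(ctg = if (planted)
      paste0(matmine:::rand_dna(500), reverse_translate(prot), "TAA",
             matmine:::rand_dna(500)) else matmine:::rand_dna(1600))
  genomes <- list(make(TRUE), make(TRUE), make(TRUE), make(FALSE))
  expect_equal(conservation_count(prot, genomes), 3L)
  expect_equal(conservation_count(matmine:::rand_protein(50),
                                  genomes[4]), 0L)
  expect_error(conservation_count(prot, list()), "at least one")
  ## the batched presence matrix agrees with per-candidate counts
  cands <- c(prot, matmine:::rand_protein(50))
  pres <- matmine:::conservation_matrix(cands, genomes)
  expect_equal(rowSums(pres), c(3, 0))
})

test_that("hit reports use the fixed column order", {
  set.seed(56)
  prot <- matmine:::rand_protein(40)
  h <- search_genome(prot, c(ctg = paste0(
    matmine:::rand_dna(200), reverse_translate(prot), "TAA")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(h, f)
  expect_equal(names(read.table(f, header = TRUE, sep = "\t")),
               c("query_id", "target_id", "score", "evalue",
                 "target_start", "target_end", "strand", "frame",
                 "identity"))
})
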