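test_that("the canonical two-repeat pro-pheromone parses as typical", {
  p <- paste0("MKFLSLLALAAVVSA", "DAEA", "WCGRPGQPC", "KR",
              "EAEA", "WCGRPGQPC", "KR")
  a <- annotate_repeats(p)
  expect_equal(a$klass, "typical")
  expect_equal(nrow(a$repeats), 2L)
  expect_equal(a$repeats$sequence, rep("WCGRPGQPC", 2))
  expect_equal(a$repeats$beta_turn, rep("GQ", 2))
  expect_equal(a$repeats$followed_by, rep("KEX", 2))
  ## intervals reconstruct the protein substrings exactly
  expect_equal(substring(p, a$repeats$start + 1, a$repeats$end),
               a$repeats$sequence)
})

test_that("a single repeat without KEX sites is the atypical class", {
  ## signal + one STE13 site (EP) + a single mature peptide, no dibasic
  p <- paste0("MKFLSLLALAAVVSA", "EP", "WCGSPGQPC",
              strrep("GSGE", 5))
  a <- annotate_repeats(p)
  expect_equal(nrow(find_kex_sites(p)), 0L)
  expect_equal(a$klass, "atypical_single_repeat")
  expect_equal(nrow(a$repeats), 1L)
  expect_equal(a$repeats$beta_turn, "GQ")
})

test_that("repeats separated by STE13 runs with a single terminal KEX
          site are STE13-dominant", {
  r1 <- "WCGSIGQICG"; r2 <- "WCGTVGQVCG"; r3 <- "WCGSMGQMCG"
  p <- paste0("MKFLSLLALAAVVSA", "DAEA", r1, "EPEP", r2, "KR",
              "DPDP", r3, "KR")
  a <- annotate_repeats(p)
  expect_equal(a$klass, "ste13_dominant")
  expect_equal(a$repeats$sequence, c(r1, r2, r3))
  expect_true(any(a$repeats$followed_by == "STE13"))
})

test_that("proteins with no recognizable grammar are unparseable", {
  a <- annotate_repeats(strrep("GHIW", 15))
  expect_equal(a$klass, "unparseable")
  expect_equal(nrow(a$repeats), 0L)
  expect_error(annotate_repeats("MKKR"), "min_total")
})

test_that("repeat intervals never overlap and respect the grammar", {
  set.seed(61)
  for (i in 1:40) {
    g <- gen_alpha_gene(n_repeats = sample(2:10, 1))
    a <- annotate_repeats(g$protein)
    r <- a$repeats
    if (nrow(r) > 1) expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
    expect_true(all(r$end <= nchar(g$protein)))
    ## beta-turn label is consistent with the sequence
    expect_equal(r$beta_turn == "GQ", grepl("GQ", r$sequence))
  }
})

test_that("out-of-range repeat lengths are flagged but retained", {
  long_rep <- "WCGSIGQGSGSGSGSICW"   # 18 aa, above the soft bound
  g <- gen_alpha_gene(long_rep, n_repeats = 3, intron = FALSE, seed = 8)
  a <- annotate_repeats(g$protein)
  expect_equal(nrow(a$repeats), 3L)
  expect_true(all(a$repeats$length_flag))
})

test_that("intergenic scanning finds planted pheromone genes on either
          strand", {
  set.seed(62)
  g <- gen_alpha_gene("WCGRPGQPC", 4, intron = FALSE, flank = 0)
  win <- paste0(matmine:::rand_dna(400), g$contig,
                matmine:::rand_dna(400))
  sc <- scan_intergenic_for_alpha(win)
  expect_gt(length(sc), 0L)
  expect_equal(nrow(sc[[1]]$annotation$repeats), 4L)
  expect_equal(sc[[1]]$annotation$repeats$sequence[1], "WCGRPGQPC")

  scm <- scan_intergenic_for_alpha(revcomp(win))
  expect_equal(scm[[1]]$annotation$repeats$sequence[1], "WCGRPGQPC")
  expect_equal(scm[[1]]$strand, "-")

  expect_length(scan_intergenic_for_alpha(matmine:::rand_dna(600)), 0L)
})

test_that("repeat sharing is exact-string incidence across species", {
  mk <- function(id, rep_seq) annotate_repeats(
    gen_alpha_gene(rep_seq, 3, intron = FALSE)$protein,
    protein_id = id)
  set.seed(63)
  anns <- list(s1 = mk("s1", "WCGRPGQPC"), s2 = mk("s2", "WCGRPGQPC"),
               s3 = mk("s3", "WCGRPGQPC"), s4 = mk("s4", "CKYVGQGCW"))
  m <- repeat_sharing_matrix(anns)
  cnt <- attr(m, "counts")
  expect_equal(unname(cnt["WCGRPGQPC"]), 3)
  expect_equal(unname(cnt["CKYVGQGCW"]), 1)
  expect_equal(dim(m), c(4L, 2L))
  ## single species: every repeat counted once
  m1 <- repeat_sharing_matrix(anns[1])
  expect_true(all(attr(m1, "counts") == 1))
})

test_that("alpha annotations export as a four-column TSV", {
  set.seed(64)
  a <- annotate_repeats(gen_alpha_gene(NULL, 3)$protein,
                        protein_id = "sp1")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_alpha_tsv(list(a), f)
  tab <- read.table(f, header = TRUE, sep = "\t")
  expect_equal(names(tab), c("protein_id", "n_repeats", "repeats",
                             "class"))
  expect_equal(tab$n_repeats, 3L)
})
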