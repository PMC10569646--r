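test_that("repeat-pair detection recovers planted direct and inverted
          pairs", {
  set.seed(81)
  R <- matmine:::rand_dna(250)
  w_inv <- paste0(matmine:::rand_dna(1000), R, matmine:::rand_dna(3000),
                  revcomp(R), matmine:::rand_dna(1000))
  inv <- detect_repeat_pairs(w_inv, 100)
  expect_equal(nrow(inv), 1L)
  expect_equal(inv$orientation, "inverted")
  expect_gte(inv$length_bp, 250L)
  expect_lte(abs(inv$a_start - 1000L), 2L)

  w_dir <- paste0(matmine:::rand_dna(800), R, matmine:::rand_dna(2000),
                  R, matmine:::rand_dna(800))
  dir_ <- detect_repeat_pairs(w_dir, 100)
  expect_equal(nrow(dir_), 1L)
  expect_equal(dir_$orientation, "direct")
  expect_gte(dir_$length_bp, 250L)

  expect_equal(nrow(detect_repeat_pairs(matmine:::rand_dna(10000), 100)),
               0L)
})

test_that("repeat-pair detection equals the shift-scan oracle on small
          windows", {
  set.seed(82)
  for (i in 1:8) {
    R <- matmine:::rand_dna(60)
    win <- paste0(matmine:::rand_dna(150), R, matmine:::rand_dna(200),
                  if (i %% 2) R else revcomp(R),
                  matmine:::rand_dna(150))
    got <- detect_repeat_pairs(win, 50)
    ref <- repeat_pairs_oracle(win, 50)
    expect_equal(nrow(got), nrow(ref))
    key <- function(d) paste(d$a_start, d$a_end, d$b_start, d$b_end,
                             d$orientation)
    expect_setequal(key(got), key(ref))
  }
})

test_that("locus location statuses intact, truncated and fragment
          genes", {
  refs <- mat_reference_subset()
  g <- gen_mat_architecture("het_MAT1_1", seed = 83)
  loc <- locate_mat_locus(g$genome, refs)
  st <- function(nm) loc$genes$status[loc$genes$name == nm]
  expect_true("intact" %in% st("MAT1-1-1"))
  expect_true("intact" %in% st("MAT1-1-5"))
  ## the short 3' MAT1-2-1 fragment is seen but not intact
  expect_false("intact" %in% st("MAT1-2-1"))
  expect_true("intact" %in% st("APN2"))
  expect_false(is.null(loc$window))
  ## truncation direction: planted 3'-only gene misses its 5' end
  g2 <- gen_mat_architecture("truncated_undetermined", seed = 84)
  loc2 <- locate_mat_locus(g2$genome, refs)
  expect_true(any(loc2$genes$status[loc2$genes$name == "MAT1-2-1"] ==
                    "truncated_5prime"))
  expect_true(any(loc2$genes$status[loc2$genes$name == "MAT1-1-1"] ==
                    "truncated_3prime"))
  ## a random genome yields no MAT evidence
  set.seed(85)
  loc3 <- locate_mat_locus(c(ctg = matmine:::rand_dna(5000)), refs)
  expect_true(all(loc3$genes$status == "absent"))
})

test_that("the thallism decision cascade follows idiomorph content", {
  gene_row <- function(name, status, contig = "c1", s = 0L, e = 100L)
    data.frame(name = name, status = status, contig = contig,
               start = s, end = e, strand = "+", coverage = 1,
               stringsAsFactors = FALSE)
  no_reps <- detect_repeat_pairs("", 100)

  ## single idiomorph with an opposite-side fragment stays heterothallic
  call <- classify_thallism(rbind(
    gene_row("MAT1-1-1", "intact"), gene_row("MAT1-1-5", "intact"),
    gene_row("MAT1-2-1", "fragment")), no_reps)
  expect_equal(call$strategy, "heterothallic_MAT1_1")

  ## the HMG-only pattern: intact MAT1-1-3 alone
  call2 <- classify_thallism(gene_row("MAT1-1-3", "intact"), no_reps)
  expect_equal(call2$strategy, "lachnellula_HMG_only")
  ## but not when MAT1-1-1 is present anywhere
  call3 <- classify_thallism(rbind(
    gene_row("MAT1-1-3", "intact"), gene_row("MAT1-1-1", "fragment")),
    no_reps)
  expect_false(call3$strategy == "lachnellula_HMG_only")

  ## both idiomorphs intact at one locus, no switching repeats
  call4 <- classify_thallism(rbind(
    gene_row("MAT1-1-1", "intact"), gene_row("MAT1-2-1", "intact")),
    no_reps)
  expect_equal(call4$strategy, "primary_homothallic")

  ## both idiomorphs on separate contigs
  call5 <- classify_thallism(rbind(
    gene_row("MAT1-1-1", "intact", "c1"),
    gene_row("MAT1-2-1", "intact", "c2")), no_reps)
  expect_equal(call5$strategy, "possible_mixed_culture")

  ## every call carries evidence
  for (cl in list(call, call2, call3, call4, call5))
    expect_gte(length(cl$evidence), 1L)
})

test_that("switching signatures require matching repeat orientation", {
  gene_row <- function(name, status, s, e)
    data.frame(name = name, status = status, contig = "c1", start = s,
               end = e, strand = "+", coverage = 0.45,
               stringsAsFactors = FALSE)
  genes <- rbind(
    gene_row("MAT1-1-5", "intact", 1000L, 1600L),
    gene_row("MAT1-2-1", "intact", 3000L, 3900L),
    gene_row("MAT1-2-10", "intact", 4500L, 5000L),
    gene_row("MAT1-1-1", "fragment", 2000L, 2500L),
    gene_row("MAT1-1-1", "fragment", 5500L, 6000L))
  genes$coverage[genes$status == "intact"] <- 1
  inv <- data.frame(a_start = 2200L, a_end = 2450L, b_start = 5600L,
                    b_end = 5850L, length_bp = 250L,
                    orientation = "inverted", identity = 1)
  expect_equal(classify_thallism(genes, inv)$strategy,
               "switching_inversion")
  dir_ <- inv; dir_$orientation <- "direct"
  expect_equal(classify_thallism(genes, dir_)$strategy,
               "switching_deletion")
})

test_that("all ten generated architectures classify to their intended
          strategy", {
  for (arch in matmine:::MAT_ARCHITECTURES) {
    res <- classify_architecture(arch, seed = 7L)
    expect_equal(res$call$strategy, res$truth$expected_strategy,
                 info = arch)
    expect_gte(length(res$call$evidence), 1L)
  }
})

test_that("locus reports serialize to JSON", {
  res <- classify_architecture("het_MAT1_2", seed = 86L)
  f <- withr::local_tempfile(fileext = ".json")
  write_locus_json("g1", res$locus, res$repeats, res$call, f)
  j <- jsonlite::read_json(f)
  expect_equal(j$strategy, "heterothallic_MAT1_2")
  expect_true(length(j$genes) > 0)
})
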