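test_that("terminal box classification follows the residue-class rules", {
  expect_equal(terminal_caax_class("MSSTTCTVM"), "CPAX")
  expect_equal(terminal_caax_class("MSSTTCVVM"), "CAAX")
  expect_equal(terminal_caax_class("MSSTTACDE"), "none")
  ## every box observed among real candidates classifies as a valid box
  for (box in c("CTVM", "CVVM", "CIVM", "CTIL", "CSIM", "CSVM"))
    expect_true(terminal_caax_class(paste0("MAAA", box)) %in%
                  c("CAAX", "CPAX"))
  expect_warning(out <- terminal_caax_class("CT"), "shorter")
  expect_equal(out, "none")
})

test_that("terminal box class depends only on the last four residues", {
  set.seed(101)
  for (i in 1:50) {
    tail4 <- matmine:::rand_protein(4)
    a <- terminal_caax_class(paste0(matmine:::rand_protein(30), tail4))
    b <- terminal_caax_class(paste0(matmine:::rand_protein(7), tail4))
    expect_identical(a, b)
  }
})

test_that("KEX site finding equals a brute-force dipeptide scan", {
  h <- find_kex_sites("WCGRPGQPCKR")
  expect_equal(nrow(h), 1L)
  expect_equal(c(h$start, h$end), c(9L, 11L))
  h2 <- find_kex_sites("AKKRA")
  expect_equal(h2$start, c(1L, 2L))
  expect_equal(nrow(find_kex_sites("ACDEFG")), 0L)
  set.seed(42)
  for (i in 1:200) {
    p <- paste(sample(c("K", "R", "A", "G", "S"), 25, TRUE),
               collapse = "")
    cc <- strsplit(p, "")[[1]]
    ref <- which(paste0(cc[-25], cc[-1]) %in% c("KR", "RR", "KK"))
    expect_equal(find_kex_sites(p)$start, ref - 1L)
  }
})

test_that("STE13 runs are maximal X[AP] dipeptide chains", {
  h <- find_ste13_sites("DAEA")
  expect_equal(c(h$start, h$end), c(0L, 4L))
  expect_equal(nrow(find_ste13_sites("KKKK")), 0L)
  ## singleton XP site is reported
  h2 <- find_ste13_sites("GGEPGG")
  expect_true(any(h2$start == 2L & h2$end == 4L))
  ## oracle: direct per-position chain walk
  set.seed(43)
  for (i in 1:200) {
    p <- paste(sample(c("A", "P", "K", "E", "G", "W"), 30, TRUE),
               collapse = "")
    cc <- strsplit(p, "")[[1]]
    okf <- function(s) s >= 1 && s <= 29 && cc[s + 1] %in% c("A", "P")
    ref <- NULL
    for (s in 1:29) {
      if (!okf(s) || okf(s - 2)) next
      k <- 0; t <- s
      while (okf(t)) { k <- k + 1; t <- t + 2 }
      ref <- rbind(ref, c(s - 1, s - 1 + 2 * k))
    }
    h <- find_ste13_sites(p)
    if (is.null(ref)) expect_equal(nrow(h), 0L)
    else {
      expect_equal(h$start, ref[, 1])
      expect_equal(h$end, ref[, 2])
    }
  }
})

test_that("S/T fraction is a windowed count with the expected bounds", {
  expect_equal(st_fraction("SSTTSSTTSS", 10), 1.0)
  expect_equal(st_fraction("AAAAAAAAAA", 10), 0.0)
  expect_equal(st_fraction("MSTSTAAAST", 10), 0.6)  # S/T at 2,3,4,5,9,10
  expect_error(st_fraction("", 10), "empty")
  ## monotone under S-substitution, always within [0, 1]
  set.seed(44)
  for (i in 1:50) {
    p <- matmine:::rand_protein(25)
    f <- st_fraction(p, 20)
    expect_gte(f, 0); expect_lte(f, 1)
    cc <- strsplit(p, "")[[1]]
    j <- which(!cc[1:20] %in% c("S", "T"))[1]
    if (!is.na(j)) {
      cc[j] <- "S"
      expect_gte(st_fraction(paste(cc, collapse = ""), 20), f)
    }
  }
})

test_that("GY motif is found only near the terminal box cysteine", {
  expect_false(is.null(find_gy_motif("MSSTTEEEEGYAACTVM", 15)))
  expect_null(find_gy_motif("MSSTTEEEEAAAACTVM", 15))
  ## GY far upstream of the box is outside the window
  p <- paste0("GY", strrep("E", 54), "CTVM")
  expect_null(find_gy_motif(p, 15))
  hit <- find_gy_motif("MSSTTEEEEGYAACTVM", 15)
  expect_equal(substr("MSSTTEEEEGYAACTVM", hit$start + 1, hit$end), "GY")
})

test_that("hydropathy segmentation counts planted membrane helices", {
  set.seed(45)
  for (ntm in c(0L, 6L, 7L, 8L)) {
    prot <- if (ntm == 0L) strrep("S", 200) else
      gen_receptor_construct(ntm)$protein
    expect_equal(nrow(hydropathy_segments(prot)), ntm)
  }
  ## appending a hydrophilic tail never changes the count
  r <- gen_receptor_construct(7L, seed = 9L)
  with_tail <- paste0(r$protein, strrep("DES", 40))
  expect_equal(nrow(hydropathy_segments(with_tail)), 7L)
  ## shorter than the window: no segments
  expect_equal(nrow(hydropathy_segments("MKLV")), 0L)
})

test_that("signal-like hydrophobic prefixes are detected", {
  sig <- find_signal(paste0("MKFLSLLALAAVVSA", strrep("DEDS", 12)))
  expect_false(is.null(sig))
  expect_lte(sig$start, 2L)
  expect_null(find_signal(strrep("DEDS", 15)))
})
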