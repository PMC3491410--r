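# A color read taken straight off a genome window: primer T plus the
# transition colors into each of the window's bases.
read_from_window <- function(window, primer = "T") {
  list(primer = primer, colors = encode_color(paste0(primer, window)))
}

test_that("only the two valid directional orientations are searched", {
  set.seed(51)
  g <- tiny_genome(c(chr1 = random_seq(400)))
  rs <- build_reference_set(g, "color")

  win <- fully_convert(substr(g$seq[[1]], 101, 150))   # unmethylated, plus
  cr <- read_from_window(win)
  hl <- count_color_orientations(cr$primer, cr$colors, rs, 0)
  expect_named(hl, c("1", "4"))
  expect_equal(length(hl[["1"]]), 1L)
  expect_equal(hl[["1"]]$pos, 100L)
  expect_equal(length(hl[["4"]]), 0L)

  # minus-strand origin lands in the Count-4 list
  win2 <- fully_convert(revcomp(substr(g$seq[[1]], 101, 150)))
  cr2 <- read_from_window(win2)
  hl2 <- count_color_orientations(cr2$primer, cr2$colors, rs, 0)
  expect_equal(length(hl2[["1"]]), 0L)
  expect_equal(length(hl2[["4"]]), 1L)

  # the invalid orientation (reversed colors) does find the read -- but only
  # the noise estimator ever searches it
  revq <- intToUtf8(rev(utf8ToInt(substr(cr$colors, 2, nchar(cr$colors)))))
  inv <- find_hits(rs$refs$FULL.PLUS, revq, 0)
  expect_length(inv, 0)   # reversed text is not a genomic operation
})

test_that("decode recovers bisulfite conversions at zero cost", {
  # error-free read from an unmethylated region decodes to the converted
  # window at cost 0
  win <- "TACGGATC"
  cr <- read_from_window(fully_convert(win))
  dec <- decode_color_read(cr$primer, cr$colors, win)
  expect_equal(dec$bases, fully_convert(win))
  expect_equal(dec$cost, 0)

  # the canonical case: ref "CG" after an A anchor, read bases "TG"
  # (bisulfite conversion): adjacent color mismatches, decode returns TG,
  # and the conversion site costs nothing
  dec2 <- decode_color_read("A", encode_color("ATG"), "CG")
  expect_equal(dec2$bases, "TG")
  expect_equal(dec2$cost, 0)
  mm2 <- color_mismatch_count("A", encode_color("ATG"), dec2$bases, "CG")
  expect_equal(as.integer(mm2), 0L)
  expect_equal(attr(mm2, "bs"), 1L)

  # a single isolated color error: reference bases recovered, cost 1
  win3 <- "ACGGATCA"
  cr3 <- read_from_window(fully_convert(win3))
  cd <- strsplit(cr3$colors, "")[[1]]
  cd[4] <- setdiff(c("0", "1", "2", "3"), cd[4])[1]
  dec3 <- decode_color_read(cr3$primer, paste(cd, collapse = ""), win3)
  expect_equal(dec3$bases, fully_convert(win3))
  expect_equal(dec3$cost, 1)
})

test_that("decode equals the exhaustive minimizer on random small cases", {
  set.seed(52)
  for (rep in 1:40) {
    n <- sample(3:5, 1)
    primer <- sample(c("A", "C", "G", "T"), 1)
    colors <- paste(sample(0:3, n, replace = TRUE), collapse = "")
    ref <- random_seq(n, gc = 0.5)
    dec <- decode_color_read(primer, colors, ref)
    oracle <- oracle_decode_exhaustive(primer, colors, ref)
    expect_equal(dec$cost, oracle$cost)
    expect_true(dec$bases %in% oracle$bases)
  }
})

test_that("adjacent-color mismatch count: BS free, SNP charged once", {
  set.seed(53)
  win <- "TAACGGTACATGCCAT"
  # bisulfite-only differences: count 0 whatever the conversion pattern
  for (rep in 1:10) {
    ch <- strsplit(win, "")[[1]]
    cs <- which(ch == "C")
    conv <- cs[runif(length(cs)) < 0.6]
    ch[conv] <- "T"
    cr <- read_from_window(paste(ch, collapse = ""))
    dec <- decode_color_read(cr$primer, cr$colors, win)
    expect_equal(as.integer(color_mismatch_count(cr$primer, cr$colors,
                                                 dec$bases, win)), 0L)
  }
  # one SNP: exactly one non-BS mismatch
  ch <- strsplit(win, "")[[1]]
  ch[7] <- "C"   # T -> C transversion is non-BS in the read direction? no:
  ch[7] <- "G"   # ref T read G, unambiguous non-BS
  cr <- read_from_window(paste(ch, collapse = ""))
  dec <- decode_color_read(cr$primer, cr$colors, win)
  expect_equal(as.integer(color_mismatch_count(cr$primer, cr$colors,
                                               dec$bases, win)), 1L)
})

test_that("stage filtering reports the first strict-minimum unique hit and
           honours the final mismatch cap", {
  set.seed(54)
  g <- tiny_genome(c(chr1 = random_seq(600)))
  rs <- build_reference_set(g, "color")
  win <- substr(g$seq[[1]], 201, 250)

  # clean read: unique hit with 0 non-BS mismatches
  cr <- read_from_window(fully_convert(win))
  hl <- count_color_orientations(cr$primer, cr$colors, rs, 4)
  res <- mismatch_stage_filter(cr$primer, cr$colors, hl, g)
  expect_equal(res$pos, 200L)
  expect_equal(res$strand, "+")
  expect_equal(res$non_bs, 0L)

  # four spaced SNPs exceed the <= 3 cap: read rejected. Substitute G at
  # reference-A positions whose neighbours are not C, so every change is an
  # isolated non-BS mismatch (a SNP adjacent to a converted C can cancel a
  # shared color and legitimately escape the adjacent-color charge).
  wch <- strsplit(win, "")[[1]]
  ok <- which(wch %in% c("A", "T") &
                c("X", wch[-length(wch)]) != "C" & c(wch[-1], "X") != "C")
  apos <- ok[1]
  for (p in ok) if (p - apos[length(apos)] >= 3) apos <- c(apos, p)
  stopifnot(length(apos) >= 4)
  apos <- apos[1:4]
  ch <- strsplit(fully_convert(win), "")[[1]]
  ch[apos] <- "G"
  crx <- read_from_window(paste(ch, collapse = ""))
  hlx <- count_color_orientations(crx$primer, crx$colors, rs, 10)
  resx <- mismatch_stage_filter(crx$primer, crx$colors, hlx, g)
  expect_null(resx)
})

test_that("dual-index mapping falls through to the non-CpG reference for
           methylated CpG-dense reads", {
  set.seed(55)
  left <- random_seq(200); right <- random_seq(200)
  # 50 bp whose only cytosines sit in CpG: 5 CpGs in total
  core <- paste0("TTACGATTGA", "TTACGTTAGG", "ATTACGAAGT", "TGAATTACGG",
                 "ATATTTACGT")
  g <- tiny_genome(c(chr1 = paste0(left, core, right)))
  rs <- build_reference_set(g, "color")

  # fully methylated read covering the CpG-dense core: 5 retained CpG Cs =
  # 10 color mismatches on FULL, 0 on NONCPG
  win <- substr(g$seq[[1]], 201, 250)
  cr <- read_from_window(win)   # no conversion at all (methylation 100%)
  r <- dual_index_map(cr$primer, cr$colors, rs, M1 = 4L, M2 = 4L)
  expect_equal(r$ref_label, "NONCPG")
  expect_equal(r$pos, 200L)

  # an unmethylated read resolves on FULL and never needs the fallback
  cr2 <- read_from_window(fully_convert(win))
  r2 <- dual_index_map(cr2$primer, cr2$colors, rs, M1 = 4L, M2 = 4L)
  expect_equal(r2$ref_label, "FULL")
})

test_that("noise estimation is near zero for valid-orientation reads and
           responds to injected reverse-complements", {
  g <- simulate_genome(30000, gc = 0.4, seed = 56)
  rs <- build_reference_set(g, "color")
  sim <- simulate_color_reads(g, 300, 50, meth_prob = 0.03, max_snps = 0,
                              color_error_rate = 0.02, seed = 57)
  cfg <- bs_config()
  m <- map_color_reads(sim$creads, rs, cfg)
  err <- estimate_noise(sim$creads, rs, cfg, m$results)
  expect_lt(err, 0.01)

  nrc <- 30
  rev_colors <- vapply(substr(sim$creads$colors[1:nrc], 2, 50),
                       function(s) intToUtf8(rev(utf8ToInt(s))),
                       character(1), USE.NAMES = FALSE)
  all <- bs_creads(c(sim$creads$id, paste0("rc", 1:nrc)),
                   c(sim$creads$primer, rep("T", nrc)),
                   c(sim$creads$colors, paste0("0", rev_colors)))
  m2 <- map_color_reads(all, rs, cfg)
  err2 <- estimate_noise(all, rs, cfg, m2$results)
  expect_gt(err2, err)
  expect_lt(abs(err2 - nrc / (300 + nrc)), 0.02)
})
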