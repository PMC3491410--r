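test_that("genome simulation is deterministic and honours GC", {
  g1 <- simulate_genome(12000, gc = 0.4, seed = 5)
  g2 <- simulate_genome(12000, gc = 0.4, seed = 5)
  expect_identical(g1$seq, g2$seq)

  g0 <- simulate_genome(5000, gc = 0, seed = 6)
  expect_false(grepl("[GC]", g0$seq[[1]]))

  gc_obs <- mean(strsplit(g1$seq[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - 0.4), 0.02)

  g3 <- simulate_genome(9000, gc = 0.5, seed = 7, n_chrom = 3)
  expect_length(g3$seq, 3L)
  expect_equal(sum(nchar(g3$seq)), 9000)
})

test_that("base-read simulation respects the methylation probability", {
  g <- simulate_genome(20000, gc = 0.5, seed = 8)
  s1 <- simulate_base_reads(g, 50, 60, meth_prob = 1, seed = 9)
  expect_true(all(s1$truth$converted == ""))       # no conversions at 100%

  s0 <- simulate_base_reads(g, 50, 60, meth_prob = 0, seed = 9)
  # every genomic C position must have been converted
  expect_true(all(!grepl("C", s0$reads$seq)))

  # conversion fraction over many cytosine sites ~ 1 - meth_prob
  sm <- simulate_base_reads(g, 2000, 75, meth_prob = 0.7, seed = 10)
  n_conv <- sum(nchar(gsub("[^,]", "", sm$truth$converted)) +
                  (sm$truth$converted != ""))
  gseq <- g$seq[[1]]
  n_c <- vapply(seq_len(nrow(sm$truth)), function(i) {
    w <- bsmapr:::cpp_window(g$seq, 1L,
                             if (sm$truth$strand[i] == "-")
                               nchar(gseq) - sm$truth$pos[i] - 75L
                             else sm$truth$pos[i],
                             75L, sm$truth$strand[i] == "-")
    lengths(regmatches(w, gregexpr("C", w)))
  }, integer(1))
  frac <- n_conv / sum(n_c)
  expect_lt(abs(frac - 0.3), 0.01)
})

test_that("reads are reproducible under a fixed seed", {
  g <- simulate_genome(10000, gc = 0.4, seed = 11)
  a <- simulate_base_reads(g, 30, 50, meth_prob = 0.5, max_snps = 2,
                           seed = 12)
  b <- simulate_base_reads(g, 30, 50, meth_prob = 0.5, max_snps = 2,
                           seed = 12)
  expect_identical(a$reads$seq, b$reads$seq)
  expect_identical(a$truth, b$truth)
  c1 <- simulate_color_reads(g, 30, 50, meth_prob = 0.5, seed = 13)
  c2 <- simulate_color_reads(g, 30, 50, meth_prob = 0.5, seed = 13)
  expect_identical(c1$creads$colors, c2$creads$colors)
})

test_that("color simulation: encoding order and error counts", {
  g <- simulate_genome(20000, gc = 0.5, seed = 14)
  # no errors, full methylation: colors are exactly the window's encoding
  s <- simulate_color_reads(g, 40, 40, meth_prob = 1, max_snps = 0,
                            color_error_rate = 0, seed = 15)
  gseq <- g$seq[[1]]
  for (i in 1:40) {
    w <- bsmapr:::cpp_window(g$seq, 1L,
                             if (s$truth$strand[i] == "-")
                               nchar(gseq) - s$truth$pos[i] - 40L
                             else s$truth$pos[i],
                             40L, s$truth$strand[i] == "-")
    expect_equal(s$creads$colors[i], encode_color(paste0("T", w)))
  }

  # error count over many reads ~ rate * n_colors * n
  se <- simulate_color_reads(g, 1500, 50, meth_prob = 1, max_snps = 0,
                             color_error_rate = 0.05, seed = 16)
  n_err <- sum(nchar(gsub("[^,]", "", se$truth$color_errors)) +
                 (se$truth$color_errors != ""))
  expect_lt(abs(n_err / (1500 * 50) - 0.05), 0.005)

  # a BS conversion flips two adjacent colors, a color error flips one
  # (adjacent conversions share a color that stays code(T,T) = code(C,C),
  # so pick a read whose conversions are pairwise non-adjacent)
  s1 <- simulate_color_reads(g, 200, 50, meth_prob = 0, max_snps = 0,
                             color_error_rate = 0, seed = 17)
  conv_list <- lapply(strsplit(s1$truth$converted, ","), as.integer)
  i <- which(vapply(conv_list, function(v) {
    length(v) > 0 && (length(v) == 1 || all(diff(v) >= 2))
  }, logical(1)))[1]
  w <- bsmapr:::cpp_window(g$seq, 1L,
                           if (s1$truth$strand[i] == "-")
                             nchar(gseq) - s1$truth$pos[i] - 50L
                           else s1$truth$pos[i],
                           50L, s1$truth$strand[i] == "-")
  ref_col <- strsplit(encode_color(paste0("T", w)), "")[[1]]
  obs_col <- strsplit(s1$creads$colors[i], "")[[1]]
  conv <- as.integer(strsplit(s1$truth$converted[i], ",")[[1]])
  diff_pos <- which(ref_col != obs_col) - 1L   # 0-based color positions
  # each conversion at read position p touches colors p and p+1 only
  expected <- sort(unique(c(conv, conv + 1L)))
  expected <- expected[expected < 50]
  expect_equal(sort(diff_pos), expected)
})

test_that("evaluation scores exact-coordinate matches only", {
  truth <- data.frame(read_id = c("a", "b", "c"), chrom = "chr1",
                      pos = c(10L, 20L, 30L), strand = c("+", "-", "+"),
                      stringsAsFactors = FALSE)
  res <- data.frame(read_id = c("a", "b", "c"),
                    status = c("unique", "unique", "ambiguous"),
                    chrom = "chr1", pos = c(10L, 21L, 30L),
                    strand = c("+", "-", "+"), stringsAsFactors = FALSE)
  ev <- evaluate_mappings(res, truth)
  expect_equal(ev$recovery, 2 / 3)
  expect_equal(ev$accuracy, 1 / 2)    # off-by-one position counts wrong
  expect_equal(ev$false_positives, 1L)

  empty <- evaluate_mappings(res[res$status == "none", ], truth)
  expect_equal(empty$recovery, NaN)
  ev0 <- evaluate_mappings(transform(res, status = "unmapped"), truth)
  expect_equal(ev0$recovery, 0)
  expect_true(is.na(ev0$accuracy))
})
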