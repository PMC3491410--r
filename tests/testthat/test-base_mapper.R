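test_that("entropy matches closed forms and drives the complexity filter", {
  expect_equal(shannon_entropy(strrep("A", 40)), 0)
  expect_equal(shannon_entropy("ACGTACGTACGT"), 1)
  expect_equal(shannon_entropy(strrep("AT", 20)), 0.5)
  # Ns are excluded from the histogram
  expect_equal(shannon_entropy("AANNNN"), 0)
})

test_that("read conversion is C->T and idempotent", {
  expect_equal(convert_read("TCGA"), "TTGA")
  expect_equal(convert_read("AAAA"), "AAAA")
  expect_equal(convert_read(convert_read("CCCGGG")), convert_read("CCCGGG"))
})

test_that("orientation counting finds each simulated origin in its own list", {
  set.seed(21)
  g <- tiny_genome(c(chr1 = random_seq(400)))
  rs <- build_reference_set(g, "base")
  win <- substr(g$seq[[1]], 51, 90)

  # unmethylated plus-strand read: only Count 1 fires
  hl <- count_orientations(fully_convert(win), rs, 0)
  expect_equal(vapply(hl, length, integer(1)),
               c(`1` = 1L, `2` = 0L, `3` = 0L, `4` = 0L))
  expect_equal(hl[["1"]]$pos, 50L)

  # read sequenced from the minus strand: only Count 2
  hl2 <- count_orientations(fully_convert(revcomp(win)), rs, 0)
  expect_equal(vapply(hl2, length, integer(1)),
               c(`1` = 0L, `2` = 1L, `3` = 0L, `4` = 0L))

  # reverse complement of a plus bisulfite read (PCR complement): Count 3
  hl3 <- count_orientations(revcomp(fully_convert(win)), rs, 0)
  expect_equal(vapply(hl3, length, integer(1)),
               c(`1` = 0L, `2` = 0L, `3` = 1L, `4` = 0L))
})

test_that("list filtering drops only lists with an overloaded level", {
  fake <- function(n, mm = 0L) {
    bs_hits(rep("c", n), seq_len(n) - 1L, rep(mm, n))
  }
  # the worked example: counts (1, 0, 40, 40) at one level, cutoff 40
  hl <- list(`1` = fake(1), `2` = fake(0), `3` = fake(40), `4` = fake(40))
  kept <- list_filter(hl, 40)
  expect_named(kept, c("1", "2"))
  expect_equal(sum(vapply(kept, length, integer(1))), 1L)  # 1 hit, not 81

  # strict threshold: 39 everywhere survives
  hl2 <- list(`1` = fake(39), `2` = fake(39), `3` = fake(39), `4` = fake(39))
  expect_length(list_filter(hl2, 40), 4L)

  # color rule is strictly-greater
  hl3 <- list(`1` = fake(3), `4` = fake(11))
  expect_named(color_list_filter(hl3, 10), "1")
  hl4 <- list(`1` = fake(10), `4` = fake(10))
  expect_length(color_list_filter(hl4, 10), 2L)

  # a list with 10 hits spread over different levels is not discarded
  spread <- bs_hits(rep("c", 4), 0:3, c(0L, 1L, 2L, 3L))
  expect_length(list_filter(list(`1` = spread), 4), 1L)
})

test_that("bisulfite-aware verification separates BS from non-BS mismatches", {
  g <- tiny_genome(c(chr1 = "ACGTACGT"))
  expect_equal(verify_bs_mismatches("ATGT", list(chrom = "chr1", pos = 0L),
                                    1L, g),
               c(non_bs = 0L, bs = 1L))
  expect_equal(verify_bs_mismatches("AGGT", list(chrom = "chr1", pos = 0L),
                                    1L, g),
               c(non_bs = 1L, bs = 0L))
  # fully methylated read, no errors: clean
  expect_equal(verify_bs_mismatches("ACGT", list(chrom = "chr1", pos = 4L),
                                    1L, g),
               c(non_bs = 0L, bs = 0L))
  # minus-text orientation: read T over minus-strand C (plus G)
  w <- revcomp(substr(g$seq[[1]], 1, 4))           # "ACGT" -> minus text
  expect_equal(verify_bs_mismatches(fully_convert(w),
                                    list(chrom = "chr1", pos = 4L), 2L, g),
               c(non_bs = 0L, bs = 1L))
})

test_that("unique resolution demands a strict minimum", {
  expect_equal(resolve_unique(data.frame(non_bs = c(0L, 2L))), 1L)
  expect_true(is.na(resolve_unique(data.frame(non_bs = c(1L, 1L)))))
  expect_true(is.na(resolve_unique(data.frame(non_bs = integer(0)))))
})

test_that("end-to-end: error-free unmethylated reads map to their origin", {
  g <- simulate_genome(50000, gc = 0.4, seed = 31)
  rs <- build_reference_set(g, "base")
  sim <- simulate_base_reads(g, 400, 75, meth_prob = 0, max_snps = 0,
                             seed = 32)
  m <- map_base_reads(sim$reads, rs, bs_config(k_base = 3))
  ok <- m$results$status == "unique"
  expect_gt(mean(ok), 0.99)
  expect_true(all(m$results$non_bs[ok] == 0))
  ev <- evaluate_mappings(m$results, sim$truth)
  expect_equal(ev$accuracy, 1)
  # report partitions the read total
  rep <- m$report
  expect_equal(rep$filtered + rep$list_filtered + rep$unmapped +
                 rep$ambiguous + rep$unique, rep$total)
})

test_that("list filtering never removes a strict-minimum unique hit when all
           counts are below cutoff", {
  g <- simulate_genome(20000, gc = 0.4, seed = 33)
  rs <- build_reference_set(g, "base")
  sim <- simulate_base_reads(g, 150, 60, meth_prob = 0.5, max_snps = 1,
                             seed = 34)
  cfg <- bs_config(k_base = 3, list_cutoff_base = 40L)
  m_filt <- map_base_reads(sim$reads, rs, cfg)
  m_inf <- map_base_reads(sim$reads, rs,
                          bs_config(k_base = 3,
                                    list_cutoff_base = .Machine$integer.max))
  # when every orientation list stays under the cutoff, filtering changes
  # nothing: same uniques, same loci
  u <- m_inf$results$status == "unique"
  expect_equal(m_filt$results$status[u], m_inf$results$status[u])
  expect_equal(m_filt$results$pos[u], m_inf$results$pos[u])
})

test_that("low-complexity reads are reported as filtered, not unmapped", {
  g <- simulate_genome(5000, gc = 0.4, seed = 35)
  rs <- build_reference_set(g, "base")
  reads <- bs_reads(c("poly", "ok"),
                    c(strrep("A", 50), fully_convert(substr(g$seq[[1]], 1, 50))))
  m <- map_base_reads(reads, rs, bs_config(k_base = 2))
  expect_equal(m$results$status[1], "filtered")
  expect_equal(m$results$status[2], "unique")
})
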