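#' Simulate a random genome
#'
#' Reproducible pseudo-random chromosome sequences at a requested GC
#' fraction (bases drawn independently; A/T and G/C split evenly within
#' their class).
#'
#' @param length Total genome length (>= 1000).
#' @param gc GC fraction in `[0, 1]` (default 0.4, a vertebrate-like
#'   composition).
#' @param seed Integer seed.
#' @param n_chrom Number of equally sized chromosomes (default 1).
#' @return A sanitized [bs_genome()] with chromosomes `chr1..chrN`.
#' @export
simulate_genome <- function(length, gc = 0.4, seed = 1L, n_chrom = 1L) {
  stopifnot(length >= 1000, gc >= 0, gc <= 1)
  set.seed(as.integer(seed))
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  per <- diff(round(seq(0, length, length.out = n_chrom + 1)))
  seqs <- vapply(per, function(n) {
    paste(sample(names(probs), n, replace = TRUE, prob = probs),
          collapse = "")
  }, character(1))
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  sanitize_genome(bs_genome(seqs))
}

# Draw read origins uniformly over valid start positions of all chromosomes.
sim_origins <- function(genome, n, span) {
  lens <- nchar(genome$seq)
  valid <- pmax(lens - span + 1L, 0L)
  if (all(valid == 0)) stop("read span exceeds every chromosome")
  ci <- sample.int(length(lens), n, replace = TRUE, prob = valid)
  start <- as.integer(floor(runif(n) * valid[ci]))
  strand <- ifelse(runif(n) < 0.5, "+", "-")
  # start is the leftmost plus-strand coordinate; minus-strand reads live at
  # the mirrored offset of the reverse-complement text
  pos_text <- ifelse(strand == "-", lens[ci] - start - span, start)
  list(ci = ci, start = start, pos_text = as.integer(pos_text),
       strand = strand)
}

# Bisulfite-convert one read's character vector: each C is retained
# (methylated) with probability meth_prob, otherwise written T. Returns
# the converted vector and the 0-based read positions converted.
bs_convert_chars <- function(chars, meth_prob) {
  cpos <- which(chars == "C")
  conv <- cpos[runif(length(cpos)) >= meth_prob]
  chars[conv] <- "T"
  list(chars = chars, converted = conv - 1L)
}

inject_snps <- function(chars, max_snps) {
  n_snp <- if (max_snps > 0) sample.int(max_snps + 1L, 1L) - 1L else 0L
  spos <- if (n_snp > 0) sample.int(length(chars), n_snp) else integer(0)
  for (p in spos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  list(chars = chars, snp = sort(spos - 1L))
}

#' Simulate base-space bisulfite reads with known truth
#'
#' Reads are drawn uniformly over start positions and strands. Each C in a
#' read is retained (methylated) with probability `meth_prob` regardless
#' of context, otherwise converted to T; then 0..`max_snps` non-bisulfite
#' substitutions (uniform over that range) are injected at uniform
#' positions.
#'
#' @param genome A sanitized [bs_genome()].
#' @param n Number of reads.
#' @param read_len Read length in bases.
#' @param meth_prob Per-cytosine methylation (retention) probability.
#' @param max_snps Maximum injected substitutions per read (default 0).
#' @param seed Integer seed.
#' @return List with `reads` (a `bs_reads`) and `truth` (data frame:
#'   `read_id`, `chrom`, `pos` = 0-based plus-strand leftmost coordinate,
#'   `strand`, comma-separated 0-based `converted` and `snp` read
#'   positions).
#' @export
simulate_base_reads <- function(genome, n, read_len, meth_prob,
                                max_snps = 0L, seed = 1L) {
  stopifnot(n >= 1, meth_prob >= 0, meth_prob <= 1)
  set.seed(as.integer(seed))
  ori <- sim_origins(genome, n, read_len)
  gseqs <- genome$seq
  seqs <- character(n)
  conv_s <- character(n); snp_s <- character(n)
  for (i in seq_len(n)) {
    w <- cpp_window(gseqs, ori$ci[i], ori$pos_text[i], read_len,
                    ori$strand[i] == "-")
    ch <- strsplit(w, "")[[1]]
    b <- bs_convert_chars(ch, meth_prob)
    s <- inject_snps(b$chars, max_snps)
    seqs[i] <- paste(s$chars, collapse = "")
    conv_s[i] <- paste(b$converted, collapse = ",")
    snp_s[i] <- paste(s$snp, collapse = ",")
  }
  ids <- sprintf("r%06d", seq_len(n))
  truth <- data.frame(read_id = ids, chrom = names(gseqs)[ori$ci],
                      pos = ori$start, strand = ori$strand,
                      converted = conv_s, snp = snp_s,
                      stringsAsFactors = FALSE)
  list(reads = bs_reads(ids, seqs, strrep("I", nchar(seqs))), truth = truth)
}

#' Simulate SOLiD color-space bisulfite reads with known truth
#'
#' Base-space simulation (bisulfite conversion, then substitutions) is
#' followed by color encoding with a T primer, then per-color sequencing
#' errors at a uniform rate. Reads are simulated only in the two valid
#' directional-library orientations. A bisulfite conversion or SNP flips
#' two adjacent colors; an injected color error flips one.
#'
#' @inheritParams simulate_base_reads
#' @param read_len Number of color digits (= genomic bases) per read.
#' @param color_error_rate Per-color substitution error rate (default
#'   0.05).
#' @return List with `creads` (a `bs_creads`) and `truth` (as in
#'   [simulate_base_reads()], plus comma-separated 0-based `color_errors`).
#' @export
simulate_color_reads <- function(genome, n, read_len, meth_prob,
                                 max_snps = 0L, color_error_rate = 0.05,
                                 seed = 1L) {
  stopifnot(n >= 1, meth_prob >= 0, meth_prob <= 1)
  set.seed(as.integer(seed))
  ori <- sim_origins(genome, n, read_len)
  gseqs <- genome$seq
  colors <- character(n)
  conv_s <- character(n); snp_s <- character(n); err_s <- character(n)
  for (i in seq_len(n)) {
    w <- cpp_window(gseqs, ori$ci[i], ori$pos_text[i], read_len,
                    ori$strand[i] == "-")
    ch <- strsplit(w, "")[[1]]
    b <- bs_convert_chars(ch, meth_prob)
    s <- inject_snps(b$chars, max_snps)
    col <- encode_color(paste(c("T", s$chars), collapse = ""))
    cd <- strsplit(col, "")[[1]]
    errs <- which(runif(length(cd)) < color_error_rate)
    for (p in errs) cd[p] <- sample(setdiff(c("0", "1", "2", "3"), cd[p]), 1L)
    colors[i] <- paste(cd, collapse = "")
    conv_s[i] <- paste(b$converted, collapse = ",")
    snp_s[i] <- paste(s$snp, collapse = ",")
    err_s[i] <- paste(errs - 1L, collapse = ",")
  }
  ids <- sprintf("r%06d", seq_len(n))
  truth <- data.frame(read_id = ids, chrom = names(gseqs)[ori$ci],
                      pos = ori$start, strand = ori$strand,
                      converted = conv_s, snp = snp_s, color_errors = err_s,
                      stringsAsFactors = FALSE)
  list(creads = bs_creads(ids, rep("T", n), colors), truth = truth)
}

#' Score mapping results against simulation truth
#'
#' A unique result is correct when (chrom, pos, strand) matches the truth
#' exactly (no positional tolerance). Recovery is the fraction of all
#' reads resolved uniquely; accuracy the fraction of unique results that
#' are correct.
#'
#' @param results Results data frame from a mapping driver.
#' @param truth Truth data frame from a simulator.
#' @return List with `recovery`, `accuracy` (NA when nothing mapped),
#'   `n_unique`, `n_correct` and `false_positives`.
#' @export
evaluate_mappings <- function(results, truth) {
  m <- merge(results[results$status == "unique",
                     c("read_id", "chrom", "pos", "strand")],
             truth[, c("read_id", "chrom", "pos", "strand")],
             by = "read_id", suffixes = c("", ".true"))
  n_unique <- sum(results$status == "unique")
  n_correct <- sum(m$chrom == m$chrom.true & m$pos == m$pos.true &
                     m$strand == m$strand.true)
  list(recovery = n_unique / nrow(results),
       accuracy = if (n_unique > 0) n_correct / n_unique else NA_real_,
       n_unique = n_unique, n_correct = n_correct,
       false_positives = n_unique - n_correct)
}
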