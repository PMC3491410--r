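#' Find all k-mismatch occurrences of a query in a converted reference
#'
#' Enumerates every position where the query matches the reference text
#' with Hamming distance at most `k` (no indels). Long queries use a
#' seed-and-extend scan over a cached k-mer table (pigeonhole: one of
#' `k + 1` disjoint seeds must match exactly); short queries fall back to a
#' definitional sliding scan. The result is the exact hit set either way.
#'
#' @param ref A converted reference (`bs_convref`) from
#'   [build_reference_set()].
#' @param query Query string over the reference alphabet (bases or color
#'   digits).
#' @param k Maximum mismatches (>= 0).
#' @return A `bs_hits` list with parallel vectors `chrom`, `pos` (0-based
#'   offsets into the searched text) and `mm`, sorted by (chrom, pos).
#'   A query longer than every chromosome yields an empty hit set.
#' @export
find_hits <- function(ref, query, k) {
  stopifnot(inherits(ref, "bs_convref"), k >= 0)
  qlen <- nchar(query)
  seed_len <- qlen %/% (as.integer(k) + 1L)
  if (seed_len >= 8L) {
    idx <- ref_seed_index(ref, min(seed_len, 31L))
    h <- si_find(idx, query, as.integer(k))
  } else {
    h <- cpp_naive_find(ref$seqs, query, as.integer(k))
  }
  bs_hits(names(ref$seqs)[h$chrom], h$pos, h$mm)
}

#' Hit list container
#' @param chrom,pos,mm Parallel vectors (chromosome, 0-based offset,
#'   mismatch count).
#' @return A `bs_hits` object sorted by (chrom, pos).
#' @export
bs_hits <- function(chrom, pos, mm) {
  o <- order(chrom, pos)
  structure(list(chrom = as.character(chrom)[o], pos = as.integer(pos)[o],
                 mm = as.integer(mm)[o]), class = "bs_hits")
}

#' @export
length.bs_hits <- function(x) length(x$pos)

#' Hit counts per mismatch level
#' @param hits A `bs_hits`.
#' @param k Mismatch budget (levels 0..k are reported).
#' @return Integer vector of counts named "0".."k".
#' @export
hit_level_counts <- function(hits, k) {
  stats::setNames(tabulate(hits$mm + 1L, nbins = k + 1L),
                  as.character(0:k))
}

#' Brute-force k-mismatch search (testing oracle)
#'
#' Definition-level sliding-window Hamming scan in plain R, independent of
#' the seed-and-extend implementation. Quadratic; for tests only.
#'
#' @inheritParams find_hits
#' @param seqs Named character vector of reference texts (or a
#'   `bs_convref`).
#' @return A `bs_hits`, same contract as [find_hits()].
#' @export
brute_force_hits <- function(seqs, query, k) {
  if (inherits(seqs, "bs_convref")) seqs <- seqs$seqs
  q <- strsplit(query, "")[[1]]
  qlen <- length(q)
  chrom <- character(0); pos <- integer(0); mm <- integer(0)
  for (nm in names(seqs)) {
    t <- strsplit(seqs[[nm]], "")[[1]]
    n <- length(t)
    if (qlen > n) next
    for (p in 0:(n - qlen)) {
      d <- sum(t[(p + 1):(p + qlen)] != q)
      if (d <= k) {
        chrom <- c(chrom, nm); pos <- c(pos, p); mm <- c(mm, as.integer(d))
      }
    }
  }
  bs_hits(chrom, pos, mm)
}
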