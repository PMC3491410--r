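# Independent oracles and fixture builders, deliberately implemented apart
# from the package's C++ paths: table lookups and exhaustive enumeration
# only.

# Di-base color code as a literal lookup table.
DIBASE_TABLE <- local({
  tab <- matrix(NA_integer_, 4, 4, dimnames = list(c("A", "C", "G", "T"),
                                                   c("A", "C", "G", "T")))
  classes <- list(`0` = c("AA", "CC", "GG", "TT"),
                  `1` = c("AC", "CA", "GT", "TG"),
                  `2` = c("AG", "GA", "CT", "TC"),
                  `3` = c("AT", "TA", "CG", "GC"))
  for (col in names(classes)) {
    for (pair in classes[[col]]) {
      tab[substr(pair, 1, 1), substr(pair, 2, 2)] <- as.integer(col)
    }
  }
  tab
})

oracle_encode <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  paste(DIBASE_TABLE[cbind(ch[-length(ch)], ch[-1])], collapse = "")
}

# Decode a color chain given its first base (the di-base code is a group
# action: the next base is uniquely determined).
oracle_chain_decode <- function(first, colors) {
  ch <- strsplit(colors, "")[[1]]
  out <- character(length(ch))
  prev <- first
  for (i in seq_along(ch)) {
    nxt <- names(which(DIBASE_TABLE[prev, ] == as.integer(ch[i])))
    out[i] <- nxt
    prev <- nxt
  }
  paste(out, collapse = "")
}

# Exhaustive minimum-cost translation of a color read against a reference
# window: enumerate all 4^n base strings, cost = color disagreements along
# the chain + non-bisulfite emission disagreements.
oracle_decode_exhaustive <- function(primer, colors, ref_window) {
  n <- nchar(colors)
  obs <- as.integer(strsplit(colors, "")[[1]])
  refc <- strsplit(ref_window, "")[[1]][1:n]
  bases <- c("A", "C", "G", "T")
  grid <- do.call(expand.grid, c(rep(list(bases), n),
                                 stringsAsFactors = FALSE))
  best_cost <- Inf; best <- character(0)
  for (r in seq_len(nrow(grid))) {
    b <- as.character(grid[r, ])
    chain <- c(primer, b)
    trans <- sum(DIBASE_TABLE[cbind(chain[-length(chain)], chain[-1])] != obs)
    emis <- sum(b != refc & !(refc == "C" & b == "T"))
    cost <- trans + emis
    if (cost < best_cost) {
      best_cost <- cost
      best <- paste(b, collapse = "")
    } else if (cost == best_cost) {
      best <- c(best, paste(b, collapse = ""))
    }
  }
  list(cost = best_cost, bases = best)
}

random_seq <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

tiny_genome <- function(seqs) sanitize_genome(bs_genome(seqs))

# Sorted (chrom, pos, mm) triples for set comparison of hit lists.
hit_triples <- function(h) {
  if (length(h) == 0) return(character(0))
  sort(paste(h$chrom, h$pos, h$mm, sep = ":"))
}
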