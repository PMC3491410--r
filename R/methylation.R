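#' Call per-cytosine methylation from unique alignments
#'
#' For every strandwise reference cytosine covered by a uniquely aligned
#' read, the read base C increments the methylated count and T the
#' unmethylated count; any other read base is treated as an error or SNP
#' and ignored. Alignments carry their sequence in text-strand orientation
#' (base reads: the raw or reverse-complemented read; color reads: the
#' decoded base read), so plus-text alignments inform plus-strand
#' cytosines and minus-text alignments minus-strand cytosines. Context
#' (CG/CHG/CHH) is classified from the original genome. Sites whose
#' position or strandwise dinucleotide/trinucleotide context overlaps an
#' originally ambiguous (non-A/C/G/T) reference base are excluded.
#'
#' @param alignments Data frame of unique alignments (from a mapping
#'   driver's `results`, or [read_alignments()]): needs `status`, `chrom`,
#'   `pos` (0-based plus-strand leftmost), `strand` and `seq`.
#' @param genome A [bs_genome()] (sanitized on entry if needed).
#' @return Data frame: `chrom`, `pos` (0-based, cytosine position on its
#'   strand in plus coordinates), `strand`, `context`, `n_meth`,
#'   `n_unmeth`, `level` (percent methylated at the site).
#' @export
call_methylation <- function(alignments, genome) {
  genome <- sanitize_genome(genome)
  aln <- alignments[alignments$status == "unique", , drop = FALSE]
  gseqs <- genome$seq
  if (nrow(aln) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      n_meth = integer(0), n_unmeth = integer(0),
                      level = numeric(0)))
  }
  ci <- match(aln$chrom, names(gseqs))
  if (anyNA(ci)) stop("alignment on unknown chromosome")
  glens <- nchar(gseqs)
  minus <- aln$strand == "-"
  len <- nchar(aln$seq)
  # text-strand offset: plus text uses pos directly; minus text mirrors
  pos_text <- ifelse(minus, glens[ci] - aln$pos - len, aln$pos)
  t <- cpp_tally_meth(gseqs, ci, as.integer(pos_text), minus, aln$seq)
  calls <- data.frame(chrom = names(gseqs)[t$chrom], pos = t$pos,
                      strand = ifelse(t$strand == 1L, "-", "+"),
                      context = t$context, n_meth = t$n_meth,
                      n_unmeth = t$n_unmeth, stringsAsFactors = FALSE)
  # drop sites touching originally ambiguous reference positions
  if (any(vapply(genome$ambig, length, integer(1)) > 0)) {
    bad <- logical(nrow(calls))
    for (j in seq_len(nrow(calls))) {
      amb <- genome$ambig[[calls$chrom[j]]]
      if (length(amb) == 0) next
      p <- calls$pos[j]
      ctx <- if (calls$strand[j] == "+") p + 0:2 else p - 0:2
      bad[j] <- any(ctx %in% amb)
    }
    calls <- calls[!bad, , drop = FALSE]
  }
  calls$level <- ifelse(calls$n_meth + calls$n_unmeth > 0,
                        100 * calls$n_meth / (calls$n_meth + calls$n_unmeth),
                        NA_real_)
  rownames(calls) <- NULL
  calls
}

#' Aggregate methylation level per genomic context
#'
#' level(ctx) = 100 * sum(n_meth) / (sum(n_meth) + sum(n_unmeth)) over all
#' sites of that context.
#'
#' @param calls Data frame from [call_methylation()].
#' @return Named numeric vector `c(CG =, CHG =, CHH =)` in percent; `NA`
#'   for a context with no covered cytosines.
#' @export
level_by_context <- function(calls) {
  vapply(c(CG = "CG", CHG = "CHG", CHH = "CHH"), function(ctx) {
    s <- calls[calls$context == ctx, , drop = FALSE]
    den <- sum(s$n_meth) + sum(s$n_unmeth)
    if (den == 0) NA_real_ else 100 * sum(s$n_meth) / den
  }, numeric(1))
}
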