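#' Genome container
#'
#' A genome is a named set of chromosome sequences stored on the plus
#' strand. Construction uppercases the input; [sanitize_genome()] replaces
#' every non-A/C/G/T letter by `A` (so ambiguous stretches cannot attract
#' spurious three-letter-alphabet hits) and records the original ambiguous
#' positions so that methylation calling can exclude them.
#'
#' @param seqs Named character vector of chromosome sequences.
#' @return A `bs_genome` object.
#' @export
bs_genome <- function(seqs) {
  if (length(seqs) == 0) stop("empty genome")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all chromosomes must be named")
  seqs <- stats::setNames(toupper(as.character(seqs)), names(seqs))
  if (any(nchar(seqs) == 0)) stop("empty chromosome sequence")
  structure(list(seq = seqs, ambig = NULL, sanitized = FALSE),
            class = "bs_genome")
}

#' @export
print.bs_genome <- function(x, ...) {
  cat(sprintf("bs_genome: %d chromosome(s), %s bp total%s\n",
              length(x$seq), format(sum(nchar(x$seq)), big.mark = ","),
              if (isTRUE(x$sanitized)) ", sanitized" else ""))
  invisible(x)
}

#' Replace ambiguous symbols
#'
#' Base sequences: every character outside A/C/G/T becomes `A`. Color
#' strings: every character outside the digits 0-3 becomes `0`.
#'
#' @param seq Character vector of sequences.
#' @param space `"base"` or `"color"`.
#' @return Sanitized character vector.
#' @export
sanitize_seq <- function(seq, space = c("base", "color")) {
  space <- match.arg(space)
  if (space == "base") gsub("[^ACGT]", "A", toupper(seq))
  else gsub("[^0-3]", "0", seq)
}

#' Sanitize a genome, recording ambiguous positions
#'
#' @param genome A [bs_genome()].
#' @return The genome with alphabet exactly A/C/G/T and `$ambig` holding,
#'   per chromosome, the 0-based positions that were not A/C/G/T.
#' @export
sanitize_genome <- function(genome) {
  stopifnot(inherits(genome, "bs_genome"))
  if (isTRUE(genome$sanitized)) return(genome)
  ambig <- lapply(genome$seq, function(s) {
    m <- gregexpr("[^ACGT]", s)[[1]]
    if (m[1] < 0) integer(0) else as.integer(m) - 1L
  })
  genome$ambig <- ambig
  genome$seq <- stats::setNames(sanitize_seq(genome$seq, "base"),
                                names(genome$seq))
  genome$sanitized <- TRUE
  genome
}

#' Reverse complement
#'
#' @param seq Character vector of base sequences (non-A/C/G/T become `N`).
#' @return Reverse-complemented sequences.
#' @export
revcomp <- function(seq) {
  stats::setNames(as.character(cpp_revcomp(as.character(seq))), names(seq))
}

#' Fully convert a sequence (C to T)
#'
#' Models fully unmethylated bisulfite-treated DNA: every `C` is rewritten
#' as `T`. Idempotent.
#' @param seq Character vector.
#' @return Converted sequences.
#' @export
fully_convert <- function(seq) chartr("C", "T", seq)

#' Non-CpG conversion (C to T outside CpG)
#'
#' Models CpG-methylated DNA: a `C` immediately followed by `G` is kept,
#' every other `C` becomes `T`. A trailing `C` (no following base) is
#' converted.
#' @param seq Character vector.
#' @return Converted sequences.
#' @export
noncpg_convert <- function(seq) {
  vapply(seq, function(s) {
    gsub("C(?!G)", "T", s, perl = TRUE)
  }, character(1), USE.NAMES = FALSE)
}

#' Encode a base sequence into SOLiD color space
#'
#' Standard di-base code (0: AA/CC/GG/TT, 1: AC/CA/GT/TG, 2: AG/GA/CT/TC,
#' 3: AT/TA/CG/GC); the output has one digit per adjacent base pair, so
#' `nchar(out) == nchar(seq) - 1`.
#' @param seq Character vector of base sequences (length >= 2 each).
#' @return Character vector of color-digit strings.
#' @export
encode_color <- function(seq) as.character(cpp_encode_color(as.character(seq)))

#' Classify the genomic context of a cytosine
#'
#' CG when the strandwise next base is G; CHG when the next base is H
#' (A/C/T) and the one after is G; CHH otherwise. At a chromosome end with
#' a truncated trinucleotide, the available bases decide (next G gives CG,
#' anything else CHH).
#'
#' @param genome A sanitized [bs_genome()].
#' @param chrom Chromosome name.
#' @param pos 0-based plus-strand position. On the minus strand the plus
#'   base at `pos` must be `G` (a strandwise `C`).
#' @param strand `"+"` or `"-"`.
#' @return `"CG"`, `"CHG"` or `"CHH"`.
#' @export
classify_context <- function(genome, chrom, pos, strand = "+") {
  stopifnot(inherits(genome, "bs_genome"))
  s <- genome$seq[[chrom]]
  L <- nchar(s)
  base_at <- function(p) if (p >= 0 && p < L) substr(s, p + 1, p + 1) else ""
  comp1 <- function(b) if (nzchar(b)) chartr("ACGT", "TGCA", b) else ""
  if (strand == "+") {
    if (base_at(pos) != "C") stop("no cytosine at this position/strand")
    b1 <- base_at(pos + 1); b2 <- base_at(pos + 2)
  } else {
    if (base_at(pos) != "G") stop("no cytosine at this position/strand")
    b1 <- comp1(base_at(pos - 1)); b2 <- comp1(base_at(pos - 2))
  }
  if (b1 == "G") "CG"
  else if (nzchar(b1) && b2 == "G") "CHG"
  else "CHH"
}
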