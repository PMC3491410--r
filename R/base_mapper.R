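#' Normalized Shannon entropy of a read
#'
#' Computed from the discrete A/C/G/T histogram (other symbols excluded)
#' and divided by log2(4), so H lies in `[0, 1]`: a single-letter read has
#' H = 0, a read with equal A/C/G/T counts has H = 1, a two-letter
#' alternation has H = 0.5. Reads below the cutoff (default 0.25) are
#' discarded as low complexity before mapping.
#'
#' @param read Character vector of read sequences.
#' @return Numeric vector of entropies in `[0, 1]`.
#' @export
shannon_entropy <- function(read) as.numeric(cpp_entropy(as.character(read)))

#' In-silico bisulfite conversion of a read (C to T)
#' @param read Character vector.
#' @return Converted reads; idempotent.
#' @export
convert_read <- function(read) chartr("C", "T", read)

# Orientation table for base-space mapping: which converted query is
# searched on which converted reference, which text strand the hit lives
# on, and whether the aligned read is the raw read or its reverse
# complement.
BASE_ORIENT <- data.frame(
  orientation = 1:4,
  query = c("conv", "conv", "conv_rc", "conv_rc"),
  ref = c("FULL.PLUS", "FULL.RC", "FULL.PLUS", "FULL.RC"),
  text_minus = c(FALSE, TRUE, FALSE, TRUE),
  aligned = c("raw", "raw", "rc", "rc"),
  stringsAsFactors = FALSE)

#' Count candidate hits of a bisulfite read in all four orientations
#'
#' The C-to-T converted read and the C-to-T converted reverse complement
#' (reverse complement taken before conversion) are each searched on the
#' two fully converted references, yielding the four orientation hit lists
#' (Count 1..4).
#'
#' @param read Raw (sanitized) base read sequence.
#' @param refset Base-space `bs_refset`.
#' @param k Mismatch budget.
#' @return Named list of four `bs_hits` (`"1"`..`"4"`).
#' @export
count_orientations <- function(read, refset, k) {
  stopifnot(identical(refset$space, "base"))
  conv <- convert_read(read)
  conv_rc <- convert_read(revcomp(read))
  q <- list(conv = conv, conv_rc = conv_rc)
  out <- vector("list", 4L)
  for (i in 1:4) {
    out[[i]] <- find_hits(refset$refs[[BASE_ORIENT$ref[i]]],
                          q[[BASE_ORIENT$query[i]]], k)
  }
  names(out) <- as.character(1:4)
  out
}

#' List filtering of orientation hit lists
#'
#' An orientation's whole list is discarded when any single mismatch level
#' within it holds at least `cutoff` hits (base space) or strictly more
#' than `cutoff` hits (color space, `rule = "gt"`): such a list is likely
#' spurious repetition on one strand, and its hits would render genuinely
#' unique hits on the other strand ambiguous.
#'
#' @param hitlists Named list of `bs_hits`.
#' @param cutoff Level-count cutoff.
#' @param rule `"ge"` (discard at >= cutoff; base space) or `"gt"`
#'   (discard at > cutoff; color space).
#' @return The retained sublist (possibly empty), names preserved.
#' @export
list_filter <- function(hitlists, cutoff, rule = c("ge", "gt")) {
  rule <- match.arg(rule)
  keep <- vapply(hitlists, function(h) {
    if (length(h) == 0) return(TRUE)
    mx <- max(tabulate(h$mm + 1L))
    if (rule == "ge") mx < cutoff else mx <= cutoff
  }, logical(1))
  hitlists[keep]
}

#' Bisulfite-aware mismatch verification of one candidate hit
#'
#' Compares the original (unconverted) read, in the orientation implied by
#' its hit list, against the original genome. Positions where the
#' strandwise reference base is C and the read base is T count as
#' bisulfite mismatches; every other difference is a non-bisulfite
#' mismatch.
#'
#' @param read Raw read sequence.
#' @param hit List/row with `chrom` and `pos` (0-based offset into the
#'   searched text).
#' @param orientation Orientation index 1..4.
#' @param genome Sanitized [bs_genome()].
#' @return Named integer vector `c(non_bs =, bs =)`.
#' @export
verify_bs_mismatches <- function(read, hit, orientation, genome) {
  ori <- BASE_ORIENT[orientation, ]
  s <- if (ori$aligned == "rc") revcomp(read) else read
  ci <- match(hit$chrom, names(genome$seq))
  v <- cpp_verify_bs(s, genome$seq, ci, as.integer(hit$pos), ori$text_minus)
  c(non_bs = v[1], bs = v[2])
}

#' Resolve the unique best candidate
#'
#' A hit is unique when it is the only candidate achieving the strictly
#' lowest non-bisulfite mismatch count across all retained orientations
#' jointly.
#'
#' @param candidates Data frame with a `non_bs` column.
#' @return The row index of the unique minimum, or `NA` when the set is
#'   empty or the minimum is tied.
#' @export
resolve_unique <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NA_integer_)
  m <- min(candidates$non_bs)
  w <- which(candidates$non_bs == m)
  if (length(w) == 1L) w else NA_integer_
}

#' Map base-space bisulfite reads
#'
#' Full pipeline per read: entropy filter, C-to-T conversion,
#' four-orientation hit counting, list filtering, bisulfite-aware
#' verification of the surviving candidates against the original genome,
#' and unique-hit resolution by strictly minimal non-bisulfite mismatches.
#'
#' @param reads A `bs_reads` (see [read_fastq()]).
#' @param refset Base-space reference set from [build_reference_set()].
#' @param config A [bs_config()]; `k_base = NULL` picks 3 for reads longer
#'   than 51 bp, else 2.
#' @return List with `results` (one row per read: `read_id`, `status` in
#'   filtered/unmapped/list_filtered/ambiguous/unique, and for unique rows
#'   `chrom`, `pos` 0-based plus-strand leftmost, `strand`, `orientation`,
#'   `non_bs`, `bs`, `ref_label`, `seq` aligned to the text strand) and
#'   `report` (a [run_report()]).
#' @export
map_base_reads <- function(reads, refset, config = bs_config()) {
  stopifnot(inherits(reads, "bs_reads"), identical(refset$space, "base"))
  n <- length(reads)
  gseqs <- refset$genome$seq
  glens <- nchar(gseqs)
  raw <- sanitize_seq(reads$seq, "base")
  H <- shannon_entropy(raw)
  conv <- convert_read(raw)
  rc <- revcomp(raw)
  conv_rc <- convert_read(rc)
  ks <- if (is.null(config$k_base)) default_k_base(nchar(raw))
        else rep(config$k_base, n)
  refs <- refset$refs[BASE_ORIENT$ref]
  status <- character(n)
  chrom <- rep(NA_character_, n); pos <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n); orient <- rep(NA_integer_, n)
  non_bs <- rep(NA_integer_, n); bs <- rep(NA_integer_, n)
  seq_out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (H[i] < config$entropy_cutoff) { status[i] <- "filtered"; next }
    k <- ks[i]
    queries <- c(conv[i], conv[i], conv_rc[i], conv_rc[i])
    hl <- vector("list", 4L)
    for (o in 1:4) hl[[o]] <- find_hits(refs[[o]], queries[o], k)
    nhits <- vapply(hl, length, integer(1))
    if (sum(nhits) == 0L) { status[i] <- "unmapped"; next }
    keep <- vapply(hl, function(h) {
      length(h) == 0L || max(tabulate(h$mm + 1L)) < config$list_cutoff_base
    }, logical(1))
    if (!any(keep & nhits > 0L)) { status[i] <- "list_filtered"; next }
    # verify surviving candidates (positions normalized to the plus strand)
    rl <- nchar(raw[i])
    cand_o <- integer(0); cand_ci <- integer(0); cand_pos <- integer(0)
    cand_nb <- integer(0); cand_b <- integer(0); cand_plus <- integer(0)
    for (o in which(keep & nhits > 0L)) {
      h <- hl[[o]]
      s <- if (BASE_ORIENT$aligned[o] == "rc") rc[i] else raw[i]
      minus <- BASE_ORIENT$text_minus[o]
      ci <- match(h$chrom, names(gseqs))
      for (j in seq_along(h$pos)) {
        v <- cpp_verify_bs(s, gseqs, ci[j], h$pos[j], minus)
        cand_o <- c(cand_o, o); cand_ci <- c(cand_ci, ci[j])
        cand_pos <- c(cand_pos, h$pos[j])
        cand_plus <- c(cand_plus,
                       if (minus) glens[ci[j]] - h$pos[j] - rl else h$pos[j])
        cand_nb <- c(cand_nb, v[1]); cand_b <- c(cand_b, v[2])
      }
    }
    # uniqueness is per genomic LOCATION: a read whose forward and
    # reverse-complement interpretations land on the same locus (e.g. a
    # fully methylated or cytosine-free window, where RC(read) equals the
    # opposite strand exactly) is one candidate, not two; keep the
    # best-verifying interpretation, read-as-is orientations first
    ord <- order(cand_ci, cand_plus, cand_nb, cand_o)
    first <- !duplicated(paste(cand_ci[ord], cand_plus[ord]))
    sel <- ord[first]
    m <- min(cand_nb[sel])
    w <- sel[cand_nb[sel] == m]
    if (length(w) != 1L) { status[i] <- "ambiguous"; next }
    status[i] <- "unique"
    o <- cand_o[w]; ci <- cand_ci[w]; p <- cand_pos[w]
    minus <- BASE_ORIENT$text_minus[o]
    chrom[i] <- names(gseqs)[ci]
    pos[i] <- cand_plus[w]
    strand[i] <- if (minus) "-" else "+"
    orient[i] <- o
    non_bs[i] <- cand_nb[w]; bs[i] <- cand_b[w]
    seq_out[i] <- if (BASE_ORIENT$aligned[o] == "rc") rc[i] else raw[i]
  }
  results <- data.frame(read_id = reads$id, status = status, chrom = chrom,
                        pos = pos, strand = strand, orientation = orient,
                        non_bs = non_bs, bs = bs,
                        ref_label = ifelse(status == "unique", "FULL",
                                           NA_character_),
                        seq = seq_out, stringsAsFactors = FALSE)
  list(results = results, report = run_report(results, config))
}

#' Summarize a mapping run
#'
#' Counts partition the input read total into entropy-filtered,
#' list-filtered, unmapped, ambiguous and unique reads, with unique counts
#' broken down by reference label.
#'
#' @param results Results data frame from a mapping driver.
#' @param config The [bs_config()] used.
#' @param noise Optional noise estimate to carry along.
#' @return A `bs_report` list.
#' @export
run_report <- function(results, config = NULL, noise = NULL) {
  st <- results$status
  by_label <- table(results$ref_label[st == "unique"])
  structure(list(total = length(st),
                 filtered = sum(st == "filtered"),
                 list_filtered = sum(st == "list_filtered"),
                 unmapped = sum(st == "unmapped"),
                 ambiguous = sum(st == "ambiguous"),
                 unique = sum(st == "unique"),
                 unique_by_label = as.list(by_label),
                 noise = noise,
                 config = if (!is.null(config)) unclass(config)),
            class = "bs_report")
}

#' @export
print.bs_report <- function(x, ...) {
  cat(sprintf(paste0("bs_report: %d reads | filtered %d | list-filtered %d",
                     " | unmapped %d | ambiguous %d | unique %d\n"),
              x$total, x$filtered, x$list_filtered, x$unmapped, x$ambiguous,
              x$unique))
  if (length(x$unique_by_label))
    cat("  unique by label:",
        paste(names(x$unique_by_label), unlist(x$unique_by_label),
              sep = "=", collapse = ", "), "\n")
  if (!is.null(x$noise)) cat(sprintf("  estimated noise: %.4f\n", x$noise))
  invisible(x)
}
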