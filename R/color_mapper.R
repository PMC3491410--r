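#' Count candidate hits of a bisulfite color read (two valid orientations)
#'
#' SOLiD libraries are directional: only reads from the original
#' bisulfite-treated strands exist, so of the four read/reference
#' combinations only two are searched -- the read's informative colors
#' (primer-transition color excluded) against the plus converted color
#' text (Count 1) and against the reverse-complement converted color text
#' (Count 4). The other two combinations are invalid and are only ever
#' searched by [estimate_noise()].
#'
#' @param primer Primer base of the read.
#' @param colors Sanitized color-digit string (length n; the first digit is
#'   the primer transition).
#' @param refset Color-space `bs_refset`.
#' @param k Color mismatch budget (default 4: one bisulfite conversion
#'   costs two adjacent color mismatches).
#' @param conversion `"FULL"` or `"NONCPG"` -- which pair of converted
#'   references to search.
#' @return Named list of `bs_hits` for orientations `"1"` and `"4"`. Hit
#'   positions are 0-based offsets into the color text, which equal the
#'   0-based base offsets of the n-base window in the same text.
#' @export
count_color_orientations <- function(primer, colors, refset, k = 4L,
                                     conversion = c("FULL", "NONCPG")) {
  stopifnot(identical(refset$space, "color"))
  conversion <- match.arg(conversion)
  query <- substr(colors, 2L, nchar(colors))
  list("1" = find_hits(refset$refs[[paste0(conversion, ".PLUS")]], query, k),
       "4" = find_hits(refset$refs[[paste0(conversion, ".RC")]], query, k))
}

#' List filtering for color hit lists
#'
#' As [list_filter()] but a list is discarded only when some mismatch
#' level holds strictly more than `cutoff` hits (default 10).
#'
#' @param hitlists Named list of `bs_hits`.
#' @param cutoff Level-count cutoff (default 10).
#' @return Retained sublist.
#' @export
color_list_filter <- function(hitlists, cutoff = 10L) {
  list_filter(hitlists, cutoff, rule = "gt")
}

#' Decode a color read against a reference window
#'
#' Dynamic programming over the four candidate bases per position,
#' anchored on the primer base. A transition costs 1 when the observed
#' color disagrees with the di-base code of the adjacent base pair; an
#' emission costs 1 unless the base equals the reference base or the
#' reference is C and the base T (the zero-cost bisulfite mismatch). The
#' returned base string is the cost-minimal translation.
#'
#' @param primer Primer base.
#' @param colors Sanitized color string (n digits).
#' @param ref_window n-base window of the original genome in alignment
#'   orientation.
#' @return List with `bases` (length-n string) and `cost` (total DP cost).
#' @export
decode_color_read <- function(primer, colors, ref_window) {
  cpp_decode_color(primer, colors, ref_window)
}

#' Adjacent-color mismatch count of a decoded read
#'
#' Position i contributes 1 when both colors flanking base i disagree with
#' the reference colors and the decoded base is a non-bisulfite mismatch;
#' bisulfite-induced adjacent color mismatches (reference C, decoded T)
#' contribute 0. The final base, which has only one flanking color, is
#' charged on that single color.
#'
#' @inheritParams decode_color_read
#' @param decoded Decoded base string from [decode_color_read()].
#' @return Integer non-bisulfite mismatch count, with attribute `bs` (the
#'   bisulfite mismatch count).
#' @export
color_mismatch_count <- function(primer, colors, decoded, ref_window) {
  v <- cpp_color_mm(primer, colors, decoded, ref_window)
  structure(v[1], bs = v[2])
}

#' Mismatch stage filtering
#'
#' Candidate hits are bucket-grouped by their color-space search mismatch
#' count. Groups are examined in ascending order; every hit in a group is
#' decoded against the original genome and its non-bisulfite base
#' mismatches recounted via the adjacent-color rule. The first hit that is
#' unique at the strictly minimal base-mismatch count among all hits
#' examined so far is reported, provided it carries at most `max_final_mm`
#' non-bisulfite mismatches; otherwise the read yields no hit.
#'
#' @param primer,colors The read (sanitized colors).
#' @param hitlists Retained orientation hit lists (names `"1"`/`"4"`).
#' @param genome Sanitized [bs_genome()].
#' @param max_final_mm Cap on final non-bisulfite mismatches (default 3).
#' @return A one-row data frame (chrom, 0-based plus `pos`, `strand`,
#'   `orientation`, `non_bs`, `bs`, `search_mm`, `seq` = decoded bases) or
#'   `NULL`.
#' @export
mismatch_stage_filter <- function(primer, colors, hitlists, genome,
                                  max_final_mm = 3L) {
  gseqs <- genome$seq
  glens <- nchar(gseqs)
  nb_len <- nchar(colors)  # n colors = n aligned genomic bases
  ori <- integer(0); ci <- integer(0); p <- integer(0); smm <- integer(0)
  for (o in names(hitlists)) {
    h <- hitlists[[o]]
    if (length(h) == 0) next
    ori <- c(ori, rep(as.integer(o), length(h)))
    ci <- c(ci, match(h$chrom, names(gseqs)))
    p <- c(p, h$pos)
    smm <- c(smm, h$mm)
  }
  if (length(ori) == 0) return(NULL)
  checked_nb <- integer(0); checked_idx <- integer(0)
  dec_bases <- character(length(ori)); dec_bs <- integer(length(ori))
  for (lev in sort(unique(smm))) {
    for (j in which(smm == lev)) {
      minus <- ori[j] == 4L
      w <- cpp_window(gseqs, ci[j], p[j], nb_len, minus)
      dec <- cpp_decode_color(primer, colors, w)
      v <- cpp_color_mm(primer, colors, dec$bases, w)
      dec_bases[j] <- dec$bases
      dec_bs[j] <- v[2]
      checked_nb <- c(checked_nb, v[1])
      checked_idx <- c(checked_idx, j)
    }
    m <- min(checked_nb)
    wmin <- which(checked_nb == m)
    if (length(wmin) == 1L) {
      if (m > max_final_mm) return(NULL)
      j <- checked_idx[wmin]
      minus <- ori[j] == 4L
      pos_plus <- if (minus) glens[ci[j]] - p[j] - nb_len else p[j]
      return(data.frame(chrom = names(gseqs)[ci[j]], pos = pos_plus,
                        strand = if (minus) "-" else "+",
                        orientation = ori[j], non_bs = m, bs = dec_bs[j],
                        search_mm = smm[j], seq = dec_bases[j],
                        stringsAsFactors = FALSE))
    }
  }
  NULL
}

# One full counting -> filtering -> stage-filtering pass against one
# conversion type. Returns list(res = row or NULL, had_hits, had_survivors).
color_pass <- function(primer, colors, refset, k, conversion, list_cutoff,
                       max_final_mm) {
  if (k < 0L) return(list(res = NULL, had_hits = FALSE, had_survivors = FALSE))
  hl <- count_color_orientations(primer, colors, refset, k, conversion)
  had_hits <- sum(vapply(hl, length, integer(1))) > 0L
  hl <- color_list_filter(hl, list_cutoff)
  had_survivors <- length(hl) > 0L &&
    sum(vapply(hl, length, integer(1))) > 0L
  res <- if (had_survivors)
    mismatch_stage_filter(primer, colors, hl, refset$genome, max_final_mm)
  else NULL
  list(res = res, had_hits = had_hits, had_survivors = had_survivors)
}

#' Map one color read via the dual-index strategy
#'
#' The read is first mapped against the fully converted color references
#' at scan budget M1 (hypo-methylation biased); when no unique hit is
#' resolved, the same read is mapped against the non-CpG converted
#' references at budget M2 (CpG hyper-methylation biased). The result is
#' labeled with the reference type it came from.
#'
#' @inheritParams mismatch_stage_filter
#' @param refset Color-space `bs_refset`.
#' @param M1,M2 Scan budgets for the FULL and NONCPG references (0..5).
#' @param list_cutoff Color list-filtering cutoff (default 10).
#' @return A one-row data frame with `ref_label`, or `NULL`.
#' @export
dual_index_map <- function(primer, colors, refset, M1 = 4L, M2 = 4L,
                           list_cutoff = 10L, max_final_mm = 3L) {
  dual_map_status(primer, colors, refset, M1, M2, list_cutoff,
                  max_final_mm)$res
}

# dual_index_map plus the failure classification (ambiguous /
# list_filtered / unmapped) needed for run reports.
dual_map_status <- function(primer, colors, refset, M1, M2, list_cutoff,
                            max_final_mm) {
  p1 <- color_pass(primer, colors, refset, M1, "FULL", list_cutoff,
                   max_final_mm)
  if (!is.null(p1$res)) {
    p1$res$ref_label <- "FULL"
    return(list(res = p1$res, status = "unique"))
  }
  p2 <- color_pass(primer, colors, refset, M2, "NONCPG", list_cutoff,
                   max_final_mm)
  if (!is.null(p2$res)) {
    p2$res$ref_label <- "NONCPG"
    return(list(res = p2$res, status = "unique"))
  }
  status <- if (p1$had_survivors || p2$had_survivors) "ambiguous"
            else if (p1$had_hits || p2$had_hits) "list_filtered"
            else "unmapped"
  list(res = NULL, status = status)
}

#' Map SOLiD color-space bisulfite reads
#'
#' Driver over [dual_index_map()] for a whole read set.
#'
#' @param creads A `bs_creads` (see [read_csfasta()]).
#' @param refset Color-space reference set.
#' @param config A [bs_config()]; `mode` sets the scan budgets
#'   (fast = biased `[M1 = 0, M2 = 3]`, default = `[4, 4]`,
#'   sensitive = `[5, 5]`).
#' @return List with `results` (per read; `seq` holds the decoded base
#'   read) and `report`.
#' @export
map_color_reads <- function(creads, refset, config = bs_config()) {
  stopifnot(inherits(creads, "bs_creads"), identical(refset$space, "color"))
  n <- length(creads)
  colors <- sanitize_seq(creads$colors, "color")
  status <- character(n)
  chrom <- rep(NA_character_, n); pos <- rep(NA_integer_, n)
  strand <- rep(NA_character_, n); orient <- rep(NA_integer_, n)
  non_bs <- rep(NA_integer_, n); bs <- rep(NA_integer_, n)
  search_mm <- rep(NA_integer_, n); label <- rep(NA_character_, n)
  seq_out <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    dm <- dual_map_status(creads$primer[i], colors[i], refset,
                          config$M1, config$M2, config$list_cutoff_color,
                          config$max_final_mm)
    r <- dm$res
    if (is.null(r)) {
      status[i] <- dm$status
    } else {
      status[i] <- "unique"
      chrom[i] <- r$chrom; pos[i] <- r$pos; strand[i] <- r$strand
      orient[i] <- r$orientation; non_bs[i] <- r$non_bs; bs[i] <- r$bs
      search_mm[i] <- r$search_mm; label[i] <- r$ref_label
      seq_out[i] <- r$seq
    }
  }
  results <- data.frame(read_id = creads$id, status = status, chrom = chrom,
                        pos = pos, strand = strand, orientation = orient,
                        non_bs = non_bs, bs = bs, search_mm = search_mm,
                        ref_label = label, seq = seq_out,
                        stringsAsFactors = FALSE)
  list(results = results, report = run_report(results, config))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

reverse_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1),
         USE.NAMES = FALSE)
}

#' Estimate the mapping noise rate from read directionality
#'
#' Every read is additionally searched in its two invalid
#' (complement-strand) orientations -- the reversed informative color
#' string against both converted color texts. A read counts as mapped when
#' it resolves uniquely on either the valid or the invalid side; it is
#' marked as noise when the invalid side attains a strictly lower color
#' mismatch count than the valid side (or the valid side has no hit). The
#' estimate is marked / mapped.
#'
#' @param creads A `bs_creads`.
#' @param refset Color-space reference set.
#' @param config A [bs_config()].
#' @param results Optional precomputed results from [map_color_reads()]
#'   (recomputed when absent).
#' @return The noise estimate in `[0, 1]`, or `NA` when nothing maps.
#' @export
estimate_noise <- function(creads, refset, config = bs_config(),
                           results = NULL) {
  if (is.null(results)) results <- map_color_reads(creads, refset, config)$results
  colors <- sanitize_seq(creads$colors, "color")
  k_inv <- max(config$M1, config$M2)
  n <- length(creads)
  mapped <- 0L; marked <- 0L
  for (i in seq_len(n)) {
    revq <- reverse_string(substr(colors[i], 2L, nchar(colors[i])))
    h1 <- find_hits(refset$refs$FULL.PLUS, revq, k_inv)
    h4 <- find_hits(refset$refs$FULL.RC, revq, k_inv)
    inv_mm <- c(h1$mm, h4$mm)
    inv_min <- if (length(inv_mm)) min(inv_mm) else NA_integer_
    inv_unique <- length(inv_mm) > 0 && sum(inv_mm == inv_min) == 1L
    valid_mm <- if (results$status[i] == "unique") results$search_mm[i]
                else NA_integer_
    if (!is.na(valid_mm)) {
      mapped <- mapped + 1L
      if (!is.na(inv_min) && inv_min < valid_mm) marked <- marked + 1L
    } else if (inv_unique) {
      mapped <- mapped + 1L
      marked <- marked + 1L
    }
  }
  if (mapped == 0L) return(NA_real_)
  marked / mapped
}
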