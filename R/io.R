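#' Read a reference genome from FASTA
#'
#' Sequences are uppercased; ambiguous letters are retained (sanitization
#' happens when a reference set is built or methylation is called).
#'
#' @param path FASTA file.
#' @return A [bs_genome()].
#' @export
read_fasta <- function(path) {
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0) stop("no records in FASTA '", path, "'")
  seqs <- toupper(as.character(set))
  names(seqs) <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(names(seqs)))) stop("malformed FASTA header in '", path, "'")
  if (any(nchar(seqs) == 0)) stop("empty sequence in FASTA '", path, "'")
  bs_genome(seqs)
}

#' Write a genome to FASTA
#' @param genome A [bs_genome()].
#' @param path Output file.
#' @param width Line width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(genome$seq)) {
    s <- genome$seq[[nm]]
    writeLines(paste0(">", nm), con)
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read base-space reads from FASTQ
#'
#' Four-line records; returns reads in file order.
#'
#' @param path FASTQ file.
#' @return A `bs_reads` list with `id`, `seq` and `qual` character vectors.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4 != 0)
    stop("truncated FASTQ record near record ", length(lines) %/% 4 + 1,
         " in '", path, "'")
  ids <- lines[seq(1L, length(lines), by = 4L)]
  seqs <- toupper(lines[seq(2L, length(lines), by = 4L)])
  plus <- lines[seq(3L, length(lines), by = 4L)]
  quals <- lines[seq(4L, length(lines), by = 4L)]
  bad <- which(!startsWith(ids, "@") | !startsWith(plus, "+"))
  if (length(bad))
    stop("malformed FASTQ record ", bad[1], " in '", path, "'")
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop("sequence/quality length mismatch at FASTQ record ", bad[1],
         " in '", path, "'")
  if (any(nchar(seqs) == 0)) stop("empty read sequence in '", path, "'")
  bs_reads(sub("^@", "", sub("\\s.*$", "", ids)), seqs, quals)
}

#' Base-space read set
#' @param id,seq,qual Parallel character vectors (`qual` optional).
#' @return A `bs_reads` object.
#' @export
bs_reads <- function(id, seq, qual = NULL) {
  stopifnot(length(id) == length(seq))
  if (!is.null(qual)) stopifnot(all(nchar(qual) == nchar(seq)))
  structure(list(id = as.character(id), seq = as.character(seq),
                 qual = qual), class = "bs_reads")
}

#' @export
length.bs_reads <- function(x) length(x$id)

#' Read SOLiD color reads from CSFASTA
#'
#' Records are `>id` lines followed by a primer base and color digits.
#' Ambiguity codes (for example `.`) are retained in the color string and
#' sanitized to `0` by the mapper.
#'
#' @param path CSFASTA file.
#' @param qual_path Optional QUAL file (parsed, carried, unused).
#' @return A `bs_creads` list with `id`, `primer` and `colors`.
#' @export
read_csfasta <- function(path, qual_path = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  hdr <- startsWith(lines, ">")
  if (length(lines) == 0 ||
      !identical(hdr, rep(c(TRUE, FALSE), length.out = length(lines))))
    stop("malformed CSFASTA in '", path, "'")
  ids <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  recs <- lines[!hdr]
  if (length(recs) != length(ids)) stop("malformed CSFASTA in '", path, "'")
  primer <- toupper(substr(recs, 1L, 1L))
  bad <- which(!primer %in% c("A", "C", "G", "T"))
  if (length(bad))
    stop("CSFASTA record ", bad[1], " lacks a primer base in '", path, "'")
  colors <- substr(recs, 2L, nchar(recs))
  if (any(nchar(colors) < 2L))
    stop("color read shorter than 2 colors in '", path, "'")
  qual <- NULL
  if (!is.null(qual_path)) {
    ql <- readLines(qual_path)
    ql <- ql[nzchar(ql) & !startsWith(ql, "#")]
    qual <- ql[!startsWith(ql, ">")]
  }
  structure(list(id = ids, primer = primer, colors = colors, qual = qual),
            class = "bs_creads")
}

#' @export
length.bs_creads <- function(x) length(x$id)

#' Color read set
#' @param id,primer,colors Parallel character vectors.
#' @return A `bs_creads` object.
#' @export
bs_creads <- function(id, primer, colors) {
  stopifnot(length(id) == length(primer), length(id) == length(colors),
            all(primer %in% c("A", "C", "G", "T")), all(nchar(colors) >= 2))
  structure(list(id = as.character(id), primer = as.character(primer),
                 colors = as.character(colors), qual = NULL),
            class = "bs_creads")
}

ALN_COLS <- c("read_id", "chrom", "pos", "strand", "non_bs", "bs",
              "ref_label", "orientation", "seq")

#' Write resolved alignments as a SAM-flavoured TSV
#'
#' One line per uniquely resolved read: read id, chromosome, 1-based
#' position (leftmost plus-strand base), strand, non-bisulfite and
#' bisulfite mismatch counts, reference label (FULL or NONCPG), the
#' orientation index, and the aligned sequence (the decoded base read for
#' color reads). `#`-prefixed header lines record the configuration.
#'
#' @param results Alignment data frame from [map_base_reads()] or
#'   [map_color_reads()]; ambiguous/unmapped reads are not written.
#' @param path Output file.
#' @param config Optional [bs_config()] echoed into the header.
#' @return `path`, invisibly.
#' @export
write_alignments <- function(results, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#bsmapr-alignments\tv1", con)
  if (!is.null(config))
    writeLines(paste0("#config\t",
                      jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                       null = "null")), con)
  writeLines(paste0("#", paste(ALN_COLS, collapse = "\t")), con)
  hits <- results[results$status == "unique", , drop = FALSE]
  if (nrow(hits)) {
    out <- data.frame(read_id = hits$read_id, chrom = hits$chrom,
                      pos = hits$pos + 1L, strand = hits$strand,
                      non_bs = hits$non_bs, bs = hits$bs,
                      ref_label = hits$ref_label,
                      orientation = hits$orientation, seq = hits$seq)
    write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE)
  }
  invisible(path)
}

#' Read alignments written by [write_alignments()]
#' @param path Alignment TSV.
#' @return Data frame with 0-based `pos` and `status = "unique"` rows.
#' @export
read_alignments <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) == 0) {
    df <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(ALN_COLS)), ALN_COLS))
    df$pos <- integer(0); df$non_bs <- integer(0); df$bs <- integer(0)
    df$orientation <- integer(0); df$status <- character(0)
    return(df)
  }
  df <- read.delim(text = body, header = FALSE, col.names = ALN_COLS,
                   colClasses = c("character", "character", "integer",
                                  "character", "integer", "integer",
                                  "character", "integer", "character"))
  df$pos <- df$pos - 1L
  df$status <- "unique"
  df
}

#' Write per-cytosine methylation calls (BED-like TSV)
#'
#' Columns: chrom, 0-based position, strand, context, methylated count,
#' unmethylated count, level (percent; NA when uncovered).
#'
#' @param calls Data frame from [call_methylation()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_methylation <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("#chrom\tpos\tstrand\tcontext\tn_meth\tn_unmeth\tlevel", con)
  write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write base reads as FASTQ
#' @param reads A `bs_reads`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  qual <- reads$qual
  if (is.null(qual)) qual <- strrep("I", nchar(reads$seq))
  writeLines(rbind(paste0("@", reads$id), reads$seq, "+", qual), path)
  invisible(path)
}

#' Write color reads as CSFASTA
#' @param creads A `bs_creads`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_csfasta <- function(creads, path) {
  writeLines(rbind(paste0(">", creads$id),
                   paste0(creads$primer, creads$colors)), path)
  invisible(path)
}
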