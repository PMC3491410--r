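#' Build the converted reference set
#'
#' Base space builds the two fully converted references (plus strand and
#' reverse complement); conversion is applied to each strand after
#' reverse-complementing, so the two texts are not complementary. Color
#' space builds four references: \{fully, non-CpG\} converted x \{plus,
#' reverse complement\}, each converted in base space first and then
#' encoded into color digits.
#'
#' Seed-and-extend search tables over each text are built lazily per seed
#' length and cached inside the object.
#'
#' @param genome A [bs_genome()]; sanitized on entry if needed.
#' @param space `"base"` or `"color"`.
#' @return A `bs_refset` with elements `genome`, `space` and `refs` (named
#'   `FULL.PLUS`, `FULL.RC` and, in color space, `NONCPG.PLUS`,
#'   `NONCPG.RC`).
#' @export
build_reference_set <- function(genome, space = c("base", "color")) {
  space <- match.arg(space)
  genome <- sanitize_genome(genome)
  plus <- genome$seq
  minus <- revcomp(plus)   # minus strand 5'->3', plus coordinates mirrored
  mk <- function(seqs, conversion, orientation) {
    conv <- if (conversion == "FULL") fully_convert(seqs)
            else noncpg_convert(seqs)
    txt <- if (space == "color") encode_color(conv) else conv
    txt <- stats::setNames(txt, names(seqs))
    structure(list(label = c(conversion = conversion,
                             orientation = orientation),
                   space = space, seqs = txt, cache = new.env(parent = emptyenv())),
              class = "bs_convref")
  }
  refs <- list(FULL.PLUS = mk(plus, "FULL", "PLUS"),
               FULL.RC = mk(minus, "FULL", "RC"))
  if (space == "color") {
    refs$NONCPG.PLUS <- mk(plus, "NONCPG", "PLUS")
    refs$NONCPG.RC <- mk(minus, "NONCPG", "RC")
  }
  structure(list(genome = genome, space = space, refs = refs),
            class = "bs_refset")
}

#' @export
print.bs_refset <- function(x, ...) {
  cat(sprintf("bs_refset (%s space): %s\n", x$space,
              paste(names(x$refs), collapse = ", ")))
  print(x$genome)
  invisible(x)
}

# Seed table for a converted reference at a given seed length (cached).
ref_seed_index <- function(ref, seed_len) {
  key <- as.character(seed_len)
  idx <- ref$cache[[key]]
  if (is.null(idx)) {
    idx <- si_build(ref$seqs, as.integer(seed_len))
    assign(key, idx, envir = ref$cache)
  }
  idx
}

#' Serialize a reference set to a directory
#'
#' The on-disk form is text only: the sanitized genome as FASTA plus a JSON
#' manifest. Converted texts and seed tables are deterministic transforms
#' and are rebuilt on load.
#'
#' @param refset A `bs_refset`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_reference_set <- function(refset, dir) {
  stopifnot(inherits(refset, "bs_refset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(refset$genome, file.path(dir, "genome.fa"))
  meta <- list(format = "bsmapr-index", version = 1L, space = refset$space,
               chroms = names(refset$genome$seq),
               lengths = unname(nchar(refset$genome$seq)),
               ambig = lapply(refset$genome$ambig, as.integer))
  jsonlite::write_json(meta, file.path(dir, "index.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Load a serialized reference set
#'
#' @param dir Directory written by [write_reference_set()].
#' @return A `bs_refset`.
#' @export
read_reference_set <- function(dir) {
  meta_path <- file.path(dir, "index.json")
  if (!file.exists(meta_path)) stop("not a reference index directory: ", dir)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  if (!identical(meta$format, "bsmapr-index"))
    stop("unrecognized index manifest in ", dir)
  genome <- read_fasta(file.path(dir, "genome.fa"))
  genome$sanitized <- TRUE
  amb <- meta$ambig
  if (is.null(names(amb)) && length(amb) == length(meta$chroms))
    names(amb) <- meta$chroms
  genome$ambig <- lapply(genome$seq, function(s) integer(0))
  for (nm in intersect(names(amb), names(genome$seq)))
    genome$ambig[[nm]] <- as.integer(unlist(amb[[nm]]))
  build_reference_set(genome, meta$space)
}
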