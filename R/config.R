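#' Run configuration
#'
#' Bundles the tunable parameters of the mapping pipelines. Defaults follow
#' the method's published settings: base-space list cutoff 40, color-space
#' list cutoff 10, primary color mismatch budget 4, entropy cutoff 0.25,
#' and per-genome scan budgets M1/M2 capped at 5.
#'
#' @param k_base Mismatch budget for base-space mapping. `NULL` chooses per
#'   read length (3 for reads longer than 51 bp, 2 otherwise).
#' @param primary_color_k Color-space counting mismatch budget (default 4;
#'   a bisulfite conversion costs two adjacent color mismatches, hence the
#'   higher budget than base space).
#' @param list_cutoff_base A base-space orientation list is discarded when
#'   some mismatch level holds at least this many hits (default 40).
#' @param list_cutoff_color A color-space list is discarded when some level
#'   holds strictly more than this many hits (default 10).
#' @param entropy_cutoff Reads with normalized Shannon entropy below this
#'   are discarded as low complexity (default 0.25).
#' @param M1,M2 Scan budgets against the fully converted and non-CpG
#'   converted color genomes (each capped at 5). `NULL` defers to `mode`.
#' @param mode One of `"fast"` (M1 = 0, M2 = 3), `"default"` (4, 4) or
#'   `"sensitive"` (5, 5).
#' @param max_final_mm Cap on non-bisulfite mismatches of a resultant
#'   unique color hit (default 3).
#' @param seed Integer seed echoed into run reports.
#' @return A `bs_config` list.
#' @export
bs_config <- function(k_base = NULL, primary_color_k = 4L,
                      list_cutoff_base = 40L, list_cutoff_color = 10L,
                      entropy_cutoff = 0.25, M1 = NULL, M2 = NULL,
                      mode = c("default", "fast", "sensitive"),
                      max_final_mm = 3L, seed = 1L) {
  mode <- match.arg(mode)
  mm <- switch(mode, fast = c(0L, 3L), default = c(4L, 4L),
               sensitive = c(5L, 5L))
  if (is.null(M1)) M1 <- mm[1]
  if (is.null(M2)) M2 <- mm[2]
  M1 <- as.integer(M1); M2 <- as.integer(M2)
  if (M1 > 5L || M2 > 5L || M1 < 0L || M2 < 0L)
    stop("M1 and M2 must lie in 0..5")
  if (list_cutoff_base <= 0L || list_cutoff_color <= 0L)
    stop("list cutoffs must be positive")
  structure(list(k_base = if (!is.null(k_base)) as.integer(k_base),
                 primary_color_k = as.integer(primary_color_k),
                 list_cutoff_base = as.integer(list_cutoff_base),
                 list_cutoff_color = as.integer(list_cutoff_color),
                 entropy_cutoff = entropy_cutoff,
                 M1 = M1, M2 = M2, mode = mode,
                 max_final_mm = as.integer(max_final_mm),
                 seed = as.integer(seed)),
            class = "bs_config")
}

#' Default base-space mismatch budget for a read length
#'
#' 3 mismatches for reads longer than 51 bp, 2 otherwise, matching the
#' published experimental settings.
#' @param read_len Read length(s) in bases.
#' @return Integer mismatch budget(s).
#' @export
default_k_base <- function(read_len) ifelse(read_len > 51L, 3L, 2L)
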