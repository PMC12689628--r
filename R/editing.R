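#' Edit specification for amplicon read classification
#'
#' The programmed substitution set (the desired edit, optionally with
#' silent mutations) and the reference window in which indels are
#' called.
#'
#' @param substitutions data.frame with columns `position` (0-based on
#'   the reference), `ref_base`, `alt_base`.
#' @param window half-open 0-based interval `c(lo, hi)` on the
#'   reference used for indel calling and for the "no other
#'   difference" rule; defaults to the substitution span +/- 10 nt.
#' @param reference reference DNA string (used to validate ref bases).
#' @param name label, e.g. `"A187V"` or `"A187V+SM3"`.
#' @return object of class `edit_spec`.
#' @export
edit_spec <- function(substitutions, reference, window = NULL,
                      name = "edit") {
  stop_if_not(is.data.frame(substitutions) && nrow(substitutions) >= 1 &&
                all(c("position", "ref_base", "alt_base") %in%
                      names(substitutions)),
              "substitutions needs columns position, ref_base, alt_base")
  reference <- toupper(as.character(reference))
  refv <- strsplit(reference, "")[[1]]
  pos <- substitutions$position
  stop_if_not(all(pos >= 0 & pos < length(refv)),
              "substitution positions must lie on the reference")
  ok <- refv[pos + 1L] == toupper(substitutions$ref_base)
  stop_if_not(all(ok), "ref_base mismatch at 0-based position(s) %s",
              paste(pos[!ok], collapse = ", "))
  if (is.null(window))
    window <- c(max(0L, min(pos) - 10L), min(length(refv), max(pos) + 11L))
  stop_if_not(window[1] >= 0 && window[2] <= length(refv) &&
                window[1] < window[2], "window must lie on the reference")
  stop_if_not(all(pos >= window[1] & pos < window[2]),
              "window must contain all substitution positions")
  structure(list(substitutions = substitutions, window = as.integer(window),
                 reference = reference, name = name),
            class = "edit_spec")
}

default_alignment_scoring <- function()
  list(match = 2, mismatch = -1, gap_open = -6, gap_extend = -1)

#' Global affine-gap alignment of reads against a reference
#'
#' Optimal global (Needleman-Wunsch) alignment under affine-gap
#' scoring; a gap of length L costs `|gap_open| + L * |gap_extend|`.
#' Defaults: match +2, mismatch -1, gap open -6, gap extend -1.
#' Backed by Biostrings' pairwise aligner, whose traceback is
#' deterministic.
#'
#' @param reads character vector or `DNAStringSet` over A/C/G/T/N.
#' @param reference reference sequence.
#' @param scoring list with `match`, `mismatch`, `gap_open`,
#'   `gap_extend` (penalties negative).
#' @return list with `score` (numeric vector) and `pattern`/`subject`
#'   (character vectors of gapped aligned sequences, equal width per
#'   pair).
#' @export
align_read <- function(reads, reference,
                       scoring = default_alignment_scoring()) {
  reads <- toupper(as.character(reads))
  reference <- toupper(as.character(reference))
  stop_if_not(length(reference) == 1L && nchar(reference) > 0 &&
                all(nchar(reads) > 0), "sequences must be non-empty")
  bad <- grepl("[^ACGTN]", c(reads, reference))
  stop_if_not(!any(bad), "sequences may contain only A/C/G/T/N")
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scoring$match, mismatch = scoring$mismatch, baseOnly = FALSE)
  # N scores as a mismatch against everything, including itself
  mat["N", ] <- scoring$mismatch
  mat[, "N"] <- scoring$mismatch
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(reads), Biostrings::DNAString(reference),
    substitutionMatrix = mat, gapOpening = abs(scoring$gap_open),
    gapExtension = abs(scoring$gap_extend), type = "global")
  list(score = Biostrings::score(aln),
       pattern = as.character(Biostrings::alignedPattern(aln)),
       subject = as.character(Biostrings::alignedSubject(aln)))
}

#' Classify aligned reads against an edit specification
#'
#' Categories (mutually exclusive, precedence indel > edited >
#' other_sub > unedited):
#' \itemize{
#'   \item `indel`: any insertion or deletion overlapping the window;
#'   \item `edited`: all programmed substitutions present and no other
#'     difference anywhere in the window ("only the desired edit",
#'     where the desired edit is the full programmed set);
#'   \item `other_sub`: any other substitution in the window
#'     (including partial installs of a multi-substitution edit);
#'   \item `unedited`: no difference in the window.
#' }
#' Differences outside the window do not affect the category.
#'
#' @param alignment result of [align_read()].
#' @param spec an [edit_spec()].
#' @return character vector of categories, one per read.
#' @export
classify <- function(alignment, spec) {
  stop_if_not(inherits(spec, "edit_spec"), "spec must be an edit_spec")
  lo <- spec$window[1]; hi <- spec$window[2]   # half-open, 0-based
  pos0 <- spec$substitutions$position
  alt <- toupper(spec$substitutions$alt_base)
  vapply(seq_along(alignment$pattern), function(i) {
    p <- strsplit(alignment$pattern[i], "")[[1]]
    s <- strsplit(alignment$subject[i], "")[[1]]
    refpos <- cumsum(s != "-") - 1L            # 0-based ref coordinate
    # deletions: pattern gap at a reference position inside the window
    del_in <- any(p == "-" & refpos >= lo & refpos < hi)
    # insertions: subject gap; attributed to the ref position they precede
    ins_after <- refpos                         # position of last ref base
    ins_in <- any(s == "-" & ins_after >= lo - 1L & ins_after < hi)
    if (del_in || ins_in) return("indel")
    sub_col <- p != "-" & s != "-" & p != s
    in_win <- refpos >= lo & refpos < hi
    spec_ok <- vapply(seq_along(pos0), function(j) {
      col <- which(s != "-" & refpos == pos0[j])
      length(col) == 1L && p[col] == alt[j]
    }, logical(1))
    other <- sub_col & in_win & !(refpos %in% pos0)
    partial <- sub_col & in_win & (refpos %in% pos0)
    if (all(spec_ok) && !any(other)) return("edited")
    if (any(sub_col & in_win)) return("other_sub")
    "unedited"
  }, character(1))
}

#' Editing and indel rates for an amplicon read set
#'
#' Prime-editing efficiency is the percentage of reads containing only
#' the desired edit among all aligned reads; the indel rate is the
#' percentage of indel-containing reads.  Identical reads are
#' deduplicated before alignment, so cost scales with the number of
#' distinct sequences.
#'
#' @param reads character vector / `DNAStringSet` of merged, oriented
#'   amplicon reads.
#' @param reference reference sequence.
#' @param spec an [edit_spec()].
#' @param scoring alignment scoring (see [align_read()]).
#' @return list of class `editing_result`: counts `n_total`,
#'   `n_edited`, `n_indel`, `n_unedited`, `n_other`, percentages
#'   `editing_pct`, `indel_pct`, and `per_read` (category per input
#'   read, input order).
#' @export
quantify <- function(reads, reference, spec,
                     scoring = default_alignment_scoring()) {
  reads <- toupper(as.character(reads))
  stop_if_not(length(reads) >= 1, "read set is empty")
  uniq <- unique(reads)
  cls_u <- classify(align_read(uniq, reference, scoring), spec)
  per_read <- cls_u[match(reads, uniq)]
  n <- length(reads)
  cnt <- function(k) sum(per_read == k)
  res <- list(n_total = n, n_edited = cnt("edited"), n_indel = cnt("indel"),
              n_unedited = cnt("unedited"), n_other = cnt("other_sub"),
              editing_pct = 100 * cnt("edited") / n,
              indel_pct = 100 * cnt("indel") / n,
              per_read = per_read)
  class(res) <- "editing_result"
  res
}

#' @export
print.editing_result <- function(x, ...) {
  cat(sprintf(
    "amplicon quantification: %d reads | edited %.2f%% | indel %.2f%% | other subs %d | unedited %d\n",
    x$n_total, x$editing_pct, x$indel_pct, x$n_other, x$n_unedited))
  invisible(x)
}

#' Write an editing-result summary TSV
#'
#' @param results named list of `editing_result`s (names = samples).
#' @param path output path.
#' @export
write_editing_tsv <- function(results, path) {
  rows <- lapply(names(results), function(nm) {
    r <- results[[nm]]
    data.frame(sample = nm, n_total = r$n_total, n_edited = r$n_edited,
               n_indel = r$n_indel, editing_pct = r$editing_pct,
               indel_pct = r$indel_pct)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
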