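#' Parameters for the amplicon read simulator
#'
#' @param reference reference DNA string.
#' @param spec an [edit_spec()] describing the programmed edit.
#' @param p_edit,p_indel probabilities that a read carries the full
#'   programmed substitution set, or a nick-site indel (mutually
#'   exclusive outcomes; `p_edit + p_indel <= 1`).
#' @param p_error per-base sequencing substitution error rate.
#' @param indel_size_range integer range of indel sizes in nt.
#' @param n_reads number of reads.
#' @param seed integer seed.
#' @export
read_sim_params <- function(reference, spec, p_edit = 0.13,
                            p_indel = 0.02, p_error = 0,
                            indel_size_range = c(1L, 6L),
                            n_reads = 20000L, seed = 1L) {
  stop_if_not(inherits(spec, "edit_spec"), "spec must be an edit_spec")
  probs <- c(p_edit, p_indel, p_error)
  stop_if_not(all(probs >= 0 & probs <= 1), "probabilities must be in [0,1]")
  stop_if_not(p_edit + p_indel <= 1, "p_edit + p_indel must be <= 1")
  stop_if_not(is_count(n_reads) && n_reads >= 1, "n_reads must be >= 1")
  structure(list(reference = toupper(as.character(reference)), spec = spec,
                 p_edit = p_edit, p_indel = p_indel, p_error = p_error,
                 indel_size_range = as.integer(indel_size_range),
                 n_reads = as.integer(n_reads), seed = as_seed(seed)),
            class = "read_sim_params")
}

#' Simulate amplicon reads with programmed edit/indel/error rates
#'
#' Each read starts from the reference; with probability `p_edit` the
#' full programmed substitution set is installed, else with
#' probability `p_indel` a single insertion or deletion of random size
#' is placed within +/- 20 nt of the edit site (where nicking-induced
#' indels arise).  Per-base substitution errors are then applied at
#' rate `p_error` over the whole read.  The ground-truth label of each
#' read is recorded.
#'
#' @param params a [read_sim_params()].
#' @return list of class `read_set`: `reads` (character vector),
#'   `truth` (programmed category per read: edited/indel/unedited),
#'   `reference`, `spec`.
#' @export
gen_reads <- function(params) {
  stop_if_not(inherits(params, "read_sim_params"),
              "params must come from read_sim_params()")
  ref <- params$reference
  refv <- strsplit(ref, "")[[1]]
  spec <- params$spec
  pos0 <- spec$substitutions$position
  stop_if_not(all(pos0 >= 0 & pos0 < length(refv)),
              "edit positions must lie inside the reference")
  bases <- c("A", "C", "G", "T")

  edited_seq <- refv
  edited_seq[pos0 + 1L] <- toupper(spec$substitutions$alt_base)
  edited_seq <- paste(edited_seq, collapse = "")

  with_seed(params$seed, {
    n <- params$n_reads
    u <- stats::runif(n)
    truth <- ifelse(u < params$p_edit, "edited",
             ifelse(u < params$p_edit + params$p_indel, "indel", "unedited"))
    reads <- character(n)
    reads[truth == "unedited"] <- ref
    reads[truth == "edited"] <- edited_seq

    # indels: single event within +/- 20 nt of the edit-site centre
    centre <- round(mean(pos0))
    win_lo <- max(0L, centre - 20L); win_hi <- min(length(refv), centre + 20L)
    for (i in which(truth == "indel")) {
      size <- sample(params$indel_size_range[1]:params$indel_size_range[2], 1L)
      at <- sample(win_lo:max(win_lo, win_hi - size), 1L)  # 0-based
      if (stats::runif(1) < 0.5 && at + size <= length(refv)) {
        reads[i] <- paste0(substr(ref, 1, at),
                           substr(ref, at + size + 1L, nchar(ref)))
      } else {
        ins <- paste(sample(bases, size, replace = TRUE), collapse = "")
        reads[i] <- paste0(substr(ref, 1, at), ins,
                           substr(ref, at + 1L, nchar(ref)))
      }
    }

    if (params$p_error > 0) {
      for (i in seq_len(n)) {
        rv <- strsplit(reads[i], "")[[1]]
        hit <- which(stats::runif(length(rv)) < params$p_error)
        if (length(hit)) {
          rv[hit] <- vapply(rv[hit], function(b)
            sample(setdiff(bases, b), 1L), character(1))
          reads[i] <- paste(rv, collapse = "")
        }
      }
    }
    structure(list(reads = reads, truth = truth, reference = ref,
                   spec = spec), class = "read_set")
  })
}

#' Write / read simulated reads as FASTQ (constant quality)
#'
#' @param rs a `read_set` (or character vector of reads).
#' @param path file path; @param quality constant Phred quality char.
#' @export
write_fastq <- function(rs, path, quality = "I") {
  reads <- if (inherits(rs, "read_set")) rs$reads else as.character(rs)
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("read%06d", seq_along(x))
  q <- Biostrings::BStringSet(vapply(Biostrings::width(x), function(w)
    strrep(quality, w), character(1)))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path)
  unname(as.character(Biostrings::readDNAStringSet(path, format = "fastq")))

#' Write / read a reference FASTA
#' @param sequences named character vector; @param path file path.
#' @export
write_fasta <- function(sequences, path) {
  x <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(x))) names(x) <- sprintf("seq%d", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path)
  as.character(Biostrings::readDNAStringSet(path))
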