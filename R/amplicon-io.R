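# Amplicon read layout: 8-nt sample barcode, then a constant vector flank,
# the 20-nt guide spacer, and a 3' flank. The flank defaults are the U6
# promoter tail / scaffold head of common lentiviral sgRNA vectors; for real
# data they are configuration, not assumptions.
DEFAULT_FLANK5 <- "TTGTGGAAAGGACGAAACACCG"
DEFAULT_FLANK3 <- "GTTTAAGAGCTAAGCTGGAA"

#' Deterministic sample barcodes
#'
#' Generates unique 8-nt barcodes for a set of samples, with pairwise
#' Hamming distance >= 3 so single-mismatch demultiplexing stays
#' unambiguous.
#'
#' @param samples Character vector of sample names.
#' @param seed Optional integer seed.
#' @return Named character vector of 8-nt barcodes.
#' @export
sample_barcodes <- function(samples, seed = NULL) {
  if (anyDuplicated(samples)) abort("`samples` must be unique.")
  with_seed(seed, {
    out <- character(0)
    while (length(out) < length(samples)) {
      cand <- paste(sample(c("A", "C", "G", "T"), 8, replace = TRUE),
                    collapse = "")
      if (all(vapply(out, hamming, 0L, b = cand) >= 3L)) out <- c(out, cand)
    }
    setNames(out, samples)
  })
}

hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

#' Write synthetic amplicon reads to FASTQ
#'
#' Emits one read per counted guide occurrence:
#' `barcode + 5' flank + guide + 3' flank`, optionally corrupted with
#' uniform substitution errors. With `error_rate = 0` the reads quantify
#' back to the input counts exactly ([quantify_amplicons()]).
#'
#' @param counts A `screen_counts` tibble.
#' @param library The `guide_library` the counts refer to.
#' @param path Output FASTQ path.
#' @param barcodes Named character vector sample -> 8-nt barcode; defaults to
#'   [sample_barcodes()] on the count columns (deterministic given `seed`).
#' @param flank5,flank3 Constant flanks around the guide.
#' @param error_rate Per-base substitution probability in `[0, 1)`.
#' @param base_quality Constant Phred score written for every base.
#' @param seed Optional integer seed (errors and barcode generation).
#' @return Invisibly, a list with the `path`, the `barcodes` used, and
#'   `n_reads` written.
#' @export
write_amplicon_fastq <- function(counts, library, path, barcodes = NULL,
                                 flank5 = DEFAULT_FLANK5,
                                 flank3 = DEFAULT_FLANK3,
                                 error_rate = 0, base_quality = 37L,
                                 seed = NULL) {
  validate_guide_library(library)
  error_rate <- check_number(error_rate, "error_rate", 0, 1 - 1e-12)
  samples <- screen_design(counts)$sample
  with_seed(seed, {
    if (is.null(barcodes)) barcodes <- sample_barcodes(samples)
    validate_barcodes(barcodes, samples)
    seq_of <- setNames(library$sequence, library$guide_id)
    reads <- vector("list", length(samples))
    for (i in seq_along(samples)) {
      s <- samples[i]
      cnt <- counts[[s]]
      if (any(cnt < 0) || any(cnt != round(cnt))) {
        abort(sprintf("Counts in sample `%s` must be non-negative integers.", s))
      }
      keep <- cnt > 0
      reads[[i]] <- paste0(barcodes[[s]], flank5,
                           rep(seq_of[counts$guide_id[keep]], cnt[keep]),
                           flank3)
    }
    reads <- unlist(reads, use.names = FALSE)
    if (error_rate > 0 && length(reads)) {
      reads <- substitute_errors(reads, error_rate)
    }
    n <- length(reads)
    qual <- strrep(intToUtf8(33L + as.integer(base_quality)),
                   if (n) nchar(reads[1]) else 0L)
    dna <- Biostrings::DNAStringSet(reads)
    names(dna) <- sprintf("read_%07d", seq_len(n))
    qs <- Biostrings::QualityScaledDNAStringSet(
      dna, Biostrings::PhredQuality(rep(qual, n)))
    Biostrings::writeQualityScaledXStringSet(qs, path)
    invisible(list(path = path, barcodes = barcodes, n_reads = n))
  })
}

validate_barcodes <- function(barcodes, samples = NULL) {
  if (is.null(names(barcodes)) || any(!nzchar(names(barcodes)))) {
    abort("`barcodes` must be named by sample.")
  }
  if (any(nchar(barcodes) != 8L)) abort("Barcodes must be 8 nt.")
  if (anyDuplicated(barcodes)) abort("Barcodes must be unique across samples.")
  if (!is.null(samples) && !all(samples %in% names(barcodes))) {
    abort("Every sample needs a barcode.")
  }
  invisible(barcodes)
}

# Random substitutions at `rate` per base. Error positions are drawn
# jointly; reads with several errors are patched over successive rounds so
# every substitution lands.
substitute_errors <- function(reads, rate) {
  len <- nchar(reads[1])
  n_err <- rbinom(1L, length(reads) * len, rate)
  if (n_err == 0L) return(reads)
  at_read <- sample.int(length(reads), n_err, replace = TRUE)
  at_pos <- sample.int(len, n_err, replace = TRUE)
  sub <- sample(c("A", "C", "G", "T"), n_err, replace = TRUE)
  # a substitution equal to the original base is a silent no-op; that makes
  # the realised per-base change rate 3/4 * rate unless we resample, so draw
  # replacements conditioned on differing from the current base
  repeat {
    cur <- substr(reads[at_read], at_pos, at_pos)
    same <- sub == cur
    if (!any(same)) break
    sub[same] <- sample(c("A", "C", "G", "T"), sum(same), replace = TRUE)
  }
  while (length(at_read)) {
    first <- !duplicated(at_read)
    idx <- at_read[first]
    patched <- reads[idx]
    substr(patched, at_pos[first], at_pos[first]) <- sub[first]
    reads[idx] <- patched
    at_read <- at_read[!first]; at_pos <- at_pos[!first]; sub <- sub[!first]
  }
  reads
}
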