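#' Read amplicon FASTQ into a read batch
#'
#' @param path FASTQ path (Phred+33).
#' @return A tibble of class `read_batch` with columns `sequence` and
#'   `quality`.
#' @export
read_amplicon_fastq <- function(path) {
  # Biostrings warns when dropping its own metadata columns on subsetting;
  # nothing we need is lost
  qs <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  out <- tibble(sequence = as.character(qs),
                quality = as.character(Biostrings::quality(qs)))
  class(out) <- c("read_batch", class(out))
  out
}

#' Quality-filter reads
#'
#' Retains reads whose mean Phred score is at least `min_mean_q` — the
#' conventional reading of removing reads with poor sequencing quality for
#' amplicon data.
#'
#' @param batch A `read_batch` tibble.
#' @param min_mean_q Minimum mean Phred score (default 20).
#' @return The retained reads, with the retained fraction reported via
#'   message and attached as attribute `retained_fraction`.
#' @export
filter_reads <- function(batch, min_mean_q = 20) {
  min_mean_q <- check_number(min_mean_q, "min_mean_q", lower = 0)
  if (any(nchar(batch$sequence) != nchar(batch$quality))) {
    abort("Malformed read batch: sequence and quality lengths differ.")
  }
  keep <- phred_means(batch$quality) >= min_mean_q
  out <- batch[keep, ]
  frac <- if (nrow(batch)) mean(keep) else 1
  inform(sprintf("filter_reads: retained %d/%d reads (%.1f%%)",
                 sum(keep), nrow(batch), 100 * frac))
  attr(out, "retained_fraction") <- frac
  class(out) <- unique(c("read_batch", class(out)))
  out
}

#' Demultiplex reads by sample barcode
#'
#' Assigns each read to at most one sample by the 8-nt barcode at
#' `barcode_position`. With `max_mismatch > 0`, barcodes must be pairwise
#' separated by more than `2 * max_mismatch` Hamming distance, checked
#' before any read is processed.
#'
#' @param batch A `read_batch` tibble.
#' @param barcodes Named character vector sample -> barcode.
#' @param barcode_position 1-based offset of the barcode (default 1).
#' @param max_mismatch Maximum substitutions tolerated (default 0, exact).
#' @return The batch with a `sample` column (`NA` for unassigned reads) and
#'   an `assignment` attribute tabulating reads per sample plus unassigned.
#' @export
demultiplex_reads <- function(batch, barcodes, barcode_position = 1,
                              max_mismatch = 0) {
  validate_barcodes(barcodes)
  max_mismatch <- check_positive_int(max_mismatch, "max_mismatch", min = 0L)
  bl <- nchar(barcodes[[1]])
  if (max_mismatch > 0) {
    bc <- unname(barcodes)
    for (i in seq_along(bc)) for (j in seq_len(i - 1L)) {
      if (hamming(bc[i], bc[j]) <= 2L * max_mismatch) {
        abort(sprintf(
          "Barcodes `%s` and `%s` are ambiguous at max_mismatch = %d.",
          bc[i], bc[j], max_mismatch))
      }
    }
  }
  observed <- substr(batch$sequence, barcode_position,
                     barcode_position + bl - 1L)
  idx <- match(observed, barcodes)
  if (max_mismatch > 0 && anyNA(idx)) {
    miss <- which(is.na(idx))
    uo <- unique(observed[miss])
    dm <- vapply(uo, function(o) {
      d <- vapply(unname(barcodes), hamming, 0L, a = o)
      if (min(d) <= max_mismatch) which.min(d) else NA_integer_
    }, 0L)
    idx[miss] <- dm[match(observed[miss], uo)]
  }
  out <- mutate(batch, sample = names(barcodes)[idx])
  tab <- table(factor(out$sample, levels = names(barcodes)), useNA = "no")
  attr(out, "assignment") <- tibble(
    sample = c(names(barcodes), "unassigned"),
    reads = c(as.integer(tab), sum(is.na(idx))))
  class(out) <- unique(c("read_batch", class(out)))
  out
}

#' Count guide occurrences in a read batch
#'
#' Locates the 20-nt guide in each read — by searching for a constant 5'
#' anchor (the vector flank) and reading the next 20 nt, falling back to a
#' fixed offset when the anchor is absent — and maps it to the library by
#' exact sequence identity. Optionally rescues single-substitution guides.
#'
#' @param batch A `read_batch` tibble.
#' @param library A `guide_library`.
#' @param anchor Constant 5' flank to search for (default the vector flank
#'   used by [write_amplicon_fastq()]); NULL disables the search.
#' @param guide_offset 1-based fallback offset of the guide when the anchor
#'   is not found (default barcode + flank width).
#' @param max_mismatch 0 (exact, default) or 1 (single-substitution rescue).
#' @return A tibble `guide_id`, `count` covering the whole library, with
#'   attributes `unmapped` (reads without a library match) and
#'   `mapping_rate`.
#' @export
count_guides <- function(batch, library, anchor = DEFAULT_FLANK5,
                         guide_offset = NULL, max_mismatch = 0) {
  validate_guide_library(library)
  max_mismatch <- check_positive_int(max_mismatch, "max_mismatch", min = 0L)
  if (max_mismatch > 1L) abort("Only max_mismatch 0 or 1 is supported.")
  n <- nrow(batch)
  if (is.null(guide_offset)) {
    guide_offset <- 9L + if (is.null(anchor)) 0L else nchar(anchor)
  }
  start <- rep(as.integer(guide_offset), n)
  if (!is.null(anchor) && n) {
    hit <- regexpr(anchor, batch$sequence, fixed = TRUE)
    found <- hit > 0L
    start[found] <- hit[found] + nchar(anchor)
    if (n > 10L && mean(found) < 0.01) {
      warn(sprintf(
        "Anchor `%s` found in %.1f%% of reads; check the read layout.",
        anchor, 100 * mean(found)))
    }
  }
  observed <- substr(batch$sequence, start, start + 19L)
  idx <- match(observed, library$sequence)
  if (max_mismatch == 1L && anyNA(idx)) {
    idx[is.na(idx)] <- rescue_one_mismatch(observed[is.na(idx)],
                                           library$sequence)
  }
  counts <- tabulate(idx, nbins = nrow(library))
  unmapped <- sum(is.na(idx))
  out <- tibble(guide_id = library$guide_id, count = counts)
  attr(out, "unmapped") <- unmapped
  attr(out, "mapping_rate") <- if (n) 1 - unmapped / n else NA_real_
  inform(sprintf("count_guides: mapped %d/%d reads (%.1f%%)",
                 n - unmapped, n, if (n) 100 * (1 - unmapped / n) else 100))
  out
}

# Single-substitution rescue: look each unmapped 20-mer up against every
# 1-Hamming neighbour (20 positions x 3 bases). Ambiguous rescues (two
# library guides at distance 1) are left unmapped.
rescue_one_mismatch <- function(observed, sequences) {
  uo <- unique(observed)
  bases <- c("A", "C", "G", "T")
  res <- vapply(uo, function(o) {
    hits <- integer(0)
    for (pos in 1:20) {
      cur <- substr(o, pos, pos)
      for (b in bases[bases != cur]) {
        cand <- o
        substr(cand, pos, pos) <- b
        m <- match(cand, sequences)
        if (!is.na(m)) hits <- c(hits, m)
      }
    }
    hits <- unique(hits)
    if (length(hits) == 1L) hits else NA_integer_
  }, 0L)
  res[match(observed, uo)]
}

#' Quantify guides from amplicon FASTQ
#'
#' Full quantification chain: FASTQ -> quality filter -> barcode
#' demultiplexing -> guide extraction and exact mapping. The inverse of
#' [write_amplicon_fastq()] at `error_rate = 0`.
#'
#' @inheritParams count_guides
#' @inheritParams filter_reads
#' @inheritParams demultiplex_reads
#' @param path FASTQ path.
#' @param design Optional sample sheet (`sample`, `role`, `replicate`) to
#'   attach to the result; defaults to samples in barcode order with
#'   unknown roles.
#' @return A `screen_counts` tibble (guide_id x samples) with a `qc`
#'   attribute (reads in, retained, assigned, mapped per sample).
#' @export
quantify_amplicons <- function(path, library, barcodes, min_mean_q = 20,
                               max_mismatch = 0, anchor = DEFAULT_FLANK5,
                               guide_offset = NULL, design = NULL) {
  batch <- read_amplicon_fastq(path)
  n_in <- nrow(batch)
  batch <- filter_reads(batch, min_mean_q)
  batch <- demultiplex_reads(batch, barcodes)
  cols <- list(guide_id = library$guide_id)
  qc <- list()
  for (s in names(barcodes)) {
    sub <- batch[!is.na(batch$sample) & batch$sample == s, ]
    cv <- count_guides(sub, library, anchor = anchor,
                       guide_offset = guide_offset,
                       max_mismatch = max_mismatch)
    cols[[s]] <- cv$count
    qc[[s]] <- tibble(sample = s, reads = nrow(sub),
                      mapped = nrow(sub) - attr(cv, "unmapped"))
  }
  out <- as_tibble(cols)
  attr(out, "design") <- design %||% tibble(sample = names(barcodes),
                                            role = NA_character_,
                                            replicate = NA_integer_)
  attr(out, "qc") <- mutate(bind_rows(qc), reads_in = n_in)
  class(out) <- c("screen_counts", class(out))
  out
}
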