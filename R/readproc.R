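#' @name readproc
#' @title Read preprocessing: demultiplexing, UMI collapse, trimming
#'
#' @description Pooled PRO-IP-seq libraries carry a 6-nt inline sample
#' barcode in the 3'-adapter (read 1 therefore begins with barcode + constant
#' C) and a 6-nt UMI next to the constant C of the 5'-adapter (read 2 begins
#' with UMI + C). Preprocessing separates the pool by barcode, collapses PCR
#' duplicates on (UMI, sequence), removes adapters and the two fixed 7-nt
#' tags, and reverse-complements read 1 so the stored sequence runs 5'-3' of
#' the nascent RNA.
NULL

# printed adapter sequences of the library design (read 1 / read 2)
adapter_read1 <- function() "TGGAATTCTCGGGTGCCAAGGAACTCCAGTCAC"
adapter_read2 <- function() "GATCGTCGGACTGTAGAACTCTGAACGTGTAGATCTCGGTGGTCGCCGTATCATT"

#' Reverse complement of DNA strings
#' @param x Character vector of DNA sequences (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Extract the inline barcode and UMI from raw reads
#'
#' The barcode is the first 6 nt of read 1 (it precedes the constant C of
#' the 3'-adapter ligation site). The UMI is the first 6 nt of read 2 when
#' paired-end; for single-end reads the UMI is recovered from the 3'-side of
#' read 1 (reverse complement of the 6 nt preceding the read-1 adapter,
#' after the constant G), when the read runs through the 5'-adapter.
#'
#' @param reads Tibble with columns `read1` and optionally `read2`.
#' @return `reads` with `barcode` and `umi` columns added (`NA` UMI when it
#'   cannot be recovered from a single-end read).
#' @export
extract_tags <- function(reads) {
  reads <- as_tibble(reads)
  reads$barcode <- substr(reads$read1, 1, 6)
  if ("read2" %in% names(reads)) {
    reads$umi <- substr(reads$read2, 1, 6)
  } else {
    hit <- regexpr(adapter_read1(), reads$read1, fixed = TRUE)
    umi <- rep(NA_character_, nrow(reads))
    ok <- hit >= 8L  # need G + 6 nt before the adapter
    umi[ok] <- revcomp(substr(reads$read1[ok], hit[ok] - 6L, hit[ok] - 1L))
    reads$umi <- umi
  }
  reads
}

hamming <- function(a, b) {
  mapply(function(x, y) sum(strsplit(x, "")[[1]] != strsplit(y, "")[[1]]),
         a, b, USE.NAMES = FALSE)
}

validate_barcode_table <- function(barcode_table, max_mismatch) {
  bt <- as_tibble(barcode_table)
  stopifnot(all(c("sample", "barcode") %in% names(bt)))
  if (anyDuplicated(bt$barcode) || anyDuplicated(bt$sample)) {
    abort("barcode table: samples and barcodes must be unique")
  }
  if (any(!grepl("^[ACGT]{6}$", bt$barcode))) {
    abort("barcode table: barcodes must be 6-mers over {A,C,G,T}")
  }
  if (nrow(bt) > 1) {
    pairs <- utils::combn(bt$barcode, 2)
    d <- hamming(pairs[1, ], pairs[2, ])
    if (any(d <= 2 * max_mismatch)) {
      abort(sprintf(
        "barcode table: pairwise Hamming distance must exceed %d for max_mismatch = %d",
        2 * max_mismatch, max_mismatch))
    }
  }
  bt
}

#' Demultiplex a read pool by inline barcode
#'
#' Every read is assigned to the unique sample whose barcode lies within
#' `max_mismatch` of the read's extracted barcode; reads with no match, an
#' ambiguous match (equidistant barcodes), or an N in the barcode are left
#' unassigned. The output is a partition: each input read appears exactly
#' once.
#'
#' @param reads Tibble with a `barcode` column (see [extract_tags()]).
#' @param barcode_table Data frame with columns `sample` and `barcode`;
#'   barcodes must be pairwise more than `2 * max_mismatch` apart (checked).
#' @param max_mismatch Maximum Hamming distance for assignment. Default 0
#'   (exact inline-barcode matching).
#' @return `reads` with a `sample` column (`"unassigned"` for the unassigned
#'   bin); split with e.g. `dplyr::group_split()` if separate bins are
#'   wanted.
#' @export
split_barcodes <- function(reads, barcode_table, max_mismatch = 0) {
  bt <- validate_barcode_table(barcode_table, max_mismatch)
  reads <- as_tibble(reads)
  if (!"barcode" %in% names(reads)) reads <- extract_tags(reads)
  bc <- reads$barcode
  assign <- rep("unassigned", length(bc))
  has_n <- grepl("N", bc, fixed = TRUE)
  if (max_mismatch == 0) {
    idx <- match(bc, bt$barcode)
    ok <- !is.na(idx) & !has_n
    assign[ok] <- bt$sample[idx[ok]]
  } else {
    ubc <- unique(bc[!has_n])
    dmat <- vapply(bt$barcode, function(b) hamming(ubc, rep(b, length(ubc))),
                   numeric(length(ubc)))
    dmat <- matrix(dmat, nrow = length(ubc))
    lab <- apply(dmat, 1, function(d) {
      best <- min(d)
      if (best > max_mismatch || sum(d == best) > 1) "unassigned"
      else bt$sample[which.min(d)]
    })
    m <- match(bc, ubc)
    ok <- !is.na(m)
    assign[ok] <- lab[m[ok]]
  }
  reads$sample <- assign
  reads
}

#' Collapse PCR duplicates by UMI and read sequence
#'
#' Reads are grouped by (UMI, read-1 sequence, read-2 sequence if present)
#' and one representative per group is retained, in first-occurrence order.
#' The operation is idempotent and invariant to duplicating the input.
#'
#' @param reads Tibble with `umi` and `read1` (and optionally `read2`).
#' @return The deduplicated tibble.
#' @export
collapse_umi <- function(reads) {
  reads <- as_tibble(reads)
  stopifnot(all(c("umi", "read1") %in% names(reads)))
  key <- paste(reads$umi, reads$read1,
               if ("read2" %in% names(reads)) reads$read2 else "",
               sep = "\r")
  reads[!duplicated(key), ]
}

#' Collapse PCR duplicates among aligned molecule records
#'
#' Coordinate-level analogue of [collapse_umi()] for the simulator's aligned
#' path: records sharing (UMI, chrom, start, end, strand) are one molecule.
#'
#' @param records Tibble with `umi`, `chrom`, `start`, `end`, `strand`.
#' @return The deduplicated tibble.
#' @export
collapse_umi_records <- function(records) {
  records <- as_tibble(records)
  key <- paste(records$umi, records$chrom, records$start, records$end,
               records$strand, sep = "\r")
  records[!duplicated(key), ]
}

# remove the first full adapter occurrence; reads truncated mid-adapter are
# handled by matching adapter prefixes (>= min_overlap nt) at the read end
trim_adapter <- function(seq, adapter, min_overlap = 5L) {
  hit <- regexpr(adapter, seq, fixed = TRUE)
  found <- hit > 0
  seq[found] <- substr(seq[found], 1, hit[found] - 1L)
  todo <- which(!found)
  for (i in todo) {
    n <- nchar(seq[i])
    for (k in seq(min(n, nchar(adapter) - 1L), min_overlap)) {
      if (substr(seq[i], n - k + 1L, n) == substr(adapter, 1L, k)) {
        seq[i] <- substr(seq[i], 1L, n - k)
        break
      }
    }
  }
  seq
}

#' Trim adapters and fixed 7-nt tags; orient read 1 along the nascent RNA
#'
#' Removes the read-1 and read-2 adapter occurrences, the 7-nt barcode + C
#' tag at the start of read 1 (with the trailing G + reverse-complement UMI
#' when read 1 ran through the 5'-adapter), the 7-nt UMI + C tag at the start
#' of read 2, and reverse-complements read 1 so the stored sequence runs
#' 5'-3' along the nascent RNA. Reads left empty are dropped and counted.
#'
#' @param reads Tibble with `read1` (and optionally `read2`, `qual1`,
#'   `qual2`).
#' @param adapter1,adapter2 Adapter sequences to remove (defaults: the
#'   library's read-1 / read-2 adapters).
#' @return The processed tibble; the number of dropped reads is in
#'   `attr(, "n_dropped")`.
#' @export
trim_and_orient <- function(reads, adapter1 = adapter_read1(),
                            adapter2 = adapter_read2()) {
  reads <- as_tibble(reads)
  r1 <- reads$read1
  len_before <- nchar(r1)
  r1 <- trim_adapter(r1, adapter1)
  had_adapter <- nchar(r1) < len_before
  r1 <- substr(r1, 8, nchar(r1))          # barcode + constant C
  ran_through <- had_adapter & nchar(r1) > 7
  r1[ran_through] <- substr(r1[ran_through], 1,
                            nchar(r1[ran_through]) - 7L)  # G + revcomp UMI
  keep <- nchar(r1) >= 1
  out <- reads[keep, ]
  out$read1 <- revcomp(r1[keep])
  if ("qual1" %in% names(out)) out$qual1 <- strrep("I", nchar(out$read1))
  if ("read2" %in% names(out)) {
    r2 <- trim_adapter(out$read2, adapter2)
    r2 <- substr(r2, 8, nchar(r2))        # UMI + constant C
    out$read2 <- r2
    if ("qual2" %in% names(out)) out$qual2 <- strrep("I", nchar(r2))
  }
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Run the full preprocessing chain on a pooled read set
#'
#' [extract_tags()], [split_barcodes()], per-sample [collapse_umi()], then
#' [trim_and_orient()]; per-stage read counts are returned alongside.
#'
#' @inheritParams split_barcodes
#' @inheritParams trim_and_orient
#' @return A list: `reads` (processed tibble with `sample` column, unassigned
#'   reads removed), `log` (tibble of per-stage, per-sample counts).
#' @export
preprocess_reads <- function(reads, barcode_table, max_mismatch = 0,
                             adapter1 = adapter_read1(),
                             adapter2 = adapter_read2()) {
  tagged <- extract_tags(reads)
  split <- split_barcodes(tagged, barcode_table, max_mismatch)
  input_counts <- split |> count(.data$sample, name = "n_input")
  assigned <- split |> filter(.data$sample != "unassigned")
  dedup <- assigned |>
    group_by(.data$sample) |>
    dplyr::group_modify(~ collapse_umi(.x)) |>
    ungroup()
  trimmed <- trim_and_orient(dedup, adapter1, adapter2)
  log <- input_counts |>
    left_join(dedup |> count(.data$sample, name = "n_dedup"), by = "sample") |>
    left_join(trimmed |> count(.data$sample, name = "n_out"), by = "sample") |>
    mutate(across(c("n_dedup", "n_out"),
                  ~ ifelse(is.na(.x) & sample != "unassigned", 0L, .x)))
  list(reads = trimmed, log = log)
}
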