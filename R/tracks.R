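#' Single-nucleotide end-count tracks
#'
#' PRO-IP-seq maps engaged Pol II at nucleotide resolution: the 3'-most
#' nucleotide of a nascent RNA marks the active site of transcription and its
#' 5'-most nucleotide the initiating nucleotide. An `end_track` stores one of
#' those two signals as a sparse, strand-specific per-nucleotide count table
#' with columns `chrom`, `strand`, `pos` (0-based) and `count`. Metadata
#' (genome, end kind, sample / condition / antibody / replicate) travels in
#' attributes so tracks from different samples cannot be silently mixed.
#'
#' @param x A data frame with columns `chrom`, `strand`, `pos`, `count`.
#' @param genome Genome identifier, e.g. `"primary"` or `"spikein"`.
#' @param end_kind Either `"five_prime"` or `"three_prime"`.
#' @param sample,condition,antibody,replicate Optional sample metadata.
#' @return A tibble of class `end_track`.
#' @export
end_track <- function(x, genome, end_kind = c("three_prime", "five_prime"),
                      sample = NA_character_, condition = NA_character_,
                      antibody = NA_character_, replicate = NA_integer_) {
  end_kind <- match.arg(end_kind)
  x <- as_tibble(x)
  required <- c("chrom", "strand", "pos", "count")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0) {
    abort(paste0("end_track input lacks column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (nrow(x) > 0) {
    if (!all(x$strand %in% c("+", "-"))) {
      abort("end_track strand must be '+' or '-'")
    }
    if (any(x$count < 0)) abort("end_track counts must be non-negative")
    if (any(x$pos < 0)) abort("end_track positions must be non-negative")
  }
  x <- x |>
    dplyr::select(dplyr::all_of(required)) |>
    group_by(.data$chrom, .data$strand, .data$pos) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(.data$chrom, .data$strand, .data$pos)
  structure(
    x,
    class = c("end_track", class(tibble())),
    genome = genome,
    end_kind = end_kind,
    sample_info = list(sample = sample, condition = condition,
                       antibody = antibody, replicate = replicate)
  )
}

track_genome <- function(track) attr(track, "genome", exact = TRUE)
track_end_kind <- function(track) attr(track, "end_kind", exact = TRUE)
track_sample_info <- function(track) attr(track, "sample_info", exact = TRUE)

#' Total counted ends in a track
#' @param track An `end_track`.
#' @return A single number.
#' @export
track_total <- function(track) sum(track$count)

# preserve attributes through a dplyr-style transformation of the table body
retrack <- function(new_tbl, template, count_col = "count") {
  structure(
    as_tibble(new_tbl),
    class = class(template),
    genome = track_genome(template),
    end_kind = track_end_kind(template),
    sample_info = track_sample_info(template),
    norm = attr(template, "norm", exact = TRUE)
  )
}

#' Convert aligned reads to a single-nucleotide end track
#'
#' Each aligned molecule contributes exactly one count at its 5'- or 3'-most
#' genomic nucleotide, on its own strand. Coordinates follow the BED
#' convention (0-based, half-open): for a plus-strand record spanning
#' `[start, end)` the 5'-end is `start` and the 3'-end is `end - 1`; for a
#' minus-strand record the 5'-end is `end - 1` and the 3'-end is `start`.
#'
#' @param reads A data frame of aligned records with columns `chrom`, `start`,
#'   `end`, `strand` (BED6-style; `name`/`score` ignored).
#' @param end_kind `"five_prime"` or `"three_prime"`.
#' @param genome Genome label stored on the track.
#' @inheritParams end_track
#' @return An `end_track`.
#' @export
reads_to_end_track <- function(reads, end_kind = c("three_prime", "five_prime"),
                               genome = "primary",
                               sample = NA_character_, condition = NA_character_,
                               antibody = NA_character_,
                               replicate = NA_integer_) {
  end_kind <- match.arg(end_kind)
  reads <- as_tibble(reads)
  if (nrow(reads) > 0 && (!"strand" %in% names(reads) ||
                          any(!reads$strand %in% c("+", "-")))) {
    abort("reads_to_end_track requires stranded records ('+' or '-')")
  }
  if (nrow(reads) == 0) {
    return(end_track(tibble(chrom = character(), strand = character(),
                            pos = integer(), count = double()),
                     genome = genome, end_kind = end_kind, sample = sample,
                     condition = condition, antibody = antibody,
                     replicate = replicate))
  }
  pos <- if (end_kind == "five_prime") {
    ifelse(reads$strand == "+", reads$start, reads$end - 1L)
  } else {
    ifelse(reads$strand == "+", reads$end - 1L, reads$start)
  }
  end_track(tibble(chrom = reads$chrom, strand = reads$strand,
                   pos = pos, count = 1),
            genome = genome, end_kind = end_kind, sample = sample,
            condition = condition, antibody = antibody, replicate = replicate)
}

#' Merge replicate tracks by summing raw counts
#'
#' Replicates of the same condition/antibody are pooled by position-wise
#' summation of raw counts; the matching spike-in read counts are summed
#' alongside, so normalization factors computed for the merged sample are
#' count-weighted. Merging is commutative and associative.
#'
#' @param tracks A list of `end_track`s sharing genome and end kind.
#' @param spike_counts Optional numeric vector of per-replicate spike-in read
#'   counts (same length as `tracks`).
#' @return If `spike_counts` is supplied, a list with elements `track` and
#'   `spike_count`; otherwise the merged `end_track`.
#' @export
merge_replicates <- function(tracks, spike_counts = NULL) {
  stopifnot(length(tracks) >= 1)
  g <- unique(vapply(tracks, track_genome, character(1)))
  k <- unique(vapply(tracks, track_end_kind, character(1)))
  if (length(g) != 1 || length(k) != 1) {
    abort("merge_replicates: tracks must share genome and end_kind")
  }
  info <- track_sample_info(tracks[[1]])
  merged <- bind_rows(lapply(tracks, as_tibble)) |>
    group_by(.data$chrom, .data$strand, .data$pos) |>
    summarise(count = sum(.data$count), .groups = "drop")
  out <- end_track(merged, genome = g, end_kind = k,
                   sample = info$sample, condition = info$condition,
                   antibody = info$antibody, replicate = NA_integer_)
  if (is.null(spike_counts)) return(out)
  stopifnot(length(spike_counts) == length(tracks))
  list(track = out, spike_count = sum(spike_counts))
}

#' @export
print.end_track <- function(x, ...) {
  info <- track_sample_info(x)
  cat(sprintf("<end_track> %s ends on %s genome (%s positions, %g ends)\n",
              sub("_", "-", track_end_kind(x)), track_genome(x),
              format(nrow(x), big.mark = ","), track_total(x)))
  if (!is.na(info$sample)) {
    cat(sprintf("  sample: %s  condition: %s  antibody: %s\n",
                info$sample, info$condition, info$antibody))
  }
  NextMethod()
}

#' @importFrom generics glance
#' @export
generics::glance

#' Summarise an end track
#' @param x An `end_track`.
#' @param ... Unused.
#' @return A one-row tibble with genome, end kind, number of covered
#'   positions and total counted ends.
#' @export
glance.end_track <- function(x, ...) {
  info <- track_sample_info(x)
  tibble(genome = track_genome(x), end_kind = track_end_kind(x),
         sample = info$sample, condition = info$condition,
         antibody = info$antibody, n_positions = nrow(x),
         total_count = track_total(x))
}

# Pre-split a sparse track into per-(chrom, strand) position/value vectors so
# repeated per-gene window queries avoid rescanning the whole table.
track_index <- function(track, value_col = "count") {
  key <- paste0(track$chrom, "|", track$strand)
  idx <- lapply(split(seq_len(nrow(track)), key), function(i) {
    list(pos = track$pos[i], val = track[[value_col]][i])
  })
  structure(idx, class = "track_index")
}

# Dense numeric vector of counts at strand-aware offsets `from..to` relative
# to `anchor` (offset 0 = anchor, positive = downstream in the direction of
# transcription).  Offsets outside [0, chrom_length) are clipped to NA.
# `orient` overrides the scan direction (used when querying the opposite
# genomic strand in the gene's own frame, e.g. divergent signal).
window_counts <- function(track, chrom, strand, anchor, from, to,
                          chrom_length = NULL, value_col = "count",
                          orient = strand) {
  if (!inherits(track, "track_index")) {
    track <- track_index(track, value_col = value_col)
  }
  offs <- from:to
  dir <- if (orient == "+") 1L else -1L
  pos <- anchor + dir * offs
  vals <- numeric(length(pos))
  sub <- track[[paste0(chrom, "|", strand)]]
  if (!is.null(sub)) {
    hit_idx <- match(pos, sub$pos)
    hit <- !is.na(hit_idx)
    vals[hit] <- sub$val[hit_idx[hit]]
  }
  oob <- pos < 0
  if (!is.null(chrom_length)) oob <- oob | pos >= chrom_length
  vals[oob] <- NA_real_
  names(vals) <- offs
  vals
}
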