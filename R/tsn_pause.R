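#' @name tsn_pause
#' @title Transcription start nucleotide and pause nucleotide calling
#'
#' @description Reference-genome TSS annotations report the longest isoform,
#' not the nucleotide where initiation actually occurs; nascent-RNA 5'-ends
#' pinpoint it. The TSN (+1 nt) of a gene is the position with the highest
#' 5'-end count in the strand-aware window -100..+400 around the annotated
#' TSS. The pause nucleotide is the position with the highest 3'-end count in
#' the same window; its distance from the TSN is reported on the 1-based
#' scale (+1 = TSN, no position 0, -1 = first upstream nucleotide) and
#' classified as early (+1..+30), late (+31..+60) or outside.
NULL

# 1-based distance-from-TSN convention: downstream offset d (0 = TSN) -> d+1;
# upstream offset -d -> -d.
offset_to_distance <- function(offset) {
  ifelse(offset >= 0, offset + 1L, offset)
}

argmax_upstream <- function(vals) {
  # index of the maximum, ties broken to the smallest index (most upstream)
  which.max(vals)
}

#' Call transcription start nucleotides
#'
#' @param five_prime A 5'-end `end_track`.
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `tss`, optional
#'   `chrom_length` used to clip the query window).
#' @param window Strand-aware query window around the annotated TSS, in nt
#'   (default `c(-100, 400)`).
#' @return A tibble with one row per gene: `gene_id`, `called`, `tsn`
#'   (absolute 0-based coordinate), `tsn_offset` (nt from TSS, downstream
#'   positive), `tsn_count`. Genes with no 5'-end signal in the window are
#'   not called. Argmax ties break to the most upstream position.
#' @export
call_tsn <- function(five_prime, genes, window = c(-100, 400)) {
  genes <- as_tibble(genes)
  idx <- track_index(five_prime)
  n <- nrow(genes)
  tsn <- rep(NA_integer_, n)
  off <- rep(NA_integer_, n)
  cnt <- rep(NA_real_, n)
  called <- rep(FALSE, n)
  cl <- if ("chrom_length" %in% names(genes)) genes$chrom_length else
    rep(NA_real_, n)
  for (i in seq_len(n)) {
    v <- window_counts(idx, genes$chrom[i], genes$strand[i], genes$tss[i],
                       window[1], window[2],
                       chrom_length = if (is.na(cl[i])) NULL else cl[i])
    v[is.na(v)] <- -Inf  # clipped positions can never win
    if (!any(is.finite(v) & v > 0)) next
    j <- argmax_upstream(v)
    called[i] <- TRUE
    off[i] <- as.integer(names(v)[j])
    dir <- if (genes$strand[i] == "+") 1L else -1L
    tsn[i] <- genes$tss[i] + dir * off[i]
    cnt[i] <- v[j]
  }
  tibble(gene_id = genes$gene_id, called = called, tsn = tsn,
         tsn_offset = off, tsn_count = cnt)
}

#' Call pause nucleotides and classify them
#'
#' @param three_prime A 3'-end `end_track`.
#' @param tsn_calls Output of [call_tsn()] for the same genes.
#' @param genes Gene tibble as in [call_tsn()].
#' @param window Query window around the annotated TSS (same convention as
#'   [call_tsn()]).
#' @return A tibble per gene: `gene_id`, `pause_coord`, `pause_distance`
#'   (1-based from the TSN), `pause_class` (`early`, `late`, `outside`,
#'   `none`), `pause_count`, plus `fraction_early` / `fraction_late` from
#'   [pause_fraction()]. Genes without a called TSN or without 3'-end signal
#'   get class `none`.
#' @export
call_pause <- function(three_prime, tsn_calls, genes, window = c(-100, 400)) {
  genes <- as_tibble(genes)
  calls <- left_join(as_tibble(tsn_calls), genes, by = "gene_id")
  idx <- track_index(three_prime)
  n <- nrow(calls)
  coord <- rep(NA_integer_, n)
  dist <- rep(NA_integer_, n)
  cls <- rep("none", n)
  cnt <- rep(NA_real_, n)
  fe <- fl <- rep(NA_real_, n)
  cl <- if ("chrom_length" %in% names(calls)) calls$chrom_length else
    rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (!isTRUE(calls$called[i])) next
    v <- window_counts(idx, calls$chrom[i], calls$strand[i], calls$tss[i],
                       window[1], window[2],
                       chrom_length = if (is.na(cl[i])) NULL else cl[i])
    v[is.na(v)] <- -Inf
    fr <- pause_fraction_one(idx, calls$chrom[i], calls$strand[i],
                             calls$tsn[i])
    fe[i] <- fr[1]; fl[i] <- fr[2]
    if (!any(is.finite(v) & v > 0)) next
    j <- argmax_upstream(v)
    off <- as.integer(names(v)[j])
    dir <- if (calls$strand[i] == "+") 1L else -1L
    coord[i] <- calls$tss[i] + dir * off
    # distance from the TSN on the 1-based scale
    d0 <- off - calls$tsn_offset[i]
    dist[i] <- offset_to_distance(d0)
    cls[i] <- if (dist[i] >= 1 && dist[i] <= 30) "early"
      else if (dist[i] >= 31 && dist[i] <= 60) "late"
      else "outside"
    cnt[i] <- v[j]
  }
  tibble(gene_id = calls$gene_id, pause_coord = coord, pause_distance = dist,
         pause_class = cls, pause_count = cnt,
         fraction_early = fe, fraction_late = fl)
}

pause_fraction_one <- function(idx, chrom, strand, tsn) {
  v <- window_counts(idx, chrom, strand, tsn, 0, 59)
  v[is.na(v)] <- 0
  early <- sum(v[1:30])
  late <- sum(v[31:60])
  tot <- early + late
  if (tot <= 0) c(0, 0) else c(early / tot, late / tot)
}

#' Early / late pause fractions for one gene
#'
#' Area-under-the-curve shares of 3'-end signal in the early (+1..+30) and
#' late (+31..+60) pause windows, each divided by the total over +1..+60.
#' Both are 0 when the pause region carries no signal.
#'
#' @param three_prime A 3'-end `end_track`.
#' @param chrom,strand,tsn Location of the gene's called TSN (0-based
#'   coordinate).
#' @return Named numeric vector `c(fraction_early, fraction_late)`.
#' @export
pause_fraction <- function(three_prime, chrom, strand, tsn) {
  fr <- pause_fraction_one(track_index(three_prime), chrom, strand, tsn)
  c(fraction_early = fr[1], fraction_late = fr[2])
}

#' Detect whether a gene shows a clear pause
#'
#' A gene has a clear promoter-proximal pause when the maximum 3'-end count
#' in +1..+60 from the TSN reaches `min_count` and exceeds `enrichment`
#' times the median per-nucleotide 3'-end count over the downstream
#' background window +201..+400.
#'
#' @inheritParams pause_fraction
#' @param min_count Minimum peak count (default 5).
#' @param enrichment Minimum peak / background-median ratio (default 3).
#' @return Logical.
#' @export
detect_clear_pause <- function(three_prime, chrom, strand, tsn,
                               min_count = 5, enrichment = 3) {
  idx <- if (inherits(three_prime, "track_index")) three_prime else
    track_index(three_prime)
  pause <- window_counts(idx, chrom, strand, tsn, 0, 59)
  pause[is.na(pause)] <- 0
  bg <- window_counts(idx, chrom, strand, tsn, 200, 399)
  bg[is.na(bg)] <- 0
  peak <- max(pause)
  bg_med <- median(bg)
  peak >= min_count && peak >= enrichment * bg_med
}

#' Summarise TSN-TSS offsets across called genes
#'
#' @param tsn_calls Output of [call_tsn()].
#' @param breaks Histogram bin edges over the offset range (default 1-nt bins
#'   over -100..+400).
#' @return A list: `mean`, `median`, `n_called`, and `histogram` (tibble
#'   `offset`, `n` at 1-nt resolution).
#' @export
tss_offset_stats <- function(tsn_calls, breaks = seq(-100.5, 400.5, by = 1)) {
  calls <- filter(as_tibble(tsn_calls), .data$called)
  if (nrow(calls) == 0) abort("no called TSNs")
  h <- graphics::hist(calls$tsn_offset, breaks = breaks, plot = FALSE)
  list(mean = mean(calls$tsn_offset), median = median(calls$tsn_offset),
       n_called = nrow(calls),
       histogram = tibble(offset = h$mids, n = h$counts))
}
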