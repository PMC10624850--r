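#' @name spikein
#' @title Spike-in genome masking and counting
#'
#' @description The spike-in (foreign chromatin added at a fixed proportion
#' before the run-on reaction) provides the external normalization reference.
#' To keep primary-genome reads from inflating the spike-in count, regions of
#' the spike-in genome where deep primary-genome nascent-RNA data
#' cross-maps are masked: the mask is the merged union of those foreign
#' alignments, masked bases are set to N, and spike-in reads overlapping the
#' mask are excluded from counting.
NULL

#' Build a cross-mapping mask from foreign alignments
#'
#' @param foreign_alignments Tibble of BED-style records (`chrom`, `start`,
#'   `end`; 0-based half-open) of primary-genome reads aligned to the
#'   spike-in genome.
#' @param chrom_lengths Optional named vector of spike-in chromosome lengths;
#'   out-of-bounds records are clipped with a warning.
#' @return A tibble of class `mask_set` with sorted, merged, disjoint
#'   intervals (`chrom`, `start`, `end`).
#' @export
build_crossmap_mask <- function(foreign_alignments, chrom_lengths = NULL) {
  aln <- as_tibble(foreign_alignments)
  if (nrow(aln) == 0) {
    return(structure(tibble(chrom = character(), start = integer(),
                            end = integer()),
                     class = c("mask_set", class(tibble()))))
  }
  if (!is.null(chrom_lengths)) {
    unknown <- setdiff(unique(aln$chrom), names(chrom_lengths))
    if (length(unknown) > 0) {
      abort(paste0("foreign alignments on unknown spike-in chromosome(s): ",
                   paste(unknown, collapse = ", ")))
    }
    lim <- chrom_lengths[aln$chrom]
    if (any(aln$start < 0 | aln$end > lim)) {
      warn("clipping foreign alignments to chromosome bounds")
      aln$start <- pmax(aln$start, 0L)
      aln$end <- pmin(aln$end, lim)
      aln <- aln[aln$end > aln$start, ]
    }
  }
  gr <- GenomicRanges::reduce(GenomicRanges::GRanges(
    aln$chrom, IRanges::IRanges(aln$start + 1L, aln$end)))
  out <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                start = GenomicRanges::start(gr) - 1L,
                end = GenomicRanges::end(gr)) |>
    arrange(.data$chrom, .data$start)
  structure(out, class = c("mask_set", class(tibble())))
}

#' Mask genome sequence with Ns
#'
#' Replaces every base covered by the mask with `N`; sequence lengths and all
#' unmasked bases are unchanged. Idempotent.
#'
#' @param genome A [Biostrings::DNAStringSet] (or named character vector).
#' @param mask A `mask_set` from [build_crossmap_mask()]; its chromosomes
#'   must all be present in `genome`.
#' @return A `DNAStringSet` with masked positions set to N.
#' @export
apply_mask <- function(genome, mask) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  if (nrow(mask) == 0) return(genome)
  unknown <- setdiff(unique(mask$chrom), names(genome))
  if (length(unknown) > 0) {
    abort(paste0("mask chromosome(s) absent from genome: ",
                 paste(unknown, collapse = ", ")))
  }
  for (chr in unique(mask$chrom)) {
    m <- mask[mask$chrom == chr, ]
    at <- IRanges::IRanges(m$start + 1L, m$end)
    repl <- Biostrings::DNAStringSet(strrep("N", IRanges::width(at)))
    genome[[chr]] <- Biostrings::replaceAt(genome[[chr]], at,
                                           as.list(repl))
  }
  genome
}

#' Count usable spike-in reads
#'
#' Counts uniquely mapped spike-in reads whose interval does not overlap the
#' cross-mapping mask by a single base. This count enters the spike-in
#' normalization factor.
#'
#' @param alignments Tibble of spike-in genome records (`chrom`, `start`,
#'   `end`, and a logical `unique` mapping-uniqueness flag; if absent all
#'   records are treated as unique).
#' @param mask A `mask_set` (may be empty).
#' @return Integer count.
#' @export
count_spikein <- function(alignments, mask) {
  aln <- as_tibble(alignments)
  if (nrow(aln) == 0) return(0L)
  uniq <- if ("unique" %in% names(aln)) aln$unique else rep(TRUE, nrow(aln))
  aln <- aln[uniq, ]
  if (nrow(aln) == 0) return(0L)
  if (nrow(mask) == 0) return(nrow(aln))
  reads_gr <- GenomicRanges::GRanges(
    aln$chrom, IRanges::IRanges(aln$start + 1L, aln$end))
  mask_gr <- GenomicRanges::GRanges(
    mask$chrom, IRanges::IRanges(mask$start + 1L, mask$end))
  sum(GenomicRanges::countOverlaps(reads_gr, mask_gr) == 0L)
}

#' Export / import a mask as BED3
#' @param mask A `mask_set`.
#' @param path File path.
#' @return `path` (write) or a `mask_set` (read).
#' @export
write_mask_bed <- function(mask, path) {
  readr::write_tsv(as_tibble(mask), path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_mask_bed
#' @export
read_mask_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = c("chrom", "start", "end"),
                         col_types = "cii", progress = FALSE)
  build_crossmap_mask(raw)
}
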