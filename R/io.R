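#' @name io
#' @title Readers and writers for annotations, tracks and manifests
#' @description All genomic coordinates are stored 0-based internally. BED
#' input is taken as-is; GTF input (1-based) is shifted on import, so the
#' same transcript yields the same gene model from either format. bedGraph
#' tracks are written per strand (`_pl` / `_mn` suffixes), minus-strand
#' values as positive numbers, 0-based half-open intervals, no track lines.
NULL

#' Read gene annotations from BED12/BED6 or GTF
#'
#' @param path Annotation file; dialect inferred from the extension unless
#'   given.
#' @param dialect `"bed"` or `"gtf"`.
#' @param feature For GTF input, the feature type to keep (default
#'   `"transcript"`).
#' @return A gene tibble: `gene_id`, `chrom`, `strand`, `tss`, `cps`
#'   (0-based positions; for a minus-strand gene `tss > cps`). Strandless
#'   records are rejected.
#' @export
read_annotations <- function(path, dialect = NULL, feature = "transcript") {
  if (is.null(dialect)) {
    dialect <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed"
  }
  gr <- rtracklayer::import(path, format = dialect)
  if (dialect == "gtf") {
    keep <- S4Vectors::mcols(gr)$type == feature
    gr <- gr[keep]
    ids <- S4Vectors::mcols(gr)$transcript_id %||%
      S4Vectors::mcols(gr)$gene_id
  } else {
    ids <- S4Vectors::mcols(gr)$name
  }
  if (length(gr) == 0) abort("no usable annotation records")
  strand <- as.character(GenomicRanges::strand(gr))
  if (any(strand == "*")) {
    abort("annotation records must be stranded ('+' or '-')")
  }
  # GRanges is 1-based inclusive; internal convention is 0-based positions
  start0 <- GenomicRanges::start(gr) - 1L
  end0 <- GenomicRanges::end(gr) - 1L
  if (is.null(ids) || any(is.na(ids))) {
    ids <- sprintf("gene%05d", seq_along(gr))
  }
  tibble(gene_id = as.character(ids),
         chrom = as.character(GenomicRanges::seqnames(gr)),
         strand = strand,
         tss = ifelse(strand == "+", start0, end0),
         cps = ifelse(strand == "+", end0, start0))
}

#' Write aligned records as BED6
#' @param records Tibble `chrom`, `start`, `end`, plus optional
#'   `molecule_id` (name) and `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(records, path) {
  records <- as_tibble(records)
  out <- tibble(chrom = records$chrom, start = records$start,
                end = records$end,
                name = records$molecule_id %||% ".",
                score = 0L,
                strand = records$strand %||% ".")
  readr::write_tsv(out, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read BED6 aligned records
#' @param path BED file (>= 6 columns used).
#' @return Tibble `chrom`, `start`, `end`, `molecule_id`, `strand`,
#'   `unique` (all `TRUE`; uniqueness flags from an aligner export can be
#'   joined on afterwards).
#' @export
read_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
         start = GenomicRanges::start(gr) - 1L,
         end = GenomicRanges::end(gr),
         molecule_id = S4Vectors::mcols(gr)$name %||% NA_character_,
         strand = as.character(GenomicRanges::strand(gr)),
         unique = TRUE)
}

#' Write an end track as strand-split bedGraph
#'
#' Produces `<prefix>_pl.bedGraph` and `<prefix>_mn.bedGraph` (0-based
#' half-open single-nucleotide intervals, minus-strand values positive, no
#' track lines). The pair round-trips exactly through
#' [read_track_bedgraph()].
#'
#' @param track An `end_track` or `norm_track`.
#' @param prefix Output path prefix.
#' @return The two file paths, invisibly.
#' @export
write_track_bedgraph <- function(track, prefix) {
  paths <- paste0(prefix, c("_pl", "_mn"), ".bedGraph")
  for (i in 1:2) {
    strand <- c("+", "-")[i]
    sub <- as_tibble(track) |> filter(.data$strand == !!strand)
    out <- tibble(chrom = sub$chrom, start = sub$pos, end = sub$pos + 1,
                  value = sub$count)
    readr::write_tsv(out, paths[i], col_names = FALSE, progress = FALSE)
  }
  invisible(paths)
}

#' Read a strand-split bedGraph pair back into an end track
#'
#' @param prefix Path prefix used by [write_track_bedgraph()].
#' @inheritParams end_track
#' @return An `end_track`.
#' @export
read_track_bedgraph <- function(prefix, genome = "primary",
                                end_kind = c("three_prime", "five_prime"),
                                sample = NA_character_,
                                condition = NA_character_,
                                antibody = NA_character_,
                                replicate = NA_integer_) {
  end_kind <- match.arg(end_kind)
  parts <- lapply(1:2, function(i) {
    path <- paste0(prefix, c("_pl", "_mn")[i], ".bedGraph")
    if (!file.exists(path) || file.size(path) == 0) {
      return(tibble(chrom = character(), strand = character(),
                    pos = double(), count = double()))
    }
    gr <- rtracklayer::import(path, format = "bedGraph")
    df <- tibble(chrom = as.character(GenomicRanges::seqnames(gr)),
                 start0 = GenomicRanges::start(gr) - 1L,
                 end0 = GenomicRanges::end(gr),
                 value = S4Vectors::mcols(gr)$score)
    # expand multi-nt intervals back to per-nucleotide records
    df |>
      mutate(width = .data$end0 - .data$start0) |>
      tidyr::uncount(.data$width, .id = "k") |>
      mutate(pos = .data$start0 + .data$k - 1,
             strand = c("+", "-")[i], count = .data$value) |>
      select("chrom", "strand", "pos", "count")
  })
  end_track(bind_rows(parts), genome = genome, end_kind = end_kind,
            sample = sample, condition = condition, antibody = antibody,
            replicate = replicate)
}

#' Write / read FASTQ from a read tibble
#'
#' @param reads Tibble with `read_id`, `read1`, `qual1` (and `read2`,
#'   `qual2` for the mate file).
#' @param path,path2 Output FASTQ path(s); `path2` omitted for single-end.
#' @return File paths, invisibly.
#' @export
write_fastq <- function(reads, path, path2 = NULL) {
  reads <- as_tibble(reads)
  fq <- function(ids, seqs, quals, p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), con)
  }
  fq(reads$read_id, reads$read1, reads$qual1, path)
  if (!is.null(path2)) {
    stopifnot("read2" %in% names(reads))
    fq(reads$read_id, reads$read2, reads$qual2, path2)
  }
  invisible(c(path, path2))
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path, path2 = NULL) {
  r1 <- Biostrings::readDNAStringSet(path, format = "fastq",
                                     with.qualities = TRUE)
  out <- tibble(read_id = names(r1), read1 = unname(as.character(r1)),
                qual1 = unname(as.character(S4Vectors::mcols(r1)$qualities)))
  if (!is.null(path2)) {
    r2 <- Biostrings::readDNAStringSet(path2, format = "fastq",
                                       with.qualities = TRUE)
    out$read2 <- unname(as.character(r2))
    out$qual2 <- unname(as.character(S4Vectors::mcols(r2)$qualities))
  }
  out
}

#' Write / read genome FASTA
#' @param genome A named `DNAStringSet` or character vector.
#' @param path FASTA path.
#' @return `path` (write) or a `DNAStringSet` (read).
#' @export
write_fasta <- function(genome, path) {
  if (!methods::is(genome, "DNAStringSet")) {
    genome <- Biostrings::DNAStringSet(genome)
  }
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) Biostrings::readDNAStringSet(path)

#' Validate a sample manifest
#'
#' A manifest has one row per sample with `sample`, `condition`, `antibody`,
#' `replicate`, an optional `barcode`, and a logical `control` column
#' designating exactly one control sample. (condition, antibody, replicate)
#' must be unique, barcodes unique within the pool.
#'
#' @param manifest A data frame.
#' @return The validated manifest as a tibble (invisible errors otherwise).
#' @export
validate_manifest <- function(manifest) {
  m <- as_tibble(manifest)
  need <- c("sample", "condition", "antibody", "replicate", "control")
  missing <- setdiff(need, names(m))
  if (length(missing) > 0) {
    abort(paste0("manifest lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (sum(m$control) != 1) abort("manifest must designate exactly one control")
  key <- paste(m$condition, m$antibody, m$replicate)
  if (anyDuplicated(key)) {
    abort("(condition, antibody, replicate) must be unique in the manifest")
  }
  if ("barcode" %in% names(m) && anyDuplicated(stats::na.omit(m$barcode))) {
    abort("barcodes must be unique within a pool")
  }
  m
}

#' @rdname validate_manifest
#' @param path TSV manifest path.
#' @export
read_manifest <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if ("control" %in% names(m)) m$control <- as.logical(m$control)
  validate_manifest(m)
}
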