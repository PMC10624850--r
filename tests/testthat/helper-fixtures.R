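# tiny deterministic fixtures used across the suite

tiny_track <- function(df, end_kind = "three_prime", genome = "primary", ...) {
  end_track(df, genome = genome, end_kind = end_kind, ...)
}

# sparse track from TSS-relative offsets on one gene
offset_track <- function(offsets, counts, chrom = "chr1", strand = "+",
                         anchor = 1000L, end_kind = "three_prime") {
  dir <- if (strand == "+") 1L else -1L
  tiny_track(tibble::tibble(chrom = chrom, strand = strand,
                            pos = anchor + dir * offsets, count = counts),
             end_kind = end_kind)
}

one_gene <- function(strand = "+", tss = 1000L, body = 2000L,
                     chrom_length = 1e6) {
  dir <- if (strand == "+") 1L else -1L
  tibble::tibble(gene_id = "g1", chrom = "chr1", strand = strand,
                 tss = tss, cps = tss + dir * (body - 1L),
                 chrom_length = chrom_length)
}

small_config <- function(...) {
  sim_config(n_genes = 20, genome_length = 3e6, reads_per_sample = 5000,
             seed = 11, ...)
}

# dense-vector oracle for a sparse track restricted to one chrom/strand
dense_counts <- function(track, chrom, strand, length_out) {
  v <- numeric(length_out)
  sub <- track[track$chrom == chrom & track$strand == strand, ]
  if (nrow(sub) > 0) v[sub$pos + 1] <- sub$count
  v
}

random_sparse_track <- function(n, chrom_length = 5000, seed,
                                end_kind = "three_prime") {
  withr::with_seed(seed, {
    tiny_track(tibble::tibble(
      chrom = "chr1",
      strand = sample(c("+", "-"), n, replace = TRUE),
      pos = sample.int(chrom_length, n, replace = TRUE) - 1L,
      count = sample.int(20, n, replace = TRUE)),
      end_kind = end_kind)
  })
}

# attribute-preserving track tweaks for normalization property tests
retrack_scale <- function(track, c_factor) {
  out <- track
  out$count <- out$count * c_factor
  out
}

retrack_half <- function(track) retrack_scale(track, 0.5)

retrack_named <- function(track, sample) {
  attr(track, "sample_info") <- list(sample = sample, condition = NA_character_,
                                     antibody = NA_character_,
                                     replicate = NA_integer_)
  track
}

# independent restatement of the 1-based distance convention (+1 = TSN)
offset_to_distance_ref <- function(d0) ifelse(d0 >= 0, d0 + 1L, d0)
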