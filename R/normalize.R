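#' @name normalize
#' @title RPM and nf-cRPM normalization
#'
#' @description The nf-cRPM (normalization-factor corrected control RPM)
#' scheme scales every sample by three factors: a per-sample spike-in factor
#' against the unphosphorylated-CTD sample of the same run-on reaction
#' (`nf_spikein = spike_count_sample / spike_count_control_antibody`), a
#' per-condition factor from the ends of long (>150 kb) genes where a 30-min
#' perturbation wave cannot have arrived
#' (`nf_longGE = end_count_condition / end_count_reference_condition`,
#' computed on the control antibody), and finally reads-per-million scaling
#' by the sequencing depth of the single designated control sample. The
#' designated control (unphosphorylated CTD, unperturbed condition) therefore
#' has a combined pre-RPM factor of exactly 1.
NULL

#' Per-sample spike-in normalization factor
#'
#' @param sample_spike_count Uniquely mapped, mask-surviving spike-in reads
#'   of the sample.
#' @param control_spike_count Same count for the control-antibody sample of
#'   the same run-on reaction (condition).
#' @return `sample_spike_count / control_spike_count`.
#' @export
compute_nf_spikein <- function(sample_spike_count, control_spike_count) {
  if (any(control_spike_count <= 0)) {
    abort("control spike-in count must be positive")
  }
  sample_spike_count / control_spike_count
}

# strand-aware end window of a gene: the final `cap_fraction` of the body,
# capped at the last `cap_bp` nt before the CPS.  Returns c(from, to) offsets
# relative to the TSS anchor (0-based, downstream positive).
long_gene_end_window <- function(body_length, cap_fraction = 0.25,
                                 cap_bp = 50000) {
  w <- min(ceiling(body_length * cap_fraction), cap_bp)
  c(body_length - w, body_length - 1)
}

#' Between-condition factor from ends of long genes
#'
#' Sums 3'-end counts of the test and reference condition's control-antibody
#' tracks over the end window of every qualifying long gene and returns
#' their ratio. The end window is the final 25% of the gene body, capped at
#' the last 50 kb; genes must exceed `min_length`.
#'
#' @param track_test,track_ref 3'-end `end_track`s of the control antibody in
#'   the test and reference conditions (raw counts).
#' @param genes Gene tibble (`gene_id`, `chrom`, `strand`, `tss`, `cps`).
#' @param min_length Minimum gene length in bp (default 150,000).
#' @param cap_fraction,cap_bp End-window extent parameters.
#' @return The ratio (test / reference).
#' @export
compute_nf_longGE <- function(track_test, track_ref, genes,
                              min_length = 150000, cap_fraction = 0.25,
                              cap_bp = 50000) {
  genes <- as_tibble(genes)
  body_len <- abs(genes$cps - genes$tss) + 1
  keep <- which(body_len > min_length)
  if (length(keep) == 0) {
    abort(sprintf("no genes longer than %g bp for nf_longGE", min_length))
  }
  it <- track_index(track_test)
  ir <- track_index(track_ref)
  sum_test <- sum_ref <- 0
  for (i in keep) {
    win <- long_gene_end_window(body_len[i], cap_fraction, cap_bp)
    sum_test <- sum_test + sum(window_counts(
      it, genes$chrom[i], genes$strand[i], genes$tss[i], win[1], win[2]),
      na.rm = TRUE)
    sum_ref <- sum_ref + sum(window_counts(
      ir, genes$chrom[i], genes$strand[i], genes$tss[i], win[1], win[2]),
      na.rm = TRUE)
  }
  if (sum_ref <= 0) abort("reference long-gene end count is zero")
  sum_test / sum_ref
}

#' Assemble the normalization factor table for an experiment
#'
#' @param sample_table Tibble with one row per (merged) sample: `sample`,
#'   `condition`, `antibody`, `spike_count`, `depth` (uniquely mapped
#'   primary-genome reads).
#' @param control_antibody,control_condition Identity of the designated
#'   control sample (default: unphosphorylated CTD in the first condition of
#'   the table).
#' @param nf_longGE Named vector of per-condition long-gene-end factors from
#'   [compute_nf_longGE()] (reference condition 1); if `NULL`, all 1.
#' @return A tibble of class `norm_factors` with columns `sample`,
#'   `condition`, `antibody`, `spike_count`, `depth`, `nf_spikein`,
#'   `nf_longGE`, `control`; `attr(, "control_depth")` holds the control
#'   sample's depth.
#' @export
normalization_factors <- function(sample_table,
                                  control_antibody = "unPh",
                                  control_condition = NULL,
                                  nf_longGE = NULL) {
  st <- as_tibble(sample_table)
  stopifnot(all(c("sample", "condition", "antibody", "spike_count", "depth")
                %in% names(st)))
  if (is.null(control_condition)) control_condition <- st$condition[1]
  ctrl <- st$antibody == control_antibody & st$condition == control_condition
  if (sum(ctrl) != 1) {
    abort("exactly one designated control sample required")
  }
  ctrl_by_cond <- st |>
    filter(.data$antibody == control_antibody) |>
    select("condition", ctrl_spike = "spike_count")
  if (!all(st$condition %in% ctrl_by_cond$condition)) {
    abort("every condition needs a control-antibody sample for nf_spikein")
  }
  if (is.null(nf_longGE)) {
    nf_longGE <- setNames(rep(1, length(unique(st$condition))),
                          unique(st$condition))
  }
  if (!all(st$condition %in% names(nf_longGE))) {
    abort("nf_longGE missing for some condition(s)")
  }
  out <- st |>
    left_join(ctrl_by_cond, by = "condition") |>
    mutate(nf_spikein = compute_nf_spikein(.data$spike_count,
                                           .data$ctrl_spike),
           nf_longGE = unname(nf_longGE[.data$condition]),
           control = ctrl) |>
    select(-"ctrl_spike")
  structure(out, class = c("norm_factors", class(tibble())),
            control_depth = st$depth[ctrl],
            control_sample = st$sample[ctrl])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' Tidy a normalization factor table
#' @param x A `norm_factors` object.
#' @param ... Unused.
#' @return A plain tibble with the per-sample factors and the combined
#'   multiplicative scale applied to counts.
#' @export
tidy.norm_factors <- function(x, ...) {
  as_tibble(x) |>
    mutate(combined_nf = .data$nf_spikein * .data$nf_longGE,
           scale = 1 / .data$nf_spikein / .data$nf_longGE *
             1e6 / attr(x, "control_depth", exact = TRUE))
}

#' @export
glance.norm_factors <- function(x, ...) {
  tibble(n_samples = nrow(x),
         control_sample = attr(x, "control_sample", exact = TRUE),
         control_depth = attr(x, "control_depth", exact = TRUE))
}

#' Apply nf-cRPM scaling to a track
#'
#' Multiplies every count by
#' `(1 / nf_spikein) * (1 / nf_longGE) * 1e6 / control_depth`. For the
#' designated control sample the pre-RPM part is exactly 1, so its track is
#' plain RPM at the control depth.
#'
#' @param track An `end_track` whose sample id appears in `factors`.
#' @param factors A [normalization_factors()] table.
#' @param sample Sample id; defaults to the track's own metadata.
#' @return A normalized track (class `norm_track`, real-valued `count`) with
#'   the scheme and factors recorded in `attr(, "norm")`.
#' @export
apply_nf_cRPM <- function(track, factors, sample = NULL) {
  if (is.null(sample)) sample <- track_sample_info(track)$sample
  row <- which(factors$sample == sample)
  if (length(row) != 1) {
    abort(sprintf("sample '%s' not registered in normalization factors",
                  sample %||% "<NA>"))
  }
  control_depth <- attr(factors, "control_depth", exact = TRUE)
  scale <- 1 / factors$nf_spikein[row] / factors$nf_longGE[row] *
    1e6 / control_depth
  out <- retrack(mutate(as_tibble(track), count = .data$count * scale), track)
  class(out) <- unique(c("norm_track", class(out)))
  attr(out, "norm") <- list(scheme = "nf-cRPM",
                            nf_spikein = factors$nf_spikein[row],
                            nf_longGE = factors$nf_longGE[row],
                            control_depth = control_depth)
  out
}

#' Reads-per-million normalization by the track's own depth
#'
#' @param track An `end_track`.
#' @param depth Total mapped reads to scale by; defaults to the track's own
#'   total count.
#' @return A `norm_track` whose counts sum to 1e6 when `depth` is the track
#'   total.
#' @export
rpm <- function(track, depth = NULL) {
  if (is.null(depth)) depth <- track_total(track)
  if (depth <= 0) abort("cannot RPM-normalize an empty track")
  out <- retrack(mutate(as_tibble(track), count = .data$count * 1e6 / depth),
                 track)
  class(out) <- unique(c("norm_track", class(out)))
  attr(out, "norm") <- list(scheme = "RPM", depth = depth)
  out
}

#' Estimate the spike-in chromatin proportion
#'
#' The genome-content-weighted percentage of spike-in chromatin per run-on
#' reaction: `100 * (spike_cells * spike_ploidy * spike_genome_bp) /
#' (main_cells * main_ploidy * main_genome_bp)`. With the experiment's cell
#' counts (250,000 spike-in fibroblasts per 30 million K562 cells), genome
#' sizes (2.5e9 vs 2.9e9 bp) and genome contents (diploid vs hypotriploid),
#' this evaluates to 0.5% at one-decimal rounding.
#'
#' @param spike_cells,main_cells Cell numbers.
#' @param spike_genome_bp,main_genome_bp Haploid genome sizes in bp.
#' @param spike_ploidy,main_ploidy Genome copy numbers per cell.
#' @return Percentage (0-100 scale).
#' @export
estimate_spikein_fraction <- function(spike_cells, spike_genome_bp,
                                      spike_ploidy, main_cells,
                                      main_genome_bp, main_ploidy) {
  args <- c(spike_cells, spike_genome_bp, spike_ploidy,
            main_cells, main_genome_bp, main_ploidy)
  if (any(args <= 0)) abort("all inputs must be positive")
  100 * (spike_cells * spike_ploidy * spike_genome_bp) /
    (main_cells * main_ploidy * main_genome_bp)
}
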