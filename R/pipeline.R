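#' Run the full downstream analysis on an experiment
#'
#' Executes the stage order of the assay's downstream analysis on aligned
#' molecules: spike-in counting (mask-aware), strand-specific 5'/3'-end
#' track generation, replicate merging by raw-count summation, nf-cRPM
#' normalization anchored on the designated control sample, TSN and pause
#' calling on the control sample's tracks (one representative TSN reused for
#' every antibody and condition, unless `per_sample_tsn`), pause-fraction
#' quantification, gene-body gbRPK with summed-antibody activity grouping,
#' and heat-shock response classification when two conditions are present.
#' The run is fully deterministic in its inputs; when `outdir` is given all
#' tables and tracks are written with a provenance header.
#'
#' @param experiment A list as produced by [simulate_experiment()]:
#'   `manifest` (see [validate_manifest()]), `samples` (named list with
#'   `records`, `spike_records`, `spike_count` per sample), `genes`.
#' @param mask Optional `mask_set` applied to spike-in counting.
#' @param control_antibody,control_condition Designation of the control
#'   sample after replicate merging (defaults: first antibody and first
#'   condition of the manifest).
#' @param per_sample_tsn If `TRUE`, call a TSN per merged sample instead of
#'   reusing the control sample's representative TSN.
#' @param body_offset Gene-body start offset for gbRPK (nt from TSN).
#' @param activity_threshold Minimum summed-antibody gbRPK (normalized
#'   units) for a gene to count as active.
#' @param outdir Optional output directory for TSV/bedGraph artifacts.
#' @return A list: `factors` (`norm_factors`), `tracks3`, `tracks5` (named
#'   lists of merged raw tracks), `norm3` (normalized 3'-end tracks),
#'   `ratio_tracks` (log2 phospho/unphospho per condition),
#'   `tsn_calls`, `pause_calls` (per merged sample), `activity` (per-gene
#'   gbRPK by sample + summed activity, group, and response class), and
#'   `provenance`.
#' @export
run_pipeline <- function(experiment, mask = NULL,
                         control_antibody = NULL, control_condition = NULL,
                         per_sample_tsn = FALSE, body_offset = 500,
                         activity_threshold = 0.01, outdir = NULL) {
  manifest <- validate_manifest(experiment$manifest)
  genes <- as_tibble(experiment$genes)
  samples <- experiment$samples
  missing <- setdiff(manifest$sample, names(samples))
  if (length(missing) > 0) {
    abort(paste0("pipeline: manifest sample(s) without data: ",
                 paste(missing, collapse = ", ")))
  }
  if (is.null(mask)) {
    mask <- structure(tibble(chrom = character(), start = integer(),
                             end = integer()),
                      class = c("mask_set", class(tibble())))
  }
  if (is.null(control_antibody)) control_antibody <- manifest$antibody[1]
  if (is.null(control_condition)) control_condition <- manifest$condition[1]

  # stage 1: spike-in counting and per-replicate tracks
  per_rep <- lapply(manifest$sample, function(s) {
    d <- samples[[s]]
    row <- manifest[manifest$sample == s, ]
    list(
      track3 = reads_to_end_track(d$records, "three_prime",
                                  sample = s, condition = row$condition,
                                  antibody = row$antibody,
                                  replicate = row$replicate),
      track5 = reads_to_end_track(d$records, "five_prime",
                                  sample = s, condition = row$condition,
                                  antibody = row$antibody,
                                  replicate = row$replicate),
      spike = count_spikein(d$spike_records, mask),
      depth = nrow(d$records))
  })
  names(per_rep) <- manifest$sample

  # stage 2: merge replicates within (condition, antibody)
  merged_key <- manifest |>
    distinct(.data$condition, .data$antibody) |>
    mutate(sample = paste(.data$condition, .data$antibody, sep = "_"))
  tracks3 <- tracks5 <- vector("list", nrow(merged_key))
  names(tracks3) <- names(tracks5) <- merged_key$sample
  spike_counts <- depths <- numeric(nrow(merged_key))
  for (i in seq_len(nrow(merged_key))) {
    reps <- manifest$sample[manifest$condition == merged_key$condition[i] &
                              manifest$antibody == merged_key$antibody[i]]
    m3 <- merge_replicates(lapply(per_rep[reps], `[[`, "track3"),
                           vapply(per_rep[reps], `[[`, numeric(1), "spike"))
    tracks3[[i]] <- relabel_track(m3$track, merged_key$sample[i],
                                  merged_key$condition[i],
                                  merged_key$antibody[i])
    m5 <- merge_replicates(lapply(per_rep[reps], `[[`, "track5"))
    tracks5[[i]] <- relabel_track(m5, merged_key$sample[i],
                                  merged_key$condition[i],
                                  merged_key$antibody[i])
    spike_counts[i] <- m3$spike_count
    depths[i] <- sum(vapply(per_rep[reps], `[[`, numeric(1), "depth"))
  }

  # stage 3: normalization factors
  conditions <- unique(merged_key$condition)
  ctrl_tracks <- setNames(
    lapply(conditions, function(cond)
      tracks3[[paste(cond, control_antibody, sep = "_")]]),
    conditions)
  nf_lge <- setNames(rep(1, length(conditions)), conditions)
  long_enough <- any(abs(genes$cps - genes$tss) + 1 > 150000)
  for (cond in setdiff(conditions, control_condition)) {
    if (long_enough) {
      nf_lge[cond] <- compute_nf_longGE(ctrl_tracks[[cond]],
                                        ctrl_tracks[[control_condition]],
                                        genes)
    } else {
      inform(paste0("no genes > 150 kb; nf_longGE fixed at 1 for ", cond))
    }
  }
  sample_table <- merged_key |>
    mutate(spike_count = spike_counts, depth = depths) |>
    select("sample", "condition", "antibody", "spike_count", "depth")
  factors <- normalization_factors(sample_table,
                                   control_antibody = control_antibody,
                                   control_condition = control_condition,
                                   nf_longGE = nf_lge)
  norm3 <- lapply(tracks3, apply_nf_cRPM, factors = factors)

  # stage 4: TSN and pause calls (representative TSN from the control sample)
  control_sample <- paste(control_condition, control_antibody, sep = "_")
  rep_tsn <- call_tsn(tracks5[[control_sample]], genes)
  tsn_calls <- pause_calls <- vector("list", length(tracks3))
  names(tsn_calls) <- names(pause_calls) <- names(tracks3)
  for (s in names(tracks3)) {
    tsn_calls[[s]] <- if (per_sample_tsn) call_tsn(tracks5[[s]], genes)
      else rep_tsn
    pause_calls[[s]] <- call_pause(tracks3[[s]], tsn_calls[[s]], genes)
  }

  # stage 5: quantification on normalized tracks
  genes_tsn <- genes |>
    left_join(select(rep_tsn, "gene_id", "tsn", "called"), by = "gene_id") |>
    filter(.data$called) |>
    select(-"called")
  gbrpk_tbl <- purrr::imap(norm3, function(tr, s) {
    row <- merged_key[merged_key$sample == s, ]
    gb_rpk(tr, genes_tsn, body_offset = body_offset) |>
      mutate(sample = s, condition = row$condition, antibody = row$antibody)
  }) |> bind_rows()
  activity <- gbrpk_tbl |>
    filter(.data$condition == control_condition) |>
    sum_antibody_activity(antibodies = unique(merged_key$antibody)) |>
    mutate(active = .data$gbrpk_sum > activity_threshold)
  activity <- group_by_activity(activity,
                                n_groups = min(4, nrow(activity)))
  if (length(conditions) >= 2) {
    treated_condition <- setdiff(conditions, control_condition)[1]
    by_cond <- gbrpk_tbl |>
      group_by(.data$gene_id, .data$condition) |>
      summarise(gbrpk_sum = sum(.data$gbrpk), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "condition", values_from = "gbrpk_sum")
    activity <- activity |>
      left_join(by_cond, by = "gene_id") |>
      mutate(response_class = classify_hs_response(
        .data[[control_condition]], .data[[treated_condition]]))
  }

  # stage 6: per-nucleotide log2 ratio tracks vs the control antibody
  ratio_tracks <- list()
  for (cond in conditions) {
    den <- norm3[[paste(cond, control_antibody, sep = "_")]]
    for (ab in setdiff(unique(merged_key$antibody), control_antibody)) {
      s <- paste(cond, ab, sep = "_")
      ratio_tracks[[s]] <- log2_ratio_track(norm3[[s]], den)
    }
  }

  provenance <- list(
    package = "proipr",
    version = as.character(utils::packageVersion("proipr")),
    control_sample = control_sample,
    control_antibody = control_antibody,
    control_condition = control_condition,
    nf_longGE = as.list(nf_lge),
    body_offset = body_offset,
    activity_threshold = activity_threshold,
    per_sample_tsn = per_sample_tsn)

  result <- list(factors = factors, tracks3 = tracks3, tracks5 = tracks5,
                 norm3 = norm3, ratio_tracks = ratio_tracks,
                 tsn_calls = tsn_calls, pause_calls = pause_calls,
                 activity = activity, provenance = provenance)
  if (!is.null(outdir)) write_pipeline_outputs(result, outdir)
  result
}

relabel_track <- function(track, sample, condition, antibody) {
  attr(track, "sample_info") <- list(sample = sample, condition = condition,
                                     antibody = antibody,
                                     replicate = NA_integer_)
  track
}

prov_header <- function(provenance) {
  paste0("# proipr ", provenance$version,
         " | control=", provenance$control_sample,
         " | nf_longGE=",
         paste(names(provenance$nf_longGE),
               vapply(provenance$nf_longGE, function(x)
                 formatC(x, digits = 10, format = "g"), character(1)),
               sep = ":", collapse = ","),
         " | body_offset=", provenance$body_offset)
}

write_tsv_prov <- function(x, path, provenance) {
  writeLines(prov_header(provenance), path)
  readr::write_tsv(x, path, append = TRUE, col_names = TRUE, progress = FALSE)
}

write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  prov <- result$provenance
  write_tsv_prov(tidy(result$factors), file.path(outdir, "factors.tsv"), prov)
  tsn_all <- purrr::imap(result$tsn_calls, ~ mutate(.x, sample = .y)) |>
    bind_rows()
  write_tsv_prov(tsn_all, file.path(outdir, "tsn_calls.tsv"), prov)
  pause_all <- purrr::imap(result$pause_calls, ~ mutate(.x, sample = .y)) |>
    bind_rows()
  write_tsv_prov(pause_all, file.path(outdir, "pause_calls.tsv"), prov)
  write_tsv_prov(result$activity, file.path(outdir, "activity.tsv"), prov)
  for (s in names(result$norm3)) {
    write_track_bedgraph(result$norm3[[s]],
                         file.path(outdir, paste0(s, "_3p_nfcRPM")))
  }
  invisible(outdir)
}
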