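#' Configuration for the synthetic PRO-IP-seq generator
#'
#' The generator emulates the statistical structure the downstream analysis
#' assumes: each gene initiates at a single transcription start nucleotide
#' (TSN) lying downstream of its annotated TSS (offsets drawn from a
#' log-normal with median 55 nt and mean 77 nt, matching genome-wide
#' TSN-TSS discrepancies in nascent-RNA data); engaged Pol II distributes
#' between a promoter-proximal pause, the gene body, and a termination
#' window with antibody-specific weights; the pause is a two-component
#' positional mixture over +1..+30 (early) and +31..+60 (late) from the TSN,
#' discretized truncated normals peaking at +25 and +45; a configurable
#' fraction of molecules is uniform background noise; and a configurable
#' fraction of molecules originates from an independent spike-in genome.
#'
#' @param n_genes Number of genes to simulate.
#' @param genome_length Length (bp) of the single primary chromosome.
#' @param spike_genome_length Length (bp) of the spike-in chromosome.
#' @param tsn_offset Parameters of the TSN-TSS offset distribution:
#'   `list(meanlog, sdlog)` of a log-normal, or `list(fixed = k)` to force a
#'   constant offset. Offsets are rounded and clamped to `[0, 400]`.
#' @param gene_length Parameters (`meanlog`, `sdlog`, `min`, `max`) of the
#'   log-normal gene-body length distribution (TSN to CPS), in nt.
#' @param pause_mix Two positive weights `c(early, late)` summing to 1, the
#'   prior probability that a gene's dominant pause is early (+1..+30) or
#'   late (+31..+60).
#' @param pause_components Positional distributions of the two pause
#'   components: `list(early = c(mean, sd), late = c(mean, sd))` on the
#'   1-based distance-from-TSN scale, truncated to their windows.
#' @param pause_peak_weight Fraction of a gene's pause-bound molecules placed
#'   exactly at its dominant pause nucleotide (the rest re-drawn from the
#'   mixture), creating the single sharp pause the assay resolves.
#' @param ctd_weights Named list mapping antibody label to a length-3
#'   probability vector `c(pause, body, term)`: where the active site of a
#'   molecule bearing that CTD mark resides.
#' @param reads_per_sample Molecules per sample (pre PCR duplication).
#' @param noise_rate Fraction of primary-genome molecules placed uniformly.
#' @param spike_in_fraction Fraction of molecules from the spike-in genome.
#' @param pcr_dup_rate Expected extra PCR copies per molecule (Poisson).
#' @param term_window Length (nt) of the post-CPS termination window.
#' @param wave_front Distance (nt from the TSN) a transcriptional change can
#'   propagate during the perturbation (default 60,000 = 2 kb/min for 30
#'   min). Condition fold changes apply to the pause and to body positions
#'   within this distance; density beyond it — including the ends of long
#'   genes — keeps its reference level, which is the premise of the
#'   long-gene-end normalization factor.
#' @param barcode_table Data frame `sample`, `barcode` (6-nt, unique) used
#'   when emitting FASTQ; defaults to standard TruSeq small-RNA index
#'   hexamers.
#' @param conditions Character vector of condition labels; the first is the
#'   unperturbed reference.
#' @param hs_activated_frac,hs_repressed_frac Fractions of genes activated /
#'   repressed in non-reference conditions.
#' @param activated_fc,repressed_fc Expression fold changes applied to
#'   activated / repressed genes in non-reference conditions.
#' @param expr_sdlog Spread (sdlog) of per-gene log-normal expression weights.
#' @param seed Integer seed; all generator functions are deterministic given
#'   the config.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 200,
                       genome_length = 2e7,
                       spike_genome_length = 1e5,
                       tsn_offset = list(meanlog = log(55),
                                         sdlog = sqrt(2 * log(77 / 55))),
                       gene_length = list(meanlog = log(20000), sdlog = 1,
                                          min = 2000, max = 5e5),
                       pause_mix = c(early = 0.65, late = 0.35),
                       pause_components = list(early = c(mean = 25, sd = 3),
                                               late = c(mean = 45, sd = 6)),
                       pause_peak_weight = 0.6,
                       ctd_weights = list(
                         unPh   = c(pause = 0.70, body = 0.25, term = 0.05),
                         Ser2Ph = c(pause = 0.30, body = 0.55, term = 0.15),
                         Ser5Ph = c(pause = 0.40, body = 0.50, term = 0.10),
                         Ser7Ph = c(pause = 0.25, body = 0.65, term = 0.10)),
                       reads_per_sample = 1e5,
                       noise_rate = 0.1,
                       spike_in_fraction = 0.005,
                       pcr_dup_rate = 1,
                       term_window = 500,
                       wave_front = 60000,
                       barcode_table = NULL,
                       conditions = c("NHS", "HS30"),
                       hs_activated_frac = 0.1,
                       hs_repressed_frac = 0.3,
                       activated_fc = 4,
                       repressed_fc = 0.25,
                       expr_sdlog = 1,
                       seed = 1L) {
  if (is.null(barcode_table)) {
    barcode_table <- tibble(
      sample = paste0("S", seq_along(ctd_weights)),
      barcode = c("ATCACG", "CGATGT", "TTAGGC", "TGACCA", "ACAGTG",
                  "GCCAAT")[seq_along(ctd_weights)])
  }
  cfg <- list(n_genes = n_genes, genome_length = genome_length,
              spike_genome_length = spike_genome_length,
              tsn_offset = tsn_offset, gene_length = gene_length,
              pause_mix = pause_mix, pause_components = pause_components,
              pause_peak_weight = pause_peak_weight,
              ctd_weights = ctd_weights,
              reads_per_sample = reads_per_sample, noise_rate = noise_rate,
              spike_in_fraction = spike_in_fraction,
              pcr_dup_rate = pcr_dup_rate, term_window = term_window,
              wave_front = wave_front,
              barcode_table = as_tibble(barcode_table),
              conditions = conditions,
              hs_activated_frac = hs_activated_frac,
              hs_repressed_frac = hs_repressed_frac,
              activated_fc = activated_fc, repressed_fc = repressed_fc,
              expr_sdlog = expr_sdlog, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  frac_fields <- c("noise_rate", "spike_in_fraction", "pause_peak_weight",
                   "hs_activated_frac", "hs_repressed_frac")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || v < 0 || v > 1) {
      abort(sprintf("sim_config: %s must lie in [0, 1]", f))
    }
  }
  if (abs(sum(cfg$pause_mix) - 1) > 1e-12 || any(cfg$pause_mix < 0)) {
    abort("sim_config: pause_mix weights must be non-negative and sum to 1")
  }
  if (cfg$n_genes > 0 && cfg$reads_per_sample <= 0) {
    abort("sim_config: reads_per_sample must be positive")
  }
  for (ab in names(cfg$ctd_weights)) {
    w <- cfg$ctd_weights[[ab]]
    if (length(w) != 3 || any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      abort(sprintf(
        "sim_config: ctd_weights[['%s']] must be 3 non-negative values summing to 1",
        ab))
    }
  }
  bc <- cfg$barcode_table$barcode
  if (anyDuplicated(bc) || any(nchar(bc) != 6) ||
      any(!grepl("^[ACGTN]{6}$", bc))) {
    abort("sim_config: barcodes must be unique 6-mers over {A,C,G,T,N}")
  }
  invisible(cfg)
}

#' Read a simulator configuration from YAML
#' @param path Path to a YAML file whose keys match [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown sim_config field(s): ", paste(unknown, collapse = ", ")))
  }
  if (!is.null(raw$barcode_table)) {
    raw$barcode_table <- as_tibble(lapply(raw$barcode_table, unlist))
  }
  for (f in c("pause_mix")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  for (f in c("ctd_weights", "pause_components")) {
    if (!is.null(raw[[f]])) raw[[f]] <- lapply(raw[[f]], unlist)
  }
  do.call(sim_config, raw)
}

#' Write a simulator configuration to YAML
#' @param config A `sim_config`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  out <- unclass(config)
  out$barcode_table <- as.list(as.data.frame(out$barcode_table))
  # named atomic vectors lose names in YAML; emit them as maps
  out$pause_mix <- as.list(out$pause_mix)
  out$ctd_weights <- lapply(out$ctd_weights, as.list)
  out$pause_components <- lapply(out$pause_components, as.list)
  yaml::write_yaml(out, path)
  invisible(path)
}

draw_tsn_offsets <- function(n, spec) {
  if (!is.null(spec$fixed)) return(rep(as.integer(spec$fixed), n))
  off <- round(rlnorm(n, meanlog = spec$meanlog, sdlog = spec$sdlog))
  pmin(pmax(off, 0), 400)
}

# discretized truncated normal over integer support lo..hi
draw_trunc_norm_int <- function(n, mean, sd, lo, hi) {
  support <- lo:hi
  p <- stats::dnorm(support, mean = mean, sd = sd)
  support[sample.int(length(support), n, replace = TRUE, prob = p)]
}

#' Simulate an annotated gene set with ground truth
#'
#' Places `n_genes` non-overlapping genes on both strands of a single
#' chromosome. For each gene the true TSN is drawn at a log-normal offset
#' downstream of the annotated TSS, the dominant pause nucleotide is drawn
#' from the early/late positional mixture, a log-normal expression weight is
#' assigned, and a heat-shock response class (activated / repressed /
#' unchanged) determines its expression in non-reference conditions.
#'
#' @param config A [sim_config()].
#' @return A list with `genes` (tibble: `gene_id`, `chrom`, `strand`, `tss`,
#'   `cps`, `chrom_length`; 0-based coordinates) and `truth` (tibble adding
#'   `tsn`, `tsn_offset`, `pause_coord`, `pause_distance` (1-based from the
#'   TSN), `pause_class`, `expr_weight`, `response_class`, and per-condition
#'   expression columns `weight_<condition>`).
#' @export
simulate_gene_set <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    n <- config$n_genes
    empty_genes <- tibble(gene_id = character(), chrom = character(),
                          strand = character(), tss = integer(),
                          cps = integer(), chrom_length = double())
    if (n == 0) {
      return(list(genes = empty_genes,
                  truth = mutate(empty_genes, tsn = integer(),
                                 tsn_offset = integer(),
                                 pause_coord = integer(),
                                 pause_distance = integer(),
                                 pause_class = character(),
                                 expr_weight = double(),
                                 response_class = character())))
    }
    gl <- config$gene_length
    body_len <- round(rlnorm(n, gl$meanlog, gl$sdlog))
    body_len <- pmin(pmax(body_len, gl$min), gl$max)
    offsets <- draw_tsn_offsets(n, config$tsn_offset)
    # slot = upstream margin (TSS window) + offset + body + termination window
    upstream_pad <- 150L
    footprint <- upstream_pad + offsets + body_len + config$term_window + 100L
    min_gap <- 200L
    total <- sum(footprint + min_gap)
    if (total > config$genome_length) {
      abort(sprintf(
        "Cannot place %d genes (need %d bp) on a %g bp genome; increase genome_length",
        n, total, config$genome_length))
    }
    slack <- config$genome_length - total
    cuts <- sort(runif(n))
    extra <- floor(diff(c(0, cuts)) * slack)
    slot_start <- cumsum(c(0L, head(footprint + min_gap, -1))) +
      cumsum(extra)
    strand <- sample(c("+", "-"), n, replace = TRUE)
    # orient the gene inside its slot; coordinates are 0-based positions
    tss <- tsn <- cps <- integer(n)
    for (i in seq_len(n)) {
      if (strand[i] == "+") {
        tss[i] <- slot_start[i] + upstream_pad
        tsn[i] <- tss[i] + offsets[i]
        cps[i] <- tsn[i] + body_len[i] - 1L
      } else {
        tss[i] <- slot_start[i] + footprint[i] - upstream_pad
        tsn[i] <- tss[i] - offsets[i]
        cps[i] <- tsn[i] - body_len[i] + 1L
      }
    }
    pause_class <- sample(c("early", "late"), n, replace = TRUE,
                          prob = config$pause_mix)
    pc <- config$pause_components
    pause_distance <- integer(n)
    is_e <- pause_class == "early"
    if (any(is_e)) {
      pause_distance[is_e] <- draw_trunc_norm_int(
        sum(is_e), pc$early[["mean"]], pc$early[["sd"]], 1, 30)
    }
    if (any(!is_e)) {
      pause_distance[!is_e] <- draw_trunc_norm_int(
        sum(!is_e), pc$late[["mean"]], pc$late[["sd"]], 31, 60)
    }
    dir <- ifelse(strand == "+", 1L, -1L)
    pause_coord <- tsn + dir * (pause_distance - 1L)
    expr_weight <- rlnorm(n, 0, config$expr_sdlog)
    response_class <- sample(
      c("activated", "repressed", "unchanged"), n, replace = TRUE,
      prob = c(config$hs_activated_frac, config$hs_repressed_frac,
               1 - config$hs_activated_frac - config$hs_repressed_frac))
    genes <- tibble(gene_id = sprintf("g%04d", seq_len(n)), chrom = "chr1",
                    strand = strand, tss = tss, cps = cps,
                    chrom_length = config$genome_length)
    truth <- genes |>
      mutate(tsn = tsn, tsn_offset = offsets, pause_coord = pause_coord,
             pause_distance = pause_distance, pause_class = pause_class,
             expr_weight = expr_weight, response_class = response_class)
    for (cond in config$conditions) {
      mult <- if (cond == config$conditions[1]) {
        rep(1, n)
      } else {
        ifelse(response_class == "activated", config$activated_fc,
               ifelse(response_class == "repressed", config$repressed_fc, 1))
      }
      truth[[paste0("weight_", cond)]] <- expr_weight * mult
    }
    list(genes = genes, truth = truth)
  })
}

#' Simulate aligned molecules for one sample
#'
#' Draws `reads_per_sample` molecules. Each molecule is a nascent RNA running
#' from its 5'-end (at the gene's true TSN) to its 3'-end (the active site of
#' transcription), emitted as a BED6-style record so that plus-strand records
#' place the 5'-end at `start` and the 3'-end at `end - 1`, and minus-strand
#' records the reverse. The active site falls in the pause region, the gene
#' body, or the termination window with the antibody's `ctd_weights`;
#' `noise_rate` of primary molecules are uniform background; a
#' `spike_in_fraction` of molecules comes from the spike-in genome.
#'
#' @param genes,truth Output of [simulate_gene_set()].
#' @param config The [sim_config()] used to build the gene set.
#' @param antibody Antibody label; must be a name of `config$ctd_weights`.
#' @param condition Condition label; must appear in `config$conditions`.
#' @param sample_seed Integer seed for this sample's draws (defaults to a
#'   deterministic function of `config$seed`, `antibody` and `condition`).
#' @param with_duplicates If `TRUE`, append PCR duplicate records (sharing
#'   `molecule_id` and `umi`) at a per-molecule Poisson(`pcr_dup_rate`) rate.
#' @return A list: `records` (primary-genome tibble: `chrom`, `start`, `end`,
#'   `molecule_id`, `strand`, `umi`, `unique`), `spike_records` (same shape,
#'   spike-in genome), `n_molecules`, `spike_count`.
#' @export
simulate_sample_reads <- function(genes, truth, config, antibody, condition,
                                  sample_seed = NULL,
                                  with_duplicates = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  if (!antibody %in% names(config$ctd_weights)) {
    abort(sprintf("Unknown antibody label '%s'", antibody))
  }
  if (!condition %in% config$conditions) {
    abort(sprintf("Unknown condition '%s'", condition))
  }
  if (is.null(sample_seed)) {
    labels <- paste(rep(names(config$ctd_weights),
                        each = length(config$conditions)),
                    rep(config$conditions, length(config$ctd_weights)))
    sample_seed <- config$seed + 1000L +
      match(paste(antibody, condition), labels)
  }
  withr::with_seed(as.integer(sample_seed), {
    n <- config$reads_per_sample
    is_spike <- runif(n) < config$spike_in_fraction
    n_spike <- sum(is_spike)
    n_pri <- n - n_spike

    spike_records <- simulate_uniform_molecules(
      n_spike, "spike1", config$spike_genome_length, id_prefix = "sp")

    weights <- truth[[paste0("weight_", condition)]]
    w <- config$ctd_weights[[antibody]]
    is_noise <- runif(n_pri) < config$noise_rate
    n_noise <- sum(is_noise)
    n_sig <- n_pri - n_noise

    noise_records <- simulate_uniform_molecules(
      n_noise, "chr1", config$genome_length, id_prefix = "bg")

    if (n_sig > 0 && nrow(genes) > 0) {
      # Per-gene compartment intensities.  Condition fold changes act on the
      # pause and on body positions within `wave_front` nt of the TSN; the
      # density beyond the wave front (distal body, termination window of
      # long genes) stays at its reference level.
      ref_weights <- truth[[paste0("weight_", config$conditions[1])]]
      L <- abs(truth$cps - truth$tsn) + 1L
      body_lo <- pmin(61L, L - 1L)           # first body offset (0-based)
      n_body <- pmax(L - body_lo, 0L)        # body positions body_lo..L-1
      wf <- config$wave_front
      n_prox <- pmax(pmin(L - 1L, wf - 1L) - body_lo + 1L, 0L)
      n_prox <- pmin(n_prox, n_body)
      n_dist <- n_body - n_prox
      mult <- ifelse(ref_weights > 0, weights / ref_weights, 1)
      int_pause <- ref_weights * mult * w[["pause"]]
      int_body <- ref_weights * w[["body"]] *
        (mult * n_prox + n_dist) / pmax(n_body, 1L)
      int_term <- ref_weights * w[["term"]] *
        ifelse(L - 1L >= wf, 1, mult)
      intens <- c(int_pause, int_body, int_term)
      pick <- sample.int(3L * nrow(genes), n_sig, replace = TRUE,
                         prob = intens)
      gi <- (pick - 1L) %% nrow(genes) + 1L
      compart <- c("pause", "body", "term")[(pick - 1L) %/% nrow(genes) + 1L]
      # 3'-end offset from the TSN, 0-based (0 = TSN itself)
      off3 <- integer(n_sig)
      ip <- compart == "pause"
      if (any(ip)) off3[ip] <- draw_pause_offsets(sum(ip), gi[ip], truth, config)
      ib <- compart == "body"
      if (any(ib)) {
        # proximal vs distal body, weighted by scaled position counts
        gprox <- n_prox[gi]; gdist <- n_dist[gi]; gmult <- mult[gi]
        p_prox <- gmult * gprox / pmax(gmult * gprox + gdist, 1e-300)
        is_prox <- runif(n_sig) < p_prox
        lo <- body_lo[gi]
        off <- integer(n_sig)
        sel_p <- ib & is_prox & gprox > 0
        off[sel_p] <- lo[sel_p] +
          floor(runif(sum(sel_p)) * gprox[sel_p])
        sel_d <- ib & (!is_prox | gprox == 0) & gdist > 0
        off[sel_d] <- lo[sel_d] + gprox[sel_d] +
          floor(runif(sum(sel_d)) * gdist[sel_d])
        sel_f <- ib & !(sel_p | sel_d)   # degenerate: single-position body
        off[sel_f] <- lo[sel_f]
        off3[ib] <- off[ib]
      }
      it <- compart == "term"
      if (any(it)) {
        off3[it] <- L[gi][it] - 1L +
          sample.int(config$term_window, sum(it), replace = TRUE)
      }
      tsn <- truth$tsn[gi]
      dirn <- ifelse(truth$strand[gi] == "+", 1L, -1L)
      p5 <- tsn
      p3 <- tsn + dirn * off3
      sig_records <- tibble(
        chrom = truth$chrom[gi],
        start = pmin(p5, p3),
        end = pmax(p5, p3) + 1L,
        molecule_id = sprintf("m%07d", seq_len(n_sig)),
        strand = truth$strand[gi],
        unique = TRUE)
    } else {
      sig_records <- empty_records()
    }
    records <- bind_rows(sig_records, noise_records)
    records$umi <- random_kmers(nrow(records), 6)
    spike_records$umi <- random_kmers(nrow(spike_records), 6)
    n_molecules <- nrow(records) + nrow(spike_records)
    if (with_duplicates) {
      records <- add_pcr_duplicates(records, config$pcr_dup_rate)
      spike_records <- add_pcr_duplicates(spike_records, config$pcr_dup_rate)
    }
    list(records = records, spike_records = spike_records,
         n_molecules = n_molecules, spike_count = n_spike)
  })
}

empty_records <- function() {
  tibble(chrom = character(), start = integer(), end = integer(),
         molecule_id = character(), strand = character(), unique = logical())
}

simulate_uniform_molecules <- function(n, chrom, chrom_length, id_prefix) {
  if (n == 0) return(empty_records())
  len <- sample.int(100L, n, replace = TRUE)
  p3 <- floor(runif(n) * (chrom_length - 200)) + 100L
  strand <- sample(c("+", "-"), n, replace = TRUE)
  p5 <- ifelse(strand == "+", pmax(p3 - len + 1L, 0L),
               pmin(p3 + len - 1L, chrom_length - 1L))
  tibble(chrom = chrom, start = as.integer(pmin(p5, p3)),
         end = as.integer(pmax(p5, p3) + 1L),
         molecule_id = sprintf("%s%07d", id_prefix, seq_len(n)),
         strand = strand, unique = TRUE)
}

draw_pause_offsets <- function(n, gene_idx, truth, config) {
  at_peak <- runif(n) < config$pause_peak_weight
  out <- integer(n)
  # dominant pause of the gene (pause_distance is 1-based; offset is 0-based)
  out[at_peak] <- truth$pause_distance[gene_idx[at_peak]] - 1L
  n_mix <- sum(!at_peak)
  if (n_mix > 0) {
    cls <- sample(c("early", "late"), n_mix, replace = TRUE,
                  prob = config$pause_mix)
    pc <- config$pause_components
    d <- integer(n_mix)
    ie <- cls == "early"
    if (any(ie)) d[ie] <- draw_trunc_norm_int(sum(ie), pc$early[["mean"]],
                                              pc$early[["sd"]], 1, 30)
    if (any(!ie)) d[!ie] <- draw_trunc_norm_int(sum(!ie), pc$late[["mean"]],
                                                pc$late[["sd"]], 31, 60)
    out[!at_peak] <- d - 1L
  }
  out
}

random_kmers <- function(n, k) {
  if (n == 0) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * k, replace = TRUE), nrow = n)
  apply(m, 1, paste0, collapse = "")
}

add_pcr_duplicates <- function(records, rate) {
  if (nrow(records) == 0 || rate <= 0) return(records)
  extra <- rpois(nrow(records), rate)
  dup_rows <- rep(seq_len(nrow(records)), extra)
  bind_rows(records, records[dup_rows, ]) |>
    arrange(.data$molecule_id)
}

#' Simulate a complete multi-sample experiment
#'
#' Builds a sample manifest crossing conditions, antibodies and replicates,
#' then simulates aligned molecules for every sample. The unphosphorylated-CTD
#' antibody in the reference condition (replicate-merged) is the designated
#' normalization control.
#'
#' @param config A [sim_config()].
#' @param antibodies Antibody labels (subset of `names(config$ctd_weights)`).
#' @param conditions Condition labels (subset of `config$conditions`).
#' @param replicates Number of replicates per condition x antibody.
#' @return A list: `genes`, `truth`, `manifest` (tibble with `sample`,
#'   `condition`, `antibody`, `replicate`, `control`), and `samples` (named
#'   list of [simulate_sample_reads()] outputs, keyed by sample id).
#' @export
simulate_experiment <- function(config,
                                antibodies = names(config$ctd_weights),
                                conditions = config$conditions,
                                replicates = 2) {
  gs <- simulate_gene_set(config)
  manifest <- tidyr::expand_grid(condition = conditions,
                                 antibody = antibodies,
                                 replicate = seq_len(replicates)) |>
    mutate(sample = paste(.data$condition, .data$antibody, .data$replicate,
                          sep = "_"),
           control = .data$condition == conditions[1] &
             .data$antibody == antibodies[1] & .data$replicate == 1L) |>
    dplyr::relocate(sample)
  samples <- vector("list", nrow(manifest))
  names(samples) <- manifest$sample
  for (i in seq_len(nrow(manifest))) {
    samples[[i]] <- simulate_sample_reads(
      gs$genes, gs$truth, config,
      antibody = manifest$antibody[i], condition = manifest$condition[i],
      sample_seed = config$seed + 7919L * i)
  }
  list(genes = gs$genes, truth = gs$truth, manifest = manifest,
       samples = samples)
}

#' Simulate a pooled, barcoded, UMI-tagged read set
#'
#' Emulates the library architecture at the read level: the 3'-adapter
#' carries a constant G at the ligation site followed by a 6-nt inline sample
#' barcode, and the 5'-adapter carries a 6-nt UMI followed by a constant C.
#' Read 1 is sequenced from the 3'-adapter side, so it begins with the
#' barcode + C, continues with the reverse complement of the nascent RNA,
#' and (when the insert is short enough) runs through G + reverse-complement
#' UMI into the 3'-adapter sequence. Read 2 begins with UMI + C followed by
#' the sense RNA. PCR duplicates are extra copies sharing UMI and sequence.
#'
#' @param config A [sim_config()]; `barcode_table` defines the pool.
#' @param n_per_sample Molecules per sample in the pool.
#' @param rna_len Integer range (`c(min, max)`) of nascent-RNA insert
#'   lengths.
#' @param read_length Sequencer read length; reads are truncated to this.
#' @param seed Seed for this pool (defaults to `config$seed`).
#' @return A tibble with one row per read: `read_id`, `true_sample`,
#'   `molecule_id`, `rna`, `read1`, `read2`, `qual1`, `qual2`.
#' @export
simulate_read_pool <- function(config, n_per_sample = 100,
                               rna_len = c(20, 45), read_length = 75,
                               seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed
  withr::with_seed(as.integer(seed), {
    bt <- config$barcode_table
    mols <- tidyr::expand_grid(true_sample = bt$sample,
                               i = seq_len(n_per_sample)) |>
      left_join(bt, by = c(true_sample = "sample")) |>
      mutate(molecule_id = sprintf("%s_m%05d", .data$true_sample, .data$i),
             len = sample(seq(rna_len[1], rna_len[2]),
                          dplyr::n(), replace = TRUE))
    mols$rna <- vapply(mols$len, function(l)
      paste0(sample(c("A", "C", "G", "T"), l, replace = TRUE),
             collapse = ""), character(1))
    mols$umi <- random_kmers(nrow(mols), 6)
    copies <- 1L + rpois(nrow(mols), config$pcr_dup_rate)
    reads <- mols[rep(seq_len(nrow(mols)), copies), ]
    reads <- reads |>
      mutate(
        read1 = substr(paste0(.data$barcode, "C", revcomp(.data$rna), "G",
                              revcomp(.data$umi), adapter_read1()),
                       1, read_length),
        read2 = substr(paste0(.data$umi, "C", .data$rna, adapter_read2()),
                       1, read_length),
        qual1 = strrep("I", nchar(.data$read1)),
        qual2 = strrep("I", nchar(.data$read2)),
        read_id = sprintf("r%06d", dplyr::row_number())) |>
      select("read_id", "true_sample", "molecule_id", "rna", "umi",
             "read1", "read2", "qual1", "qual2")
    reads
  })
}
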