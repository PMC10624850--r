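#' @name profiles
#' @title Ratio tracks, composite profiles and gene-body quantification
#'
#' @description Per-nucleotide comparisons of CTD phosphorylation states are
#' made as log2 ratios of normalized end counts (phosphorylated over
#' unphosphorylated), centred at 0 for equal signal. Composite (metagene)
#' profiles anchor per-gene signal at the TSN (linear -1000..+1000), scale
#' the gene body to 50 bins, or anchor at the CPS (linear -1000..+5000), and
#' summarise across genes with the per-bin mean and a 12.5-87.5% band.
#' Productive elongation is quantified as gbRPK: normalized 3'-end counts in
#' the gene body per kilobase.
NULL

#' Per-nucleotide log2 ratio track
#'
#' At every position covered by either input, computes
#' `log2((num + pseudocount) / (den + pseudocount))`. With the default
#' symmetric pseudocount, equal inputs (including double zeros) give exactly
#' 0.
#'
#' @param numerator,denominator Normalized `end_track`s on the same genome
#'   and end kind.
#' @param pseudocount Added to both numerator and denominator (default 0.5).
#' @return A tibble of class `ratio_track` (`chrom`, `strand`, `pos`,
#'   `value`).
#' @export
log2_ratio_track <- function(numerator, denominator, pseudocount = 0.5) {
  if (!identical(track_genome(numerator), track_genome(denominator)) ||
      !identical(track_end_kind(numerator), track_end_kind(denominator))) {
    abort("ratio tracks require matching genome and end_kind")
  }
  joined <- full_join(
    as_tibble(numerator) |> rename(num = "count"),
    as_tibble(denominator) |> rename(den = "count"),
    by = c("chrom", "strand", "pos")) |>
    mutate(num = tidyr::replace_na(.data$num, 0),
           den = tidyr::replace_na(.data$den, 0),
           value = log2((.data$num + pseudocount) /
                          (.data$den + pseudocount))) |>
    select("chrom", "strand", "pos", "value") |>
    arrange(.data$chrom, .data$strand, .data$pos)
  structure(joined, class = c("ratio_track", class(tibble())),
            genome = track_genome(numerator),
            end_kind = track_end_kind(numerator),
            pseudocount = pseudocount,
            numerator = track_sample_info(numerator)$sample,
            denominator = track_sample_info(denominator)$sample)
}

profile_value_col <- function(track) {
  if ("value" %in% names(track)) "value" else "count"
}

#' Anchored composite (metagene) profile
#'
#' Extracts per-gene signal strand-aware (minus-strand genes are reversed so
#' downstream of transcription is rightward), assembles a genes x bins
#' matrix, and summarises each bin with its mean and 12.5% / 87.5% quantiles
#' across genes.
#'
#' Anchor modes: `"tsn"` -- linear window (default -1000..+1000) around the
#' called TSN at 1- or 5-nt bins; `"cps"` -- linear window (default
#' -1000..+5000) around the CPS; `"body"` -- the TSN..CPS gene body divided
#' into `n_bins` equal-share bins (bin value = mean per-nt signal), which
#' conserves per-gene mass: sum(bin mean x bin width) equals the summed body
#' signal.
#'
#' @param track An `end_track`, `norm_track` or `ratio_track`.
#' @param genes Gene tibble; needs `tsn` for TSN/body anchors (join the
#'   [call_tsn()] output or truth table) and `cps` for CPS/body anchors.
#' @param anchor `"tsn"`, `"body"` or `"cps"`.
#' @param window Linear window `c(from, to)` in nt for the TSN / CPS modes;
#'   must be an exact multiple of `bin`.
#' @param bin Bin width in nt for the linear modes (1 or 5 typical).
#' @param n_bins Number of scaled bins in body mode (default 50); genes
#'   shorter than `n_bins` nt are excluded with a warning.
#' @param strand_mode `"sense"` profiles the gene's own strand,
#'   `"antisense"` the opposite genomic strand (divergent / convergent
#'   signal).
#' @return A list of class `composite_profile`: `matrix` (genes x bins),
#'   `summary` tibble (`bin`, `position`, `mean`, `q12.5`, `q87.5`, `n`),
#'   `anchor`, `bin_width`, `n_genes`.
#' @export
composite_profile <- function(track, genes,
                              anchor = c("tsn", "body", "cps"),
                              window = NULL, bin = 1, n_bins = 50,
                              strand_mode = c("sense", "antisense")) {
  anchor <- match.arg(anchor)
  strand_mode <- match.arg(strand_mode)
  genes <- arrange(as_tibble(genes), .data$gene_id)
  value_col <- profile_value_col(track)
  idx <- track_index(track, value_col = value_col)
  if (anchor %in% c("tsn", "body")) {
    if (!"tsn" %in% names(genes) || any(is.na(genes$tsn))) {
      abort("composite_profile: every gene needs a called TSN for this anchor")
    }
  }
  if (anchor %in% c("cps", "body")) stopifnot("cps" %in% names(genes))
  if (anchor != "body") {
    if (is.null(window)) {
      window <- if (anchor == "tsn") c(-1000, 1000) else c(-1000, 5000)
    }
    span <- window[2] - window[1]
    if (span %% bin != 0) {
      abort("composite_profile: window must be an exact multiple of bin")
    }
    nb <- span %/% bin
    anchors <- if (anchor == "tsn") genes$tsn else genes$cps
    cl <- if ("chrom_length" %in% names(genes)) genes$chrom_length else
      rep(NA_real_, nrow(genes))
    mat <- matrix(NA_real_, nrow(genes), nb)
    for (i in seq_len(nrow(genes))) {
      strand <- profile_strand(genes$strand[i], strand_mode)
      v <- window_counts(idx, genes$chrom[i], strand, anchors[i],
                         window[1], window[2] - 1,
                         chrom_length = if (is.na(cl[i])) NULL else cl[i],
                         orient = genes$strand[i])
      v[is.na(v)] <- 0
      mat[i, ] <- colMeans(matrix(v, nrow = bin))
    }
    positions <- window[1] + bin * (seq_len(nb) - 1) + (bin - 1) / 2
    bin_width <- rep(bin, nb)
  } else {
    body_len <- abs(genes$cps - genes$tsn) + 1
    short <- body_len < n_bins
    if (any(short)) {
      warn(sprintf("excluding %d gene(s) shorter than %d nt from body profile",
                   sum(short), n_bins))
      genes <- genes[!short, ]
      body_len <- body_len[!short]
    }
    if (nrow(genes) == 0) abort("no genes long enough for body profile")
    mat <- matrix(NA_real_, nrow(genes), n_bins)
    for (i in seq_len(nrow(genes))) {
      strand <- profile_strand(genes$strand[i], strand_mode)
      v <- window_counts(idx, genes$chrom[i], strand, genes$tsn[i],
                         0, body_len[i] - 1, orient = genes$strand[i])
      v[is.na(v)] <- 0
      edges <- floor((0:n_bins) * body_len[i] / n_bins)
      mat[i, ] <- vapply(seq_len(n_bins), function(b)
        mean(v[(edges[b] + 1):edges[b + 1]]), numeric(1))
    }
    positions <- (seq_len(n_bins) - 0.5) / n_bins
    bin_width <- NA_real_
    nb <- n_bins
  }
  rownames(mat) <- genes$gene_id
  smry <- tibble(
    bin = seq_len(nb), position = positions,
    mean = colMeans(mat),
    `q12.5` = apply(mat, 2, quantile, probs = 0.125, names = FALSE),
    `q87.5` = apply(mat, 2, quantile, probs = 0.875, names = FALSE),
    n = nrow(mat))
  structure(list(matrix = mat, summary = smry, anchor = anchor,
                 bin_width = bin_width, n_genes = nrow(mat),
                 strand_mode = strand_mode),
            class = "composite_profile")
}

profile_strand <- function(gene_strand, strand_mode) {
  if (strand_mode == "sense") gene_strand
  else if (gene_strand == "+") "-" else "+"
}

#' @export
print.composite_profile <- function(x, ...) {
  cat(sprintf("<composite_profile> anchor=%s, %d genes x %d bins (%s strand)\n",
              x$anchor, x$n_genes, nrow(x$summary), x$strand_mode))
  print(x$summary)
  invisible(x)
}

#' Tidy a composite profile
#' @param x A `composite_profile`.
#' @param ... Unused.
#' @return The per-bin summary tibble.
#' @export
tidy.composite_profile <- function(x, ...) x$summary

#' @export
glance.composite_profile <- function(x, ...) {
  tibble(anchor = x$anchor, n_genes = x$n_genes, n_bins = nrow(x$summary),
         strand_mode = x$strand_mode)
}

#' Plot a composite profile
#'
#' Mean per-bin signal with the 12.5-87.5% band across genes.
#'
#' @param object A `composite_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.composite_profile <- function(object, ...) {
  s <- object$summary
  xlab <- switch(object$anchor,
                 tsn = "Position relative to TSN (nt)",
                 cps = "Position relative to CPS (nt)",
                 body = "Scaled gene body (fraction)")
  ggplot2::ggplot(s, ggplot2::aes(x = .data$position)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$`q12.5`,
                                      ymax = .data$`q87.5`),
                         fill = "grey70", alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean), linewidth = 0.4) +
    ggplot2::labs(x = xlab, y = "Signal",
                  subtitle = sprintf("n = %d genes", object$n_genes)) +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' First sustained crossing of two per-bin profiles
#'
#' Scans the search range for the first bin where `a - b` turns positive and
#' stays positive for at least `k` consecutive bins (used, e.g., to locate
#' where relative serine-7 phosphorylation overtakes serine-5).
#'
#' @param a,b Numeric vectors of per-bin means on a shared binning.
#' @param search Integer range `c(from, to)` of bins to scan (default all).
#' @param k Number of consecutive positive bins required (default 5).
#' @return The bin index, or `NA_integer_` if no sustained crossing occurs.
#' @export
crossing_point <- function(a, b, search = NULL, k = 5) {
  stopifnot(length(a) == length(b))
  d <- a - b
  if (is.null(search)) search <- c(1L, length(d))
  lo <- max(1L, search[1]); hi <- min(length(d), search[2])
  for (i in lo:hi) {
    if (d[i] > 0 && (i == 1L || d[i - 1L] <= 0)) {
      run_end <- min(i + k - 1L, length(d))
      if (run_end - i + 1L >= k && all(d[i:run_end] > 0)) return(i)
    }
  }
  NA_integer_
}

#' Gene-body Pol II density (gbRPK)
#'
#' Summed (normalized) 3'-end counts in the gene body divided by body length
#' and multiplied by 1000: reads per kilobase of gene body, the measure of
#' productive elongation. The body starts `body_offset` nt downstream of the
#' TSN (excluding the promoter-proximal region) and ends at the CPS.
#'
#' @param track A (normalized) 3'-end `end_track`.
#' @param genes Gene tibble with `tsn` and `cps`.
#' @param body_offset Distance from TSN to body start (default 500 nt).
#' @return A tibble `gene_id`, `gbrpk`, `body_length`.
#' @export
gb_rpk <- function(track, genes, body_offset = 500) {
  genes <- as_tibble(genes)
  value_col <- profile_value_col(track)
  idx <- track_index(track, value_col = value_col)
  n <- nrow(genes)
  out <- numeric(n)
  blen <- numeric(n)
  for (i in seq_len(n)) {
    total_len <- abs(genes$cps[i] - genes$tsn[i]) + 1
    from <- min(body_offset, total_len - 1)
    blen[i] <- total_len - from
    if (blen[i] <= 0) abort("zero-length gene body")
    v <- window_counts(idx, genes$chrom[i], genes$strand[i], genes$tsn[i],
                       from, total_len - 1)
    out[i] <- sum(v, na.rm = TRUE) / blen[i] * 1000
  }
  tibble(gene_id = genes$gene_id, gbrpk = out, body_length = blen)
}

#' Summed-antibody transcriptional activity
#'
#' Adds the gbRPK of the four CTD antibodies (unphosphorylated, Ser2Ph,
#' Ser5Ph, Ser7Ph) per gene; all four must be present.
#'
#' @param gbrpk_tbl Tibble with columns `gene_id`, `antibody`, `gbrpk`.
#' @param antibodies The four required antibody labels.
#' @return Tibble `gene_id`, `gbrpk_sum`.
#' @export
sum_antibody_activity <- function(gbrpk_tbl,
                                  antibodies = c("unPh", "Ser2Ph", "Ser5Ph",
                                                 "Ser7Ph")) {
  gbrpk_tbl <- as_tibble(gbrpk_tbl)
  have <- unique(gbrpk_tbl$antibody)
  missing <- setdiff(antibodies, have)
  if (length(missing) > 0) {
    abort(paste0("missing antibody gbRPK(s): ", paste(missing, collapse = ", ")))
  }
  gbrpk_tbl |>
    filter(.data$antibody %in% antibodies) |>
    group_by(.data$gene_id) |>
    summarise(gbrpk_sum = sum(.data$gbrpk), .groups = "drop")
}

#' Group genes by transcriptional activity
#'
#' Quantile-based partition of genes into `n_groups` activity classes by a
#' score (typically summed-antibody gbRPK). Ties are resolved
#' deterministically by gene id order; group 1 is the least active.
#'
#' @param records Tibble with `gene_id` and the score column.
#' @param n_groups Number of groups (default 4).
#' @param score Name of the score column (default `"gbrpk_sum"`).
#' @return `records` with an integer `activity_group` column.
#' @export
group_by_activity <- function(records, n_groups = 4, score = "gbrpk_sum") {
  records <- as_tibble(records)
  n <- nrow(records)
  if (n < n_groups) abort("fewer genes than groups")
  ord <- order(records[[score]], records$gene_id)
  grp <- integer(n)
  grp[ord] <- ceiling(seq_len(n) * n_groups / n)
  records$activity_group <- grp
  records
}

#' Classify the heat-shock response of a gene
#'
#' @param gbrpk_reference,gbrpk_treated Gene-body densities in the reference
#'   and treated condition.
#' @param up_fc Minimum treated/reference fold change to call activation
#'   (default 2).
#' @param down_fc Maximum fold change to call repression (default 0.5).
#' @param min_activity Minimum density in the relevant condition for a call
#'   (treated for activation, reference for repression).
#' @return Character vector: `"activated"`, `"repressed"` or `"unchanged"`.
#'   A zero reference with adequate treated signal is activated.
#' @export
classify_hs_response <- function(gbrpk_reference, gbrpk_treated,
                                 up_fc = 2, down_fc = 0.5,
                                 min_activity = 0) {
  if (up_fc <= 1 || down_fc >= 1) {
    abort("require up_fc > 1 and down_fc < 1")
  }
  ratio <- ifelse(gbrpk_reference > 0, gbrpk_treated / gbrpk_reference,
                  ifelse(gbrpk_treated > 0, Inf, 1))
  dplyr::case_when(
    ratio >= up_fc & gbrpk_treated >= min_activity ~ "activated",
    ratio <= down_fc & gbrpk_reference >= min_activity ~ "repressed",
    .default = "unchanged")
}
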