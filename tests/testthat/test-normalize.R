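# two-condition sample table with controllable spike counts / depths
make_sample_table <- function(spike = c(1000, 2000, 1500, 3000),
                              depth = c(5e6, 4e6, 6e6, 3e6)) {
  tibble::tibble(
    sample = c("NHS_unPh", "NHS_Ser5Ph", "HS30_unPh", "HS30_Ser5Ph"),
    condition = rep(c("NHS", "HS30"), each = 2),
    antibody = rep(c("unPh", "Ser5Ph"), 2),
    spike_count = spike, depth = depth)
}

test_that("spike-in factor is the ratio to the control-antibody count", {
  expect_equal(compute_nf_spikein(1000, 1000), 1)
  expect_equal(compute_nf_spikein(2000, 1000), 2)
  expect_error(compute_nf_spikein(10, 0), "positive")
  f <- normalization_factors(make_sample_table(),
                             control_antibody = "unPh",
                             control_condition = "NHS")
  expect_equal(f$nf_spikein, c(1, 2, 1, 2))
  # control sample against itself
  expect_equal(f$nf_spikein[f$control], 1)
})

test_that("long-gene-end factor matches a dense window-sum oracle", {
  gene <- tibble::tibble(gene_id = "gl", chrom = "chr1", strand = "+",
                         tss = 0L, cps = 200000L - 1L)
  t_ref <- random_sparse_track(4000, chrom_length = 200000, seed = 31)
  t_test <- random_sparse_track(4000, chrom_length = 200000, seed = 32)
  expect_equal(compute_nf_longGE(t_ref, t_ref, gene), 1)

  half <- retrack_half(t_ref)
  expect_equal(compute_nf_longGE(half, t_ref, gene), 0.5)

  got <- compute_nf_longGE(t_test, t_ref, gene)
  # oracle: end window = last min(25%, 50 kb) = last 50 kb of the body
  dense_test <- dense_counts(t_test, "chr1", "+", 200000)
  dense_ref <- dense_counts(t_ref, "chr1", "+", 200000)
  win <- 150001:200000
  expect_equal(got, sum(dense_test[win]) / sum(dense_ref[win]))

  short_gene <- dplyr::mutate(gene, cps = 1000L)
  expect_error(compute_nf_longGE(t_test, t_ref, short_gene), "150000")
})

test_that("minus-strand long genes use the strand-aware end window", {
  gene <- tibble::tibble(gene_id = "gl", chrom = "chr1", strand = "-",
                         tss = 200000L - 1L, cps = 0L)
  t_ref <- random_sparse_track(4000, chrom_length = 200000, seed = 33)
  t_test <- random_sparse_track(4000, chrom_length = 200000, seed = 34)
  got <- compute_nf_longGE(t_test, t_ref, gene)
  dense_test <- dense_counts(t_test, "chr1", "-", 200000)
  dense_ref <- dense_counts(t_ref, "chr1", "-", 200000)
  win <- 1:50000  # low coordinates are the 3'-end of a minus-strand gene
  expect_equal(got, sum(dense_test[win]) / sum(dense_ref[win]))
})

test_that("nf-cRPM scales counts by the three factors", {
  tr <- tiny_track(tibble::tibble(chrom = "chr1", strand = "+", pos = 10L,
                                  count = 10), sample = "HS30_Ser5Ph")
  st <- make_sample_table(spike = c(1000, 1000, 1000, 2000),
                          depth = c(5e6, 1, 1, 1))
  f <- normalization_factors(st, control_antibody = "unPh",
                             control_condition = "NHS")
  out <- apply_nf_cRPM(tr, f)
  # 10 * (1/2) * (1/1) * 1e6/5e6 = 1
  expect_equal(out$count, 1)

  # control sample: scaled only by 1e6 / its own depth
  ctrl <- tiny_track(tibble::tibble(chrom = "chr1", strand = "+", pos = 10L,
                                    count = 10), sample = "NHS_unPh")
  expect_equal(apply_nf_cRPM(ctrl, f)$count, 10 * 1e6 / 5e6)

  # identity when every factor is 1 and depth is 1e6
  st2 <- make_sample_table(spike = rep(1000, 4), depth = rep(1e6, 4))
  f2 <- normalization_factors(st2, control_antibody = "unPh",
                              control_condition = "NHS")
  expect_equal(apply_nf_cRPM(tr, f2)$count, tr$count)
  expect_error(apply_nf_cRPM(tiny_track(tibble::tibble(
    chrom = "chr1", strand = "+", pos = 1L, count = 1), sample = "zz"), f),
    "not registered")
})

test_that("RPM normalizes to one million by own depth", {
  tr <- tiny_track(tibble::tibble(chrom = "chr1", strand = "+",
                                  pos = c(1L, 2L), count = c(7, 3)))
  r <- rpm(tr)
  expect_equal(r$count, c(7e5, 3e5))
  expect_equal(track_total(r), 1e6)
  dense <- dense_counts(tr, "chr1", "+", 10) * 1e6 / track_total(tr)
  expect_equal(dense_counts(r, "chr1", "+", 10), dense)
  empty <- tiny_track(tibble::tibble(chrom = character(), strand = character(),
                                     pos = integer(), count = double()))
  expect_error(rpm(empty), "empty")
})

test_that("nf-cRPM is invariant to joint scaling and inverse in spike count", {
  tr <- random_sparse_track(500, seed = 41)
  st <- make_sample_table()
  f <- normalization_factors(st, control_antibody = "unPh",
                             control_condition = "NHS")
  base <- apply_nf_cRPM(retrack_named(tr, "HS30_Ser5Ph"), f)

  # scaling a non-control sample's raw counts and spike count by c together
  # leaves its normalized track unchanged
  c_factor <- 3.7
  st_scaled <- make_sample_table(spike = c(1000, 2000, 1500, 3000 * c_factor))
  f_scaled <- normalization_factors(st_scaled, control_antibody = "unPh",
                                    control_condition = "NHS")
  scaled <- apply_nf_cRPM(retrack_named(retrack_scale(tr, c_factor),
                                        "HS30_Ser5Ph"), f_scaled)
  expect_equal(scaled$count, base$count, tolerance = 1e-12)

  # scaling only the spike count by c divides the track by c
  spike_only <- apply_nf_cRPM(retrack_named(tr, "HS30_Ser5Ph"), f_scaled)
  expect_equal(spike_only$count, base$count / c_factor, tolerance = 1e-12)

  # equal spike counts and nf_longGE 1: nf-cRPM equals control-depth RPM
  st_eq <- make_sample_table(spike = rep(1000, 4))
  f_eq <- normalization_factors(st_eq, control_antibody = "unPh",
                                control_condition = "NHS")
  eq <- apply_nf_cRPM(retrack_named(tr, "HS30_Ser5Ph"), f_eq)
  ctrl_depth_rpm <- rpm(tr, depth = attr(f_eq, "control_depth"))
  expect_equal(eq$count, ctrl_depth_rpm$count, tolerance = 1e-12)
})

test_that("the designated control's combined factor is exactly one", {
  st <- make_sample_table(spike = c(1234, 777, 999, 555),
                          depth = c(2.5e6, 1e6, 3e6, 2e6))
  f <- normalization_factors(st, control_antibody = "unPh",
                             control_condition = "NHS")
  ctrl <- tidy(f) |> dplyr::filter(control)
  expect_identical(ctrl$combined_nf, 1)
  expect_error(normalization_factors(dplyr::filter(st, antibody != "unPh")),
               "control")
})

test_that("spike-in chromatin proportion arithmetic", {
  expect_equal(estimate_spikein_fraction(1, 100, 2, 1, 100, 2), 100)
  expect_equal(estimate_spikein_fraction(2, 100, 2, 1, 100, 2),
               2 * estimate_spikein_fraction(1, 100, 2, 1, 100, 2))
  expect_error(estimate_spikein_fraction(0, 1, 1, 1, 1, 1), "positive")
})
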