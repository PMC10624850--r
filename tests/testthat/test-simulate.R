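test_that("gene placement honours the configured TSN offset and is reproducible", {
  cfg <- sim_config(n_genes = 1, genome_length = 1e6,
                    tsn_offset = list(fixed = 55), seed = 5)
  gs <- simulate_gene_set(cfg)
  expect_equal(nrow(gs$genes), 1)
  expect_equal(abs(gs$truth$tsn - gs$truth$tss), 55)
  expect_equal(gs$truth$tsn_offset, 55)

  cfg2 <- small_config()
  expect_identical(simulate_gene_set(cfg2), simulate_gene_set(cfg2))

  empty <- simulate_gene_set(sim_config(n_genes = 0, seed = 1))
  expect_equal(nrow(empty$genes), 0)
  expect_equal(nrow(empty$truth), 0)
})

test_that("generated genes are non-overlapping, both strands, truth complete", {
  gs <- simulate_gene_set(small_config())
  g <- gs$genes
  expect_setequal(unique(g$strand), c("+", "-"))
  expect_equal(anyDuplicated(g$gene_id), 0)
  expect_equal(gs$truth$gene_id, g$gene_id)
  # span including upstream window must not overlap between genes
  lo <- pmin(g$tss, g$cps) - 100
  hi <- pmax(g$tss, g$cps)
  ord <- order(lo)
  expect_true(all(lo[ord][-1] > hi[ord][-length(ord)]))
  # TSN within -100..+400 of the annotated TSS
  expect_true(all(gs$truth$tsn_offset >= -100 & gs$truth$tsn_offset <= 400))
  # dominant pause inside the pause region with matching class
  expect_true(all(gs$truth$pause_distance >= 1 & gs$truth$pause_distance <= 60))
  expect_true(all((gs$truth$pause_distance <= 30) ==
                    (gs$truth$pause_class == "early")))
})

test_that("placement failure on a too-small genome raises an error", {
  expect_error(simulate_gene_set(sim_config(n_genes = 50, genome_length = 1e4,
                                            seed = 1)),
               "genome_length")
})

test_that("sample reads respect compartment weights, totals and determinism", {
  cfg <- sim_config(n_genes = 5, genome_length = 1e6, reads_per_sample = 2000,
                    noise_rate = 0, spike_in_fraction = 0,
                    ctd_weights = list(unPh = c(pause = 1, body = 0, term = 0)),
                    seed = 7)
  gs <- simulate_gene_set(cfg)
  sm <- simulate_sample_reads(gs$genes, gs$truth, cfg, "unPh", "NHS")
  expect_equal(nrow(sm$records) + nrow(sm$spike_records), 2000)
  # with all weight on the pause, every 3'-end lies within +1..+60 of its TSN
  t3 <- reads_to_end_track(sm$records, "three_prime")
  by_gene <- lapply(seq_len(nrow(gs$truth)), function(i) {
    tr <- gs$truth[i, ]
    dir <- if (tr$strand == "+") 1 else -1
    d <- dir * (t3$pos[t3$strand == tr$strand] - tr$tsn)
    d[d >= 0 & d < 2000]
  })
  d_all <- unlist(by_gene)
  expect_true(all(d_all >= 0 & d_all <= 59))
  expect_identical(sm, simulate_sample_reads(gs$genes, gs$truth, cfg,
                                             "unPh", "NHS"))
  expect_error(simulate_sample_reads(gs$genes, gs$truth, cfg, "bogus", "NHS"),
               "antibody")
})

test_that("spike-in fraction matches its target within binomial error", {
  cfg <- sim_config(n_genes = 5, genome_length = 1e6,
                    reads_per_sample = 20000, spike_in_fraction = 0.05,
                    seed = 13)
  gs <- simulate_gene_set(cfg)
  sm <- simulate_sample_reads(gs$genes, gs$truth, cfg, "unPh", "NHS")
  n <- cfg$reads_per_sample
  p <- cfg$spike_in_fraction
  tol <- 4 * sqrt(n * p * (1 - p))
  expect_lt(abs(sm$spike_count - n * p), tol)
})

test_that("minus-strand molecules place the 5'-end at the higher coordinate", {
  cfg <- sim_config(n_genes = 10, genome_length = 2e6, reads_per_sample = 3000,
                    noise_rate = 0, spike_in_fraction = 0, seed = 23)
  gs <- simulate_gene_set(cfg)
  sm <- simulate_sample_reads(gs$genes, gs$truth, cfg, "Ser2Ph", "NHS")
  minus_genes <- gs$truth[gs$truth$strand == "-", ]
  expect_gt(nrow(minus_genes), 0)
  rec <- sm$records[sm$records$strand == "-", ]
  t5 <- reads_to_end_track(rec, "five_prime")
  # on the minus strand, 5'-ends concentrate at each gene's TSN
  expect_true(all(minus_genes$tsn %in% t5$pos))
  top <- t5[order(-t5$count), ][seq_len(nrow(minus_genes)), ]
  expect_setequal(top$pos, minus_genes$tsn)
})

test_that("PCR duplication is collapsible back to the molecule count", {
  cfg <- sim_config(n_genes = 5, genome_length = 1e6, reads_per_sample = 1500,
                    pcr_dup_rate = 1.5, seed = 17)
  gs <- simulate_gene_set(cfg)
  sm <- simulate_sample_reads(gs$genes, gs$truth, cfg, "unPh", "NHS",
                              with_duplicates = TRUE)
  n_all <- nrow(sm$records) + nrow(sm$spike_records)
  expect_gt(n_all, sm$n_molecules)  # duplicates were added
  # collapsing the duplicated set must reproduce the collapse of the
  # pre-duplication molecule set (duplicates are exact UMI+coordinate copies)
  sm0 <- simulate_sample_reads(gs$genes, gs$truth, cfg, "unPh", "NHS",
                               with_duplicates = FALSE)
  dedup <- dplyr::arrange(collapse_umi_records(sm$records), molecule_id)
  dedup0 <- dplyr::arrange(collapse_umi_records(sm0$records), molecule_id)
  expect_equal(dedup, dedup0)
})

test_that("heat-shock condition scales activated and repressed genes", {
  cfg <- sim_config(n_genes = 40, genome_length = 6e6, seed = 19,
                    hs_activated_frac = 0.25, hs_repressed_frac = 0.25)
  gs <- simulate_gene_set(cfg)
  tr <- gs$truth
  act <- tr$response_class == "activated"
  rep_ <- tr$response_class == "repressed"
  expect_equal(tr$weight_HS30[act], tr$weight_NHS[act] * cfg$activated_fc)
  expect_equal(tr$weight_HS30[rep_], tr$weight_NHS[rep_] * cfg$repressed_fc)
  unch <- !(act | rep_)
  expect_equal(tr$weight_HS30[unch], tr$weight_NHS[unch])
})

test_that("config validation rejects malformed settings", {
  expect_error(sim_config(noise_rate = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(pause_mix = c(0.7, 0.7)), "sum to 1")
  expect_error(sim_config(ctd_weights = list(unPh = c(1, 1, 1))), "summing to 1")
  expect_error(
    sim_config(barcode_table = data.frame(sample = c("a", "b"),
                                          barcode = c("ATCACG", "ATCACG"))),
    "unique")
})

test_that("sim_config YAML round-trip preserves the configuration", {
  cfg <- small_config()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  cfg2 <- read_sim_config(path)
  expect_equal(cfg2$n_genes, cfg$n_genes)
  expect_equal(cfg2$ctd_weights, cfg$ctd_weights)
  expect_equal(cfg2$barcode_table, cfg$barcode_table)
  expect_identical(simulate_gene_set(cfg2), simulate_gene_set(cfg))
})
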