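norm_like <- function(df, sample = "x") {
  tr <- tiny_track(df, sample = sample)
  class(tr) <- unique(c("norm_track", class(tr)))
  tr
}

test_that("log2 ratio track centres equal signal at zero", {
  a <- norm_like(tibble::tibble(chrom = "chr1", strand = "+",
                                pos = c(1L, 5L), count = c(4, 4)))
  r0 <- log2_ratio_track(a, a)
  expect_true(all(r0$value == 0))

  num <- norm_like(tibble::tibble(chrom = "chr1", strand = "+", pos = 1L,
                                  count = 8))
  den <- norm_like(tibble::tibble(chrom = "chr1", strand = "+", pos = 1L,
                                  count = 2))
  expect_equal(log2_ratio_track(num, den, pseudocount = 0)$value, 2)

  # symmetric pseudocount keeps double zeros at zero
  z1 <- norm_like(tibble::tibble(chrom = "chr1", strand = "+", pos = 2L,
                                 count = 0))
  z2 <- norm_like(tibble::tibble(chrom = "chr1", strand = "+", pos = 2L,
                                 count = 0))
  expect_equal(log2_ratio_track(z1, z2, pseudocount = 0.5)$value, 0)

  # positions covered by only one input are kept, with the other side at 0
  b <- norm_like(tibble::tibble(chrom = "chr1", strand = "+", pos = 9L,
                                count = 3))
  r <- log2_ratio_track(a, b)
  expect_setequal(r$pos, c(1, 5, 9))
  expect_equal(r$value[r$pos == 9], log2(0.5 / 3.5))
})

test_that("composite profiles: constant input, averaging, and dense oracle", {
  genes <- dplyr::bind_rows(one_gene(), one_gene(strand = "-", tss = 9000L)) |>
    dplyr::mutate(gene_id = c("g1", "g2"), tsn = tss)
  # constant signal 2.0 across both bodies
  rows <- list()
  for (i in 1:2) {
    dir <- if (genes$strand[i] == "+") 1 else -1
    rows[[i]] <- tibble::tibble(chrom = "chr1", strand = genes$strand[i],
                                pos = genes$tss[i] + dir * (0:1999),
                                count = 2)
  }
  tr <- tiny_track(dplyr::bind_rows(rows))
  prof <- composite_profile(tr, genes, anchor = "body")
  expect_equal(unname(prof$summary$mean), rep(2, 50))
  expect_equal(prof$summary$`q12.5`, prof$summary$`q87.5`)

  # two genes with constant 1 and 3 average to 2 with a 1..3 band
  tr13 <- tiny_track(dplyr::bind_rows(
    dplyr::mutate(rows[[1]], count = 1), dplyr::mutate(rows[[2]], count = 3)))
  prof13 <- composite_profile(tr13, genes, anchor = "body")
  expect_equal(unname(prof13$summary$mean), rep(2, 50))

  # random signal: bin means equal a dense per-gene extraction oracle
  rnd <- random_sparse_track(800, chrom_length = 12000, seed = 61)
  profr <- composite_profile(rnd, genes, anchor = "body")
  for (i in 1:2) {
    dir <- if (genes$strand[i] == "+") 1 else -1
    v <- vapply(0:1999, function(off) {
      p <- genes$tss[i] + dir * off
      row <- rnd[rnd$chrom == "chr1" & rnd$strand == genes$strand[i] &
                   rnd$pos == p, ]
      if (nrow(row) == 0) 0 else row$count
    }, numeric(1))
    expected <- vapply(seq_len(50), function(b) {
      mean(v[(floor((b - 1) * 2000 / 50) + 1):floor(b * 2000 / 50)])
    }, numeric(1))
    expect_equal(unname(profr$matrix[genes$gene_id[i], ]), expected)
  }
})

test_that("gene-body profiles conserve per-gene mass and ignore gene order", {
  withr::with_seed(71, {
    genes <- dplyr::bind_rows(
      one_gene(tss = 1000L, body = 777L),
      one_gene(strand = "-", tss = 9000L, body = 1234L),
      one_gene(tss = 20000L, body = 150L)) |>
      dplyr::mutate(gene_id = c("a", "b", "c"), tsn = tss)
    tr <- random_sparse_track(2000, chrom_length = 25000, seed = 72)
  })
  prof <- composite_profile(tr, genes, anchor = "body")
  dense_p <- dense_counts(tr, "chr1", "+", 25000)
  dense_m <- dense_counts(tr, "chr1", "-", 25000)
  for (i in seq_len(nrow(genes))) {
    L <- abs(genes$cps[i] - genes$tss[i]) + 1
    dir <- if (genes$strand[i] == "+") 1 else -1
    posns <- genes$tss[i] + dir * (0:(L - 1))
    total <- sum((if (genes$strand[i] == "+") dense_p else dense_m)[posns + 1])
    edges <- floor((0:50) * L / 50)
    widths <- diff(edges)
    mass <- sum(prof$matrix[genes$gene_id[i], ] * widths)
    expect_equal(mass, total, tolerance = 1e-9)
  }
  # permuting the gene table leaves the profile unchanged
  prof_rev <- composite_profile(tr, genes[c(3, 1, 2), ], anchor = "body")
  expect_equal(prof_rev$matrix, prof$matrix)
  expect_equal(prof_rev$summary, prof$summary)

  # genes shorter than the bin count are excluded with a warning
  tiny <- dplyr::mutate(one_gene(body = 30L), tsn = tss)
  expect_warning(composite_profile(tr, dplyr::bind_rows(genes, tiny),
                                   anchor = "body"), "shorter")
})

test_that("linear anchored profiles window and bin correctly", {
  g <- dplyr::mutate(one_gene(tss = 5000L, body = 3000L), tsn = tss + 100L)
  tr <- tiny_track(tibble::tibble(chrom = "chr1", strand = "+",
                                  pos = g$tsn + c(-1000, 0, 500, 999),
                                  count = c(5, 7, 2, 4)))
  prof <- composite_profile(tr, g, anchor = "tsn", window = c(-1000, 1000),
                            bin = 1)
  expect_equal(ncol(prof$matrix), 2000)
  v <- prof$matrix[1, ]
  expect_equal(unname(v[1]), 5)       # offset -1000
  expect_equal(unname(v[1001]), 7)    # offset 0 = TSN
  expect_equal(unname(v[1501]), 2)
  expect_equal(sum(v), 18)
  # 5-nt bins average within each bin
  prof5 <- composite_profile(tr, g, anchor = "tsn", window = c(-1000, 1000),
                             bin = 5)
  expect_equal(ncol(prof5$matrix), 400)
  expect_equal(unname(prof5$matrix[1, 201]), 7 / 5)
  expect_error(composite_profile(tr, g, anchor = "tsn",
                                 window = c(-1000, 1000), bin = 3),
               "multiple")
  # CPS anchor centres on the cleavage site
  cps_tr <- tiny_track(tibble::tibble(chrom = "chr1", strand = "+",
                                      pos = g$cps, count = 9))
  profc <- composite_profile(cps_tr, g, anchor = "cps",
                             window = c(-1000, 5000), bin = 1)
  expect_equal(unname(profc$matrix[1, 1001]), 9)
})

test_that("antisense profiling reads the opposite genomic strand", {
  g <- dplyr::mutate(one_gene(tss = 5000L), tsn = tss)
  anti <- tiny_track(tibble::tibble(chrom = "chr1", strand = "-",
                                    pos = g$tsn - 50, count = 6))
  prof <- composite_profile(anti, g, anchor = "tsn", window = c(-100, 100),
                            bin = 1, strand_mode = "antisense")
  # upstream divergent signal appears at offset -50
  expect_equal(unname(prof$matrix[1, 51]), 6)
  sense <- composite_profile(anti, g, anchor = "tsn", window = c(-100, 100),
                             bin = 1)
  expect_equal(sum(sense$matrix), 0)
})

test_that("crossing point finds the first sustained sign change", {
  b <- rep(0, 200)
  expect_equal(crossing_point(rep(1, 200), b), 1)
  expect_true(is.na(crossing_point(rep(-1, 200), b)))
  # sigmoid crossing zero at bin 140
  x <- seq_len(200)
  a <- 1 / (1 + exp(-(x - 139.5) / 3)) - 0.5
  expect_equal(crossing_point(a, b), 140)
  # a short blip does not count as sustained
  blip <- rep(-1, 200); blip[50:52] <- 1; blip[150:200] <- 1
  expect_equal(crossing_point(blip, b, k = 5), 150)
})

test_that("gbRPK is body density times 1000 and linear in the track", {
  g <- dplyr::mutate(one_gene(tss = 1000L, body = 10500L), tsn = tss)
  # 500 counts spread over the 10,000-nt body (offset 500..10499)
  tr <- tiny_track(tibble::tibble(chrom = "chr1", strand = "+",
                                  pos = g$tsn + 500 + 20 * (0:499),
                                  count = 1))
  got <- gb_rpk(tr, g, body_offset = 500)
  expect_equal(got$gbrpk, 500 / 10000 * 1000)
  expect_equal(gb_rpk(retrack_scale(tr, 2), g)$gbrpk, 2 * got$gbrpk)
  none <- tiny_track(tibble::tibble(chrom = "chr1", strand = "+",
                                    pos = 1L, count = 5))
  expect_equal(gb_rpk(none, g)$gbrpk, 0)
})

test_that("summed-antibody activity requires all four antibodies", {
  tbl <- tidyr::expand_grid(gene_id = c("g1", "g2"),
                            antibody = c("unPh", "Ser2Ph", "Ser5Ph",
                                         "Ser7Ph")) |>
    dplyr::mutate(gbrpk = c(1, 2, 3, 4, 0, 0, 0, 0))
  s <- sum_antibody_activity(tbl)
  expect_equal(s$gbrpk_sum[s$gene_id == "g1"], 10)
  expect_equal(s$gbrpk_sum[s$gene_id == "g2"], 0)
  # permutation invariance
  s2 <- sum_antibody_activity(tbl[sample(nrow(tbl)), ])
  expect_equal(dplyr::arrange(s2, gene_id), dplyr::arrange(s, gene_id))
  expect_error(sum_antibody_activity(dplyr::filter(tbl, antibody != "unPh")),
               "missing antibody")
})

test_that("activity grouping splits genes into deterministic quantile groups", {
  rec <- tibble::tibble(gene_id = sprintf("g%02d", 1:8),
                        gbrpk_sum = c(5, 2, 8, 1, 9, 3, 7, 4))
  g <- group_by_activity(rec, 4)
  expect_equal(as.integer(table(g$activity_group)), rep(2L, 4))
  expect_equal(g$activity_group[order(g$gbrpk_sum)], rep(1:4, each = 2))
  # all-equal scores fall back to gene-id order
  eq <- group_by_activity(dplyr::mutate(rec, gbrpk_sum = 1), 4)
  expect_equal(eq$activity_group, rep(1:4, each = 2))
  expect_error(group_by_activity(rec[1:3, ], 4), "fewer")
  # boundaries agree with a full-sort oracle
  withr::with_seed(88, {
    rec2 <- tibble::tibble(gene_id = sprintf("g%03d", 1:101),
                           gbrpk_sum = stats::runif(101))
  })
  g2 <- group_by_activity(rec2, 4)
  ord <- order(rec2$gbrpk_sum, rec2$gene_id)
  expect_equal(g2$activity_group[ord], ceiling(seq_len(101) * 4 / 101))
})

test_that("heat-shock response classification and antisymmetry", {
  expect_equal(classify_hs_response(10, 40), "activated")
  expect_equal(classify_hs_response(40, 10), "repressed")
  expect_equal(classify_hs_response(10, 12), "unchanged")
  expect_equal(classify_hs_response(0, 5), "activated")
  expect_equal(classify_hs_response(0, 0), "unchanged")
  # antisymmetric for symmetric thresholds
  withr::with_seed(91, {
    a <- stats::runif(50, 0, 20)
    b <- stats::runif(50, 0, 20)
  })
  fwd <- classify_hs_response(a, b)
  rev_ <- classify_hs_response(b, a)
  expect_equal(rev_ == "activated", fwd == "repressed")
  expect_equal(rev_ == "repressed", fwd == "activated")
  expect_error(classify_hs_response(1, 2, up_fc = 0.9), "up_fc")
})

test_that("tidy, glance and autoplot work on composite profiles", {
  g <- dplyr::mutate(one_gene(), tsn = tss)
  tr <- random_sparse_track(200, chrom_length = 5000, seed = 99)
  prof <- composite_profile(tr, g, anchor = "body")
  expect_equal(tidy(prof), prof$summary)
  expect_equal(glance(prof)$n_genes, 1)
  p <- ggplot2::autoplot(prof)
  expect_s3_class(p, "ggplot")
})
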