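test_that("breakend adjacencies join junction-adjacent boundaries", {
  canonical <- dplyr::bind_rows(
    mk_block("r", 0, 2000, "+", "AAV", 928, 2928, read_len = 9000),
    mk_block("r", 2000, 9000, "+", "chr5", 10000, 17000, read_len = 9000)
  )
  adj <- derive_adjacencies(canonical)
  expect_equal(nrow(adj), 1)
  expect_equal(adj$posA, 2928)        # vector segment end
  expect_equal(adj$sideA, "end")
  expect_equal(adj$posB, 10001)       # host segment start
  expect_equal(adj$sideB, "start")
  expect_equal(adj$read_gap, 0L)

  spanned <- dplyr::bind_rows(
    mk_block("r", 0, 3000, "+", "chr5", 7000, 10000, read_len = 9000),
    mk_block("r", 3000, 5928, "+", "AAV", 0, 2928, read_len = 9000),
    mk_block("r", 5928, 9000, "+", "chr5", 10000, 13072, read_len = 9000)
  )
  expect_equal(nrow(derive_adjacencies(spanned)), 2)

  single <- mk_block("r", 0, 2000, "+", "chr5", 0, 2000, read_len = 2000)
  expect_equal(nrow(derive_adjacencies(single)), 0)
})

test_that("vector-host selection keeps exactly mixed-reference pairs", {
  blocks <- dplyr::bind_rows(
    mk_block("r1", 0, 2000, "+", "AAV", 928, 2928, read_len = 9000),
    mk_block("r1", 2000, 9000, "+", "chr5", 10000, 17000, read_len = 9000),
    mk_block("r2", 0, 2000, "+", "chr5", 0, 2000, read_len = 4000),
    mk_block("r2", 2000, 4000, "+", "chr7", 100, 2100, read_len = 4000),
    mk_block("r3", 0, 2928, "+", "AAV", 0, 2928, read_len = 5856),
    mk_block("r3", 2928, 5856, "+", "AAV", 0, 2928, read_len = 5856)
  )
  sel <- select_vector_host(derive_adjacencies(blocks))
  expect_equal(sel$read_id, "r1")
  expect_equal(sel$chrom, "chr5")
  expect_equal(sel$pos1, 10001)
  expect_equal(sel$side, "right")

  # read gaps beyond the window are rejected
  far <- dplyr::bind_rows(
    mk_block("r4", 0, 2000, "+", "AAV", 928, 2928, read_len = 9000),
    mk_block("r4", 2100, 9000, "+", "chr5", 10000, 16900, read_len = 9000)
  )
  expect_equal(nrow(select_vector_host(derive_adjacencies(far), window = 50)), 0)
})

test_that("single-linkage clustering uses the lower-middle median", {
  mk_sel <- function(pos, ids = paste0("r", seq_along(pos))) {
    tibble::tibble(read_id = ids, chrom = "chr5", pos1 = pos, side = "right",
                   vector_pos1 = 2928, read_gap = 0L)
  }
  e1 <- cluster_events(mk_sel(c(1000, 1003, 1010)), tol = 25)
  expect_equal(nrow(e1), 1)
  expect_equal(e1$pos1, 1003)
  expect_equal(e1$support, 3L)

  e2 <- cluster_events(mk_sel(c(1000, 5000)), tol = 25)
  expect_equal(nrow(e2), 2)

  # chaining: pairwise links at <= tol merge the whole run
  e3 <- cluster_events(mk_sel(c(1000, 1020, 1040)), tol = 25)
  expect_equal(nrow(e3), 1)
  expect_equal(e3$pos1, 1020)

  # permutation invariance
  set.seed(9)
  pos <- sample(c(2000:2008, 7000:7004, 40000))
  ref <- cluster_events(mk_sel(pos), tol = 25)
  for (i in 1:5) {
    p <- sample(seq_along(pos))
    shuf <- cluster_events(mk_sel(pos[p], ids = paste0("r", p)), tol = 25)
    expect_equal(as.data.frame(shuf[order(shuf$pos1), ]),
                 as.data.frame(ref[order(ref$pos1), ]))
  }
})

test_that("baseline is the best-supported event, ties to the tighter cluster", {
  mk_events <- function(supports, positions, spreads) {
    tibble::tibble(
      chrom = "chr5", pos1 = positions, side = "right", support = supports,
      read_names = lapply(supports, function(n) paste0("r", seq_len(n))),
      vector_pos1 = 2928, is_baseline = FALSE,
      member_positions = purrr::map2(positions, spreads,
                                     function(p, s) c(p - s / 2, p + s / 2))
    )
  }
  e <- rank_baseline(mk_events(c(7L, 3L), c(1000, 9000), c(2, 2)))
  expect_equal(e$pos1[e$is_baseline], 1000)
  expect_equal(sum(e$is_baseline), 1)

  single <- rank_baseline(mk_events(4L, 500, 0))
  expect_true(single$is_baseline)

  tie <- rank_baseline(mk_events(c(4L, 4L), c(9000, 1000), c(2, 18)))
  expect_equal(tie$pos1[tie$is_baseline], 9000)   # spread 2 beats spread 18

  expect_warning(rank_baseline(cluster_events(select_vector_host(
    empty_adj <- derive_adjacencies(mk_block("x", 0, 100, "+", "chr1", 0, 100))))),
    "no events")
})

test_that("vector structures classify deletions, concatemers and full length", {
  full <- dplyr::bind_rows(
    mk_block("r", 0, 3000, "+", "chr5", 7000, 10000, read_len = 9000),
    mk_block("r", 3000, 5928, "+", "AAV", 0, 2928, read_len = 9000),
    mk_block("r", 5928, 9000, "+", "chr5", 10000, 13072, read_len = 9000)
  )
  s <- reconstruct_vector_structure(full, vector_length = 2928)
  expect_equal(s$label, "full_length")
  expect_equal(s$n_segments, 1L)
  expect_equal(s$junction_gaps[[1]], c(0L, 0L))

  deletion <- dplyr::bind_rows(
    mk_block("r", 0, 1200, "+", "AAV", 0, 1200, read_len = 1628),
    mk_block("r", 1200, 1628, "+", "AAV", 2500, 2928, read_len = 1628)
  )
  sd <- reconstruct_vector_structure(deletion, vector_length = 2928)
  expect_equal(sd$alterations[[1]]$type, "deletion")
  expect_equal(sd$alterations[[1]]$size, 1300)

  concat <- dplyr::bind_rows(
    mk_block("r", 0, 2928, "+", "AAV", 0, 2928, read_len = 5856),
    mk_block("r", 2928, 5856, "+", "AAV", 0, 2928, read_len = 5856)
  )
  sc <- reconstruct_vector_structure(concat, vector_length = 2928)
  expect_equal(sc$alterations[[1]]$type, "duplication")
  expect_equal(sc$alterations[[1]]$size, 2928)

  partial <- mk_block("r", 0, 1000, "+", "AAV", 500, 1500, read_len = 1000)
  expect_equal(reconstruct_vector_structure(partial, 2928)$label, "partial")
})

test_that("every event's supporting read has a pair within tolerance", {
  clone <- fx_clone()
  href <- fx_hybrid()
  cfg <- sim_config(seed = 71, long_read = list(mean_len = 4000, sd_len = 800))
  sim <- simulate_long_reads(clone$genome, 60, cfg, regions = clone$cassette)
  res <- run_long_pipeline(sim$reads, href, verbose = FALSE)
  expect_gt(nrow(res$events), 0)
  for (i in seq_len(nrow(res$events))) {
    ev <- res$events[i, ]
    for (rid in ev$read_names[[1]]) {
      p <- res$pairs[res$pairs$read_id == rid &
                       res$pairs$chrom == ev$chrom &
                       res$pairs$side == ev$side, ]
      expect_true(any(abs(p$pos1 - ev$pos1) <= 25))
    }
  }
})
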