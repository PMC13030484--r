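test_that("chimeric candidates are the adjacent host/vector pairs of a read", {
  canonical <- dplyr::bind_rows(
    mk_block("r", 0, 150, "+", "AAV", 2778, 2928),
    mk_block("r", 150, 300, "+", "chr5", 10000, 10150)
  )
  p <- extract_chimeric_candidates(canonical)
  expect_equal(nrow(p), 1)
  expect_true(p$vector_first)
  expect_equal(p$gap, 0L)

  host_only <- dplyr::bind_rows(
    mk_block("r", 0, 150, "+", "chr5", 10000, 10150),
    mk_block("r", 150, 300, "+", "chr5", 10150, 10300)
  )
  expect_equal(nrow(extract_chimeric_candidates(host_only)), 0)

  spanned <- dplyr::bind_rows(
    mk_block("r", 0, 100, "+", "chr5", 9900, 10000),
    mk_block("r", 100, 200, "+", "AAV", 0, 100),
    mk_block("r", 200, 300, "+", "chr5", 10000, 10100)
  )
  p2 <- extract_chimeric_candidates(spanned)
  expect_equal(nrow(p2), 2)
  expect_equal(p2$vector_first, c(FALSE, TRUE))
})

test_that("the matched-base filter is a strict >35 nt threshold on both blocks", {
  mk_pair <- function(hm, vm, hs = 0.95, vs = 0.95) {
    tibble::tibble(read_id = "r", vector_first = TRUE, gap = 0L, collinear = TRUE,
                   host_read_start = 150L, host_read_end = 300L,
                   host_strand = "+", host_ref = "chr5",
                   host_ref_start = 10000, host_ref_end = 10150,
                   host_matches = hm, host_span = 150L, host_score = hs,
                   vector_read_start = 0L, vector_read_end = 150L,
                   vector_block_strand = "+", vector_ref = "AAV",
                   vector_ref_start = 2778, vector_ref_end = 2928,
                   vector_matches = vm, vector_span = 150L, vector_score = vs)
  }
  expect_true(filter_pairs(mk_pair(36, 36))$filter_pass)
  expect_false(filter_pairs(mk_pair(35, 36))$filter_pass)
  expect_equal(filter_pairs(mk_pair(35, 36))$filter_reason, "host_matches")
  expect_false(filter_pairs(mk_pair(36, 35))$filter_pass)
  expect_false(filter_pairs(mk_pair(50, 50, hs = 0.5))$filter_pass)
  expect_equal(filter_pairs(mk_pair(50, 50, hs = 0.5))$filter_reason, "host_score")

  # raising the threshold is monotone: never accepts more pairs
  set.seed(3)
  pairs <- dplyr::bind_rows(lapply(1:50, function(i) {
    mk_pair(sample(20:80, 1), sample(20:80, 1))
  }))
  acc <- vapply(c(20, 35, 50, 65),
                function(th) sum(filter_pairs(pairs, min_match_nt = th)$filter_pass),
                numeric(1))
  expect_true(all(diff(acc) <= 0))
})

test_that("consistency requires proximity on the read; overlaps are tolerated", {
  p <- tibble::tibble(gap = c(0L, 25L, -8L), collinear = TRUE)
  out <- check_consistency(p, window = 20)
  expect_equal(out$consistency_pass, c(TRUE, FALSE, TRUE))
  expect_equal(out$consistency_reason, c(NA, "gap", NA))
  expect_false(check_consistency(tibble::tibble(gap = 0L, collinear = FALSE),
                                 window = 20)$consistency_pass)
})

test_that("junction coordinates follow vector-segment orientation", {
  derive1 <- function(host_strand, vector_first) {
    blocks <- if (vector_first) {
      dplyr::bind_rows(mk_block("r", 0, 150, "+", "AAV", 2778, 2928),
                       mk_block("r", 150, 300, host_strand, "chr5", 10000, 10150))
    } else {
      dplyr::bind_rows(mk_block("r", 0, 150, host_strand, "chr5", 10000, 10150),
                       mk_block("r", 150, 300, "+", "AAV", 0, 150))
    }
    extract_chimeric_candidates(blocks) %>%
      filter_pairs() %>% check_consistency() %>% derive_junctions()
  }
  c1 <- derive1("+", TRUE)
  expect_equal(c1$pos1, 10001)
  expect_equal(c1$side, "right")
  expect_equal(c1$vector_pos1, 2928)

  c2 <- derive1("-", TRUE)
  expect_equal(c2$pos1, 10150)
  expect_equal(c2$side, "left")

  c3 <- derive1("+", FALSE)
  expect_equal(c3$pos1, 10150)
  expect_equal(c3$side, "left")
  expect_equal(c3$vector_pos1, 1)
})

test_that("aggregation counts distinct reads per unique coordinate", {
  calls <- tibble::tibble(
    read_id = c(paste0("a", 1:5), "b1", "b2", "b2"),
    chrom = c(rep("chr5", 5), rep("chr9", 3)),
    pos1 = c(rep(10001, 5), rep(700, 3)),
    side = c(rep("right", 5), rep("left", 3))
  )
  s <- aggregate_junctions(calls)
  expect_equal(nrow(s), 2)
  expect_equal(s$support, c(5L, 2L))      # duplicate read counted once
  expect_equal(s$chrom, c("chr5", "chr9"))

  empty <- aggregate_junctions(calls[0, ])
  expect_equal(nrow(empty), 0)
})

test_that("calling is invariant under reverse-complementing the input reads", {
  clone <- fx_clone()
  href <- fx_hybrid()
  cfg <- sim_config(seed = 61, short_read = list(sub_rate = 0),
                    enrichment = list(on_target_fraction = 1.0))
  sim <- simulate_short_pairs(clone$genome, 300, cfg, regions = clone$cassette)
  fwd <- run_short_pipeline(sim$r1, sim$r2, href, verbose = FALSE)
  rc_r1 <- Biostrings::reverseComplement(sim$r1)
  rc_r2 <- Biostrings::reverseComplement(sim$r2)
  rev <- run_short_pipeline(rc_r1, rc_r2, href, verbose = FALSE)
  expect_equal(as.data.frame(rev$summary), as.data.frame(fwd$summary))
})

test_that("short-read truth recovery is exact on error-free pairs", {
  clone <- fx_clone()
  href <- fx_hybrid()
  cfg <- sim_config(seed = 62, short_read = list(sub_rate = 0),
                    enrichment = list(on_target_fraction = 0.9))
  sim <- simulate_short_pairs(clone$genome, 800, cfg, regions = clone$cassette)
  res <- run_short_pipeline(sim$r1, sim$r2, href, verbose = FALSE)
  top <- res$summary[1, ]
  truth_row <- clone$junctions[clone$junctions$side == top$side, ]
  expect_equal(top$chrom, truth_row$chrom)
  expect_equal(top$pos1, truth_row$pos1)
})
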