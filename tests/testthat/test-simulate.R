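test_that("host genome simulation is reproducible with controlled GC", {
  g1 <- simulate_host_genome(c(100000, 80000), gc = 0.41, seed = 7)
  g2 <- simulate_host_genome(c(100000, 80000), gc = 0.41, seed = 7)
  expect_identical(as.character(g1), as.character(g2))
  expect_equal(names(g1), c("chr1", "chr2"))

  gc_only <- simulate_host_genome(c(500), gc = 1.0, seed = 1)
  expect_true(grepl("^[GC]+$", as.character(gc_only[[1]])))

  g <- simulate_host_genome(c(100000), gc = 0.5, seed = 3)
  f <- Biostrings::letterFrequency(g[[1]], "GC", as.prob = TRUE)
  expect_gt(f, 0.48)
  expect_lt(f, 0.52)
})

test_that("simulated vector has terminal imperfect-palindrome ITRs and features", {
  vec <- simulate_vector(2928, 145, seed = 1)
  expect_equal(nchar(vec$sequence), 2928)
  expect_equal(vec$itr$start0, c(0L, 2783L))
  expect_equal(vec$itr$end0, c(145L, 2928L))
  expect_true(all(itr_palindrome_identity(vec) >= 0.8))
  # features partition the interior between the ITRs
  expect_equal(vec$features$label, c("promoter", "transgene", "wpre"))
  expect_equal(vec$features$start0[1], 145L)
  expect_equal(vec$features$end0[3], 2783L)
  expect_equal(vec$features$start0[-1], vec$features$end0[-3])

  expect_identical(simulate_vector(seed = 5)$sequence,
                   simulate_vector(seed = 5)$sequence)
  v0 <- simulate_vector(1000, 0, seed = 2)
  expect_equal(nrow(v0$itr), 0)
})

test_that("planting preserves sequence accounting for all truth structures", {
  host <- fx_host()
  vec <- fx_vector()
  L <- Biostrings::width(host)[1]

  full <- plant_integration(host, vec, integration_truth("c", "chr1", 15000))
  expect_equal(Biostrings::width(full$genome)[1], L + 2928)
  expect_identical(as.character(full$genome[["chr2"]]),
                   as.character(host[["chr2"]]))

  concat <- plant_integration(host, vec, integration_truth(
    "c", "chr1", 15000,
    segments = tibble::tibble(start0 = c(0L, 0L), end0 = c(2928L, 2928L),
                              orient = c("+", "+"))))
  expect_equal(Biostrings::width(concat$genome)[1], L + 5856)

  partial <- plant_integration(host, vec, integration_truth(
    "c", "chr1", 15000,
    segments = tibble::tibble(start0 = c(0L, 2500L), end0 = c(1200L, 2928L),
                              orient = c("+", "+"))))
  expect_equal(Biostrings::width(partial$genome)[1], L + 1628)

  expect_error(plant_integration(host, vec, integration_truth("c", "chr1", 10^6)),
               "bounds")
})

test_that("clone length conservation holds over random truth structures", {
  host <- fx_host()
  vec <- fx_vector()
  set.seed(11)
  for (i in 1:15) {
    nseg <- sample(1:3, 1)
    s0 <- sort(sample(0:2000, nseg))
    segs <- tibble::tibble(start0 = s0,
                           end0 = s0 + sample(200:900, nseg, TRUE),
                           orient = sample(c("+", "-"), nseg, TRUE))
    del <- sample(0:50, 1)
    ind <- as.integer(sample(-20:20, 2, TRUE))
    tr <- integration_truth("c", "chr1", sample(5000:25000, 1),
                            host_deletion = del, segments = segs,
                            junction_indels = ind)
    clone <- plant_integration(host, vec, tr)
    expect_equal(Biostrings::width(clone$genome)[1],
                 Biostrings::width(host)[1] - del +
                   sum(segs$end0 - segs$start0) + sum(ind))
  }
})

test_that("junction-spanning reads contain the exact planted junction string", {
  clone <- fx_clone()
  cfg <- sim_config(seed = 21,
                    long_read = list(sub_rate = 0, ins_rate = 0, del_rate = 0,
                                     mean_len = 4000, sd_len = 800))
  sim <- simulate_long_reads(clone$genome, 40, cfg, regions = clone$cassette,
                             junctions = clone$junctions)
  k <- 20
  cs <- clone$junctions$clone_cass_start1[1]
  ce <- clone$junctions$clone_cass_end1[1]
  chr1 <- as.character(clone$genome[["chr1"]])
  jstr <- c(substr(chr1, cs - k, cs + k - 1),    # left junction 2k-mer
            substr(chr1, ce - k + 1, ce + k))    # right junction 2k-mer
  spanning <- sim$truth$read_id[sim$truth$spans_junction]
  expect_gt(length(spanning), 0)
  for (rid in spanning) {
    rd <- as.character(sim$reads[[rid]])
    hit <- vapply(c(jstr, revcomp_dna(jstr)), grepl, logical(1), x = rd,
                  fixed = TRUE)
    expect_true(any(hit))
  }
})

test_that("short pairs are inward mates from opposite fragment ends", {
  clone <- fx_clone()
  cfg <- sim_config(seed = 31,
                    short_read = list(fragment_mean = 250, fragment_sd = 0,
                                      read_len = 150, sub_rate = 0))
  sim <- simulate_short_pairs(clone$genome, 30, cfg)
  ch <- as.character(clone$genome)
  for (i in seq_len(5)) {
    tr <- sim$truth[i, ]
    frag <- substr(ch[[tr$chrom]], tr$start1, tr$end1)
    if (tr$strand == "-") frag <- revcomp_dna(frag)
    expect_equal(as.character(sim$r1[[paste0(tr$read_id, "/1")]]),
                 substr(frag, 1, 150))
    expect_equal(as.character(sim$r2[[paste0(tr$read_id, "/2")]]),
                 revcomp_dna(substr(frag, 101, 250)))
  }
  # the mates overlap by 50 nt in the fragment middle
  expect_equal(unique(sim$truth$end1 - sim$truth$start1 + 1), 250)

  # read_len >= fragment: reads truncated to the fragment
  cfg2 <- sim_config(seed = 32,
                     short_read = list(fragment_mean = 100, fragment_sd = 0,
                                       read_len = 150, sub_rate = 0))
  sim2 <- simulate_short_pairs(clone$genome, 5, cfg2)
  expect_true(all(Biostrings::width(sim2$r1) == 100))
})

test_that("identical seeds give byte-identical FASTQ output", {
  clone <- fx_clone()
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  for (f in c(f1, f2)) {
    sim <- simulate_short_pairs(clone$genome, 20, sim_config(seed = 8),
                                regions = clone$cassette)
    write_fastq(sim$r1, f)
  }
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("full enrichment draws only cassette-overlapping fragments", {
  clone <- fx_clone()
  cfg <- sim_config(seed = 41, enrichment = list(on_target_fraction = 1.0))
  sim <- simulate_long_reads(clone$genome, 50, cfg, regions = clone$cassette)
  cs <- clone$cassette
  expect_true(all(sim$truth$chrom == cs$chrom &
                    sim$truth$start1 <= cs$end1 &
                    sim$truth$end1 >= cs$start1))
})

test_that("junction-spanning counts match the coverage oracle", {
  host <- simulate_host_genome(c(100000, 100000), gc = 0.41, seed = 55)
  vec <- fx_vector()
  clone <- plant_integration(host, vec, integration_truth("c", "chr1", 50000))
  L <- 8000
  n <- 500
  cfg <- sim_config(seed = 56,
                    long_read = list(mean_len = L, sd_len = 0,
                                     sub_rate = 0, ins_rate = 0, del_rate = 0),
                    enrichment = list(on_target_fraction = 0))
  sim <- simulate_long_reads(clone$genome, n, cfg)
  a <- 30
  cs <- clone$junctions$clone_cass_start1[1]
  # empirical: fragments covering the left junction with >= a nt on each side
  emp <- sum(sim$truth$chrom == "chr1" &
               sim$truth$start1 <= cs - a & sim$truth$end1 >= cs + a - 1)
  # analytic: chromosome drawn by length, start uniform over valid positions
  lens <- Biostrings::width(clone$genome)
  cl1 <- lens[1]
  p <- (lens[1] / sum(lens)) * (L - 2 * a + 1) / (cl1 - L + 1)
  expect_lt(abs(emp - n * p), 3 * sqrt(n * p * (1 - p)) + 1e-9)
})
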