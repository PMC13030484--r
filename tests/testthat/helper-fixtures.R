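# Shared desk-scale fixtures, built once per test run.  A 2 x 30 kb host
# keeps unit tests fast; acceptance tests build their own full-size inputs.

fx_env <- new.env()

fx_host <- function() {
  if (is.null(fx_env$host)) {
    fx_env$host <- simulate_host_genome(c(30000, 20000), gc = 0.41, seed = 101)
  }
  fx_env$host
}

fx_vector <- function() {
  if (is.null(fx_env$vector)) fx_env$vector <- simulate_vector(seed = 101)
  fx_env$vector
}

fx_clone <- function() {
  if (is.null(fx_env$clone)) {
    fx_env$clone <- plant_integration(
      fx_host(), fx_vector(),
      integration_truth("cloneA", "chr1", 15000))
  }
  fx_env$clone
}

fx_hybrid <- function() {
  if (is.null(fx_env$hybrid)) {
    fx_env$hybrid <- build_hybrid_reference(fx_host(), fx_vector())
  }
  fx_env$hybrid
}

# a block-table row for constructing caller inputs by hand
mk_block <- function(read_id, read_start, read_end, strand, ref_name,
                     ref_start, ref_end, matches = read_end - read_start,
                     read_len = 300, is_vector = grepl("AAV", ref_name)) {
  tibble::tibble(
    read_id = read_id, read_len = read_len,
    read_start = as.integer(read_start), read_end = as.integer(read_end),
    strand = strand, ref_name = ref_name,
    ref_start = ref_start, ref_end = ref_end,
    matches = as.integer(matches),
    aligned_span = as.integer(read_end - read_start),
    score = as.integer(matches), match_score = matches / (read_end - read_start),
    source = "internal", is_vector = is_vector
  )
}
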