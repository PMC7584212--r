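# Shared reduced-scale sweep, computed once per test session and reused by
# every test that needs landscape-level replication: 10 replicates x 5
# habitat proportions x 10 detection levels, occupancy records kept at
# p = 0.5 (abundance GLM) and p = 1 (occupancy distributions).

.ct_cache <- new.env(parent = emptyenv())

ct_shared_sweep <- function() {
  if (is.null(.ct_cache$sweep)) {
    .ct_cache$sweep <- run_sweep(reps = 10L, root_seed = 101L,
                                 occupancy_at = c(0.5, 1))
  }
  .ct_cache$sweep
}

# replicate one-step comparisons between the vectorized engine and the
# per-individual reference on the tiny fixture; cached because both the
# engine tests and the property battery use them
ct_oracle_totals <- function(n_rep = 1000L) {
  if (is.null(.ct_cache$oracle)) {
    fx <- make_fixture("tiny", seed = 12)
    cfg <- fx$config
    set.seed(12)
    st0 <- initialize_communities(fx$grid, fx$gsad, cfg$K)
    set.seed(1001)
    eng <- t(replicate(n_rep, colSums(
      step_community(st0, fx$grid, fx$pool, fx$gsad, cfg))))
    set.seed(2002)
    ref <- t(replicate(n_rep, colSums(
      ref_step(st0, fx$grid, fx$pool, fx$gsad, cfg))))
    .ct_cache$oracle <- list(engine = eng, reference = ref)
  }
  .ct_cache$oracle
}

# ten further replicates at h_A = 0.9, pooled with the sweep's ten for
# occupancy-distribution checks that want ~20 replicates
ct_extra_homogeneous_occ <- function() {
  if (is.null(.ct_cache$extra_occ)) {
    .ct_cache$extra_occ <- purrr::map_dfr(seq_len(10L), function(i) {
      rec <- run_simulation(sim_config(h_A = 0.9, seed = 7100L + i))
      dplyr::mutate(occupancy_from_record(rec, p = 1),
                    run_id = 1000L + i, p = 1, .before = 1)
    })
  }
  .ct_cache$extra_occ
}
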