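# Dispersal kernel and the demographic engine.

test_that("half-normal kernel moments follow from the 99th percentile", {
  z995 <- qnorm(0.995)
  for (q in c(2, 4, 8)) {
    k <- kernel_from_q99(q)
    expect_equal(k$sigma, q / z995, tolerance = 1e-12)
    expect_equal(k$mean, k$sigma * sqrt(2 / pi), tolerance = 1e-12)
    # q99 recoverable from sigma
    expect_equal(k$sigma * z995, q, tolerance = 1e-9)
  }
  expect_equal(kernel_from_q99(2)$mean, 0.620, tolerance = 1e-3)
  expect_equal(kernel_from_q99(8)$mean, 2.478, tolerance = 1e-3)
  expect_error(kernel_from_q99(0), "positive")
  expect_error(kernel_from_q99(-1), "positive")
})

test_that("sampled dispersal distances match the kernel's closed forms", {
  set.seed(51)
  k <- kernel_from_q99(4)
  r <- abs(rnorm(1e5, 0, k$sigma))
  se_mean <- k$sigma * sqrt(1 - 2 / pi) / sqrt(1e5)
  expect_lt(abs(mean(r) - k$mean), 3 * se_mean)
  expect_equal(unname(quantile(r, 0.99)), 4, tolerance = 0.05)
})

test_that("initialization fills every cell to exactly K from the GSAD", {
  fx <- make_fixture("tiny")
  st <- initialize_communities(fx$grid, fx$gsad, K = 5)
  expect_true(all(rowSums(st) == 5))
  expect_equal(sum(st), 16 * 5)

  # species frequencies across a larger landscape match the weights
  set.seed(52)
  g <- generate_landscape(16, 16, h_A = 0.5)
  w <- draw_gsad(10)
  st <- initialize_communities(g, w, K = 100)
  n <- sum(st)
  freq <- colSums(st) / n
  se <- sqrt(as.numeric(w) * (1 - as.numeric(w)) / n)
  expect_true(all(abs(freq - as.numeric(w)) < 3.5 * se))

  deg <- structure(c(1, rep(0, 9)), class = "gsad")
  mono <- initialize_communities(g, deg, K = 10)
  expect_true(all(mono[, 1] == 10) && all(mono[, -1] == 0))
})

test_that("mortality is independent binomial thinning", {
  fx <- make_fixture("tiny")
  st <- initialize_communities(fx$grid, fx$gsad, K = 5)
  expect_identical(unclass(apply_mortality(st, 0)), unclass(st))
  expect_true(all(apply_mortality(st, 1) == 0))

  set.seed(53)
  big <- structure(matrix(100L, 1e4, 1), grid_dim = c(100L, 100L),
                   class = "community_state")
  surv <- apply_mortality(big, 0.5)
  se <- sqrt(100 * 0.25 / 1e4)
  expect_lt(abs(mean(surv) - 50), 3 * se)
})

test_that("only matched adults reproduce, at their natal cell", {
  pool <- build_species_pool(4)           # species 1-2 prefer A, 3-4 prefer B
  fx <- make_fixture("homogeneous")        # all habitat A
  st <- structure(matrix(0L, 64, 4), grid_dim = c(8L, 8L),
                  class = "community_state")
  st[10, 1] <- 3L   # 3 A-specialists in an A cell
  st[10, 3] <- 5L   # 5 B-specialists in the same A cell
  prop <- produce_propagules(st, pool, fx$grid, f = 2)
  expect_equal(prop[10, ], c(6, 0, 0, 0))
  expect_equal(sum(prop), 6)
  empty <- structure(matrix(0L, 64, 4), grid_dim = c(8L, 8L),
                     class = "community_state")
  expect_equal(sum(produce_propagules(empty, pool, fx$grid, 2)), 0)
})

test_that("exactly the mismatched adults enter the dispersal pool", {
  pool <- build_species_pool(4)
  fx <- make_fixture("homogeneous")
  st <- structure(matrix(0L, 64, 4), grid_dim = c(8L, 8L),
                  class = "community_state")
  st[20, 1] <- 60L  # matched
  st[20, 4] <- 5L   # mismatched
  out <- collect_adult_dispersers(st, pool, fx$grid)
  expect_equal(out$state[20, ], c(60, 0, 0, 0))
  expect_equal(out$dispersers[20, ], c(0, 0, 0, 5))
  expect_equal(sum(out$dispersers), 5)

  # all-A landscape with only A-specialists: nobody moves
  st[, ] <- 0L; st[, 1] <- 2L
  out <- collect_adult_dispersers(st, pool, fx$grid)
  expect_equal(sum(out$dispersers), 0)
})

test_that("a vanishing kernel keeps every propagule in its natal cell", {
  set.seed(54)
  fx <- make_fixture("homogeneous")
  pool <- matrix(0L, 64, 4)
  pool[c(1, 30, 64), 2] <- 7L
  arr <- disperse(pool, kernel_from_q99(1e-9), fx$grid)
  expect_identical(arr, pool + 0L)
})

test_that("dispersal conserves propagules up to boundary losses", {
  set.seed(55)
  fx <- make_fixture("homogeneous")
  pool <- matrix(5L, 64, 4)
  arr <- disperse(pool, kernel_from_q99(4), fx$grid)
  expect_lte(sum(arr), sum(pool))
  expect_gt(sum(arr), 0)
})

test_that("establishment fills empty slots from arrivals and immigrants", {
  fx <- make_fixture("homogeneous")
  w <- fx$gsad
  empty_arr <- matrix(0L, 64, 4)

  st <- structure(matrix(3L, 64, 4), grid_dim = c(8L, 8L),
                  class = "community_state")  # occupancy 12 of K = 20
  expect_identical(unclass(establish(st, empty_arr, w, m = 0, K = 20)),
                   unclass(st))

  set.seed(56)
  full_imm <- establish(st, empty_arr, w, m = 1, K = 20)
  expect_true(all(rowSums(full_imm) == 20))

  # 40 empty slots, 10 arrivals, m = 0: exactly the 10 arrivals establish
  st1 <- structure(matrix(0L, 64, 4), grid_dim = c(8L, 8L),
                   class = "community_state")
  st1[5, ] <- c(20L, 20L, 10L, 10L)  # occupancy 60 of K = 100
  arr <- empty_arr; arr[5, ] <- c(4L, 3L, 2L, 1L)
  out <- establish(st1, arr, w, m = 0, K = 100)
  expect_equal(out[5, ] - st1[5, ], c(4, 3, 2, 1))
  expect_equal(sum(out) - sum(st1), 10)

  # without-replacement draw when arrivals exceed slots
  st2 <- structure(matrix(0L, 64, 4), grid_dim = c(8L, 8L),
                   class = "community_state")
  st2[7, 1] <- 95L
  arr2 <- empty_arr; arr2[7, ] <- c(10L, 10L, 0L, 0L)
  out2 <- establish(st2, arr2, w, m = 0, K = 100)
  expect_equal(sum(out2[7, ]) , 100)
  expect_lte(max(out2[7, 2]), 10)

  st_over <- structure(matrix(30L, 64, 4), grid_dim = c(8L, 8L),
                       class = "community_state")
  expect_error(establish(st_over, empty_arr, w, m = 0, K = 100),
               "consistency")
})

test_that("a full matched community with no mortality is a fixed point", {
  fx <- make_fixture("homogeneous")
  pool <- build_species_pool(4)
  cfg <- sim_config(width = 8, height = 8, n_species = 4, K = 10,
                    d = 0, m = 0, q99 = 2, n_steps = 1, W = 1)
  st <- structure(matrix(0L, 64, 4), grid_dim = c(8L, 8L),
                  class = "community_state")
  st[, 1] <- 10L   # species 1 prefers A; every cell full
  set.seed(57)
  expect_equal(unclass(step_community(st, fx$grid, pool, fx$gsad, cfg)),
               unclass(st), ignore_attr = TRUE)
})

test_that("total mortality without immigration empties the landscape", {
  # death precedes birth, so nobody reproduces and nothing establishes
  fx <- make_fixture("homogeneous")
  pool <- build_species_pool(4)
  cfg <- sim_config(width = 8, height = 8, n_species = 4, K = 10,
                    d = 1, m = 0, q99 = 2, n_steps = 1, W = 1)
  st <- initialize_communities(fx$grid, fx$gsad, K = 10)
  set.seed(58)
  expect_true(all(step_community(st, fx$grid, pool, fx$gsad, cfg) == 0))
})

test_that("capacity is conserved after every step", {
  fx <- make_fixture("tiny")
  set.seed(59)
  st <- initialize_communities(fx$grid, fx$gsad, K = fx$config$K)
  pool <- fx$pool
  for (i in 1:30) {
    st <- step_community(st, fx$grid, pool, fx$gsad, fx$config)
    expect_true(all(rowSums(st) <= fx$config$K))
    expect_true(all(st >= 0))
  }
})

test_that("runs are reproducible from the seed and respect the window", {
  cfg <- sim_config(width = 8, height = 8, n_species = 4, K = 10,
                    n_steps = 5, W = 5, q99 = 2, seed = 60)
  rec1 <- run_simulation(cfg)
  rec2 <- run_simulation(cfg)
  expect_identical(rec1$focal_abundance, rec2$focal_abundance)
  expect_identical(rec1$landscape_abundance, rec2$landscape_abundance)
  # T = W: every step recorded
  expect_equal(nrow(rec1$focal_abundance), 5)
  expect_true(all(rowSums(rec1$focal_abundance) <= 10))
  expect_true(all(rec1$focal_abundance >= 0))

  td <- tidy(rec1)
  expect_named(td, c("year", "species_id", "true_abundance"))
  expect_equal(nrow(td), 5 * 4)
})

test_that("record serialization writes the three plain-text artifacts", {
  cfg <- sim_config(width = 8, height = 8, n_species = 4, K = 10,
                    n_steps = 5, W = 5, q99 = 2, seed = 61)
  rec <- run_simulation(cfg)
  dir <- withr::local_tempdir()
  write_simulation_record(rec, dir)
  expect_setequal(list.files(dir), c("focal_occupancy.csv",
                                     "landscape_abundance.csv",
                                     "run_metadata.json"))
  meta <- jsonlite::read_json(file.path(dir, "run_metadata.json"))
  expect_equal(meta$config$K, 10)
  expect_equal(meta$similarity, rec$similarity)
})

test_that("heterogeneous landscapes host more true transients at the focus
           than homogeneous ones", {
  sw <- ct_shared_sweep()
  per_run <- dplyr::summarise(
    dplyr::filter(sw, p == 1, h_A %in% c(0.5, 0.9)),
    n_tr = mean(n_obs_transient), .by = c("run_id", "h_A"))
  m <- tapply(per_run$n_tr, per_run$h_A, mean)
  expect_gt(m[["0.5"]], m[["0.9"]])
})

test_that("focal richness is at equilibrium over the recorded window", {
  # no temporal trend in focal richness across steps 151-200 of 200:
  # the replicate-mean slope's confidence interval covers zero
  recs <- purrr::map_dfr(1:10, function(i) {
    rec <- run_simulation(sim_config(h_A = 0.7, W = 50, seed = 8200 + i))
    rich <- rowSums(rec$focal_abundance > 0)
    tibble::tibble(rep = i,
                   slope = coef(lm(rich ~ seq_along(rich)))[2])
  })
  ci <- t.test(recs$slope)$conf.int
  expect_true(ci[1] < 0 && ci[2] > 0)
})
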