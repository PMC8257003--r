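test_that("population initialization assigns priors by role", {
  g <- net_scale_free(150, 4, seed = 1)
  cfg <- sim_config(size_net = 150, prop_biased = 0.10, mu0 = 0.1,
                    lambda0 = 0.6, seed = 1)
  roles <- assign_bias_roles(g, 0.10, seed = 2)
  pop <- initialize_population(cfg, roles)
  expect_equal(sum(pop$biased), 15)
  unb <- prior_from_bias(bias_profile(0.5, 0.9))
  b <- prior_from_bias(bias_profile(0.1, 0.6))
  expect_true(all(pop$alpha[!pop$biased] == unb["alpha"]))
  expect_true(all(pop$alpha[pop$biased] == b["alpha"]))
  expect_false(any(pop$fixed))
  # all-unbiased and all-fixed limits
  pop0 <- initialize_population(sim_config(size_net = 150, prop_biased = 0,
                                           seed = 1),
                                assign_bias_roles(g, 0, seed = 2))
  expect_true(all(pop0$alpha == unb["alpha"]) && !any(pop0$biased))
  popf <- initialize_population(sim_config(size_net = 150, prop_biased = 1,
                                           mu0 = 0.1, lambda0 = 0, seed = 1),
                                assign_bias_roles(g, 1, seed = 2))
  expect_true(all(popf$fixed) && all(popf$fixed_value == 0.1))
})

test_that("initial-language exposure updates every non-fixed agent once", {
  g <- net_scale_free(20, 4, seed = 3)
  cfg <- sim_config(size_net = 20, prop_biased = 0.5, mu0 = 0.1, lambda0 = 0,
                    seed = 1)
  pop <- initialize_population(cfg, assign_bias_roles(g, 0.5, seed = 4))
  before <- pop
  # empty batch: nothing changes
  expect_identical(expose_initial_language(pop, 0, 0), pop)
  after <- expose_initial_language(pop, 4, 4)
  live <- !pop$fixed
  expect_equal(after$alpha[live], before$alpha[live] + 4)
  expect_equal(after$beta[live], before$beta[live])
  expect_equal(after$alpha[!live], before$alpha[!live])
  expect_error(expose_initial_language(pop, 5, 4), "k0 <= n0")
})

test_that("asynchronous pseudo-count totals grow by exactly degree per iteration", {
  set.seed(100)
  for (i in 1:10) {
    net_type <- sample(c("random", "small-world", "scale-free"), 1)
    n <- sample(c(30, 60, 100), 1)
    t_iter <- sample(c(1, 5, 20), 1)
    cfg <- sim_config(size_net = n, network = net_type,
                      learners = sample(c("SAM", "MAP"), 1),
                      mu0 = 0.1, lambda0 = sample(c(0, 0.1, 0.6), 1),
                      prop_biased = runif(1, 0, 0.5),
                      init_k0 = 4, init_n0 = 4, n_iterations = t_iter,
                      seed = sample.int(1e6, 1))
    run <- run_simulation(cfg)
    deg <- igraph::degree(run$network)
    fs <- run$final_states
    live <- !fs$fixed
    pop <- initialize_population(cfg, run$roles)
    start <- pop$alpha + pop$beta
    expect_equal(fs$alpha[live] + fs$beta[live],
                 start[live] + 4 + t_iter * deg[live])
  }
})

test_that("isolated agents neither change nor influence anyone", {
  # 3 agents: edge 1-2, agent 3 isolated
  path <- tempfile(fileext = ".edges")
  writeLines("1 2", path)
  g <- net_read_edgelist(path, n = 3)
  cfg <- sim_config(size_net = 3, prop_biased = 0, n_iterations = 10, seed = 5)
  run <- run_simulation(cfg, network = g)
  unb <- prior_from_bias(bias_profile(0.5, 0.9))
  expect_equal(run$final_states$alpha[3] + run$final_states$beta[3],
               unname(sum(unb)) + 4)
  expect_equal(run$final_states$alpha[1] + run$final_states$beta[1],
               unname(sum(unb)) + 4 + 10)
})

test_that("connected fixed agents stay constant and produce a flat series", {
  path <- tempfile(fileext = ".edges")
  writeLines("1 2", path)
  g <- net_read_edgelist(path, n = 2)
  cfg <- sim_config(size_net = 2, prop_biased = 1, mu0 = 0.1, lambda0 = 0,
                    n_iterations = 50, seed = 6)
  run <- run_simulation(cfg, network = g)
  expect_true(all(run$series[, "all"] == 0.1))
  expect_true(all(run$final_states$language_value == 0.1))
})

test_that("runs are byte-for-byte deterministic in their master seed", {
  cfg <- sim_config(size_net = 60, prop_biased = 0.2, lambda0 = 0.3,
                    n_iterations = 60, seed = 77)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$final_states, r2$final_states)
  expect_identical(r1$partition$membership, r2$partition$membership)
  r3 <- run_simulation(sim_config(size_net = 60, prop_biased = 0.2,
                                  lambda0 = 0.3, n_iterations = 60,
                                  seed = 78))
  expect_false(identical(r1$series, r3$series))
})

test_that("language values stay in [0, 1] and the zero-iteration run is exposure only", {
  cfg <- sim_config(size_net = 50, prop_biased = 0.3, lambda0 = 0.1,
                    n_iterations = 120, seed = 8)
  run <- run_simulation(cfg)
  expect_true(all(run$series >= 0 & run$series <= 1))
  expect_true(all(run$final_states$language_value >= 0 &
                    run$final_states$language_value <= 1))
  expect_equal(nrow(run$series), 121)
  r0 <- run_simulation(sim_config(size_net = 50, n_iterations = 0, seed = 8))
  expect_equal(nrow(r0$series), 1)
})

test_that("an unbiased society with an initial convention converges high", {
  vals <- sapply(1:50, function(s)
    run_simulation(sim_config(size_net = 150, prop_biased = 0,
                              n_iterations = 500,
                              seed = derive_seed(2024, paste("unb", s))))
    $metrics$langval_all)
  expect_gt(mean(vals), 0.8)
})

test_that("synchronous and asynchronous updating give very similar outcomes", {
  finals <- sapply(1:30, function(s) {
    a <- run_simulation(sim_config(size_net = 150, lambda0 = 0.1,
                                   prop_biased = 0.1, n_iterations = 500,
                                   seed = s))$metrics$langval_all
    b <- run_simulation(sim_config(size_net = 150, lambda0 = 0.1,
                                   prop_biased = 0.1, n_iterations = 500,
                                   update_mode = "synchronous",
                                   seed = s))$metrics$langval_all
    c(a, b)
  })
  expect_lt(abs(mean(finals[1, ]) - mean(finals[2, ])), 0.05)
})

test_that("group means decompose exactly by biased fraction", {
  run <- run_simulation(sim_config(size_net = 100, prop_biased = 0.23,
                                   lambda0 = 0.3, n_iterations = 50,
                                   seed = 13))
  m <- run$metrics
  ups <- mean(run$final_states$role == "biased")
  expect_equal(m$langval_all,
               ups * m$langval_biased + (1 - ups) * m$langval_control)
})

test_that("run export writes series, agent table and manifest", {
  run <- run_simulation(sim_config(size_net = 30, n_iterations = 20, seed = 3))
  dir <- tempfile()
  paths <- write_run(run, dir)
  expect_true(all(file.exists(paths)))
  series <- read.csv(paths[1])
  expect_equal(nrow(series), 21)
  expect_equal(series$all, unname(run$series[, "all"]))
  agents <- read.csv(paths[2])
  expect_equal(nrow(agents), 30)
  man <- yaml::read_yaml(paths[3])
  expect_equal(man$seed, 3)
})
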