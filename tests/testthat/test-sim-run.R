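test_that("trajectories are deterministic given a seed, for both engines", {
  cfg <- tiny_config(l = 2, m = 3, n_groups = 8, generations = 12,
                     init_s = 0.3)
  for (engine in c("cpp", "r")) {
    a <- run_replicate(cfg, seed = 101, engine = engine)
    b <- run_replicate(cfg, seed = 101, engine = engine)
    expect_identical(a, b)
    c <- run_replicate(cfg, seed = 102, engine = engine)
    expect_false(identical(a$mean_P, c$mean_P))
  }
})

test_that("a zero-generation run reports only the initial state", {
  cfg <- tiny_config(generations = 0, init_q = 0.37, init_s = 0.2)
  for (engine in c("cpp", "r")) {
    tr <- run_replicate(cfg, seed = 1, engine = engine)
    expect_equal(nrow(tr), 1)
    expect_equal(tr$mean_q, 0.37)
    expect_equal(tr$mean_s, 0.2)
    expect_true(is.na(tr$mean_P))
  }
})

test_that("trajectories stay in [0,1] and respect the locked-s control", {
  cfg <- tiny_config(l = 1, m = 10, n_groups = 20, generations = 60,
                     s_locked_at_zero = TRUE, init_s = 0.9)
  tr <- run_replicate(cfg, seed = 4)
  expect_true(all(tr$mean_s == 0))
  expect_true(all(tr$mean_q >= 0 & tr$mean_q <= 1))
  expect_true(all(tr$mean_P >= 0 & tr$mean_P <= 1))
  expect_equal(nrow(tr), 60)
  cfg_free <- tiny_config(l = 1, m = 10, n_groups = 20, generations = 60,
                          init_s = 0.5)
  tr_free <- run_replicate(cfg_free, seed = 4)
  expect_true(all(tr_free$mean_s >= 0 & tr_free$mean_s <= 1))
})

test_that("a monomorphic uncoordinated population realizes the analytical fitness", {
  # direct bridge between the simulator's one-generation steps and the
  # random-specializer expectation: mean cell fecundity = w_FR(q, q)
  q <- 0.35
  cfg <- tiny_config(l = 2, m = 5, epsilon = 0.8, n_groups = 3000,
                     init_q = q, init_s = 0)
  withr::with_seed(13, {
    cells <- grow_groups(init_founders(cfg), cfg)
    cells <- resolve_phenotypes(
      cells, tibble::tibble(group = integer(), receiver = integer(),
                            sender = integer()), cfg)
    cells <- group_fecundities(cells, cfg)
  })
  expected <- fitness_random(q, q, cfg$params)
  se <- stats::sd(tapply(cells$fecundity, cells$group, mean)) / sqrt(3000)
  expect_lt(abs(mean(cells$fecundity) - expected), 4 * se + 1e-4)
})

test_that("both engines agree on where evolution settles (statistically)", {
  base <- list(l = 1, m = 8, n_groups = 25, generations = 400,
               s_locked_at_zero = TRUE)
  cfg <- do.call(tiny_config, base)
  mean_cpp <- mean(run_replicate(cfg, 31, engine = "cpp")$mean_q[201:400])
  mean_r <- mean(run_replicate(cfg, 32, engine = "r")$mean_q[201:400])
  target <- ess_random_closed(cfg$params)$q_star
  expect_lt(abs(mean_cpp - target), 0.12)
  expect_lt(abs(mean_r - target), 0.12)
})

test_that("experiments summarize replicates over the trailing window", {
  cfg <- tiny_config(l = 1, m = 5, n_groups = 10, generations = 30,
                     replicates = 3, record_fraction = 0.2)
  ex <- run_experiment(cfg, seed = 7, keep_trajectories = TRUE)
  expect_equal(nrow(ex$replicates), 3)
  for (i in 1:3) {
    expect_equal(
      ex$replicates[i, c("mean_q", "mean_s", "mean_P")],
      window_summary(ex$trajectories[[i]], 0.2),
      ignore_attr = TRUE
    )
  }
  # replicate seeds are a deterministic stream: the first replicates of a
  # larger experiment reproduce the smaller experiment exactly
  cfg1 <- tiny_config(l = 1, m = 5, n_groups = 10, generations = 30,
                      replicates = 1, record_fraction = 0.2)
  ex1 <- run_experiment(cfg1, seed = 7)
  expect_equal(ex1$replicates[1, ], ex$replicates[1, ])
  expect_equal(ex1$summary$mean,
               unlist(ex1$replicates[1, c("mean_P", "mean_q", "mean_s")]),
               ignore_attr = TRUE)
  # tidiers
  expect_identical(generics::tidy(ex), ex$replicates)
  gl <- generics::glance(ex)
  expect_equal(nrow(gl), 1)
  expect_true(all(c("mean_mean_q", "se_mean_P", "n_replicates") %in% names(gl)))
})

test_that("variance comparison reports ratios and flags degeneracy", {
  mk_traj <- function(s_level, p_level) {
    tibble::tibble(generation = 1:10, mean_q = 0.5,
                   mean_s = s_level, mean_P = p_level)
  }
  x <- c(0.1, 0.2, 0.3, 0.4, 0.5, 0.6)
  trajs <- purrr::map2(2 * x, x, mk_traj)  # var(s) = 4 var(P) exactly
  rep_var <- variability_test(trajs, window = 1)
  expect_equal(rep_var$ratio, 4)
  expect_equal(rep_var$p_value,
               stats::pf(4, 5, 5, lower.tail = FALSE))
  expect_false(rep_var$degenerate)
  same <- purrr::map(1:4, ~ mk_traj(0.3, 0.4))
  expect_true(variability_test(same)$degenerate)
  expect_error(variability_test(trajs[1]), "at least two")
})

test_that("trajectory plots build", {
  cfg <- tiny_config(l = 1, m = 5, n_groups = 5, generations = 10)
  expect_s3_class(ggplot2::autoplot(run_replicate(cfg, 1)), "ggplot")
})
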