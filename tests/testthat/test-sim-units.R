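test_that("coordination cost shapes share endpoints and differ in curvature", {
  shapes <- c("decelerating", "linear", "accelerating")
  for (sh in shapes) {
    expect_equal(coordination_cost(0, 0.025, sh), 0)
    expect_equal(coordination_cost(1, 0.025, sh), 0.025 * (1 - exp(-5)))
  }
  expect_equal(coordination_cost(1, 0.025), 0.0248316, tolerance = 1e-5)
  s <- seq(0, 1, by = 0.01)
  expect_true(all(diff(diff(coordination_cost(s, 0.025))) < 0))          # concave
  expect_true(all(diff(diff(coordination_cost(s, 0.025, "accelerating"))) > 0))
  expect_error(coordination_cost(0.5, -0.1), "nonnegative")
})

test_that("groups grow as l lineages of m clone-mates with relatedness 1/l", {
  cfg <- tiny_config(l = 2, m = 3, n_groups = 4)
  cells <- grow_groups(init_founders(cfg), cfg)
  expect_equal(nrow(cells), 4 * 6)
  per <- dplyr::count(cells, group, lineage)
  expect_true(all(per$n == 3))
  # clonal when l = 1
  cfg1 <- tiny_config(l = 1, m = 5, n_groups = 3)
  f1 <- init_founders(cfg1)
  f1$q <- c(0.2, 0.5, 0.9)
  cells1 <- grow_groups(f1, cfg1)
  expect_true(all(tapply(cells1$q, cells1$group, dplyr::n_distinct) == 1))
  # whole-group relatedness (pair drawn with replacement shares a founder)
  shares <- cells |>
    dplyr::group_by(group) |>
    dplyr::summarise(r = sum((table(lineage) / dplyr::n())^2))
  expect_true(all(abs(shares$r - 1 / cfg$params$l) < 1e-12))
  expect_error(grow_groups(init_founders(cfg)[-1, ], cfg), "Expected")
})

test_that("coordination links are receiver-driven Bernoulli draws", {
  cfg <- tiny_config(l = 1, m = 20, n_groups = 250)
  f <- init_founders(cfg)
  f$s <- 0
  cells <- grow_groups(f, cfg)
  expect_equal(nrow(build_links(cells, cfg)), 0)
  f$s <- 1
  links_full <- build_links(grow_groups(f, cfg), cfg)
  indeg <- dplyr::count(links_full, group, receiver)
  expect_true(all(indeg$n == 19))
  expect_equal(nrow(indeg), 250 * 20)
  # s = 0.5: in-degree ~ Binomial(19, 0.5), check the mean within 3 SE
  withr::with_seed(11, {
    f$s <- 0.5
    links_half <- build_links(grow_groups(f, cfg), cfg)
  })
  n_draws <- 250 * 20
  se <- sqrt(19 * 0.25 / n_draws)
  expect_lt(abs(nrow(links_half) / n_draws - 9.5), 3 * se)
  # own-lineage scope never crosses lineages
  cfg2 <- tiny_config(l = 2, m = 4, n_groups = 30,
                      coordination_scope = "own_lineage")
  f2 <- init_founders(cfg2); f2$s <- 1
  cells2 <- grow_groups(f2, cfg2)
  links2 <- build_links(cells2, cfg2)
  lin <- cells2$lineage[order(cells2$group, cells2$cell)]
  key <- function(g, c) (g - 1) * 8 + c
  expect_true(all(lin[key(links2$group, links2$receiver)] ==
                    lin[key(links2$group, links2$sender)]))
  indeg2 <- dplyr::count(links2, group, receiver)
  expect_true(all(indeg2$n == 3))
})

test_that("the switching rule compares observed helper fraction with the target", {
  # target 0.4: half the observed neighbors helping -> reproductive,
  # a quarter helping -> helper; exact tie -> reproductive
  expect_false(helper_decision(0.5, 0.4))
  expect_true(helper_decision(0.25, 0.4))
  expect_false(helper_decision(0.4, 0.4))
  expect_false(helper_decision(0, 0))
})

test_that("phenotype resolution has the random and coordinated limits", {
  # q = 0 with no links: nobody helps
  cfg <- tiny_config(l = 1, m = 8, n_groups = 20, init_q = 0)
  cells <- grow_groups(init_founders(cfg), cfg)
  none <- resolve_phenotypes(cells, build_links(cells, cfg), cfg)
  expect_false(any(none$helper))
  # full coordination in clonal groups realizes the target within 1/n
  cfg1 <- tiny_config(l = 1, m = 10, n_groups = 40, init_s = 1)
  for (seed in 1:3) {
    withr::with_seed(seed, {
      for (q in c(0, 0.3, 0.45, 0.7, 1)) {
        f <- init_founders(cfg1); f$q <- q
        cells <- grow_groups(f, cfg1)
        res <- resolve_phenotypes(cells, build_links(cells, cfg1), cfg1)
        P <- tapply(res$helper, res$group, mean)
        expect_true(all(abs(P - q) <= 1 / 10 + 1e-12))
      }
    })
  }
  # coordination tightens the spread of P around the target vs pure noise
  withr::with_seed(21, {
    cfgr <- tiny_config(l = 1, m = 10, n_groups = 300, init_q = 0.4, init_s = 0)
    cr <- grow_groups(init_founders(cfgr), cfgr)
    dev_random <- abs(tapply(
      resolve_phenotypes(cr, build_links(cr, cfgr), cfgr)$helper,
      cr$group, mean) - 0.4)
    cfgc <- tiny_config(l = 1, m = 10, n_groups = 300, init_q = 0.4, init_s = 1)
    cc <- grow_groups(init_founders(cfgc), cfgc)
    dev_coord <- abs(tapply(
      resolve_phenotypes(cc, build_links(cc, cfgc), cfgc)$helper,
      cc$group, mean) - 0.4)
    expect_lt(mean(dev_coord), mean(dev_random))
  })
})

test_that("fecundities follow cost, phenotype and group benefit", {
  cfg <- tiny_config(l = 1, m = 5, n_groups = 1, epsilon = 1)
  cells <- grow_groups(init_founders(cfg), cfg)
  cells$helper <- c(TRUE, TRUE, FALSE, FALSE, FALSE)   # P = 0.4
  cells$s <- 0
  out <- group_fecundities(cells, cfg)
  expect_equal(out$P, rep(0.4, 5))
  expect_equal(out$fecundity[1:2], c(0, 0))
  expect_equal(out$fecundity[3:5], rep(0.4, 3))
  # a coordinating reproductive pays the machinery cost
  cfg0 <- tiny_config(l = 1, m = 5, n_groups = 1, epsilon = 0)
  cells$s <- 1
  out0 <- group_fecundities(cells, cfg0)
  expect_equal(out0$fecundity[3], 1 - 0.025 * (1 - exp(-5)))
})

test_that("mutation perturbs traits at the configured rate and stays in [0,1]", {
  cfg <- tiny_config(l = 1, m = 2, n_groups = 50000, generations = 1)
  f <- init_founders(cfg)  # q = 0.5
  withr::with_seed(5, mutated <- mutate_genotypes(f, cfg))
  changed <- mutated$q != 0.5
  expect_equal(mean(changed), 0.01, tolerance = 0.15)
  # step distribution, measured on a bigger mutated sample
  cfg_hi <- tiny_config(l = 2, m = 2, n_groups = 50000, p_mut = 0.2)
  withr::with_seed(15, mut_hi <- mutate_genotypes(init_founders(cfg_hi), cfg_hi))
  steps <- (mut_hi$q - 0.5)[mut_hi$q != 0.5]
  expect_equal(sd(steps), 0.1, tolerance = 0.02)
  expect_equal(mean(steps), 0, tolerance = 0.005)
  # no mutation, identical table
  cfg0 <- tiny_config(n_groups = 20, p_mut = 0)
  f0 <- init_founders(cfg0)
  expect_identical(mutate_genotypes(f0, cfg0), f0)
  # clamping at the boundary
  cfgb <- tiny_config(l = 1, m = 2, n_groups = 5000, init_q = 0, p_mut = 1)
  withr::with_seed(6, mb <- mutate_genotypes(init_founders(cfgb), cfgb))
  expect_true(all(mb$q >= 0 & mb$q <= 1))
  expect_true(any(mb$q == 0))  # negative deviations clamp to exactly 0
})

test_that("global competition samples founders by fecundity", {
  cfg <- tiny_config(l = 1, m = 3, n_groups = 4, p_mut = 0)
  cells <- grow_groups(init_founders(cfg), cfg)
  cells$q <- 0.7; cells$s <- 0.2
  cells$fecundity <- 0
  cells$fecundity[5] <- 1
  cells$q[5] <- 0.9
  withr::with_seed(3, nxt <- next_generation(cells, cfg))
  expect_equal(nrow(nxt), 4)
  expect_true(all(nxt$q == 0.9))
  # all-helper populations cannot reproduce
  cells$fecundity <- 0
  expect_error(next_generation(cells, cfg), "zero")
  # uniform fecundities: founder counts look multinomial-uniform
  cfg2 <- tiny_config(l = 1, m = 1, n_groups = 6, p_mut = 0)
  cells2 <- grow_groups(init_founders(cfg2), cfg2)
  cells2$q <- seq(0.1, 0.6, by = 0.1)  # label cells by q
  cells2$fecundity <- 1
  withr::with_seed(9, {
    draws <- purrr::map(1:150, ~ next_generation(cells2, cfg2)$q)
  })
  counts <- table(unlist(draws))
  chi <- stats::chisq.test(counts)
  expect_gt(chi$p.value, 1e-4)
})
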