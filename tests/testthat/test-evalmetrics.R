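t_abcd1 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
t_abcd2 <- parse_newick("((A:1,C:1):1,(B:1,D:1):1);")

test_that("clade sharing uses tip sets and ignores rotation", {
  expect_identical(length(shared_clades(t_abcd1, t_abcd1)), 3L)
  expect_identical(shared_clades(t_abcd1, t_abcd2), "A,B,C,D")
  rot <- parse_newick("((B:1,A:1):1,(D:1,C:1):1);")
  expect_identical(length(shared_clades(t_abcd1, rot)), 3L)
  expect_error(shared_clades(t_abcd1, parse_newick("((A:1,B:1):1,C:2);")),
               "tip sets")
})

test_that("MAPE is the median percentage error over shared clades", {
  fx <- make_fixtures(1)
  expect_equal(mape_node_ages(fx$mape_true, fx$mape_true), 0)
  expect_equal(mape_node_ages(fx$mape_true, fx$mape_est), 17.5)

  # robustness: one wild overestimate among exact nodes leaves it at 0
  set.seed(901)
  true <- ape::rcoal(9)
  est <- retime_tree(true, function(a) {
    a[which.max(a == min(a))] <- a[which.max(a == min(a))] * 50
    a
  })
  expect_equal(mape_node_ages(true, est), 0)

  # invariance to ladderization of either input
  tr2 <- ape::ladderize(true)
  expect_equal(mape_node_ages(true, est), mape_node_ages(tr2, est))
})

test_that("topological error and RF match brute-force clade counting", {
  expect_identical(topological_error(t_abcd1, t_abcd1), 0L)
  expect_identical(rf_distance(t_abcd1, t_abcd1), 0L)
  expect_identical(topological_error(t_abcd1, t_abcd2), 2L)
  expect_identical(rf_distance(t_abcd1, t_abcd2), 4L)

  set.seed(902)
  for (i in 1:100) {
    pr <- random_tree_pair(8)
    expect_identical(rf_distance(pr$a, pr$b), bf_rf(pr$a, pr$b))
    expect_identical(topological_error(pr$a, pr$b), bf_topo(pr$a, pr$b))
    # binary same-tip trees: symmetric distance is twice the one-sided
    expect_identical(rf_distance(pr$a, pr$b),
                     2L * topological_error(pr$a, pr$b))
  }
})

test_that("RF behaves as a metric on random instances", {
  set.seed(903)
  for (i in 1:25) {
    pr <- random_tree_pair(8)
    c3 <- ape::rtree(8); c3$tip.label <- sample(pr$a$tip.label)
    expect_identical(rf_distance(pr$a, pr$b), rf_distance(pr$b, pr$a))
    expect_identical(rf_distance(pr$a, pr$a), 0L)
    expect_gte(rf_distance(pr$a, c3) + rf_distance(c3, pr$b),
               rf_distance(pr$a, pr$b))
  }
})

test_that("branch score follows the Kuhner-Felsenstein definition", {
  a <- parse_newick("((A:1,B:1):0.5,C:2);")
  b <- parse_newick("((A:1,B:1):0.2,C:2);")
  expect_equal(branch_score(a, a), 0)
  expect_equal(branch_score(a, b), 0.3)

  # a branch present in only one tree contributes its full length
  poly <- parse_newick("(A:1,B:1,C:2);")
  only <- parse_newick("((A:1,B:1):0.2,C:2);")
  expect_equal(branch_score(poly, only), 0.2)

  set.seed(904)
  for (i in 1:100) {
    pr <- random_tree_pair(8)
    expect_equal(branch_score(pr$a, pr$b), bf_branch_score(pr$a, pr$b),
                 tolerance = 1e-12)
  }
})

test_that("HPD width scoring is linear in the interval widths", {
  fx <- make_fixtures(1)
  dt <- read_annotated_nexus(fx$hpd_nexus)
  expect_equal(hpd_width_pct(dt), 40)

  zero <- dt; zero$hpd[, 1] <- zero$hpd[, 2] <- dt$ages
  expect_equal(hpd_width_pct(zero), 0)

  doubled <- dt
  mid <- rowMeans(dt$hpd)
  doubled$hpd <- cbind(mid - (mid - dt$hpd[, 1]) * 2,
                       mid + (dt$hpd[, 2] - mid) * 2)
  expect_equal(hpd_width_pct(doubled), 80)

  none <- dt; none$hpd[] <- NA
  expect_error(hpd_width_pct(none), "HPD")
})

test_that("gamma matches the closed form and the reference implementation", {
  fx <- make_fixtures(1)
  expect_equal(gamma_statistic(fx$gamma_tree), -sqrt(3) / 5,
               tolerance = 1e-12)

  set.seed(905)
  for (i in 1:100) {
    phy <- ape::rcoal(sample(4:30, 1))
    expect_equal(gamma_statistic(phy), ape::gammaStat(phy),
                 tolerance = 1e-10)
    expect_equal(gamma_statistic(phy), bf_gamma(phy), tolerance = 1e-10)
  }

  # monotonicity: stretching the oldest internode (g2 >> g3 - length
  # concentrated in old branches) raises gamma relative to its reverse
  deep_heavy <- parse_newick("((A:1,B:1):9,C:10);")     # g2 = 9, g3 = 1
  shallow_heavy <- parse_newick("((A:9,B:9):1,C:10);")  # g2 = 1, g3 = 9
  expect_gt(gamma_statistic(deep_heavy), gamma_statistic(shallow_heavy))

  expect_error(gamma_statistic(parse_newick("(A:1,B:1);")), "3 tips")
  expect_error(gamma_statistic(parse_newick("((A:1,B:2):1,C:3);")),
               "ultrametric")
})

test_that("gamma difference signs the direction of node-age bias", {
  set.seed(906)
  true <- ape::rcoal(20)
  expect_equal(gamma_difference(true, true), 0)

  # pushing internal ages rootward (older) lowers gamma
  root_age <- max(ape::branching.times(true))
  older <- retime_tree(true, function(a) root_age * (a / root_age)^0.4)
  expect_lt(gamma_difference(older, true), 0)
  expect_equal(gamma_difference(older, true),
               -gamma_difference(true, older))
})

test_that("metrics_report bundles all scores consistently", {
  fx <- make_fixtures(1)
  rep <- metrics_report(fx$mape_true, fx$mape_est)
  expect_equal(rep$mape, 17.5)
  expect_identical(rep$topo_error, 0L)
  expect_equal(rep$gamma_diff, rep$gamma_est - rep$gamma_true)
  expect_true(is.na(rep$hpd_width))
})
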