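test_that("waiting times and event choice follow the summed event rates", {
  set.seed(101)
  expect_error(draw_waiting_time(numeric(0), 0.1, 1), "empty")

  # single lineage, only speciation possible
  ev <- replicate(500, draw_waiting_time(0.5, 0, 0)$event)
  expect_true(all(ev == "speciation"))

  # waiting-time distribution: KS against Exp(total rate)
  dts <- replicate(1e4, draw_waiting_time(0.5, 0, 0)$dt)
  expect_gt(stats::ks.test(dts, "pexp", 0.5)$p.value, 0.01)

  # P(rate_jump) = q / (lambda + mu + q) = 50 / 50.3
  ev <- replicate(2e4, draw_waiting_time(0.2, 0.1, 50)$event)
  p_hat <- mean(ev == "rate_jump")
  p0 <- 50 / 50.3
  expect_lt(abs(p_hat - p0), 3 * sqrt(p0 * (1 - p0) / 2e4))

  # two lineages: mean dt = 1 / (0.1 + 0.3 + 2*(0.1 + 1)) = 1/2.6
  dts <- replicate(1e4, draw_waiting_time(c(0.1, 0.3), 0.1, 1)$dt)
  expect_lt(abs(mean(dts) - 1 / 2.6), 3 * stats::sd(dts) / sqrt(1e4))
})

test_that("rate increments have the configured covariance structure", {
  p0 <- sim_params(sigma2_lambda = 0, sigma2_r = 0)
  st <- list(lambda = 0.2, r = 0.01)
  expect_identical(apply_rate_jump(st, p0, 1), st)
  expect_error(apply_rate_jump(st, p0, -1), "non-negative")

  set.seed(202)
  # rho = 0: sample covariance of increments compatible with 0
  pu <- sim_params(rho = 0)
  inc <- draw_rate_increments(pu, dt = 1, n = 1e5)
  se <- sqrt((pu$sigma2_lambda * pu$sigma2_r +
                stats::cov(inc)[1, 2]^2) / 1e5)
  expect_lt(abs(stats::cov(inc)[1, 2]), 3 * se)
  expect_lt(abs(stats::var(inc[, 1]) - pu$sigma2_lambda),
            3 * pu$sigma2_lambda * sqrt(2 / 1e5))

  # Continuous: covariance 0.0044 recovered
  pc <- sim_params(cov_lr = 0.0044)
  inc <- draw_rate_increments(pc, dt = 1, n = 1e5)
  se <- sqrt((pc$sigma2_lambda * pc$sigma2_r + 0.0044^2) / 1e5)
  expect_lt(abs(stats::cov(inc)[1, 2] - 0.0044), 3 * se)

  # increments scale with elapsed time
  inc4 <- draw_rate_increments(pc, dt = 4, n = 1e5)
  expect_lt(abs(stats::var(inc4[, 2]) / stats::var(inc[, 2]) - 4),
            4 * 0.05)
})

test_that("rates stay positive under both evolution scales", {
  set.seed(303)
  p_log <- sim_params(sigma2_lambda = 0.5, sigma2_r = 0.5)
  p_nat <- sim_params(sigma2_lambda = 0.5, sigma2_r = 0.5,
                      rate_scale = "natural")
  st <- list(lambda = 0.01, r = 0.001)
  for (i in 1:200) {
    st_l <- apply_rate_jump(st, p_log, 5)
    st_n <- apply_rate_jump(st, p_nat, 5)
    expect_gt(st_l$lambda, 0); expect_gt(st_l$r, 0)
    expect_gte(st_n$lambda, p_nat$rate_floor)
    expect_gte(st_n$r, p_nat$rate_floor)
  }
})

test_that("pure-birth runs stop at the tip target with no extinct tips", {
  set.seed(404)
  p <- sim_params(lambda0 = 1, mu = 0, q = 1,
                  sigma2_lambda = 0, sigma2_r = 0, n_tips = 10)
  run <- simulate_full_tree(p, stop_tips = 10)
  expect_false(run$failed)
  alive <- is.na(run$death)
  expect_identical(sum(alive), 10L)
  # extinct tip = dead lineage with no daughters
  dead_no_kids <- !alive & !(seq_along(run$parent) %in% run$parent)
  expect_identical(sum(dead_no_kids), 0L)
})

test_that("zero-variance jumps leave all rates at their initial values", {
  set.seed(405)
  p <- sim_params(lambda0 = 0.4, r0 = 0.02, mu = 0.1, q = 40,
                  sigma2_lambda = 0, sigma2_r = 0, n_tips = 8)
  run <- simulate_full_tree(p, stop_tips = 8)
  expect_true(all(run$u_lam == log(0.4)))
  expect_true(all(run$jumps$u_lam == log(0.4)))
  expect_true(all(run$jumps$u_r == log(0.02)))
})

test_that("pure-birth crown age matches the Yule closed form", {
  # time for 2 -> m lineages: sum_{k=2}^{m-1} Exp(k * lambda) waits
  set.seed(406)
  m <- 8; lam <- 1
  expected <- sum(1 / (2:(m - 1) * lam))
  p <- sim_params(lambda0 = lam, mu = 0, q = 0.5,
                  sigma2_lambda = 0, sigma2_r = 0, n_tips = m)
  ages <- replicate(300, simulate_full_tree(p, stop_tips = m)$t_end)
  expect_lt(abs(mean(ages) - expected), 3 * stats::sd(ages) / sqrt(300))
})

test_that("GSA picks tip-count intervals proportionally to duration", {
  run <- two_interval_run()

  # deterministic case: with the second interval removed, the only
  # candidate is always chosen
  run1 <- run
  run1$events <- lapply(run1$events, `[`, 1:2)
  run1$t_end <- 4.5
  run1$parent <- run1$parent[1:4]; run1$birth <- run1$birth[1:4]
  run1$death <- run1$death[1:4]; run1$death[4] <- NA
  run1$u_lam <- run1$u_lam[1:4]; run1$u_r <- run1$u_r[1:4]
  run1$lastj0 <- run1$lastj0[1:4]
  set.seed(501)
  for (i in 1:25) {
    snap <- gsa_condition(run1, 3)
    expect_false(snap$failed)
    expect_true(snap$present > 1 && snap$present < 4)
    expect_identical(sum(is.na(snap$death)), 3L)
  }

  # two candidates with durations 3 and 1: first chosen ~75% of the time
  set.seed(502)
  first <- replicate(4e3, gsa_condition(run, 3)$present < 4)
  expect_lt(abs(mean(first) - 0.75), 3 * sqrt(0.75 * 0.25 / 4e3))

  # unattainable tip number flags the run as failed
  expect_true(gsa_condition(run, 10)$failed)
})

test_that("conditioned trees are ultrametric with the exact tip count", {
  set.seed(503)
  for (i in 1:10) {
    n <- sample(5:12, 1)
    sim <- small_replicate(n_tips = n)
    tt <- sim$time_tree
    expect_identical(length(tt$tip.label), n)
    depth <- ape::node.depth.edgelength(tt)
    tipd <- depth[seq_len(n)]
    expect_lt(max(abs(tipd - max(tipd))) / max(tipd), 1e-9)
    expect_true(all(tt$edge.length > 0))
  }
})

test_that("pruning merges extinct-daughter chains and keeps the books", {
  fx <- make_fixtures(1)
  tt <- prune_extinct(fx$extinct_cherry)
  expect_identical(length(tt$tip.label), 2L)
  expect_identical(sum(tt$edge_hidden), 1L)      # the pruned cherry node
  expect_equal(tt$edge.length, c(3, 3))
  expect_equal(tt$edge_subs, c(0.03, 0.03))      # r0 * duration
  expect_equal(tt$root_age, 3)

  # error paths
  expect_error(prune_extinct(list()))
  unconditioned <- fx$extinct_cherry; unconditioned$present <- NULL
  expect_error(prune_extinct(unconditioned), "conditioned")
})

test_that("hidden-event counts equal independently counted pruned nodes", {
  set.seed(504)
  for (i in 1:8) {
    sim <- small_replicate(n_tips = 8)
    run <- sim$run; tt <- sim$time_tree
    # independent count: surviving non-extant lineages at or below the
    # extant MRCA whose speciation kept exactly one surviving daughter
    nlin <- length(run$parent)
    extant <- is.na(run$death)
    surv <- extant
    for (j in rev(seq_len(nlin))) {
      kids <- which(run$parent == j)
      if (!surv[j] && length(kids)) surv[j] <- any(surv[kids])
    }
    n_surv_kids <- vapply(seq_len(nlin), function(j)
      sum(surv[which(run$parent == j)]), 0L)
    # MRCA chain: walk from the top until the first 2-survivor split
    roots <- which(run$parent == 0L)
    above_mrca <- integer(0)
    if (sum(surv[roots]) == 1L) {
      cur <- roots[surv[roots]]
      while (n_surv_kids[cur] == 1L) {
        above_mrca <- c(above_mrca, cur)
        cur <- which(run$parent == cur)[surv[which(run$parent == cur)]]
      }
      above_mrca <- c(above_mrca, cur)  # the MRCA lineage itself
    }
    hidden_expected <- sum(!extant & surv & n_surv_kids == 1L) -
      sum(n_surv_kids[above_mrca] == 1L)
    expect_identical(sum(tt$edge_hidden), as.integer(hidden_expected))
  }
})

test_that("gradual substitution expectation is conserved through pruning", {
  set.seed(505)
  sim <- small_replicate(n_tips = 10)
  run <- sim$run; tt <- sim$time_tree
  # independent integration per lineage from the raw jump log
  lin_subs <- vapply(seq_along(run$parent), function(i) {
    ji <- which(run$jumps$lineage == i)
    ts <- c(run$birth[i], run$jumps$time[ji])
    rs <- exp(c(run$u_r[i], run$jumps$u_r[ji]))
    end <- if (is.na(run$death[i])) run$present else run$death[i]
    sum(rs * diff(c(ts, end)))
  }, 0)
  chains <- unlist(tt$edge_chains)
  expect_equal(sum(tt$edge_subs), sum(lin_subs[chains]), tolerance = 1e-12)
})

test_that("zero-variance control collapses to constant-rate birth-death", {
  set.seed(506)
  p <- sim_params(lambda0 = 0.5, r0 = 0.03, mu = 0.1, q = 20,
                  sigma2_lambda = 0, sigma2_r = 0, n_tips = 10)
  sim <- simulate_time_tree(p)
  tt <- sim$time_tree
  expect_equal(tt$edge_subs, 0.03 * tt$edge.length, tolerance = 1e-12)
  expect_equal(unname(sim$phylogram$edge.length),
               0.03 * tt$edge.length, tolerance = 1e-12)
})

test_that("branch substitution integration is a plain dot product", {
  expect_equal(integrate_branch_substitutions(5, 0.01), 0.05)
  expect_equal(integrate_branch_substitutions(c(2, 1), c(0.01, 0.03)), 0.05)
  expect_identical(integrate_branch_substitutions(numeric(0), numeric(0)), 0)
  expect_error(integrate_branch_substitutions(c(1, 2), c(0.1, -0.1)))
})
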