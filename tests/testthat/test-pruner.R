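test_that("smell concentration is the guarded reciprocal distance", {
  expect_equal(smell_concentration(0, 0, 1e-6), 1e6)
  expect_lt(smell_concentration(2, 0, 1e-6), 0.5)
  set.seed(31)
  X <- runif(10, 0, 2); Y <- runif(10, 0, 2)
  s <- smell_concentration(X, Y, 1e-6)
  for (m in 1:10)
    expect_equal(s[m], 1 / (sqrt(X[m]^2 + Y[m]^2) + 1e-6), tolerance = 1e-12)
  expect_error(smell_concentration(Inf, 0), "finite")
})

test_that("pruning_code thresholds at 0.5 and repairs all-zero masks", {
  expect_equal(pruning_code(c(0.9, 0.4, 0.51)), c(1L, 0L, 1L))
  expect_equal(pruning_code(c(0.5, 0.9)), c(0L, 1L))     # exact 0.5 -> 0
  expect_equal(pruning_code(c(0.5, 0.4, 0.2)), c(1L, 1L, 1L))  # repaired
})

test_that("balance_factor grows from 1 to alpha over the iterations", {
  expect_equal(balance_factor(1, 20, alpha = 13), 1)
  expect_equal(balance_factor(21, 20, alpha = 13), 13)
  om <- vapply(1:20, balance_factor, numeric(1), MaxFEs = 20, alpha = 13)
  expect_true(all(diff(om) > 0))
  expect_equal(balance_factor(5, 7, alpha = 2), 2^(4 / 7))
  expect_error(balance_factor(1, 20, alpha = -1), "positive")
})

test_that("init_population places the full-ensemble fly first in every subswarm", {
  pop <- init_population(D = 3, G = 3, M = 10, seed = 4)
  expect_length(pop, 3)
  expect_equal(sum(lengths(lapply(pop, `[[`, "flies"))), 9)
  for (sub in pop) {
    first <- sub$flies[[1]]
    expect_equal(first$position$X, rep(0, 10))
    expect_equal(first$mask, rep(1L, 10))
    for (f in sub$flies) {
      expect_true(all(f$position$X >= 0 & f$position$X <= 2))
      expect_equal(f$mask, pruning_code(f$smell))
      expect_true(any(f$mask == 1L))
    }
  }
  pop2 <- init_population(D = 3, G = 3, M = 10, seed = 4)
  expect_identical(pop, pop2)
})

test_that("olfactory_step perturbs around the best with scale omega", {
  best <- depf:::new_fly(rep(1, 5), rep(1, 5), 1e-6)
  still <- olfactory_step(best, omega = 0, seed = 1)
  expect_equal(still$position, best$position)
  off1 <- olfactory_step(best, omega = 0.5, seed = 7)
  off2 <- olfactory_step(best, omega = 0.5, seed = 7)
  expect_identical(off1, off2)
  # empirical step magnitude scales linearly with omega
  steps <- function(om) {
    mean(vapply(1:400, function(s) {
      o <- olfactory_step(best, om, bounds = c(-100, 100), seed = s)
      mean(abs(o$position$X - best$position$X))
    }, numeric(1)))
  }
  expect_equal(steps(2) / steps(1), 2, tolerance = 0.05)
})

test_that("vision phase replaces flies and bests only under dominance", {
  mk <- function(dev, cp) {
    f <- depf:::new_fly(runif(3), runif(3), 1e-6)
    f$obj <- objective_pair(dev, cp)
    f
  }
  sub <- list(flies = list(mk(1, 1), mk(2, 2)), subspace_index = 1L,
              best = mk(1.5, 1.5))
  # offspring dominated by parents everywhere: nothing changes
  worse <- list(mk(3, 3), mk(4, 4))
  upd <- vision_update(sub, worse)
  expect_equal(upd$flies[[1]]$obj$signed, c(1, 1))
  expect_equal(upd$flies[[2]]$obj$signed, c(2, 2))
  # fly 1 (1,1) dominates the incumbent best (1.5,1.5)
  expect_equal(upd$best$obj$signed, c(1, 1))
  # a dominating offspring replaces its parent and can become best
  better <- list(mk(0.5, 0.5), mk(5, 5))
  upd2 <- vision_update(upd, better)
  expect_equal(upd2$flies[[1]]$obj$signed, c(0.5, 0.5))
  expect_equal(upd2$best$obj$signed, c(0.5, 0.5))
})

test_that("exchange_information rotates bests around the ring", {
  mk <- function(tag) {
    f <- depf:::new_fly(rep(tag, 2), rep(tag, 2), 1e-6)
    f$obj <- objective_pair(tag, tag)
    f
  }
  subswarms <- lapply(1:3, function(d)
    list(flies = list(mk(d), mk(d + 10)), subspace_index = d, best = mk(d)))
  out <- exchange_information(subswarms)
  # 1 -> 2, 2 -> 3, 3 -> 1; masks preserved, objectives invalidated
  expect_equal(out[[2]]$flies[[1]]$position$X, rep(1, 2))
  expect_equal(out[[3]]$flies[[1]]$position$X, rep(2, 2))
  expect_equal(out[[1]]$flies[[1]]$position$X, rep(3, 2))
  expect_null(out[[2]]$flies[[1]]$obj)
  expect_equal(out[[2]]$flies[[1]]$mask, subswarms[[1]]$best$mask)
  # single subswarm: no-op
  one <- subswarms[1]
  expect_identical(exchange_information(one), one)
})

test_that("prune_ensemble keeps >= 1 partition per subspace, is elitist and reproducible", {
  sp <- make_aligned_spaces(120, 3, 3, dim = 3, sep = 5, seed = 61)
  ens <- generate_ensemble(sp$Z, k = 3, T_runs = 4, seed = 12, p = 80)
  pr <- prune_ensemble(ens, sp$Z, k = 3, direction = 1L, max_fes = 5,
                       seed = 99)
  expect_s3_class(pr, "PruningResult")
  # trace covers every iteration for every subswarm
  expect_equal(nrow(pr$trace), 5 * 3)
  # masks keep at least one member per subspace
  for (m in pr$selected) expect_gte(sum(m), 1)
  kept <- length(pr$pruned_ensemble$partitions)
  expect_lte(kept, length(ens$partitions))
  expect_gte(kept, 3)
  # elitism: per-subswarm best never worsens in either objective under
  # dominance (the recorded pair is never dominated by a later one)
  for (d in 1:3) {
    tr <- pr$trace[pr$trace$subswarm == d, ]
    for (i in seq_len(nrow(tr) - 1)) {
      later <- objective_pair(tr$dev[i + 1], tr$cp[i + 1])
      earlier <- objective_pair(tr$dev[i], tr$cp[i])
      expect_false(dominates(earlier, later))
    }
  }
  # bitwise reproducibility
  pr2 <- prune_ensemble(ens, sp$Z, k = 3, direction = 1L, max_fes = 5,
                        seed = 99)
  expect_identical(pr$selected, pr2$selected)
  expect_identical(consensus_cluster(pr$pruned_ensemble, 3)$labels,
                   consensus_cluster(pr2$pruned_ensemble, 3)$labels)
  # archive is a non-dominated set
  for (i in seq_along(pr$archive)) for (j in seq_along(pr$archive)) {
    if (i == j) next
    expect_false(dominates(
      objective_pair(pr$archive[[j]]$dev, pr$archive[[j]]$cp, pr$direction),
      objective_pair(pr$archive[[i]]$dev, pr$archive[[i]]$cp, pr$direction)))
  }
})
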