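test_that("all generators are pure functions of settings and seed", {
  t1 <- sim_bd_tree(0.15, 0.05, stop = list(age = 15), seed = 11)
  t2 <- sim_bd_tree(0.15, 0.05, stop = list(age = 15), seed = 11)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))

  s1 <- sim_shifted_tree(0.1, 0, shifts = list(time = 5, b = 0.4, d = 0),
                         stop = list(age = 12), seed = 7, min_clade_tips = 3)
  s2 <- sim_shifted_tree(0.1, 0, shifts = list(time = 5, b = 0.4, d = 0),
                         stop = list(age = 12), seed = 7, min_clade_tips = 3)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(s1$true_clades, s2$true_clades)

  b1 <- sim_bisse_tree(list(lambda0 = 0.1, lambda1 = 0.3, mu0 = 0.02,
                            mu1 = 0.05, q01 = 0.05, q10 = 0.05),
                       stop = list(age = 15), seed = 4)
  b2 <- sim_bisse_tree(list(lambda0 = 0.1, lambda1 = 0.3, mu0 = 0.02,
                            mu1 = 0.05, q01 = 0.05, q10 = 0.05),
                       stop = list(age = 15), seed = 4)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))
  expect_identical(b1$states, b2$states)

  ## generators do not disturb the caller's RNG stream
  set.seed(99); x1 <- stats::runif(1)
  set.seed(99); invisible(sim_bd_tree(0.2, 0, stop = list(age = 5), seed = 3))
  x2 <- stats::runif(1)
  expect_identical(x1, x2)
})

test_that("pure-birth tip counts match the analytic expectation", {
  ns <- vapply(1:1000, function(i)
    length(sim_bd_tree(0.1, 0, stop = list(age = 10), seed = i)$tip.label), 0)
  se <- stats::sd(ns) / sqrt(length(ns))
  expect_lt(abs(mean(ns) - 2 * exp(0.1 * 10)), 3 * se)
  ## and the per-lineage count law from a forward count oracle
  set.seed(1)
  cnt <- oracle_sim_counts(0.1, 0, 10, 20000)
  ana <- exp(clade_size_lnl(10, 1:8, piece_rates(0.1, 0, "yule")))
  emp <- tabulate(pmin(cnt, 9), 9) / length(cnt)
  chi <- sum((emp - c(ana, 1 - sum(ana)))^2 / c(ana, 1 - sum(ana))) * length(cnt)
  expect_gt(stats::pchisq(chi, df = 8, lower.tail = FALSE), 0.01)
})

test_that("simulated trees satisfy every structural invariant", {
  for (seed in 1:10) {
    tr <- sim_bd_tree(0.25, 0.1, stop = list(taxa = 20), seed = seed)
    expect_true(validate_time_tree(tr, require_binary = TRUE))
    expect_equal(length(tr$tip.label), 20)
  }
  expect_error(sim_bd_tree(0.05, 0.5, stop = list(age = 30), seed = 1,
                           max_tries = 20), "budget")
})

test_that("planted shift clades are clades of the output tree", {
  for (seed in c(5, 6, 7)) {
    st <- sim_shifted_tree(0.1, 0, shifts = list(time = 6, b = 0.5, d = 0),
                           stop = list(age = 14), seed = seed,
                           min_clade_tips = 5)
    expect_true(is_monophyletic_key(st$tree, st$true_clades[[1]]))
    expect_gte(length(st$true_clades[[1]]), 5)
  }
})

test_that("a degenerate shift scenario reduces to the plain generator", {
  ## same rates in both regimes: tip counts indistinguishable
  n_plain <- vapply(1:200, function(i)
    length(sim_bd_tree(0.12, 0, stop = list(age = 12), seed = 9000 + i)$tip.label), 0)
  n_shift <- vapply(1:200, function(i)
    length(sim_shifted_tree(0.12, 0,
                            shifts = list(time = 6, b = 0.12, d = 0),
                            stop = list(age = 12), seed = 9500 + i,
                            min_clade_tips = 1)$tree$tip.label), 0)
  ks <- suppressWarnings(stats::ks.test(n_plain, n_shift))
  expect_gt(ks$p.value, 0.01)
})

test_that("genus collapse conserves species counts on monophyletic blocks", {
  tr <- sim_bd_tree(0.2, 0.05, stop = list(taxa = 50), seed = 3)
  cg <- collapse_genera(tr, 20, seed = 2)
  expect_equal(length(cg$tree$tip.label), 20)
  expect_equal(sum(cg$richness), 50)
  expect_true(validate_time_tree(cg$tree, require_binary = TRUE))
  ## collapsing nothing leaves richness at one each
  cg0 <- collapse_genera(tr, 50, seed = 2)
  expect_true(all(cg0$richness == 1))
  expect_identical(ape::write.tree(cg0$tree), ape::write.tree(tr))
})

test_that("pseudo-posterior replicates preserve tip sets and validity", {
  tr <- sim_bd_tree(0.2, 0.05, stop = list(taxa = 30), seed = 8)
  ps0 <- pseudo_posterior(tr, 4, age_sd = 0, topo_rate = 0, seed = 1)
  for (p in ps0) expect_identical(ape::write.tree(p), ape::write.tree(tr))
  ps <- pseudo_posterior(tr, 6, age_sd = 0.1, topo_rate = 0.2, seed = 5)
  for (p in ps) {
    expect_true(validate_time_tree(p, require_binary = TRUE))
    expect_identical(sort(p$tip.label), sort(tr$tip.label))
  }
  expect_length(attr(ps, "tip_mismatch"), 0)
})

test_that("clade recovery degrades as topology noise increases", {
  st <- fixture_shifted(2021)
  key <- st$true_clades[[1]]
  frac_mono <- vapply(c(0, 0.25, 0.7), function(rate) {
    ps <- pseudo_posterior(st$tree, 30, age_sd = 0, topo_rate = rate, seed = 17)
    mean(vapply(ps, is_monophyletic_key, logical(1), key = key))
  }, numeric(1))
  expect_equal(frac_mono[1], 1)
  expect_true(all(diff(frac_mono) <= 0))
  expect_lt(frac_mono[3], frac_mono[1])
})

test_that("state-dependent simulation respects its degenerate cases", {
  b0 <- sim_bisse_tree(list(lambda0 = 0.2, lambda1 = 0.9, mu0 = 0, mu1 = 0,
                            q01 = 0, q10 = 0), stop = list(age = 8),
                       root_state = 0L, seed = 4)
  expect_true(all(b0$states == 0))

  ## symmetric fast switching approaches equal state frequencies
  set.seed(2)
  fr <- vapply(1:60, function(i) {
    sim <- sim_bisse_tree(list(lambda0 = 0.25, lambda1 = 0.25, mu0 = 0,
                               mu1 = 0, q01 = 2, q10 = 2),
                          stop = list(age = 10), seed = 300 + i)
    mean(sim$states == 1)
  }, numeric(1))
  expect_lt(abs(mean(fr) - 0.5), 3 * stats::sd(fr) / sqrt(length(fr)))

  ## state-0-only parameters match the plain generator distributionally
  n_a <- vapply(1:150, function(i)
    length(sim_bd_tree(0.15, 0.03, stop = list(age = 10), seed = 700 + i)$tip.label), 0)
  n_b <- vapply(1:150, function(i)
    length(sim_bisse_tree(list(lambda0 = 0.15, lambda1 = 0.9, mu0 = 0.03,
                               mu1 = 0.9, q01 = 0, q10 = 0),
                          stop = list(age = 10), seed = 800 + i)$tree$tip.label), 0)
  ks <- suppressWarnings(stats::ks.test(n_a, n_b))
  expect_gt(ks$p.value, 0.01)

  ## subsampling emulates incomplete sampling
  sub <- sim_bisse_tree(list(lambda0 = 0.3, lambda1 = 0.3, mu0 = 0, mu1 = 0,
                             q01 = 0.5, q10 = 0.5), stop = list(age = 12),
                        seed = 10, sampling_f = c(0.5, 0.5))
  expect_true(validate_time_tree(sub$tree, require_binary = TRUE))
})
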