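test_that("pure-birth likelihood is the d -> 0 limit of the bd likelihood", {
  set.seed(11)
  for (i in 1:5) {
    tr <- sim_bd_tree(0.2, 0.05, stop = list(taxa = 10 + 5 * i), seed = 40 + i)
    for (b in c(0.05, 0.2, 1)) {
      ly <- resolved_lnl(tr, piece_rates(b, 0, "yule"))
      lb <- resolved_lnl(tr, piece_rates(b, 1e-14, "bd"))
      expect_lt(abs(ly - lb), 1e-9)
    }
  }
})

test_that("clade-size law is a proper geometric distribution", {
  rates <- piece_rates(0.2, 0.1, "bd")
  p <- exp(clade_size_lnl(20, 1:1e6, rates))
  expect_lt(abs(sum(p) - 1), 1e-6)
  ## conditioned and unconditioned forms differ by the survival probability
  lc <- clade_size_lnl(20, 3, rates)
  lu <- clade_size_lnl(20, 3, rates, conditioned = FALSE)
  expect_lt(lu, lc)
  expect_error(clade_size_lnl(20, 0, rates), ">= 1")
  expect_error(clade_size_lnl(0, 2, rates), "> 0")
})

test_that("probability of a monotypic clade decreases with stem age (b > d)", {
  rates <- piece_rates(0.2, 0.05, "bd")
  p1 <- exp(clade_size_lnl(seq(1, 50, by = 5), 1, rates))
  expect_true(all(diff(p1) < 0))
})

test_that("clade-size law matches forward simulation (spot check)", {
  set.seed(21)
  cnt <- oracle_sim_counts(0.15, 0.05, 12, 20000)
  surv <- cnt[cnt > 0]
  rates <- piece_rates(0.15, 0.05, "bd")
  ana <- exp(clade_size_lnl(12, 1:8, rates))
  emp <- tabulate(pmin(surv, 9), 9) / length(surv)
  chi <- sum((emp - c(ana, 1 - sum(ana)))^2 / c(ana, 1 - sum(ana))) * length(surv)
  expect_gt(stats::pchisq(chi, df = 8, lower.tail = FALSE), 0.01)
})

test_that("resolved likelihood equals a term-by-term oracle", {
  set.seed(31)
  for (i in 1:8) {
    tr <- sim_bd_tree(0.2, 0.04, stop = list(taxa = 8 + 3 * i), seed = 60 + i)
    rich <- richness_table(stats::setNames(sample(1:6, length(tr$tip.label), TRUE),
                                           tr$tip.label))
    for (rt in list(c(0.2, 0.04), c(0.1, 0), c(0.08, 0.2))) {
      got <- resolved_lnl(tr, piece_rates(rt[1], rt[2], "bd"), richness = rich)
      want <- oracle_tree_lnl(tr, rt[1], rt[2], richness = rich)
      expect_lt(abs(got - want), 1e-8)
    }
  }
})

test_that("likelihood is invariant under tip-label permutation", {
  tr <- sim_bd_tree(0.2, 0.05, stop = list(taxa = 15), seed = 77)
  tr2 <- tr
  tr2$tip.label <- rev(tr2$tip.label)
  tr2 <- as_time_tree(tr2)
  r <- piece_rates(0.15, 0.03, "bd")
  expect_equal(resolved_lnl(tr, r), resolved_lnl(tr2, r))
})

test_that("piecewise likelihood composes and decomposes exactly", {
  st <- fixture_shifted(881)
  tr <- st$tree
  rich <- richness_table(stats::setNames(rep(1L, length(tr$tip.label)), tr$tip.label))
  root <- length(tr$tip.label) + 1L
  r0 <- piece_rates(0.14, 0, "yule")

  ## zero shifts reproduces the single-regime likelihood
  l0 <- piecewise_lnl(tr, rich, integer(0), stats::setNames(list(r0), root))
  expect_equal(as.numeric(l0), resolved_lnl(tr, r0, richness = rich))

  ## planting a shift with identical rates changes nothing
  v <- mrca_node(tr, st$true_clades[[1]])
  l1 <- piecewise_lnl(tr, rich, v, stats::setNames(list(r0, r0), c(root, v)))
  expect_equal(as.numeric(l1), as.numeric(l0), tolerance = 1e-10)

  ## three-regime configuration equals the sum of independent piece oracles
  kids <- tr$edge[tr$edge[, 1] == v, 2]
  v2 <- kids[kids > length(tr$tip.label)][1]
  rates <- stats::setNames(list(piece_rates(0.1, 0.02, "bd"),
                                piece_rates(0.7, 0, "yule"),
                                piece_rates(0.3, 0.1, "bd")),
                           c(root, v, v2))
  l3 <- piecewise_lnl(tr, rich, c(v, v2), rates)
  per <- attr(l3, "pieces")
  expect_equal(sum(per), as.numeric(l3))
  ## recompute each piece with the plain-R oracle over explicit members
  idx <- shiftscape:::.tree_index(tr, rich)
  fs <- shiftscape:::.first_shift_above(idx, c(v, v2))
  pieces <- shiftscape:::.build_pieces(idx, fs, "stem")
  for (id in names(pieces)) {
    p <- pieces[[id]]
    want <- oracle_piece_lnl(p$n_b, p$int_s, p$int_t, p$tip_s, p$tip_n,
                             rates[[id]]$b, rates[[id]]$d)
    expect_lt(abs(per[[id]] - want), 1e-8)
  }

  ## editing one piece's rates changes only that piece's contribution
  rates2 <- rates
  rates2[[as.character(v2)]] <- piece_rates(0.5, 0.2, "bd")
  l3b <- piecewise_lnl(tr, rich, c(v, v2), rates2)
  per2 <- attr(l3b, "pieces")
  keep <- setdiff(names(per), as.character(v2))
  expect_equal(per2[keep], per[keep])
  expect_false(isTRUE(all.equal(per2[[as.character(v2)]], per[[as.character(v2)]])))
})

test_that("piecewise likelihood rejects malformed shift sets", {
  tr <- sim_bd_tree(0.2, 0, stop = list(taxa = 8), seed = 5)
  rich <- richness_table(stats::setNames(rep(1L, 8), tr$tip.label))
  root <- 9L
  r0 <- list(piece_rates(0.2, 0, "yule"))
  expect_error(piecewise_lnl(tr, rich, c(10L, 10L), stats::setNames(r0, root)),
               "distinct")
  expect_error(piecewise_lnl(tr, rich, root, stats::setNames(r0, root)), "root")
  expect_error(piecewise_lnl(tr, rich, 10L, stats::setNames(r0, root)),
               "missing rates")
})

test_that("maximum-likelihood piece fits are stable and recover the truth", {
  ## analytic pure-birth estimate on an all-singleton tree
  tr <- sim_bd_tree(0.15, 0, stop = list(taxa = 50), seed = 91)
  f <- fit_resolved(tr, flavor = "yule")
  expect_equal(f$rates$b, (50 - 2) / sum(tr$edge.length), tolerance = 1e-8)

  ## refits from extra random starts agree to 1e-6 in lnL
  set.seed(14)
  f1 <- fit_resolved(tr, flavor = "bd", n_starts = 1)
  f5 <- fit_resolved(tr, flavor = "bd", n_starts = 5)
  expect_lt(abs(f1$lnl - f5$lnl), 1e-6)
  expect_gte(f5$lnl + 1e-9, f$lnl)   # bd never beats its own yule limit from below

  ## strong extinction is identified, and the d > b region is reachable by
  ## the optimizer (finite, well-behaved likelihood there)
  trd <- sim_bd_tree(0.4, 0.32, stop = list(taxa = 80), seed = 13,
                     max_tries = 5000)
  fd <- fit_resolved(trd, flavor = "bd")
  expect_gt(fd$rates$epsilon, 0.2)
  ld <- resolved_lnl(trd, piece_rates(0.2, 0.3, "bd"))
  expect_true(is.finite(ld) && ld > -1e9)
})

test_that("degenerate single-tip pieces maximize the clade-size law alone", {
  ## a 1-tip piece with richness n: the geometric supremum sits at
  ## e^{-b s} = 1/n, lnl = log((1/n)((n-1)/n)^(n-1)) under conditioning;
  ## here tested through the internal piece interface
  piece <- list(id = 1L, int_s = numeric(0), int_t = numeric(0), n_b = 0,
                tip_s = 12, tip_n = 8, tip_ids = 1L,
                condition_root = FALSE, root_age = 12)
  f <- shiftscape:::.fit_piece(piece, "yule")
  expect_equal(f$rates$b, log(8) / 12, tolerance = 1e-8)
  expect_lte(f$lnl, 0)
  ## bd adds nothing for a single unresolved clade
  fb <- shiftscape:::.fit_piece(piece, "bd")
  expect_equal(fb$lnl, f$lnl, tolerance = 1e-9)
})

test_that("information criteria satisfy their defining identities", {
  expect_equal(aic_score(-100, 3), 206)
  expect_equal(aicc_score(-100, 3, 50), 206 + 2 * 3 * 4 / 46)
  expect_gte(aicc_score(-100, 3, 50), aic_score(-100, 3))
  expect_lt(abs(aicc_score(-100, 3, 1e9) - aic_score(-100, 3)), 1e-6)
  expect_identical(aicc_score(-100, 10, 11), Inf)
})
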