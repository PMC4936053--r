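test_that("separable profile blocks are recovered exactly", {
  m <- matrix(0L, 4, 6, dimnames = list(sprintf("GH%d", 1:4), sprintf("g%d", 1:6)))
  m[1:2, 1:3] <- 10L
  m[3:4, 4:6] <- 10L
  suppressWarnings(lab <- cluster_guilds(percent_of_cazy(m), 2))
  expect_equal(length(unique(lab[1:3])), 1L)
  expect_equal(length(unique(lab[4:6])), 1L)
  expect_false(lab["g1"] == lab["g4"])

  expect_error(cluster_guilds(percent_of_cazy(m), 7), class = "guildomics_bad_k")
  same <- matrix(5L, 4, 4, dimnames = list(sprintf("GH%d", 1:4), sprintf("g%d", 1:4)))
  expect_error(cluster_guilds(percent_of_cazy(same), 2),
               class = "guildomics_no_structure")
})

test_that("indval reproduces its analytic special cases", {
  m <- matrix(0L, 2, 9, dimnames = list(c("f1", "f2"), sprintf("g%d", 1:9)))
  labels <- stats::setNames(rep(c("k1", "k2", "k3"), each = 3), colnames(m))
  m["f1", 1:3] <- 5L          # present only in guild 1: perfect indicator
  m["f2", ] <- 4L             # identical mean, full occupancy everywhere
  iv <- indval(m, labels, n_perm = 99, seed = 1)
  expect_equal(unname(iv$indval["f1", "k1"]), 100)
  expect_equal(unname(iv$summary$stat[1]), 100)
  expect_equal(unname(iv$summary$stat[2]), 100 / 3, tolerance = 1e-12)
  expect_equal(iv$summary$best_guild[2], "k1")  # tie broken to lowest index
})

test_that("indval A responds to per-genome rescaling but B does not", {
  set.seed(4)
  m <- matrix(rpois(40, 5) + 1L, 4, 10,
              dimnames = list(sprintf("f%d", 1:4), sprintf("g%d", 1:10)))
  labels <- stats::setNames(rep(c("k1", "k2"), each = 5), colnames(m))
  iv1 <- indval(m, labels, n_perm = 99, seed = 1)
  m2 <- m; m2[, 1] <- m2[, 1] * 7L
  iv2 <- indval(m2, labels, n_perm = 99, seed = 1)
  expect_identical(iv1$B, iv2$B)
  expect_false(isTRUE(all.equal(iv1$A, iv2$A)))
})

test_that("all-zero families are flagged with indval 0 and p 1", {
  m <- rbind(dead = rep(0L, 6), ok = rep(3L, 6))
  colnames(m) <- sprintf("g%d", 1:6)
  labels <- stats::setNames(rep(c("k1", "k2"), each = 3), colnames(m))
  iv <- indval(m, labels, n_perm = 99, seed = 1)
  expect_true(iv$summary$degenerate[iv$summary$family == "dead"])
  expect_equal(iv$summary$stat[iv$summary$family == "dead"], 0)
  expect_equal(iv$summary$p[iv$summary$family == "dead"], 1)
})

test_that("permutation p-values are uniform under the null", {
  set.seed(10)
  m <- matrix(rnbinom(200 * 16, size = 1 / 0.3, mu = 6), 200, 16,
              dimnames = list(sprintf("f%03d", 1:200), sprintf("g%02d", 1:16)))
  labels <- stats::setNames(rep(c("k1", "k2"), each = 8), colnames(m))
  iv <- indval(m, labels, n_perm = 999, seed = 99)
  ks <- suppressWarnings(stats::ks.test(iv$summary$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("NB pairwise test is antisymmetric and drops dead families", {
  sim <- simulate_cazy_counts(guild_sim_params(seed = 3))
  m <- sim$counts
  m["GH060", ] <- 0L
  d12 <- nb_pairwise_da(m, sim$labels, c("alpha_glucan", "plant_glycan"))
  d21 <- nb_pairwise_da(m, sim$labels, c("plant_glycan", "alpha_glucan"))
  expect_equal(d12$lfc, -d21$lfc)
  expect_equal(d12$p, d21$p)
  expect_false("GH060" %in% d12$family)
  expect_true(all(d12$q >= d12$p))
})

test_that("the dual criterion intersects both evidence streams", {
  sim <- simulate_cazy_counts(guild_sim_params(seed = 11))
  iv <- indval(sim$counts, sim$labels, n_perm = 499, seed = 1)
  da <- nb_all_pairs(sim$counts, sim$labels)
  def <- define_guild_enzymes(iv, da, sim$labels, alpha = 0.05)
  guilds <- names(def$defining)
  for (k in guilds) {
    for (fam in def$defining[[k]]) {
      row <- iv$summary[iv$summary$family == fam, ]
      expect_equal(row$best_guild, k)
      expect_lte(row$q, 0.05)
      for (other in setdiff(guilds, k)) {
        key <- paste(sort(c(k, other)), collapse = "|")
        dd <- da[[key]]
        pair <- attr(dd, "pair")
        lfc <- dd$lfc[dd$family == fam]
        expect_lte(dd$q[dd$family == fam], 0.05)
        expect_true(if (pair[2] == k) lfc > 0 else lfc < 0)
      }
    }
  }
  # monotone in alpha
  def_strict <- define_guild_enzymes(iv, da, sim$labels, alpha = 0.01)
  for (k in guilds)
    expect_true(all(def_strict$defining[[k]] %in% def$defining[[k]]))
  # a family significant on one arm only is excluded: families enriched vs
  # just one alternative never appear
  expect_error(define_guild_enzymes(iv, da[1], sim$labels),
               class = "guildomics_missing_pair")
})

test_that("recovery on synthetic defaults reaches the achievable level", {
  aris <- jacs <- numeric(5)
  for (s in 1:5) {
    sim <- simulate_cazy_counts(guild_sim_params(seed = s))
    lab <- cluster_guilds(percent_of_cazy(sim$counts), 3)
    aris[s] <- mclust::adjustedRandIndex(lab[names(sim$labels)], sim$labels)
    iv <- indval(sim$counts, sim$labels, n_perm = 499, seed = s)
    da <- nb_all_pairs(sim$counts, sim$labels)
    def <- define_guild_enzymes(iv, da, sim$labels)
    truth <- unlist(lapply(names(sim$defining), function(k)
      paste(k, sim$defining[[k]])))
    found <- unlist(lapply(names(def$defining), function(k)
      paste(k, def$defining[[k]])))
    jacs[s] <- jaccard(found, truth)
  }
  expect_gte(mean(aris), 0.9)
  # power against the 5-genome guild bounds what any test can recover here;
  # see the methods vignette for the power analysis behind this floor
  expect_gte(mean(jacs), 0.45)
  expect_true(all(jacs <= 1))
})

test_that("ordination matches an eigen-decomposition oracle", {
  set.seed(8)
  x <- matrix(rnorm(200), 20, 10,
              dimnames = list(sprintf("f%d", 1:20), sprintf("g%d", 1:10)))
  ord <- ordinate(x)
  e <- eigen(stats::cov(t(x)) * (9 / 10))   # population covariance of columns
  expect_equal(ord$explained, (e$values / sum(e$values))[1:2], tolerance = 1e-9)
  # scores match up to the fixed sign convention
  pr <- stats::prcomp(t(x), center = TRUE)
  for (i in 1:2)
    expect_equal(abs(unname(ord$scores[, i])), abs(unname(pr$x[, i])),
                 tolerance = 1e-9)
  expect_lte(sum(ord$explained), 1)

  # two separated clouds land apart on PC1
  y <- cbind(matrix(rnorm(50), 5, 10), matrix(rnorm(50, 8), 5, 10))
  colnames(y) <- sprintf("g%d", 1:20); rownames(y) <- sprintf("f%d", 1:5)
  o2 <- ordinate(y)
  expect_true(max(o2$scores[1:10, 1]) < min(o2$scores[11:20, 1]) ||
                min(o2$scores[1:10, 1]) > max(o2$scores[11:20, 1]))

  expect_error(ordinate(matrix(1, 3, 4, dimnames = list(letters[1:3], letters[4:7]))),
               class = "guildomics_no_structure")
})
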