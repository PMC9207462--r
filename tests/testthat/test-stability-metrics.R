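test_that("Cq to relative quantity follows the efficiency power law", {
  suppressWarnings(  # g3 is deliberately down to 2 present values
    cq <- make_cq(rbind(g1 = c(20, 21, 22), g2 = c(20, 20, 20),
                        g3 = c(20, 21, NA))))
  rq <- cq_to_relative_quantity(cq, 2)
  expect_equal(unname(rq$q["g1", ]), c(1, 0.5, 0.25))
  expect_equal(unname(rq$q["g2", ]), c(1, 1, 1))
  expect_true(is.na(rq$q["g3", 3]))
  rq15 <- cq_to_relative_quantity(cq, 1.5)
  expect_equal(unname(rq15$q["g1", 1:2]), c(1, 1 / 1.5))
  expect_equal(unname(apply(rq$q, 1, max, na.rm = TRUE)), rep(1, 3))
  expect_error(cq_to_relative_quantity(cq, 1), "> 1")
})

test_that("delta-Ct reproduces hand-computed pairwise SDs", {
  cq <- make_cq(rbind(A = c(20, 21, 22, 23),
                      B = c(25, 26, 27, 28),
                      C = c(20, 23, 22, 25)))
  r <- delta_ct_stability(cq)
  # A-B constant => SD 0; A-C = (0,-2,0,-2) => sample SD 2/sqrt(3)
  expect_equal(unname(r$stability),
               c(1 / sqrt(3), 1 / sqrt(3), 2 / sqrt(3)), tolerance = 1e-12)
  expect_equal(unname(r$extras$pairwise_sd["A", "B"]), 0)
  expect_equal(unname(r$rank), c(1.5, 1.5, 3))
  # two perfectly co-stable genes alone
  r2 <- delta_ct_stability(make_cq(rbind(A = c(20, 21, 22),
                                         B = c(25, 26, 27))))
  expect_equal(unname(r2$stability), c(0, 0))
  # permutation invariance
  perm <- c(3, 1, 4, 2)
  rp <- delta_ct_stability(make_cq(cq$cq[, perm]))
  expect_equal(rp$stability, r$stability)
  # matches the brute-force oracle on random data
  set.seed(5)
  m <- matrix(rnorm(5 * 8, 25, 1), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  expect_equal(delta_ct_stability(make_cq(m))$stability, oracle_delta_ct(m),
               tolerance = 1e-12)
})

test_that("delta-Ct skips pairs with too few common samples", {
  m <- rbind(A = c(20, 21, 22, 23, 24),
             B = c(25, 26, 27, 28, 29),
             C = c(21, 22, NA, NA, 25),
             D = c(NA, NA, 24, 25, 26))
  expect_warning(r <- delta_ct_stability(make_cq(m)), "C/D")
  expect_true(is.na(r$extras$pairwise_sd["C", "D"]))
  # the skipped pair is excluded from the means; A/B pairs intact
  expect_equal(unname(r$extras$pairwise_sd["A", "B"]), 0)
  expect_error(delta_ct_stability(make_cq(m[1, , drop = FALSE])),
               "at least 2 genes")
})

test_that("BestKeeper descriptors and index behave as defined", {
  # two identical genes: tied rank, index equals their common profile
  cq <- make_cq(rbind(A = c(24, 25, 26), B = c(24, 25, 26)))
  r <- bestkeeper(cq)
  d <- r$extras$descriptors
  expect_equal(unname(r$rank), c(1.5, 1.5))
  expect_equal(d$r_index, c(1, 1))
  expect_equal(unname(r$extras$index), c(24, 25, 26))
  # direct formula on a 2-value gene (padded to 3 complete samples)
  cq2 <- make_cq(rbind(G = c(24, 26, 25), H = c(20, 20, 20)))
  d2 <- bestkeeper(cq2)$extras$descriptors
  expect_equal(d2$sd[d2$gene == "G"], 1, tolerance = 1e-12)
  expect_equal(d2$cv_pct[d2$gene == "G"], 4, tolerance = 1e-12)
  expect_equal(d2$sd[d2$gene == "H"], 0)
  expect_equal(d2$cv_pct[d2$gene == "H"], 0)
  # constant gene ranks first
  expect_equal(unname(bestkeeper(cq2)$rank["H"]), 1)
  # sample-mode SD on two values: (24,26) -> sqrt(2)
  expect_equal(sd_if <- long_sd(c(24, 26)), sqrt(2))
  # index = per-sample geometric mean of Cq (mixed-gene table)
  cq3 <- make_cq(rbind(A = c(24, 25, 26), B = c(24, 25, 26),
                       C = c(30, 27, 29)))
  idx <- bestkeeper(cq3)$extras$index
  expect_equal(unname(idx),
               unname(apply(cq3$cq, 2, function(v) exp(mean(log(v))))))
})

test_that("adding an unstable gene never changes other genes' BestKeeper SD", {
  set.seed(9)
  base <- matrix(rnorm(4 * 10, 25, 0.3), 4, 10,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  r1 <- bestkeeper(make_cq(base))
  noisy <- rbind(base, wild = rnorm(10, 28, 3))
  r2 <- bestkeeper(make_cq(noisy))
  expect_identical(r1$stability, r2$stability[paste0("g", 1:4)])
  # MAD variant is selectable
  rm <- bestkeeper(make_cq(base), use_mad = TRUE)
  expect_equal(unname(rm$stability),
               apply(base, 1, function(v) mean(abs(v - mean(v)))),
               ignore_attr = TRUE)
  suppressWarnings(cq_small <- make_cq(base[, 1:2]))
  expect_error(bestkeeper(cq_small), "complete-case")
})

test_that("geNorm reproduces the worked 3-gene instance", {
  y <- rbind(A = c(0, -1, -2, -3), B = c(0, -1, -2, -3),
             C = c(0, -2, -1, -3))
  q <- 2^y
  colnames(q) <- paste0("s", 1:4)
  r <- genorm(q)
  v_ac <- long_sd(y["A", ] - y["C", ])
  expect_equal(v_ac, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(r$stability[c("A", "B", "C")]),
               c(v_ac / 2, v_ac / 2, v_ac), tolerance = 1e-12)
  expect_equal(unname(r$rank[c("A", "B", "C")]), c(1.5, 1.5, 3))
  expect_equal(r$extras$removal_order, "C")
})

test_that("geNorm is invariant to proportional scaling of genes", {
  set.seed(21)
  base <- 2^matrix(rnorm(4 * 6, -2, 1), 4, 6,
                   dimnames = list(paste0("g", 1:4), paste0("s", 1:6)))
  # all genes proportional to one profile: every M is 0
  prof <- base[1, ]
  prop <- rbind(g1 = prof, g2 = 0.5 * prof, g3 = 0.1 * prof,
                g4 = 0.01 * prof)
  colnames(prop) <- paste0("s", 1:6)
  expect_equal(unname(genorm(prop)$stability), rep(0, 4))
  # scaling one gene's quantities leaves its M unchanged
  r0 <- genorm(base)
  scaled <- base
  scaled[2, ] <- scaled[2, ] * 7.3
  expect_equal(genorm(scaled)$stability, r0$stability, tolerance = 1e-12)
  expect_error(genorm(base[1:2, ]), "at least 3 genes")
})

test_that("stepwise geNorm agrees with from-scratch recomputation", {
  set.seed(33)
  for (i in 1:25) {
    G <- sample(3:6, 1)
    S <- sample(4:8, 1)
    q <- 2^matrix(rnorm(G * S, 0, 1), G, S,
                  dimnames = list(paste0("g", seq_len(G)),
                                  paste0("s", seq_len(S))))
    got <- genorm(q)
    want <- oracle_genorm(q)
    expect_equal(got$stability, want$m, tolerance = 1e-12)
    expect_equal(got$rank, want$rank)
    expect_equal(got$extras$removal_order, want$removal_order)
  }
})

test_that("geNorm pairwise variation is zero for proportional genes", {
  prof <- 2^c(0, -1, -2.5, -0.5, -3)
  q <- rbind(g1 = prof, g2 = 0.3 * prof, g3 = 0.9 * prof, g4 = 0.05 * prof)
  colnames(q) <- paste0("s", 1:5)
  v <- genorm(q)$extras$pairwise_variation
  expect_equal(v$n, c(2, 3))
  expect_equal(v$v, c(0, 0), tolerance = 1e-12)
})

test_that("NormFinder scores symmetry, noise and group shifts correctly", {
  # single group, one clearly noisier gene ranks last (seeded)
  sim <- simulate_cq_experiment(n_genes = 4, group_sizes = 20,
                                sigma = c(0.05, 0.05, 0.05, 0.5), seed = 14)
  r <- normfinder(sim$cq)
  expect_equal(unname(r$rank["gene04"]), 4)
  # equal-variance genes: no systematic winner, stabilities comparable
  sim2 <- simulate_cq_experiment(n_genes = 4, group_sizes = 40,
                                 sigma = rep(0.3, 4), seed = 15)
  r2 <- normfinder(sim2$cq)
  expect_lt(max(r2$stability) / min(r2$stability), 3)
  # two groups: a pure group shift on one gene dominates its |d|
  shifts <- matrix(0, 4, 2)
  shifts[4, 2] <- 2
  sim3 <- simulate_cq_experiment(n_genes = 4, group_sizes = c(10, 10),
                                 sigma = rep(0.05, 4), shifts = shifts,
                                 seed = 16)
  r3 <- normfinder(sim3$cq)
  expect_equal(unname(r3$rank["gene04"]), 4)
  expect_equal(which.max(abs(r3$extras$d[, 2])), c(gene04 = 4L))
  # intergroup deviations sum to ~0 over genes and over groups
  expect_equal(colSums(r3$extras$d), c(grp1 = 0, grp2 = 0), tolerance = 1e-12)
  expect_equal(unname(rowSums(r3$extras$d)), rep(0, 4), tolerance = 1e-12)
})

test_that("NormFinder rejects undersized groups by name", {
  cqm <- rbind(a = c(20, 21, 22, 23), b = c(22, 23, 24, 25),
               c = c(24, 25, 26, 27))
  cq <- make_cq(cqm, group = c("big", "big", "big", "tiny"))
  expect_error(normfinder(cq), "tiny")
})

test_that("all four methods are invariant to sample permutation", {
  sim <- simulate_cq_experiment(n_genes = 5, group_sizes = c(6, 6),
                                seed = 8)
  cq <- sim$cq
  perm <- sample(ncol(cq$cq))
  cqp <- cq_table(cq$cq[, perm], cq$metadata[perm, ])
  expect_equal(delta_ct_stability(cqp)$stability,
               delta_ct_stability(cq)$stability)
  expect_equal(bestkeeper(cqp)$stability, bestkeeper(cq)$stability)
  expect_equal(genorm(cqp)$stability, genorm(cq)$stability)
  expect_equal(normfinder(cqp)$stability, normfinder(cq)$stability)
})
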