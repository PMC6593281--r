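# Synthetic cohort generator: latent graphs, perturbation, covariance map,
# simulation, cohort writing, parameter recovery.

test_that("make_small_world_graph satisfies its structural contract", {
  g0 <- make_small_world_graph(20, 4, 0, seed = 1)
  expect_true(all(rowSums(g0) == 4))               # lattice degree at p = 0
  expect_equal(sum(g0) / 2, 20 * 4 / 2)
  expect_equal(clustering_coef(g0)$cp, 0.5, tolerance = 1e-12)  # 3(k-2)/(4(k-1))
  expect_equal(as.numeric(char_path_length(g0)), oracle_char_path_length(g0),
               tolerance = 1e-12)
  for (p in c(0.1, 0.5, 1)) {
    g <- make_small_world_graph(20, 4, p, seed = 2)
    expect_equal(sum(g) / 2, 40)                   # edge count preserved
    expect_true(all(diag(g) == 0))
    expect_identical(g, t(g))
  }
  expect_identical(make_small_world_graph(30, 6, 0.3, seed = 5),
                   make_small_world_graph(30, 6, 0.3, seed = 5))
  expect_error(make_small_world_graph(20, 3, 0.1), "even")
  expect_error(make_small_world_graph(4, 4, 0.1), "smaller than n")
  expect_error(make_small_world_graph(20, 4, 1.5), "\\[0, 1\\]")
})

test_that("perturb_group_graph plants clustering without degree blow-up", {
  g0 <- make_small_world_graph(20, 4, 0, seed = 1)
  expect_identical(perturb_group_graph(g0, 0, seed = 1), g0)
  g1 <- perturb_group_graph(g0, 0.2, seed = 3)
  expect_gte(clustering_coef(g1)$cp, 0.5)
  expect_equal(sum(g1) / 2, sum(g0) / 2 + round(0.2 * sum(g0) / 2))
  expect_true(all(g1[g0 == 1] == 1))               # only adds edges
  # every added edge closes a triangle
  added <- which(g1 == 1 & g0 == 0 & upper.tri(g0), arr.ind = TRUE)
  for (r in seq_len(nrow(added))) {
    expect_gt((g0 %*% g0)[added[r, 1], added[r, 2]], 0)
  }
  # saturated graph: no candidate pair remains -> explicit error, no hang
  k5 <- matrix(1L, 5, 5); diag(k5) <- 0L
  expect_error(perturb_group_graph(k5, 0.5, seed = 1), "no closable")
})

test_that("adjacency_to_covariance yields a distance-decaying PD matrix", {
  ring <- make_small_world_graph(20, 4, 0, seed = 1)
  expect_identical(adjacency_to_covariance(ring, 0), diag(20))
  s <- adjacency_to_covariance(ring, 0.1)
  expect_gt(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), 0)
  expect_equal(diag(s), rep(1, 20))
  d <- oracle_distances(ring)
  expect_gt(min(s[d == 1]), max(s[d >= 3]))        # adjacency beats distance >= 3
  lam <- max(abs(eigen(ring, symmetric = TRUE, only.values = TRUE)$values))
  expect_error(adjacency_to_covariance(ring, 1 / lam + 0.01),
               "spectral bound")
})

test_that("simulate_timeseries is seed-deterministic with correct moments", {
  a <- simulate_timeseries(diag(5), 100, seed = 4)
  b <- simulate_timeseries(diag(5), 100, seed = 4)
  expect_equal(a$values, b$values)
  expect_false(identical(a$values,
                         simulate_timeseries(diag(5), 100, seed = 5)$values))
  # identity covariance, long series: sample correlations near zero
  big <- simulate_timeseries(diag(8), 10000, seed = 6, band = NULL)
  r <- stats::cor(big$values)
  expect_lt(mean(abs(r[upper.tri(r)])), 0.05)
  expect_error(simulate_timeseries(matrix(c(1, 2, 2, 1), 2, 2), 100),
               "positive definite")
})

test_that("sample FC recovers the generating correlation structure", {
  ring <- make_small_world_graph(20, 4, 0, seed = 1)
  s <- adjacency_to_covariance(ring, 0.2)
  ts <- simulate_timeseries(s, 2000, seed = 8)
  fc <- pearson_matrix(ts)
  truth <- s; diag(truth) <- 0
  ut <- upper.tri(truth)
  expect_gt(stats::cor(fc$r[ut], truth[ut]), 0.9)
})

test_that("binarized sample FC recovers the latent edge set (T = 2000)", {
  g <- make_small_world_graph(30, 4, 0.3, seed = 2)
  s <- adjacency_to_covariance(g, 0.15)
  ts <- simulate_timeseries(s, 2000, seed = 9)
  dens <- sum(g) / (nrow(g) * (nrow(g) - 1))
  ghat <- sparsity_binarize(pearson_matrix(ts), dens)
  shared <- sum(ghat == 1 & g == 1) / sum(g)
  expect_gt(shared, 0.8)
})

test_that("generate_cohort writes a complete, reproducible cohort", {
  spec <- ground_truth_spec(n_regions = 20, lattice_degree = 4,
                            rewire_prob = 0.25, coupling = 0.1,
                            group_effect = 0.3, seed = 42)
  link <- list(region = 5L, sparsity = 0.2, intercept = 22, beta = 0.35,
               noise_sd = 1)
  dir1 <- tempfile("cohort")
  expect_error(generate_cohort(spec, n_per_group = 3, n_volumes = 60,
                               dir = dir1,
                               score_link = modifyList(link,
                                                       list(region = 28L))),
               "1\\.\\.20")
  mf <- generate_cohort(spec, n_per_group = 3, n_volumes = 60, dir = dir1,
                        score_link = link)
  expect_equal(nrow(mf), 6)
  expect_equal(as.vector(table(mf$group)), c(3L, 3L))
  expect_true(all(file.exists(mf$file)))
  expect_true(file.exists(file.path(dir1, "manifest.csv")))
  ts <- read_subject_ts(mf$file[1])
  expect_equal(dim(ts$values), c(60L, 20L))
  gt <- attr(mf, "ground_truth")
  expect_gte(clustering_coef(gt$patient)$cp, clustering_coef(gt$control)$cp)
  # refuses to overwrite silently
  expect_error(generate_cohort(spec, n_per_group = 3, n_volumes = 60,
                               dir = dir1, score_link = link), "not empty")
  # same seed reproduces byte-identical series; different seed does not
  dir2 <- tempfile("cohort"); dir3 <- tempfile("cohort")
  generate_cohort(spec, n_per_group = 3, n_volumes = 60, dir = dir2,
                  score_link = link)
  generate_cohort(spec, n_per_group = 3, n_volumes = 60, dir = dir3,
                  seed = 43, score_link = link)
  f1 <- readLines(file.path(dir1, basename(mf$file[1])))
  expect_identical(f1, readLines(file.path(dir2, basename(mf$file[1]))))
  expect_false(identical(f1, readLines(file.path(dir3, basename(mf$file[1])))))
  unlink(c(dir1, dir2, dir3), recursive = TRUE)
})

test_that("a noiseless score link is recovered as partial correlation ~ 1", {
  spec <- ground_truth_spec(n_regions = 20, lattice_degree = 4,
                            rewire_prob = 0.25, coupling = 0.1,
                            group_effect = 0, seed = 7)
  dir <- tempfile("cohort")
  mf <- generate_cohort(spec, n_per_group = 6, n_volumes = 60, dir = dir,
                        score_link = list(region = 5L, sparsity = 0.2,
                                          intercept = 20, beta = 0.5,
                                          noise_sd = 0))
  deg <- vapply(mf$file, function(f) {
    g <- sparsity_binarize(pearson_matrix(read_subject_ts(f)), 0.2)
    nodal_degree(g)[5]
  }, numeric(1))
  pc <- partial_correlation(mf$moca, deg)
  expect_gt(pc$r, 0.999)
  unlink(dir, recursive = TRUE)
})

test_that("score-metric link is recovered within sampling error (20 reps)", {
  # regenerate the score from a known linear model on an observed nodal
  # metric and check that the recovered correlation stays inside the 95%
  # sampling band of the generating correlation
  spec <- ground_truth_spec(n_regions = 20, lattice_degree = 4,
                            rewire_prob = 0.25, coupling = 0.1,
                            group_effect = 0, seed = 11)
  dir <- tempfile("cohort")
  mf <- generate_cohort(spec, n_per_group = 15, n_volumes = 60, dir = dir,
                        score_link = list(region = 5L, sparsity = 0.2,
                                          intercept = 20, beta = 0.6,
                                          noise_sd = 1))
  deg <- vapply(mf$file, function(f) {
    g <- sparsity_binarize(pearson_matrix(read_subject_ts(f)), 0.2)
    nodal_degree(g)[5]
  }, numeric(1))
  rho <- 0.6 * stats::sd(deg) / sqrt(0.6^2 * stats::var(deg) + 1)
  set.seed(99)
  r_rec <- vapply(1:20, function(i) {
    score <- 20 + 0.6 * deg + rnorm(length(deg))
    partial_correlation(score, deg)$r
  }, numeric(1))
  band <- tanh(atanh(rho) + c(-1, 1) * 1.96 / sqrt(length(deg) - 3))
  expect_gt(mean(r_rec >= band[1] & r_rec <= band[2]), 0.8)
  unlink(dir, recursive = TRUE)
})

test_that("ground_truth_spec and read_manifest validate their inputs", {
  expect_error(ground_truth_spec(n_regions = 3), "n_regions")
  expect_error(ground_truth_spec(lattice_degree = 5))
  expect_error(ground_truth_spec(rewire_prob = 1.5))
  bad <- tempfile(fileext = ".csv")
  utils::write.csv(data.frame(subject_id = "s1"), bad, row.names = FALSE)
  expect_error(read_manifest(bad), "missing required columns")
})
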