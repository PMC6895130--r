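test_that("icc matches the brute-force ANOVA oracle on random matrices", {
  set.seed(10)
  for (i in 1:10) {
    n <- sample(4:12, 1); k <- sample(2:5, 1)
    x <- matrix(rnorm(n * k, sd = runif(1, 0.5, 3)), n, k)
    expect_equal(icc(x, "agreement")$estimate, icc_oracle(x, "agreement"),
                 tolerance = 1e-12)
    expect_equal(icc(x, "consistency")$estimate, icc_oracle(x, "consistency"),
                 tolerance = 1e-12)
  }
  # small-integer fixture pinned against the oracle
  m <- matrix(c(9, 6, 8, 7, 2, 1, 4, 1, 5, 2, 4, 3), 4, 3)
  expect_equal(icc(m, "agreement")$estimate, icc_oracle(m, "agreement"),
               tolerance = 1e-12)
})

test_that("identical columns give ICC 1; additive shifts split the two types", {
  set.seed(2)
  v <- rnorm(8)
  m <- cbind(v, v, v)
  expect_equal(icc(m, "agreement")$estimate, 1)
  expect_equal(icc(m, "consistency")$estimate, 1)
  shifted <- cbind(v, v + 1, v - 0.5)
  expect_equal(icc(shifted, "consistency")$estimate, 1)
  expect_lt(icc(shifted, "agreement")$estimate, 1)
  # estimate invariance under subject reordering
  p <- sample(8)
  expect_equal(icc(shifted[p, ], "agreement")$estimate,
               icc(shifted, "agreement")$estimate, tolerance = 1e-12)
  # consistency invariant under adding a constant to one column
  m2 <- shifted; m2[, 2] <- m2[, 2] + 3
  expect_equal(icc(m2, "consistency")$estimate,
               icc(shifted, "consistency")$estimate, tolerance = 1e-12)
})

test_that("agreement never exceeds consistency when raters vary more than noise", {
  set.seed(3)
  for (i in 1:20) {
    x <- matrix(rnorm(30), 10, 3) + rep(rnorm(10, sd = 2), 3)
    x <- x + rep(c(0, 1.5, -1), each = 10)   # rater shifts ensure MSC >= MSE
    ms <- icc(x, "agreement")$ms
    if (ms$msc >= ms$mse) {
      expect_lte(icc(x, "agreement")$estimate,
                 icc(x, "consistency")$estimate + 1e-12)
    }
  }
})

test_that("constant ratings are undefined, not an arbitrary number", {
  r <- icc(matrix(5, 4, 3), "agreement")
  expect_true(is.na(r$estimate))
  expect_match(r$note, "undefined")
  expect_error(icc(matrix(c(1, NA, 2, 3, 4, 5), 2, 3)), "complete")
})

test_that("banding follows the guideline boundaries, closed on the left", {
  expect_equal(icc_band(0.9), "excellent")
  expect_equal(icc_band(0.75), "excellent")
  expect_equal(icc_band(0.74), "good")
  expect_equal(icc_band(0.60), "good")
  expect_equal(icc_band(0.59), "fair")
  expect_equal(icc_band(0.40), "fair")
  expect_equal(icc_band(0.19), "poor")
})

test_that("replicate reliability is high for reactive samples, low for a blank", {
  cfg <- sim_config(n_samples = 8, n_epitopes = 50, n_replicates = 3,
                    n_plates = 1, reactivity = c(rep(1, 7), 0),
                    sample_sd = 0.5, seed = 9)
  st <- simulate_study(cfg)
  b <- quantify(st$plates, st$design)
  rel <- replicate_reliability(b)
  reactive <- rel$estimate[1:7]
  expect_true(all(reactive > 0.75))
  expect_true(all(rel$band[1:7] == "excellent"))
  # the non-reactive control sits near the zero floor: low agreement
  expect_lt(rel$estimate[8], 0.4)
  expect_equal(rel$band[8], "poor")
})

test_that("unbalanced replicate groups are skipped with a warning", {
  b <- matrix(rnorm(5 * 4), 5, 4, dimnames = list(NULL, paste0("e", 1:4)))
  bind <- make_binding(b, plate = "p1",
                       sample = c("S1", "S1", "S1", "S2", "S2"),
                       replicate = c(1, 2, 3, 1, 2))
  expect_warning(rel <- replicate_reliability(bind), "skipped")
  expect_true(is.na(rel$estimate[rel$sample == "S2"]))
})

test_that("center reproducibility separates consistency from agreement", {
  set.seed(5)
  base <- matrix(rnorm(6 * 20, sd = 1.5), 6, 20,
                 dimnames = list(paste0("S", 1:6), paste0("e", 1:20)))
  centers <- list(c1 = base, c2 = base + 0.8, c3 = base - 0.5)
  cons <- center_reproducibility(centers, by = "sample", type = "consistency")
  agr <- center_reproducibility(centers, by = "sample", type = "agreement")
  expect_true(all(cons$estimate > 0.999))
  expect_true(all(agr$estimate < cons$estimate))
  # noise monotonicity: more center noise, lower consistency
  noisy1 <- list(c1 = base, c2 = base + matrix(rnorm(120, sd = 0.3), 6, 20))
  noisy2 <- list(c1 = base, c2 = base + matrix(rnorm(120, sd = 1.5), 6, 20))
  m1 <- attr(center_reproducibility(noisy1, by = "sample"), "mean_icc")
  m2 <- attr(center_reproducibility(noisy2, by = "sample"), "mean_icc")
  expect_gt(m1, m2)
  # per-epitope arrangement works too
  bye <- center_reproducibility(centers, by = "epitope")
  expect_equal(nrow(bye), 20)
  # mismatched epitope sets intersect with warning
  centers2 <- list(c1 = base, c2 = base[, 1:15] + 0.1)
  expect_warning(center_reproducibility(centers2, by = "sample"), "intersect")
})

test_that("consistency CIs cover a known ICC about 95% of the time", {
  set.seed(123)
  sigma_a <- 1; sigma_e <- 0.6
  truth <- sigma_a^2 / (sigma_a^2 + sigma_e^2)
  rater_shift <- c(0, 0.4, -0.3)
  hits <- replicate(400, {
    subj <- rnorm(25, 0, sigma_a)
    x <- outer(subj, rater_shift, "+") + matrix(rnorm(75, 0, sigma_e), 25, 3)
    r <- icc(x, "consistency")
    r$ci_low <= truth && truth <= r$ci_high
  })
  expect_gt(mean(hits), 0.92); expect_lt(mean(hits), 0.98)
})

test_that("replicate trees cluster triplicates into clades and round-trip Newick", {
  cfg <- sim_config(n_samples = 6, n_epitopes = 40, n_replicates = 3,
                    n_plates = 1, sample_sd = 1, profile_sd = 1,
                    noise_sd = 0.15, seed = 14)
  st <- simulate_study(cfg)
  b <- quantify(st$plates, st$design)
  labs <- paste(b$meta$sample, b$meta$replicate, sep = "_")
  tr <- replicate_tree(b, labels = labs)
  for (s in unique(b$meta$sample)) {
    tips <- labs[b$meta$sample == s]
    expect_true(ape::is.monophyletic(tr$phylo, tips))
  }
  # Newick round-trip preserves topology and heights
  path <- tempfile(fileext = ".nwk")
  write_newick(tr, path)
  back <- ape::read.tree(path)
  expect_equal(ape::dist.topo(ape::unroot(back), ape::unroot(tr$phylo))[1], 0)
  expect_equal(sort(ape::node.depth.edgelength(back)),
               sort(ape::node.depth.edgelength(tr$phylo)), tolerance = 1e-6)
})

test_that("tree distances equal a brute-force rank-correlation oracle", {
  set.seed(6)
  m <- matrix(rnorm(4 * 12), 4, 12, dimnames = list(paste0("r", 1:4), NULL))
  tr <- replicate_tree(m)
  d <- as.matrix(tr$dist)
  for (i in 1:3) for (j in (i + 1):4) {
    ri <- rank(m[i, ]); rj <- rank(m[j, ])
    rho <- sum((ri - mean(ri)) * (rj - mean(rj))) /
      sqrt(sum((ri - mean(ri))^2) * sum((rj - mean(rj))^2))
    expect_equal(unname(d[i, j]), 1 - rho, tolerance = 1e-12)
  }
  # identical rows merge at height zero
  m2 <- rbind(a = m[1, ], b = m[1, ], c = m[2, ], d = m[3, ])
  tr2 <- replicate_tree(m2)
  expect_equal(min(tr2$hclust$height), 0)
  # constant rows are dropped with a warning
  m3 <- rbind(m, flat = rep(1, 12))
  expect_warning(replicate_tree(m3), "constant")
})
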