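test_that("shrinkage limits behave: d0 = 0 is classical, d0 = Inf pools fully", {
  set.seed(1)
  s2 <- rchisq(20, 5) / 5
  eb0 <- ebayes_shrink(s2, df = 5, d0 = 0)
  expect_equal(eb0$s_tilde_sq, s2)
  ebi <- ebayes_shrink(s2, df = 5, d0 = Inf)
  expect_equal(unique(ebi$s_tilde_sq), mean(s2))
  # monotone shrinkage toward s0 for any finite positive d0
  eb <- ebayes_shrink(s2, df = 5)
  expect_true(all(abs(eb$s_tilde_sq - eb$s0_sq) <= abs(s2 - eb$s0_sq) + 1e-12))
  # degenerate inputs
  expect_warning(ebz <- ebayes_shrink(c(0, 1, 2), df = 3), "zero variance")
  expect_true(all(ebz$s_tilde_sq > 0))
  expect_warning(ebc <- ebayes_shrink(c(1, 1, 1), df = 3), "identical")
  expect_identical(ebc$d0, Inf)
})

test_that("prior parameters are recovered from a generative model", {
  set.seed(11)
  d0 <- 4; s0 <- 0.04; df <- 7
  sigma2 <- d0 * s0 / rchisq(5000, d0)
  s2 <- sigma2 * rchisq(5000, df) / df
  eb <- ebayes_shrink(s2, df)
  expect_equal(eb$d0, d0, tolerance = 0.1)
  expect_equal(eb$s0_sq, s0, tolerance = 0.1)
})

test_that("shrinkage agrees with an independent empirical-Bayes implementation", {
  set.seed(21)
  s2 <- 0.04 * 4 / rchisq(300, 4) * rchisq(300, 6) / 6
  eb <- ebayes_shrink(s2, df = 6)
  sq <- limma::squeezeVar(s2, df = 6)
  expect_equal(eb$d0, sq$df.prior, tolerance = 1e-6)
  expect_equal(eb$s0_sq, sq$var.prior, tolerance = 1e-6)
  expect_equal(eb$s_tilde_sq, sq$var.post, tolerance = 1e-8)
})

test_that("moderated paired test requires pairing and handles a null epitope", {
  pos <- matrix(c(1, 1, 1, 2, 3, 4), 2, 3, byrow = TRUE,
                dimnames = list(c("null", "up"), paste0("r", 1:3)))
  neg <- matrix(c(1, 1, 1, 0, 0, 0), 2, 3, byrow = TRUE,
                dimnames = dimnames(pos))
  expect_error(moderated_paired_test(pos, neg), "pairing")
  # the all-zero difference row has zero variance, which is flagged
  expect_warning(
    res <- moderated_paired_test(pos, neg,
                                 pairing = data.frame(pos = colnames(pos),
                                                      neg = colnames(neg))),
    "zero variance")
  i <- which(res$epitope == "null")
  expect_equal(res$t_mod[i], 0)
  expect_equal(res$p[i], 1)
  expect_false(res$detected[i])
})

test_that("d0 = 0 bypass reproduces the hand-computed classical paired t", {
  pos <- rbind(e1 = c(3.1, 2.8, 3.4), e2 = c(1.2, 1.1, 0.9))
  neg <- rbind(e1 = c(1.0, 1.2, 0.8), e2 = c(1.0, 1.1, 1.2))
  colnames(pos) <- colnames(neg) <- c("a", "b", "c")
  res <- moderated_paired_test(pos, neg, d0 = 0,
                               pairing = data.frame(colnames(pos), colnames(neg)))
  for (e in c("e1", "e2")) {
    d <- pos[e, ] - neg[e, ]
    tt <- t.test(d)
    i <- which(res$epitope == e)
    expect_equal(res$t_mod[i], unname(tt$statistic), tolerance = 1e-12)
    expect_equal(res$p[i], tt$p.value, tolerance = 1e-12)
    # effect size identity: t_classical / sqrt(n)
    expect_equal(res$effect_size[i], unname(tt$statistic) / sqrt(3),
                 tolerance = 1e-12)
  }
})

test_that("moderated p-values converge to classical ones as d0 -> 0", {
  set.seed(31)
  pos <- matrix(rnorm(40, 1), 5, 8); neg <- matrix(rnorm(40), 5, 8)
  colnames(pos) <- colnames(neg) <- paste0("r", 1:8)
  pairing <- data.frame(colnames(pos), colnames(neg))
  p_bypass <- moderated_paired_test(pos, neg, pairing, d0 = 0)$p
  p_tiny <- moderated_paired_test(pos, neg, pairing, d0 = 1e-12)$p
  expect_lt(max(abs(p_bypass - p_tiny)), 1e-10)
})

test_that("detection power and day-shift immunity hold in the paired design", {
  sim <- simulate_detection_experiment(n_epitopes = 66, n_pairs = 8,
                                       delta = 1, noise_sd = 0.2,
                                       day_shift = 0.7, seed = 4)
  res <- moderated_paired_test(sim$pos, sim$neg, sim$pairing)
  expect_equal(mean(res$detected[sim$truth$true_positive]), 1)
})

test_that("differential binding applies the conjunctive fold-change/FDR gate", {
  set.seed(41)
  n <- 20
  grp <- rep(c("ctl", "case"), each = n / 2)
  base <- matrix(rnorm(n * 3, sd = 1e-4), n, 3,
                 dimnames = list(NULL, c("big", "small", "null")))
  base[grp == "case", "big"] <- base[grp == "case", "big"] + 1.0
  base[grp == "case", "small"] <- base[grp == "case", "small"] + log2(1.4)
  res <- differential_binding(base, grp)
  expect_true(res$detected[res$epitope == "big"])        # fch 2.0, p ~ 0
  i <- which(res$epitope == "small")
  expect_lt(res$fdr[i], 0.05)                            # p passes...
  expect_false(res$detected[i])                          # ...but fch 1.4 < 1.5
  expect_false(res$detected[res$epitope == "null"])
  expect_error(differential_binding(base, rep("one", n)), "2 levels")
  expect_error(differential_binding(base[1:3, ], grp[c(1, 1, 11)]), ">= 2 samples")
  # covariate identical to group -> rank error
  expect_error(differential_binding(base, grp,
                                    covariates = data.frame(copy = grp)),
               "rank deficient")
})

test_that("null group differences yield almost no significant epitopes", {
  set.seed(51)
  X <- matrix(rnorm(24 * 50), 24, 50)
  res <- differential_binding(X, rep(c("a", "b"), each = 12))
  expect_lte(sum(res$detected), 1)
})

test_that("BH adjustment equals the step-up oracle and restores input order", {
  expect_equal(bh_fdr(0.037), 0.037)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(61)
  for (i in 1:20) {
    p <- round(runif(sample(2:8, 1)), 2)
    expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_fdr(c(0.5, -0.1)), "\\[0, 1\\]")
})

test_that("the isotype contrast is a log-scale difference and anti-symmetric", {
  igg4 <- matrix(c(7.81, 2, 0, 1), 2, 2)
  ige <- matrix(c(2.4, 2, 1, 0), 2, 2)
  d <- igg4_ige_contrast(igg4, ige)
  expect_equal(d[1, 1], 5.41)
  expect_equal(d[1, 2], -1)
  expect_equal(attr(d, "isotype"), "IgG4-IgE")
  expect_equal(unclass(igg4_ige_contrast(ige, igg4)), -unclass(d),
               ignore_attr = TRUE)
  expect_true(all(igg4_ige_contrast(igg4, igg4) == 0))
  expect_error(igg4_ige_contrast(igg4, ige[1, , drop = FALSE]), "dimensions")
})
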