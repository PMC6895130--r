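test_that("noiseless plate shift is recovered exactly and removal is idempotent", {
  b0 <- matrix(rep(c(2, 3, 4, 2, 3, 4), 2), 6, 2,
               dimnames = list(NULL, c("e1", "e2")))
  b0[4:6, ] <- b0[4:6, ] + 1          # plate 2 shifted by +1
  bind <- make_binding(b0, plate = rep(c("p1", "p2"), each = 3),
                       sample = paste0("S", 1:6))
  fit <- fit_plate_model(bind)
  expect_equal(unname(fit$gamma[, "p2"]), c(1, 1), tolerance = 1e-12)
  adj <- remove_plate_effects(bind, fit)
  # reference-plate rows unchanged; plate-2 rows shifted down by exactly 1
  expect_equal(adj$b[1:3, ], bind$b[1:3, ])
  expect_equal(adj$b[4:6, ], bind$b[4:6, ] - 1)
  # refit on adjusted data: gamma ~ 0; re-adjustment changes nothing
  refit <- fit_plate_model(adj)
  expect_lt(max(abs(refit$gamma)), 1e-8)
  adj2 <- remove_plate_effects(adj, refit)
  expect_equal(adj2$b, adj$b, tolerance = 1e-10)
  # within-plate contrasts are invariant under adjustment
  expect_equal(diff(adj$b[4:6, 1]), diff(bind$b[4:6, 1]))
})

test_that("complete plate/diagnosis confounding raises the rank error", {
  b0 <- matrix(rnorm(12), 6, 2, dimnames = list(NULL, c("e1", "e2")))
  bind <- make_binding(b0, plate = rep(c("p1", "p2"), each = 3),
                       sample = paste0("S", 1:6),
                       extra = data.frame(diagnosis = rep(c("allergic", "control"),
                                                          each = 3)))
  expect_error(fit_plate_model(bind, terms = "diagnosis"), "confounded")
})

test_that("null plate effects are covered by 2-SE intervals ~95% of the time", {
  cfg <- sim_config(n_samples = 48, n_epitopes = 40, n_replicates = 2,
                    n_plates = 2, sample_sd = 0, profile_sd = 0,
                    noise_sd = 0.3, seed = 61)
  st <- simulate_study(cfg)
  b <- quantify(st$plates, st$design, nsb = FALSE)
  fit <- fit_plate_model(b)
  cover <- mean(abs(fit$gamma) <= 2 * fit$gamma_se)
  expect_gt(cover, 0.88)
})

test_that("gamma error shrinks with samples per plate", {
  mae <- sapply(c(12, 48), function(n) {
    cfg <- sim_config(n_samples = 2 * n, n_epitopes = 30, n_replicates = 1,
                      n_plates = 2, plate_effects = c(0, 0.4),
                      sample_sd = 0, profile_sd = 0, noise_sd = 0.3,
                      seed = 100 + n)
    st <- simulate_study(cfg)
    fit <- fit_plate_model(quantify(st$plates, st$design, nsb = FALSE))
    mean(abs(fit$gamma[, 1] - 0.4))
  })
  # 4x the samples should roughly halve the error
  expect_lt(mae[2], mae[1] / 1.4)
})

test_that("mixed-model variant estimates plate effects with a subject intercept", {
  cfg <- sim_config(n_samples = 24, n_epitopes = 5, n_replicates = 2,
                    n_plates = 2, plate_effects = c(0, 0.6),
                    sample_sd = 0.8, profile_sd = 0, noise_sd = 0.2, seed = 77)
  st <- simulate_study(cfg)
  b <- quantify(st$plates, st$design, nsb = FALSE)
  b$meta$subject <- b$meta$sample
  fit <- fit_plate_model(b, random_subject = "subject")
  expect_equal(fit$method, "mixed")
  expect_equal(unname(colMeans(fit$gamma)), 0.6, tolerance = 0.25)
})

test_that("well coefficients come back in reading order with calibrated nulls", {
  cfg <- sim_config(n_samples = 62, n_epitopes = 6, n_replicates = 3,
                    n_plates = 2, sample_sd = 1, profile_sd = 0.5,
                    noise_sd = 0.3, randomize_wells = TRUE, seed = 7)
  st <- simulate_study(cfg)
  b <- quantify(st$plates, st$design)
  wf <- fit_well_effects(b)
  one <- wf[wf$epitope == wf$epitope[1], ]
  expect_equal(one$reading_index, sort(one$reading_index))
  expect_true(all(wf$ci_low <= wf$estimate & wf$estimate <= wf$ci_high))
  excl <- mean(wf$ci_low > 0 | wf$ci_high < 0)
  expect_gt(excl, 0.005); expect_lt(excl, 0.12)
  # row-H shift is recovered
  omega <- rep(0, 96); omega[85:96] <- 0.5
  cfg2 <- sim_config(n_samples = 62, n_epitopes = 6, n_replicates = 3,
                     n_plates = 2, well_effects = omega, sample_sd = 1,
                     profile_sd = 0.5, noise_sd = 0.3,
                     randomize_wells = TRUE, seed = 8)
  st2 <- simulate_study(cfg2)
  wf2 <- fit_well_effects(quantify(st2$plates, st2$design))
  hrow <- wf2[wf2$reading_index >= 84, ]
  expect_gt(mean(hrow$ci_low <= 0.5 & hrow$ci_high >= 0.5), 0.85)
  # unreplicated single-plate layout is confounded
  cfg3 <- sim_config(n_samples = 31, n_epitopes = 2, n_replicates = 3,
                     n_plates = 1, randomize_wells = TRUE, seed = 9)
  st3 <- simulate_study(cfg3)
  expect_error(fit_well_effects(quantify(st3$plates, st3$design)),
               "confounded")
})

test_that("PVCA attributes a clean group split entirely to the group factor", {
  set.seed(2)
  X <- matrix(rnorm(40 * 20, sd = 0.01), 40, 20)
  X[21:40, ] <- X[21:40, ] + matrix(rnorm(20, sd = 2), 40 - 20, 20, byrow = TRUE)
  fac <- data.frame(group = rep(c("a", "b"), each = 20))
  pv <- pvca(X, fac, pc_threshold = 0.8)
  expect_gt(pv$wapv[["group"]], 0.9)
  expect_lt(pv$wapv[["residual"]], 0.1)
  expect_equal(sum(pv$wapv), 1, tolerance = 1e-9)
})

test_that("PVCA gives pure noise to the residual and recovers a 1:9 split", {
  set.seed(3)
  X <- matrix(rnorm(60 * 30), 60, 30)
  fac <- data.frame(arbitrary = rep(c("a", "b", "c"), each = 20))
  pv <- pvca(X, fac)
  expect_lt(pv$wapv[["arbitrary"]], 0.1)
  expect_gt(pv$wapv[["residual"]], 0.9)
  # plate profile variance : residual = 1 : 9, averaged over replicate draws
  wapv_plate <- sapply(8:10, function(seed) {
    set.seed(seed)
    n_per <- 12; n_plate <- 8; n_epi <- 40
    plate <- rep(paste0("p", 1:n_plate), each = n_per)
    plate_profiles <- matrix(rnorm(n_plate * n_epi, sd = 1), n_plate, n_epi)
    X2 <- plate_profiles[rep(1:n_plate, each = n_per), ] +
      matrix(rnorm(n_per * n_plate * n_epi, sd = 3), n_per * n_plate, n_epi)
    pvca(X2, data.frame(plate = plate))$wapv[["plate"]]
  })
  expect_lt(abs(mean(wapv_plate) - 0.1), 0.05)
  # permutation invariance of factor order
  set.seed(8)
  n_per <- 20; n_plate <- 4; n_epi <- 40
  plate <- rep(paste0("p", 1:n_plate), each = n_per)
  X2 <- matrix(rnorm(n_plate * n_epi, sd = 1), n_plate, n_epi)[
    rep(1:n_plate, each = n_per), ] +
    matrix(rnorm(n_per * n_plate * n_epi, sd = 3), n_per * n_plate, n_epi)
  fac2 <- data.frame(plate = plate, junk = rep(c("x", "y"), n_per * n_plate / 2))
  pvA <- pvca(X2, fac2)
  pvB <- pvca(X2, fac2[, c("junk", "plate")])
  expect_equal(pvA$wapv[c("plate", "junk", "residual")],
               pvB$wapv[c("plate", "junk", "residual")], tolerance = 1e-8)
})

test_that("single-level PVCA factors are dropped with a warning", {
  set.seed(1)
  X <- matrix(rnorm(30 * 10), 30, 10)
  expect_warning(pv <- pvca(X, data.frame(ok = rep(c("a", "b"), 15),
                                          flat = "z")),
                 "single-level")
  expect_false("flat" %in% names(pv$wapv))
})
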