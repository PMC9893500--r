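test_that("pedigree realizes the configured parent overlap exactly", {
  cfg <- simulation_config(seed = 123)
  ped <- simulate_pedigree(cfg)
  st <- attr(ped, "steers")
  sires_of <- function(yr) {
    unique(ped$sire[match(st$animal[st$year == yr], ped$animal)])
  }
  dams_of <- function(yr) {
    unique(ped$dam[match(st$animal[st$year == yr], ped$animal)])
  }
  expect_length(intersect(sires_of(1), sires_of(2)), 8)
  expect_length(sires_of(1), 24)
  expect_length(sires_of(2), 24)
  expect_length(intersect(dams_of(1), dams_of(2)), 19)
  # every steer has both parents; founders have none
  steers <- ped[ped$animal %in% st$animal, ]
  expect_false(anyNA(steers$sire))
  expect_false(anyNA(steers$dam))
  founders <- attr(ped, "founders")
  expect_true(all(is.na(ped$sire[ped$animal %in% founders])))
})

test_that("single-year pedigrees use every parent once, no overlap logic", {
  cfg <- simulation_config(n_years = 1, seed = 5)
  ped <- simulate_pedigree(cfg)
  st <- attr(ped, "steers")
  expect_equal(nrow(st), 80)
  expect_length(unique(ped$dam[!is.na(ped$dam)]), 80)
  expect_length(unique(ped$sire[!is.na(ped$sire)]), 24)
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 9)
  p1 <- simulate_pedigree(cfg)
  p2 <- simulate_pedigree(cfg)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write.table(p1, f1, row.names = FALSE)
  write.table(p2, f2, row.names = FALSE)
  expect_identical(readLines(f1), readLines(f2))

  s1 <- simulate_temperature_series("A1", 39.8, 0.25, 16, 3, cfg, seed = 3)
  s2 <- simulate_temperature_series("A1", 39.8, 0.25, 16, 3, cfg, seed = 3)
  expect_identical(s1, s2)

  w1 <- simulate_weather("2016-11-16", 30, seed = 4)
  w2 <- simulate_weather("2016-11-16", 30, seed = 4)
  expect_identical(w1, w2)
})

test_that("infeasible configurations are rejected with a message", {
  expect_error(simulation_config(sire_overlap_fraction = 1.2),
               "proportions")
  expect_error(simulation_config(n_sires = 0), "positive")
  cfg <- simulation_config(n_dams = 90, n_steers_per_year = 80)
  expect_error(simulate_pedigree(cfg), "dam")
  expect_error(simulation_config(G0 = matrix(c(1, 2, 2, 1), 2)),
               "semidefinite")
})

test_that("zero G0 produces zero additive values (pure-noise phenotypes)", {
  ped <- data.frame(animal = c("S", "D", "O1", "O2"),
                    sire = c(NA, NA, "S", "S"), dam = c(NA, NA, "D", "D"))
  gv <- simulate_genetic_values(ped, matrix(0, 2, 2), diag(2), seed = 1)
  expect_true(all(gv$additive$a_fw == 0))
  expect_true(all(gv$additive$a_ws == 0))
  expect_gt(sd(gv$phenotypes$fw), 0)
})

test_that("additive values have covariance A kron G0 across replicates", {
  ped <- data.frame(animal = c("S", "D1", "D2", "O1", "O2", "O3"),
                    sire = c(NA, NA, NA, "S", "S", "S"),
                    dam = c(NA, NA, NA, "D1", "D1", "D2"))
  A <- additive_relationship_matrix(ped)
  G0 <- matrix(c(1, 0.5, 0.5, 2), 2)
  set.seed(33)
  n_rep <- 2000
  draws <- array(NA_real_, c(n_rep, nrow(A), 2))
  for (r in seq_len(n_rep)) {
    gv <- simulate_genetic_values(ped, G0, diag(2))
    m <- match(rownames(A), gv$additive$animal_id)
    draws[r, , ] <- as.matrix(gv$additive[m, c("a_fw", "a_ws")])
  }
  # spot-check representative entries of cov(a) against A[i,j] * G0[s,t],
  # tolerance 3 Monte-Carlo SEs of the empirical covariance
  cases <- rbind(c(4, 5, 1, 1), c(4, 5, 1, 2), c(4, 6, 2, 2),
                 c(4, 4, 1, 2), c(1, 4, 1, 1))
  for (k in seq_len(nrow(cases))) {
    i <- cases[k, 1]; j <- cases[k, 2]; s <- cases[k, 3]; t <- cases[k, 4]
    prod <- draws[, i, s] * draws[, j, t]
    se <- sd(prod) / sqrt(n_rep)
    expect_lt(abs(mean(prod) - A[i, j] * G0[s, t]), 3 * se + 1e-8)
  }
})

test_that("full sibs correlate 0.5 under unit G0 (brute-force Monte Carlo)", {
  ped <- data.frame(animal = c("S", "D", "O1", "O2"),
                    sire = c(NA, NA, "S", "S"), dam = c(NA, NA, "D", "D"))
  set.seed(44)
  n_rep <- 1e4
  sib <- matrix(NA_real_, n_rep, 2)
  for (r in seq_len(n_rep)) {
    gv <- simulate_genetic_values(ped, diag(2), diag(2))
    a <- gv$additive
    sib[r, ] <- a$a_fw[match(c("O1", "O2"), a$animal_id)]
  }
  expect_equal(cor(sib[, 1], sib[, 2]), 0.5, tolerance = 0.03)
})

test_that("noiseless rhythm generator peaks at the acrophase with 2x amplitude range", {
  cfg <- simulation_config(artifact_rate = 0, glitch_rate = 0,
                           dropout_rate = 0, noise_sd = 0, seed = 1)
  sim <- simulate_temperature_series("A1", 39.8, 0.25, 16, days = 1,
                                     config = cfg, mesor_ar1_sd = 0,
                                     seed = 1)
  expect_equal(sim$time_h[which.max(sim$temp_c)], 16)
  expect_equal(max(sim$temp_c) - min(sim$temp_c), 0.5, tolerance = 1e-10)
  expect_equal(nrow(sim), 288)

  flat <- simulate_temperature_series("A1", 39.8, 0, 16, days = 1,
                                      config = cfg, mesor_ar1_sd = 0,
                                      seed = 1)
  expect_equal(flat$temp_c, rep(39.8, 288))
})

test_that("injected artifacts are recoverable from the truth channel", {
  cfg <- simulation_config(artifact_rate = 8, glitch_rate = 0.01,
                           dropout_rate = 0, seed = 6)
  sim <- simulate_temperature_series("A1", 39.8, 0.25, 16, days = 5,
                                     config = cfg, seed = 6)
  expect_gt(sum(sim$truth_artifact), 0)
  expect_gt(sum(sim$truth_glitch), 0)
  # artifact-corrupted samples all lie below the clean trace
  art <- sim$truth_artifact & !sim$truth_glitch
  expect_true(all(sim$temp_c[art] < sim$truth_clean[art] + 3 * cfg$noise_sd))
  # glitches land outside the physiological range
  expect_true(all(sim$temp_c[sim$truth_glitch] < 32 |
                    sim$temp_c[sim$truth_glitch] > 42))
  expect_error(
    simulate_temperature_series("A1", 39.8, -0.1, 16, 1, cfg), "amplitude")
})

test_that("ambient coupling shifts the trace by slope times anomaly", {
  cfg <- simulation_config(artifact_rate = 0, glitch_rate = 0,
                           dropout_rate = 0, noise_sd = 0,
                           ambient_coupling = -0.011, seed = 2)
  amb <- data.frame(dry_bulb = c(-20, -10, 0))
  sim <- simulate_temperature_series("A1", 39.8, 0, 16, days = 3,
                                     config = cfg, ambient = amb,
                                     mesor_ar1_sd = 0, seed = 2)
  day_means <- tapply(sim$temp_c, sim$date, mean)
  expect_equal(unname(day_means[1] - day_means[3]),
               -0.011 * (-20 - 0), tolerance = 1e-10)
})

test_that("weather generator hits the seasonal window means", {
  fw <- simulate_weather("2016-11-16", 85, seed = 11)
  ws <- simulate_weather("2017-02-23", 78, seed = 12)
  expect_lt(abs(mean(fw$dry_bulb) - (-11.7)), 3)
  expect_lt(abs(mean(ws$dry_bulb) - (-0.8)), 3)
  expect_gt(mean(fw$relative_humidity), mean(ws$relative_humidity))
  expect_true(all(fw$relative_humidity >= 0 & fw$relative_humidity <= 100))
  expect_equal(fw$thi, thi(fw$dry_bulb, fw$relative_humidity))
})

test_that("performance generator honours its own truth channel", {
  n <- 30
  sim0 <- simulate_performance(sprintf("A%02d", 1:n), adg_true = 0.9,
                               start_wt = 262, wt_noise_sd = 0, seed = 3)
  for (d in split(sim0$weights, sim0$weights$animal_id)) {
    expect_equal(compute_adg(d$day, d$weight_kg)$adg, 0.9,
                 tolerance = 1e-10)
  }
  expect_lt(abs(mean(sim0$truth$rfi_true)), 1e-12)
})

test_that("intake regression recovers the generating coefficients at large n", {
  n <- 1e4
  set.seed(13)
  beta <- c(0.5, 2.2, 0.09, 0.05)
  sim <- simulate_performance(sprintf("A%05d", 1:n),
                              adg_true = rnorm(n, 0.85, 0.15),
                              start_wt = rnorm(n, 262, 16),
                              beta = beta, seed = 13)
  tr <- sim$truth
  perf <- sim$performance
  X <- cbind(1, tr$adg_true, tr$mwt_true, perf$d_bkft)
  bhat <- solve(crossprod(X), crossprod(X, perf$dmi))
  expect_equal(bhat[, 1], beta, tolerance = 0.02, ignore_attr = TRUE)
})

test_that("offspring-midparent regression recovers the simulated heritability", {
  # 300 unrelated trios, phenotype = a + e with equal variances (h2 = 0.5)
  n_fam <- 300
  ped <- data.frame(
    animal = c(sprintf("S%03d", 1:n_fam), sprintf("D%03d", 1:n_fam),
               sprintf("O%03d", 1:n_fam)),
    sire = c(rep(NA, 2 * n_fam), sprintf("S%03d", 1:n_fam)),
    dam = c(rep(NA, 2 * n_fam), sprintf("D%03d", 1:n_fam)))
  gv <- simulate_genetic_values(ped, diag(2), diag(2),
                                phenotyped = ped$animal, seed = 17)
  ph <- gv$phenotypes
  mid <- (ph$fw[1:n_fam] + ph$fw[(n_fam + 1):(2 * n_fam)]) / 2
  off <- ph$fw[(2 * n_fam + 1):(3 * n_fam)]
  slope <- coef(lm(off ~ mid))[2]
  expect_equal(unname(slope), 0.5, tolerance = 0.15)
})
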