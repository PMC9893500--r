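test_that("A-matrix reproduces textbook relationships", {
  ped <- data.frame(animal = c("S", "D", "O"), sire = c(NA, NA, "S"),
                    dam = c(NA, NA, "D"))
  A <- additive_relationship_matrix(ped)
  expect_equal(A["S", "O"], 0.5)
  expect_equal(diag(A), c(S = 1, D = 1, O = 1))

  sibs <- data.frame(animal = c("S", "D", "O1", "O2"),
                     sire = c(NA, NA, "S", "S"),
                     dam = c(NA, NA, "D", "D"))
  expect_equal(additive_relationship_matrix(sibs)["O1", "O2"], 0.5)

  half <- data.frame(animal = c("S", "D1", "D2", "O1", "O2"),
                     sire = c(NA, NA, NA, "S", "S"),
                     dam = c(NA, NA, NA, "D1", "D2"))
  expect_equal(additive_relationship_matrix(half)["O1", "O2"], 0.25)

  inbred <- data.frame(animal = c("S", "D", "O1", "O2", "X"),
                       sire = c(NA, NA, "S", "S", "O1"),
                       dam = c(NA, NA, "D", "D", "O2"))
  A5 <- additive_relationship_matrix(inbred)
  expect_equal(A5["X", "X"], 1.25) # F = 0.25 from full-sib mating
})

test_that("A-matrix agrees with the path-counting oracle on small pedigrees", {
  peds <- list(
    data.frame(animal = c("A", "B", "C", "D", "E", "F"),
               sire = c(NA, NA, "A", "A", "C", "C"),
               dam = c(NA, NA, "B", "B", "D", "D")),
    data.frame(animal = c("S1", "S2", "D1", "D2", "X", "Y", "Z"),
               sire = c(NA, NA, NA, NA, "S1", "S2", "X"),
               dam = c(NA, NA, NA, NA, "D1", "D1", "Y")),
    {
      cfg <- simulation_config(n_years = 2, n_steers_per_year = 2,
                               n_sires = 2, n_dams = 2,
                               sire_overlap_fraction = 0.5,
                               dam_overlap_fraction = 0.5, seed = 4)
      simulate_pedigree(cfg)
    })
  for (ped in peds) {
    A <- additive_relationship_matrix(ped)
    expect_lte(nrow(A), 12)
    for (i in rownames(A)) {
      for (j in colnames(A)) {
        expect_equal(A[i, j], oracle_relationship(ped, i, j),
                     tolerance = 1e-12,
                     label = paste("A[", i, ",", j, "]"))
      }
    }
  }
})

test_that("A-inverse from Henderson's rules inverts the tabular A", {
  set.seed(2)
  cfg <- simulation_config(n_years = 2, n_steers_per_year = 10,
                           n_sires = 3, n_dams = 10,
                           sire_overlap_fraction = 1 / 3,
                           dam_overlap_fraction = 0.2, seed = 2)
  ped <- simulate_pedigree(cfg)
  A <- additive_relationship_matrix(ped)
  Ai <- ainverse(ped)
  expect_lt(max(abs(A %*% Ai - diag(nrow(A)))), 1e-8)
})

test_that("pedigree cycles are fatal and reported", {
  bad <- data.frame(animal = c("A", "B", "C"), sire = c("C", "A", "B"),
                    dam = c(NA, NA, NA))
  expect_error(sort_pedigree(bad), "cycle")
})

test_that("chain geometry stores floor((n_iter - burn_in)/thin) samples", {
  expect_identical(n_stored_samples(1e6, 1e5, 250), 3600L)
  expect_identical(n_stored_samples(chain_config(20000, 2000, 10)), 1800L)
  expect_error(chain_config(n_iter = 100, burn_in = 200))
  expect_error(chain_config(thin = 0))
})

small_biv_data <- function(seed = 31, n_sires = 6, n_steers = 24) {
  cfg <- simulation_config(n_years = 2, n_steers_per_year = n_steers,
                           n_sires = n_sires, n_dams = n_steers,
                           sire_overlap_fraction = 1 / n_sires,
                           dam_overlap_fraction = 0.1, seed = seed)
  ped <- simulate_pedigree(cfg)
  st <- attr(ped, "steers")
  gv <- simulate_genetic_values(ped, diag(2), diag(2),
                                phenotyped = st$animal, seed = seed + 1)
  ph <- gv$phenotypes
  ph$year <- st$year[match(ph$animal_id, st$animal)]
  list(ped = ped, ph = ph)
}

test_that("stored sample count of a real chain matches the geometry", {
  d <- small_biv_data()
  fit <- gibbs_bivariate(d$ph, c("fw", "ws"), ~ factor(year), d$ped,
                         chain_config(1100, 100, 7), seed = 1)
  expect_equal(fit$n_stored, n_stored_samples(1100, 100, 7))
  expect_equal(nrow(fit$samples), (1100 - 100) %/% 7)
})

test_that("chains are reproducible under a fixed seed", {
  d <- small_biv_data()
  f1 <- gibbs_bivariate(d$ph, c("fw", "ws"), ~ factor(year), d$ped,
                        chain_config(600, 100, 5), seed = 99)
  f2 <- gibbs_bivariate(d$ph, c("fw", "ws"), ~ factor(year), d$ped,
                        chain_config(600, 100, 5), seed = 99)
  expect_identical(f1$samples, f2$samples)
})

test_that("posterior h2 concentrates near zero when simulated h2 is zero", {
  cfg <- simulation_config(seed = 41)
  ped <- simulate_pedigree(cfg)
  st <- attr(ped, "steers")
  gv <- simulate_genetic_values(ped, G0 = matrix(0, 2, 2), R0 = diag(2),
                                phenotyped = st$animal, seed = 42)
  ph <- gv$phenotypes
  ph$year <- st$year[match(ph$animal_id, st$animal)]
  expect_true(all(abs(gv$additive$a_fw) < 1e-12))
  # near-flat prior so the concentration at zero reflects the data, not
  # the regularizing default scale
  fit <- gibbs_bivariate(ph, c("fw", "ws"), ~ factor(year), ped,
                         chain_config(20000, 2000, 10,
                                      prior_g = 0.01 * diag(2),
                                      prior_r = 0.01 * diag(2)),
                         seed = 43)
  sm <- summarize_posterior(fit)
  expect_lt(sm$hpd_upper[sm$parameter == "h2_1"], 0.2)
  expect_lt(sm$hpd_upper[sm$parameter == "h2_2"], 0.2)
})

test_that("posterior summaries are stable across seeds at long chain length", {
  d <- small_biv_data(seed = 51, n_sires = 8, n_steers = 40)
  f1 <- gibbs_bivariate(d$ph, c("fw", "ws"), ~ factor(year), d$ped,
                        chain_config(50000, 5000, 20), seed = 7)
  f2 <- gibbs_bivariate(d$ph, c("fw", "ws"), ~ factor(year), d$ped,
                        chain_config(50000, 5000, 20), seed = 8)
  s1 <- summarize_posterior(f1)
  s2 <- summarize_posterior(f2)
  for (p in c("h2_1", "h2_2")) {
    expect_lt(abs(s1$mean[s1$parameter == p] - s2$mean[s2$parameter == p]),
              0.03)
  }
})

test_that("no-pedigree univariate reduction matches the conjugate posterior", {
  set.seed(61)
  n <- 60
  y <- rnorm(n, 5, 2)
  X <- matrix(1, n, 1)
  out <- gibbs_univariate(y, X, n_iter = 30000, burn_in = 2000,
                          prior_scale_e = 1, prior_df_e = 1, seed = 62)
  s2 <- out$samples$sigma2_e
  # closed form: with b integrated over its flat prior, the marginal
  # posterior of sigma2 is scaled inverse chi-squared with df = nu0 + n - 1
  # and scale (nu0*s0 + SSE) where SSE is about the sample mean
  nu_post <- 1 + n - 1
  sc_post <- 1 * 1 + sum((y - mean(y))^2)
  expect_equal(mean(s2), sc_post / (nu_post - 2), tolerance = 0.05)
  qs <- quantile(s2, c(0.1, 0.5, 0.9))
  qth <- sc_post / qchisq(c(0.9, 0.5, 0.1), nu_post)
  expect_equal(unname(qs), qth, tolerance = 0.05)
})

test_that("univariate pedigree sampler recovers a moderate heritability", {
  cfg <- simulation_config(n_years = 1, n_steers_per_year = 60,
                           n_sires = 10, n_dams = 60, seed = 71)
  ped <- simulate_pedigree(cfg)
  st <- attr(ped, "steers")
  gv <- simulate_genetic_values(ped, diag(2), diag(2),
                                phenotyped = st$animal, seed = 72)
  y <- gv$phenotypes$fw
  out <- gibbs_univariate(y, matrix(1, length(y), 1),
                          animal_id = gv$phenotypes$animal_id,
                          pedigree = ped, n_iter = 4000, burn_in = 500,
                          seed = 73)
  h2 <- out$samples$h2
  expect_true(all(h2 >= 0 & h2 <= 1))
  hp <- hpd_interval(h2)
  expect_true(hp[1] <= 0.5 && 0.5 <= hp[2])
})

test_that("HPD matches the exhaustive window oracle; summaries behave", {
  set.seed(81)
  for (x in list(rnorm(500), rexp(300), rbeta(400, 2, 5))) {
    expect_equal(hpd_interval(x), oracle_hpd(x))
  }
  const <- data.frame(g11 = rep(2, 200), g12 = rep(0.5, 200),
                      g22 = rep(1, 200), r11 = rep(1, 200),
                      r12 = rep(0.2, 200), r22 = rep(1, 200))
  const$h2_1 <- const$g11 / (const$g11 + const$r11)
  const$h2_2 <- const$g22 / (const$g22 + const$r22)
  const$rg <- const$g12 / sqrt(const$g11 * const$g22)
  const$rp <- (const$g12 + const$r12) /
    sqrt((const$g11 + const$r11) * (const$g22 + const$r22))
  sm <- summarize_posterior(const)
  expect_true(all(sm$psd == 0))
  expect_equal(sm$hpd_lower, sm$hpd_upper)
  expect_true(all(sm$mean[1:2] >= 0 & sm$mean[1:2] <= 1))
  expect_error(summarize_posterior(const[1:50, ]), "100")
})
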