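# Independent oracles used across test files. Each is deliberately written
# with a different algorithm than the package implementation it checks.

# Additive relationship by path counting: a_ij = sum over common ancestors C
# and disjoint ancestral paths of (1/2)^(len_i + len_j) * (1 + F_C).
# Recursion on the (smaller) ancestor pedigree supplies F_C.
oracle_relationship <- function(ped, id1, id2) {
  ped <- as.data.frame(ped)
  parent_of <- function(id) {
    r <- ped[ped$animal == id, ]
    if (!nrow(r)) return(character(0))
    p <- c(r$sire, r$dam)
    p[!is.na(p)]
  }
  # all ancestral paths from id up to each ancestor (list: ancestor -> list of paths)
  paths_up <- function(id) {
    out <- list()
    walk <- function(node, path) {
      out[[length(out) + 1]] <<- list(anc = node, path = path)
      for (p in parent_of(node)) walk(p, c(path, p))
    }
    walk(id, id)
    out
  }
  inbreeding <- function(id) {
    pr <- ped[ped$animal == id, ]
    if (!nrow(pr) || is.na(pr$sire) || is.na(pr$dam)) return(0)
    0.5 * oracle_relationship(ped, pr$sire, pr$dam)
  }
  if (id1 == id2) return(1 + inbreeding(id1))
  p1 <- paths_up(id1)
  p2 <- paths_up(id2)
  total <- 0
  for (a in p1) {
    for (b in p2) {
      if (a$anc != b$anc) next
      # paths must be disjoint except at the common ancestor
      shared <- intersect(a$path[-length(a$path)], b$path[-length(b$path)])
      if (length(shared)) next
      l1 <- length(a$path) - 1
      l2 <- length(b$path) - 1
      total <- total + 0.5^(l1 + l2) * (1 + inbreeding(a$anc))
    }
  }
  total
}

# Cosinor brute force: phi on a fine grid, closed-form LS for (k, alpha)
# at each phi, pick the minimum-RSS candidate.
oracle_cosinor_grid <- function(time_h, y, phi_step = 0.05, period = 24) {
  w <- 2 * pi / period
  best <- NULL
  for (phi in seq(0, period - phi_step, by = phi_step)) {
    cc <- cos(w * (time_h - phi))
    fit <- stats::lm.fit(cbind(1, cc), y)
    rss <- sum(fit$residuals^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(k = unname(fit$coefficients[1]),
                   alpha = unname(fit$coefficients[2]),
                   phi = phi, rss = rss)
    }
  }
  # negative alpha means the peak is half a period away
  if (best$alpha < 0) {
    best$alpha <- -best$alpha
    best$phi <- (best$phi + period / 2) %% period
  }
  best
}

# Iterative nonlinear least squares from several phase starts
oracle_cosinor_nls <- function(time_h, y, period = 24) {
  w <- 2 * pi / period
  best <- NULL
  for (phi0 in c(2, 8, 14, 20)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ k + alpha * cos(w * (time_h - phi)),
        start = list(k = mean(y), alpha = max(sd(y), 0.01), phi = phi0),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- coef(fit)
      best <- list(k = cf[["k"]], alpha = cf[["alpha"]],
                   phi = cf[["phi"]], rss = rss)
    }
  }
  if (best$alpha < 0) {
    best$alpha <- -best$alpha
    best$phi <- best$phi + period / 2
  }
  best$phi <- best$phi %% period
  best
}

# HPD by exhaustive O(n^2) window search over the sorted sample
oracle_hpd <- function(x, prob = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  best <- c(NA, NA)
  width <- Inf
  for (i in seq_len(n - m)) {
    wd <- x[i + m] - x[i]
    if (wd < width) {
      width <- wd
      best <- c(x[i], x[i + m])
    }
  }
  best
}

# Partial correlation via explicit two-stage regression on the animal factor
oracle_partial_cor <- function(x, y, animal) {
  rx <- resid(lm(x ~ factor(animal)))
  ry <- resid(lm(y ~ factor(animal)))
  cor(rx, ry)
}

# A small cohort with telemetry + truth, shared by telemetry/cosinor tests
make_test_cohort <- function(n_animals = 4, days = 10, seed = 42,
                             config = simulation_config(seed = seed)) {
  set.seed(seed)
  mesors <- rnorm(n_animals, 39.8, 0.1)
  lapply(seq_len(n_animals), function(i) {
    simulate_temperature_series(
      animal_id = sprintf("A%02d", i), mesor = mesors[i], amplitude = 0.25,
      acrophase = 16, days = days, config = config,
      seed = seed + i)
  })
}
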