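#' Gibbs chain configuration
#'
#' Bundles chain geometry and the inverse-Wishart priors for the additive
#' (G0) and residual (R0) 2x2 covariance matrices. The default desk-scale
#' geometry is 20,000 iterations with 2,000 burn-in and thinning 10; the
#' full-scale geometry used for production genetic evaluation (1,000,000
#' iterations, 100,000 burn-in, thinning 250, giving 3,600 stored samples)
#' is available by passing those values. Priors default to identity scale
#' with minimal degrees of freedom (dim + 1 = 3).
#'
#' With cohorts of a few hundred animals in small half-sib families the
#' likelihood carries limited information about the additive variance, so
#' the prior scale matters: the identity default regularizes heritability
#' away from the \[0, 1\] boundaries (stabilizing interval estimates),
#' while a small scale such as `0.01 * diag(2)` is nearly flat and lets
#' the data dominate (appropriate when testing whether the data alone push
#' a variance to zero). Report a sensitivity check across prior scales for
#' any serious analysis at this cohort size.
#'
#' @param n_iter Total iterations.
#' @param burn_in Burn-in iterations (< n_iter).
#' @param thin Thinning interval (>= 1).
#' @param prior_g,prior_r Scale matrices (2x2, symmetric PD).
#' @param df_g,df_r Prior degrees of freedom (>= 3 for a 2x2).
#' @return List of class `chain_config`.
#' @export
chain_config <- function(n_iter = 20000, burn_in = 2000, thin = 10,
                         prior_g = diag(2), prior_r = diag(2),
                         df_g = 3, df_r = 3) {
  stopifnot(n_iter > 0, burn_in >= 0, burn_in < n_iter, thin >= 1)
  .check_pd(prior_g, "prior_g")
  .check_pd(prior_r, "prior_r")
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), prior_g = prior_g,
                 prior_r = prior_r, df_g = df_g, df_r = df_r),
            class = "chain_config")
}

#' Number of samples a Gibbs chain stores
#'
#' A chain of `n_iter` iterations stores every `thin`-th draw after
#' `burn_in`, i.e. `floor((n_iter - burn_in) / thin)` samples:
#' 1,000,000 iterations with 100,000 burn-in thinned by 250 store 3,600.
#'
#' @param n_iter,burn_in,thin Chain geometry (or pass a `chain_config` as
#'   `n_iter`).
#' @return Integer count of stored samples.
#' @examples
#' n_stored_samples(1e6, 1e5, 250) # 3600
#' @export
n_stored_samples <- function(n_iter, burn_in = NULL, thin = NULL) {
  if (inherits(n_iter, "chain_config")) {
    cfg <- n_iter
    n_iter <- cfg$n_iter; burn_in <- cfg$burn_in; thin <- cfg$thin
  }
  stopifnot(burn_in < n_iter, thin >= 1)
  as.integer((n_iter - burn_in) %/% thin)
}

.check_pd <- function(S, name) {
  if (!is.matrix(S) || any(dim(S) != c(2, 2)) ||
      max(abs(S - t(S))) > 1e-8 || any(eigen(S, TRUE, TRUE)$values <= 0)) {
    stop("`", name, "` must be a symmetric positive definite 2x2 matrix")
  }
  invisible(TRUE)
}

#' Bivariate pedigree animal model via Gibbs sampling
#'
#' Treats the two feeding regimes as two traits of the same animal:
#' y_t = X_t b_t + Z u_t + e_t with additive values u ~ N(0, G0 kron A)
#' over the pedigree and residual pairs correlated within animal,
#' e_i ~ N(0, R0). Fixed effects (per trait) are whatever `fixed` encodes,
#' typically pen and year plus an initial-weight covariate. Location
#' parameters are drawn from their normal full conditionals (matrix-normal
#' block for b, single-site bivariate updates for each animal's u), G0 and
#' R0 from their inverse-Wishart full conditionals.
#'
#' @param phenotypes Data.frame with `animal_id` and the two trait columns
#'   named in `traits` (complete cases only are used).
#' @param traits Character(2): column names of the two trait measurements
#'   (e.g. FW and WS expressions of MESOR).
#' @param fixed One-sided formula for the per-trait fixed effects evaluated
#'   in `phenotypes` (default `~ 1`); the design is built with
#'   `model.matrix`, dropping the first level of each factor.
#' @param pedigree Pedigree data.frame (see [sort_pedigree()]); must contain
#'   every phenotyped animal.
#' @param config A [chain_config()].
#' @param seed Optional integer seed (applied via `set.seed`).
#' @return Object of class `gibbs_fit`: list with `samples` (data.frame of
#'   stored draws of g11, g12, g22, r11, r12, r22 plus derived h2_1, h2_2,
#'   rg, rp), `n_stored`, `config`, `n_records`, `n_animals`.
#' @export
gibbs_bivariate <- function(phenotypes, traits, fixed = ~1, pedigree,
                            config = chain_config(), seed = NULL) {
  stopifnot(inherits(config, "chain_config"), length(traits) == 2)
  df <- as.data.frame(phenotypes)
  stopifnot(all(c("animal_id", traits) %in% names(df)))
  df <- df[complete.cases(df[, traits]), , drop = FALSE]
  if (!nrow(df)) stop("no complete bivariate records")
  ped <- sort_pedigree(pedigree)
  missing_ped <- setdiff(as.character(df$animal_id), ped$animal)
  if (length(missing_ped)) {
    stop("phenotyped animals absent from pedigree: ",
         paste(head(missing_ped, 5), collapse = ", "))
  }
  Ainv <- ainverse(ped)
  animal_idx <- match(as.character(df$animal_id), ped$animal)
  X <- model.matrix(fixed, df)
  if (qr(X)$rank < ncol(X)) {
    stop("fixed-effect design is rank deficient after constraints")
  }
  Y <- as.matrix(df[, traits])
  if (!is.null(seed)) set.seed(seed)
  res <- .gibbs_bivariate_cpp(Y, X, as.integer(animal_idx), Ainv,
                              config$prior_g, config$df_g,
                              config$prior_r, config$df_r,
                              config$n_iter, config$burn_in, config$thin)
  s <- as.data.frame(res$samples)
  names(s) <- c("g11", "g12", "g22", "r11", "r12", "r22")
  s$h2_1 <- s$g11 / (s$g11 + s$r11)
  s$h2_2 <- s$g22 / (s$g22 + s$r22)
  s$rg <- s$g12 / sqrt(s$g11 * s$g22)
  s$rp <- (s$g12 + s$r12) / sqrt((s$g11 + s$r11) * (s$g22 + s$r22))
  structure(list(samples = s, n_stored = res$n_stored, config = config,
                 n_records = nrow(df), n_animals = nrow(ped)),
            class = "gibbs_fit")
}

#' @export
print.gibbs_fit <- function(x, ...) {
  cat(sprintf(
    "bivariate animal model: %d records, %d pedigree animals, %d stored draws\n",
    x$n_records, x$n_animals, x$n_stored))
  print(summarize_posterior(x))
  invisible(x)
}

#' Shortest 95% highest-posterior-density interval
#'
#' The narrowest contiguous window of the sorted sample containing at least
#' `prob` of the draws.
#'
#' @param x Numeric sample.
#' @param prob Mass to cover, default 0.95.
#' @return Numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(x, prob = 0.95) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (!n) return(c(NA_real_, NA_real_))
  m <- max(1L, ceiling(prob * n))
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m)
  widths <- x[starts + m] - x[starts]
  i <- which.min(widths)
  c(x[i], x[i + m])
}

#' Posterior summaries of a bivariate animal-model chain
#'
#' Per trait: heritability posterior mean, posterior SD (PSD) and 95% HPD
#' interval, plus the genetic variance; across traits: genetic and
#' phenotypic correlations with PSD and HPD95. Non-finite draws (possible
#' when a variance draw collapses numerically) are excluded and counted.
#'
#' @param fit A `gibbs_fit` (or its `samples` data.frame).
#' @param prob HPD mass, default 0.95.
#' @return Data.frame with rows h2_1, h2_2, sigma_g1, sigma_g2, rg, rp and
#'   columns `mean`, `psd`, `hpd_lower`, `hpd_upper`; attribute
#'   `n_excluded`.
#' @export
summarize_posterior <- function(fit, prob = 0.95) {
  s <- if (inherits(fit, "gibbs_fit")) fit$samples else as.data.frame(fit)
  if (nrow(s) < 100) stop("need at least 100 stored samples to summarize")
  vars <- c("h2_1", "h2_2", "g11", "g22", "rg", "rp")
  labels <- c("h2_1", "h2_2", "sigma_g1", "sigma_g2", "rg", "rp")
  n_excl <- 0L
  rows <- lapply(seq_along(vars), function(i) {
    x <- s[[vars[i]]]
    bad <- !is.finite(x)
    n_excl <<- n_excl + sum(bad)
    x <- x[!bad]
    h <- hpd_interval(x, prob)
    data.frame(parameter = labels[i], mean = mean(x), psd = sd(x),
               hpd_lower = h[1], hpd_upper = h[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_excl
  out
}

#' Univariate animal / repeated-measures model via Gibbs sampling
#'
#' Companion sampler for the single-trait model y = X b + Z u + e with
#' u ~ N(0, sigma_a^2 A) and e ~ N(0, sigma_e^2 I), using scaled
#' inverse-chi-squared priors. Covers the repeated-measures alternative to
#' the bivariate formulation (records from both regimes stacked, regime as
#' a fixed effect) and, with no random term (`pedigree = NULL`), reduces to
#' the conjugate normal-inverse-gamma model, which has a closed-form
#' posterior useful for validation.
#'
#' Written in plain R; intended for moderate problem sizes.
#'
#' @param y Response vector.
#' @param X Fixed-effect design matrix (full rank, with intercept).
#' @param animal_id Character vector mapping records to pedigree animals
#'   (ignored when `pedigree` is `NULL`).
#' @param pedigree Pedigree data.frame, or `NULL` for no genetic term.
#' @param n_iter,burn_in,thin Chain geometry.
#' @param prior_scale_a,prior_df_a,prior_scale_e,prior_df_e Scaled
#'   inverse-chi-squared priors for the two variances.
#' @param seed Optional seed.
#' @return List with `samples` (data.frame `sigma2_a` (if fitted),
#'   `sigma2_e`, `h2`) and `n_stored`.
#' @export
gibbs_univariate <- function(y, X, animal_id = NULL, pedigree = NULL,
                             n_iter = 5000, burn_in = 500, thin = 1,
                             prior_scale_a = 1, prior_df_a = 1,
                             prior_scale_e = 1, prior_df_e = 1,
                             seed = NULL) {
  stopifnot(burn_in < n_iter, thin >= 1)
  if (!is.null(seed)) set.seed(seed)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  XtXinv <- solve(crossprod(X))
  Lx <- t(chol(XtXinv))
  use_u <- !is.null(pedigree)
  if (use_u) {
    ped <- sort_pedigree(pedigree)
    Ainv <- ainverse(ped)
    q <- nrow(Ainv)
    ai <- match(as.character(animal_id), ped$animal)
    stopifnot(!anyNA(ai))
    Z <- matrix(0, n, q)
    Z[cbind(seq_len(n), ai)] <- 1
    u <- numeric(q)
    s2a <- prior_scale_a
  }
  b <- rep(0, p)
  s2e <- prior_scale_e
  keep <- n_stored_samples(n_iter, burn_in, thin)
  out <- matrix(NA_real_, keep, if (use_u) 3 else 1)
  kept <- 0
  for (iter in seq_len(n_iter)) {
    ystar <- if (use_u) y - Z %*% u else y
    bhat <- XtXinv %*% crossprod(X, ystar)
    b <- as.numeric(bhat + sqrt(s2e) * (Lx %*% rnorm(p)))
    r <- y - X %*% b
    if (use_u) {
      # joint draw of u from N(C^{-1} rhs, s2e C^{-1}), C = Z'Z + k Ainv
      k <- s2e / s2a
      C <- crossprod(Z) + k * Ainv
      Lc <- chol(C)
      rhs <- crossprod(Z, r)
      mu <- backsolve(Lc, forwardsolve(t(Lc), rhs))
      u <- as.numeric(mu + sqrt(s2e) * backsolve(Lc, rnorm(q)))
      df_a <- prior_df_a + q
      sc_a <- prior_df_a * prior_scale_a + as.numeric(t(u) %*% Ainv %*% u)
      s2a <- sc_a / rchisq(1, df_a)
      r <- r - Z %*% u
    }
    df_e <- prior_df_e + n
    sc_e <- prior_df_e * prior_scale_e + sum(r^2)
    s2e <- sc_e / rchisq(1, df_e)
    if (iter > burn_in && (iter - burn_in) %% thin == 0) {
      kept <- kept + 1
      out[kept, ] <- if (use_u) c(s2a, s2e, s2a / (s2a + s2e)) else s2e
    }
  }
  samples <- as.data.frame(out)
  names(samples) <- if (use_u) c("sigma2_a", "sigma2_e", "h2") else "sigma2_e"
  list(samples = samples, n_stored = kept)
}
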