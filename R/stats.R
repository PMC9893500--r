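#' Pairwise Pearson correlations with t-test p-values
#'
#' Long-format correlation table over the numeric columns of a phenotype
#' table, pairwise-complete. For `scope = "between_regimes"` supply `table2`
#' holding the same animals' values in the other regime (matched on
#' `animal_id`): each variable is then correlated with its own counterpart
#' across regimes, the between-regime repeatability surface.
#'
#' @param table Data.frame with `animal_id` and numeric trait columns.
#' @param scope One of `"within_FW"`, `"within_WS"`, `"between_regimes"`.
#' @param table2 Second-regime table (required for `between_regimes`).
#' @return Data.frame: `var1`, `var2`, `r`, `p_value`, `n`, `scope`.
#'   Zero-variance pairs carry `NA` with an attribute-free flag column
#'   `defined`.
#' @export
correlation_matrix <- function(table,
                               scope = c("within_FW", "within_WS",
                                         "between_regimes"),
                               table2 = NULL) {
  scope <- match.arg(scope)
  df <- as.data.frame(table)
  num <- names(df)[vapply(df, is.numeric, logical(1))]
  if (scope == "between_regimes") {
    stopifnot(!is.null(table2), "animal_id" %in% names(df),
              "animal_id" %in% names(table2))
    df2 <- as.data.frame(table2)
    m <- match(df$animal_id, df2$animal_id)
    rows <- lapply(intersect(num, names(df2)), function(v) {
      .cor_row(df[[v]], df2[[v]][m], v, v, scope)
    })
  } else {
    pairs <- utils::combn(num, 2, simplify = FALSE)
    rows <- lapply(pairs, function(p) {
      .cor_row(df[[p[1]]], df[[p[2]]], p[1], p[2], scope)
    })
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.cor_row <- function(x, y, n1, n2, scope) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) {
    return(data.frame(var1 = n1, var2 = n2, r = NA_real_,
                      p_value = NA_real_, n = n, scope = scope,
                      defined = FALSE, stringsAsFactors = FALSE))
  }
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    return(data.frame(var1 = n1, var2 = n2, r = NA_real_,
                      p_value = NA_real_, n = n, scope = scope,
                      defined = FALSE, stringsAsFactors = FALSE))
  }
  r <- cor(x, y)
  p <- if (abs(r) >= 1) 0 else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  data.frame(var1 = n1, var2 = n2, r = r, p_value = p, n = n,
             scope = scope, defined = TRUE, stringsAsFactors = FALSE)
}

#' Within-animal (partial) correlation of two daily series
#'
#' Correlation of two daily variables after removing each animal's mean
#' from both — the repeated-measures adjustment used when relating e.g.
#' daily ambient temperature to daily MESOR, where between-animal level
#' differences would otherwise confound the day-to-day relationship.
#' Equivalent to correlating the residuals of each variable regressed on
#' the animal factor. With a single animal this reduces to the plain
#' correlation (warned).
#'
#' @param x,y Numeric daily series, same length.
#' @param animal Factor/vector of animal IDs, same length.
#' @return Data.frame row as in [correlation_matrix()] with scope
#'   `"within_animal"`; `n` is the number of complete daily observations.
#'   If `x` (or `y`) is constant within every animal the correlation is
#'   undefined and flagged.
#' @export
partial_correlation <- function(x, y, animal) {
  stopifnot(length(x) == length(y), length(x) == length(animal))
  ok <- is.finite(x) & is.finite(y) & !is.na(animal)
  x <- x[ok]; y <- y[ok]; animal <- factor(animal[ok])
  if (nlevels(animal) < 2) {
    warning("single animal: partial correlation reduces to plain correlation")
  }
  counts <- table(animal)
  if (any(counts < 3)) {
    warning("animals with fewer than 3 days contribute little information")
  }
  xc <- x - ave(x, animal)
  yc <- y - ave(y, animal)
  out <- .cor_row(xc, yc, "x", "y", "within_animal")
  # adjust the t-test df for the animal means removed
  if (out$defined) {
    dfree <- out$n - nlevels(animal) - 1
    if (dfree < 1) {
      out$p_value <- NA_real_
    } else if (abs(out$r) < 1) {
      tstat <- out$r * sqrt(dfree / (1 - out$r^2))
      out$p_value <- 2 * pt(abs(tstat), dfree, lower.tail = FALSE)
    }
  }
  out
}

#' @importFrom stats ave
NULL

#' Least-squares means of a response by class, adjusted for design factors
#'
#' Fits the additive fixed-effects model `value ~ class + regime + year`
#' (terms dropped when a factor is constant) and reports the
#' model-predicted mean for each class level averaged over a balanced grid
#' of the other factors, with standard errors — the classical LS-means. In
#' a balanced design these equal raw class means.
#'
#' @param values Numeric response.
#' @param class_factor Efficiency (or MESOR) class factor.
#' @param regime_factor,year_factor Optional design factors.
#' @return Data.frame: `class`, `lsmean`, `se`, `n`.
#' @export
class_lsmeans <- function(values, class_factor, regime_factor = NULL,
                          year_factor = NULL) {
  df <- data.frame(value = values, class = factor(class_factor))
  form <- value ~ class
  if (!is.null(regime_factor) && length(unique(regime_factor)) > 1) {
    df$regime <- factor(regime_factor)
    form <- stats::update(form, . ~ . + regime)
  }
  if (!is.null(year_factor) && length(unique(year_factor)) > 1) {
    df$year <- factor(year_factor)
    form <- stats::update(form, . ~ . + year)
  }
  cell_n <- table(df[, setdiff(names(df), "value"), drop = FALSE])
  if (any(cell_n == 0)) {
    warning("empty design cell(s): LS-means for affected margins are ",
            "extrapolations")
  }
  fit <- lm(form, data = df)
  em <- emmeans::emmeans(fit, "class")
  es <- as.data.frame(em)
  data.frame(class = as.character(es$class), lsmean = es$emmean,
             se = es$SE, n = as.integer(table(df$class)[as.character(es$class)]),
             stringsAsFactors = FALSE)
}
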