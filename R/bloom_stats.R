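#' Log-transform an abundance series
#'
#' `log10(x + pseudocount)` elementwise. Cell counts span orders of
#' magnitude across a bloom, so correlations and regressions are run on the
#' log scale; the pseudocount (default 1) keeps zero counts in the domain.
#'
#' @param series Numeric vector of non-negative abundances.
#' @param pseudocount Added before taking logs. Default 1.
#' @return Numeric vector, same length.
#' @export
#' @examples
#' log_transform(c(0, 9, 99))  # 0 1 2
log_transform <- function(series, pseudocount = 1) {
  if (any(series < 0, na.rm = TRUE)) abort("abundances must be non-negative")
  if (any(series + pseudocount <= 0, na.rm = TRUE)) {
    abort("pseudocount too small: log of non-positive value")
  }
  log10(series + pseudocount)
}

#' Spearman correlations between clade abundances and environment
#'
#' Spearman rank correlation (average ranks for ties) with a two-sided p
#' value for every (clade, variable) pair, on pairwise-complete
#' observations. Pairs with fewer than `min_n` complete observations, or
#' with a constant series (rho undefined), are reported with `NA`.
#'
#' @param clades Data frame of clade abundance columns (one column per
#'   clade), rows aligned with `env`.
#' @param env Data frame of environmental variable columns, same row order.
#' @param min_n Minimum paired observations. Default 5.
#' @return Tibble with `clade`, `variable`, `n`, `rho`, `p`.
#' @export
spearman_matrix <- function(clades, env, min_n = 5) {
  clades <- as_tibble(clades)
  env <- as_tibble(env)
  if (nrow(clades) != nrow(env)) abort("clades and env must align by row")
  grid <- tidyr::expand_grid(clade = names(clades), variable = names(env))
  purrr::pmap(grid, function(clade, variable) {
    x <- as.numeric(clades[[clade]])
    y <- as.numeric(env[[variable]])
    ok <- !is.na(x) & !is.na(y)
    n_ok <- sum(ok)
    if (n_ok < min_n || length(unique(x[ok])) < 2 ||
        length(unique(y[ok])) < 2) {
      return(tibble(clade = clade, variable = variable, n = n_ok,
                    rho = NA_real_, p = NA_real_))
    }
    ct <- suppressWarnings(
      cor.test(x[ok], y[ok], method = "spearman", alternative = "two.sided"))
    tibble(clade = clade, variable = variable, n = n_ok,
           rho = unname(ct$estimate), p = ct$p.value)
  }) |> bind_rows()
}

#' Stepwise forward linear regression
#'
#' Builds a linear model by repeatedly adding the candidate predictor with
#' the smallest partial-F p value, as long as that p value is below
#' `p_enter`; stops when no candidate qualifies. With `criterion = "AIC"`
#' the candidate with the largest AIC improvement enters instead, as long
#' as AIC decreases.
#'
#' @param response Numeric response vector (typically log-transformed
#'   abundances).
#' @param predictors Data frame of candidate predictor columns, rows
#'   aligned with `response`.
#' @param p_enter Entry threshold on the partial-F p value. Default 0.05.
#' @param criterion `"F"` (partial-F entry, the default) or `"AIC"`.
#' @return Object of class `stepwise_fit`: list with `fit` (the final
#'   [lm()]), `selected` (predictors in entry order), `entry` (tibble of
#'   per-step statistics), `r_squared`.
#' @export
stepwise_forward <- function(response, predictors, p_enter = 0.05,
                             criterion = c("F", "AIC")) {
  criterion <- match.arg(criterion)
  predictors <- as_tibble(predictors)
  if (length(response) != nrow(predictors)) {
    abort("response and predictors must align by row")
  }
  qrs <- qr(as.matrix(cbind(1, predictors)))
  if (qrs$rank < ncol(predictors) + 1) {
    abort(paste0("rank-deficient design; collinear predictor(s) among: ",
                 paste(names(predictors), collapse = ", ")))
  }
  dat <- cbind(tibble(.response = response), predictors)
  selected <- character(0)
  entry <- list()
  fit <- lm(.response ~ 1, data = dat)
  repeat {
    remaining <- setdiff(names(predictors), selected)
    if (length(remaining) == 0) break
    scope <- as.formula(paste("~ . +", paste(remaining, collapse = " + ")))
    a1 <- add1(fit, scope, test = if (criterion == "F") "F" else "none")
    a1 <- a1[-1, , drop = FALSE]            # drop the <none> row
    if (criterion == "F") {
      p <- a1[["Pr(>F)"]]
      best <- which.min(p)
      if (length(best) == 0 || !(p[best] < p_enter)) break
      step_stat <- tibble(term = rownames(a1)[best],
                          statistic = a1[["F value"]][best],
                          p.value = p[best])
    } else {
      best <- which.min(a1$AIC)
      if (a1$AIC[best] >= stats::AIC(fit)) break
      step_stat <- tibble(term = rownames(a1)[best],
                          statistic = a1$AIC[best], p.value = NA_real_)
    }
    term <- rownames(a1)[best]
    selected <- c(selected, term)
    entry[[length(entry) + 1]] <- step_stat
    fit <- lm(as.formula(paste(".response ~",
                               paste(selected, collapse = " + "))),
              data = dat)
  }
  structure(
    list(
      fit = fit,
      selected = selected,
      entry = if (length(entry) > 0) bind_rows(entry) else
        tibble(term = character(), statistic = numeric(),
               p.value = numeric()),
      r_squared = summary(fit)$r.squared
    ),
    class = "stepwise_fit"
  )
}

#' @export
print.stepwise_fit <- function(x, ...) {
  cat("<stepwise_fit> ", length(x$selected), " predictor(s) selected",
      if (length(x$selected) > 0)
        paste0(": ", paste(x$selected, collapse = " -> ")) else "",
      "\nR-squared: ", signif(x$r_squared, 4), "\n", sep = "")
  invisible(x)
}

#' Tidy the coefficients of a stepwise fit
#'
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `statistic`,
#'   `p.value` for the final model.
#' @exportS3Method generics::tidy
tidy.stepwise_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
         statistic = s[, 3], p.value = s[, 4])
}

#' One-row summary of a stepwise fit
#'
#' @param x A `stepwise_fit`.
#' @param ... Unused.
#' @return Tibble with `n_selected`, `r.squared`, `adj.r.squared`, `sigma`,
#'   `df.residual`.
#' @exportS3Method generics::glance
glance.stepwise_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(n_selected = length(x$selected), r.squared = s$r.squared,
         adj.r.squared = s$adj.r.squared, sigma = s$sigma,
         df.residual = x$fit$df.residual)
}
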