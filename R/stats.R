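#' Paired t test with Cohen's d
#'
#' Classical two-sided paired t on the differences `a - b`, with two paired
#' effect-size conventions reported side by side: `d_z` (mean difference
#' over the SD of the differences) and `d_av` (mean difference over the
#' average of the two group SDs). Identical samples return the degenerate
#' but well-defined `t = 0, p = 1, d = 0`; non-identical samples with zero
#' difference variance raise an error.
#'
#' @param a,b Per-subject paired values (equal length, n >= 2).
#' @return One-row tibble: `estimate` (mean difference), `t`, `df`, `p`,
#'   `d_z`, `d_av`, `n`.
#' @export
paired_ttest_with_d <- function(a, b) {
  if (length(a) != length(b)) abort("`a` and `b` must have equal length.")
  n <- length(a)
  if (n < 2) abort("Need n >= 2 pairs.")
  d <- a - b
  if (sd(d) == 0) {
    if (all(d == 0)) {
      return(tibble(estimate = 0, t = 0, df = n - 1, p = 1,
                    d_z = 0, d_av = 0, n = n))
    }
    abort("Zero difference variance with non-zero mean: t undefined.",
          class = "oscicouple_degenerate_variance")
  }
  tt <- t.test(a, b, paired = TRUE)
  tibble(
    estimate = mean(d),
    t = unname(tt$statistic),
    df = unname(tt$parameter),
    p = tt$p.value,
    d_z = mean(d) / sd(d),
    d_av = mean(d) / ((sd(a) + sd(b)) / 2),
    n = n
  )
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjusted p values with a rejection mask at level `q`.
#'
#' @param pvals P values in `[0, 1]`.
#' @param q FDR level.
#' @return Tibble with `p`, `p_adj`, `significant`.
#' @export
fdr_bh <- function(pvals, q = 0.05) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    abort("All p values must lie in [0, 1].")
  }
  adj <- p.adjust(pvals, method = "BH")
  tibble(p = pvals, p_adj = adj, significant = adj <= q)
}

#' Stepwise linear regression by BIC
#'
#' Starts from the intercept-only model and alternates forward-addition and
#' backward-removal steps, at each step taking the single move that most
#' decreases the Bayesian Information Criterion; stops when no move
#' decreases it. Predictors are standardized internally (and the response
#' centered and scaled), so the reported coefficients are standardized
#' betas and the selection is invariant to predictor scaling. Exactly
#' collinear predictors (|r| = 1) are resolved by excluding the
#' later-listed one with a warning. Ties between moves are broken by
#' predictor input order.
#'
#' @param y Response, one value per subject.
#' @param X Data frame (or matrix) of candidate predictors.
#' @param add_first If `TRUE` (default) additions are examined before
#'   removals within each sweep; the alternative ordering is exposed as a
#'   sensitivity switch.
#' @return An object of class `oc_stepwise`: `selected`, `coefficients`
#'   (tibble with standardized `beta`, `se`, `t`, `p`), `bic`, `r2`, and
#'   the underlying `lm` fit on standardized variables.
#' @export
stepwise_bic <- function(y, X, add_first = TRUE) {
  X <- as.data.frame(X)
  n <- length(y)
  if (n <= 2) abort("Need n > 2 observations.")
  if (nrow(X) != n) abort("`y` and `X` must agree in length.")
  keep <- vapply(X, function(col) sd(col) > 0, logical(1))
  if (any(!keep)) {
    warn(sprintf("Dropping constant predictor(s): %s",
                 paste(names(X)[!keep], collapse = ", ")))
    X <- X[keep]
  }
  # resolve exact collinearity toward the earlier-listed predictor
  if (ncol(X) >= 2) {
    cm <- abs(cor(X))
    drop <- rep(FALSE, ncol(X))
    for (j in 2:ncol(X)) {
      if (!drop[j] && any(cm[j, seq_len(j - 1)][!drop[seq_len(j - 1)]] >
                          1 - 1e-12)) {
        drop[j] <- TRUE
      }
    }
    if (any(drop)) {
      warn(sprintf("Excluding exactly collinear predictor(s): %s",
                   paste(names(X)[drop], collapse = ", ")))
      X <- X[!drop]
    }
  }
  Z <- as.data.frame(scale(X))
  ys <- as.numeric(scale(y))
  dat <- cbind(.y = ys, Z)
  fit_set <- function(vars) {
    f <- if (length(vars) == 0) ".y ~ 1" else
      paste(".y ~", paste(vars, collapse = " + "))
    lm(stats::as.formula(f), data = dat)
  }
  current <- character(0)
  fit <- fit_set(current)
  current_bic <- BIC(fit)
  repeat {
    moves <- list()
    adds <- setdiff(names(Z), current)
    removes <- current
    ordered <- if (add_first) c(lapply(adds, function(v) list(op = "+", var = v)),
                                lapply(removes, function(v) list(op = "-", var = v)))
    else c(lapply(removes, function(v) list(op = "-", var = v)),
           lapply(adds, function(v) list(op = "+", var = v)))
    if (length(ordered) == 0) break
    bics <- vapply(ordered, function(m) {
      vars <- if (m$op == "+") c(current, m$var) else setdiff(current, m$var)
      BIC(fit_set(vars))
    }, numeric(1))
    best <- which.min(bics) # first minimum: deterministic tie-break
    if (bics[best] < current_bic - 1e-10) {
      m <- ordered[[best]]
      current <- if (m$op == "+") c(current, m$var) else setdiff(current, m$var)
      fit <- fit_set(current)
      current_bic <- bics[best]
    } else {
      break
    }
  }
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- rownames(co)
  coefs <- tibble(
    term = terms,
    beta = unname(co[, 1]),
    se = unname(co[, 2]),
    t = unname(co[, 3]),
    p = unname(co[, 4])
  )
  structure(list(
    selected = current, coefficients = coefs,
    bic = current_bic, r2 = sm$r.squared, fit = fit,
    candidates = names(Z)
  ), class = "oc_stepwise")
}

#' @export
print.oc_stepwise <- function(x, ...) {
  cat(sprintf("<oc_stepwise> selected {%s}, BIC %.2f, R^2 %.3f\n",
              paste(x$selected, collapse = ", "), x$bic, x$r2))
  invisible(x)
}
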