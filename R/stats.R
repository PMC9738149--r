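# Statistical battery: wild-bootstrap regression of variance metrics on
# maternal risk factors (MRFs) with gestational-age adjustment and CHD
# interactions, Benjamini-Hochberg FDR, GA-adjusted Kolmogorov-Smirnov group
# comparison, histogram-moment tests, and Welch t tests.

MRF_PREDICTORS <- c("any_mrf", "diabetes", "hypertension", "obesity")

#' Build a regression design matrix
#'
#' Main-effect models regress a metric on `[1, GA, predictor]`; interaction
#' models expand to `[1, GA, predictor, CHD, predictor:CHD]` with the
#' interaction term as the coefficient under test.
#'
#' @param records data.frame with columns `ga_weeks`, `chd`, and the
#'   predictor.
#' @param predictor MRF column name (binary).
#' @param include_interaction add CHD main effect and predictor x CHD
#'   interaction; the target becomes the interaction coefficient.
#' @return object of class `design_matrix`: list with `X` (n x k numeric
#'   matrix), `target` (name of the coefficient under test), `predictor`,
#'   `include_interaction`.
#' @export
build_design <- function(records, predictor, include_interaction = FALSE) {
  for (col in c("ga_weeks", predictor, if (include_interaction) "chd")) {
    if (!col %in% names(records)) {
      abort2(sprintf("records lack column '%s'", col), "boldvar_bad_field")
    }
  }
  n <- nrow(records)
  k <- if (include_interaction) 5L else 3L
  if (n < k + 2L) {
    stop_degenerate(sprintf("degenerate design: %d records for %d columns",
                            n, k))
  }
  p <- as.numeric(records[[predictor]])
  if (stats::sd(p) == 0) {
    stop_degenerate(sprintf("degenerate design: predictor '%s' is constant",
                            predictor))
  }
  X <- cbind(intercept = 1, ga = as.numeric(records$ga_weeks), p)
  colnames(X)[3] <- predictor
  target <- predictor
  if (include_interaction) {
    chd <- as.numeric(records$chd)
    X <- cbind(X, chd = chd, p * chd)
    target <- paste0(predictor, ":chd")
    colnames(X)[5] <- target
  }
  if (qr(X)$rank < ncol(X)) {
    stop_degenerate("degenerate design: matrix is rank deficient")
  }
  structure(list(X = X, target = target, predictor = predictor,
                 include_interaction = include_interaction),
            class = "design_matrix")
}

design_X <- function(design) {
  if (inherits(design, "design_matrix")) design$X else as.matrix(design)
}

#' Ordinary least squares fit
#'
#' @param design a [build_design()] object or numeric matrix (full rank).
#' @param y response vector.
#' @return list with `coefficients`, `residuals`, `fitted`.
#' @export
ols_fit <- function(design, y) {
  X <- design_X(design)
  if (length(y) != nrow(X)) {
    abort2("length(y) must equal nrow(X)", "boldvar_bad_field")
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    stop_degenerate("degenerate design: matrix is rank deficient")
  }
  beta <- qr.coef(qx, y)
  fitted <- drop(X %*% beta)
  list(coefficients = beta, residuals = y - fitted, fitted = fitted)
}

#' One-sided wild-bootstrap p-value for one coefficient
#'
#' Null-restricted wild bootstrap with Rademacher multipliers, valid under
#' heteroskedastic errors: the model with the target coefficient forced to 0
#' is fitted, bootstrap responses `y* = fitted_null + r_null * v` (v i.i.d.
#' +/-1 per observation) are formed, the full model is refitted per replicate
#' and the target coefficient collected.  The one-sided p-value is
#' `(1 + #extreme) / (n_boot + 1)`, which never returns exactly 0.
#'
#' Replicate refits are evaluated in closed form (`beta* = w'y*` with `w` the
#' target row of `(X'X)^{-1} X'`), which is algebraically identical to a full
#' per-replicate OLS refit.
#'
#' @param design a [build_design()] object.
#' @param y response vector.
#' @param n_boot bootstrap replicates (>= 100; default 5000).
#' @param seed integer seed; fixed seed gives a deterministic p-value.
#' @param direction `"less"` (lower tail, the stated hypothesis that risk
#'   factors decrease variance) or `"greater"`.
#' @return object of class `regression_result`: list with `coefficient`,
#'   `p_one_sided`, `p_fdr` (NA until [fdr_adjust()] is applied across a
#'   family), `n_boot`, `n_obs`, `seed`, `direction`, `target`.
#' @export
wild_bootstrap_p <- function(design, y, n_boot = 5000L, seed = 1L,
                             direction = c("less", "greater")) {
  direction <- match.arg(direction)
  chk_num(n_boot, "n_boot", lower = 100, integerish = TRUE)
  chk_num(seed, "seed", integerish = TRUE)
  X <- design_X(design)
  ti <- match(design$target, colnames(X))
  if (is.na(ti)) abort2("target column not found", "boldvar_bad_field")
  n <- nrow(X)

  fit <- ols_fit(X, y)
  bhat <- unname(fit$coefficients[ti])
  fit0 <- ols_fit(X[, -ti, drop = FALSE], y)

  w <- solve(crossprod(X), t(X))[ti, ]
  c0 <- sum(w * fit0$fitted)
  wr <- w * fit0$residuals
  bstar <- with_seed(seed, {
    V <- matrix(sample(c(-1, 1), n * n_boot, replace = TRUE), n, n_boot)
    c0 + drop(crossprod(wr, V))
  })
  extreme <- if (direction == "less") sum(bstar <= bhat) else
    sum(bstar >= bhat)
  structure(
    list(coefficient = bhat,
         p_one_sided = (1 + extreme) / (n_boot + 1),
         p_fdr = NA_real_, n_boot = as.integer(n_boot), n_obs = n,
         seed = as.integer(seed), direction = direction,
         target = design$target),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf(
    "<regression_result> %s: coef = %.4g, one-sided p (%s) = %.4g [B = %d, n = %d]\n",
    x$target, x$coefficient, x$direction, x$p_one_sided, x$n_boot, x$n_obs))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, monotone in rank order and clipped at 1.  The
#' intended family is the four MRF predictors within one
#' (tissue, metric, effect-type) block.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted p-values, same order as the input.
#' @export
fdr_adjust <- function(p) {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p > 1)) {
    abort2("p-values must lie in [0, 1]", "boldvar_bad_field")
  }
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / seq(m, 1)))[ro]
}

#' Remove the gestational-age trend from a metric
#'
#' Residuals from one pooled least-squares fit of the values on `[1, GA]`
#' (pooled, not per group, so a group difference under test is not absorbed
#' by the adjustment).
#'
#' @param values metric values.
#' @param ga gestational ages (same length, >= 3).
#' @return zero-mean residual vector.
#' @export
ga_adjust <- function(values, ga) {
  if (length(values) != length(ga) || length(values) < 3) {
    abort2("values and ga must have equal length >= 3", "boldvar_bad_field")
  }
  if (stats::sd(ga) == 0) {
    warning("constant gestational age: returning mean-centred values")
    return(values - mean(values))
  }
  ols_fit(cbind(1, ga), values)$residuals
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum absolute difference of the two empirical CDFs; the
#' p-value uses the asymptotic K-S distribution.
#'
#' @param a,b numeric samples, each of length >= 5.
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(a, b) {
  if (length(a) < 5 || length(b) < 5) {
    abort2("each group needs >= 5 observations", "boldvar_bad_field")
  }
  kt <- suppressWarnings(stats::ks.test(a, b, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

sample_skewness <- function(x) {
  z <- x - mean(x)
  mean(z^3) / mean(z^2)^1.5
}

sample_kurtosis <- function(x) {
  z <- x - mean(x)
  mean(z^4) / mean(z^2)^2 - 3
}

#' Compare distribution moments between two groups
#'
#' Variance is compared with the two-sided variance-ratio F-test.  Skewness
#' and excess kurtosis are compared with a seeded permutation test on the
#' moment difference (an F-test is not defined for those moments).
#'
#' @param a,b numeric samples, each of length >= 8, nonzero variance.
#' @param n_perm permutation replicates.
#' @param seed integer seed for the permutation test.
#' @return list of `(statistic, p)` pairs for `variance`, `skewness`,
#'   `kurtosis`.
#' @export
moment_compare <- function(a, b, n_perm = 5000L, seed = 1L) {
  if (length(a) < 8 || length(b) < 8) {
    abort2("each group needs >= 8 observations", "boldvar_bad_field")
  }
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    abort2("zero variance in one of the groups", "boldvar_zero_variance")
  }
  chk_num(n_perm, "n_perm", lower = 1, integerish = TRUE)
  Fstat <- stats::var(a) / stats::var(b)
  df1 <- length(a) - 1L; df2 <- length(b) - 1L
  pF <- 2 * min(stats::pf(Fstat, df1, df2),
                1 - stats::pf(Fstat, df1, df2))
  pF <- min(1, pF)

  pooled <- c(a, b)
  na <- length(a)
  obs_sk <- sample_skewness(a) - sample_skewness(b)
  obs_ku <- sample_kurtosis(a) - sample_kurtosis(b)
  perm <- with_seed(seed, {
    sk <- numeric(n_perm); ku <- numeric(n_perm)
    for (i in seq_len(n_perm)) {
      ia <- sample.int(length(pooled), na)
      pa <- pooled[ia]; pb <- pooled[-ia]
      sk[i] <- sample_skewness(pa) - sample_skewness(pb)
      ku[i] <- sample_kurtosis(pa) - sample_kurtosis(pb)
    }
    list(sk = sk, ku = ku)
  })
  list(
    variance = list(statistic = Fstat, p = pF),
    skewness = list(statistic = obs_sk,
                    p = (1 + sum(abs(perm$sk) >= abs(obs_sk))) / (n_perm + 1)),
    kurtosis = list(statistic = obs_ku,
                    p = (1 + sum(abs(perm$ku) >= abs(obs_ku))) / (n_perm + 1))
  )
}

as_summary_triple <- function(x, name) {
  if (is.numeric(x) && is.null(names(x)) && length(x) > 1) {
    if (length(x) < 2) abort2(sprintf("'%s' needs n >= 2", name),
                              "boldvar_bad_field")
    return(list(mean = mean(x), sd = stats::sd(x), n = length(x)))
  }
  x <- as.list(x)
  if (!all(c("mean", "sd", "n") %in% names(x))) {
    abort2(sprintf("'%s' must be a raw sample or (mean, sd, n)", name),
           "boldvar_bad_field")
  }
  x
}

#' Welch unequal-variance t test
#'
#' Accepts raw samples or printed summary triples `(mean, sd, n)`, so cohort
#' tables published as mean (SD) can be tested directly.
#'
#' @param a,b numeric vectors or `list(mean =, sd =, n =)`.
#' @return list with `t`, `df`, `p` (two-sided).
#' @export
welch_t <- function(a, b) {
  sa <- as_summary_triple(a, "a")
  sb <- as_summary_triple(b, "b")
  if (sa$n < 2 || sb$n < 2) {
    abort2("each group needs n >= 2", "boldvar_bad_field")
  }
  va <- sa$sd^2 / sa$n; vb <- sb$sd^2 / sb$n
  se2 <- va + vb
  if (se2 == 0) return(list(t = 0, df = sa$n + sb$n - 2, p = 1))
  t <- (sa$mean - sb$mean) / sqrt(se2)
  df <- se2^2 / (va^2 / (sa$n - 1) + vb^2 / (sb$n - 1))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

#' Full MRF regression battery
#'
#' One wild-bootstrap regression per (metric column x predictor x
#' effect-type), mirroring the main-effect / CHD-interaction table layout.
#' FDR adjustment is applied across the four MRF predictors within each
#' (tissue, metric, effect-type) block.
#'
#' @param cohort data.frame with covariates and metric columns (see
#'   [generate_cohort()]).
#' @param metrics metric column names, `"<metric>_<tissue>"`.
#' @param predictors MRF predictor columns.
#' @param n_boot,seed,direction passed to [wild_bootstrap_p()]; per-cell
#'   seeds are derived deterministically from `seed`.
#' @return data.frame with one row per cell: `tissue`, `metric`,
#'   `predictor`, `effect_type`, `coefficient`, `p_one_sided`, `p_fdr`,
#'   `n_boot`, `seed`.
#' @export
mrf_battery <- function(cohort, metrics = c("tv_placenta", "sv_placenta",
                                            "tv_brain", "sv_brain"),
                        predictors = MRF_PREDICTORS, n_boot = 5000L,
                        seed = 1L, direction = "less") {
  cells <- expand.grid(predictor = predictors,
                       effect_type = c("main", "interaction"),
                       metric_col = metrics, stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(cells))
  rows <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    mc <- cells$metric_col[i]
    parts <- strsplit(mc, "_", fixed = TRUE)[[1]]
    cell <- tryCatch({
      des <- build_design(cohort, cells$predictor[i],
                          include_interaction = cells$effect_type[i] ==
                            "interaction")
      res <- wild_bootstrap_p(des, cohort[[mc]], n_boot = n_boot,
                              seed = seeds[i], direction = direction)
      list(coefficient = res$coefficient, p = res$p_one_sided,
           note = NA_character_)
    }, boldvar_degenerate_design = function(e) {
      # a degenerate design is reported as such, never as a number
      list(coefficient = NA_real_, p = NA_real_, note = conditionMessage(e))
    })
    rows[[i]] <- data.frame(
      tissue = parts[2], metric = parts[1], predictor = cells$predictor[i],
      effect_type = cells$effect_type[i], coefficient = cell$coefficient,
      p_one_sided = cell$p, p_fdr = NA_real_,
      n_boot = as.integer(n_boot), seed = seeds[i], note = cell$note,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  for (mc in unique(paste(out$tissue, out$metric))) {
    for (et in c("main", "interaction")) {
      sel <- paste(out$tissue, out$metric) == mc & out$effect_type == et &
        !is.na(out$p_one_sided)
      if (any(sel)) out$p_fdr[sel] <- fdr_adjust(out$p_one_sided[sel])
    }
  }
  out
}

#' CHD group comparison for one metric
#'
#' GA-adjusts the metric with one pooled regression, then compares CHD and
#' non-CHD residual distributions (K-S), their moments (F / permutation), and
#' the raw group means (Welch t).
#'
#' @param cohort data.frame with `chd`, `ga_weeks` and the metric column.
#' @param metric metric column name.
#' @param n_perm,seed permutation settings for [moment_compare()].
#' @return nested list (JSON-serializable) with `ks`, `moments`, `welch`,
#'   and group sizes.
#' @export
group_compare <- function(cohort, metric = "tv_placenta", n_perm = 5000L,
                          seed = 1L) {
  if (!metric %in% names(cohort)) {
    abort2(sprintf("metric column '%s' not found", metric),
           "boldvar_bad_field")
  }
  resid <- ga_adjust(cohort[[metric]], cohort$ga_weeks)
  a <- resid[cohort$chd == 1]
  b <- resid[cohort$chd == 0]
  out <- list(metric = metric, n_chd = length(a), n_non_chd = length(b))
  out$ks <- if (length(a) >= 5 && length(b) >= 5) ks_two_sample(a, b) else
    "skipped: group size < 5"
  out$moments <- if (length(a) >= 8 && length(b) >= 8) {
    moment_compare(a, b, n_perm = n_perm, seed = seed)
  } else {
    "skipped: group size < 8"
  }
  out$welch <- welch_t(cohort[[metric]][cohort$chd == 1],
                       cohort[[metric]][cohort$chd == 0])
  out
}
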