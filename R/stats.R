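#' Box-Cox transformation with profile-likelihood lambda selection
#'
#' Transforms positive data by `(x^lambda - 1) / lambda`, choosing lambda
#' by profile likelihood within `lambda_range` (default (0.1, 1.1), so the
#' log branch is never reached). Used to improve normality of pooled
#' profile values before parametric testing. Values must be positive;
#' baseline-relative dB profiles are offset to positivity first (see
#' [offset_to_positive()]).
#'
#' @param values Positive numeric vector.
#' @param lambda_range Length-2 numeric, the lambda search interval.
#' @return A list: `transformed`, `lambda`, `loglik`.
#' @export
#' @examples
#' box_cox(rlnorm(50))$lambda
box_cox <- function(values, lambda_range = c(0.1, 1.1)) {
  if (any(values <= 0)) {
    abort("Box-Cox requires positive values; offset the data first (see `offset_to_positive()`).")
  }
  grid <- seq(lambda_range[1], lambda_range[2], length.out = 201)
  # fit with y retained so MASS::boxcox does not refit the model in its
  # own frame (where this function's local data would not be visible)
  fit <- lm(values ~ 1, data = data.frame(values = values), y = TRUE)
  prof <- MASS::boxcox(fit, lambda = grid, plotit = FALSE)
  lambda <- prof$x[which.max(prof$y)]
  list(transformed = box_cox_transform(values, lambda),
       lambda = lambda,
       loglik = max(prof$y))
}

#' @rdname box_cox
#' @param lambda Transformation exponent.
#' @export
box_cox_transform <- function(values, lambda) {
  if (abs(lambda) < 1e-12) log(values) else (values^lambda - 1) / lambda
}

#' @rdname box_cox
#' @param y Transformed values.
#' @export
inv_box_cox <- function(y, lambda) {
  if (abs(lambda) < 1e-12) exp(y) else (y * lambda + 1)^(1 / lambda)
}

#' @rdname box_cox
#' @export
offset_to_positive <- function(values) {
  offset <- if (min(values) <= 0) 1 + abs(min(values)) else 0
  list(values = values + offset, offset = offset)
}

#' Compare two perfusion profiles (or paired sample sets)
#'
#' Whole-profile comparisons pool each curve's values, offset them to
#' positivity and apply a common Box-Cox transformation before testing
#' (two-sided t-test, Kruskal-Wallis, or Wilcoxon rank-sum). Point-wise
#' comparisons use `transform = FALSE`: the Wilcoxon test applied to the
#' raw dB values at one time point. Rank tests use exact enumeration of
#' the permutation null when the combined sample size is at most
#' `exact_max_n` (midranks under ties), and the standard large-sample
#' reference otherwise.
#'
#' @param a,b Numeric vectors (profile values on a common schedule, or the
#'   per-mouse values at one time point).
#' @param method One of `"t"`, `"kruskal_wallis"`, `"wilcoxon"`.
#' @param transform Apply offset + Box-Cox before testing?
#' @param exact_max_n Largest combined n for exact enumeration.
#' @return One-row tibble: `method`, `statistic`, `p_value`, `n_a`, `n_b`,
#'   `lambda` (`NA` when `transform = FALSE`), `exact`.
#' @export
#' @examples
#' compare_profiles(c(1, 2, 3), c(10, 11, 12), method = "wilcoxon",
#'                  transform = FALSE)
compare_profiles <- function(a, b,
                             method = c("t", "kruskal_wallis", "wilcoxon"),
                             transform = TRUE, exact_max_n = 12) {
  method <- match.arg(method)
  if (length(a) < 2 || length(b) < 2) {
    abort("Need at least 2 values per profile.")
  }
  lambda <- NA_real_
  if (transform) {
    pooled <- offset_to_positive(c(a, b))
    bc <- box_cox(pooled$values)
    lambda <- bc$lambda
    a <- bc$transformed[seq_along(a)]
    b <- bc$transformed[-seq_along(a)]
  }
  n <- length(a) + length(b)
  exact <- n <= exact_max_n && method != "t"
  if (length(unique(c(a, b))) == 1) {
    return(tibble(method = method, statistic = 0, p_value = 1,
                  n_a = length(a), n_b = length(b), lambda = lambda,
                  exact = exact))
  }
  res <- switch(
    method,
    t = {
      ht <- stats::t.test(a, b)
      c(unname(ht$statistic), ht$p.value)
    },
    wilcoxon = {
      if (exact) {
        rank_sum_exact(a, b)
      } else {
        ht <- suppressWarnings(stats::wilcox.test(a, b))
        c(unname(ht$statistic), ht$p.value)
      }
    },
    kruskal_wallis = {
      g <- factor(rep(c("a", "b"), c(length(a), length(b))))
      ht <- suppressWarnings(stats::kruskal.test(c(a, b), g))
      H <- unname(ht$statistic)
      if (exact) c(H, kruskal_exact_p(a, b, H)) else c(H, ht$p.value)
    }
  )
  tibble(method = method, statistic = res[1], p_value = res[2],
         n_a = length(a), n_b = length(b), lambda = lambda, exact = exact)
}

# Exact two-sided rank-sum test: enumerate every assignment of the pooled
# midranks to group a, statistic W = rank sum of a, p = 2 * min(tails)
# capped at 1. Returns c(W, p).
rank_sum_exact <- function(a, b) {
  r <- rank(c(a, b))
  na <- length(a)
  w_obs <- sum(r[seq_len(na)])
  combos <- utils::combn(length(r), na)
  w_all <- colSums(matrix(r[combos], nrow = na))
  eps <- 1e-9
  p <- min(1, 2 * min(mean(w_all <= w_obs + eps), mean(w_all >= w_obs - eps)))
  c(w_obs, p)
}

# Exact p-value for the (tie-corrected) two-group Kruskal-Wallis statistic
# by enumeration: p = P(H >= H_obs) under random assignment.
kruskal_exact_p <- function(a, b, h_obs) {
  r <- rank(c(a, b))
  n <- length(r)
  na <- length(a)
  ties <- table(r)
  tie_corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  combos <- utils::combn(n, na)
  ra <- colSums(matrix(r[combos], nrow = na))
  rb <- sum(r) - ra
  h_all <- (12 / (n * (n + 1))) * (ra^2 / na + rb^2 / (n - na)) - 3 * (n + 1)
  if (tie_corr > 0) h_all <- h_all / tie_corr
  mean(h_all >= h_obs - 1e-9)
}

#' Rank-based covariate-adjusted group comparison
#'
#' Permutation analogue of non-parametric ANCOVA: tests whether the mean
#' response differs between two groups while controlling for continuous
#' covariates. The response is rank-transformed, both the ranked response
#' and the group indicator are residualized against the covariates, and
#' the absolute cross-product of the residuals is compared with its
#' permutation distribution (Freedman-Lane style residual permutation).
#' Constant covariates are dropped with a warning. Seeded and reproducible.
#'
#' @param df Tibble with the response, a two-level group column, and the
#'   covariate columns.
#' @param value,group Column names (strings) for response and group.
#' @param covariates Character vector of covariate column names.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return One-row tibble: `statistic`, `p_value`, `n_perm`, `seed`, plus
#'   the per-group sample sizes.
#' @export
#' @examples
#' df <- tibble::tibble(y = rnorm(16), g = rep(c("A", "B"), 8),
#'                      age = runif(16, 6, 14), weight = runif(16, 20, 40))
#' ancova_adjusted_comparison(df, "y", "g", c("age", "weight"), seed = 1)
ancova_adjusted_comparison <- function(df, value, group,
                                       covariates = c("age_months", "weight_g"),
                                       n_perm = 999, seed = 1L) {
  if (!all(c(value, group, covariates) %in% names(df))) {
    abort("Missing columns in `df`.")
  }
  g <- factor(df[[group]])
  if (nlevels(g) != 2) abort("`group` must have exactly two levels.")
  if (min(table(g)) < 3) abort("Need at least 3 observations per group.")
  keep <- covariates[vapply(covariates,
                            function(cv) {
                              ok <- is.finite(df[[cv]]) & !is.na(df[[cv]])
                              all(ok) && sd(df[[cv]]) > 0
                            }, logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(dropped) > 0) {
    warn(sprintf("Dropping constant/non-finite covariate(s): %s",
                 paste(dropped, collapse = ", ")))
  }
  y <- rank(df[[value]])
  g01 <- as.numeric(g) - 1
  if (length(keep) > 0) {
    X <- as.matrix(df[keep])
    ry <- resid(lm(y ~ X))
    rg <- resid(lm(g01 ~ X))
  } else {
    ry <- y - mean(y)
    rg <- g01 - mean(g01)
  }
  obs <- abs(sum(ry * rg))
  set.seed(seed)
  perm <- vapply(seq_len(n_perm),
                 function(i) abs(sum(sample(ry) * rg)), numeric(1))
  p <- (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
  tibble(statistic = obs, p_value = p, n_perm = n_perm, seed = seed,
         n_a = sum(g01 == 0), n_b = sum(g01 == 1))
}

#' Glucose-tolerance AUCs by the trapezoid rule
#'
#' @param assay Tibble with `time_min` (must include -30, 0, 30, 60, 90)
#'   and `glucose` (mg/dL, > 0).
#' @return One-row tibble: `baseline` (the -30 min value), `auc_0_30`,
#'   `auc_30_90` (mg min/dL).
#' @export
#' @examples
#' glucose_aucs(tibble::tibble(time_min = c(-30, 0, 30, 60, 90),
#'                             glucose = c(150, 160, 300, 250, 200)))
glucose_aucs <- function(assay) {
  need <- c(-30, 0, 30, 60, 90)
  if (!all(need %in% assay$time_min)) {
    abort("Assay must include glucose at -30, 0, 30, 60, 90 min.")
  }
  if (any(assay$glucose <= 0)) abort("Glucose values must be positive.")
  gl <- function(t) assay$glucose[match(t, assay$time_min)]
  tibble(
    baseline = gl(-30),
    auc_0_30 = pracma::trapz(c(0, 30), gl(c(0, 30))),
    auc_30_90 = pracma::trapz(c(30, 60, 90), gl(c(30, 60, 90)))
  )
}

#' Classify a glucose-tolerance assay as diabetic
#'
#' A mouse is positive for diabetes when its fasting baseline (at -30 min)
#' exceeds `baseline_threshold` mg/dL AND both the 0-30 min and 30-90 min
#' AUCs are significantly elevated against a reference cohort of
#' non-diabetic assays (one-sample rank test of the reference AUCs against
#' the mouse's value, p < `alpha`).
#'
#' @param assay Tibble (`time_min`, `glucose`) for the mouse under test.
#' @param reference Tibble (`mouse_id`, `time_min`, `glucose`) of
#'   non-diabetic reference assays.
#' @param baseline_threshold Fasting-glucose gate, mg/dL.
#' @param alpha Significance level for the AUC comparisons.
#' @return A list: `positive` (logical) and `detail` (one-row tibble with
#'   the baseline, AUCs and p-values).
#' @export
classify_diabetic <- function(assay, reference, baseline_threshold = 200,
                              alpha = 0.05) {
  mouse <- glucose_aucs(assay)
  ref <- reference %>%
    group_by(.data$mouse_id) %>%
    dplyr::group_modify(~ glucose_aucs(.x)) %>%
    ungroup()
  if (nrow(ref) < 2) abort("Reference cohort needs at least 2 assays.")
  p1 <- suppressWarnings(
    stats::wilcox.test(ref$auc_0_30, mu = mouse$auc_0_30,
                       alternative = "less")$p.value)
  p2 <- suppressWarnings(
    stats::wilcox.test(ref$auc_30_90, mu = mouse$auc_30_90,
                       alternative = "less")$p.value)
  positive <- mouse$baseline > baseline_threshold && p1 < alpha && p2 < alpha
  list(positive = positive,
       detail = mouse %>% mutate(p_auc_0_30 = p1, p_auc_30_90 = p2))
}
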