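# Hydrophobicity trend regression and PLS variable importance.

#' Fixed-intercept log-log regression of recovery on TPSA
#'
#' Fits log10(recovery) = slope * log10(TPSA / 1 nm^2) by least squares
#' through the origin, which implements the convention "100% recovery at the
#' panel's maximum TPSA of 1 nm^2" exactly: a compound at 1 nm^2 has x = 0
#' and the fitted recovery is pinned at 1. The slope is reported in
#' log(recovery)/log(TPSA) units together with its 95% t interval
#' (slope SE = sqrt(sum((y - s x)^2) / ((n - 1) sum(x^2)))) and the ordinary
#' Pearson correlation of the transformed points.
#'
#' Recoveries above 1 (replicate noise) are retained up to 1.5 rather than
#' truncated, so the slope is not biased toward sorption; set
#' `truncate = TRUE` to cap them at 1 instead.
#'
#' @param tpsa_nm2 TPSA values (nm^2), > 0, not all equal to 1.
#' @param recovery Recovery fractions in (0, 1.5].
#' @param material Label carried on the fit (e.g. "PDMS").
#' @param norm_area_cm2 Surface area the recoveries are normalized to
#'   (needed for cross-material comparison).
#' @param level Confidence level, default 0.95.
#' @param truncate Cap recoveries at 1 before fitting (default FALSE).
#' @return Object of class `trend_fit`: `material`, `slope`, `slope_ci`,
#'   `pearson_r`, `n_points`, `norm_area_cm2`, `level`.
#' @export
fixed_intercept_loglog_fit <- function(tpsa_nm2, recovery,
                                       material = NA_character_,
                                       norm_area_cm2 = 1, level = 0.95,
                                       truncate = FALSE) {
  if (length(tpsa_nm2) != length(recovery)) stop("input lengths differ")
  n <- length(tpsa_nm2)
  if (n < 3) stop("need at least 3 points for a trend fit")
  if (any(tpsa_nm2 <= 0)) stop("TPSA must be > 0")
  if (any(recovery <= 0) || any(recovery > 1.5)) {
    stop("recoveries must lie in (0, 1.5]; censor or inspect outliers first")
  }
  if (truncate) recovery <- pmin(recovery, 1)

  x <- log10(tpsa_nm2)
  y <- log10(recovery)
  if (all(x == 0)) {
    stop("all TPSA values equal 1 nm^2: through-origin slope is undefined")
  }

  fit <- stats::lm(y ~ 0 + x)
  slope <- unname(stats::coef(fit)[1])
  # closed-form through-origin slope SE (df = n - 1); degenerate noiseless
  # input gives se = 0 and a point interval
  se <- sqrt(sum(stats::residuals(fit)^2) / ((n - 1) * sum(x^2)))
  half <- stats::qt((1 + level) / 2, df = n - 1) * se
  ci <- c(slope - half, slope + half)

  structure(
    list(material = material, slope = slope, slope_ci = ci,
         pearson_r = if (stats::sd(y) == 0) NA_real_ else stats::cor(x, y),
         n_points = n, norm_area_cm2 = norm_area_cm2, level = level),
    class = "trend_fit"
  )
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf(
    "<trend_fit> %s: slope %.3f (CI %.3f; %.3f), Pearson r %.2f, n = %d, at %g cm^2\n",
    ifelse(is.na(x$material), "?", x$material), x$slope, x$slope_ci[1],
    x$slope_ci[2], x$pearson_r, x$n_points, x$norm_area_cm2))
  invisible(x)
}

#' Compare trend fits across materials
#'
#' Orders materials by slope (steeper slope = stronger hydrophobicity-driven
#' sorption) and flags pairwise overlap of the slope confidence intervals.
#' All fits must be normalized to the same surface area.
#'
#' @param fits List of [fixed_intercept_loglog_fit()] objects.
#' @return List with `table` (data.frame ordered by slope:
#'   `material`, `slope`, `ci_low`, `ci_high`, `pearson_r`, `n`) and
#'   `overlap` (logical matrix of pairwise CI overlap).
#' @export
compare_material_trends <- function(fits) {
  stopifnot(length(fits) >= 1,
            all(vapply(fits, inherits, logical(1), "trend_fit")))
  areas <- vapply(fits, `[[`, numeric(1), "norm_area_cm2")
  if (length(unique(areas)) != 1) {
    stop("fits are normalized to different areas; renormalize before comparing")
  }
  tab <- data.frame(
    material = vapply(fits, `[[`, character(1), "material"),
    slope = vapply(fits, `[[`, numeric(1), "slope"),
    ci_low = vapply(fits, function(f) f$slope_ci[1], numeric(1)),
    ci_high = vapply(fits, function(f) f$slope_ci[2], numeric(1)),
    pearson_r = vapply(fits, `[[`, numeric(1), "pearson_r"),
    n = vapply(fits, `[[`, integer(1), "n_points"),
    stringsAsFactors = FALSE
  )
  ord <- order(tab$slope)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  k <- nrow(tab)
  overlap <- matrix(TRUE, k, k, dimnames = list(tab$material, tab$material))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      overlap[i, j] <- tab$ci_low[i] <= tab$ci_high[j] &&
        tab$ci_low[j] <= tab$ci_high[i]
    }
  }
  list(table = tab, overlap = overlap)
}

# -- PLS (NIPALS) with VIP scores ---------------------------------------------

# PLS1 NIPALS on autoscaled X and centered y; X-deflation only (equivalent to
# the classical algorithm for a univariate response).
nipals_pls1 <- function(X, y, ncomp) {
  n <- nrow(X); p <- ncol(X)
  W <- matrix(0, p, ncomp); TT <- matrix(0, n, ncomp)
  P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  Xa <- X; ya <- y
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xa, ya))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) stop("rank-deficient X: no variance left for component ", a)
    w <- w / nw
    t <- drop(Xa %*% w)
    tt <- sum(t^2)
    if (tt < 1e-12) stop("degenerate score vector at component ", a)
    pl <- drop(crossprod(Xa, t)) / tt
    qa <- sum(ya * t) / tt
    Xa <- Xa - tcrossprod(t, pl)
    ya <- ya - qa * t
    W[, a] <- w; TT[, a] <- t; P[, a] <- pl; q[a] <- qa
  }
  list(W = W, T = TT, P = P, q = q)
}

pls1_predict <- function(model, Xnew, ncomp) {
  # regression coefficients from weights/loadings for the first ncomp comps
  W <- model$W[, seq_len(ncomp), drop = FALSE]
  P <- model$P[, seq_len(ncomp), drop = FALSE]
  q <- model$q[seq_len(ncomp)]
  Wstar <- W %*% solve(crossprod(P, W))
  drop(Xnew %*% (Wstar %*% q))
}

# leave-one-out PRESS per component count, one-standard-error selection
select_ncomp_loo <- function(X, y, ncomp_max) {
  n <- nrow(X)
  errs <- matrix(NA_real_, n, ncomp_max)
  for (i in seq_len(n)) {
    Xi <- X[-i, , drop = FALSE]; yi <- y[-i]
    mu <- colMeans(Xi); sdv <- apply(Xi, 2, stats::sd)
    sdv[sdv == 0] <- 1
    Xs <- scale(Xi, mu, sdv); ym <- mean(yi)
    amax <- min(ncomp_max, qr(Xs)$rank)
    model <- tryCatch(nipals_pls1(Xs, yi - ym, amax), error = function(e) NULL)
    if (is.null(model)) next
    xnew <- (X[i, ] - mu) / sdv
    for (a in seq_len(amax)) {
      pred <- ym + pls1_predict(model, matrix(xnew, 1), a)
      errs[i, a] <- (y[i] - pred)^2
    }
  }
  cv <- colMeans(errs, na.rm = TRUE)
  se <- apply(errs, 2, function(e) stats::sd(e, na.rm = TRUE) /
                sqrt(sum(!is.na(e))))
  best <- which.min(cv)
  # one-standard-error rule: smallest model within one SE of the minimum
  which(cv <= cv[best] + se[best])[1]
}

#' PLS regression with variable-importance-in-projection scores
#'
#' Fits a univariate-response partial least squares regression (NIPALS) on an
#' autoscaled descriptor matrix and computes the VIP score of each
#' descriptor:
#'
#'   VIP_j = sqrt( p * sum_a SS_a (w_ja / ||w_a||)^2 / sum_a SS_a )
#'
#' where SS_a = q_a^2 t_a' t_a is the response variance captured by component
#' a. VIP scores satisfy mean(VIP^2) = 1 by construction; descriptors scoring
#' clearly above 1 matter for the response. When `n_components` is NULL the
#' component count is chosen by leave-one-out cross-validation with a
#' one-standard-error rule.
#'
#' @param X A [build_descriptor_matrix()] result (must be autoscaled) or a
#'   plain numeric matrix already autoscaled.
#' @param y Numeric response (e.g. log10 recovery per compound); centered
#'   internally.
#' @param n_components Number of PLS components, or NULL to select by LOO-CV.
#' @return Object of class `vip_result`: `descriptor_scores` (named, sorted
#'   decreasing), `n_components`, `y_variance_explained`.
#' @export
pls_vip <- function(X, y, n_components = NULL) {
  if (inherits(X, "descriptor_matrix")) {
    if (!X$autoscaled) stop("descriptor matrix must be autoscaled for PLS")
    X <- X$values
  }
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains missing values; impute first")
  if (nrow(X) != length(y)) stop("X rows and y length differ")
  yc <- y - mean(y)
  rankX <- qr(X)$rank
  if (!is.null(n_components) && n_components > rankX) {
    stop("n_components exceeds rank of X (", rankX, ")")
  }
  if (is.null(n_components)) {
    n_components <- select_ncomp_loo(X, y, min(rankX, ncol(X), nrow(X) - 2, 10))
  }

  model <- nipals_pls1(X, yc, n_components)
  ss <- model$q^2 * colSums(model$T^2)
  p <- ncol(X)
  w2 <- model$W^2 # columns already unit norm
  vip <- sqrt(p * drop(w2 %*% ss) / sum(ss))
  names(vip) <- colnames(X)

  fitted <- pls1_predict(model, X, n_components)
  r2y <- 1 - sum((yc - fitted)^2) / sum(yc^2)

  structure(
    list(descriptor_scores = sort(vip, decreasing = TRUE),
         n_components = n_components, y_variance_explained = r2y),
    class = "vip_result"
  )
}

#' @export
print.vip_result <- function(x, ...) {
  cat(sprintf("<vip_result> %d component(s), R2y = %.3f\n",
              x$n_components, x$y_variance_explained))
  top <- utils::head(x$descriptor_scores, 5)
  cat(paste(sprintf("  %-32s %.2f", names(top), top), collapse = "\n"), "\n")
  invisible(x)
}
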