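#' Association-analysis settings
#'
#' Numerical and inferential constants used by the dosage regressions and
#' Bayes-factor computation.
#'
#' @param ci_level Confidence level for odds-ratio / slope intervals.
#' @param abf_prior_sd Prior standard deviation \eqn{W} of the effect on the
#'   log-odds scale for the approximate Bayes factor. 0.2 corresponds to a
#'   95\% prior belief that the per-allele odds ratio lies within about
#'   (0.68, 1.48), a standard choice for complex-trait candidate variants.
#' @param irls_tol Convergence tolerance (max absolute coefficient change)
#'   for the iteratively reweighted least squares fitter.
#' @param irls_max_iter Maximum IRLS iterations.
#' @param alpha Nominal family-wise significance level before correction.
#' @return A list of class `assoc_config`.
#' @export
assoc_config <- function(ci_level = 0.95, abf_prior_sd = 0.2,
                         irls_tol = 1e-8, irls_max_iter = 25, alpha = 0.05) {
  if (!(ci_level > 0 && ci_level < 1)) stop_ubc("ci_level must be in (0,1)")
  if (abf_prior_sd <= 0) stop_ubc("abf_prior_sd must be > 0")
  structure(list(ci_level = ci_level, abf_prior_sd = abf_prior_sd,
                 irls_tol = irls_tol, irls_max_iter = irls_max_iter,
                 alpha = alpha),
            class = "assoc_config")
}

#' Minor allele frequency from a genotype-count triple
#'
#' Counts may be fractional (posterior-probability sums from imputed data).
#' The frequency of the first-listed allele is `p = (2 nAA + nAB) / (2 N)`;
#' the minor allele frequency is `min(p, 1 - p)`, which makes the result
#' invariant to allele relabelling.
#'
#' @param nAA,nAB,nBB Non-negative (possibly fractional) genotype counts.
#' @return Minor allele frequency in `[0, 0.5]`.
#' @examples
#' maf_from_counts(167, 455, 294)  # 0.4307...
#' @export
maf_from_counts <- function(nAA, nAB, nBB) {
  if (any(c(nAA, nAB, nBB) < 0)) stop_ubc("genotype counts must be >= 0")
  n <- nAA + nAB + nBB
  if (n <= 0) stop_ubc("total genotype count is zero; MAF undefined")
  p <- (2 * nAA + nAB) / (2 * n)
  min(p, 1 - p)
}

#' Genotype count triples for all, cases and controls
#'
#' With genotype-probability triples, each cell is the sum of per-patient
#' posterior probabilities (hence possibly fractional); with hard dosages
#' (integral 0/1/2) the counts are integers.
#'
#' @param prob Optional n x 3 matrix of per-patient probabilities (AA, AB, BB).
#' @param dosage Optional numeric vector of allele dosages; used only when
#'   `prob` is absent and all dosages are (near-)integral.
#' @param case_mask Logical vector: TRUE for cases.
#' @return List with numeric length-3 vectors `all`, `cases`, `controls`.
#' @export
genotype_count_triples <- function(prob = NULL, dosage = NULL, case_mask) {
  if (is.null(prob) && is.null(dosage))
    stop_ubc("one of prob or dosage is required")
  if (is.null(prob)) {
    if (any(abs(dosage - round(dosage)) > 1e-6))
      stop_ubc("fractional dosages without probability triples: counts undefined")
    g <- as.integer(round(dosage))
    prob <- matrix(0, length(g), 3)
    prob[cbind(seq_along(g), g + 1L)] <- 1
  }
  prob <- as.matrix(prob)
  if (ncol(prob) != 3L) stop_ubc("prob must have 3 columns")
  if (nrow(prob) != length(case_mask))
    stop_ubc("case_mask length does not match genotype rows")
  tri <- function(m) if (nrow(m)) colSums(m) else c(0, 0, 0)
  list(all      = unname(tri(prob)),
       cases    = unname(tri(prob[case_mask, , drop = FALSE])),
       controls = unname(tri(prob[!case_mask, , drop = FALSE])))
}

# shared design-matrix assembly and NA handling for the dosage fitters
build_design <- function(y, g, covariates) {
  X <- cbind(`(Intercept)` = 1, dosage = g)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]
  # constant adjustment covariates (e.g. sex in a single-sex subgroup) are
  # dropped rather than allowed to break the fit; a constant dosage still
  # errors in the callers
  if (ncol(X) > 2L) {
    const <- vapply(seq_len(ncol(X)), function(j)
      j > 2L && stats::var(X[, j]) == 0, logical(1))
    X <- X[, !const, drop = FALSE]
  }
  list(y = y[ok], X = X, n = sum(ok))
}

#' Logistic regression on allele dosage
#'
#' Maximum-likelihood logistic regression fitted by iteratively reweighted
#' least squares, with Wald standard errors from the inverse observed
#' information. The dosage coefficient is the per-allele log odds ratio under
#' an additive model. Non-convergence or quasi-separation is flagged
#' (`converged = FALSE`) and the last iterate is still reported with a
#' warning, so sparse subgroups remain visible rather than silently dropped.
#'
#' @param y Binary outcome vector (0/1 or logical).
#' @param g Allele dosage vector in `[0, 2]`. Missing dosages drop the patient
#'   from this fit only.
#' @param covariates Optional numeric matrix / data.frame of adjustment
#'   covariates (e.g. sex coded 0/1).
#' @param config An [assoc_config()].
#' @return List with `beta`, `se`, `z`, `p`, `or`, `ci` (length 2),
#'   `converged`, `n`, and the full `coefficients` vector.
#' @export
fit_logistic_dosage <- function(y, g, covariates = NULL, config = assoc_config()) {
  y <- as.numeric(y)
  d <- build_design(y, g, covariates)
  y <- d$y; X <- d$X
  if (d$n < ncol(X) + 1L) stop_ubc("too few complete observations (n=%d)", d$n)
  if (all(y == 0) || all(y == 1))
    stop_ubc("outcome has no cases or no controls")
  if (sd(X[, "dosage"]) == 0) stop_ubc("dosage is constant")

  p <- ncol(X)
  beta <- numeric(p)
  beta[1] <- qlogis(mean(y))
  converged <- FALSE
  XtWX <- NULL
  for (it in seq_len(config$irls_max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    zresp <- eta + (y - mu) / w
    sw <- sqrt(w)
    fit <- qr(X * sw)
    if (fit$rank < p) stop_ubc("design matrix is rank deficient")
    beta_new <- qr.coef(fit, zresp * sw)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    if (delta < config$irls_tol) { converged <- TRUE; break }
  }
  eta <- drop(X %*% beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-10)
  XtWX <- crossprod(X * sqrt(w))
  vc <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(vc)) stop_ubc("information matrix is singular")
  # quasi-separation: runaway coefficient with fitted probs at the boundary
  if (max(abs(beta)) > 12) converged <- FALSE
  if (!converged)
    warn_ubc("logistic fit did not converge (possible separation); estimates reported as-is")

  b <- beta[2]
  se <- sqrt(diag(vc))[2]
  z <- b / se
  pval <- 2 * pnorm(-abs(z))
  q <- qnorm(1 - (1 - config$ci_level) / 2)
  list(beta = unname(b), se = unname(se), z = unname(z),
       p = unname(pval), or = exp(unname(b)),
       ci = exp(c(b - q * se, b + q * se)),
       converged = converged, n = d$n,
       coefficients = stats::setNames(as.vector(beta), colnames(X)))
}

#' Linear regression on allele dosage
#'
#' Ordinary least squares for continuous outcomes (age at diagnosis), with
#' t-based two-sided p-values for the per-allele slope.
#'
#' @inheritParams fit_logistic_dosage
#' @param y Continuous outcome vector.
#' @return List with `beta`, `se`, `t`, `p`, `ci`, `n`, `coefficients`.
#' @export
fit_linear_dosage <- function(y, g, covariates = NULL, config = assoc_config()) {
  d <- build_design(as.numeric(y), g, covariates)
  y <- d$y; X <- d$X
  p <- ncol(X)
  if (d$n <= p) stop_ubc("n must exceed the number of parameters")
  if (sd(X[, "dosage"]) == 0) stop_ubc("dosage is constant")
  fit <- qr(X)
  if (fit$rank < p) stop_ubc("design matrix is rank deficient")
  beta <- qr.coef(fit, y)
  res <- y - drop(X %*% beta)
  df <- d$n - p
  sigma2 <- sum(res^2) / df
  vc <- sigma2 * chol2inv(qr.R(fit))
  b <- beta[2]
  se <- sqrt(diag(vc))[2]
  tstat <- b / se
  pval <- 2 * pt(-abs(tstat), df)
  qv <- stats::qt(1 - (1 - config$ci_level) / 2, df)
  list(beta = unname(b), se = unname(se), t = unname(tstat), p = unname(pval),
       ci = unname(c(b - qv * se, b + qv * se)), n = d$n,
       coefficients = stats::setNames(as.vector(beta), colnames(X)))
}

#' Approximate Bayes factor (alternative vs null), log10 scale
#'
#' Wakefield-style closed form: with a Normal(0, W^2) prior on the effect and
#' an approximately Normal likelihood `betahat ~ N(beta, se^2)`,
#' `BF = sqrt(se^2/(se^2+W^2)) * exp(z^2 W^2 / (2 (se^2+W^2)))` with
#' `z = beta/se`. Values above 0 favour association; below 0 favour the null.
#'
#' @param beta Estimated effect (log odds ratio or slope).
#' @param se Standard error, `> 0`.
#' @param W Prior standard deviation of the effect, `> 0`.
#' @return log10 Bayes factor (vectorised over its arguments).
#' @export
log10_abf <- function(beta, se, W = 0.2) {
  if (any(se <= 0)) stop_ubc("se must be > 0")
  if (any(W <= 0)) stop_ubc("W must be > 0")
  z <- beta / se
  r <- W^2 / (se^2 + W^2)
  (0.5 * log(1 - r) + z^2 * r / 2) / log(10)
}

#' Imputation INFO score from genotype-probability triples
#'
#' IMPUTE-style measure of imputation certainty. With per-patient expected
#' dosage `e_i` and second moment `f_i = pAB_i + 4 pBB_i`, and
#' `theta = sum(e_i) / (2N)`:
#' `info = 1 - sum(f_i - e_i^2) / (2 N theta (1 - theta))`.
#' Hard (degenerate) calls give 1; triples carrying no information beyond the
#' allele frequency give 0. Defined as 1 when `theta` is 0 or 1. The raw ratio
#' is clamped into `[0, 1]`: posteriors more dispersed than the binomial
#' reference (which cannot arise from a consistent imputation model) would
#' otherwise produce values below 0.
#'
#' @param prob n x 3 matrix of genotype probabilities (AA, AB, BB) per patient.
#' @return INFO score in `[0, 1]`.
#' @export
info_score <- function(prob) {
  prob <- as.matrix(prob)
  if (ncol(prob) != 3L) stop_ubc("prob must have 3 columns")
  if (any(prob < -1e-8) || any(abs(rowSums(prob) - 1) > 1e-6))
    stop_ubc("rows of prob must be probability triples summing to 1")
  n <- nrow(prob)
  e <- prob[, 2] + 2 * prob[, 3]
  f <- prob[, 2] + 4 * prob[, 3]
  theta <- sum(e) / (2 * n)
  if (theta <= 0 || theta >= 1) return(1)
  raw <- 1 - sum(f - e^2) / (2 * n * theta * (1 - theta))
  min(1, max(0, raw))
}

#' Linkage disequilibrium r-squared between two dosage vectors
#'
#' Squared Pearson correlation of allele dosages across the same patients;
#' invariant to allele flips (`g -> 2 - g`).
#'
#' @param g1,g2 Dosage vectors of equal length.
#' @return r^2 in `[0, 1]`.
#' @export
ld_r2 <- function(g1, g2) {
  if (length(g1) != length(g2)) stop_ubc("dosage vectors differ in length")
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]
  if (sd(g1) == 0 || sd(g2) == 0)
    stop_ubc("constant dosage vector: r^2 undefined")
  cor(g1, g2)^2
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha Family-wise significance level.
#' @param m Number of tests in the outcome family, `>= 1`.
#' @return `alpha / m`.
#' @examples
#' bonferroni_alpha(0.05, 69)  # 0.000724...
#' @export
bonferroni_alpha <- function(alpha, m) {
  if (length(m) != 1L || is.na(m) || m < 1) stop_ubc("m must be >= 1")
  alpha / m
}
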