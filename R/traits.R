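#' One-way ANOVA of a structure metric across trait categories
#'
#' Classical between/within sum-of-squares decomposition, treating each
#' group (e.g. each beetle family) as an independent unit. Requires at least
#' two categories with data and at least one residual degree of freedom.
#'
#' @param values Numeric vector of per-group metric values (e.g. NRI).
#' @param groups Category labels, one per value.
#' @return An object of class `"anova_oneway"`: list with `df_between`,
#'   `df_within`, `ss_between`, `ss_within`, `ms_between`, `ms_within`,
#'   `F`, `p`.
#' @export
anova_oneway <- function(values, groups) {
  values <- as.numeric(values)
  groups <- factor(as.character(groups))
  if (length(values) != length(groups))
    stop("anova_oneway: values and groups differ in length")
  if (anyNA(values) || anyNA(groups)) stop("anova_oneway: missing values")
  groups <- droplevels(groups)
  if (nlevels(groups) < 2)
    stop("anova_oneway: need at least two categories (no test performed)")
  if (length(values) - nlevels(groups) < 1)
    stop("anova_oneway: no residual degrees of freedom")
  tab <- suppressWarnings(stats::anova(stats::lm(values ~ groups)))
  out <- list(df_between = tab$Df[1], df_within = tab$Df[2],
              ss_between = tab$`Sum Sq`[1], ss_within = tab$`Sum Sq`[2],
              ms_between = tab$`Mean Sq`[1], ms_within = tab$`Mean Sq`[2],
              F = tab$`F value`[1], p = tab$`Pr(>F)`[1])
  if (out$ss_between < 1e-12 && out$ss_within < 1e-12) {
    # fully constant response: no variance to apportion
    out$F <- 0; out$p <- 1
  }
  structure(out, class = "anova_oneway")
}

#' @export
print.anova_oneway <- function(x, ...) {
  cat("One-way ANOVA\n")
  cat(sprintf("  between: df = %d, SS = %.4g, MS = %.4g\n",
              x$df_between, x$ss_between, x$ms_between))
  cat(sprintf("  within:  df = %d, SS = %.4g, MS = %.4g\n",
              x$df_within, x$ss_within, x$ms_within))
  cat(sprintf("  F = %.4g on (%d, %d) df, p = %.4g\n",
              x$F, x$df_between, x$df_within, x$p))
  invisible(x)
}

#' Pearson chi-square test on a count table
#'
#' Pearson X^2 = sum (O - E)^2 / E with expected counts from the row and
#' column margins; df = (R - 1)(C - 1). No continuity correction by default.
#' Used to ask whether the proportional representation of BINs in the local
#' community varies with a trait.
#'
#' @param counts Non-negative count matrix (R x C).
#' @param correct Apply the Yates continuity correction (2 x 2 only).
#'   Default `FALSE`.
#' @return List with `statistic`, `df`, `p`, and the `expected` counts.
#' @export
chisq_counts <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || anyNA(counts)) stop("chisq_counts: counts must be non-negative")
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("chisq_counts: need at least a 2 x 2 table")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("chisq_counts: zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value, expected = ct$expected)
}

#' Paired t-test between two analyses
#'
#' Pairs the two metric vectors by their names (e.g. family names) when both
#' are named, dropping and reporting unpaired entries; unnamed vectors of
#' equal length are paired positionally. The test is the standard paired t
#' on the differences `x - y`, two-tailed.
#'
#' @param x,y Numeric metric vectors, named by group for name-based pairing.
#' @return An object of class `"paired_t"`: list with `n_pairs`,
#'   `mean_diff`, `sd_diff`, `t`, `df`, `p`, `dropped`.
#' @export
paired_t <- function(x, y) {
  if (!is.null(names(x)) && !is.null(names(y))) {
    shared <- intersect(names(x), names(y))
    dropped <- union(setdiff(names(x), shared), setdiff(names(y), shared))
    x_p <- x[shared]; y_p <- y[shared]
  } else {
    if (length(x) != length(y))
      stop("paired_t: unnamed vectors must have equal length")
    dropped <- character(0)
    x_p <- x; y_p <- y
  }
  ok <- !is.na(x_p) & !is.na(y_p)
  x_p <- x_p[ok]; y_p <- y_p[ok]
  if (length(x_p) < 2) stop("paired_t: need at least 2 complete pairs")
  d <- x_p - y_p
  if (stats::sd(d) == 0 && mean(d) == 0) {
    res <- list(t = 0, df = length(d) - 1, p = 1)
  } else {
    tt <- stats::t.test(x_p, y_p, paired = TRUE)
    res <- list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
  }
  structure(list(n_pairs = length(d), mean_diff = mean(d), sd_diff = stats::sd(d),
                 t = res$t, df = res$df, p = res$p, dropped = dropped),
            class = "paired_t")
}

#' @export
print.paired_t <- function(x, ...) {
  cat(sprintf("Paired t-test: t = %.4g on %d df, p = %.4g (n = %d pairs",
              x$t, x$df, x$p, x$n_pairs))
  if (length(x$dropped)) cat(", dropped: ", paste(x$dropped, collapse = ", "))
  cat(")\n")
  cat(sprintf("  mean difference %.4g (sd %.4g)\n", x$mean_diff, x$sd_diff))
  invisible(x)
}

#' Brownian-motion covariance structure of a tree
#'
#' Under Brownian motion the expected trait covariance between two tips is
#' the shared path length from the root to their most recent common
#' ancestor; the diagonal holds the root-to-tip lengths. Paths are measured
#' from the tree's root node (for a star phylogeny every off-diagonal entry
#' is zero). A backbone tree with unit branch lengths is the typical input
#' for family-level analyses.
#'
#' @param tree A `phylo` tree with branch lengths, rooted at its root node.
#' @return Symmetric positive semidefinite covariance matrix over the tips.
#' @export
brownian_vcv <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("brownian_vcv: tree has no branch lengths")
  ape::vcv.phylo(tree)
}

#' Phylogenetic generalized least squares under Brownian motion
#'
#' Fits the linear model `formula` by generalized least squares with error
#' covariance proportional to the Brownian-motion structure of `tree`
#' (or an explicit covariance matrix `V`):
#' beta = (X' V^-1 X)^-1 X' V^-1 y. The Brownian rate sigma2 is the maximum
#' likelihood estimate RSS_V / n; coefficient standard errors use the
#' unbiased error variance RSS_V / (n - k) (the convention of standard GLS
#' summary tables), with t statistics on n - k degrees of freedom and
#' two-tailed p-values. With `V` equal to the identity the fit reduces to
#' ordinary least squares, and rescaling `V` by any positive constant leaves
#' the coefficients, t statistics and p-values unchanged. Categorical
#' predictors use treatment contrasts with the alphabetically first level as
#' reference.
#'
#' @param formula Model formula; the response is the per-tip metric.
#' @param data Data frame whose row names are the tip labels of `tree`
#'   (or the labels of `V`).
#' @param tree A rooted `phylo` tree with branch lengths; used to build the
#'   Brownian covariance via [brownian_vcv()]. Ignored when `V` is given.
#' @param V Optional explicit covariance matrix over the tips.
#' @return An object of class `"pgls_bm"` supporting `print`, `summary`,
#'   `coef`, `vcov`, `residuals`, `fitted`, `predict` and `logLik`.
#' @export
pgls_bm <- function(formula, data, tree = NULL, V = NULL) {
  if (is.null(V)) {
    if (is.null(tree)) stop("pgls_bm: supply either tree or V")
    V <- brownian_vcv(tree)
  }
  if (is.null(rownames(V)) || !identical(rownames(V), colnames(V)))
    stop("pgls_bm: V must carry identical row/column labels")
  if (is.null(rownames(data)))
    stop("pgls_bm: data must have row names matching the tips")
  if (!setequal(rownames(data), rownames(V)))
    stop("pgls_bm: data rows and covariance tips do not match; missing: ",
         paste(c(setdiff(rownames(V), rownames(data)),
                 setdiff(rownames(data), rownames(V))), collapse = ", "))
  data <- data[rownames(V), , drop = FALSE]
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  n <- length(y); k <- ncol(X)
  if (qr(X)$rank < k) {
    stop("pgls_bm: singular design; collinear columns among: ",
         paste(colnames(X), collapse = ", "))
  }
  L <- tryCatch(chol(V), error = function(e)
    stop("pgls_bm: covariance structure is not positive definite"))
  # whitened regression: solve L' z = . gives V^{-1/2}-transformed data
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  colnames(Xw) <- colnames(X)
  fit <- stats::lm.fit(Xw, yw)
  beta <- stats::setNames(fit$coefficients, colnames(X))
  rss <- sum(fit$residuals^2)
  sigma2_ml <- rss / n
  sigma2_err <- rss / (n - k)
  XtViX_inv <- solve(crossprod(Xw))
  dimnames(XtViX_inv) <- list(colnames(X), colnames(X))
  se <- sqrt(sigma2_err * diag(XtViX_inv))
  tval <- beta / se
  pval <- 2 * stats::pt(abs(tval), df = n - k, lower.tail = FALSE)
  logdetV <- 2 * sum(log(diag(L)))
  ll <- -0.5 * (n * log(2 * pi * sigma2_ml) + logdetV + n)
  structure(list(coefficients = beta, se = se, t = tval, p = pval,
                 sigma2 = sigma2_ml, sigma2_err = sigma2_err,
                 log_likelihood = ll, df_residual = n - k, n = n,
                 fitted = drop(X %*% beta), residuals = drop(y - X %*% beta),
                 cov_unscaled = XtViX_inv, formula = formula,
                 call = match.call(), terms = stats::terms(mf),
                 xlevels = stats::.getXlevels(stats::terms(mf), mf)),
            class = "pgls_bm")
}

#' @export
print.pgls_bm <- function(x, ...) {
  cat("Phylogenetic GLS (Brownian motion)\n")
  cat("Coefficients:\n")
  print(x$coefficients)
  cat(sprintf("sigma2 (ML) = %.4g, logLik = %.4g, n = %d\n",
              x$sigma2, x$log_likelihood, x$n))
  invisible(x)
}

#' @export
summary.pgls_bm <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se,
               `t value` = object$t, `Pr(>|t|)` = object$p)
  structure(list(coefficients = tab, sigma2 = object$sigma2,
                 log_likelihood = object$log_likelihood,
                 df_residual = object$df_residual, call = object$call),
            class = "summary.pgls_bm")
}

#' @export
print.summary.pgls_bm <- function(x, ...) {
  cat("Phylogenetic GLS (Brownian motion)\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nsigma2 (ML) = %.4g on %d residual df, logLik = %.4g\n",
              x$sigma2, x$df_residual, x$log_likelihood))
  invisible(x)
}

#' @export
coef.pgls_bm <- function(object, ...) object$coefficients

#' @export
vcov.pgls_bm <- function(object, ...) object$sigma2_err * object$cov_unscaled

#' @export
residuals.pgls_bm <- function(object, ...) object$residuals

#' @export
fitted.pgls_bm <- function(object, ...) object$fitted

#' @export
logLik.pgls_bm <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$coefficients) + 1,
            nobs = object$n, class = "logLik")
}

#' @export
nobs.pgls_bm <- function(object, ...) object$n

#' Predict expected values from a PGLS fit
#'
#' Returns the population-level expectation `X beta` for new data (the
#' phylogenetic correlation affects uncertainty, not the expectation).
#' @param object A `"pgls_bm"` fit.
#' @param newdata Optional data frame of predictors; defaults to fitted values.
#' @param ... Unused.
#' @export
predict.pgls_bm <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels)
  X <- stats::model.matrix(tt, mf)
  drop(X %*% object$coefficients)
}
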