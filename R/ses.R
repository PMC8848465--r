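#' Mean pairwise distance of a community
#'
#' Average of the distances over all unordered pairs of community members.
#' On the worked 4-taxon example with nodal distances
#' \{AB = 1, AC = 2, AD = 3, BC = 2, BD = 3, CD = 2\} this is
#' (1 + 2 + 3 + 2 + 3 + 2) / 6 = 2.1667.
#'
#' @param D Symmetric labelled distance matrix over the regional pool.
#' @param community Character vector of community member labels (>= 2),
#'   a subset of the matrix labels.
#' @return The mean pairwise distance.
#' @export
mpd <- function(D, community) {
  community <- .check_community(D, community)
  sub <- D[community, community, drop = FALSE]
  mean(sub[upper.tri(sub)])
}

#' Mean nearest-taxon distance of a community
#'
#' For each member, the minimum distance to any other member; the metric is
#' the mean of these per-tip minima. The minima are directional, so a
#' community of k members contributes k terms (on the worked 4-taxon
#' example: (1 + 1 + 2 + 2) / 4 = 1.5).
#'
#' @inheritParams mpd
#' @return The mean nearest-taxon distance.
#' @export
mntd <- function(D, community) {
  community <- .check_community(D, community)
  sub <- D[community, community, drop = FALSE]
  diag(sub) <- Inf
  mean(apply(sub, 1, min))
}

# fast kernels over integer tip indices (diagonal of D is zero)
.mpd_idx <- function(D, idx, k) sum(D[idx, idx]) / (k * (k - 1))

.mntd_idx <- function(D, idx, k) {
  sub <- D[idx, idx]
  diag(sub) <- Inf
  mean(sub[cbind(seq_len(k), max.col(-sub))])
}

.check_community <- function(D, community) {
  .check_distance_matrix(D)
  community <- as.character(community)
  if (anyDuplicated(community)) stop("community labels must be unique")
  if (length(community) < 2) stop("community must have at least 2 members")
  missing <- setdiff(community, rownames(D))
  if (length(missing))
    stop("community labels absent from distance matrix: ",
         paste(missing, collapse = ", "))
  community
}

#' Standardized effect size of a community metric (NRI / NTI)
#'
#' Compares the observed MPD or MNTD of a local community against a null
#' distribution obtained by drawing `n_iter` random communities of the same
#' richness uniformly from the regional pool (equivalent to shuffling the
#' tip labels of the regional phylogeny). The standardized effect size is
#' sign-flipped, ses = -(observed - null mean) / null sd, so that positive
#' values indicate phylogenetic clustering and negative values
#' overdispersion; for MPD this is the net relatedness index (NRI), for MNTD
#' the nearest taxon index (NTI). The primary p-value is the one-tailed
#' permutation probability of clustering, (number of null values <= observed
#' + 1) / (n_iter + 1), which cannot be zero and attains 1/(n_iter + 1) when
#' the observed value lies below the whole null distribution. A two-tailed
#' quantile p-value is reported alongside, since overdispersion is equally
#' interpretable.
#'
#' @inheritParams mpd
#' @param metric `"mpd"` or `"mntd"`.
#' @param n_iter Number of null randomizations. Default 1000.
#' @param seed Integer random seed (mandatory; results are reproducible).
#' @return An object of class `"ses_result"`: a list with elements `metric`,
#'   `observed`, `null_mean`, `null_sd`, `ses`, `p_value` (one-tailed,
#'   clustering), `p_two_sided`, `n_iterations`, `richness`, `seed`.
#' @seealso [nri()], [nti()]
#' @export
ses_metric <- function(D, community, metric = c("mpd", "mntd"),
                       n_iter = 1000, seed) {
  metric <- match.arg(metric)
  if (missing(seed)) stop("ses_metric: seed is mandatory")
  community <- .check_community(D, community)
  pool <- rownames(D)
  if (setequal(community, pool))
    stop("ses_metric: community equals the pool; null distribution is degenerate")
  # validated once above; the null loop uses unchecked integer-index kernels
  k <- length(community)
  n <- length(pool)
  fun <- if (metric == "mpd") .mpd_idx else .mntd_idx
  observed <- fun(D, match(community, pool), k)
  set.seed(seed)
  null <- vapply(seq_len(n_iter),
                 function(i) fun(D, sample.int(n, k), k), numeric(1))
  null_mean <- mean(null)
  null_sd <- stats::sd(null)
  if (!is.finite(null_sd) || null_sd < 1e-12)
    stop("ses_metric: degenerate null distribution (sd = 0)")
  p_low <- (sum(null <= observed) + 1) / (n_iter + 1)
  p_high <- (sum(null >= observed) + 1) / (n_iter + 1)
  structure(list(metric = toupper(metric), observed = observed,
                 null_mean = null_mean, null_sd = null_sd,
                 ses = -(observed - null_mean) / null_sd,
                 p_value = p_low,
                 p_two_sided = min(1, 2 * min(p_low, p_high)),
                 n_iterations = n_iter, richness = k, seed = seed),
            class = "ses_result")
}

#' Net relatedness index
#'
#' [ses_metric()] with `metric = "mpd"`: the sign-flipped standardized
#' effect size of the community's mean pairwise distance.
#' @inheritParams ses_metric
#' @return An object of class `"ses_result"`.
#' @export
nri <- function(D, community, n_iter = 1000, seed)
  ses_metric(D, community, metric = "mpd", n_iter = n_iter, seed = seed)

#' Nearest taxon index
#'
#' [ses_metric()] with `metric = "mntd"`: the sign-flipped standardized
#' effect size of the community's mean nearest-taxon distance.
#' @inheritParams ses_metric
#' @return An object of class `"ses_result"`.
#' @export
nti <- function(D, community, n_iter = 1000, seed)
  ses_metric(D, community, metric = "mntd", n_iter = n_iter, seed = seed)

#' @export
print.ses_result <- function(x, ...) {
  index <- if (x$metric == "MPD") "NRI" else "NTI"
  cat(sprintf("<ses_result> %s (%s), richness %d, %d randomizations\n",
              index, x$metric, x$richness, x$n_iterations))
  cat(sprintf("  observed %.4f, null %.4f +/- %.4f\n",
              x$observed, x$null_mean, x$null_sd))
  cat(sprintf("  %s = %.3f, one-tailed p (clustering) = %.4g, two-tailed p = %.4g\n",
              index, x$ses, x$p_value, x$p_two_sided))
  invisible(x)
}

#' Holm stepdown multiple-testing correction
#'
#' Stepdown family-wise error control: with the m raw p-values sorted
#' ascending, the i-th adjusted value is min(1, max over j <= i of
#' (m - j + 1) p_(j)), returned in the original input order. The smallest of
#' 16 raw p-values at p = .001 adjusts to .016.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @export
holm_bonferroni <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("holm_bonferroni: p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "holm")
}
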