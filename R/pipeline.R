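#' Run the full community-phylogenetics pipeline from files
#'
#' Orchestrates every stage on a BOLD-style TSV + FASTA export: ingestion,
#' quality filtering, regional/local subsetting by bounding box, group
#' selection (families or genera with at least `min_local_bins` local BINs),
#' reduction of each BIN to its centroid sequence, per-group distance-based
#' neighbor-joining trees, and NRI/NTI standardized effect sizes of the
#' local community against the group's regional pool, with stepdown
#' (Holm) corrected p-values across groups.
#'
#' @param metadata_file,fasta_file Paths to the specimen export.
#' @param local_box [region_box()] delimiting the local community.
#' @param regional_box Optional [region_box()] delimiting the regional pool;
#'   by default every filtered record belongs to the pool. Re-running with a
#'   tighter box is the restricted-pool sensitivity analysis.
#' @param rank `"family"` or `"genus"`.
#' @param min_local_bins Minimum distinct local BINs per group. Default 3.
#' @param marker_name,min_length,max_ambiguous_fraction Passed to
#'   [filter_records()].
#' @param model Distance model for [seq_distance_matrix()]. Default `"JC69"`.
#' @param trim_to Alignment columns kept before distance computation.
#'   Default 658.
#' @param n_iter Null randomizations per group. Default 1000.
#' @param seed Integer random seed (mandatory); group g uses `seed + g`.
#' @return An object of class `"bincomm_run"`: list with the per-group
#'   results `table` (group, n_pool, n_local, pct_local, NRI, p columns,
#'   Holm-adjusted p columns), the per-group `trees`, `groups`, the filtered
#'   datasets, and the call parameters.
#' @export
run_pipeline <- function(metadata_file, fasta_file, local_box,
                         regional_box = NULL, rank = c("family", "genus"),
                         min_local_bins = 3, marker_name = "COI-5P",
                         min_length = 500, max_ambiguous_fraction = 0.01,
                         model = "JC69", trim_to = 658, n_iter = 1000, seed) {
  rank <- match.arg(rank)
  if (missing(seed)) stop("run_pipeline: seed is mandatory")
  ds <- read_records(metadata_file, fasta_file)
  filtered <- filter_records(ds, marker_name = marker_name,
                             min_length = min_length,
                             max_ambiguous_fraction = max_ambiguous_fraction)
  regional <- if (is.null(regional_box)) filtered
              else subset_by_region(filtered, regional_box)
  local <- subset_by_region(filtered, local_box)
  groups <- select_groups(regional, local, rank = rank,
                          min_local_bins = min_local_bins)
  res <- run_group_metrics(regional, local, groups, rank = rank,
                           model = model, trim_to = trim_to,
                           n_iter = n_iter, seed = seed)
  res$datasets <- list(filtered = filtered, regional = regional, local = local)
  res$params <- list(rank = rank, min_local_bins = min_local_bins,
                     marker_name = marker_name, min_length = min_length,
                     max_ambiguous_fraction = max_ambiguous_fraction,
                     model = model, trim_to = trim_to, n_iter = n_iter,
                     seed = seed)
  res
}

#' Per-group community metrics from regional and local datasets
#'
#' The computational core of [run_pipeline()], exposed for workflows that
#' build their datasets in memory: for each group it reduces the group's
#' regional records to BIN centroids, builds a neighbor-joining tree from
#' the chosen distance model, and computes NRI and NTI for the group's
#' local BIN set against its regional pool.
#'
#' @inheritParams run_pipeline
#' @param regional,local [bin_dataset()] objects (already filtered).
#' @param groups Character vector of group names to analyze.
#' @return An object of class `"bincomm_run"` (see [run_pipeline()]).
#' @export
run_group_metrics <- function(regional, local, groups,
                              rank = c("family", "genus"), model = "JC69",
                              trim_to = 658, n_iter = 1000, seed) {
  rank <- match.arg(rank)
  if (missing(seed)) stop("run_group_metrics: seed is mandatory")
  trees <- list()
  rows <- list()
  for (g in seq_along(groups)) {
    group <- groups[g]
    stage <- function(what, expr) {
      tryCatch(expr, error = function(e)
        stop(sprintf("[%s] group %s: %s", what, group, conditionMessage(e)),
             call. = FALSE))
    }
    reg_g <- .keep_rows(regional, which(regional[[rank]] == group))
    loc_bins <- unique(local$bin_id[local[[rank]] == group])
    centroids <- stage("centroids",
                       reduce_to_centroids(reg_g, bin_alignments(reg_g,
                                                                 trim_to = trim_to)))
    aln <- stage("alignment",
                 dna_alignment(centroids$bin_id,
                               .trim_seqs(centroids$sequence, trim_to)))
    D_seq <- stage("distance", seq_distance_matrix(aln, model = model))
    tree <- stage("tree", nj_tree(D_seq))
    D <- tree_distance_matrix(tree, mode = "branch_length")
    community <- intersect(rownames(D), loc_bins)
    res_nri <- stage("nri", nri(D, community, n_iter = n_iter, seed = seed + g))
    res_nti <- stage("nti", nti(D, community, n_iter = n_iter, seed = seed + g))
    trees[[group]] <- tree
    rows[[group]] <- data.frame(
      group = group, n_pool = nrow(centroids), n_local = length(community),
      pct_local = round(100 * length(community) / nrow(centroids)),
      mpd_obs = res_nri$observed, nri = res_nri$ses, p_nri = res_nri$p_value,
      mntd_obs = res_nti$observed, nti = res_nti$ses, p_nti = res_nti$p_value,
      stringsAsFactors = FALSE)
  }
  table <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), n_pool = integer(), n_local = integer(),
               pct_local = numeric(), mpd_obs = numeric(), nri = numeric(),
               p_nri = numeric(), mntd_obs = numeric(), nti = numeric(),
               p_nti = numeric())
  rownames(table) <- NULL
  if (nrow(table)) {
    table$p_nri_holm <- holm_bonferroni(table$p_nri)
    table$p_nti_holm <- holm_bonferroni(table$p_nti)
  } else {
    table$p_nri_holm <- numeric(0)
    table$p_nti_holm <- numeric(0)
  }
  structure(list(table = table, groups = groups, trees = trees),
            class = "bincomm_run")
}

.trim_seqs <- function(seqs, trim_to) {
  if (!is.null(trim_to) && any(nchar(seqs) > trim_to))
    substr(seqs, 1L, as.integer(trim_to))
  else seqs
}

#' @export
print.bincomm_run <- function(x, ...) {
  cat(sprintf("<bincomm_run> %d group(s)\n", nrow(x$table)))
  if (nrow(x$table))
    print(x$table, digits = 4)
  invisible(x)
}

#' Paired comparison of two analyses
#'
#' Pairs two result tables by group name and compares their NRI and their
#' NTI values with paired t-tests -- the comparison used between a full and
#' a restricted regional pool, or between two regions sharing groups.
#'
#' @param a,b `"bincomm_run"` objects (or their `$table` data frames with
#'   columns `group`, `nri`, `nti`).
#' @return An object of class `"analysis_comparison"`: list with `nri` and
#'   `nti` [paired_t()] results, `n_pairs` and `dropped`.
#' @export
compare_analyses <- function(a, b) {
  ta <- if (is.data.frame(a)) a else a$table
  tb <- if (is.data.frame(b)) b else b$table
  va <- stats::setNames(ta$nri, ta$group)
  vb <- stats::setNames(tb$nri, tb$group)
  nri_cmp <- paired_t(va, vb)
  nti_cmp <- paired_t(stats::setNames(ta$nti, ta$group),
                      stats::setNames(tb$nti, tb$group))
  structure(list(nri = nri_cmp, nti = nti_cmp,
                 n_pairs = nri_cmp$n_pairs, dropped = nri_cmp$dropped),
            class = "analysis_comparison")
}

#' @export
print.analysis_comparison <- function(x, ...) {
  cat(sprintf("Paired comparison over %d shared group(s)\n", x$n_pairs))
  cat(sprintf("  NRI: t = %.4g, df = %d, p = %.4g\n", x$nri$t, x$nri$df, x$nri$p))
  cat(sprintf("  NTI: t = %.4g, df = %d, p = %.4g\n", x$nti$t, x$nti$df, x$nti$p))
  if (length(x$dropped))
    cat("  dropped:", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Published per-family community-structure tables
#'
#' Loads the transcribed per-family metrics for the 16 Coleoptera families
#' of Churchill, MB: BIN and sequence counts for the regional pool (Canada +
#' Alaska) and the local community, trait categories (habitat, adult and
#' larval feeding mode), and the published NRI/NTI clustering values with
#' their permutation p-values. `pool = "restricted"` loads the
#' sensitivity-analysis rerun in which the regional pool was restricted to
#' Manitoba, Nunavut, Northwest Territories, Saskatchewan and Ontario.
#' These tables are the worked inputs for the paired sensitivity
#' comparisons, the significance accounting and the trait analyses.
#'
#' @param pool `"full"` or `"restricted"`.
#' @return Data frame with columns `family`, `n_bins_regional`,
#'   `n_bins_local`, `pct_local`, `n_seqs_regional`, `n_seqs_local`,
#'   `habitat`, `adult_diet`, `larval_diet`, `nri`, `p_nri`, `nti`, `p_nti`.
#' @export
load_family_metrics <- function(pool = c("full", "restricted")) {
  pool <- match.arg(pool)
  fname <- if (pool == "full") "churchill_family_metrics.tsv"
           else "churchill_family_metrics_restricted.tsv"
  path <- system.file("extdata", fname, package = "bincomm", mustWork = TRUE)
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
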