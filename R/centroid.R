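#' Construct an aligned set of sequences
#'
#' @param labels Character vector of unique row labels.
#' @param rows Character vector of equal-length nucleotide strings over
#'   `{A, C, G, T, N, -}` (case-insensitive).
#' @return An object of class `"dna_alignment"` with elements `labels`,
#'   `rows` (named by label) and `length` (number of columns).
#' @export
dna_alignment <- function(labels, rows) {
  labels <- as.character(labels)
  rows <- toupper(as.character(rows))
  if (length(labels) != length(rows))
    stop("dna_alignment: labels and rows differ in length")
  if (length(labels) == 0) stop("dna_alignment: empty alignment")
  if (anyDuplicated(labels))
    stop("dna_alignment: duplicate labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "))
  len <- unique(nchar(rows))
  if (length(len) != 1)
    stop("dna_alignment: rows are not all the same length")
  if (len == 0) stop("dna_alignment: zero-length rows")
  bad <- grepl("[^ACGTN-]", rows)
  if (any(bad))
    stop("dna_alignment: invalid characters in rows: ",
         paste(labels[bad], collapse = ", "))
  names(rows) <- labels
  structure(list(labels = labels, rows = rows, length = len),
            class = "dna_alignment")
}

#' @export
print.dna_alignment <- function(x, ...) {
  cat(sprintf("<dna_alignment> %d sequences x %d columns\n",
              length(x$labels), x$length))
  invisible(x)
}

# Character matrix view of an alignment (rows = sequences).
.aln_matrix <- function(aln) {
  m <- matrix(unlist(strsplit(aln$rows, "", fixed = TRUE), use.names = FALSE),
              nrow = length(aln$labels), ncol = aln$length, byrow = TRUE)
  rownames(m) <- aln$labels
  m
}

.aln_subset_cols <- function(aln, cols) {
  m <- .aln_matrix(aln)[, cols, drop = FALSE]
  dna_alignment(aln$labels, apply(m, 1, paste, collapse = ""))
}

#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of differing sites among the columns where both characters are
#' unambiguous bases (pairwise deletion of N and gap characters).
#'
#' @param a,b Equal-length nucleotide strings.
#' @return Proportion in `[0, 1]`.
#' @export
p_distance <- function(a, b) {
  a <- strsplit(toupper(a), "", fixed = TRUE)[[1]]
  b <- strsplit(toupper(b), "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) stop("p_distance: sequences differ in length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  if (!any(ok))
    stop("p_distance: no comparable columns (distance undefined)")
  mean(a[ok] != b[ok])
}

# All pairwise p-distances within an alignment; errors name the offending
# pair when no comparable columns exist.
.pairwise_p <- function(aln) {
  m <- .aln_matrix(aln)
  good <- m == "A" | m == "C" | m == "G" | m == "T"
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(aln$labels, aln$labels))
  if (n == 1) return(D)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- good[i, ] & good[j, ]
      n_ok <- sum(ok)
      if (n_ok == 0)
        stop("p-distance undefined (no comparable columns) for pair: ",
             aln$labels[i], ", ", aln$labels[j])
      D[i, j] <- D[j, i] <- sum(m[i, ok] != m[j, ok]) / n_ok
    }
  }
  D
}

#' Centroid sequence of a BIN
#'
#' The centroid is the member with the minimum average p-distance to all
#' other members of its BIN; it is the single representative carried forward
#' into phylogenetic analysis. Ties are broken by the lexicographically
#' smallest label so the choice is independent of row order.
#'
#' @param bin_alignment A [dna_alignment()] of all members of one BIN.
#' @return The chosen label, with the per-member mean distances attached as
#'   attribute `"mean_distances"`.
#' @export
centroid <- function(bin_alignment) {
  stopifnot(inherits(bin_alignment, "dna_alignment"))
  labs <- bin_alignment$labels
  if (length(labs) == 1)
    return(structure(labs, mean_distances = stats::setNames(0, labs)))
  D <- .pairwise_p(bin_alignment)
  means <- rowSums(D) / (length(labs) - 1)
  best <- min(means)
  chosen <- sort(names(means)[means <= best + 1e-12])[1]
  structure(chosen, mean_distances = means)
}

#' Per-BIN alignments from a dataset
#'
#' Splits a dataset's sequences by BIN and packages each group as a
#' [dna_alignment()] keyed by record id. Sequences within a BIN must already
#' be aligned (equal length); sequences generated by the synthetic module are
#' aligned by construction, real data should be re-imported as aligned FASTA.
#'
#' @param ds A [bin_dataset()] in which every record has a BIN.
#' @param trim_to Optional column count; alignments longer than this are
#'   trimmed to their first `trim_to` positions (the conventional 658-bp
#'   barcode window).
#' @return Named list of [dna_alignment()] objects, one per BIN.
#' @export
bin_alignments <- function(ds, trim_to = NULL) {
  stopifnot(inherits(ds, "bin_dataset"))
  if (anyNA(ds$bin_id))
    stop("bin_alignments: records without a BIN: ",
         paste(ds$record_id[is.na(ds$bin_id)], collapse = ", "))
  out <- lapply(split(seq_len(nrow(ds)), ds$bin_id), function(idx) {
    seqs <- ds$sequence[idx]
    if (length(unique(nchar(seqs))) != 1)
      stop("bin_alignments: unaligned sequences (unequal lengths) in BIN ",
           ds$bin_id[idx[1]])
    if (!is.null(trim_to) && nchar(seqs[1]) > trim_to)
      seqs <- substr(seqs, 1L, as.integer(trim_to))
    dna_alignment(ds$record_id[idx], seqs)
  })
  out[sort(names(out))]
}

#' Reduce a dataset to one centroid record per BIN
#'
#' @param ds A [bin_dataset()] in which every record has a BIN.
#' @param per_bin_alignments Named list of [dna_alignment()] objects, one per
#'   BIN, covering all of that BIN's member record ids. Defaults to
#'   [bin_alignments()] on `ds` itself.
#' @return A [bin_dataset()] with exactly one record per distinct BIN; the
#'   selection report (bin_id, record_id, mean distance) is attached as
#'   attribute `"centroid_report"`.
#' @export
reduce_to_centroids <- function(ds, per_bin_alignments = NULL) {
  stopifnot(inherits(ds, "bin_dataset"))
  if (is.null(per_bin_alignments)) per_bin_alignments <- bin_alignments(ds)
  bins <- sort(unique(ds$bin_id))
  if (anyNA(bins))
    stop("reduce_to_centroids: records without a BIN assignment present")
  missing_aln <- setdiff(bins, names(per_bin_alignments))
  if (length(missing_aln))
    stop("reduce_to_centroids: no alignment for BIN(s): ",
         paste(missing_aln, collapse = ", "))
  chosen <- character(length(bins))
  meandist <- numeric(length(bins))
  for (k in seq_along(bins)) {
    members <- ds$record_id[ds$bin_id == bins[k]]
    aln <- per_bin_alignments[[bins[k]]]
    uncovered <- setdiff(members, aln$labels)
    if (length(uncovered))
      stop("reduce_to_centroids: alignment for BIN ", bins[k],
           " does not cover member(s): ", paste(uncovered, collapse = ", "))
    # restrict the alignment to this BIN's members before choosing
    keep <- aln$labels %in% members
    aln <- dna_alignment(aln$labels[keep], aln$rows[keep])
    lab <- centroid(aln)
    chosen[k] <- lab
    meandist[k] <- attr(lab, "mean_distances")[[lab]]
  }
  out <- .keep_rows(ds, match(chosen, ds$record_id))
  out <- .log_step(out, sprintf("reduce_to_centroids: %d records -> %d BIN centroids",
                                nrow(ds), nrow(out)))
  attr(out, "centroid_report") <- data.frame(bin_id = bins, record_id = chosen,
                                             mean_distance = meandist,
                                             stringsAsFactors = FALSE)
  out
}
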