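#' Pairwise sequence distance matrix
#'
#' Computes pairwise distances between all rows of an alignment under the
#' uncorrected p-distance or one of the classical corrections. Sites where
#' either sequence carries N or a gap are deleted pairwise. Corrections are
#' `JC69`, d = -(3/4) log(1 - (4/3) p), and `K80`, the two-parameter formula
#' d = -(1/2) log((1 - 2P - Q) sqrt(1 - 2Q)) with P and Q the transition and
#' transversion proportions. Pairs for which the correction is undefined
#' (log argument <= 0) raise a saturation error naming the pair.
#'
#' @param aln A [dna_alignment()] with at least two rows.
#' @param model `"JC69"` (default), `"p"` or `"K80"`.
#' @return A symmetric numeric matrix with zero diagonal, labelled by the
#'   alignment labels.
#' @export
seq_distance_matrix <- function(aln, model = c("JC69", "p", "K80")) {
  model <- match.arg(model)
  stopifnot(inherits(aln, "dna_alignment"))
  n <- length(aln$labels)
  if (n < 2) stop("seq_distance_matrix: need at least 2 sequences")
  m <- .aln_matrix(aln)
  good <- m == "A" | m == "C" | m == "G" | m == "T"
  purine <- m == "A" | m == "G"
  D <- matrix(0, n, n, dimnames = list(aln$labels, aln$labels))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- good[i, ] & good[j, ]
      n_ok <- sum(ok)
      if (n_ok == 0)
        stop("seq_distance_matrix: no comparable columns for pair: ",
             aln$labels[i], ", ", aln$labels[j])
      diff <- m[i, ok] != m[j, ok]
      p <- sum(diff) / n_ok
      d <- switch(model,
        p = p,
        JC69 = {
          if (p >= 0.75)
            stop("seq_distance_matrix: JC69 saturated (p = ", signif(p, 4),
                 ") for pair: ", aln$labels[i], ", ", aln$labels[j])
          -0.75 * log(1 - 4 * p / 3)
        },
        K80 = {
          ts <- sum(diff & (purine[i, ok] == purine[j, ok])) / n_ok
          tv <- p - ts
          a1 <- 1 - 2 * ts - tv
          a2 <- 1 - 2 * tv
          if (a1 <= 0 || a2 <= 0)
            stop("seq_distance_matrix: K80 saturated for pair: ",
                 aln$labels[i], ", ", aln$labels[j])
          -0.5 * log(a1 * sqrt(a2))
        })
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

.check_distance_matrix <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop("distance matrix must be square")
  if (is.null(rownames(D)) || is.null(colnames(D)) ||
      !identical(rownames(D), colnames(D)))
    stop("distance matrix must carry identical row/column labels")
  if (anyDuplicated(rownames(D))) stop("distance matrix labels must be unique")
  if (any(D < 0)) stop("distance matrix must be non-negative")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix must have zero diagonal")
  invisible(TRUE)
}

# Deterministic pair choice: among (i, j) pairs attaining the minimum
# criterion (within tol), take the one whose sorted representative-label
# pair is lexicographically smallest.
.pick_pair <- function(crit, reps, tol = 1e-12) {
  lo <- min(crit[upper.tri(crit)])
  cand <- which(upper.tri(crit) & crit <= lo + tol, arr.ind = TRUE)
  keys <- apply(cand, 1, function(ij) {
    pair <- sort(c(reps[ij[1]], reps[ij[2]]))
    paste(pair, collapse = "\r")
  })
  cand[order(keys)[1], ]
}

#' Neighbor-joining tree
#'
#' Classical agglomerative neighbor joining on a labelled distance matrix:
#' at each step the pair minimizing the Q criterion
#' Q(i,j) = (m - 2) d(i,j) - r(i) - r(j) is joined and branch lengths are
#' assigned by the divergence formula. On additive matrices the tree's path
#' distances reproduce the input exactly. Ties in Q are broken by the
#' lexicographically smallest label pair (labels of the original tips
#' represent their clusters), so the result is independent of input order.
#' A negative branch length is clamped to zero and the deficit transferred
#' to its sister branch, preserving the pair's total.
#'
#' @param D Symmetric labelled distance matrix with at least 3 labels.
#' @return An unrooted `phylo` tree (see \pkg{ape}).
#' @export
nj_tree <- function(D) {
  .check_distance_matrix(D)
  m <- nrow(D)
  if (m < 3) stop("nj_tree: need at least 3 labels")
  if (all(D == 0)) stop("nj_tree: degenerate all-zero distance matrix")
  labs <- rownames(D)
  # assemble via placeholder labels: real labels may hold newick
  # metacharacters (BOLD BIN ids contain ':')
  ph <- sprintf("Lx%dx", seq_len(m))
  frag <- ph                   # newick fragment per active cluster
  reps <- labs                 # representative (smallest) original label
  fmt <- function(x) sprintf("%.12g", x)
  while (m > 3) {
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    ij <- .pick_pair(Q, reps)
    i <- ij[1]; j <- ij[2]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    bi <- max(bi, 0); bj <- max(bj, 0)
    new_frag <- paste0("(", frag[i], ":", fmt(bi), ",", frag[j], ":", fmt(bj), ")")
    new_rep <- min(reps[i], reps[j])
    keep <- setdiff(seq_len(m), c(i, j))
    d_new <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    d_new <- pmax(d_new, 0)
    D <- rbind(cbind(D[keep, keep, drop = FALSE], d_new),
               c(d_new, 0))
    frag <- c(frag[keep], new_frag)
    reps <- c(reps[keep], new_rep)
    m <- m - 1
    dimnames(D) <- list(reps, reps)
  }
  # final 3-cluster star: closed-form three-point branch lengths
  b1 <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b2 <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  b3 <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  nwk <- paste0("(", frag[1], ":", fmt(b[1]), ",", frag[2], ":", fmt(b[2]),
                ",", frag[3], ":", fmt(b[3]), ");")
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- labs[match(tree$tip.label, ph)]
  tree
}

#' Bootstrap replicate trees
#'
#' Resamples alignment columns with replacement (keeping the original
#' length), recomputes the distance matrix and neighbor-joining tree for
#' each replicate. Replicates whose distance matrix is saturated or
#' degenerate are skipped and counted.
#'
#' @param aln A [dna_alignment()].
#' @param B Number of replicates (>= 1).
#' @param model Distance model passed to [seq_distance_matrix()].
#' @param seed Integer random seed (mandatory; replicates are reproducible).
#' @return List of `phylo` trees with attributes `"skipped"` (number of
#'   failed replicates), `"skip_messages"`, and `"seed"`.
#' @export
bootstrap_replicates <- function(aln, B, model = "JC69", seed) {
  stopifnot(inherits(aln, "dna_alignment"))
  if (missing(seed)) stop("bootstrap_replicates: seed is mandatory")
  if (B < 1) stop("bootstrap_replicates: B must be >= 1")
  set.seed(seed)
  trees <- vector("list", B)
  msgs <- character(0)
  for (b in seq_len(B)) {
    cols <- sample.int(aln$length, aln$length, replace = TRUE)
    rep_aln <- .aln_subset_cols(aln, cols)
    t_b <- tryCatch(nj_tree(seq_distance_matrix(rep_aln, model = model)),
                    error = function(e) e)
    if (inherits(t_b, "error")) {
      msgs <- c(msgs, sprintf("replicate %d: %s", b, conditionMessage(t_b)))
      trees[[b]] <- NULL
    } else {
      trees[[b]] <- t_b
    }
  }
  out <- Filter(Negate(is.null), trees)
  attr(out, "skipped") <- B - length(out)
  attr(out, "skip_messages") <- msgs
  attr(out, "seed") <- seed
  out
}

# Canonical keys for the nontrivial bipartitions of a tree: each internal
# edge splits the tips in two; the key is the sorted side not containing the
# overall smallest tip label.
.bipartition_keys <- function(tree) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  pp <- ape::prop.part(tree)
  n <- length(tree$tip.label)
  keys <- vapply(pp, function(part) {
    side <- sort(tree$tip.label[part])
    if (length(side) < 2 || length(side) > n - 2) return(NA_character_)
    if (anchor %in% side) side <- setdiff(tips, side)
    paste(side, collapse = "\r")
  }, character(1))
  keys  # aligned with internal nodes n+1 .. n+Nnode; NA for trivial splits
}

#' Annotate a tree with bootstrap clade support
#'
#' Each internal edge of `main` is annotated (as a node label) with the
#' percentage of replicate trees containing the same bipartition of tip
#' labels. The median of the nodal support values is attached as attribute
#' `"median_support"`.
#'
#' @param main A `phylo` tree.
#' @param replicates List of `phylo` trees over the same tip set.
#' @return `main` with percentage supports in `$node.label`.
#' @export
clade_support <- function(main, replicates) {
  stopifnot(inherits(main, "phylo"))
  if (length(replicates) == 0) stop("clade_support: no replicates")
  for (r in replicates)
    if (!setequal(r$tip.label, main$tip.label))
      stop("clade_support: replicate has a different tip set")
  B <- length(replicates)
  # one vote per bipartition per replicate (a rooted tree's two root-child
  # clades canonicalize to the same split)
  rep_keys <- unlist(lapply(replicates, function(t) {
    k <- .bipartition_keys(t)
    unique(k[!is.na(k)])
  }), use.names = FALSE)
  counts <- table(rep_keys)
  main_keys <- .bipartition_keys(main)
  supp <- ifelse(is.na(main_keys), NA_real_,
                 100 * as.numeric(counts[main_keys]) / B)
  supp[is.na(supp) & !is.na(main_keys)] <- 0
  main$node.label <- ifelse(is.na(supp), "", sprintf("%g", supp))
  attr(main, "support") <- supp
  attr(main, "median_support") <- stats::median(supp, na.rm = TRUE)
  main
}

#' Maximum clade credibility tree of a replicate set
#'
#' Scores every replicate by the sum, over its nontrivial bipartitions, of
#' that bipartition's frequency across all replicates, and returns the
#' replicate with the highest score (ties broken by first index). The
#' majority-rule (> 50 percent) consensus topology is attached as attribute
#' `"majority_consensus"`.
#'
#' @param replicates Non-empty list of `phylo` trees over a common tip set.
#' @return The maximum clade credibility `phylo` tree, with attributes
#'   `"score"` and `"majority_consensus"`.
#' @export
mcc_tree <- function(replicates) {
  if (length(replicates) == 0) stop("mcc_tree: empty replicate list")
  B <- length(replicates)
  key_list <- lapply(replicates, function(t) {
    k <- .bipartition_keys(t)
    unique(k[!is.na(k)])
  })
  freq <- table(unlist(key_list, use.names = FALSE)) / B
  scores <- vapply(key_list, function(k) {
    if (!length(k)) return(0)
    sum(as.numeric(freq[k]))
  }, numeric(1))
  best <- which.max(scores)
  out <- replicates[[best]]
  attr(out, "score") <- scores[best]
  attr(out, "majority_consensus") <-
    if (B > 1) ape::consensus(replicates, p = 0.5) else replicates[[1]]
  out
}

#' Root a tree with an outgroup
#'
#' Places the root on the edge separating the outgroup clade from the rest.
#' If the outgroup is not monophyletic in the unrooted tree, a warning is
#' issued and the tree is rooted on the pendant edge of the first listed
#' outgroup tip instead.
#'
#' @param tree A `phylo` tree.
#' @param outgroup_labels Character vector of outgroup tip labels (a strict
#'   subset of the tips).
#' @return A rooted `phylo` tree.
#' @export
root_with_outgroup <- function(tree, outgroup_labels) {
  stopifnot(inherits(tree, "phylo"))
  if (!length(outgroup_labels) || !all(outgroup_labels %in% tree$tip.label))
    stop("root_with_outgroup: outgroup labels must be a subset of tips")
  if (length(outgroup_labels) >= length(tree$tip.label))
    stop("root_with_outgroup: outgroup cannot contain all tips")
  mono <- length(outgroup_labels) == 1 ||
    .is_split(tree, outgroup_labels)
  if (!mono) {
    warning("root_with_outgroup: outgroup not monophyletic; rooting on first tip '",
            outgroup_labels[1], "'")
    outgroup_labels <- outgroup_labels[1]
  }
  ape::root(tree, outgroup = outgroup_labels, resolve.root = TRUE)
}

# Does `side` form one side of some bipartition (edge) of the unrooted tree?
.is_split <- function(tree, side) {
  tips <- sort(tree$tip.label)
  anchor <- tips[1]
  side <- sort(side)
  if (anchor %in% side) side <- setdiff(tips, side)
  key <- paste(side, collapse = "\r")
  key %in% .bipartition_keys(tree)
}

#' Tip-to-tip distance matrix of a tree
#'
#' In `branch_length` mode (the patristic distance, default for the
#' community metrics) each entry is the sum of branch lengths along the path
#' between two tips. In `nodal` mode the entry is the number of internal
#' nodes crossed on that path, the count used in the worked example that
#' accompanies the community metrics: on the caterpillar `(((A,B),C),D)` the
#' nodal distances are AB = 1, AC = 2, AD = 3, BC = 2, BD = 3, CD = 2.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param mode `"branch_length"` or `"nodal"`.
#' @return Symmetric labelled distance matrix.
#' @export
tree_distance_matrix <- function(tree, mode = c("branch_length", "nodal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(tree, "phylo"))
  if (mode == "branch_length") {
    if (is.null(tree$edge.length))
      stop("tree_distance_matrix: tree has no branch lengths")
    D <- stats::cophenetic(tree)
  } else {
    unit <- tree
    unit$edge.length <- rep(1, nrow(unit$edge))
    D <- stats::cophenetic(unit) - 1   # edges on path minus 1 = internal nodes
    diag(D) <- 0
  }
  D[rownames(D), rownames(D), drop = FALSE]
}

#' Read trees from a Newick file
#'
#' Thin wrapper over \pkg{ape}'s Newick parser; support values stored as
#' internal node labels are preserved.
#'
#' @param path Path to a Newick file (one or more trees).
#' @return A `phylo` tree, or a list of them if the file holds several.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("read_newick: cannot read ", path)
  out <- ape::read.tree(path)
  if (inherits(out, "multiPhylo")) unclass(out) else out
}

#' Write trees to a Newick file
#'
#' @param trees A `phylo` tree or list of trees.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(trees, path) {
  if (inherits(trees, "phylo")) trees <- list(trees)
  txt <- vapply(trees, function(t) ape::write.tree(t, digits = 12), character(1))
  writeLines(txt, path)
  invisible(path)
}
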