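# Shared fixtures, all built in code.

# 4-taxon caterpillar used in the worked community-metric example.
fig3_tree <- function() ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1);")

# A small clean BOLD-style dataset written to tempfiles; returns the paths.
write_tiny_export <- function(records, dir = tempfile("export")) {
  dir.create(dir)
  ds <- bin_dataset(records)
  write_dataset(ds, file.path(dir, "meta.tsv"), file.path(dir, "seqs.fasta"))
}

tiny_records <- function(n = 3, seq = strrep("ACGT", 20)) {
  out <- data.frame(record_id = sprintf("REC%03d", seq_len(max(n, 1))),
                    bin_id = sprintf("BOLD:AAA%04d", seq_len(max(n, 1))),
                    family = "Carabidae", genus = "Amara", species = "sp1",
                    marker = "COI-5P", lat = 58.65, lon = -94.0,
                    sequence = seq, stringsAsFactors = FALSE)
  out[seq_len(n), ]
}

# plain data-frame view, free of provenance/report attributes
records_frame <- function(ds) {
  out <- as.data.frame(ds)
  attributes(out) <- attributes(out)[c("names", "row.names", "class")]
  class(out) <- "data.frame"
  out
}

# Additive distance matrix from a random tree, labels sorted.
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  D <- stats::cophenetic(tr)
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}

# Independent stepdown oracle for the Holm correction.
holm_brute_force <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj[ord[i]] <- min(1, running)
  }
  adj
}

# Brute-force Pearson chi-square from margins.
chisq_brute_force <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}
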