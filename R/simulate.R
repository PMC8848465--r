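#' Configuration for the synthetic barcode-data generator
#'
#' Bundles every knob of the generator with validated defaults chosen to
#' emulate a BOLD-style regional beetle dataset: a 100-tip regional pool on
#' a pure-birth tree, 658-bp barcode-like sequences, a few specimens per
#' BIN with small intra-BIN divergence, and a local community of 20 BINs
#' drawn from the pool neutrally, under environmental filtering, or under
#' repulsion. Planted quality faults have exact counts so filter accounting
#' is deterministic.
#'
#' @param n_pool_tips Number of regional pool tips (= BINs). Default 100.
#' @param seq_length Alignment length in bp. Default 658.
#' @param birth_rate Per-lineage speciation rate of the pure-birth tree.
#'   Default 1.
#' @param substitution_rate Expected substitutions per site per unit branch
#'   length. Default 0.05.
#' @param community_richness Number of BINs in the local community.
#'   Default 20.
#' @param assembly_mode `"neutral"`, `"filtering"` or `"repulsion"`.
#' @param lambda Filtering/repulsion strength (>= 0; 0 reduces any mode to
#'   neutral). Default 0.
#' @param n_per_bin Specimen records per BIN. Default 5.
#' @param intrabin_divergence Expected p-distance between a BIN member and
#'   its planted centroid. Default 0.005.
#' @param local_box,regional_box [region_box()] objects for local-community
#'   and regional coordinates. Defaults: the Churchill study box inside a
#'   northern North America box.
#' @param n_families Number of family labels to spread over the pool tips.
#'   Default 1.
#' @param n_missing_bin,n_missing_gps,n_wrong_marker,n_short,n_gappy Exact
#'   numbers of records planted to violate each quality filter. Default 0.
#' @param seed Integer random seed. Default 1.
#' @return An object of class `"sim_config"`.
#' @export
sim_config <- function(n_pool_tips = 100, seq_length = 658, birth_rate = 1,
                       substitution_rate = 0.05, community_richness = 20,
                       assembly_mode = c("neutral", "filtering", "repulsion"),
                       lambda = 0, n_per_bin = 5, intrabin_divergence = 0.005,
                       local_box = region_box(58.6, 58.7, -94.2, -93.8),
                       regional_box = region_box(42, 70, -141, -52),
                       n_families = 1,
                       n_missing_bin = 0, n_missing_gps = 0,
                       n_wrong_marker = 0, n_short = 0, n_gappy = 0,
                       seed = 1) {
  assembly_mode <- match.arg(assembly_mode)
  stopifnot(n_pool_tips >= 2, seq_length >= 1, birth_rate > 0,
            substitution_rate >= 0, n_per_bin >= 1,
            intrabin_divergence >= 0, intrabin_divergence <= 1,
            lambda >= 0, n_families >= 1)
  if (community_richness > n_pool_tips)
    stop("sim_config: community_richness must be <= n_pool_tips")
  structure(list(n_pool_tips = n_pool_tips, seq_length = seq_length,
                 birth_rate = birth_rate, substitution_rate = substitution_rate,
                 community_richness = community_richness,
                 assembly_mode = assembly_mode, lambda = lambda,
                 n_per_bin = n_per_bin, intrabin_divergence = intrabin_divergence,
                 local_box = local_box, regional_box = regional_box,
                 n_families = n_families,
                 n_missing_bin = n_missing_bin, n_missing_gps = n_missing_gps,
                 n_wrong_marker = n_wrong_marker, n_short = n_short,
                 n_gappy = n_gappy, seed = seed),
            class = "sim_config")
}

#' Simulate a pure-birth (Yule) tree
#'
#' Forward simulation with exponential waiting times: starting from the
#' root's two daughter lineages, with k lineages extant the time to the
#' next speciation is Exp(k * birth_rate) and a uniformly chosen lineage
#' splits; after the n-th lineage appears the process runs for one further
#' Exp(n * birth_rate) interval. The tree is ultrametric with expected
#' root-to-tip depth sum_{k=2}^{n} 1 / (k * birth_rate).
#'
#' @param n_tips Number of tips (>= 2).
#' @param birth_rate Per-lineage speciation rate.
#' @param seed Integer random seed (mandatory).
#' @return An ultrametric rooted `phylo` tree with tips `t1 ... tn`.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed) {
  if (missing(seed)) stop("simulate_yule_tree: seed is mandatory")
  stopifnot(n_tips >= 2, birth_rate > 0)
  set.seed(seed)
  # node bookkeeping: 1 is the root, split at time 0
  children <- list(c(2L, 3L))
  start <- c(0, 0, 0)
  split_time <- c(0, NA, NA)
  active <- c(2L, 3L)
  t_now <- 0
  k <- 2L
  while (k < n_tips) {
    t_now <- t_now + stats::rexp(1, rate = k * birth_rate)
    who <- active[sample.int(k, 1)]
    a <- length(start) + 1L
    b <- length(start) + 2L
    children[[who]] <- c(a, b)
    split_time[who] <- t_now
    start <- c(start, t_now, t_now)
    split_time <- c(split_time, NA, NA)
    active <- c(setdiff(active, who), a, b)
    k <- k + 1L
  }
  t_end <- t_now + stats::rexp(1, rate = n_tips * birth_rate)
  is_tip <- seq_along(start) %in% active
  tip_label <- character(length(start))
  tip_label[sort(active)] <- sprintf("t%d", seq_len(n_tips))
  fmt <- function(x) sprintf("%.12g", x)
  nwk <- function(id) {
    if (is_tip[id]) return(paste0(tip_label[id], ":", fmt(t_end - start[id])))
    kids <- children[[id]]
    inner <- paste0("(", nwk(kids[1]), ",", nwk(kids[2]), ")")
    if (id == 1L) paste0(inner, ";")
    else paste0(inner, ":", fmt(split_time[id] - start[id]))
  }
  ape::read.tree(text = nwk(1L))
}

#' Evolve aligned sequences along a tree
#'
#' Jukes-Cantor simulation from a uniform-random root sequence, with branch
#' lengths scaled by `substitution_rate` (expected substitutions per site
#' per unit branch length). No indels are introduced, so the output is
#' aligned by construction.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @param seq_length Number of sites. Default 658.
#' @param substitution_rate Scaling of branch lengths to substitutions per
#'   site. Default 1.
#' @param seed Integer random seed (mandatory).
#' @return A [dna_alignment()] with one row per tip.
#' @export
evolve_sequences <- function(tree, seq_length = 658, substitution_rate = 1, seed) {
  if (missing(seed)) stop("evolve_sequences: seed is mandatory")
  stopifnot(inherits(tree, "phylo"), seq_length >= 1, substitution_rate >= 0)
  set.seed(seed)
  scaled <- tree
  scaled$edge.length <- tree$edge.length * substitution_rate
  sim <- phangorn::simSeq(scaled, l = seq_length, type = "DNA")
  m <- toupper(as.character(sim))
  dna_alignment(rownames(m), apply(m, 1, paste, collapse = ""))
}

#' Expand pool tips into BINs of specimen records
#'
#' Each alignment row (pool tip) becomes one BIN containing `n_per_bin`
#' specimen records: the first is the planted centroid (the tip sequence
#' unchanged) and the others carry independent per-site substitutions at
#' rate `intrabin_divergence`, so the expected p-distance of a member to the
#' centroid equals `intrabin_divergence`.
#'
#' @param aln A [dna_alignment()] of pool-tip sequences.
#' @param n_per_bin Records per BIN. Default 5.
#' @param intrabin_divergence Per-site substitution probability. Default 0.005.
#' @param seed Integer random seed (mandatory).
#' @return Data frame with columns `record_id`, `bin_id`, `tip`, `sequence`;
#'   the planted centroid record ids are attached as attribute
#'   `"planted_centroids"` (named by bin_id).
#' @export
make_bins <- function(aln, n_per_bin = 5, intrabin_divergence = 0.005, seed) {
  if (missing(seed)) stop("make_bins: seed is mandatory")
  stopifnot(inherits(aln, "dna_alignment"), n_per_bin >= 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  rows <- list()
  planted <- character(0)
  for (i in seq_along(aln$labels)) {
    tip <- aln$labels[i]
    bin_id <- sprintf("BOLD:SIM%04d", i)
    base_seq <- aln$rows[[tip]]
    for (j in seq_len(n_per_bin)) {
      rid <- sprintf("SIM%04d-%02d", i, j)
      s <- base_seq
      if (j > 1 && intrabin_divergence > 0) {
        chars <- strsplit(s, "", fixed = TRUE)[[1]]
        hit <- which(stats::runif(length(chars)) < intrabin_divergence)
        for (h in hit)
          chars[h] <- sample(setdiff(bases, chars[h]), 1)
        s <- paste(chars, collapse = "")
      }
      rows[[length(rows) + 1L]] <- data.frame(record_id = rid, bin_id = bin_id,
                                              tip = tip, sequence = s,
                                              stringsAsFactors = FALSE)
      if (j == 1) planted[bin_id] <- rid
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "planted_centroids") <- planted
  out
}

#' Assemble a local community from a regional tree
#'
#' Draws `richness` tips without replacement from the pool. `neutral` draws
#' uniformly. `filtering` picks a uniform focal tip and then draws the
#' remaining members with weight proportional to exp(-lambda * d(focal, i))
#' in patristic distance, concentrating the community around the focal
#' lineage (environmental filtering; produces clustering). `repulsion`
#' draws sequentially with weight proportional to exp(+lambda * min
#' distance to the already-selected members), pushing members apart
#' (produces overdispersion). `lambda = 0` reduces every mode to neutral.
#'
#' @param tree A `phylo` tree for the regional pool.
#' @param richness Community size (2 <= richness <= number of tips).
#' @param mode `"neutral"`, `"filtering"` or `"repulsion"`.
#' @param lambda Strength parameter (>= 0).
#' @param seed Integer random seed (mandatory).
#' @return Character vector of selected tip labels.
#' @export
assemble_community <- function(tree, richness,
                               mode = c("neutral", "filtering", "repulsion"),
                               lambda = 0, seed) {
  mode <- match.arg(mode)
  if (missing(seed)) stop("assemble_community: seed is mandatory")
  stopifnot(inherits(tree, "phylo"), lambda >= 0)
  labels <- tree$tip.label
  if (richness < 2 || richness > length(labels))
    stop("assemble_community: richness must be in [2, n_tips]")
  set.seed(seed)
  if (mode == "neutral" || lambda == 0)
    return(sample(labels, richness))
  D <- stats::cophenetic(tree)
  if (mode == "filtering") {
    focal <- sample(labels, 1)
    rest <- setdiff(labels, focal)
    d <- D[focal, rest]
    w <- exp(-lambda * (d - min(d)))   # shift for numerical stability
    c(focal, sample(rest, richness - 1, prob = w))
  } else {
    selected <- sample(labels, 1)
    while (length(selected) < richness) {
      rest <- setdiff(labels, selected)
      mind <- apply(D[rest, selected, drop = FALSE], 1, min)
      w <- exp(lambda * (mind - max(mind)))
      selected <- c(selected, sample(rest, 1, prob = w))
    }
    selected
  }
}

.runif_in_box <- function(n, box) {
  data.frame(lat = stats::runif(n, box$lat_min, box$lat_max),
             lon = stats::runif(n, box$lon_min, box$lon_max))
}

.runif_outside_box <- function(n, outer, inner) {
  lat <- numeric(n); lon <- numeric(n)
  for (i in seq_len(n)) {
    for (try in 1:10000) {
      la <- stats::runif(1, outer$lat_min, outer$lat_max)
      lo <- stats::runif(1, outer$lon_min, outer$lon_max)
      inside <- la >= inner$lat_min && la <= inner$lat_max &&
        lo >= inner$lon_min && lo <= inner$lon_max
      if (!inside) break
    }
    if (inside) stop("could not sample a coordinate outside the local box")
    lat[i] <- la; lon[i] <- lo
  }
  data.frame(lat = lat, lon = lon)
}

#' Emit a full synthetic BOLD-style dataset
#'
#' Runs the whole generator: pure-birth regional tree, sequence evolution,
#' BIN expansion, community assembly, coordinates (local-community records
#' inside the local box, all others inside the regional box but outside the
#' local box), and exact-count planted quality faults (missing BIN, missing
#' GPS, wrong marker, short sequence, gappy sequence, applied to disjoint
#' record sets so per-rule filter accounting is deterministic). The dataset
#' is written as the TSV + FASTA dialect that [read_records()] consumes.
#'
#' @param config A [sim_config()].
#' @param metadata_file,fasta_file Output paths (defaults under [tempdir()]).
#' @return Invisibly, a list with the output `paths`, the in-memory
#'   `dataset` (including faults), the regional `tree`, the pool `alignment`,
#'   `community_tips`, `community_bins`, the planted centroid map `planted`,
#'   the per-fault record ids `faults`, and `config`.
#' @export
emit_bold_dataset <- function(config,
                              metadata_file = file.path(tempdir(), "records.tsv"),
                              fasta_file = file.path(tempdir(), "records.fasta")) {
  stopifnot(inherits(config, "sim_config"))
  seed <- config$seed
  tree <- simulate_yule_tree(config$n_pool_tips, config$birth_rate, seed = seed)
  aln <- evolve_sequences(tree, config$seq_length, config$substitution_rate,
                          seed = seed + 1)
  bins <- make_bins(aln, config$n_per_bin, config$intrabin_divergence,
                    seed = seed + 2)
  community_tips <- assemble_community(tree, config$community_richness,
                                       config$assembly_mode, config$lambda,
                                       seed = seed + 3)
  set.seed(seed + 4)
  # taxonomy: families spread over the pool tips in sorted blocks
  tips_sorted <- sort(aln$labels)
  fam_of_tip <- stats::setNames(
    sprintf("Fam%02d", ceiling(seq_along(tips_sorted) /
                                 ceiling(length(tips_sorted) / config$n_families))),
    tips_sorted)
  n_rec <- nrow(bins)
  is_local <- bins$tip %in% community_tips
  coords <- data.frame(lat = numeric(n_rec), lon = numeric(n_rec))
  if (any(is_local))
    coords[is_local, ] <- .runif_in_box(sum(is_local), config$local_box)
  if (any(!is_local))
    coords[!is_local, ] <- .runif_outside_box(sum(!is_local),
                                              config$regional_box,
                                              config$local_box)
  records <- data.frame(record_id = bins$record_id, bin_id = bins$bin_id,
                        family = unname(fam_of_tip[bins$tip]),
                        genus = paste0("g", unname(fam_of_tip[bins$tip])),
                        species = bins$tip, marker = "COI-5P",
                        lat = coords$lat, lon = coords$lon,
                        sequence = bins$sequence, stringsAsFactors = FALSE)
  # plant faults on disjoint record sets so each record fails exactly one rule
  n_faults <- c(missing_bin = config$n_missing_bin,
                missing_gps = config$n_missing_gps,
                wrong_marker = config$n_wrong_marker,
                short = config$n_short, gappy = config$n_gappy)
  if (sum(n_faults) > n_rec)
    stop("emit_bold_dataset: more planted faults than records")
  fault_rows <- sample.int(n_rec, sum(n_faults))
  fault_ids <- split(fault_rows, rep(names(n_faults), n_faults))
  if (length(fault_ids$missing_bin))
    records$bin_id[fault_ids$missing_bin] <- NA
  if (length(fault_ids$missing_gps))
    records$lat[fault_ids$missing_gps] <- NA
  if (length(fault_ids$wrong_marker))
    records$marker[fault_ids$wrong_marker] <- "ITS"
  if (length(fault_ids$short))
    records$sequence[fault_ids$short] <-
      substr(records$sequence[fault_ids$short], 1L, 300L)
  if (length(fault_ids$gappy)) {
    n_gap <- max(1L, ceiling(0.02 * config$seq_length))
    records$sequence[fault_ids$gappy] <- paste0(
      strrep("-", n_gap),
      substr(records$sequence[fault_ids$gappy], n_gap + 1L, config$seq_length))
  }
  ds <- bin_dataset(records, provenance = sprintf(
    "emit_bold_dataset: %d records, %d BINs, mode=%s, lambda=%g, seed=%d",
    n_rec, config$n_pool_tips, config$assembly_mode, config$lambda, seed))
  paths <- write_dataset(ds, metadata_file, fasta_file)
  tip_to_bin <- stats::setNames(bins$bin_id[!duplicated(bins$tip)],
                                bins$tip[!duplicated(bins$tip)])
  invisible(list(paths = paths, dataset = ds, tree = tree, alignment = aln,
                 community_tips = community_tips,
                 community_bins = unname(tip_to_bin[community_tips]),
                 planted = attr(bins, "planted_centroids"),
                 faults = lapply(fault_ids, function(i) records$record_id[i]),
                 config = config))
}
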