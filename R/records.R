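#' Geographic bounding box
#'
#' A rectangular region in decimal degrees used to subset specimen records,
#' e.g. the Churchill, MB study box (latitude 58.6--58.7, longitude -94.2 to
#' -93.8). Membership is closed on all four edges so boundary specimens are
#' never silently lost.
#'
#' @param lat_min,lat_max Latitude limits in decimal degrees, `lat_min < lat_max`.
#' @param lon_min,lon_max Longitude limits in decimal degrees, `lon_min < lon_max`.
#' @return An object of class `"region_box"`.
#' @examples
#' churchill <- region_box(58.6, 58.7, -94.2, -93.8)
#' @export
region_box <- function(lat_min, lat_max, lon_min, lon_max) {
  stopifnot(is.numeric(lat_min), is.numeric(lat_max),
            is.numeric(lon_min), is.numeric(lon_max))
  if (!(lat_min < lat_max)) stop("region_box: lat_min must be < lat_max")
  if (!(lon_min < lon_max)) stop("region_box: lon_min must be < lon_max")
  if (lat_min < -90 || lat_max > 90) stop("region_box: latitude outside [-90, 90]")
  if (lon_min < -180 || lon_max > 180) stop("region_box: longitude outside [-180, 180]")
  structure(list(lat_min = lat_min, lat_max = lat_max,
                 lon_min = lon_min, lon_max = lon_max),
            class = "region_box")
}

#' @export
print.region_box <- function(x, ...) {
  cat(sprintf("<region_box> lat [%g, %g], lon [%g, %g]\n",
              x$lat_min, x$lat_max, x$lon_min, x$lon_max))
  invisible(x)
}

.dataset_columns <- c("record_id", "bin_id", "family", "genus", "species",
                      "marker", "lat", "lon", "sequence")

#' Construct a specimen dataset
#'
#' A `bin_dataset` is a data frame of barcode specimen records (one row per
#' record) carrying a provenance log of every filter applied to it. Columns:
#' `record_id`, `bin_id`, `family`, `genus`, `species`, `marker`, `lat`,
#' `lon`, `sequence`.
#'
#' @param records Data frame with the columns listed above.
#' @param provenance Character vector of processing-log lines.
#' @return An object of classes `"bin_dataset"` and `"data.frame"`.
#' @export
bin_dataset <- function(records, provenance = character()) {
  stopifnot(is.data.frame(records))
  missing_cols <- setdiff(.dataset_columns, names(records))
  if (length(missing_cols))
    stop("bin_dataset: missing columns: ", paste(missing_cols, collapse = ", "))
  records <- as.data.frame(records)[, .dataset_columns, drop = FALSE]
  records$record_id <- as.character(records$record_id)
  for (col in c("bin_id", "family", "genus", "species", "marker", "sequence"))
    records[[col]] <- as.character(records[[col]])
  records$lat <- as.numeric(records$lat)
  records$lon <- as.numeric(records$lon)
  if (nrow(records)) {
    if (anyNA(records$record_id) || any(!nzchar(records$record_id)))
      stop("bin_dataset: record_id must be non-empty")
    dup <- records$record_id[duplicated(records$record_id)]
    if (length(dup))
      stop("bin_dataset: duplicate record_id: ", paste(unique(dup), collapse = ", "))
    bad_lat <- !is.na(records$lat) & (records$lat < -90 | records$lat > 90)
    bad_lon <- !is.na(records$lon) & (records$lon < -180 | records$lon > 180)
    if (any(bad_lat) || any(bad_lon))
      stop("bin_dataset: coordinates out of range for: ",
           paste(records$record_id[bad_lat | bad_lon], collapse = ", "))
    if (anyNA(records$sequence) || any(!nzchar(records$sequence)))
      stop("bin_dataset: empty sequence for: ",
           paste(records$record_id[is.na(records$sequence) | !nzchar(records$sequence)],
                 collapse = ", "))
  }
  rownames(records) <- NULL
  structure(records, provenance = as.character(provenance),
            class = c("bin_dataset", "data.frame"))
}

#' @export
print.bin_dataset <- function(x, ...) {
  cat(sprintf("<bin_dataset> %d records, %d distinct BINs\n",
              nrow(x), length(unique(stats::na.omit(x$bin_id)))))
  prov <- attr(x, "provenance")
  if (length(prov)) {
    cat("provenance:\n")
    for (line in prov) cat("  - ", line, "\n", sep = "")
  }
  invisible(x)
}

#' @export
provenance <- function(ds) attr(ds, "provenance")

.log_step <- function(ds, line) {
  attr(ds, "provenance") <- c(attr(ds, "provenance"), line)
  ds
}

.keep_rows <- function(ds, keep) {
  out <- as.data.frame(ds)[keep, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, provenance = attr(ds, "provenance"),
            filter_report = attr(ds, "filter_report"),
            class = class(ds))
}

# Map a BOLD-style export header onto the internal column names.
.bold_column_map <- c(record_id = "processid", bin_id = "bin_uri",
                      family = "family_name", genus = "genus_name",
                      species = "species_name", marker = "markercode",
                      lat = "lat", lon = "lon")

#' Read BOLD-style specimen records
#'
#' Joins a tab-separated metadata table against a FASTA file of barcode
#' sequences. The metadata table must contain the BOLD export columns
#' `processid`, `bin_uri`, `family_name`, `genus_name`, `species_name`,
#' `markercode`, `lat`, `lon`; the first whitespace-delimited token of each
#' FASTA header is taken as the record id. Metadata rows with no matching
#' sequence are reported (message + provenance), not silently dropped.
#'
#' @param metadata_file Path to the tab-separated metadata table.
#' @param fasta_file Path to the FASTA file of sequences.
#' @return A [bin_dataset()] with one record per metadata row that has a
#'   matching sequence.
#' @export
read_records <- function(metadata_file, fasta_file) {
  if (!file.exists(metadata_file)) stop("read_records: cannot read ", metadata_file)
  if (!file.exists(fasta_file)) stop("read_records: cannot read ", fasta_file)
  meta <- utils::read.delim(metadata_file, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, colClasses = "character",
                            na.strings = c("NA", ""))
  missing_cols <- setdiff(unname(.bold_column_map), names(meta))
  if (length(missing_cols))
    stop("read_records: metadata lacks columns: ", paste(missing_cols, collapse = ", "))
  seqs <- Biostrings::readDNAStringSet(fasta_file)
  seq_ids <- vapply(strsplit(names(seqs), "[[:space:]]+"), `[`, character(1), 1L)
  if (anyDuplicated(seq_ids))
    stop("read_records: duplicate record_id in FASTA: ",
         paste(unique(seq_ids[duplicated(seq_ids)]), collapse = ", "))
  ids <- meta[[.bold_column_map[["record_id"]]]]
  if (anyDuplicated(ids))
    stop("read_records: duplicate record_id in metadata: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  records <- data.frame(record_id = ids, stringsAsFactors = FALSE)
  for (col in setdiff(names(.bold_column_map), "record_id"))
    records[[col]] <- meta[[.bold_column_map[[col]]]]
  has_seq <- records$record_id %in% seq_ids
  orphans <- records$record_id[!has_seq]
  records <- records[has_seq, , drop = FALSE]
  records$sequence <- toupper(as.character(seqs[match(records$record_id, seq_ids)]))
  prov <- sprintf("read_records: %d metadata rows, %d with sequences, %d orphan rows",
                  length(ids), nrow(records), length(orphans))
  if (length(orphans)) {
    message("read_records: ", length(orphans), " metadata row(s) without sequences: ",
            paste(utils::head(orphans, 5), collapse = ", "),
            if (length(orphans) > 5) ", ..." else "")
  }
  ds <- bin_dataset(records, provenance = prov)
  attr(ds, "orphans") <- orphans
  ds
}

# Sequence length = non-gap characters; the ambiguity budget counts N and '-'
# jointly against the full raw sequence length.
.seq_length <- function(seq) nchar(gsub("-", "", seq, fixed = TRUE))

.ambiguous_fraction <- function(seq) {
  n_amb <- nchar(seq) - nchar(gsub("[N-]", "", seq))
  n_amb / nchar(seq)
}

#' Quality-filter specimen records
#'
#' Applies the standard barcode quality filters in a fixed order: records
#' must (1) carry a BIN assignment, (2) carry both GPS coordinates, (3) match
#' the requested marker exactly, (4) have a sequence of at least `min_length`
#' non-gap base pairs, and (5) have a joint N-plus-gap content of at most
#' `max_ambiguous_fraction` of the raw sequence length. A record failing more
#' than one rule is counted under the first failing rule only, so the
#' per-rule removal counts plus the retained count always sum to the input
#' size.
#'
#' @param ds A [bin_dataset()].
#' @param marker_name Marker the record must come from. Default `"COI-5P"`.
#' @param min_length Minimum sequence length in base pairs, counting
#'   A/C/G/T/N and excluding alignment gaps. Default 500.
#' @param max_ambiguous_fraction Maximum allowed fraction of N and `-`
#'   characters relative to the raw sequence length. Default 0.01.
#' @return A filtered [bin_dataset()]; the per-rule removal counts are stored
#'   in `attr(, "filter_report")` and appended to the provenance log.
#' @export
filter_records <- function(ds, marker_name = "COI-5P", min_length = 500,
                           max_ambiguous_fraction = 0.01) {
  stopifnot(inherits(ds, "bin_dataset"))
  n0 <- nrow(ds)
  fails <- list(
    no_bin = is.na(ds$bin_id) | !nzchar(ds$bin_id),
    no_coordinates = is.na(ds$lat) | is.na(ds$lon),
    wrong_marker = is.na(ds$marker) | ds$marker != marker_name,
    too_short = .seq_length(ds$sequence) < min_length,
    too_ambiguous = .ambiguous_fraction(ds$sequence) > max_ambiguous_fraction
  )
  removed_by <- rep(NA_character_, n0)
  for (rule in names(fails)) {
    hit <- fails[[rule]] & is.na(removed_by)
    removed_by[hit] <- rule
  }
  report <- vapply(names(fails), function(r) sum(removed_by == r, na.rm = TRUE),
                   integer(1))
  report <- c(report, retained = sum(is.na(removed_by)))
  out <- .keep_rows(ds, is.na(removed_by))
  attr(out, "filter_report") <- report
  .log_step(out, sprintf(
    "filter_records(marker=%s, min_length=%d, max_ambiguous=%g): %d -> %d (%s)",
    marker_name, min_length, max_ambiguous_fraction, n0, nrow(out),
    paste(sprintf("%s=%d", names(report), report), collapse = ", ")))
}

#' Subset records by geographic bounding box
#'
#' Retains records whose coordinates fall inside `box`, closed on all four
#' edges. All records must already carry coordinates; run [filter_records()]
#' first.
#'
#' @param ds A [bin_dataset()] whose records all carry coordinates.
#' @param box A [region_box()].
#' @return The subset [bin_dataset()].
#' @export
subset_by_region <- function(ds, box) {
  stopifnot(inherits(ds, "bin_dataset"), inherits(box, "region_box"))
  if (nrow(ds) && (anyNA(ds$lat) || anyNA(ds$lon)))
    stop("subset_by_region: records without coordinates (run filter_records first): ",
         paste(ds$record_id[is.na(ds$lat) | is.na(ds$lon)], collapse = ", "))
  keep <- if (nrow(ds)) {
    ds$lat >= box$lat_min & ds$lat <= box$lat_max &
      ds$lon >= box$lon_min & ds$lon <= box$lon_max
  } else logical(0)
  out <- .keep_rows(ds, keep)
  .log_step(out, sprintf("subset_by_region(lat [%g, %g], lon [%g, %g]): %d -> %d",
                         box$lat_min, box$lat_max, box$lon_min, box$lon_max,
                         nrow(ds), nrow(out)))
}

#' Select analyzable taxonomic groups
#'
#' Returns the groups (families or genera) with at least `min_local_bins`
#' distinct BINs present in the local community -- the inclusion rule used to
#' decide which groups support a community-structure analysis. Distinct BINs
#' are counted, not records.
#'
#' @param regional A [bin_dataset()] for the regional pool (kept for interface
#'   symmetry; the inclusion rule counts local BINs only).
#' @param local A [bin_dataset()] for the local community.
#' @param rank `"family"` or `"genus"`.
#' @param min_local_bins Minimum number of distinct local BINs. Default 3.
#' @return Character vector of group names, sorted lexicographically.
#' @export
select_groups <- function(regional, local, rank = c("family", "genus"),
                          min_local_bins = 3) {
  rank <- match.arg(rank)
  stopifnot(inherits(local, "bin_dataset"))
  if (nrow(local) == 0) return(character(0))
  grp <- local[[rank]]
  if (anyNA(grp) || any(!nzchar(grp)))
    stop("select_groups: ", rank, " missing on record(s): ",
         paste(local$record_id[is.na(grp) | !nzchar(grp)], collapse = ", "))
  counts <- tapply(local$bin_id, grp, function(b) length(unique(b)))
  sort(names(counts)[counts >= min_local_bins])
}

#' Write a dataset back to TSV + FASTA
#'
#' Emits the same BOLD-style dialect that [read_records()] consumes, so a
#' write/read round trip is the identity on the record table.
#'
#' @param ds A [bin_dataset()].
#' @param metadata_file,fasta_file Output paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_dataset <- function(ds, metadata_file, fasta_file) {
  stopifnot(inherits(ds, "bin_dataset"))
  meta <- data.frame(processid = ds$record_id, bin_uri = ds$bin_id,
                     family_name = ds$family, genus_name = ds$genus,
                     species_name = ds$species, markercode = ds$marker,
                     lat = ds$lat, lon = ds$lon, stringsAsFactors = FALSE)
  utils::write.table(meta, metadata_file, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  seqs <- Biostrings::DNAStringSet(ds$sequence)
  names(seqs) <- ds$record_id
  Biostrings::writeXStringSet(seqs, fasta_file, width = 80L)
  invisible(list(metadata = metadata_file, fasta = fasta_file))
}

#' Render a filter report as text
#'
#' @param ds A [bin_dataset()] produced by [filter_records()].
#' @return Character vector of report lines (invisibly printed).
#' @export
filter_report <- function(ds) {
  rep <- attr(ds, "filter_report")
  if (is.null(rep)) stop("filter_report: dataset has no filter report")
  lines <- c("filter report (rules applied in order; first failing rule counted):",
             sprintf("  %-15s %d", names(rep), rep))
  cat(lines, sep = "\n")
  invisible(lines)
}
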