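#' Aligned (or raw) sequence matrix for one barcode marker
#'
#' A `marker_matrix` holds the sequences of one marker (or of a multi-marker
#' concatenation) together with the specimen ids and species labels needed by
#' every downstream analysis. Sequences are stored as upper-case character
#' strings using IUPAC letters, `-` for an alignment gap and `N`/`?` for
#' missing data. When all sequences share one length the matrix is flagged
#' `aligned`; distance and tree operations refuse unaligned matrices.
#'
#' @param seqs named character vector of sequences; names are specimen ids.
#' @param species character vector of binomial species names, parallel to
#'   `seqs`.
#' @param marker marker name (e.g. `"rbcL"`).
#' @param partition optional named list of 0-based half-open column intervals
#'   (`c(start, end)`), present on concatenated matrices.
#'
#' @return An object of class `marker_matrix` with fields `marker`, `seqs`,
#'   `species`, `columns` (`NA` when unaligned), `aligned`, `partition`.
#' @export
marker_matrix <- function(seqs, species, marker = "marker", partition = NULL) {
  if (length(seqs) == 0L) stop("marker_matrix needs at least one sequence")
  if (length(species) != length(seqs)) {
    stop("`species` must be parallel to `seqs`")
  }
  ids <- names(seqs)
  if (is.null(ids) || anyNA(ids) || any(ids == "")) {
    stop("sequences must be named by specimen id")
  }
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate specimen id(s): ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(seqs))) stop("empty sequence(s) for: ",
                               paste(ids[!nzchar(seqs)], collapse = ", "))
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  aligned <- length(unique(lens)) == 1L
  structure(
    list(
      marker = marker,
      seqs = seqs,
      species = as.character(species),
      columns = if (aligned) unname(lens[1L]) else NA_integer_,
      aligned = aligned,
      partition = partition
    ),
    class = "marker_matrix"
  )
}

#' @export
print.marker_matrix <- function(x, ...) {
  cat(sprintf(
    "marker_matrix '%s': %d sequences, %d species, %s\n",
    x$marker, length(x$seqs), length(unique(x$species)),
    if (x$aligned) sprintf("%d aligned columns", x$columns) else "UNALIGNED"
  ))
  invisible(x)
}

#' Number of sequences in a marker matrix
#' @param x a `marker_matrix`.
#' @export
n_sequences <- function(x) length(x$seqs)

specimen_ids <- function(x) names(x$seqs)

# Fail early for operations that only make sense on aligned matrices.
assert_aligned <- function(x, what = "this operation") {
  if (!inherits(x, "marker_matrix")) stop("expected a marker_matrix")
  if (!isTRUE(x$aligned)) {
    stop(sprintf("matrix '%s' is not aligned; %s requires equal-length sequences",
                 x$marker, what))
  }
  invisible(x)
}

#' Species lookup table of a marker matrix
#'
#' @param x a `marker_matrix`.
#' @return data.frame with columns `specimen_id`, `species`, `genus`.
#' @export
species_map <- function(x) {
  data.frame(
    specimen_id = specimen_ids(x),
    species = x$species,
    genus = genus_of(x$species),
    stringsAsFactors = FALSE
  )
}

#' Crop all rows of an aligned matrix to a column interval
#'
#' Emulates the "equal trimming" preprocessing applied to public-database
#' sequence sets before cross-data-set comparison: every row is cut to the
#' same 0-based half-open column interval.
#'
#' @param x aligned `marker_matrix`.
#' @param interval integer vector `c(start, end)`, 0-based half-open.
#' @export
crop_matrix <- function(x, interval) {
  assert_aligned(x, "crop_matrix")
  if (length(interval) != 2L || interval[1] < 0 || interval[2] > x$columns ||
      interval[1] >= interval[2]) {
    stop("interval must be 0-based half-open within [0, ", x$columns, ")")
  }
  seqs <- substr(x$seqs, interval[1] + 1L, interval[2])
  names(seqs) <- specimen_ids(x)
  marker_matrix(seqs, x$species, marker = x$marker)
}
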