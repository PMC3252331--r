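#' Read one marker's sequences from a FASTA file
#'
#' Headers must encode the species and the specimen id under a fixed
#' convention, by default `Genus_species|specimenID` (underscores in the
#' species part become spaces). Sequence characters are upper-cased on read.
#' If the sequences do not all share one length the matrix is flagged
#' unaligned and distance/tree operations will refuse it.
#'
#' @param path FASTA file path.
#' @param marker marker name to attach.
#' @param id_sep single character separating species from specimen id in the
#'   header (default `"|"`).
#' @return a [marker_matrix()] whose rows preserve file order.
#' @export
read_marker_fasta <- function(path, marker = "marker", id_sep = "|") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(trimws(lines) != "")
  if (length(nonblank) == 0L) stop("empty FASTA file: ", path)
  first <- nonblank[1L]
  if (!startsWith(lines[first], ">")) {
    stop(sprintf("malformed FASTA at line %d of %s: expected '>' header", first, path))
  }
  headers <- character(0)
  seqs <- character(0)
  buf <- character(0)
  for (i in nonblank) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      if (length(headers) > 0L) {
        if (length(buf) == 0L) {
          stop(sprintf("malformed FASTA at line %d of %s: header with no sequence", i, path))
        }
        seqs <- c(seqs, paste(buf, collapse = ""))
      }
      hd <- trimws(sub("^>", "", ln))
      if (hd == "") stop(sprintf("malformed FASTA at line %d of %s: empty header", i, path))
      headers <- c(headers, hd)
      buf <- character(0)
    } else {
      sq <- gsub("[[:space:]]", "", ln)
      if (grepl("[^A-Za-z?.-]", sq)) {
        stop(sprintf("malformed FASTA at line %d of %s: illegal sequence character", i, path))
      }
      buf <- c(buf, sq)
    }
  }
  if (length(buf) == 0L) {
    stop(sprintf("malformed FASTA at line %d of %s: header with no sequence",
                 nonblank[length(nonblank)], path))
  }
  seqs <- c(seqs, paste(buf, collapse = ""))

  parsed <- parse_headers(headers, id_sep)
  if (anyDuplicated(parsed$specimen_id)) {
    dup <- unique(parsed$specimen_id[duplicated(parsed$specimen_id)])
    stop("duplicate specimen id(s) in ", path, ": ", paste(dup, collapse = ", "))
  }
  names(seqs) <- parsed$specimen_id
  marker_matrix(seqs, parsed$species, marker = marker)
}

# `Genus_species<sep>specimenID` -> species ("Genus species") + specimen id.
parse_headers <- function(headers, id_sep = "|") {
  parts <- strsplit(headers, id_sep, fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) {
    stop("header(s) not matching 'Genus_species", id_sep, "specimenID': ",
         paste(headers[bad], collapse = ", "))
  }
  species <- gsub("_", " ", vapply(parts, `[[`, character(1), 1L))
  ids <- vapply(parts, `[[`, character(1), 2L)
  data.frame(species = species, specimen_id = ids, stringsAsFactors = FALSE)
}

#' Write a marker matrix as FASTA
#'
#' Inverse of [read_marker_fasta()]: headers are written as
#' `Genus_species<sep>specimenID`, so a write/read round trip reproduces the
#' sequences and labels exactly.
#'
#' @param x a `marker_matrix`.
#' @param path output path.
#' @param id_sep header separator (default `"|"`).
#' @export
write_marker_fasta <- function(x, path, id_sep = "|") {
  stopifnot(inherits(x, "marker_matrix"))
  headers <- paste0(">", gsub(" ", "_", x$species), id_sep, specimen_ids(x))
  out <- character(2L * length(x$seqs))
  out[c(TRUE, FALSE)] <- headers
  out[c(FALSE, TRUE)] <- unname(x$seqs)
  writeLines(out, path)
  invisible(path)
}

#' Filter policy for barcode record curation
#'
#' Records with more than `max_ambiguous` `N`s (strictly greater; a record
#' with exactly `max_ambiguous` is retained), and records belonging to
#' unnamed species (epithet `sp.` or `sp`), are removed by
#' [filter_records()].
#'
#' @param max_ambiguous tolerated count of `N` characters (default 10).
#' @param drop_unnamed drop species whose epithet is `sp.` (default TRUE).
#' @export
filter_policy <- function(max_ambiguous = 10L, drop_unnamed = TRUE) {
  stopifnot(max_ambiguous >= 0)
  structure(list(max_ambiguous = as.integer(max_ambiguous),
                 drop_unnamed = isTRUE(drop_unnamed)),
            class = "filter_policy")
}

#' Apply record-curation filters to a marker matrix
#'
#' @param x a `marker_matrix`.
#' @param policy a [filter_policy()].
#' @return list with `matrix` (the retained rows, or `NULL` when everything
#'   was removed) and `log`, a data.frame (`specimen_id`, `species`,
#'   `reason`) with one row per removal.
#' @export
filter_records <- function(x, policy = filter_policy()) {
  stopifnot(inherits(x, "marker_matrix"), inherits(policy, "filter_policy"))
  n_count <- vapply(strsplit(x$seqs, "", fixed = TRUE),
                    function(ch) sum(ch == "N"), integer(1))
  too_ambiguous <- n_count > policy$max_ambiguous
  epithet <- vapply(strsplit(x$species, "[ _]+"), function(tok) {
    if (length(tok) >= 2L) tok[2L] else ""
  }, character(1))
  unnamed <- policy$drop_unnamed & epithet %in% c("sp.", "sp")
  drop <- too_ambiguous | unnamed
  reason <- ifelse(too_ambiguous,
                   sprintf("ambiguous: %d N > %d", n_count, policy$max_ambiguous),
                   "unnamed species")
  log <- data.frame(
    specimen_id = specimen_ids(x)[drop],
    species = x$species[drop],
    reason = reason[drop],
    stringsAsFactors = FALSE
  )
  if (all(drop)) {
    warning("all records removed by filter")
    return(list(matrix = NULL, log = log))
  }
  keep <- !drop
  list(
    matrix = marker_matrix(x$seqs[keep], x$species[keep], marker = x$marker),
    log = log
  )
}

#' Write a removal log as TSV
#' @param log data.frame from [filter_records()].
#' @param path output path.
#' @export
write_filter_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Concatenate marker alignments into a supermatrix
#'
#' Specimens lacking any of the input markers are excluded (complete-data
#' rule for combined analyses). Columns are the in-order concatenation of
#' the inputs; the returned matrix carries a partition map of 0-based
#' half-open column intervals per marker.
#'
#' @param matrices list of aligned `marker_matrix` objects (length >= 2).
#' @param name marker name of the result (default: inputs joined by `+`).
#' @return a `marker_matrix` with a `partition` field.
#' @export
concatenate_markers <- function(matrices, name = NULL) {
  if (length(matrices) < 2L) stop("need at least 2 matrices to concatenate")
  for (m in matrices) assert_aligned(m, "concatenation")
  ids <- Reduce(intersect, lapply(matrices, specimen_ids))
  if (length(ids) == 0L) stop("no specimen is present in every input matrix")
  widths <- vapply(matrices, function(m) m$columns, integer(1))
  starts <- cumsum(c(0L, widths[-length(widths)]))
  partition <- Map(function(s, w) c(s, s + w), starts, widths)
  names(partition) <- vapply(matrices, function(m) m$marker, character(1))
  seqs <- vapply(ids, function(id) {
    paste(vapply(matrices, function(m) unname(m$seqs[id]), character(1)),
          collapse = "")
  }, character(1))
  species <- matrices[[1L]]$species[match(ids, specimen_ids(matrices[[1L]]))]
  # species labels must agree across inputs for shared specimens
  for (m in matrices[-1L]) {
    sp <- m$species[match(ids, specimen_ids(m))]
    if (any(sp != species)) {
      stop("conflicting species labels for specimen(s): ",
           paste(ids[sp != species], collapse = ", "))
    }
  }
  marker_matrix(seqs, species,
                marker = name %||% paste(names(partition), collapse = "+"),
                partition = partition)
}

#' Write a concatenation's partition map as JSON
#' @param x concatenated `marker_matrix`.
#' @param path output path.
#' @export
write_partition_map <- function(x, path) {
  stopifnot(inherits(x, "marker_matrix"), !is.null(x$partition))
  jsonlite::write_json(x$partition, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}
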