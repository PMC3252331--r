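#' Reference library for the best-match identification test
#'
#' Mirrors the rows of a marker matrix as (specimen id, species, sequence)
#' entries. A library built from a concatenated matrix inherits the
#' complete-data exclusion rule applied by [concatenate_markers()].
#'
#' @param x a `marker_matrix`.
#' @return object of class `ref_library`.
#' @export
build_library <- function(x) {
  stopifnot(inherits(x, "marker_matrix"))
  if (n_sequences(x) == 0L) stop("cannot build a library from an empty matrix")
  structure(
    list(specimen_id = specimen_ids(x),
         species = x$species,
         seqs = unname(x$seqs),
         marker = x$marker),
    class = "ref_library"
  )
}

#' @export
print.ref_library <- function(x, ...) {
  cat(sprintf("ref_library '%s': %d entries, %d species\n",
              x$marker, length(x$seqs), length(unique(x$species))))
  invisible(x)
}

#' 100% identity over the entire query length
#'
#' TRUE iff every column where the query has an unambiguous base (A/C/G/T)
#' carries the identical base in the subject, and the query has at least one
#' unambiguous base. Gaps and missing data in the query are ignored; a
#' column where the query has a base but the subject has a gap or missing
#' character fails the match (the subject does not cover the entire query).
#'
#' @param query,subject aligned sequence strings of equal length.
#' @export
full_length_identity <- function(query, subject) {
  q <- encode_base(seq_chars(toupper(query)))
  s <- encode_base(seq_chars(toupper(subject)))
  if (length(q) != length(s)) stop("sequences have unequal lengths")
  qi <- !is.na(q)
  if (!any(qi)) return(FALSE)
  all(!is.na(s[qi]) & s[qi] == q[qi])
}

# Directed all-pairs 100%-match matrix (row = query, col = subject).
match_matrix <- function(lib) {
  enc <- encode_matrix(stats::setNames(lib$seqs, lib$specimen_id))
  n <- nrow(enc)
  M <- matrix(FALSE, n, n, dimnames = list(lib$specimen_id, lib$specimen_id))
  for (q in seq_len(n)) {
    qi <- which(!is.na(enc[q, ]))
    if (length(qi) == 0L) next
    sub <- enc[, qi, drop = FALSE]
    tgt <- matrix(enc[q, qi], n, length(qi), byrow = TRUE)
    hit <- sub == tgt
    hit[is.na(hit)] <- FALSE
    M[q, ] <- rowSums(hit) == length(qi)
  }
  diag(M) <- FALSE # self-match excluded
  M
}

#' Best-match species identification over a reference library
#'
#' Every query is compared against every other library entry (leave-one-out;
#' the self-match is excluded). Let `M(q)` be the set of species owning a
#' subject 100%-identical to the query over its entire length. Per query:
#' *success* iff `M(q)` equals exactly the query's own species; *failure*
#' iff `M(q)` contains any other species; *no_match* iff `M(q)` is empty.
#' Per species: *failure* if any of its queries 100%-matches another
#' species' reference, else *success* if at least one query succeeds, else
#' *no_match*. Only species with outcome *success* count toward the success
#' rate: `success_rate = 100 * n_success / n_species`.
#'
#' @param lib a [build_library()] object with at least 2 entries.
#' @param query_mode `"per_sequence"` (every entry queried, default) or
#'   `"per_species_first"` (only the first entry of each species queried).
#' @return object of class `identification_report` with `per_query` and
#'   `per_species` data.frames, `n_species`, `n_success`, `success_rate`.
#' @export
identify_species <- function(lib, query_mode = c("per_sequence", "per_species_first")) {
  query_mode <- match.arg(query_mode)
  stopifnot(inherits(lib, "ref_library"))
  n <- length(lib$seqs)
  if (n < 2L) stop("identification needs a library with at least 2 entries")
  M <- match_matrix(lib)
  queries <- if (query_mode == "per_sequence") {
    seq_len(n)
  } else {
    which(!duplicated(lib$species))
  }
  per_query <- do.call(rbind, lapply(queries, function(q) {
    hit_species <- unique(lib$species[M[q, ]])
    own <- lib$species[q]
    outcome <- if (length(hit_species) == 0L) {
      "no_match"
    } else if (any(hit_species != own)) {
      "failure"
    } else {
      "success"
    }
    data.frame(specimen_id = lib$specimen_id[q], species = own,
               outcome = outcome,
               matching_species = paste(sort(hit_species), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  species <- unique(lib$species[queries])
  per_species <- do.call(rbind, lapply(species, function(sp) {
    rows <- per_query[per_query$species == sp, ]
    outcome <- if (any(rows$outcome == "failure")) {
      "failure"
    } else if (any(rows$outcome == "success")) {
      "success"
    } else {
      "no_match"
    }
    hits <- setdiff(unique(unlist(strsplit(rows$matching_species, ","))), c(sp, ""))
    data.frame(species = sp, outcome = outcome,
               matching_species = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  }))
  n_success <- sum(per_species$outcome == "success")
  structure(
    list(per_query = per_query,
         per_species = per_species,
         n_species = nrow(per_species),
         n_success = n_success,
         success_rate = 100 * n_success / nrow(per_species),
         query_mode = query_mode,
         marker = lib$marker),
    class = "identification_report"
  )
}

#' @export
print.identification_report <- function(x, ...) {
  cat(sprintf("identification_report '%s': %d/%d species correct (%.2f%%)\n",
              x$marker, x$n_success, x$n_species, x$success_rate))
  tab <- table(x$per_species$outcome)
  cat("  species outcomes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Marker-set comparison table of identification efficiency
#'
#' One row per marker set: species tested, species correctly identified,
#' success rate (%), and (where supplied) the overall K2P distance of the
#' single marker.
#'
#' @param reports named list of `identification_report` objects.
#' @param overall_k2p optional named numeric vector (substitutions/site) of
#'   overall K2P distances for single markers; matched by name.
#' @return data.frame (`marker_set`, `n_species`, `n_success`,
#'   `success_rate`, `overall_k2p_pct`).
#' @export
success_table <- function(reports, overall_k2p = NULL) {
  stopifnot(length(reports) >= 1L)
  do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    k2p <- if (!is.null(overall_k2p) && nm %in% names(overall_k2p)) {
      100 * unname(overall_k2p[nm])
    } else {
      NA_real_
    }
    data.frame(marker_set = nm, n_species = r$n_species,
               n_success = r$n_success, success_rate = r$success_rate,
               overall_k2p_pct = k2p, stringsAsFactors = FALSE)
  }))
}

#' Write an identification report as TSV (per species) and JSON summary
#' @param report an `identification_report`.
#' @param tsv_path,json_path output paths (either may be `NULL`).
#' @export
write_identification_report <- function(report, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path)) {
    utils::write.table(report$per_species, tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(marker = report$marker, query_mode = report$query_mode,
           n_species = report$n_species, n_success = report$n_success,
           success_rate = report$success_rate),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(report)
}
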