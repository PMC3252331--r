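#' Per-pair site classification under pairwise deletion
#'
#' Compares two equal-length aligned sequences column by column. Columns
#' where either sequence carries a gap (`-`), missing data (`N`, `?`) or any
#' IUPAC ambiguity code other than A/C/G/T are excluded (pairwise deletion).
#' Remaining columns are classified as identical, transition (A<->G, C<->T)
#' or transversion.
#'
#' @param a,b aligned sequence strings of equal length.
#' @return list with `n_valid`, `n_ts`, `n_tv`.
#' @export
site_counts <- function(a, b) {
  ca <- encode_base(seq_chars(toupper(a)))
  cb <- encode_base(seq_chars(toupper(b)))
  if (length(ca) != length(cb)) stop("sequences have unequal lengths")
  ok <- !is.na(ca) & !is.na(cb)
  if (!any(ok)) stop("no comparable sites")
  xa <- ca[ok]; xb <- cb[ok]
  diff <- xa != xb
  # purines A(1),G(3); pyrimidines C(2),T(4): transition iff both same parity
  ts <- diff & ((xa %% 2L) == (xb %% 2L))
  list(n_valid = sum(ok), n_ts = sum(ts), n_tv = sum(diff & !ts))
}

#' Distance from site counts under the p, JC or K2P model
#'
#' With `P = n_ts/n_valid`, `Q = n_tv/n_valid` and `p = P + Q`:
#' p-distance `= p`; Jukes-Cantor `= -3/4 * log(1 - 4p/3)`; Kimura
#' 2-parameter `= -1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)`. All distances
#' are in substitutions per site. Saturated pairs (where the correction's
#' logarithm argument is non-positive) raise an error rather than returning
#' `NaN` silently.
#'
#' @param counts list from [site_counts()].
#' @param model one of `"p"`, `"JC"`, `"K2P"`.
#' @return distance (substitutions/site).
#' @export
model_distance <- function(counts, model = c("K2P", "JC", "p")) {
  model <- match.arg(model)
  if (counts$n_valid <= 0) stop("no comparable sites")
  P <- counts$n_ts / counts$n_valid
  Q <- counts$n_tv / counts$n_valid
  p <- P + Q
  switch(model,
    p = p,
    JC = {
      if (p >= 0.75) stop(sprintf("saturated pair: p = %.4f >= 0.75 under JC", p))
      -0.75 * log(1 - 4 * p / 3)
    },
    K2P = {
      if ((1 - 2 * P - Q) <= 0 || (1 - 2 * Q) <= 0) {
        stop(sprintf("saturated pair: P = %.4f, Q = %.4f under K2P", P, Q))
      }
      -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q)
    }
  )
}

# Pairwise n_valid / n_ts / n_match matrices for all rows at once.
# Indicator-matrix products keep the all-pairs computation O(n^2 L) in BLAS.
pair_count_matrices <- function(enc) {
  V <- !is.na(enc)
  storage.mode(V) <- "double"
  n_valid <- tcrossprod(V)
  I <- lapply(1:4, function(b) {
    M <- !is.na(enc) & enc == b
    storage.mode(M) <- "double"
    M
  })
  n_match <- Reduce(`+`, lapply(I, tcrossprod))
  n_ts <- tcrossprod(I[[1]], I[[3]]) + tcrossprod(I[[3]], I[[1]]) +
    tcrossprod(I[[2]], I[[4]]) + tcrossprod(I[[4]], I[[2]])
  list(n_valid = n_valid, n_ts = n_ts,
       n_tv = n_valid - n_match - n_ts)
}

#' All-pairs distance matrix for an aligned marker matrix
#'
#' Computes [site_counts()] + [model_distance()] for every unordered pair.
#' Any pair with no comparable sites, or saturated under the chosen model,
#' aborts with an error listing the offending pairs.
#'
#' @param x aligned `marker_matrix` with at least 2 rows.
#' @param model `"p"`, `"JC"` or `"K2P"`.
#' @return symmetric numeric matrix (zero diagonal) with specimen ids as
#'   dimnames and attribute `model`.
#' @export
distance_matrix <- function(x, model = c("K2P", "JC", "p")) {
  model <- match.arg(model)
  assert_aligned(x, "distance computation")
  n <- n_sequences(x)
  if (n < 2L) stop("need at least 2 sequences for a distance matrix")
  enc <- encode_matrix(x$seqs)
  cm <- pair_count_matrices(enc)
  ids <- specimen_ids(x)

  up <- upper.tri(cm$n_valid)
  bad <- which(up & cm$n_valid == 0, arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop("no comparable sites for pair(s): ",
         paste(sprintf("%s/%s", ids[bad[, 1]], ids[bad[, 2]]), collapse = ", "))
  }
  P <- cm$n_ts / cm$n_valid
  Q <- cm$n_tv / cm$n_valid
  d <- switch(model,
    p = P + Q,
    JC = {
      arg <- 1 - 4 * (P + Q) / 3
      sat <- which(up & arg <= 0, arr.ind = TRUE)
      if (nrow(sat) > 0L) {
        stop("saturated pair(s) under JC: ",
             paste(sprintf("%s/%s", ids[sat[, 1]], ids[sat[, 2]]), collapse = ", "))
      }
      -0.75 * log(arg)
    },
    K2P = {
      a1 <- 1 - 2 * P - Q
      a2 <- 1 - 2 * Q
      sat <- which(up & (a1 <= 0 | a2 <= 0), arr.ind = TRUE)
      if (nrow(sat) > 0L) {
        stop("saturated pair(s) under K2P: ",
             paste(sprintf("%s/%s", ids[sat[, 1]], ids[sat[, 2]]), collapse = ", "))
      }
      -0.5 * log(a1) - 0.25 * log(a2)
    }
  )
  diag(d) <- 0
  dimnames(d) <- list(ids, ids)
  attr(d, "model") <- model
  d
}

#' Mean pairwise distance over the strict upper triangle
#'
#' The "overall distance" summary of a data set: the arithmetic mean over
#' all unordered specimen pairs.
#'
#' @param dm symmetric distance matrix from [distance_matrix()].
#' @export
overall_mean_distance <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm), nrow(dm) >= 2)
  mean(dm[upper.tri(dm)])
}

#' Realized transition/transversion count ratio of an alignment
#'
#' `R = sum(transitions) / sum(transversions)` over all unordered pairs
#' under pairwise deletion. A transversion-free data set has no defined
#' ratio and raises an error.
#'
#' @param x aligned `marker_matrix`.
#' @export
ts_tv_ratio <- function(x) {
  assert_aligned(x, "ts/tv ratio")
  if (n_sequences(x) < 2L) stop("need at least 2 sequences")
  cm <- pair_count_matrices(encode_matrix(x$seqs))
  up <- upper.tri(cm$n_ts)
  tv <- sum(cm$n_tv[up])
  if (tv == 0) stop("undefined transition/transversion ratio: no transversions")
  sum(cm$n_ts[up]) / tv
}

#' Binned relative-frequency distribution of pairwise distances
#'
#' Pairs are partitioned by whether the two specimens share a species name;
#' `scope` selects all pairs, only interspecific, or only intraspecific
#' pairs. Bins are half-open `[k*w, (k+1)*w)` and counts are normalized to
#' relative frequencies.
#'
#' @param dm distance matrix from [distance_matrix()].
#' @param species named character vector (or [species_map()] data.frame)
#'   mapping specimen id to species.
#' @param scope `"all"`, `"interspecific"` or `"intraspecific"`.
#' @param bin_width bin width in substitutions/site (default 0.005).
#' @return data.frame (`bin_start`, `bin_end`, `count`, `rel_freq`); empty
#'   (with a warning) when no pair falls in scope.
#' @export
distance_histogram <- function(dm, species,
                               scope = c("all", "interspecific", "intraspecific"),
                               bin_width = 0.005) {
  scope <- match.arg(scope)
  stopifnot(bin_width > 0)
  if (is.data.frame(species)) {
    species <- stats::setNames(species$species, species$specimen_id)
  }
  ids <- rownames(dm)
  sp <- species[ids]
  if (anyNA(sp)) stop("species mapping missing for some specimens")
  up <- which(upper.tri(dm), arr.ind = TRUE)
  same <- sp[up[, 1]] == sp[up[, 2]]
  keep <- switch(scope, all = rep(TRUE, nrow(up)),
                 interspecific = !same, intraspecific = same)
  vals <- dm[up][keep]
  if (length(vals) == 0L) {
    warning("no pairs in scope '", scope, "'")
    return(data.frame(bin_start = numeric(0), bin_end = numeric(0),
                      count = integer(0), rel_freq = numeric(0)))
  }
  k <- floor(vals / bin_width)
  tab <- table(factor(k, levels = 0:max(k)))
  data.frame(
    bin_start = as.numeric(names(tab)) * bin_width,
    bin_end = (as.numeric(names(tab)) + 1) * bin_width,
    count = as.integer(tab),
    rel_freq = as.integer(tab) / length(vals)
  )
}

#' Write / read a distance matrix as square TSV (labels in first column)
#' @param dm distance matrix.
#' @param path file path.
#' @export
write_distance_tsv <- function(dm, path) {
  df <- data.frame(label = rownames(dm), dm, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_tsv
#' @export
read_distance_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
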