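#' Neighbor-joining tree from a distance matrix
#'
#' Canonical neighbor joining: at each step the pair minimizing
#' `Q_ij = (n-2) d_ij - r_i - r_j` (with `r_i` the row sum of the current
#' matrix) is joined, branch lengths follow the standard formulas
#' `v_i = d_ij/2 + (r_i - r_j) / (2(n-2))`, and the reduced matrix uses
#' `d_uk = (d_ik + d_jk - d_ij)/2`. Ties in the Q matrix are broken
#' deterministically by the lowest (row, column) index pair in the current
#' label order, so the result is reproducible; newly created nodes are
#' appended at the end of the label order. A negative branch length is set
#' to zero and the difference transferred to the branch of its sibling, so
#' path lengths through the new node are preserved. On an additive matrix
#' the returned unrooted tree reproduces the generating topology and every
#' path length exactly.
#'
#' @param dm symmetric numeric distance matrix with unique dimnames, at
#'   least 3 taxa, finite non-negative entries.
#' @return unrooted tree of class `phylo` (base trifurcation).
#' @export
nj_tree <- function(dm) {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) stop("dm must be a square matrix")
  n0 <- nrow(dm)
  if (n0 < 3L) stop("neighbor joining needs at least 3 taxa")
  if (any(!is.finite(dm))) stop("distance matrix has non-finite entries")
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix is not symmetric")
  labels <- rownames(dm)
  if (is.null(labels) || anyDuplicated(labels)) {
    stop("dm needs unique row/column labels")
  }
  if (any(grepl("[ ,():;]", labels))) {
    stop("tip labels may not contain Newick metacharacters or spaces")
  }

  D <- unname(dm)
  # each active element is a Newick fragment (a tip label or a subtree)
  frag <- labels

  fmt <- function(x) sprintf("%.15g", x)

  while (nrow(D) > 3L) {
    n <- nrow(D)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    Q[lower.tri(Q, diag = TRUE)] <- Inf
    m <- min(Q)
    cand <- which(Q == m, arr.ind = TRUE)
    cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
    i <- cand[1, 1]; j <- cand[1, 2]

    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    if (vi < 0) vi <- 0

    newfrag <- paste0("(", frag[i], ":", fmt(vi), ",", frag[j], ":", fmt(vj), ")")
    dnew <- (D[i, -c(i, j)] + D[j, -c(i, j)] - D[i, j]) / 2

    keep <- setdiff(seq_len(n), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    D <- rbind(cbind(D, dnew), c(dnew, 0))
    frag <- c(frag[keep], newfrag)
  }

  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  va <- max(va, 0); vb <- max(vb, 0); vc <- max(vc, 0)
  nwk <- paste0("(", frag[1], ":", fmt(va), ",", frag[2], ":", fmt(vb), ",",
                frag[3], ":", fmt(vc), ");")
  ape::read.tree(text = nwk)
}
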