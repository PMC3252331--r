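# Fixtures and independent oracles used across the suite.

mk_matrix <- function(seqs, species = NULL, marker = "test") {
  if (is.null(names(seqs))) names(seqs) <- sprintf("s%02d", seq_along(seqs))
  if (is.null(species)) species <- paste("Genus", names(seqs))
  marker_matrix(seqs, species, marker = marker)
}

random_seq <- function(len, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Random aligned matrix of *related* sequences (common ancestor, per-site
# substitution probability `sub`), with occasional gaps / Ns to exercise
# pairwise deletion; divergences stay far from saturation.
random_matrix <- function(n, len, p_missing = 0.05, sub = 0.08) {
  anc <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
  seqs <- vapply(seq_len(n), function(i) {
    x <- anc
    mut <- stats::runif(len) < sub
    x[mut] <- sample(c("A", "C", "G", "T"), sum(mut), replace = TRUE)
    if (p_missing > 0) {
      miss <- stats::runif(len) < p_missing
      x[miss] <- sample(c("N", "-"), sum(miss), replace = TRUE)
    }
    paste(x, collapse = "")
  }, character(1))
  mk_matrix(seqs)
}

## ---- distance oracle: literal double loop over site_counts/model_distance

oracle_distance_loop <- function(x, model) {
  ids <- names(x$seqs)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <-
        model_distance(site_counts(x$seqs[[i]], x$seqs[[j]]), model)
    }
  }
  d
}

## ---- identification oracle: literal restatement of the best-match rule

oracle_match <- function(q, s) {
  qc <- strsplit(toupper(q), "")[[1]]
  sc <- strsplit(toupper(s), "")[[1]]
  idx <- which(qc %in% c("A", "C", "G", "T"))
  if (length(idx) == 0) return(FALSE)
  all(sc[idx] == qc[idx])
}

oracle_identify <- function(lib) {
  n <- length(lib$seqs)
  q_outcome <- character(n)
  q_hits <- vector("list", n)
  for (q in seq_len(n)) {
    hits <- character(0)
    for (s in seq_len(n)) {
      if (s == q) next
      if (oracle_match(lib$seqs[q], lib$seqs[s])) hits <- c(hits, lib$species[s])
    }
    hits <- unique(hits)
    q_hits[[q]] <- hits
    q_outcome[q] <- if (length(hits) == 0) {
      "no_match"
    } else if (any(hits != lib$species[q])) {
      "failure"
    } else {
      "success"
    }
  }
  species <- unique(lib$species)
  sp_outcome <- vapply(species, function(sp) {
    oc <- q_outcome[lib$species == sp]
    if (any(oc == "failure")) "failure"
    else if (any(oc == "success")) "success"
    else "no_match"
  }, character(1))
  list(per_query = q_outcome, per_species = sp_outcome,
       success_rate = 100 * sum(sp_outcome == "success") / length(species))
}

random_library <- function(n_species_max = 10, acc_max = 3, len = 12) {
  ns <- sample(2:n_species_max, 1)
  species <- sprintf("Genus sp%02d", seq_len(ns))
  # a small sequence pool forces 100% collisions between species
  pool <- replicate(max(2, ns %/% 2), random_seq(len, c("A", "C", "G", "T", "N", "-")))
  seqs <- character(0); sp <- character(0)
  for (s in species) {
    k <- sample(seq_len(acc_max), 1)
    base <- sample(pool, 1)
    for (a in seq_len(k)) {
      x <- strsplit(base, "")[[1]]
      if (stats::runif(1) < 0.5) { # mutate some accessions
        i <- sample(len, 1)
        x[i] <- sample(c("A", "C", "G", "T", "N"), 1)
      }
      seqs <- c(seqs, paste(x, collapse = ""))
      sp <- c(sp, s)
    }
  }
  names(seqs) <- sprintf("q%03d", seq_along(seqs))
  build_library(marker_matrix(seqs, sp, marker = "toy"))
}

## ---- monophyly oracle: enumerate clade tip sets from the edge table

oracle_clades <- function(tree) {
  ntip <- length(tree$tip.label)
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  collect <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    unlist(lapply(kids[[as.character(node)]], collect))
  }
  nodes <- (ntip + 1):(ntip + tree$Nnode)
  lapply(nodes, collect)
}

oracle_monophyletic <- function(tree, tips, outgroup) {
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  clades <- c(oracle_clades(rooted), as.list(rooted$tip.label))
  any(vapply(clades, function(cl) setequal(cl, tips), logical(1)))
}

## ---- NJ oracles

# Additive matrix with known generating tree.
random_additive <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(length(tr$edge.length), 0.1, 2)
  list(tree = tr, dm = ape::cophenetic.phylo(tr))
}

topo_equal <- function(t1, t2) {
  isTRUE(all.equal(phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)), 0))
}

# All unrooted binary topologies on the given labels (3 for n=4, 15 for n=5),
# built by inserting each further taxon on every edge.
all_topologies <- function(labels) {
  trees <- list(
    ape::read.tree(text = sprintf("((%s,%s),(%s,%s));",
                                  labels[1], labels[2], labels[3], labels[4])),
    ape::read.tree(text = sprintf("((%s,%s),(%s,%s));",
                                  labels[1], labels[3], labels[2], labels[4])),
    ape::read.tree(text = sprintf("((%s,%s),(%s,%s));",
                                  labels[1], labels[4], labels[2], labels[3]))
  )
  trees <- lapply(trees, ape::unroot)
  for (lab in labels[-(1:4)]) {
    out <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edge))) {
        t2 <- tr
        t2$edge.length <- rep(1, nrow(t2$edge))
        tip <- list(edge = matrix(c(2L, 1L), 1, 2), tip.label = lab,
                    edge.length = 1, Nnode = 1L)
        class(tip) <- "phylo"
        out[[length(out) + 1]] <- ape::unroot(ape::bind.tree(t2, tip, where = t2$edge[e, 2],
                                                             position = 0.5))
      }
    }
    # deduplicate by topology
    keep <- list()
    for (tr in out) {
      if (!any(vapply(keep, topo_equal, logical(1), tr))) keep[[length(keep) + 1]] <- tr
    }
    trees <- keep
  }
  trees
}

# Least-squares branch-length fit of a topology to a distance matrix;
# returns the residual sum of squares (0 iff the matrix is additive on it).
ls_fit_rss <- function(topology, dm) {
  labels <- rownames(dm)
  tr <- topology
  tr$edge.length <- rep(1, nrow(tr$edge))
  ntip <- length(tr$tip.label)
  pairs <- utils::combn(labels, 2)
  # path edges via node paths from a rooted copy
  rt <- ape::root(tr, outgroup = labels[1], resolve.root = TRUE)
  rt$edge.length <- rep(1, nrow(rt$edge))
  # incidence matrix: rows = pairs, cols = edges on the path between the pair
  A <- matrix(0, ncol(pairs), nrow(rt$edge))
  y <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- match(pairs[1, k], rt$tip.label)
    j <- match(pairs[2, k], rt$tip.label)
    p <- ape::nodepath(rt, i, j)
    eidx <- vapply(seq_len(length(p) - 1), function(m) {
      which((rt$edge[, 1] == p[m] & rt$edge[, 2] == p[m + 1]) |
              (rt$edge[, 2] == p[m] & rt$edge[, 1] == p[m + 1]))
    }, integer(1))
    A[k, eidx] <- 1
    y[k] <- dm[pairs[1, k], pairs[2, k]]
  }
  fit <- stats::lm.fit(A, y)
  list(rss = sum(fit$residuals^2), tree = rt)
}
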