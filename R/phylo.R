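## Bootstrap support and monophyly accounting on NJ trees.

# Canonical key of the bipartition induced by a clade tip set: take the side
# not containing the lexicographically first label of the whole tip set, so
# the key is invariant to which side of the (unrooted) edge is named.
bipartition_key <- function(clade_tips, all_tips) {
  ref <- min(all_tips)
  side <- if (ref %in% clade_tips) setdiff(all_tips, clade_tips) else clade_tips
  paste(sort(side), collapse = "\r")
}

# Non-trivial bipartition keys of a tree, named by the internal node whose
# subtending edge induces them (base node excluded: it has no parent edge).
tree_bipartitions <- function(tree) {
  ntip <- length(tree$tip.label)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  keys <- character(0)
  nodes <- integer(0)
  for (k in seq_along(parts)) {
    node <- ntip + k
    clade <- labs[parts[[k]]]
    if (length(clade) >= ntip - 1L || k == 1L) next # trivial / base node
    keys <- c(keys, bipartition_key(clade, labs))
    nodes <- c(nodes, node)
  }
  stats::setNames(keys, nodes)
}

#' Nonparametric bootstrap support for an NJ tree
#'
#' Builds the point-estimate NJ tree from the full alignment, then resamples
#' alignment columns with replacement (keeping the column count), recomputes
#' the distance matrix and NJ tree per replicate, and scores each internal
#' edge of the point tree by the percentage of replicate trees containing
#' the same bipartition (tip-set comparison; branch lengths ignored). A
#' replicate whose resampled alignment yields an incomparable or saturated
#' pair is discarded with a warning and does not count in the denominator.
#'
#' @param x aligned `marker_matrix`.
#' @param model distance model passed to [distance_matrix()].
#' @param replicates number of pseudoreplicates (default 1000).
#' @param seed integer seed; the run is reproducible given the seed.
#' @return the point-estimate `phylo` tree with `node.label` holding support
#'   percentages (`NA` on the base node) and attribute `replicates_used`.
#' @export
bootstrap_support <- function(x, model = "JC", replicates = 1000, seed = 1) {
  assert_aligned(x, "bootstrap")
  stopifnot(replicates >= 1)
  point <- nj_tree(distance_matrix(x, model))
  keys <- tree_bipartitions(point)
  hits <- stats::setNames(numeric(length(keys)), names(keys))
  chars <- do.call(rbind, strsplit(unname(x$seqs), "", fixed = TRUE))
  rownames(chars) <- specimen_ids(x)
  used <- 0L
  with_seed(seed, {
    for (r in seq_len(replicates)) {
      cols <- sample.int(ncol(chars), ncol(chars), replace = TRUE)
      seqs <- apply(chars[, cols, drop = FALSE], 1, paste, collapse = "")
      mm <- marker_matrix(seqs, x$species, marker = x$marker)
      tr <- tryCatch(nj_tree(distance_matrix(mm, model)), error = function(e) NULL)
      if (is.null(tr)) {
        warning(sprintf("bootstrap replicate %d discarded: incomparable or saturated pair", r))
        next
      }
      used <- used + 1L
      rep_keys <- tree_bipartitions(tr)
      hits <- hits + (keys %in% rep_keys)
    }
  })
  if (used == 0L) stop("all bootstrap replicates were discarded")
  support <- 100 * hits / used
  ntip <- length(point$tip.label)
  node.label <- rep(NA_real_, point$Nnode)
  node.label[as.integer(names(keys)) - ntip] <- support
  point$node.label <- node.label
  attr(point, "replicates_used") <- used
  point
}

#' Root a tree on an outgroup
#'
#' @param tree a `phylo` tree.
#' @param outgroup tip label (or vector of labels) to root on.
#' @return rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (length(outgroup) == 0L) stop("outgroup must name at least one tip")
  missing <- setdiff(outgroup, tree$tip.label)
  if (length(missing) > 0L) {
    stop("outgroup tip(s) absent from tree: ", paste(missing, collapse = ", "))
  }
  ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
}

#' Is a tip set monophyletic on an outgroup-rooted tree?
#'
#' TRUE iff the smallest clade of the rooted tree containing all given tips
#' contains no other tips.
#'
#' @param tree a `phylo` tree (rooted or not; it is rooted on `outgroup`).
#' @param tips tip labels of the group to test.
#' @param outgroup tip label(s) used to root the tree.
#' @export
is_monophyletic_group <- function(tree, tips, outgroup) {
  missing <- setdiff(tips, tree$tip.label)
  if (length(missing) > 0L) {
    stop("tip(s) absent from tree: ", paste(missing, collapse = ", "))
  }
  if (length(intersect(tips, outgroup)) > 0L) {
    stop("group tips overlap the outgroup")
  }
  rooted <- root_on_outgroup(tree, outgroup)
  ape::is.monophyletic(rooted, tips)
}

#' Species and genus monophyly accounting
#'
#' Evaluates, on the outgroup-rooted tree, every species and every genus
#' represented by at least two tips (singletons carry no grouping signal and
#' are excluded from the counts).
#'
#' @param tree a `phylo` tree whose tips are specimen ids.
#' @param species data.frame from [species_map()] (or a named character
#'   vector specimen id -> species).
#' @param outgroup tip label(s) to root on; outgroup tips are excluded from
#'   the groups.
#' @return object of class `monophyly_summary`: data.frames `species` and
#'   `genera` (`group`, `n_tips`, `monophyletic`) plus counts
#'   `n_species_monophyletic`, `n_genera_monophyletic`.
#' @export
monophyly_summary <- function(tree, species, outgroup) {
  if (is.data.frame(species)) {
    species <- stats::setNames(species$species, species$specimen_id)
  }
  rooted <- root_on_outgroup(tree, outgroup)
  tips <- setdiff(tree$tip.label, outgroup)
  sp <- species[tips]
  if (anyNA(sp)) stop("species mapping missing for some tips")
  eval_groups <- function(assign) {
    groups <- split(tips, assign)
    groups <- groups[lengths(groups) >= 2L]
    if (length(groups) == 0L) {
      return(data.frame(group = character(0), n_tips = integer(0),
                        monophyletic = logical(0), stringsAsFactors = FALSE))
    }
    data.frame(
      group = names(groups),
      n_tips = lengths(groups),
      monophyletic = vapply(groups, function(g) ape::is.monophyletic(rooted, g),
                            logical(1)),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  sp_df <- eval_groups(sp)
  gen_df <- eval_groups(genus_of(sp))
  if (nrow(sp_df) == 0L && nrow(gen_df) == 0L) {
    warning("no species or genus has 2 or more tips; empty summary")
  }
  structure(
    list(species = sp_df, genera = gen_df,
         n_species_monophyletic = sum(sp_df$monophyletic),
         n_genera_monophyletic = sum(gen_df$monophyletic)),
    class = "monophyly_summary"
  )
}

#' @export
print.monophyly_summary <- function(x, ...) {
  cat(sprintf("monophyly_summary: %d/%d species, %d/%d genera monophyletic\n",
              x$n_species_monophyletic, nrow(x$species),
              x$n_genera_monophyletic, nrow(x$genera)))
  invisible(x)
}

#' Write a monophyly summary as TSV
#' @param x a `monophyly_summary`.
#' @param path output path.
#' @export
write_monophyly_tsv <- function(x, path) {
  df <- rbind(
    cbind(level = rep("species", nrow(x$species)), x$species),
    cbind(level = rep("genus", nrow(x$genera)), x$genera)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
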