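#' Configuration for the synthetic barcode-family simulator
#'
#' The generator emulates a plant family sampled for plastid barcodes:
#' a Yule (pure-birth) species tree with short internal branches near the
#' present (a recent radiation), several accessions per species, one or more
#' markers evolved under the Kimura 2-parameter substitution model with
#' transition bias, and spacer-like indels on non-coding markers. Defaults
#' mirror a 46-species family sampled at ~2 accessions per species with
#' three plastid markers (two coding, one spacer) of lengths 632/797/679 and
#' overall K2P divergences 0.6%/1.4%/0.7%.
#'
#' @param n_species number of ingroup species (default 46).
#' @param accessions_per_species integer, or integer vector of length
#'   `n_species` (default 2).
#' @param markers data.frame with columns `name`, `seq_length`, `divergence`
#'   (target overall mean pairwise K2P, substitutions/site), `indel_rate`
#'   (indel events per site per unit branch length; 0 for coding markers)
#'   and `missing_rate` (probability a specimen lacks the marker).
#' @param intra_divergence expected K2P distance between conspecific
#'   accessions, in substitutions/site (default 0.001, a typical plastid
#'   value). `0` makes conspecific accessions identical in expectation.
#'   Held absolute rather than proportional to `divergence`: intraspecific
#'   plastid variation is roughly constant across families while
#'   interspecific divergence varies, which is what creates (or destroys)
#'   the barcoding gap.
#' @param kappa transition/transversion *rate* ratio of the substitution
#'   model. `NULL` (default) calibrates it with [kappa_for_ts_tv()] so the
#'   realized transition/transversion *count* ratio is about 2.09 at the
#'   mean marker divergence.
#' @param indel_mean_length mean indel length in bp (geometric; default 11.4).
#' @param genus_depth lineages crossing this time before present (fraction
#'   of tree depth) define genera (default 0.6).
#' @param include_outgroup attach a distant outgroup specimen (default TRUE).
#' @param outgroup_depth outgroup divergence time as a multiple of the
#'   ingroup crown depth (default 2).
#' @param seed master seed; every stochastic draw flows from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_species = 46,
                       accessions_per_species = 2,
                       markers = default_markers(),
                       intra_divergence = 0.001,
                       kappa = NULL,
                       indel_mean_length = 11.4,
                       genus_depth = 0.6,
                       include_outgroup = TRUE,
                       outgroup_depth = 2,
                       seed = 1) {
  stopifnot(n_species >= 2, all(accessions_per_species >= 1),
            intra_divergence >= 0, indel_mean_length >= 1,
            genus_depth > 0, genus_depth < 1, outgroup_depth > 1)
  if (length(accessions_per_species) == 1L) {
    accessions_per_species <- rep(as.integer(accessions_per_species), n_species)
  }
  if (length(accessions_per_species) != n_species) {
    stop("accessions_per_species must have length 1 or n_species")
  }
  req <- c("name", "seq_length", "divergence", "indel_rate", "missing_rate")
  if (!all(req %in% names(markers))) {
    stop("markers needs columns: ", paste(req, collapse = ", "))
  }
  stopifnot(all(markers$divergence > 0), all(markers$divergence < 0.75),
            all(markers$seq_length >= 1), all(markers$indel_rate >= 0),
            all(markers$missing_rate >= 0), all(markers$missing_rate < 1))
  if (is.null(kappa)) {
    kappa <- kappa_for_ts_tv(2.09, mean(markers$divergence))
  }
  stopifnot(kappa > 0)
  structure(
    list(n_species = as.integer(n_species),
         accessions_per_species = as.integer(accessions_per_species),
         markers = markers,
         intra_divergence = intra_divergence,
         kappa = kappa,
         indel_mean_length = indel_mean_length,
         genus_depth = genus_depth,
         include_outgroup = isTRUE(include_outgroup),
         outgroup_depth = outgroup_depth,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' Default three-marker configuration (two coding genes plus one spacer)
#'
#' Lengths and overall divergences follow a typical plastid barcode study
#' (rbcL 632 bp / 0.6%, matK 797 bp / 1.4%, trnH-psbA 679 bp / 0.7%); the
#' spacer receives indels at a rate chosen so a family-scale data set
#' accumulates on the order of 30 indel events; per-marker missing rates
#' reproduce uneven sequencing success (92, 101 and 99 of 101 specimens).
#'
#' @export
default_markers <- function() {
  data.frame(
    name = c("rbcL", "matK", "trnH_psbA"),
    seq_length = c(632L, 797L, 679L),
    divergence = c(0.006, 0.014, 0.007),
    indel_rate = c(0, 0, 0.7),
    missing_rate = c(0.089, 0, 0.02),
    stringsAsFactors = FALSE
  )
}

#' Rate-ratio kappa giving a target realized transition/transversion count ratio
#'
#' The Kimura model's `kappa` is a rate-matrix parameter, whereas the
#' ratio reported from data is a realized count ratio, which decays with
#' divergence as transitions saturate. Under the model with transition rate
#' `alpha = kappa * beta` (normalized so `alpha + 2 beta = 1`), the expected
#' transition and transversion proportions at distance `d` are
#' `P = 1/4 + 1/4 exp(-4 beta d) - 1/2 exp(-2 (alpha+beta) d)` and
#' `Q = 1/2 (1 - exp(-4 beta d))`; this solves `P/Q = ratio` for `kappa`.
#'
#' @param ratio target realized count ratio (e.g. 2.09).
#' @param divergence pairwise distance at which the ratio is realized.
#' @export
kappa_for_ts_tv <- function(ratio, divergence) {
  stopifnot(ratio > 0.5, divergence > 0, divergence < 0.75)
  f <- function(kappa) expected_ts_tv(kappa, divergence) - ratio
  stats::uniroot(f, c(0.51, 500), tol = 1e-10)$root
}

# Expected P/Q count ratio at distance d under the two-parameter model.
expected_ts_tv <- function(kappa, d) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  P <- 0.25 + 0.25 * exp(-4 * beta * d) - 0.5 * exp(-2 * (alpha + beta) * d)
  Q <- 0.5 * (1 - exp(-4 * beta * d))
  P / Q
}

#' Simulate the true species tree and specimen bookkeeping
#'
#' Draws a pure-birth (Yule) species tree scaled to unit depth, assigns
#' genera by cutting the tree at `genus_depth` (every lineage crossing that
#' time before present founds a genus, so genera are clades on the true
#' tree), and allocates accession ids per species. Deterministic given the
#' config seed.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_tree`: `species_tree` (unit-depth `phylo`,
#'   tips are `Genus_species` labels), `map` (data.frame `specimen_id`,
#'   `species`, `genus`), `outgroup_id` (or `NULL`).
#' @export
simulate_species_tree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    tr <- ape::rphylo(config$n_species, birth = 1, death = 0)
    depth <- max(ape::node.depth.edgelength(tr))
    tr$edge.length <- tr$edge.length / depth

    genus_id <- assign_genera(tr, config$genus_depth)
    genus_names <- sprintf("Genus%02d", genus_id)
    sp_names <- sprintf("%s_species%02d", genus_names, seq_len(config$n_species))
    tr$tip.label <- sp_names

    k <- config$accessions_per_species
    specimen_id <- sprintf("S%03d", seq_len(sum(k)))
    map <- data.frame(
      specimen_id = specimen_id,
      species = gsub("_", " ", rep(sp_names, k)),
      genus = rep(genus_names, k),
      stringsAsFactors = FALSE
    )
    outgroup_id <- NULL
    if (config$include_outgroup) {
      outgroup_id <- "OUT1"
      map <- rbind(map, data.frame(specimen_id = "OUT1",
                                   species = "Outgroupus distans",
                                   genus = "Outgroupus",
                                   stringsAsFactors = FALSE))
    }
    structure(list(species_tree = tr, map = map, outgroup_id = outgroup_id,
                   config = config),
              class = "sim_tree")
  })
}

# Genus index per tip: tips sharing the lineage that crosses `depth` time
# before present belong to one genus.
assign_genera <- function(tr, depth) {
  n <- length(tr$tip.label)
  h <- ape::node.depth.edgelength(tr) # depth from root
  tbp <- max(h[seq_len(n)]) - h       # time before present
  parent <- integer(max(tr$edge))
  parent[tr$edge[, 2]] <- tr$edge[, 1]
  founder <- integer(n)
  for (tip in seq_len(n)) {
    node <- tip
    while (parent[node] != 0 && tbp[parent[node]] < depth) node <- parent[node]
    founder[tip] <- node
  }
  match(founder, unique(founder))
}

#' Accession-level tree in substitutions/site for one marker
#'
#' Scales the unit-depth species tree so the accession-weighted mean
#' pairwise path among ingroup accessions equals the marker's target
#' overall divergence, then replaces each species tip by a star of
#' accession tips whose height is half the target conspecific distance
#' (carved out of the pendant branch, so interspecific paths are
#' unchanged), and finally attaches the outgroup below the ingroup crown.
#'
#' @param sim a `sim_tree` from [simulate_species_tree()].
#' @param divergence target overall mean pairwise K2P (substitutions/site).
#' @param intra_divergence target conspecific pairwise distance; defaults to
#'   the config value.
#' @return `phylo` tree with specimen-id tips, branch lengths in
#'   substitutions/site.
#' @export
accession_tree <- function(sim, divergence,
                           intra_divergence = sim$config$intra_divergence) {
  stopifnot(inherits(sim, "sim_tree"))
  cfg <- sim$config
  tr <- sim$species_tree
  k <- cfg$accessions_per_species
  ingroup <- sim$map[sim$map$specimen_id != (sim$outgroup_id %||% ""), ]
  acc_ids <- split(ingroup$specimen_id, match(ingroup$species,
                                              gsub("_", " ", tr$tip.label)))

  paths <- ape::cophenetic.phylo(tr) # unit-scale species paths
  w <- outer(k, k)
  inter_w <- sum(w[upper.tri(w)] * paths[upper.tri(paths)])
  n_total <- sum(k)
  n_pairs <- choose(n_total, 2)
  n_intra <- sum(choose(k, 2))
  s <- (divergence * n_pairs - n_intra * intra_divergence) / inter_w
  if (s <= 0) {
    stop("intra_divergence too large for the requested overall divergence")
  }
  h <- intra_divergence / 2

  fmt <- function(x) sprintf("%.15g", x)
  children <- split(tr$edge[, 2], tr$edge[, 1])
  elen <- numeric(max(tr$edge))
  elen[tr$edge[, 2]] <- tr$edge.length
  ntip <- length(tr$tip.label)

  build <- function(node) {
    if (node <= ntip) {
      ids <- acc_ids[[as.character(node)]]
      pend <- s * elen[node]
      if (length(ids) == 1L) {
        return(paste0(ids, ":", fmt(pend)))
      }
      hh <- min(h, 0.9 * pend)
      star <- paste(paste0(ids, ":", fmt(hh)), collapse = ",")
      return(paste0("(", star, "):", fmt(pend - hh)))
    }
    subs <- vapply(children[[as.character(node)]], build, character(1))
    paste0("(", paste(subs, collapse = ","), "):", fmt(s * elen[node]))
  }
  root <- ntip + 1L
  crown <- paste0("(",
                  paste(vapply(children[[as.character(root)]], build,
                               character(1)), collapse = ","),
                  ")")
  if (!is.null(sim$outgroup_id)) {
    stem <- s * (cfg$outgroup_depth - 1)
    nwk <- paste0("(", crown, ":", fmt(stem), ",", sim$outgroup_id, ":",
                  fmt(s * cfg$outgroup_depth), ");")
  } else {
    nwk <- paste0(crown, ";")
  }
  ape::read.tree(text = nwk)
}

#' Evolve an aligned marker matrix along a tree
#'
#' The root sequence is uniform over A/C/G/T; sites evolve independently
#' under the Kimura 2-parameter rate matrix with transition/transversion
#' rate ratio `kappa`, with branch lengths read as expected substitutions
#' per site. When `indel_rate > 0`, indel events are laid on branches with
#' probability proportional to branch length (count Poisson with mean
#' `indel_rate * seq_length * total branch length`), lengths geometric with
#' the given mean, positions uniform; each event gaps the affected columns
#' in the clade below the branch (or, for insertion-type events, in its
#' complement), so the output alignment reflects the true homology.
#'
#' @param tree `phylo` with specimen-id tips, branch lengths in subs/site.
#' @param map data.frame `specimen_id` -> `species` (see [species_map()]).
#' @param seq_length alignment columns.
#' @param kappa transition/transversion rate ratio.
#' @param indel_rate indel events per site per unit branch length.
#' @param indel_mean_length mean indel length (bp).
#' @param marker marker name for the result.
#' @param seed optional seed; `NULL` uses the current RNG stream.
#' @return an aligned [marker_matrix()].
#' @export
evolve_alignment <- function(tree, map, seq_length, kappa = 4.2,
                             indel_rate = 0, indel_mean_length = 11.4,
                             marker = "sim", seed = NULL) {
  run <- function() {
    sim <- phangorn::simSeq(tree, l = seq_length,
                            Q = c(1, kappa, 1, 1, kappa, 1),
                            bf = rep(0.25, 4), type = "DNA")
    chars <- toupper(as.character(sim))
    if (indel_rate > 0) chars <- overlay_indels(chars, tree, indel_rate,
                                                indel_mean_length)
    seqs <- apply(chars, 1, paste, collapse = "")
    species <- map$species[match(names(seqs), map$specimen_id)]
    if (anyNA(species)) stop("tree tips missing from species map")
    marker_matrix(seqs, species, marker = marker)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Gap columns of clade/complement tip sets to mimic indel events.
overlay_indels <- function(chars, tree, rate, mean_len) {
  L <- ncol(chars)
  total <- sum(tree$edge.length)
  n_events <- stats::rpois(1, rate * L * total)
  if (n_events == 0) return(chars)
  ntip <- length(tree$tip.label)
  for (ev in seq_len(n_events)) {
    edge <- sample.int(nrow(tree$edge), 1, prob = tree$edge.length)
    node <- tree$edge[edge, 2]
    below <- if (node <= ntip) tree$tip.label[node] else {
      tree$tip.label[unlist(phangorn::Descendants(tree, node, "tips"))]
    }
    affected <- if (stats::runif(1) < 0.5) below else setdiff(tree$tip.label, below)
    if (length(affected) == 0L || length(affected) == ntip) next
    len <- 1L + stats::rgeom(1, 1 / mean_len)
    start <- sample.int(L, 1)
    cols <- start:min(L, start + len - 1L)
    chars[affected, cols] <- "-"
  }
  chars
}

#' Simulate a complete multi-marker barcode data set
#'
#' One species tree; each configured marker evolved on its own
#' substitutions/site scaling of that tree (coding markers indel-free,
#' spacer-like markers with indels); per-marker missing specimens dropped
#' at the configured rates. Fully reproducible from the config seed.
#'
#' @param config a [sim_config()].
#' @return object of class `sim_output`: `tree` (the `sim_tree`),
#'   `accession_trees` (named list of per-marker `phylo`, subs/site),
#'   `markers` (named list of `marker_matrix`), `map`, `outgroup_id`,
#'   `realized` (data.frame `marker`, `n_sequences`, `overall_k2p`,
#'   `ts_tv`), `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_species_tree(config)
  out <- with_seed(config$seed + 1L, {
    trees <- list()
    mats <- list()
    for (i in seq_len(nrow(config$markers))) {
      mk <- config$markers[i, ]
      tr <- accession_tree(sim, mk$divergence)
      mm <- evolve_alignment(tr, sim$map, mk$seq_length, kappa = config$kappa,
                             indel_rate = mk$indel_rate,
                             indel_mean_length = config$indel_mean_length,
                             marker = mk$name)
      if (mk$missing_rate > 0) {
        drop <- stats::runif(n_sequences(mm)) < mk$missing_rate
        drop[specimen_ids(mm) == (sim$outgroup_id %||% "")] <- FALSE
        if (sum(!drop) >= 2L && any(drop)) {
          mm <- marker_matrix(mm$seqs[!drop], mm$species[!drop], marker = mm$marker)
        }
      }
      trees[[mk$name]] <- tr
      mats[[mk$name]] <- mm
    }
    list(trees = trees, mats = mats)
  })
  realized <- do.call(rbind, lapply(names(out$mats), function(nm) {
    mm <- out$mats[[nm]]
    keep <- specimen_ids(mm) != (sim$outgroup_id %||% "")
    ing <- marker_matrix(mm$seqs[keep], mm$species[keep], marker = nm)
    dm <- distance_matrix(ing, "K2P")
    data.frame(marker = nm, n_sequences = n_sequences(ing),
               overall_k2p = overall_mean_distance(dm),
               ts_tv = tryCatch(ts_tv_ratio(ing), error = function(e) NA_real_),
               stringsAsFactors = FALSE)
  }))
  structure(
    list(tree = sim, accession_trees = out$trees, markers = out$mats,
         map = sim$map, outgroup_id = sim$outgroup_id,
         realized = realized, config = config),
    class = "sim_output"
  )
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("sim_output: %d species, %d specimens, %d markers (seed %d)\n",
              x$config$n_species, nrow(x$map), length(x$markers),
              x$config$seed))
  print(x$realized)
  invisible(x)
}

#' Write a simulated data set to disk
#'
#' Per-marker aligned FASTA, true species tree Newick, species map TSV and
#' a manifest JSON recording the configuration and realized statistics.
#'
#' @param sim a `sim_output`.
#' @param dir output directory (created if needed).
#' @return named list of file paths (`fasta` per marker, `tree`, `map`,
#'   `manifest`).
#' @export
write_sim_output <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_output"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fasta <- vapply(names(sim$markers), function(nm) {
    path <- file.path(dir, paste0(nm, ".fasta"))
    write_marker_fasta(sim$markers[[nm]], path)
    path
  }, character(1))
  tree_path <- file.path(dir, "species_tree.nwk")
  ape::write.tree(sim$tree$species_tree, tree_path)
  map_path <- file.path(dir, "species_map.tsv")
  utils::write.table(sim$map, map_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  manifest_path <- file.path(dir, "manifest.json")
  cfg <- sim$config
  jsonlite::write_json(
    list(n_species = cfg$n_species,
         accessions_per_species = cfg$accessions_per_species,
         markers = cfg$markers,
         intra_divergence = cfg$intra_divergence,
         kappa = cfg$kappa,
         indel_mean_length = cfg$indel_mean_length,
         include_outgroup = cfg$include_outgroup,
         outgroup_id = sim$outgroup_id,
         seed = cfg$seed,
         realized = sim$realized),
    manifest_path, auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  list(fasta = fasta, tree = tree_path, map = map_path,
       manifest = manifest_path)
}
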