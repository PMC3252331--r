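small_cfg <- function(..., markers = data.frame(
                        name = "m1", seq_length = 500, divergence = 0.02,
                        indel_rate = 0, missing_rate = 0,
                        stringsAsFactors = FALSE)) {
  sim_config(n_species = 6, accessions_per_species = 2, markers = markers,
             seed = 1, ...)
}

test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_species = 1), "n_species")
  expect_error(small_cfg(intra_divergence = -0.1), "intra_divergence")
  expect_error(small_cfg(markers = data.frame(
    name = "m", seq_length = 100, divergence = 0.9, indel_rate = 0,
    missing_rate = 0)), "divergence")
  expect_error(sim_config(n_species = 4, accessions_per_species = c(2, 2)),
               "length 1 or n_species")
})

test_that("two species with two accessions give a four-tip tree of two cherries", {
  cfg <- sim_config(n_species = 2, accessions_per_species = 2,
                    include_outgroup = FALSE, seed = 3,
                    markers = small_cfg()$markers)
  sim <- simulate_species_tree(cfg)
  tr <- accession_tree(sim, 0.02)
  expect_equal(length(tr$tip.label), 4)
  sp <- stats::setNames(sim$map$species, sim$map$specimen_id)
  for (s in unique(sp)) {
    expect_true(oracle_monophyletic(ape::unroot(tr),
                                    names(sp)[sp == s],
                                    names(sp)[sp != s][1]))
  }
})

test_that("the species tree and data set are reproducible from the seed", {
  cfg <- small_cfg()
  t1 <- simulate_species_tree(cfg)
  t2 <- simulate_species_tree(cfg)
  expect_identical(ape::write.tree(t1$species_tree),
                   ape::write.tree(t2$species_tree))
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$markers$m1$seqs, d2$markers$m1$seqs)
  cfg2 <- small_cfg()
  cfg2$seed <- 2L
  d3 <- simulate_dataset(cfg2)
  expect_false(identical(d1$markers$m1$seqs, d3$markers$m1$seqs))
})

test_that("zero intraspecific divergence makes conspecific accessions identical", {
  cfg <- small_cfg(intra_divergence = 0)
  out <- simulate_dataset(cfg)
  seqs <- out$markers$m1$seqs
  sp <- stats::setNames(out$map$species, out$map$specimen_id)
  for (s in setdiff(unique(sp), "Outgroupus distans")) {
    ids <- intersect(names(seqs), names(sp)[sp == s])
    expect_equal(length(unique(unname(seqs[ids]))), 1, info = s)
  }
})

test_that("the accession tree hits the target mean pairwise divergence exactly", {
  # tiny intraspecific height so no accession star is clipped by a short
  # pendant branch (clipping trades a little intraspecific depth for exactness)
  cfg <- sim_config(n_species = 12, accessions_per_species = c(rep(1, 6), rep(3, 6)),
                    seed = 5, intra_divergence = 1e-5,
                    markers = small_cfg()$markers)
  sim <- simulate_species_tree(cfg)
  for (target in c(0.005, 0.02, 0.06)) {
    tr <- accession_tree(sim, target)
    ing <- setdiff(tr$tip.label, sim$outgroup_id)
    cp <- ape::cophenetic.phylo(tr)[ing, ing]
    expect_equal(mean(cp[upper.tri(cp)]), target, tolerance = 1e-9)
  }
})

test_that("a zero-length tree yields identical rows", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,c:0);")
  map <- data.frame(specimen_id = c("a", "b", "c"),
                    species = c("X x", "X x", "X y"))
  m <- evolve_alignment(tr, map, 200, seed = 2)
  expect_equal(length(unique(unname(m$seqs))), 1)
})

test_that("kappa calibration matches its closed form and large kappa kills transversions", {
  k <- kappa_for_ts_tv(2.09, 0.014)
  expect_equal(barcodegauge:::expected_ts_tv(k, 0.014), 2.09, tolerance = 1e-8)
  expect_gt(k, 2 * 2.09 - 0.5) # count ratio ~ kappa/2 at low divergence
  tr <- ape::read.tree(text = "((a:0.02,b:0.02):0.01,c:0.03);")
  map <- data.frame(specimen_id = c("a", "b", "c"),
                    species = c("X x", "X y", "X z"))
  m <- evolve_alignment(tr, map, 4000, kappa = 500, seed = 9)
  cnt <- site_counts(m$seqs[["a"]], m$seqs[["b"]])
  expect_gt(cnt$n_ts, 0)
  expect_lt(cnt$n_tv, cnt$n_ts / 10)
})

test_that("realized transition/transversion ratio increases with kappa", {
  set.seed(14)
  tr <- ape::rtree(10)
  tr$edge.length <- tr$edge.length / sum(tr$edge.length) * 0.5
  map <- data.frame(specimen_id = tr$tip.label,
                    species = paste("X", tr$tip.label))
  ratios <- vapply(c(1, 4, 16), function(kap) {
    mean(vapply(1:3, function(s) {
      m <- evolve_alignment(tr, map, 1500, kappa = kap, seed = 100 * kap + s)
      ts_tv_ratio(m)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("spacer-like markers carry indels; coding markers stay gap-free", {
  cfg <- sim_config(
    n_species = 12, accessions_per_species = 2, seed = 8,
    markers = data.frame(
      name = c("cod", "spc"), seq_length = c(500, 679),
      divergence = c(0.02, 0.02), indel_rate = c(0, 0.7),
      missing_rate = c(0, 0), stringsAsFactors = FALSE))
  out <- simulate_dataset(cfg)
  expect_false(any(grepl("-", out$markers$cod$seqs, fixed = TRUE)))
  expect_true(any(grepl("-", out$markers$spc$seqs, fixed = TRUE)))
  # gap runs have geometric-like lengths: just check some run exceeds 1 column
  runs <- unlist(lapply(out$markers$spc$seqs, function(s) {
    r <- rle(strsplit(s, "")[[1]] == "-")
    r$lengths[r$values]
  }))
  expect_gt(max(runs), 1)
})

test_that("per-marker missing specimens are dropped but the outgroup is kept", {
  cfg <- sim_config(n_species = 20, accessions_per_species = 2, seed = 4,
                    markers = data.frame(
                      name = "m1", seq_length = 300, divergence = 0.02,
                      indel_rate = 0, missing_rate = 0.3,
                      stringsAsFactors = FALSE))
  out <- simulate_dataset(cfg)
  expect_lt(n_sequences(out$markers$m1), nrow(out$map))
  expect_true(out$outgroup_id %in% names(out$markers$m1$seqs))
})

test_that("simulated data are written as FASTA/Newick/TSV/JSON and read back", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg()
  out <- simulate_dataset(cfg)
  paths <- write_sim_output(out, dir)
  expect_true(all(file.exists(unlist(paths))))
  back <- read_marker_fasta(paths$fasta[["m1"]], marker = "m1")
  expect_equal(back$seqs, out$markers$m1$seqs)
  expect_equal(back$species,
               out$map$species[match(names(back$seqs), out$map$specimen_id)])
  manifest <- jsonlite::read_json(paths$manifest)
  expect_equal(manifest$seed, 1)
  expect_equal(length(manifest$realized), nrow(out$realized))
  tre <- ape::read.tree(paths$tree)
  expect_equal(length(tre$tip.label), cfg$n_species)
})

test_that("genus assignment partitions species into clades of the true tree", {
  cfg <- sim_config(n_species = 25, accessions_per_species = 1, seed = 6,
                    include_outgroup = FALSE, markers = small_cfg()$markers)
  sim <- simulate_species_tree(cfg)
  tr <- sim$species_tree
  genus <- genus_of(gsub("_", " ", tr$tip.label))
  for (g in unique(genus)) {
    tips <- tr$tip.label[genus == g]
    other <- tr$tip.label[genus != g]
    if (length(tips) < 2 || length(other) == 0) next
    expect_true(oracle_monophyletic(tr, tips, other[1]), info = g)
  }
})

test_that("NJ on low-noise simulated data recovers most species groupings", {
  hits <- vapply(1:3, function(s) {
    cfg <- sim_config(n_species = 15, accessions_per_species = 2, seed = s,
                      intra_divergence = 1e-4,
                      markers = data.frame(
                        name = "m1", seq_length = 2500, divergence = 0.05,
                        indel_rate = 0, missing_rate = 0,
                        stringsAsFactors = FALSE))
    out <- simulate_dataset(cfg)
    tr <- nj_tree(distance_matrix(out$markers$m1, "JC"))
    ms <- monophyly_summary(tr, out$map, out$outgroup_id)
    ms$n_species_monophyletic / nrow(ms$species)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})
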