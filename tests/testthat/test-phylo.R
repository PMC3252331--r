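test_that("neighbor joining rejects degenerate inputs", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(d), "at least 3")
  d3 <- matrix(c(0, 1, 2, 9, 0, 3, 2, 3, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(d3), "not symmetric")
  d3[1, 3] <- Inf; d3[3, 1] <- Inf
  expect_error(nj_tree(d3), "non-finite")
})

test_that("three taxa follow the three-point formulas", {
  lab <- c("a", "b", "c")
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, 3, dimnames = list(lab, lab))
  tr <- nj_tree(d)
  cp <- ape::cophenetic.phylo(tr)
  expect_equal(cp[lab, lab], d, tolerance = 1e-12, ignore_attr = TRUE)
  # va = (dab + dac - dbc)/2 = 1, vb = 2, vc = 3
  v <- stats::setNames(tr$edge.length[match(seq_along(lab), tr$edge[, 2])],
                       tr$tip.label)
  expect_equal(unname(v[lab]), c(1, 2, 3))
})

test_that("a hand-built 4-taxon additive matrix is recovered exactly", {
  # generating tree ((A:1,B:2):1,(C:3,D:4))
  lab <- c("A", "B", "C", "D")
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4, dimnames = list(lab, lab))
  tr <- nj_tree(d)
  expect_equal(ape::cophenetic.phylo(tr)[lab, lab], d,
               tolerance = 1e-12, ignore_attr = TRUE)
  truth <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  expect_true(topo_equal(tr, truth))
  # tip branch lengths
  v <- stats::setNames(tr$edge.length[match(match(lab, tr$tip.label),
                                            tr$edge[, 2])], lab)
  expect_equal(unname(v), c(1, 2, 3, 4))
})

test_that("NJ reconstructs random additive matrices of 4 to 8 taxa exactly", {
  set.seed(13)
  for (n in 4:8) {
    for (rep in 1:5) {
      gen <- random_additive(n)
      tr <- nj_tree(gen$dm)
      expect_true(topo_equal(tr, gen$tree))
      expect_equal(ape::cophenetic.phylo(tr)[rownames(gen$dm), colnames(gen$dm)],
                   gen$dm, tolerance = 1e-9, ignore_attr = TRUE)
    }
  }
})

test_that("two identical rows become zero-length siblings", {
  lab <- c("a", "b", "c", "d")
  d <- matrix(c(0, 0, 4, 5,
                0, 0, 4, 5,
                4, 4, 0, 3,
                5, 5, 3, 0), 4, 4, dimnames = list(lab, lab))
  tr <- nj_tree(d)
  # a and b are siblings with zero terminal branches
  va <- tr$edge.length[tr$edge[, 2] == match("a", tr$tip.label)]
  vb <- tr$edge.length[tr$edge[, 2] == match("b", tr$tip.label)]
  expect_equal(va, 0)
  expect_equal(vb, 0)
  pa <- tr$edge[tr$edge[, 2] == match("a", tr$tip.label), 1]
  pb <- tr$edge[tr$edge[, 2] == match("b", tr$tip.label), 1]
  expect_equal(pa, pb)
})

test_that("NJ topology is invariant under taxon permutation and matches ape", {
  set.seed(31)
  for (rep in 1:8) {
    n <- sample(5:9, 1)
    gen <- random_additive(n)
    noise <- matrix(stats::runif(n * n, 0, 0.05), n)
    noise <- (noise + t(noise)) / 2; diag(noise) <- 0
    d <- gen$dm + noise
    tr <- nj_tree(d)
    perm <- sample(n)
    tr_p <- nj_tree(d[perm, perm])
    expect_true(topo_equal(tr, tr_p))
    expect_true(topo_equal(tr, ape::nj(as.dist(d))))
  }
})

test_that("a cleanly separated pair of species gets full bootstrap support", {
  seqs <- c(a1 = strrep("A", 50), a2 = strrep("A", 50),
            b1 = paste0(strrep("A", 25), strrep("G", 25)),
            b2 = paste0(strrep("A", 25), strrep("G", 25)))
  m <- marker_matrix(seqs, c("Aa aa", "Aa aa", "Bb bb", "Bb bb"))
  tr <- bootstrap_support(m, "JC", replicates = 50, seed = 4)
  sup <- tr$node.label[!is.na(tr$node.label)]
  expect_equal(unname(sup), 100)
  expect_equal(attr(tr, "replicates_used"), 50)
})

test_that("bootstrap support is deterministic given the seed and bounded", {
  set.seed(8)
  m <- random_matrix(8, 120, p_missing = 0)
  m$species <- rep(sprintf("Aa sp%d", 1:4), each = 2)
  t1 <- bootstrap_support(m, "JC", replicates = 30, seed = 11)
  t2 <- bootstrap_support(m, "JC", replicates = 30, seed = 11)
  expect_identical(t1$node.label, t2$node.label)
  sup <- t1$node.label[!is.na(t1$node.label)]
  expect_true(all(sup >= 0 & sup <= 100))
})

test_that("bootstrap support is invariant to tip order up to bipartitions", {
  set.seed(9)
  m <- random_matrix(7, 150, p_missing = 0)
  perm <- sample(7)
  m2 <- marker_matrix(m$seqs[perm], m$species[perm])
  t1 <- bootstrap_support(m, "JC", replicates = 25, seed = 2)
  t2 <- bootstrap_support(m2, "JC", replicates = 25, seed = 2)
  s1 <- sort(t1$node.label[!is.na(t1$node.label)])
  s2 <- sort(t2$node.label[!is.na(t2$node.label)])
  expect_equal(s1, s2)
})

test_that("monophyly follows the smallest-containing-clade rule", {
  tr <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:1,B2:1):1);")
  expect_true(is_monophyletic_group(tr, c("A1", "A2"), outgroup = c("B1", "B2")))
  tr2 <- ape::read.tree(text = "((A1:1,B1:1):1,(A2:1,B2:1):1,O:3);")
  expect_false(is_monophyletic_group(tr2, c("A1", "A2"), outgroup = "O"))
  expect_error(is_monophyletic_group(tr2, c("A1", "A2"), outgroup = "missing"),
               "absent")
  expect_error(is_monophyletic_group(tr2, c("A1", "O"), outgroup = "O"),
               "overlap")
  expect_error(is_monophyletic_group(tr2, c("A1", "nope"), outgroup = "O"),
               "absent")
})

test_that("monophyly matches the clade-enumeration oracle on random trees", {
  set.seed(77)
  for (i in 1:60) {
    tr <- ape::rtree(8)
    tr$tip.label <- sprintf("t%d", 1:8)
    out <- sample(tr$tip.label, 1)
    tips <- sample(setdiff(tr$tip.label, out), sample(2:5, 1))
    expect_equal(is_monophyletic_group(tr, tips, out),
                 oracle_monophyletic(tr, tips, out),
                 info = paste(tips, collapse = ","))
  }
})

test_that("swapping one tip out of a monophyletic set breaks monophyly", {
  set.seed(55)
  tried <- 0
  for (i in 1:40) {
    tr <- ape::rtree(8)
    tr$tip.label <- sprintf("t%d", 1:8)
    out <- tr$tip.label[1]
    rooted <- ape::root(tr, outgroup = out, resolve.root = TRUE)
    clades <- Filter(function(cl) length(cl) >= 2 && !(out %in% cl) &&
                       length(cl) < 7, oracle_clades(rooted))
    if (length(clades) == 0) next
    cl <- clades[[sample(length(clades), 1)]]
    outside <- setdiff(tr$tip.label, c(cl, out))
    if (length(outside) == 0) next
    swapped <- c(cl[-1], sample(outside, 1))
    expect_true(is_monophyletic_group(tr, cl, out))
    expect_false(is_monophyletic_group(tr, swapped, out))
    tried <- tried + 1
  }
  expect_gt(tried, 10)
})

test_that("monophyly summary counts multi-tip species and genera", {
  tr <- ape::read.tree(
    text = "(((a1:1,a2:1):1,((b1:1,c1:1):1,(b2:1,c2:1):1):1):1,OUT:5);")
  sp <- data.frame(
    specimen_id = c("a1", "a2", "b1", "b2", "c1", "c2", "OUT"),
    species = c("Aa aa", "Aa aa", "Bb bb", "Bb bb", "Bb cc", "Bb cc",
                "Out out"),
    stringsAsFactors = FALSE
  )
  ms <- monophyly_summary(tr, sp, outgroup = "OUT")
  expect_equal(ms$n_species_monophyletic, 1) # only Aa aa
  got <- stats::setNames(ms$species$monophyletic, ms$species$group)
  expect_true(got[["Aa aa"]])
  expect_false(got[["Bb bb"]])
  expect_false(got[["Bb cc"]])
  # genera: Aa monophyletic, Bb (b1,c1,b2,c2) monophyletic as a clade
  gen <- stats::setNames(ms$genera$monophyletic, ms$genera$group)
  expect_true(gen[["Aa"]])
  expect_true(gen[["Bb"]])
})

test_that("all-singleton species give an empty summary with a warning", {
  tr <- ape::read.tree(text = "((a1:1,b1:1):1,OUT:2);")
  sp <- data.frame(specimen_id = c("a1", "b1", "OUT"),
                   species = c("Aa aa", "Bb bb", "Out out"))
  expect_warning(ms <- monophyly_summary(tr, sp, "OUT"), "no species or genus")
  expect_equal(nrow(ms$species), 0)
  expect_equal(ms$n_species_monophyletic, 0)
})

test_that("support values survive a Newick round trip", {
  seqs <- c(a1 = strrep("A", 40), a2 = strrep("A", 40),
            b1 = paste0(strrep("A", 30), strrep("G", 10)),
            b2 = paste0(strrep("A", 30), strrep("G", 10)),
            c1 = paste0(strrep("A", 20), strrep("G", 20)))
  m <- marker_matrix(seqs, c("Aa aa", "Aa aa", "Bb bb", "Bb bb", "Cc cc"))
  tr <- bootstrap_support(m, "JC", replicates = 10, seed = 1)
  f <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tr, f)
  back <- ape::read.tree(f)
  expect_setequal(back$tip.label, tr$tip.label)
  got <- suppressWarnings(as.numeric(back$node.label))
  expect_setequal(got[!is.na(got)], tr$node.label[!is.na(tr$node.label)])
})
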