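test_that("feature profiles count sliding words and skip ambiguous windows", {
  p <- ffp_profile("ACGAC", L = 2)
  expect_equal(p$counts[c("AC", "CG", "GA")], c(AC = 2L, CG = 1L, GA = 1L))
  expect_equal(p$total, 4)

  set.seed(51)
  s <- random_dna(500)
  p2 <- ffp_profile(s, L = 20)
  expect_equal(p2$total, 500 - 20 + 1)

  sn <- seq_record("n", paste0(strrep("A", 30), "N", strrep("C", 30)),
                   degenerate = TRUE)
  p3 <- ffp_profile(sn, L = 10)
  expect_equal(p3$total, (61 - 10 + 1) - 10) # 10 windows contain the N
  expect_error(ffp_profile("ACG", L = 20), "shorter")
})

test_that("profile divergence satisfies the Jensen-Shannon axioms", {
  set.seed(52)
  a <- ffp_profile(random_dna(300), L = 8)
  b <- ffp_profile(random_dna(300), L = 8)
  expect_equal(ffp_distance(a, a), 0)
  expect_equal(ffp_distance(a, b), ffp_distance(b, a))
  expect_gte(ffp_distance(a, b), 0)
  expect_lte(ffp_distance(a, b), log(2) + 1e-12)
  # disjoint feature sets sit at the ln 2 maximum
  expect_equal(ffp_distance(ffp_profile(strrep("A", 30), 5),
                            ffp_profile(strrep("C", 30), 5)), log(2))
  # and the value matches direct summation over the feature union
  expect_equal(ffp_distance(a, b), oracle_jsd(a$counts, b$counts))
  expect_error(ffp_distance(a, ffp_profile(random_dna(100), L = 9)),
               "feature lengths")
})

test_that("neighbor-joining solves the three-taxon case in closed form", {
  D <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  # three-point formulas: a = (dab+dac-dbc)/2 etc.
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 1, c = 2))
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ reconstructs trees exactly from additive distances", {
  set.seed(53)
  for (n in c(4, 6, 8)) {
    tr <- ape::rtree(n, br = function(k) runif(k, 0.1, 1))
    tr <- ape::unroot(tr)
    D <- cophenetic(tr)
    got <- nj_tree(D)
    expect_equal(phangorn::RF.dist(got, tr), 0)
    expect_equal(cophenetic(got)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("the assignment solver matches exhaustive matching", {
  set.seed(54)
  for (rep in 1:10) {
    n <- sample(2:5, 1)
    cost <- matrix(sample(0:9, n * n, replace = TRUE), n, n)
    expect_equal(tmpclust:::hungarian_min_cost(cost), oracle_assignment(cost),
                 label = paste("case", rep))
  }
})

test_that("Matching Splits distance behaves on worked examples", {
  t1 <- ape::read.tree(text = "((a,b),(c,d));")
  t2 <- ape::read.tree(text = "((a,c),(b,d));")
  expect_equal(matching_splits(t1, t1)$ms, 0)
  expect_equal(matching_splits(t1, t2)$ms, 2)
  expect_equal(matching_splits(t1, t2)$ms, matching_splits(t2, t1)$ms)
  # distance to the star tree counts each split at its smaller side size
  t8 <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  s8 <- star_tree(letters[1:8])
  # splits: 2+2+2+2 (cherries) + 4-leaf side of the central edge = min(4,4)
  expect_equal(matching_splits(t8, s8)$ms, 2 + 2 + 2 + 2 + 4)
  expect_equal(matching_splits(t8, s8)$pct_of_star, 100)
  expect_error(matching_splits(t1, ape::read.tree(text = "((a,b),(c,e));")),
               "leaf sets")
})

test_that("Matching Splits equals the exhaustive oracle on random trees", {
  set.seed(55)
  for (rep in 1:8) {
    n <- sample(5:7, 1)
    t1 <- ape::rtree(n, tip.label = letters[1:n])
    t2 <- ape::rtree(n, tip.label = letters[1:n])
    labels <- sort(t1$tip.label)
    s1 <- tmpclust:::tree_splits(ape::unroot(t1), labels)
    s2 <- tmpclust:::tree_splits(ape::unroot(t2), labels)
    expect_equal(matching_splits(t1, t2)$ms,
                 oracle_matching_splits(s1, s2, n), label = paste("case", rep))
  }
})

test_that("bootstrap consensus keeps unanimous splits at full support", {
  # 4 identical-signal taxa pairs: every replicate yields the same topology
  rows <- c(a = strrep("AAAACCCC", 8), b = strrep("AAAACCCC", 8),
            c = strrep("CCCCAAAA", 8), d = strrep("CCCCAAAA", 8))
  set.seed(56)
  cons <- bootstrap_consensus(rows, replicates = 50)
  expect_true(ape::is.monophyletic(cons, c("a", "b")) ||
              ape::is.monophyletic(cons, c("c", "d")))
  sup <- suppressWarnings(as.numeric(cons$node.label))
  sup <- sup[!is.na(sup)]
  expect_true(all(sup > 50 & sup <= 100))
  expect_true(any(sup == 100))
  expect_error(bootstrap_consensus(rows, replicates = 0), "replicates")
})

test_that("majority rule drops the minority resolution of conflicting signal", {
  # 6 columns support ab|cd, 4 columns support ac|bd: the 60% split is kept
  col1 <- c(a = "A", b = "A", c = "C", d = "C")
  col2 <- c(a = "A", b = "C", c = "A", d = "C")
  rows <- vapply(names(col1), function(tx)
    paste(c(rep(col1[tx], 6), rep(col2[tx], 4)), collapse = ""), "")
  set.seed(57)
  cons <- bootstrap_consensus(rows, replicates = 400)
  expect_true(ape::is.monophyletic(cons, c("a", "b")))
  expect_false(ape::is.monophyletic(cons, c("a", "c")))
})

test_that("gsi is 1 exactly for monophyletic groups and drops with dispersal", {
  tr <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  expect_equal(gsi(tr, c("a", "b")), 1)
  expect_equal(gsi(tr, c("a", "b", "c", "d")), 1)
  # two leaves on opposite sides of the balanced 8-leaf tree:
  # gs = 1/5 over 5 uniting nodes, min = 1/7 -> gsi = 1/15
  expect_equal(gsi(tr, c("a", "e")), 1 / 15)
  expect_lt(gsi(tr, c("a", "e")), 1)
  expect_error(gsi(tr, c("a", "z")), "not in tree")
  expect_error(gsi(tr, "a"), ">= 2 members")
  expect_error(gsi(ape::unroot(tr), c("a", "b")), "rooted")
})

test_that("pulling a member into the group's clade never lowers gsi", {
  tr <- ape::read.tree(text = "(((a,b),c),((d,e),f));")
  inside <- gsi(tr, c("a", "b", "c"))   # one clade
  outside <- gsi(tr, c("a", "b", "d"))  # d dispersed to the far side
  expect_gt(inside, outside)
  expect_equal(inside, 1)
})

test_that("clade recovery reports monophyly and gsi per labelled group", {
  tr <- ape::read.tree(text = "(((a1,a2),(b1,b2)),((c1,c2),x));")
  labs <- label_table(c("a1", "a2", "b1", "b2", "c1", "c2", "x"),
                      c("A", "A", "A", "A", "C", "C", "X"),
                      c("A1", "A1", "A2", "A2", "C1", "C1", ""))
  rep <- clade_recovery(tr, labs)
  a1 <- rep[rep$group == "A1", ]
  expect_true(a1$monophyletic)
  expect_equal(a1$gsi, 1)
  # singleton groups are reported as not applicable
  expect_true(is.na(rep$monophyletic[rep$group == "X"]))
  # a grafted member breaks monophyly and depresses gsi
  tr2 <- ape::read.tree(text = "(((a1,c1),(b1,b2)),((a2,c2),x));")
  rep2 <- clade_recovery(tr2, labs)
  a1b <- rep2[rep2$group == "A1", ]
  expect_false(a1b$monophyletic)
  expect_lt(a1b$gsi, 1)
  # empty label table gives an empty report
  expect_equal(nrow(clade_recovery(tr, labs[0, ])), 0)
})
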