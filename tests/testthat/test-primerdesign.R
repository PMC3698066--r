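test_that("fully conserved alignments yield windows at every start and length", {
  rows <- rep(paste0(strrep("ACGT", 7), "AC"), 3) # 30 columns, identical
  w <- find_conserved_windows(rows)
  # every start for every allowed length 16..22
  expect_equal(nrow(w), sum(30 - 16:22 + 1))
  expect_true(all(w$degenerate_positions == 0))
  expect_true(all(w$gap_free))
  # longest windows reported first
  expect_equal(w$length[1], 22)
})

test_that("a polymorphic column forces the IUPAC consensus code", {
  base <- strrep("ACGTG", 6)
  alt <- base
  substr(alt, 9, 9) <- "C" # T -> C at column 9: consensus Y
  w <- find_conserved_windows(c(base, alt), min_len = 16, max_len = 16)
  covering <- w[w$msa_column_start <= 9 & w$msa_column_start + 15 >= 9, ]
  expect_true(all(covering$degenerate_positions == 1))
  expect_true(all(substr(covering$consensus,
                         9 - covering$msa_column_start + 1,
                         9 - covering$msa_column_start + 1) == "Y"))
})

test_that("windows are rejected when every candidate is too degenerate", {
  set.seed(41)
  base <- random_dna(60)
  alt <- base
  # polymorphism every 4th column: any 16-mer window holds >= 4 of them
  for (i in seq(1, 60, by = 4)) {
    cur <- substr(base, i, i)
    substr(alt, i, i) <- setdiff(c("A", "C", "G", "T"), cur)[1]
  }
  expect_equal(nrow(find_conserved_windows(c(base, alt))), 0)
})

test_that("gapped columns disqualify windows and ragged input errors", {
  rows <- c(strrep("A", 40), paste0(strrep("A", 20), "-", strrep("A", 19)))
  w <- find_conserved_windows(rows)
  expect_true(all(w$msa_column_start + w$length - 1 < 21 |
                  w$msa_column_start > 21))
  expect_error(find_conserved_windows(c("AC", "ACG")), "ragged")
})

test_that("primer pairs are designed within the product range on every row", {
  set.seed(42)
  anc <- random_dna(600)
  rows <- c(a = anc, b = diverge(anc, 0.03, seed = 1))
  w <- find_conserved_windows(rows)
  pairs <- design_primer_pairs(w, rows, product_range = c(150, 500))
  expect_gt(nrow(pairs), 0)
  for (i in seq_len(min(nrow(pairs), 10))) {
    lens <- pairs$products[[i]]
    expect_true(all(lens >= 150 & lens <= 500))
    expect_true(nchar(pairs$forward[i]) %in% 16:22)
    expect_true(nchar(pairs$reverse[i]) %in% 16:22)
  }
  expect_equal(nrow(design_primer_pairs(w[0, ], rows)), 0)
})

test_that("design-time product length equals the in-silico PCR product", {
  set.seed(43)
  anc <- random_dna(700)
  rows <- c(a = anc, b = diverge(anc, 0.05, seed = 2))
  pairs <- design_primer_pairs(find_conserved_windows(rows), rows,
                               product_range = c(200, 600))
  expect_gt(nrow(pairs), 0)
  for (i in seq_len(min(nrow(pairs), 5))) {
    for (id in names(rows)) {
      amp <- insilico_pcr(seq_record(id, rows[[id]]), pairs[i, ])
      expect_true(pairs$products[[i]][[id]] %in% amp$length)
    }
  }
})

test_that("in-silico PCR spans the whole template for terminal primers", {
  set.seed(44)
  s <- seq_record("t", random_dna(400))
  pair <- list(forward = substr(s$residues, 1, 20),
               reverse = revcomp(substr(s$residues, 381, 400)))
  amp <- insilico_pcr(s, pair)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$start, 1)
  expect_equal(amp$end, 400)
  expect_equal(amp$length, 400)
})

test_that("in-silico PCR honours IUPAC degeneracy and the template-N rule", {
  t1 <- seq_record("c_tmpl", paste0("GGGG", "ACCTG", strrep("A", 200),
                                    "CAGGT", "CCCC"))
  # forward ACYTG: Y covers the template C at its third base
  pair <- list(forward = "ACYTG", reverse = "ACCTG") # revcomp(ACCTG)=CAGGT
  amp <- insilico_pcr(t1, pair, max_product = 500)
  expect_equal(nrow(amp), 1)
  # over a template A at the Y position the primer no longer binds
  t2 <- seq_record("a_tmpl", gsub("ACCTG", "ACATG", t1$residues))
  expect_equal(nrow(insilico_pcr(t2, pair, max_product = 500)), 0)
  # a degenerate template base at the primer site blocks annealing
  t3 <- seq_record("n_tmpl", sub("ACCTG", "ACNTG", t1$residues),
                   degenerate = TRUE)
  expect_equal(nrow(insilico_pcr(t3, pair, max_product = 500)), 0)
  expect_equal(nrow(insilico_pcr(t3, pair, max_product = 500,
                                 match_template_n = TRUE)), 1)
})

test_that("amplicon lengths are strand-symmetric", {
  set.seed(45)
  s <- random_dna(500)
  pair <- list(forward = substr(s, 51, 70),
               reverse = revcomp(substr(s, 401, 420)))
  a1 <- insilico_pcr(seq_record("fwd", s), pair)
  a2 <- insilico_pcr(seq_record("rev", revcomp(s)), pair)
  expect_equal(sort(a1$length), sort(a2$length))
})

test_that("cross-reactivity screening separates subclusters", {
  cfg <- synth_config(n_clusters = 2, subclusters_per_cluster = 2,
                      members_per_subcluster = 2, genome_length = 4000,
                      tmp_length = 1500, tmp_start = 501, seed = 46)
  p <- generate_panel(cfg)
  panel <- reference_panel(p$tmp_genes,
                           label_table(p$truth$id, p$truth$cluster,
                                       p$truth$subcluster))
  pairs <- do.call(rbind, lapply(unique(p$truth$subcluster), function(sc) {
    rows <- msa(p$tmp_genes[p$truth$subcluster == sc])
    design_primer_pairs(find_conserved_windows(rows), rows,
                        product_range = c(150, 900), group = sc)[1, ]
  }))
  m <- cross_reactivity(panel, pairs)
  for (i in seq_len(nrow(pairs))) {
    own <- p$truth$subcluster == pairs$group[i]
    expect_true(all(m[i, own] >= 1), label = paste("amplifies own", pairs$group[i]))
    expect_true(all(m[i, !own] == 0), label = paste("specific", pairs$group[i]))
  }
  # empty pair list gives an empty matrix
  expect_equal(dim(cross_reactivity(panel, pairs[0, ])), c(0L, 8L))
})

test_that("primers from an undifferentiated panel amplify every template", {
  s <- random_dna(600)
  recs <- lapply(paste0("t", 1:3), function(id) seq_record(id, s))
  panel <- reference_panel(recs, label_table(paste0("t", 1:3), "A",
                                             c("A1", "A1", "A2")))
  rows <- setNames(rep(s, 2), c("t1", "t2"))
  pairs <- design_primer_pairs(find_conserved_windows(rows), rows,
                               product_range = c(150, 500), group = "A1")[1, ]
  m <- cross_reactivity(panel, pairs)
  expect_true(all(m >= 1))
})
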