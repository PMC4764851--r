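test_that("1:1 ortholog selection keeps only unambiguous reciprocal pairs", {
  # g1: mutual best in both species -> selected
  # g2: absent from species B -> excluded
  # g3: two equally-best co-orthologs in species A -> excluded
  spA <- list(
    ab = make_hits(hit_line("g1", "a1", ev = 1e-80),
                   hit_line("g2", "a2", ev = 1e-80),
                   hit_line("g3", "a3", ev = 1e-80, bits = 200),
                   hit_line("g3", "a4", ev = 1e-80, bits = 200)),
    ba = make_hits(hit_line("a1", "g1", ev = 1e-80),
                   hit_line("a2", "g2", ev = 1e-80),
                   hit_line("a3", "g3", ev = 1e-80),
                   hit_line("a4", "g3", ev = 1e-80)))
  spB <- list(
    ab = make_hits(hit_line("g1", "b1", ev = 1e-70),
                   hit_line("g3", "b3", ev = 1e-70)),
    ba = make_hits(hit_line("b1", "g1", ev = 1e-70),
                   hit_line("b3", "g3", ev = 1e-70)))
  sel <- select_121_orthologs(list(A = spA, B = spB))
  expect_equal(sel$anchor, "g1")
  expect_equal(sel$A, "a1")
  expect_equal(sel$B, "b1")

  # hits above the e-value cutoff do not count
  sel2 <- select_121_orthologs(list(A = spA, B = spB), e_max = 1e-90)
  expect_equal(nrow(sel2), 0L)
  expect_error(select_121_orthologs(list(A = list(ab = spA$ab))),
               "missing hit table")
})

test_that("tie detection matches a brute-force co-ortholog graph check", {
  set.seed(61)
  # random bipartite best-hit structure; a gene is 1:1 iff its best edge is
  # unique both ways — checked by explicit enumeration
  genes <- sprintf("g%d", 1:8); subs <- sprintf("s%d", 1:8)
  lines_ab <- character(0); lines_ba <- character(0)
  for (g in genes) {
    tgt <- sample(subs, 3)
    evs <- sample(c(1e-60, 1e-60, 1e-70), 3)
    for (i in 1:3)
      lines_ab <- c(lines_ab, hit_line(g, tgt[i], ev = evs[i], bits = 100))
  }
  for (s in subs) {
    tgt <- sample(genes, 3)
    evs <- sample(c(1e-60, 1e-65, 1e-70), 3)
    for (i in 1:3)
      lines_ba <- c(lines_ba, hit_line(s, tgt[i], ev = evs[i], bits = 100))
  }
  ab <- make_hits(lines_ab); ba <- make_hits(lines_ba)
  sel <- select_121_orthologs(list(S = list(ab = ab, ba = ba)),
                              e_max = 1e-50)
  brute_best <- function(tab, q) {
    h <- tab[tab$query_id == q, ]
    best_e <- min(h$e_value)
    top <- h[h$e_value == best_e & h$bitscore == max(h$bitscore[h$e_value == best_e]), ]
    if (length(unique(top$subject_id)) > 1) NA_character_
    else top$subject_id[1]
  }
  expected <- character(0)
  for (g in genes) {
    b <- brute_best(ab, g)
    if (is.na(b)) next
    back <- brute_best(ba, b)
    if (!is.na(back) && back == g) expected <- c(expected, g)
  }
  expect_setequal(sel$anchor, expected)
})

test_that("column filtering removes gapped columns and re-indexes partitions", {
  rows <- c(t1 = "ACD-EF", t2 = "ACDQEF", t3 = "ACXQEF")
  part <- data.frame(gene = c("gA", "gB"), start = c(1L, 4L),
                     end = c(3L, 6L))
  blk <- alignment_block(rows, part, alphabet = "aa")
  f <- filter_columns(blk)
  # column 3 (X in t3) and 4 (gap in t1) drop; hand-filtered expectation
  expect_equal(unname(f$rows), c("ACEF", "ACEF", "ACEF"))
  expect_equal(f$partition$gene, c("gA", "gB"))
  expect_equal(f$partition$start, c(1L, 3L))
  expect_equal(f$partition$end, c(2L, 4L))

  # gap-free conserved block passes unchanged
  clean <- alignment_block(c(a = "MKV", b = "MKV", c = "MKV"))
  expect_equal(filter_columns(clean)$rows, clean$rows)

  # tolerant threshold keeps columns under the gap fraction
  f2 <- filter_columns(blk, max_gap_fraction = 0.5)
  expect_equal(nchar(f2$rows[[1]]), 6L)

  # everything removed -> empty, flagged
  gappy <- alignment_block(c(a = "--", b = "AA", c = "A-"))
  fe <- filter_columns(gappy)
  expect_equal(nchar(fe$rows[[1]]), 0L)
  expect_true(isTRUE(attr(fe, "flagged")))

  # filtering never increases length
  set.seed(71)
  for (i in 1:5) {
    chars <- sample(c("A", "R", "N", "-", "X"), 60, replace = TRUE,
                    prob = c(0.4, 0.3, 0.2, 0.05, 0.05))
    rr <- c(x = paste(chars[1:20], collapse = ""),
            y = paste(chars[21:40], collapse = ""),
            z = paste(chars[41:60], collapse = ""))
    bb <- alignment_block(rr)
    expect_lte(nchar(filter_columns(bb)$rows[[1]]), 20L)
  }
})

test_that("concatenation is name-keyed and length-conserving", {
  b1 <- alignment_block(c(A = "MKVLQWERTY", B = "MKVLQWERTY",
                          C = "MKVLQWERTE"),
                        data.frame(gene = "g1", start = 1L, end = 10L))
  b2 <- alignment_block(c(C = "NNNNNDDDDDEEEEE", A = "NNNNNDDDDDEEEEE",
                          B = "NNNNNDDDDDEEEEE"),
                        data.frame(gene = "g2", start = 1L, end = 15L))
  cc <- concatenate_blocks(list(b1, b2))
  expect_equal(nchar(cc$rows[["A"]]), 25L)
  expect_equal(cc$partition$gene, c("g1", "g2"))
  expect_equal(cc$partition$end, c(10L, 25L))
  # row order in the second block was permuted; rows joined by name
  expect_equal(substr(cc$rows[["C"]], 10, 11), "EN")
  expect_equal(substr(cc$rows[["A"]], 10, 11), "YN")
  # single block -> identity
  one <- concatenate_blocks(list(b1))
  expect_equal(one$rows, b1$rows)
  # taxon mismatch errors with the offending name
  b3 <- alignment_block(c(A = "MK", B = "MK", D = "MK"))
  expect_error(concatenate_blocks(list(b1, b3)), "D")
})

test_that("relative-rate counts match the brute-force site classifier", {
  # 12-column toy with hand-classified patterns
  blk <- alignment_block(c(
    in1 = "AAAACDEFGH-K",
    in2 = "AAQACDEFGYWK",
    out = "AAQACDXFGYWK"), alphabet = "aa")
  r <- tajima_rrt(blk, "in1", "in2", "out")
  o <- oracle_rrt_counts(blk$rows[["in1"]], blk$rows[["in2"]],
                         blk$rows[["out"]], aa_resolved)
  expect_equal(r$m1, o$m1)
  expect_equal(r$m2, o$m2)
  expect_equal(r$n_used, o$n_used)
  # columns with X or gap never enter
  expect_equal(r$n_used, 10L)
  # chi2 and p from the closed form
  expect_equal(r$chi2, (r$m1 - r$m2)^2 / (r$m1 + r$m2))
  expect_equal(r$p, pchisq(r$chi2, 1, lower.tail = FALSE))

  # identical rows: no signal, p 1
  same <- alignment_block(c(a = "MKV", b = "MKV", c = "MKV"))
  rs <- tajima_rrt(same, "a", "b", "c")
  expect_equal(c(rs$m1, rs$m2, rs$chi2, rs$p), c(0, 0, 0, 1))

  # swapping ingroup labels swaps m1/m2 and preserves chi2, p
  rsw <- tajima_rrt(blk, "in2", "in1", "out")
  expect_equal(rsw$m1, r$m2)
  expect_equal(rsw$m2, r$m1)
  expect_equal(rsw$chi2, r$chi2)
  expect_equal(rsw$p, r$p)

  expect_error(tajima_rrt(blk, "in1", "nope", "out"), "nope")
})

test_that("relative-rate counts agree with the oracle on simulated alignments", {
  tree <- ape::read.tree(text = "(A:0.05,B:0.05,C:0.2);")
  for (s in c(3, 14)) {
    blk <- evolve_alignment(tree, 2000, seed = s,
                            rate_multipliers = c(A = 2))
    r <- tajima_rrt(blk, "A", "B", "C")
    o <- oracle_rrt_counts(blk$rows[["A"]], blk$rows[["B"]],
                           blk$rows[["C"]], aa_resolved)
    expect_equal(r$m1, o$m1)
    expect_equal(r$m2, o$m2)
  }
})

test_that("the relative-rate report covers every triple with a significance mark", {
  tree <- ape::read.tree(text = "((F:0.05,X:0.05):0.02,(Y:0.05,O1:0.1):0.02);")
  blk <- evolve_alignment(tree, 3000, seed = 5,
                          rate_multipliers = c(F = 4))
  tab <- rrt_table(blk, "F", c("X", "Y"), "O1")
  expect_equal(nrow(tab), 2L)
  expect_true(all(tab$significant))
  expect_true(all(tab$m1 > tab$m2))
})

test_that("counting Ka/Ks classifies substitutions like the path oracle", {
  # identical sequences
  k0 <- kaks_counting("GGGAAACCC", "GGGAAACCC")
  expect_equal(c(k0$ka, k0$ks), c(0, 0))
  expect_true(is.na(k0$omega))

  # one synonymous third-position change
  k1 <- kaks_counting("GGGAAACCCTTTGAT", "GGAAAACCCTTTGAT")
  expect_equal(k1$ka, 0)
  expect_gt(k1$ks, 0)

  # codon differing at two positions: path averaging vs explicit orders
  k2 <- kaks_counting("TTTAAAGGG", "GTAAAAGGG")
  o1 <- oracle_codon_paths("TTT", "GTA")
  expect_equal(k2$Sd, unname(o1[1]))
  expect_equal(k2$Nd, unname(o1[2]))

  # symmetric in the sequence order
  k3 <- kaks_counting("GTAAAAGGG", "TTTAAAGGG")
  expect_equal(k2$ka, k3$ka)
  expect_equal(k2$ks, k3$ks)

  # consistency: total classified differences equal nucleotide differences
  a <- "ATGGCTAGCGATCGATTTAAACCC"; b <- "ATGGCAAGCGTTCGCTTTAGACCC"
  k4 <- kaks_counting(a, b)
  ndiff <- sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_equal(k4$Sd + k4$Nd, ndiff)

  expect_error(kaks_counting("ATGTAAAAA", "ATGTACAAA"), "codon 2")
  expect_error(kaks_counting("ATGC", "ATGC"), "divisible by 3")
})

test_that("motif scanning counts overlapping windows", {
  m11 <- count_motif(strrep("CNPAADPAC", 11))
  expect_equal(m11$count, 11L)
  expect_equal(m11$positions, seq(1, 91, by = 9))

  expect_equal(count_motif("CDPQQDPLC")$count, 1L)
  expect_equal(count_motif("CQPQQDPLC")$count, 0L)

  # engineered overlap: matches at 1 and 5, both counted
  s <- "CNPACDPACDPAC"
  m <- count_motif(s)
  expect_equal(m$positions, oracle_motif_count(s))
  expect_equal(m$count, 2L)
})
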