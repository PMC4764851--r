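cand <- function(id, len, hit = FALSE, doms = list(character(0))) {
  data.frame(id = id, length = len, proteome_hit = hit,
             domains = I(doms), stringsAsFactors = FALSE)
}

test_that("repeat-library filtering applies the three rules with re-inclusion", {
  wl <- c("IPR000477", "IPR023109")
  # proteome hit but a whitelisted (reverse transcriptase) domain -> retained
  a <- cand("a", 500, hit = TRUE, doms = list("IPR000477"))
  expect_equal(filter_repeat_library(a, wl)$retained_by, "te_domain")
  # proteome hit, no domains -> removed
  b <- cand("b", 500, hit = TRUE)
  expect_equal(nrow(filter_repeat_library(b, wl)), 0L)
  # non-TE domain -> removed; clean candidate -> retained
  c_ <- cand("c", 500, doms = list("IPR999999"))
  expect_equal(nrow(filter_repeat_library(c_, wl)), 0L)
  d <- cand("d", 500)
  expect_equal(filter_repeat_library(d, wl)$retained_by, "clean")
  # length exactly at the bound is removed (strictly longer than 100 nt)
  e <- cand("e", 100)
  expect_equal(nrow(filter_repeat_library(e, wl)), 0L)
  expect_equal(nrow(filter_repeat_library(cand("f", 101), wl)), 1L)
})

test_that("library filtering is monotone in its parameters", {
  set.seed(55)
  n <- 60
  lib <- data.frame(
    id = sprintf("r%02d", 1:n),
    length = sample(50:400, n, replace = TRUE),
    proteome_hit = runif(n) < 0.4,
    domains = I(lapply(1:n, function(i)
      sample(c("IPR000477", "IPR999999", "IPR888888"),
             sample(0:2, 1)))),
    stringsAsFactors = FALSE)
  wl_small <- "IPR000477"
  wl_big <- c("IPR000477", "IPR999999")
  k100 <- filter_repeat_library(lib, wl_small, min_length = 100)$id
  k200 <- filter_repeat_library(lib, wl_small, min_length = 200)$id
  expect_true(all(k200 %in% k100))
  kbig <- filter_repeat_library(lib, wl_big, min_length = 100)$id
  expect_true(all(k100 %in% kbig))
})

test_that("repeat summaries merge same-class overlaps and count elements raw", {
  hits <- data.frame(query_id = c("tx1", "tx1"), begin = c(1L, 1L),
                     end = c(100L, 100L), repeat_name = c("r1", "r1"),
                     repeat_class = c("LINE", "LINE"),
                     subfamily = c("L2", "L2"),
                     divergence_pct = c(1, 2), score = c(500, 400),
                     stringsAsFactors = FALSE)
  s <- summarize_repeat_hits(hits, scanned_bp = 10000,
                             transcript_lengths = c(tx1 = 500))
  cls <- s$per_class[s$per_class$subfamily == "", ]
  expect_equal(cls$n_elements, 2L)
  expect_equal(cls$bp, 100L)
  expect_equal(s$masked_bp, 100L)
  expect_equal(cls$pct, 1.00)

  # empty input -> zeros
  s0 <- summarize_repeat_hits(hits[0, ], scanned_bp = 100)
  expect_equal(s0$masked_bp, 0L)
  expect_equal(nrow(s0$per_class), 0L)

  # unknown transcript / overlong hit are errors
  expect_error(summarize_repeat_hits(hits, 1000,
                                     transcript_lengths = c(zz = 10)),
               "unknown")
  expect_error(summarize_repeat_hits(hits, 1000,
                                     transcript_lengths = c(tx1 = 50)),
               "beyond")
})

test_that("cross-class overlaps resolve to the higher score and conserve masked bp", {
  hits <- data.frame(
    query_id = c("tx1", "tx1", "tx2"),
    begin = c(1L, 51L, 10L), end = c(100L, 150L, 40L),
    repeat_name = c("r1", "r2", "r3"),
    repeat_class = c("LINE", "DNA", "SINE"),
    subfamily = "", divergence_pct = 0,
    score = c(900, 300, 100), stringsAsFactors = FALSE)
  s <- summarize_repeat_hits(hits, scanned_bp = 1e4)
  # union on tx1 is 1..150 plus 31 bp on tx2
  expect_equal(s$masked_bp, 181L)
  # overlap 51..100 goes to the higher-scoring LINE
  expect_equal(unname(s$class_bp_resolved["LINE"]), 100)
  expect_equal(unname(s$class_bp_resolved["DNA"]), 50)
  expect_equal(sum(s$class_bp_resolved), s$masked_bp)
  # plain per-class totals keep each class's own intervals
  pc <- s$per_class
  expect_equal(pc$bp[pc$class == "DNA"], 100L)
  expect_true(s$masked_bp <= 1e4)
})

test_that("summaries from simulated transcriptomes conserve masked bases", {
  cfg <- sim_config(n_transcripts = 400, seed = 23)
  tr <- simulate_transcriptome(cfg)
  scanned <- sum(tr$truth$length)
  s <- summarize_repeat_hits(tr$repeat_hits, scanned,
                             setNames(tr$truth$length,
                                      tr$truth$transcript_id))
  expect_equal(sum(s$class_bp_resolved), s$masked_bp)
  expect_lte(s$masked_bp, scanned)
  # per-class bp equals the planted interval total (one TE per transcript,
  # no overlaps by construction)
  tt <- tr$truth[tr$truth$te_class != "none", ]
  planted <- tapply(tt$te_end - tt$te_begin + 1, tt$te_class, sum)
  cls <- s$per_class[s$per_class$subfamily == "", ]
  expect_equal(cls$bp[match(names(planted), cls$class)],
               as.integer(planted))
})

test_that("calibrated TE activity follows the reduced-transcriptome arithmetic", {
  counts <- matrix(c(100, 200, 50,
                     400, 800, 200), 3, 2,
                   dimnames = list(c("cal1", "cal2", "te1"),
                                   c("s1", "s2")))
  lens <- c(cal1 = 1000, cal2 = 2000, te1 = 500)
  # all three at equal per-base rate r per sample -> activity 1e6*r/(2r)
  act <- calibrated_te_activity(counts, lens, c(te1 = "LINE"),
                                c("cal1", "cal2"))
  expect_equal(as.numeric(act$per_class["LINE", ]), c(5e5, 5e5))
  # scale invariance: doubling a sample's counts changes nothing
  act2 <- calibrated_te_activity(cbind(counts[, 1] * 2, counts[, 2]),
                                 lens, c(te1 = "LINE"), c("cal1", "cal2"))
  expect_equal(unname(act2$per_class[1, 1]), unname(act$per_class[1, 1]))
  # zero-count TE contributes zero
  counts2 <- rbind(counts, te2 = c(0, 0))
  act3 <- calibrated_te_activity(counts2, c(lens, te2 = 300),
                                 c(te1 = "LINE", te2 = "LINE"),
                                 c("cal1", "cal2"))
  expect_equal(act3$per_class["LINE", ], act$per_class["LINE", ])
  # calibration genes absent or overlapping the TE set are errors
  expect_error(calibrated_te_activity(counts, lens, c(te1 = "LINE"),
                                      c("cal1", "nope")), "absent")
  expect_error(calibrated_te_activity(counts, lens, c(cal1 = "LINE"),
                                      c("cal1", "cal2")), "disjoint")
  # silent calibration set is an error naming the sample
  counts3 <- counts; counts3[c("cal1", "cal2"), 2] <- 0
  expect_error(calibrated_te_activity(counts3, lens, c(te1 = "LINE"),
                                      c("cal1", "cal2")), "s2")
})

test_that("the summary writer reproduces totals and rounded percentages", {
  per_class <- data.frame(
    class = c("SINE", "LINE", "LINE", "LTR", "DNA", "SmallRNA"),
    subfamily = c("", "", "L2", "", "", ""),
    n_elements = c(10L, 20L, 15L, 5L, 8L, 2L),
    bp = c(1000L, 3000L, 2200L, 500L, 1200L, 90L),
    stringsAsFactors = FALSE)
  tab <- repeat_summary_table(per_class, scanned_bp = 100000,
                              masked_bp = 5600)
  expect_equal(tab$bp[tab$row == "Retroelements"], 4500)
  expect_equal(tab$n_elements[tab$row == "Retroelements"], 35L)
  expect_equal(tab$bp[tab$row == "Total interspersed repeats:"], 5700)
  expect_equal(tab$pct[tab$row == "Retroelements"], 4.50)
  expect_equal(tab$pct[tab$row == "  L2"], 2.20)
  expect_equal(attr(tab, "masked_pct"), 5.60)
})

test_that("half-up rounding follows table conventions", {
  expect_equal(round_half_up(0.005, 2), 0.01)
  expect_equal(round_half_up(2.4678, 2), 2.47)
  expect_equal(round_half_up(1.005, 2), 1.01)
  expect_equal(round_half_up(-0.005, 2), -0.01)
})
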