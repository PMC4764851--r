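#' Transcripts-per-million expression matrix
#'
#' Per sample, each transcript's count is divided by its effective length
#' (per-base read rate), and rates are rescaled to sum to one million, so
#' values are proportional to relative molar RNA concentration and
#' comparable across libraries of different depth.
#'
#' @param counts integer matrix, transcripts x samples.
#' @param lengths effective transcript lengths (nt), recycled by name or
#'   position.
#' @return numeric matrix of TPM values; columns sum to 1e6.
#' @export
compute_tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts))
    stop("need one effective length per transcript")
  if (any(lengths <= 0)) stop("effective lengths must be positive")
  zero <- colSums(counts) == 0
  if (any(zero))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[zero], collapse = ", "))
  rate <- counts / as.numeric(lengths)
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

.group_weighted_proportion <- function(y, n) {
  # weighted proportion with method-of-moments between-library variance
  p_i <- y / n
  w <- n / sum(n)
  p_hat <- sum(w * p_i)
  k <- length(y)
  if (k == 1) {
    return(list(p = p_hat, var = p_hat * (1 - p_hat) / n, k = 1L))
  }
  binom_part <- p_hat * (1 - p_hat) * sum(w * (1 - w) / n)
  s2_b <- max(0, (sum(w * (p_i - p_hat)^2) - binom_part) / (1 - sum(w^2)))
  v <- p_hat * (1 - p_hat) / sum(n) + s2_b * sum(w^2)
  list(p = p_hat, var = v, k = k, s2_b = s2_b,
       binom = p_hat * (1 - p_hat) / sum(n), w2 = sum(w^2))
}

#' Beta-binomial weighted-proportions test for one transcript
#'
#' Two-group test on count proportions in the spirit of the SAGE
#' beta-binomial proportions test: per group, libraries are combined into a
#' depth-weighted proportion whose variance adds the within-library
#' binomial component and a method-of-moments estimate of between-library
#' (beta-binomial) overdispersion, pooled across the two groups (the model
#' assumes a common overdispersion). The statistic is the difference of
#' weighted proportions over the pooled standard error. With one library
#' per group the test degenerates exactly to the unpooled two-proportion
#' z-test; with replicates, a t reference with Satterthwaite-style degrees
#' of freedom is used, in which only the estimated overdispersion
#' component (not the known binomial part) consumes degrees of freedom.
#'
#' @param y1,y2 per-sample counts of the transcript in groups 1 and 2.
#' @param n1,n2 per-sample library sizes.
#' @return list with `statistic`, `p` (two-sided), per-group weighted
#'   proportions `p1`, `p2`, `df` (Inf for the normal reference), and
#'   `flagged` (TRUE when the transcript is absent from both groups and
#'   p = 1 is returned by convention).
#' @export
baggerly_proportions_test <- function(y1, n1, y2, n2) {
  stopifnot(length(y1) == length(n1), length(y2) == length(n2),
            length(y1) >= 1, length(y2) >= 1,
            all(n1 > 0), all(n2 > 0), all(y1 >= 0), all(y2 >= 0))
  if (sum(y1) == 0 && sum(y2) == 0)
    return(list(statistic = 0, p = 1, p1 = 0, p2 = 0, df = Inf,
                flagged = TRUE))
  g1 <- .group_weighted_proportion(y1, n1)
  g2 <- .group_weighted_proportion(y2, n2)
  if (g1$k == 1 || g2$k == 1) {
    se2 <- g1$var + g2$var
    stat <- if (se2 > 0) (g1$p - g2$p) / sqrt(se2) else 0
    p <- 2 * stats::pnorm(abs(stat), lower.tail = FALSE)
    df <- Inf
  } else {
    # the beta-binomial model assumes one common overdispersion, so the
    # between-library variance is pooled across groups; the binomial
    # component is known, so only the pooled estimate (k1 + k2 - 2 df)
    # enters the Satterthwaite combination
    df0 <- g1$k + g2$k - 2
    s2p <- ((g1$k - 1) * g1$s2_b + (g2$k - 1) * g2$s2_b) / df0
    v1 <- g1$binom + s2p * g1$w2
    v2 <- g2$binom + s2p * g2$w2
    se2 <- v1 + v2
    stat <- if (se2 > 0) (g1$p - g2$p) / sqrt(se2) else 0
    u <- s2p * (g1$w2 + g2$w2)
    df <- if (u > 0) se2^2 * df0 / u^2 else Inf
    p <- if (is.finite(df)) 2 * pt(abs(stat), df = df, lower.tail = FALSE)
         else 2 * stats::pnorm(abs(stat), lower.tail = FALSE)
  }
  list(statistic = stat, p = min(1, p), p1 = g1$p, p2 = g2$p, df = df,
       flagged = FALSE)
}

#' Differential expression over a count matrix
#'
#' Applies the weighted-proportions test to every transcript passing a
#' reliability filter (total count across all samples of at least
#' `min_total_count`; only that subset enters the Bonferroni correction),
#' computes the signed fold change of weighted proportions with a
#' pseudo-proportion floor of 1/(total library size) guarding zeros, and
#' flags transcripts meeting both the fold-change and the corrected
#' p-value criterion.
#'
#' @param counts transcripts x samples count matrix.
#' @param groups character vector assigning each column to a group.
#' @param g1,g2 the two group labels to contrast.
#' @param fc_min minimum |fold change| (default 2).
#' @param alpha Bonferroni-corrected p-value cutoff (default 0.01).
#' @param min_total_count reliability filter defining the tested universe.
#' @param library_sizes optional per-sample sizes; defaults to column sums.
#' @return data.frame with one row per transcript: weighted proportions,
#'   signed `fold_change`, `statistic`, `p_raw`, `p_bonferroni`, `tested`,
#'   `floored` (pseudo-proportion used), and `de` (passes both criteria).
#' @export
run_differential_expression <- function(counts, groups, g1, g2,
                                        fc_min = 2, alpha = 0.01,
                                        min_total_count = 10,
                                        library_sizes = NULL) {
  counts <- as.matrix(counts)
  stopifnot(length(groups) == ncol(counts))
  i1 <- which(groups == g1); i2 <- which(groups == g2)
  if (!length(i1) || !length(i2)) stop("both groups must be present")
  if (length(intersect(i1, i2))) stop("groups must be disjoint")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  n1 <- library_sizes[i1]; n2 <- library_sizes[i2]
  floor_p <- 1 / sum(c(n1, n2))
  tested <- rowSums(counts) >= min_total_count
  n_tests <- sum(tested)
  res <- data.frame(transcript_id = rownames(counts),
                    p1 = NA_real_, p2 = NA_real_,
                    fold_change = NA_real_, statistic = NA_real_,
                    p_raw = NA_real_, p_bonferroni = NA_real_,
                    tested = tested, floored = FALSE, de = FALSE,
                    stringsAsFactors = FALSE)
  for (g in which(tested)) {
    t_ <- baggerly_proportions_test(counts[g, i1], n1, counts[g, i2], n2)
    f1 <- max(t_$p1, floor_p); f2 <- max(t_$p2, floor_p)
    fc <- if (f1 >= f2) f1 / f2 else -f2 / f1
    res$p1[g] <- t_$p1; res$p2[g] <- t_$p2
    res$fold_change[g] <- fc
    res$statistic[g] <- t_$statistic
    res$p_raw[g] <- t_$p
    res$p_bonferroni[g] <- min(1, t_$p * n_tests)
    res$floored[g] <- t_$p1 < floor_p || t_$p2 < floor_p
  }
  res$de <- res$tested & !is.na(res$p_bonferroni) &
    abs(res$fold_change) >= fc_min & res$p_bonferroni < alpha
  attr(res, "n_tests") <- n_tests
  res
}

#' Hypergeometric over-representation of annotation terms
#'
#' Upper-tail hypergeometric test per term: the probability of observing at
#' least the seen number of annotated items in the flagged draw, given the
#' term's prevalence in the universe. A term is called over-represented
#' when p < `p_max` and the observed count strictly exceeds
#' `min_observed`.
#'
#' @param flagged character vector of flagged item ids (subset of
#'   `universe`).
#' @param universe character vector of all tested item ids.
#' @param annotation named list: term id -> character vector of item ids,
#'   or a two-column data.frame (item, term).
#' @param p_max significance cutoff (default 1e-5).
#' @param min_observed strict lower bound on observed matches (default 5).
#' @return data.frame per term: `observed`, `universe_annotated`, `drawn`,
#'   `universe`, `p_hypergeom`, `over_represented`; terms annotating
#'   nothing in the universe are skipped.
#' @export
hypergeometric_enrichment <- function(flagged, universe, annotation,
                                      p_max = 1e-5, min_observed = 5) {
  if (!all(flagged %in% universe))
    stop("flagged items must be a subset of the universe")
  if (is.data.frame(annotation))
    annotation <- split(annotation[[1]], annotation[[2]])
  N <- length(universe); k <- length(flagged)
  rows <- lapply(names(annotation), function(term) {
    ann <- intersect(annotation[[term]], universe)
    m <- length(ann)
    if (m == 0) return(NULL)
    q <- length(intersect(ann, flagged))
    p <- phyper(q - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(term = term, observed = q, universe_annotated = m,
               drawn = k, universe = N, p_hypergeom = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(), observed = integer(),
                      universe_annotated = integer(), drawn = integer(),
                      universe = integer(), p_hypergeom = numeric(),
                      over_represented = logical()))
  out$over_represented <- out$p_hypergeom < p_max &
    out$observed > min_observed
  out[order(out$p_hypergeom), , drop = FALSE]
}

#' Bootstrap-supported average-linkage clustering of samples
#'
#' Clusters samples by average linkage on the dissimilarity
#' d = 1 - Pearson correlation of square-root-transformed expression, and
#' attaches to each internal node the percentage of gene-resampled
#' bootstrap trees containing that node's sample bipartition (ordinary
#' bootstrap probability).
#'
#' @param expr expression matrix (e.g. TPM), genes x samples.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @return list with `hclust` (the reference clustering), `tree` (an
#'   `ape::phylo` whose node labels are support percentages), and
#'   `support` (numeric vector over internal nodes, 0-100).
#' @export
bootstrap_average_linkage <- function(expr, n_boot = 1000, seed = 1L) {
  expr <- as.matrix(expr)
  if (ncol(expr) < 3) stop("need at least 3 samples to cluster")
  x <- sqrt(expr)
  sds <- apply(x, 2, sd)
  if (any(sds == 0))
    stop("constant expression vector (undefined correlation) in sample(s): ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  hc <- hclust(as.dist(1 - cor(x)), method = "average")
  ref <- ape::as.phylo(hc)
  set.seed(seed)
  boots <- vector("list", n_boot)
  b <- 1L
  guard <- 0L
  while (b <= n_boot) {
    idx <- sample.int(nrow(x), replace = TRUE)
    xb <- x[idx, , drop = FALSE]
    cb <- suppressWarnings(cor(xb))
    if (anyNA(cb)) {
      guard <- guard + 1L
      if (guard > 100 * n_boot) stop("bootstrap resamples degenerate")
      next
    }
    boots[[b]] <- ape::as.phylo(hclust(as.dist(1 - cb),
                                       method = "average"))
    b <- b + 1L
  }
  cnt <- ape::prop.clades(ref, boots, rooted = TRUE)
  cnt[is.na(cnt)] <- 0
  support <- 100 * cnt / n_boot
  ref$node.label <- formatC(support, format = "f", digits = 1)
  list(hclust = hc, tree = ref, support = support)
}
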