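#' Global pairwise amino-acid identity
#'
#' Identity on a Needleman-Wunsch global alignment, defined as matches over
#' alignment columns (internal and terminal gap columns included in the
#' denominator).
#'
#' @param a,b amino-acid sequences (character or AAString).
#' @return identity in [0, 1].
#' @export
pairwise_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(as.character(a)),
    Biostrings::AAString(as.character(b)),
    type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  pa <- as.character(Biostrings::alignedPattern(aln))
  ps <- as.character(Biostrings::alignedSubject(aln))
  va <- strsplit(pa, "")[[1]]; vs <- strsplit(ps, "")[[1]]
  sum(va == vs & va != "-") / length(va)
}

#' Greedy redundancy reduction of a protein set
#'
#' Longest-first greedy clustering: sequences are visited in decreasing
#' length order; each joins the first existing representative it matches at
#' a global identity of at least `identity_min`, otherwise it founds a new
#' cluster. Only representatives are returned. Used to strip splice
#' variants, allelic polymorphisms, and near-identical assembly artifacts
#' before counting gene-family members.
#'
#' @param proteins named character vector or `AAStringSet`.
#' @param identity_min identity threshold in [0, 1] (default 0.75).
#' @return character vector of representative ids (longest member of each
#'   cluster), with the cluster assignment as an attribute.
#' @export
cluster_reduce <- function(proteins, identity_min = 0.75) {
  if (methods::is(proteins, "XStringSet"))
    proteins <- setNames(as.character(proteins), names(proteins))
  if (!length(proteins)) return(character(0))
  stopifnot(!is.null(names(proteins)))
  ord <- order(-nchar(proteins), names(proteins))
  reps <- character(0)
  assignment <- setNames(character(length(proteins)), names(proteins)[ord])
  for (id in names(proteins)[ord]) {
    placed <- FALSE
    for (r in reps) {
      if (pairwise_identity(proteins[[id]], proteins[[r]]) >= identity_min) {
        assignment[id] <- r; placed <- TRUE; break
      }
    }
    if (!placed) { reps <- c(reps, id); assignment[id] <- id }
  }
  structure(reps, clusters = assignment)
}

#' One-sided Grubbs outlier test for an a-priori focal value
#'
#' Tests whether the focal species' count is an upper outlier relative to
#' reference species. The statistic is G = (focal - mean) / sd over the
#' pooled sample including the focal value (classic Grubbs pooling). Since
#' the focal observation is chosen a priori (not scanned for), the
#' one-sided p-value is the exact per-observation tail
#' P(T_{N-2} >= t) with t = sqrt(N (N-2) G^2 / ((N-1)^2 - N G^2)); the
#' reported critical value is the matching closed form
#' ((N-1)/sqrt(N)) * sqrt(t_a^2 / (N-2 + t_a^2)) at the upper-alpha t
#' quantile, so G > critical iff p < alpha. The call is one-sided upper:
#' a focal value that is not the sample maximum is never flagged.
#'
#' @param focal the focal species' count.
#' @param references counts in the reference species (length >= 2).
#' @param alpha significance level (default 0.05).
#' @return list with `G`, `critical`, `p_one_sided`, `expanded`, and
#'   `untestable` (TRUE when the pooled sd is 0, in which case
#'   `expanded` is FALSE and p is NA).
#' @export
grubbs_one_sided <- function(focal, references, alpha = 0.05) {
  x <- c(focal, references)
  N <- length(x)
  if (N < 3) stop("Grubbs test needs at least 3 values in total")
  s <- sd(x)
  if (s == 0)
    return(list(G = NA_real_, critical = NA_real_, p_one_sided = NA_real_,
                expanded = FALSE, untestable = TRUE))
  G <- (focal - mean(x)) / s
  crit_t <- qt(alpha, df = N - 2, lower.tail = FALSE)
  critical <- (N - 1) / sqrt(N) * sqrt(crit_t^2 / (N - 2 + crit_t^2))
  if (N * G^2 >= (N - 1)^2) {
    p <- if (G > 0) 0 else 1
  } else {
    t_stat <- sign(G) * sqrt(N * (N - 2) * G^2 / ((N - 1)^2 - N * G^2))
    p <- pt(t_stat, df = N - 2, lower.tail = FALSE)
  }
  list(G = G, critical = critical, p_one_sided = p,
       expanded = (focal == max(x)) && !is.na(p) && p < alpha,
       untestable = FALSE)
}

#' Scan a domain-count table for focal-species expansions
#'
#' Every domain annotated in at least `min_focal_count` focal-species
#' sequences is tested against each reference group independently with the
#' one-sided Grubbs test; domains significant against every group are
#' reported as the intersection. No multiple-testing correction is applied
#' across domains (the number of domains tested is reported alongside as a
#' caveat).
#'
#' @param table matrix or data.frame, domains x species.
#' @param focal name of the focal species column.
#' @param reference_groups named list: group label -> character vector of
#'   reference species columns (each of length >= 2).
#' @param min_focal_count inclusion threshold on the focal count
#'   (default 20).
#' @param alpha per-test significance level (default 0.05).
#' @return list with `results` (long data.frame: domain, group, focal
#'   count, group mean, G, p, expanded), `expanded_by_group` (list of
#'   domain id vectors), `intersection`, and `n_tested`.
#' @export
scan_expansions <- function(table, focal, reference_groups,
                            min_focal_count = 20, alpha = 0.05) {
  table <- as.matrix(table)
  stopifnot(focal %in% colnames(table))
  if (any(lengths(reference_groups) < 2))
    stop("each reference group needs at least 2 species")
  miss <- setdiff(unlist(reference_groups), colnames(table))
  if (length(miss))
    stop("reference species missing from the table: ",
         paste(miss, collapse = ", "))
  # order-invariant: iterate domains by sorted id
  doms <- sort(rownames(table))
  tested <- doms[table[doms, focal] >= min_focal_count]
  rows <- list()
  for (d in tested) {
    for (grp in names(reference_groups)) {
      refs <- as.numeric(table[d, reference_groups[[grp]]])
      g <- grubbs_one_sided(as.numeric(table[d, focal]), refs,
                            alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        domain = d, group = grp, focal_count = table[d, focal],
        reference_mean = mean(refs), G = g$G, p_one_sided = g$p_one_sided,
        expanded = g$expanded, untestable = g$untestable,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(rows)) do.call(rbind, rows) else
    data.frame(domain = character(), group = character(),
               focal_count = numeric(), reference_mean = numeric(),
               G = numeric(), p_one_sided = numeric(),
               expanded = logical(), untestable = logical())
  by_group <- lapply(names(reference_groups), function(grp)
    res$domain[res$group == grp & res$expanded])
  names(by_group) <- names(reference_groups)
  list(results = res, expanded_by_group = by_group,
       intersection = Reduce(intersect, by_group),
       n_tested = length(tested))
}
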