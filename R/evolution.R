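.best_hits_strict <- function(hits, e_max) {
  # best subject per query at e <= e_max; flags ties (equal e-value AND
  # equal bitscore at the top) which disqualify 1:1 orthology
  h <- hits[hits$e_value <= e_max, , drop = FALSE]
  if (!nrow(h))
    return(data.frame(query_id = character(), subject_id = character(),
                      tied = logical()))
  o <- order(h$query_id, h$e_value, -h$bitscore, h$subject_id)
  h <- h[o, , drop = FALSE]
  first <- !duplicated(h$query_id)
  best <- h[first, , drop = FALSE]
  # a tie exists when the runner-up hit matches the best e-value & bitscore
  idx <- which(first)
  nxt <- idx + 1L
  has_next <- nxt <= nrow(h) & h$query_id[pmin(nxt, nrow(h))] == h$query_id[idx]
  tied <- has_next &
    h$e_value[pmin(nxt, nrow(h))] == best$e_value &
    h$bitscore[pmin(nxt, nrow(h))] == best$bitscore &
    h$subject_id[pmin(nxt, nrow(h))] != best$subject_id
  data.frame(query_id = best$query_id, subject_id = best$subject_id,
             tied = tied, stringsAsFactors = FALSE)
}

#' Select 1:1 orthologs across species via an anchor
#'
#' From reciprocal best-hit tables between an anchor species and every
#' other species, keeps the anchor genes that have exactly one reciprocal
#' best-hit partner in every species at the strict e-value cutoff. Genes
#' with tied co-orthologs (equal best e-value and bit score) in any species
#' are excluded: the orthology must be unambiguously 1:1.
#'
#' @param hit_tables named list, one entry per non-anchor species, each a
#'   list with elements `ab` (anchor -> species hit table) and `ba` (the
#'   reciprocal), in [read_hit_table()] layout.
#' @param e_max e-value cutoff (default 1e-50).
#' @return data.frame with one row per selected anchor gene and one column
#'   per species giving the orthologous member id.
#' @export
select_121_orthologs <- function(hit_tables, e_max = 1e-50) {
  if (!length(hit_tables) || is.null(names(hit_tables)))
    stop("supply a named list of per-species hit-table pairs")
  per_species <- lapply(names(hit_tables), function(sp) {
    tabs <- hit_tables[[sp]]
    if (is.null(tabs$ab) || is.null(tabs$ba))
      stop("missing hit table (ab/ba) for species: ", sp)
    fwd <- .best_hits_strict(tabs$ab, e_max)
    rev <- .best_hits_strict(tabs$ba, e_max)
    fwd_ok <- fwd[!fwd$tied, , drop = FALSE]
    rev_ok <- rev[!rev$tied, , drop = FALSE]
    back <- setNames(rev_ok$subject_id, rev_ok$query_id)
    keep <- !is.na(back[fwd_ok$subject_id]) &
      back[fwd_ok$subject_id] == fwd_ok$query_id
    setNames(fwd_ok$subject_id[keep], fwd_ok$query_id[keep])
  })
  names(per_species) <- names(hit_tables)
  genes <- Reduce(intersect, lapply(per_species, names))
  genes <- sort(genes)
  out <- data.frame(anchor = genes, stringsAsFactors = FALSE)
  for (sp in names(per_species))
    out[[sp]] <- unname(per_species[[sp]][genes])
  out
}

.ambiguous_aa <- c("-", ".", "*", "X", "B", "Z", "J", "U", "O")
.is_resolved <- function(chars, alphabet) {
  if (alphabet == "aa") !(chars %in% .ambiguous_aa)
  else chars %in% c("A", "C", "G", "T")
}

.block_matrix <- function(block)
  do.call(rbind, strsplit(toupper(block$rows), ""))

#' Remove alignment columns with gaps or ambiguous positions
#'
#' Drops every column whose fraction of gap/ambiguity characters exceeds
#' `max_gap_fraction` (the default 0 removes any column with a single
#' missing position) and re-indexes the partition map. This emulates the
#' missing-position cleanup applied to per-gene alignments before
#' concatenation; divergence-based block heuristics are deliberately not
#' reimplemented.
#'
#' @param block an [alignment_block()].
#' @param max_gap_fraction maximum tolerated gap/ambiguity fraction per
#'   column (default 0).
#' @return a filtered [alignment_block()]; when everything is removed, an
#'   empty block with attribute `flagged = TRUE`.
#' @export
filter_columns <- function(block, max_gap_fraction = 0) {
  stopifnot(inherits(block, "alignment_block"))
  m <- .block_matrix(block)
  resolved <- matrix(.is_resolved(as.vector(m), block$alphabet), nrow(m))
  bad_frac <- colMeans(!resolved)
  keep <- bad_frac <= max_gap_fraction
  if (!any(keep)) {
    empty <- alignment_block(setNames(rep("", length(block$rows)),
                                      names(block$rows)),
                             partition = block$partition[0, , drop = FALSE],
                             alphabet = block$alphabet)
    attr(empty, "flagged") <- TRUE
    return(empty)
  }
  rows <- apply(m[, keep, drop = FALSE], 1, paste, collapse = "")
  names(rows) <- names(block$rows)
  cum <- cumsum(keep)
  parts <- block$partition
  new_parts <- lapply(seq_len(nrow(parts)), function(i) {
    kept_in <- sum(keep[parts$start[i]:parts$end[i]])
    if (kept_in == 0) return(NULL)
    end_new <- cum[parts$end[i]]
    data.frame(gene = parts$gene[i], start = end_new - kept_in + 1L,
               end = end_new, stringsAsFactors = FALSE)
  })
  new_parts <- do.call(rbind, new_parts)
  if (is.null(new_parts))
    new_parts <- parts[0, , drop = FALSE]
  alignment_block(rows, partition = new_parts, alphabet = block$alphabet)
}

#' Concatenate per-gene alignment blocks into a supermatrix
#'
#' Joins blocks column-wise in input order, matching rows by taxon name
#' (row order within blocks is irrelevant). The partition map records each
#' gene's column interval in the concatenated alignment.
#'
#' @param blocks list of [alignment_block()]s over an identical taxon set.
#' @return one [alignment_block()].
#' @export
concatenate_blocks <- function(blocks) {
  stopifnot(length(blocks) >= 1)
  taxa <- sort(names(blocks[[1]]$rows))
  for (b in blocks) {
    this <- sort(names(b$rows))
    d <- c(setdiff(taxa, this), setdiff(this, taxa))
    if (length(d))
      stop("taxon set mismatch across blocks: ", paste(d, collapse = ", "))
  }
  taxa <- names(blocks[[1]]$rows)
  rows <- vapply(taxa, function(tx)
    paste(vapply(blocks, function(b) unname(b$rows[tx]), character(1)),
          collapse = ""), character(1))
  offset <- 0L
  parts <- list()
  for (k in seq_along(blocks)) {
    p <- blocks[[k]]$partition
    if (nrow(p)) {
      p$start <- p$start + offset; p$end <- p$end + offset
      parts[[length(parts) + 1L]] <- p
    }
    offset <- offset + nchar(blocks[[k]]$rows[[1]])
  }
  parts <- do.call(rbind, parts)
  if (anyDuplicated(parts$gene))
    parts$gene <- make.unique(parts$gene)
  alignment_block(rows, partition = parts,
                  alphabet = blocks[[1]]$alphabet)
}

#' Tajima's relative rate test on a three-taxon alignment
#'
#' Compares the number of sites where each ingroup alone differs (the
#' other ingroup agreeing with the outgroup) — under equal rates these two
#' counts have equal expectation, so chi2 = (m1 - m2)^2 / (m1 + m2) is
#' referred to a chi-square with 1 df. Sites carrying a gap or ambiguity
#' character in any of the three rows are excluded.
#'
#' @param block an [alignment_block()] containing the three taxa.
#' @param ingroup1,ingroup2,outgroup taxon names.
#' @return list with `m1`, `m2`, `n_used`, `chi2`, `p` (p = 1 when
#'   m1 + m2 = 0).
#' @export
tajima_rrt <- function(block, ingroup1, ingroup2, outgroup) {
  stopifnot(inherits(block, "alignment_block"))
  taxa <- c(ingroup1, ingroup2, outgroup)
  miss <- setdiff(taxa, names(block$rows))
  if (length(miss))
    stop("taxon not present in the alignment: ",
         paste(miss, collapse = ", "))
  m <- .block_matrix(alignment_block(block$rows[taxa],
                                     alphabet = block$alphabet))
  ok <- .is_resolved(m[1, ], block$alphabet) &
    .is_resolved(m[2, ], block$alphabet) &
    .is_resolved(m[3, ], block$alphabet)
  a <- m[1, ok]; b <- m[2, ok]; o <- m[3, ok]
  m1 <- sum(a != b & b == o)
  m2 <- sum(b != a & a == o)
  if (m1 + m2 == 0) {
    chi2 <- 0; p <- 1
  } else {
    chi2 <- (m1 - m2)^2 / (m1 + m2)
    p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  }
  list(m1 = m1, m2 = m2, n_used = sum(ok), chi2 = chi2, p = p)
}

#' Relative-rate test table over focal/other/outgroup triples
#'
#' Runs [tajima_rrt()] for a focal taxon against every other ingroup
#' taxon, once per outgroup, reproducing the usual one-row-per-comparison
#' report with a significance mark.
#'
#' @param block concatenated [alignment_block()].
#' @param focal focal taxon (ingroup 1 in every test).
#' @param others ingroup-2 taxa.
#' @param outgroups outgroup taxa, used separately.
#' @param alpha significance level for the mark (default 0.05).
#' @return data.frame: focal, other, outgroup, m1, m2, n_used, chi2, p,
#'   significant.
#' @export
rrt_table <- function(block, focal, others, outgroups, alpha = 0.05) {
  rows <- list()
  for (o in outgroups) for (sp in others) {
    r <- tajima_rrt(block, focal, sp, o)
    rows[[length(rows) + 1L]] <- data.frame(
      focal = focal, other = sp, outgroup = o,
      m1 = r$m1, m2 = r$m2, n_used = r$n_used,
      chi2 = r$chi2, p = r$p, significant = r$p < alpha,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

.codon_split <- function(s) {
  s <- toupper(s)
  if (nchar(s) %% 3 != 0) stop("sequence length not divisible by 3")
  substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
}

.GC <- NULL
.genetic_code <- function() {
  Biostrings::GENETIC_CODE
}

.syn_sites_codon <- function(codon, gc) {
  # per position, fraction of the 3 possible changes that are synonymous;
  # changes creating a stop count as non-synonymous
  nts <- c("A", "C", "G", "T")
  aa <- gc[[codon]]
  s <- 0
  for (j in 1:3) {
    for (b in setdiff(nts, substr(codon, j, j))) {
      alt <- codon
      substr(alt, j, j) <- b
      if (gc[[alt]] == aa && gc[[alt]] != "*") s <- s + 1 / 3
    }
  }
  s
}

.path_diffs <- function(c1, c2, gc) {
  # average synonymous/non-synonymous difference counts over all
  # substitution orders between two codons, skipping paths through stops
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(pos)) return(c(sd = 0, nd = 0))
  perms <- if (length(pos) == 1) list(pos)
  else if (length(pos) == 2) list(pos, rev(pos))
  else {
    p <- pos
    list(p[c(1,2,3)], p[c(1,3,2)], p[c(2,1,3)],
         p[c(2,3,1)], p[c(3,1,2)], p[c(3,2,1)])
  }
  acc <- matrix(0, 0, 2)
  for (ord in perms) {
    cur <- c1; sdiff <- 0; ndiff <- 0; valid <- TRUE
    for (j in ord) {
      nxt <- cur
      substr(nxt, j, j) <- substr(c2, j, j)
      if (gc[[nxt]] == "*") { valid <- FALSE; break }
      if (gc[[nxt]] == gc[[cur]]) sdiff <- sdiff + 1 else ndiff <- ndiff + 1
      cur <- nxt
    }
    if (valid) acc <- rbind(acc, c(sdiff, ndiff))
  }
  if (!nrow(acc)) {
    # all paths pass through a stop; fall back to averaging over all orders
    for (ord in perms) {
      cur <- c1; sdiff <- 0; ndiff <- 0
      for (j in ord) {
        nxt <- cur
        substr(nxt, j, j) <- substr(c2, j, j)
        if (gc[[nxt]] != "*" && gc[[nxt]] == gc[[cur]])
          sdiff <- sdiff + 1 else ndiff <- ndiff + 1
        cur <- nxt
      }
      acc <- rbind(acc, c(sdiff, ndiff))
    }
  }
  c(sd = mean(acc[, 1]), nd = mean(acc[, 2]))
}

#' Counting-method Ka/Ks for a pairwise codon alignment
#'
#' Nei-Gojobori-style estimator: synonymous and non-synonymous site counts
#' are averaged over the two sequences (mutations to stop codons count as
#' non-synonymous); observed differences are averaged over the shortest
#' substitution paths between differing codons (paths through stop codons
#' excluded); proportions are corrected for multiple hits with the
#' Jukes-Cantor formula. omega = Ka/Ks is undefined (NA) when Ks = 0.
#'
#' @param seq1,seq2 in-frame coding sequences of equal length, no internal
#'   stop codons.
#' @return list with `ka`, `ks`, `omega`, and the underlying site and
#'   difference counts (`S`, `N`, `Sd`, `Nd`).
#' @export
kaks_counting <- function(seq1, seq2) {
  gc <- .genetic_code()
  c1 <- .codon_split(seq1); c2 <- .codon_split(seq2)
  if (length(c1) != length(c2))
    stop("sequences must be aligned to equal length")
  for (i in seq_along(c1)) {
    if (gc[[c1[i]]] == "*" || gc[[c2[i]]] == "*")
      stop("internal stop codon at codon ", i)
  }
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(c1)) {
    S <- S + (.syn_sites_codon(c1[i], gc) + .syn_sites_codon(c2[i], gc)) / 2
    d <- .path_diffs(c1[i], c2[i], gc)
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  N <- 3 * length(c1) - S
  jc <- function(p) {
    if (p == 0) return(0)
    if (p >= 0.75) return(NA_real_)
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  ks <- jc(if (S > 0) Sd / S else 0)
  ka <- jc(if (N > 0) Nd / N else 0)
  omega <- if (!is.na(ks) && !is.na(ka) && ks > 0) ka / ks else NA_real_
  list(ka = ka, ks = ks, omega = omega, S = S, N = N, Sd = Sd, Nd = Nd)
}

#' Count occurrences of a fixed-length residue motif
#'
#' Sliding-window scan for a motif given in the compact notation where
#' `x`/`X` matches any residue and bracket groups list alternatives (e.g.
#' the 9-residue actinodin repeat `C[ND]PxxDPxC`). Overlapping matches are
#' all counted.
#'
#' @param sequence amino-acid string.
#' @param pattern motif in compact notation.
#' @return list with `count` and 1-based `positions` of match starts.
#' @export
count_motif <- function(sequence, pattern = "C[ND]PxxDPxC") {
  regex <- gsub("[xX]", ".", pattern)
  m <- gregexpr(paste0("(?=", regex, ")"), toupper(sequence), perl = TRUE)[[1]]
  if (length(m) == 1 && m[1] == -1)
    return(list(count = 0L, positions = integer(0)))
  list(count = length(m), positions = as.integer(m))
}
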