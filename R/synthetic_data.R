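#' Simulation configuration
#'
#' Collects every parameter of the synthetic-data generators in one
#' validated object. All randomness downstream is a pure function of this
#' configuration (including its seed): rerunning any generator with the
#' same config yields identical output.
#'
#' @param n_transcripts number of transcripts to simulate.
#' @param length_meanlog,length_sdlog log-normal transcript-length
#'   parameters (nt); lengths are floored at `length_min`.
#' @param length_min minimum transcript length in nt (assembly convention).
#' @param te_fraction named numeric vector: target fraction of transcripts
#'   carrying an embedded TE segment, per repeat class. Fractions must sum
#'   to at most 1.
#' @param groups character vector of group labels, one per sample.
#' @param library_sizes integer reads per sample (recycled to the number
#'   of samples).
#' @param overdispersion beta-binomial dispersion rho in [0, 1); 0
#'   degenerates to binomial/multinomial sampling. The default 1e-4 gives
#'   a between-library biological CV near 0.3 for a median-expression
#'   transcript (proportion ~1e-3), typical of bulk RNA-seq replicates.
#' @param de_genes named numeric vector of planted fold changes (group 2
#'   relative to group 1), names are transcript indices or ids.
#' @param n_domains,n_ref_species,domain_mu_meanlog,domain_mu_sdlog,domain_nb_size
#'   parameters of the domain-count generator.
#' @param planted_expansions named numeric vector: domain index ->
#'   multiplicative inflation of the focal species count.
#' @param seed integer seed fixing all randomness.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 1000,
                       length_meanlog = log(1200), length_sdlog = 0.6,
                       length_min = 250,
                       te_fraction = c(LINE = 0.03, SINE = 0.01,
                                       LTR = 0.02, DNA = 0.015),
                       groups = c("g1", "g1", "g1", "g2", "g2", "g2"),
                       library_sizes = 1e6,
                       overdispersion = 1e-4,
                       de_genes = numeric(0),
                       n_domains = 50, n_ref_species = 9,
                       domain_mu_meanlog = log(60), domain_mu_sdlog = 0.5,
                       domain_nb_size = 50,
                       planted_expansions = numeric(0),
                       seed = 1L) {
  stopifnot(n_transcripts > 0, length_min > 0,
            all(te_fraction >= 0), all(te_fraction <= 1))
  if (sum(te_fraction) > 1)
    stop("te_fraction values sum to more than 1")
  library_sizes <- rep_len(as.numeric(library_sizes), length(groups))
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  if (overdispersion < 0 || overdispersion >= 1)
    stop("overdispersion must lie in [0, 1)")
  if (n_ref_species < 3)
    stop("at least 3 reference species are required (outlier test needs n >= 3)")
  structure(list(
    n_transcripts = as.integer(n_transcripts),
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    length_min = as.integer(length_min),
    te_fraction = te_fraction,
    groups = groups, library_sizes = library_sizes,
    overdispersion = overdispersion, de_genes = de_genes,
    n_domains = as.integer(n_domains),
    n_ref_species = as.integer(n_ref_species),
    domain_mu_meanlog = domain_mu_meanlog,
    domain_mu_sdlog = domain_mu_sdlog,
    domain_nb_size = domain_nb_size,
    planted_expansions = planted_expansions,
    seed = as.integer(seed)), class = "sim_config")
}

.te_consensus <- function() {
  read_fasta(system.file("extdata", "te_consensus_synthetic.fasta",
                         package = "transevo"), alphabet = "dna")
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Simulate a transcriptome with planted TE-derived segments
#'
#' Draws transcript lengths from a floored log-normal, fills them with
#' random nucleotides, and embeds in a configured fraction of transcripts a
#' contiguous segment copied from a packaged synthetic TE consensus library
#' (one segment per transcript, class drawn per transcript). The planted
#' intervals are emitted both as a repeat-hit table (the format a masking
#' scan would produce) and as ground truth.
#'
#' @param config a [sim_config()].
#' @return list with `sequences` (DNAStringSet), `repeat_hits` (data.frame
#'   in [parse_repeatmasker_out()] layout), and `truth` (data.frame with
#'   per-transcript class label, interval, and length).
#' @export
simulate_transcriptome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_transcripts
  lens <- pmax(config$length_min,
               round(rlnorm(n, config$length_meanlog, config$length_sdlog)))
  ids <- sprintf("contig_%05d", seq_len(n))
  seqs <- vapply(lens, .random_dna, character(1))

  tf <- config$te_fraction
  cls_levels <- c(names(tf), "none")
  prob <- c(tf, 1 - sum(tf))
  labels <- sample(cls_levels, n, replace = TRUE, prob = prob)

  cons <- .te_consensus()
  cons_class <- sub("-consensus-.*$", "", names(cons))

  hit_rows <- list()
  te_begin <- te_end <- rep(NA_integer_, n)
  te_name <- rep(NA_character_, n)
  for (i in which(labels != "none")) {
    cand <- which(cons_class == labels[i])
    j <- if (length(cand) == 1) cand else sample(cand, 1)
    seg_len <- min(Biostrings::width(cons)[j], max(60L, floor(lens[i] / 3)))
    seg <- substr(as.character(cons[[j]]), 1, seg_len)
    start <- sample.int(lens[i] - seg_len + 1L, 1)
    substr(seqs[i], start, start + seg_len - 1L) <- seg
    te_begin[i] <- start; te_end[i] <- start + seg_len - 1L
    te_name[i] <- names(cons)[j]
    hit_rows[[length(hit_rows) + 1L]] <- data.frame(
      query_id = ids[i], begin = start, end = start + seg_len - 1L,
      repeat_name = names(cons)[j], repeat_class = labels[i],
      subfamily = "", divergence_pct = round(runif(1, 0, 15), 1),
      score = round(seg_len * runif(1, 5, 9)), stringsAsFactors = FALSE)
  }
  repeat_hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
    parse_repeatmasker_out(character(0))
  truth <- data.frame(transcript_id = ids, length = lens, te_class = labels,
                      te_begin = te_begin, te_end = te_end,
                      te_name = te_name, stringsAsFactors = FALSE)
  sequences <- Biostrings::DNAStringSet(setNames(seqs, ids))
  list(sequences = sequences, repeat_hits = repeat_hits, truth = truth)
}

#' Beta-binomial random deviates
#'
#' Mean/dispersion parameterization: `prob` is the mean proportion and
#' `rho` in [0, 1) the dispersion; `rho = 0` degenerates to the binomial.
#' The per-draw success probability is Beta with a = prob(1-rho)/rho,
#' b = (1-prob)(1-rho)/rho, giving Var(p) = rho * prob * (1 - prob).
#'
#' @param n number of deviates.
#' @param size number of trials.
#' @param prob mean success probability.
#' @param rho dispersion in [0, 1).
#' @return integer vector of counts.
#' @export
rbetabinom <- function(n, size, prob, rho = 0) {
  stopifnot(rho >= 0, rho < 1, prob >= 0, prob <= 1)
  if (rho == 0 || prob == 0 || prob == 1)
    return(rbinom(n, size, prob))
  a <- prob * (1 - rho) / rho
  b <- (1 - prob) * (1 - rho) / rho
  rbinom(n, size, rbeta(n, a, b))
}

#' Simulate an overdispersed count matrix with tissue structure
#'
#' True expression proportions are drawn once from a log-normal and
#' normalized; planted fold changes multiply the group-2 proportions (then
#' renormalized within the sample, so fold changes are realized in
#' expectation up to the renormalization factor). Per sample, proportions
#' are perturbed by a Beta draw (between-library overdispersion rho) and
#' counts are drawn multinomially at the configured library size, so column
#' sums match library sizes exactly.
#'
#' @param config a [sim_config()].
#' @param truth optional transcriptome truth from [simulate_transcriptome()];
#'   when supplied, its transcript ids and lengths are reused.
#' @return list with `counts` (matrix transcripts x samples), `lengths`,
#'   `groups`, and `truth` (data.frame of true proportions per group and
#'   the planted DE set).
#' @export
simulate_counts <- function(config, truth = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  n <- config$n_transcripts
  if (!is.null(truth)) {
    ids <- truth$transcript_id; lens <- truth$length
    n <- length(ids)
  } else {
    ids <- sprintf("contig_%05d", seq_len(n))
    lens <- pmax(config$length_min,
                 round(rlnorm(n, config$length_meanlog, config$length_sdlog)))
  }
  base <- rlnorm(n, meanlog = 0, sdlog = 1.2)
  p1 <- base / sum(base)
  p2 <- p1
  de_idx <- integer(0)
  if (length(config$de_genes)) {
    de_idx <- if (is.null(names(config$de_genes)) ||
                  all(names(config$de_genes) == ""))
      seq_along(config$de_genes) else match(names(config$de_genes), ids)
    if (anyNA(de_idx)) de_idx <- as.integer(names(config$de_genes))
    p2[de_idx] <- p2[de_idx] * as.numeric(config$de_genes)
    p2 <- p2 / sum(p2)
  }
  groups <- config$groups
  glev <- unique(groups)
  rho <- config$overdispersion
  counts <- matrix(0L, n, length(groups),
                   dimnames = list(ids, sprintf("%s_s%d", groups,
                                                seq_along(groups))))
  for (s in seq_along(groups)) {
    p <- if (groups[s] == glev[1] || length(glev) == 1) p1 else p2
    q <- p
    if (rho > 0) {
      pos <- p > 0
      a <- p[pos] * (1 - rho) / rho
      b <- (1 - p[pos]) * (1 - rho) / rho
      q[pos] <- rbeta(sum(pos), a, b)
      q <- q / sum(q)
    }
    counts[, s] <- as.integer(rmultinom(1, config$library_sizes[s], q))
  }
  truth_df <- data.frame(transcript_id = ids, length = lens,
                         prop_group1 = p1, prop_group2 = p2,
                         is_de = seq_len(n) %in% de_idx,
                         stringsAsFactors = FALSE)
  list(counts = counts, lengths = setNames(lens, ids),
       groups = groups, truth = truth_df)
}

#' Construct an alignment block
#'
#' An alignment block is the unit consumed by relative-rate testing and
#' concatenation: equal-length aligned rows keyed by taxon name plus a
#' partition map recording which columns belong to which gene.
#'
#' @param rows named character vector of aligned sequences (equal length).
#' @param partition data.frame with columns `gene`, `start`, `end`
#'   (1-based inclusive column intervals, disjoint and ordered); defaults
#'   to one partition covering the whole block.
#' @param alphabet "aa" or "dna".
#' @return object of class `alignment_block`.
#' @export
alignment_block <- function(rows, partition = NULL, alphabet = "aa") {
  stopifnot(is.character(rows), !is.null(names(rows)),
            all(nzchar(names(rows))))
  w <- unique(nchar(rows))
  if (length(w) != 1)
    stop("alignment rows have unequal lengths")
  if (is.null(partition))
    partition <- data.frame(gene = "g1", start = 1L, end = w,
                            stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "start", "end") %in% names(partition)))
  if (nrow(partition)) {
    o <- order(partition$start)
    partition <- partition[o, , drop = FALSE]
    if (any(partition$end < partition$start) ||
        any(partition$end > w) ||
        (nrow(partition) > 1 &&
         any(partition$start[-1] <= partition$end[-nrow(partition)])))
      stop("partition intervals must be disjoint, ordered, and within the block")
  }
  structure(list(rows = rows, partition = partition, alphabet = alphabet),
            class = "alignment_block")
}

#' @export
print.alignment_block <- function(x, ...) {
  cat(sprintf("alignment_block: %d taxa x %d columns (%s), %d partition(s)\n",
              length(x$rows), nchar(x$rows[[1]]), x$alphabet,
              nrow(x$partition)))
  invisible(x)
}

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

#' Evolve a protein alignment down a tree with per-lineage rate multipliers
#'
#' Sites evolve i.i.d. under an equal-exchangeability 20-state process
#' (Jukes-Cantor-like on amino acids): along a branch of expected length d
#' substitutions/site, a site differs from its parent with probability
#' (19/20) * (1 - exp(-20/19 * d)), and a differing site takes a uniform
#' draw over the other 19 residues. Rate multipliers, keyed by tip label,
#' scale the terminal branch leading to that tip, modelling lineage-specific
#' accelerations or decelerations.
#'
#' @param tree an `ape::phylo` with branch lengths (expected
#'   substitutions/site), 3 or more tips.
#' @param n_sites number of alignment columns.
#' @param seed integer seed.
#' @param rate_multipliers named numeric vector (tip label -> multiplier);
#'   missing tips default to 1.
#' @return an [alignment_block()] over the tip labels.
#' @export
evolve_alignment <- function(tree, n_sites, seed = 1L,
                             rate_multipliers = numeric(0)) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) < 3)
    stop("relative-rate testing needs at least 3 taxa; supply 3 or more tips")
  if (is.null(tree$edge.length) || any(tree$edge.length < 0))
    stop("tree must carry non-negative branch lengths")
  set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  nnode <- ntip + tree$Nnode
  states <- matrix(0L, nnode, n_sites)
  states[root, ] <- sample.int(20L, n_sites, replace = TRUE)
  # traverse edges parent-before-child
  ord <- order(tree$edge[, 1])
  for (k in ord) {
    par <- tree$edge[k, 1]; child <- tree$edge[k, 2]
    d <- tree$edge.length[k]
    if (child <= ntip) {
      m <- rate_multipliers[tree$tip.label[child]]
      if (!is.na(m) && length(m)) d <- d * as.numeric(m)
    }
    p_diff <- (19 / 20) * (1 - exp(-20 / 19 * d))
    x <- states[par, ]
    flip <- runif(n_sites) < p_diff
    if (any(flip)) {
      shift <- sample.int(19L, sum(flip), replace = TRUE)
      x[flip] <- ((x[flip] - 1L + shift) %% 20L) + 1L
    }
    states[child, ] <- x
  }
  rows <- vapply(seq_len(ntip), function(i)
    paste(AA20[states[i, ]], collapse = ""), character(1))
  names(rows) <- tree$tip.label
  alignment_block(rows, alphabet = "aa")
}

#' Simulate per-species protein-domain count tables
#'
#' Reference-species counts for each domain are drawn from a shared
#' negative binomial (domain-specific mean, common size parameter); planted
#' expansions multiply the focal species' mean for the chosen domains. The
#' focal species is the first column.
#'
#' @param config a [sim_config()].
#' @return list with `table` (matrix domains x species, focal species first,
#'   column "focal") and `truth` (character vector of truly expanded domain
#'   ids).
#' @export
simulate_domain_tables <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  nd <- config$n_domains; ns <- config$n_ref_species
  dom <- sprintf("IPR%06d", seq_len(nd))
  mu <- rlnorm(nd, config$domain_mu_meanlog, config$domain_mu_sdlog)
  tab <- matrix(0L, nd, ns + 1L,
                dimnames = list(dom, c("focal", sprintf("ref%02d",
                                                        seq_len(ns)))))
  exp_idx <- integer(0)
  if (length(config$planted_expansions)) {
    exp_idx <- as.integer(names(config$planted_expansions))
    if (anyNA(exp_idx)) exp_idx <- match(names(config$planted_expansions), dom)
  }
  fac <- rep(1, nd)
  fac[exp_idx] <- as.numeric(config$planted_expansions)
  for (d in seq_len(nd)) {
    tab[d, -1] <- rnbinom(ns, size = config$domain_nb_size, mu = mu[d])
    tab[d, 1] <- rnbinom(1, size = config$domain_nb_size,
                         mu = mu[d] * fac[d])
  }
  list(table = tab, truth = dom[exp_idx])
}

#' Simulate BLAST-style reciprocal hit tables for ortholog pairs
#'
#' Emits two hit tables (assembly vs reference and the reciprocal) for a
#' set of true ortholog pairs in which a configured fraction of assembled
#' transcripts is 5'/3'-truncated: the truncated transcripts hit only a
#' sub-interval of their reference ortholog, so the planted truncation
#' fraction is recoverable from the resulting ortholog-hit-ratio
#' distribution.
#'
#' @param n_pairs number of ortholog pairs.
#' @param truncation_fraction fraction of pairs whose hit covers less than
#'   `full_length_min` of the ortholog.
#' @param full_length_min coverage ratio separating full-length from
#'   truncated (default 0.8).
#' @param identity_range percent-identity range of the simulated hits.
#' @param seed integer seed.
#' @return list with `hits_ab`, `hits_ba` (hit-table data.frames),
#'   `subject_lengths` (named vector), and `truth` (logical vector: pair is
#'   full-length).
#' @export
simulate_ortholog_hits <- function(n_pairs = 1000,
                                   truncation_fraction = 0.3,
                                   full_length_min = 0.8,
                                   identity_range = c(91, 99),
                                   seed = 1L) {
  stopifnot(n_pairs > 0, truncation_fraction >= 0, truncation_fraction <= 1)
  set.seed(seed)
  qid <- sprintf("contig_%05d", seq_len(n_pairs))
  sid <- sprintf("ref_%05d", seq_len(n_pairs))
  slen <- sample(200:1500, n_pairs, replace = TRUE)
  truncated <- runif(n_pairs) < truncation_fraction
  cov <- ifelse(truncated,
                runif(n_pairs, 0.10, full_length_min - 1e-9),
                runif(n_pairs, full_length_min, 1))
  span <- pmax(1L, round(cov * slen))
  s_start <- vapply(slen - span + 1L, function(m) sample.int(m, 1), integer(1))
  s_end <- s_start + span - 1L
  ident <- runif(n_pairs, identity_range[1], identity_range[2])
  ev <- 10^(-runif(n_pairs, 60, 180))
  bits <- round(span * 1.8)
  hits_ab <- data.frame(query_id = qid, subject_id = sid,
                        percent_identity = round(ident, 2),
                        aln_length = span, mismatches = 0L, gap_opens = 0L,
                        q_start = 1L, q_end = span,
                        s_start = s_start, s_end = s_end,
                        e_value = ev, bitscore = bits,
                        stringsAsFactors = FALSE)
  hits_ba <- hits_ab
  hits_ba$query_id <- sid; hits_ba$subject_id <- qid
  hits_ba$q_start <- s_start; hits_ba$q_end <- s_end
  hits_ba$s_start <- 1L; hits_ba$s_end <- span
  list(hits_ab = hits_ab, hits_ba = hits_ba,
       subject_lengths = setNames(slen, sid),
       truth = !truncated)
}
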