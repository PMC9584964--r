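# Preranked gene set enrichment with a gene-label permutation null.
#
# The ranked list is an organ's transcripts ordered from most to least
# expressed (replicate-averaged TMM-adjusted values); transcripts not
# expressed in the organ are excluded before ranking.

#' Running-sum enrichment score
#'
#' Walks the ranked list; at a set member the running sum increases by
#' |score|^weight normalized over the set members' scores, at a non-member it
#' decreases by 1/(N - set size). The enrichment score is the signed maximum
#' deviation from zero.
#'
#' @param ranked Named numeric vector of ranking scores, ordered from most to
#'   least expressed; names are transcript ids.
#' @param set Character vector of member transcript ids.
#' @param weight_exponent Exponent on |score| for hit increments; 0 gives the
#'   unweighted Kolmogorov-Smirnov-style statistic.
#' @return Enrichment score in [-1, 1].
#' @export
enrichment_score <- function(ranked, set, weight_exponent = 1) {
  ids <- names(ranked)
  hit <- ids %in% set
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set does not intersect the ranked list")
  n <- length(ids)
  if (n_hit == n) stop("gene set covers the whole ranked list")
  w <- abs(ranked)^weight_exponent
  inc <- numeric(n)
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (n - n_hit)
  running <- cumsum(inc)
  running[which.max(abs(running))]
}

#' Preranked gene set enrichment analysis
#'
#' Computes the enrichment score of each set against the ranked list and a
#' nominal p-value from a gene-label permutation null: set labels are
#' reassigned to random positions of the list, and
#' p = (1 + #\{permuted |ES*| >= |ES|\}) / (n_perm + 1), a two-sided test on
#' the magnitude of the enrichment score, which keeps the nominal rejection
#' rate of random sets at the significance level itself.
#' Sets whose intersection with the ranked list is below `min_size` are
#' dropped before testing.
#'
#' @param ranked Named numeric vector, ordered most- to least-expressed. Ties
#'   are re-broken deterministically (score descending, then id).
#' @param sets Named list of character vectors (gene sets).
#' @param min_size Minimum set size after intersection with the ranked list.
#' @param n_perm Number of label permutations.
#' @param alpha Nominal significance level; rows with p < alpha are flagged.
#' @param seed Random seed for the permutation null.
#' @param weight_exponent Passed to [enrichment_score()].
#' @param keep_all If `FALSE` (default) only rows with p < alpha are
#'   returned, mirroring a nominal-p cutoff report; if `TRUE` all tested sets
#'   are returned with a `significant` flag.
#' @return `data.frame` with `term`, `size`, `es`, `pval`, `n_perm`,
#'   `significant`.
#' @export
gsea_preranked <- function(ranked, sets, min_size = 15L, n_perm = 1000L,
                           alpha = 0.01, seed = NULL, weight_exponent = 1,
                           keep_all = FALSE) {
  stopifnot(n_perm >= 1L)
  ord <- order(-ranked, names(ranked))
  ranked <- ranked[ord]
  ids <- names(ranked)
  sizes <- vapply(sets, function(s) sum(ids %in% s), integer(1))
  test <- sizes >= min_size
  if (!any(test)) {
    warning("no gene set passes the minimum size filter")
    return(data.frame(term = character(), size = integer(), es = numeric(),
                      pval = numeric(), n_perm = integer(),
                      significant = logical()))
  }
  if (!is.null(seed)) set.seed(seed)
  n <- length(ids)
  rows <- lapply(names(sets)[test], function(term) {
    members <- intersect(sets[[term]], ids)
    es <- enrichment_score(ranked, members, weight_exponent)
    k <- length(members)
    null_es <- vapply(seq_len(n_perm), function(i) {
      enrichment_score(ranked, sample(ids, k), weight_exponent)
    }, numeric(1))
    p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
    data.frame(term = term, size = k, es = es, pval = p,
               n_perm = as.integer(n_perm), significant = p < alpha)
  })
  out <- do.call(rbind, rows)
  if (!keep_all) out <- out[out$significant, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Organ-wise ranked list from an expression layer
#'
#' Averages an organ's replicate columns, drops transcripts with mean value
#' not exceeding zero, and orders the remainder from most to least expressed
#' (ties broken by transcript id).
#'
#' @param expr Expression matrix (TMM-adjusted layer), transcripts x samples.
#' @param sample_organs Organ label of each column.
#' @param organ Organ to rank.
#' @return Named numeric vector of scores, descending.
#' @export
ranked_list <- function(expr, sample_organs, organ) {
  cols <- which(sample_organs == organ)
  if (length(cols) == 0L) stop("unknown organ: ", organ)
  m <- rowMeans(as.matrix(expr)[, cols, drop = FALSE])
  m <- m[m > 0]
  m[order(-m, names(m))]
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then member ids, tab-separated.
#'
#' @param path File path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    parts[-(1:2)]
  })
  names(out) <- vapply(lines, function(l) {
    strsplit(l, "\t", fixed = TRUE)[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  out
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param description Per-set description column (recycled).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path, description = "na") {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
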