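# Expression normalization (FPKM, TMM) and per-organ presence analysis.
#
# Counts enter as a transcripts x samples integer matrix whose column names
# are "organ.replicate" pairs. Effective length is the transcript length (no
# fragment-length correction).

#' Fragments per kilobase per million mapped fragments
#'
#' FPKM = count / (length/1000 * library_size/1e6), with the per-sample
#' library size taken as the column sum unless given.
#'
#' @param counts Non-negative count matrix, transcripts x samples.
#' @param lengths Positive transcript lengths (nt), recycled over rows by
#'   name when named.
#' @param lib_sizes Optional per-sample library sizes; defaults to column
#'   sums.
#' @return FPKM matrix, same dimensions as `counts`.
#' @export
compute_fpkm <- function(counts, lengths, lib_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts")
  if (!is.null(names(lengths)) && !is.null(rownames(counts))) {
    lengths <- lengths[rownames(counts)]
  }
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("transcript lengths must be positive")
  }
  if (is.null(lib_sizes)) lib_sizes <- colSums(counts)
  if (any(lib_sizes <= 0)) stop("zero library size")
  sweep(counts / (lengths / 1000), 2, lib_sizes / 1e6, "/")
}

.tmm_pair_factor <- function(obs, ref, n_obs, n_ref,
                             logratio_trim = 0.3, abundance_trim = 0.05,
                             weighted = TRUE) {
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  w <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; w <- w[fin]
  if (length(m) == 0L) {
    stop("no transcript is nonzero in both samples of a pair")
  }
  if (max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * abundance_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  f <- if (weighted) {
    sum(m[keep] / w[keep]) / sum(1 / w[keep])
  } else {
    mean(m[keep])
  }
  if (is.na(f)) f <- 0
  2^f
}

#' Trimmed-mean-of-M-values scaling factors
#'
#' Between-sample scaling by the trimmed mean of M-values: the reference is
#' the sample whose upper quartile of library-size-scaled counts is closest to
#' the mean upper quartile (unless `ref_sample` is given); per sample,
#' transcripts zero in either member of the pair are excluded, 30% of
#' M-values and 5% of A-values are trimmed two-sided, and the factor is two to
#' the precision-weighted trimmed mean of M. The returned values are
#' effective size factors -- library size times the TMM normalization factor
#' -- rescaled to geometric mean 1, so that dividing a sample's counts by its
#' factor makes samples comparable. The edgeR-convention normalization
#' factors are attached as attribute `norm_factors`.
#'
#' @param counts Count matrix, transcripts x samples (>= 2 samples).
#' @param ref_sample Optional reference sample name or index.
#' @param logratio_trim Two-sided trim fraction on M-values.
#' @param abundance_trim Two-sided trim fraction on A-values.
#' @param weighted Use inverse-variance precision weights in the trimmed
#'   mean (the published default); `FALSE` gives the plain trimmed mean.
#' @return Named numeric vector of effective size factors with geometric mean
#'   1; attributes `norm_factors` and `ref_sample`.
#' @export
tmm_factors <- function(counts, ref_sample = NULL,
                        logratio_trim = 0.3, abundance_trim = 0.05,
                        weighted = TRUE) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("need at least two samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("zero library size")
  counts <- counts[rowSums(counts > 0) > 0L, , drop = FALSE]
  if (is.null(ref_sample)) {
    uq <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- if (is.character(ref_sample)) match(ref_sample, colnames(counts))
           else as.integer(ref_sample)
    if (is.na(ref) || ref < 1L || ref > ncol(counts)) {
      stop("unknown reference sample")
    }
  }
  nf <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair_factor(counts[, j], counts[, ref], lib[j], lib[ref],
                     logratio_trim, abundance_trim, weighted)
  }, numeric(1))
  nf <- nf / exp(mean(log(nf)))
  sf <- nf * lib
  sf <- sf / exp(mean(log(sf)))
  names(sf) <- colnames(counts)
  attr(sf, "norm_factors") <- stats::setNames(nf, colnames(counts))
  attr(sf, "ref_sample") <- if (is.null(colnames(counts))) ref
                            else colnames(counts)[ref]
  sf
}

#' FPKM and TMM-adjusted expression layers
#'
#' Computes the raw FPKM layer and a TMM-adjusted layer in which the library
#' size is replaced by the effective library size (geometric-mean library
#' size times the sample's effective size factor).
#'
#' @param counts Count matrix.
#' @param lengths Transcript lengths (nt).
#' @return List with `fpkm`, `tmm` matrices and `factors` from
#'   [tmm_factors()].
#' @export
normalize_expression <- function(counts, lengths) {
  counts <- as.matrix(counts)
  sf <- tmm_factors(counts)
  lib <- colSums(counts)
  eff <- as.numeric(sf) * exp(mean(log(lib)))
  list(
    fpkm = compute_fpkm(counts, lengths),
    tmm = compute_fpkm(counts, lengths, lib_sizes = eff),
    factors = sf
  )
}

#' Per-organ presence calls
#'
#' A transcript is called expressed in an organ iff its mean expression over
#' that organ's replicate samples exceeds `threshold` (strictly).
#'
#' @param expr Expression matrix (typically the TMM-adjusted layer),
#'   transcripts x samples.
#' @param sample_organs Character vector mapping each column of `expr` to an
#'   organ label.
#' @param threshold Strict lower bound on the replicate mean.
#' @return List with logical matrix `presence` (transcripts x organs),
#'   numeric matrix `organ_means`, and `per_organ` expressed counts.
#' @export
organ_presence <- function(expr, sample_organs, threshold = 0) {
  expr <- as.matrix(expr)
  if (length(sample_organs) != ncol(expr)) {
    stop("sample_organs must map every sample")
  }
  organs <- unique(sample_organs)
  means <- vapply(organs, function(o) {
    cols <- which(sample_organs == o)
    if (length(cols) == 0L) stop("organ without replicates: ", o)
    rowMeans(expr[, cols, drop = FALSE])
  }, numeric(nrow(expr)))
  colnames(means) <- organs
  pres <- means > threshold
  list(
    presence = pres,
    organ_means = means,
    per_organ = colSums(pres)
  )
}

#' Organ set summary (exclusive and shared intersection sizes)
#'
#' For every non-empty organ combination, reports the number of transcripts
#' expressed in exactly that combination (`exclusive`) and the number
#' expressed in at least those organs (`shared`).
#'
#' @param presence Logical matrix, transcripts x organs.
#' @return `data.frame` with `combo`, `n_organs`, `exclusive`, `shared`.
#' @export
organ_set_summary <- function(presence) {
  presence <- as.matrix(presence)
  organs <- colnames(presence)
  k <- length(organs)
  pattern <- apply(presence, 1, function(r) paste(as.integer(r), collapse = ""))
  pat_counts <- table(pattern)
  combos <- list()
  for (size in seq_len(k)) {
    cc <- utils::combn(k, size, simplify = FALSE)
    combos <- c(combos, cc)
  }
  rows <- lapply(combos, function(idx) {
    mask <- rep(FALSE, k)
    mask[idx] <- TRUE
    excl_pat <- paste(as.integer(mask), collapse = "")
    excl <- if (excl_pat %in% names(pat_counts))
      as.integer(pat_counts[[excl_pat]]) else 0L
    shared <- sum(vapply(names(pat_counts), function(p) {
      bits <- as.integer(strsplit(p, "")[[1]]) == 1L
      if (all(bits[idx])) as.integer(pat_counts[[p]]) else 0L
    }, integer(1)))
    data.frame(
      combo = paste(organs[idx], collapse = "+"),
      n_organs = length(idx),
      exclusive = excl,
      shared = shared
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a count matrix with a two-row header
#'
#' Tab-separated: first header row gives the organ of each sample column,
#' second row the replicate label; first column holds transcript ids.
#'
#' @param path File path.
#' @return List with integer matrix `counts` (columns named
#'   "organ.replicate") and character vector `sample_organs`.
#' @export
read_count_matrix <- function(path) {
  hdr <- utils::read.delim(path, header = FALSE, nrows = 2,
                           stringsAsFactors = FALSE)
  organs <- as.character(hdr[1, -1])
  reps <- as.character(hdr[2, -1])
  dat <- utils::read.delim(path, header = FALSE, skip = 2,
                           stringsAsFactors = FALSE)
  counts <- as.matrix(dat[, -1, drop = FALSE])
  rownames(counts) <- dat[[1]]
  colnames(counts) <- paste(organs, reps, sep = ".")
  storage.mode(counts) <- "integer"
  list(counts = counts, sample_organs = organs)
}

#' Write a count matrix with a two-row header
#' @param counts Count matrix with "organ.replicate" column names.
#' @param sample_organs Organ of each column.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_count_matrix <- function(counts, sample_organs, path) {
  reps <- sub("^[^.]*\\.", "", colnames(counts))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("transcript_id", sample_organs), collapse = "\t"), con)
  writeLines(paste(c("replicate", reps), collapse = "\t"), con)
  utils::write.table(counts, con, sep = "\t", quote = FALSE,
                     col.names = FALSE, row.names = TRUE)
  invisible(path)
}
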