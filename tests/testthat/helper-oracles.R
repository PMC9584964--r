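# Independent brute-force oracles used across the test files. Each oracle is
# a direct, unoptimized transcription of the operation's definition and never
# shares code with the implementation it checks.

# all maximal start-to-stop ORFs by walking every codon of all 6 frames
oracle_orfs <- function(seq, min_aa) {
  stops <- c("TAA", "TAG", "TGA")
  n <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else {
      as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    }
    for (fr in 0:2) {
      starts <- seq.int(fr + 1L, n, by = 3L)
      starts <- starts[starts + 2L <= n]
      if (length(starts) == 0L) next
      codons <- substring(s, starts, starts + 2L)
      last_stop <- 0L
      for (i in seq_along(codons)) {
        if (codons[i] %in% stops) {
          last_stop <- i
          next
        }
        if (codons[i] == "ATG") {
          prev <- if (last_stop + 1L <= i - 1L)
            codons[(last_stop + 1L):(i - 1L)] else character(0)
          if (!("ATG" %in% prev)) {   # maximal: first ATG after previous stop
            j <- i
            while (j <= length(codons) && !(codons[j] %in% stops)) j <- j + 1L
            complete <- j <= length(codons)
            cds <- (j - i) * 3L
            if (cds / 3L >= min_aa) {
              st <- starts[i] - 1L
              en <- st + cds + if (complete) 3L else 0L
              if (strand == "-") {
                tmp <- n - en
                en <- n - st
                st <- tmp
              }
              out[[length(out) + 1L]] <- data.frame(
                start = st, end = en, strand = strand,
                cds_length_nt = cds, complete = complete
              )
            }
          }
        }
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character(), cds_length_nt = integer(),
                      complete = logical()))
  }
  d <- do.call(rbind, out)
  d <- d[order(d$start, d$end, d$strand), ]
  rownames(d) <- NULL
  d
}

# literal step-by-step TMM: reference by upper quartile, pairwise M/A on
# library-scaled counts, two-sided rank trims, precision-weighted mean,
# effective size factors rescaled to geometric mean 1
oracle_tmm <- function(counts) {
  lib <- colSums(counts)
  counts <- counts[apply(counts > 0, 1, any), , drop = FALSE]
  uq <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    uq[j] <- quantile(counts[, j], 0.75) / lib[j]
  }
  ref <- which.min(abs(uq - mean(uq)))
  nf <- numeric(ncol(counts))
  for (j in seq_len(ncol(counts))) {
    both <- counts[, j] > 0 & counts[, ref] > 0
    o <- counts[both, j]
    r <- counts[both, ref]
    m <- log2((o / lib[j]) / (r / lib[ref]))
    # same arithmetic form as the published recipe: algebraically equivalent
    # A formulations differ in the last float bit, which can flip the rank of
    # near-tied A-values across the trim boundary
    a <- (log2(o / lib[j]) + log2(r / lib[ref])) / 2
    w <- (lib[j] - o) / (lib[j] * o) + (lib[ref] - r) / (lib[ref] * r)
    if (max(abs(m)) < 1e-6) {
      nf[j] <- 1
      next
    }
    nn <- length(m)
    lo_m <- floor(nn * 0.3) + 1
    hi_m <- nn + 1 - lo_m
    lo_a <- floor(nn * 0.05) + 1
    hi_a <- nn + 1 - lo_a
    keep <- rank(m) >= lo_m & rank(m) <= hi_m &
      rank(a) >= lo_a & rank(a) <= hi_a
    nf[j] <- 2^(sum(m[keep] / w[keep]) / sum(1 / w[keep]))
  }
  nf <- nf / exp(mean(log(nf)))
  sf <- nf * lib
  sf / exp(mean(log(sf)))
}

# direct running-sum walk
oracle_es <- function(scores, set_ids, weight = 1) {
  ids <- names(scores)
  nh <- sum(ids %in% set_ids)
  n <- length(ids)
  denom <- sum(abs(scores[ids %in% set_ids])^weight)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (ids[i] %in% set_ids) {
      run <- run + abs(scores[i])^weight / denom
    } else {
      run <- run - 1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# exhaustive enumeration over the 2^k presence patterns
oracle_set_summary <- function(presence) {
  organs <- colnames(presence)
  k <- length(organs)
  rows <- list()
  for (size in seq_len(k)) {
    for (idx in utils::combn(k, size, simplify = FALSE)) {
      excl <- 0L
      shared <- 0L
      for (r in seq_len(nrow(presence))) {
        inset <- which(presence[r, ])
        if (setequal(inset, idx)) excl <- excl + 1L
        if (all(idx %in% inset)) shared <- shared + 1L
      }
      rows[[length(rows) + 1L]] <- data.frame(
        combo = paste(organs[idx], collapse = "+"),
        n_organs = size, exclusive = excl, shared = shared
      )
    }
  }
  d <- do.call(rbind, rows)
  rownames(d) <- NULL
  d
}

# small default-structured study shared by several test files
small_study <- function(seed = 11, n = 260, contaminants = 20) {
  generate_study(sim_config(n_transcripts = n, n_contaminants = contaminants,
                            seed = seed))
}

random_peptide <- function(n) {
  paste(sample(names(conmine:::AA_RESIDUE_MASS), n, replace = TRUE),
        collapse = "")
}
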