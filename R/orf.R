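# Open reading frame prediction, translation and peptide molecular weight.
#
# Coordinates are 0-based half-open on the input transcript throughout, for
# both strands; minus-strand ORFs report the interval they occupy on the
# forward sequence.

# Average (not monoisotopic) residue masses in daltons, as used for
# conventional protein size reporting in kDa.
AA_RESIDUE_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

#' Average molecular weight of a peptide
#'
#' Sums standard average residue masses and adds one water mass, reporting the
#' result in kilodaltons. This is the sequence-only weight used for the
#' molecular-weight window filter of the aminotransferase cascade and for
#' candidate-table reporting; no post-translational modification is assumed.
#'
#' @param peptide Single amino-acid string over the 20 standard residues.
#' @return Molecular weight in kDa.
#' @examples
#' peptide_mw("G")  # free glycine, 0.07507 kDa
#' @export
peptide_mw <- function(peptide) {
  stopifnot(is.character(peptide), length(peptide) == 1L)
  if (!nzchar(peptide)) stop("empty peptide")
  aa <- strsplit(peptide, "", fixed = TRUE)[[1]]
  m <- AA_RESIDUE_MASS[aa]
  if (anyNA(m)) {
    bad <- unique(aa[is.na(m)])
    stop("unknown residue(s): ", paste(bad, collapse = ", "))
  }
  (sum(m) + WATER_MASS) / 1000
}

#' Convert a coding-sequence length to residues
#'
#' The length convention is that the nucleotide size of a coding sequence
#' excludes the stop codon, so the peptide length is exactly nt/3.
#'
#' @param cds_length_nt Coding-sequence length in nucleotides (no stop codon).
#' @return Length in amino-acid residues.
#' @export
cds_len_to_aa_len <- function(cds_length_nt) {
  stopifnot(is.numeric(cds_length_nt))
  if (any(cds_length_nt %% 3 != 0)) {
    stop("cds length not divisible by 3")
  }
  as.integer(cds_length_nt / 3)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

.translate_cds <- function(seq) {
  # seq: nucleotide string whose length is a multiple of 3, no stop expected
  n <- nchar(seq)
  starts <- seq.int(1L, n, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  aa <- .codon_table()[codons]
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

.revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Scan one reading frame of `seq` (forward orientation) for maximal ORFs.
# Returns a data.frame of 0-based half-open coordinates on `seq`.
.scan_frame <- function(seq, frame, min_len_aa) {
  n <- nchar(seq)
  if (n - 2L < frame + 1L) return(NULL)
  starts <- seq.int(frame + 1L, n - 2L, by = 3L)
  codons <- substring(seq, starts, starts + 2L)
  is_stop <- codons %in% STOP_CODONS
  is_atg <- codons == "ATG"
  out <- list()
  # maximal ORF per stop segment: first ATG after the previous stop
  seg_start <- 1L
  bounds <- c(which(is_stop), length(codons) + 1L)
  for (b in bounds) {
    if (b > seg_start) {
      atg <- which(is_atg[seg_start:(b - 1L)])
      if (length(atg) > 0L) {
        i <- seg_start + atg[1L] - 1L          # codon index of ATG
        complete <- b <= length(codons)        # segment ended at a stop codon
        cds_nt <- (b - i) * 3L
        orf_start <- starts[i] - 1L            # 0-based
        orf_end <- orf_start + cds_nt + if (complete) 3L else 0L
        if (cds_nt / 3L >= min_len_aa) {
          out[[length(out) + 1L]] <- data.frame(
            start = orf_start, end = orf_end,
            cds_length_nt = cds_nt, complete = complete
          )
        }
      }
    }
    seg_start <- b + 1L
  }
  if (length(out) == 0L) NULL else do.call(rbind, out)
}

#' Find open reading frames on both strands
#'
#' Scans all six reading frames for maximal start-to-stop ORFs (first ATG
#' after the preceding stop). ORFs reaching the end of the sequence without a
#' stop codon are reported with `complete = FALSE`. Coordinates are 0-based
#' half-open intervals on the input transcript; minus-strand ORFs report the
#' interval they occupy on the forward sequence.
#'
#' @param id Transcript identifier.
#' @param sequence Nucleotide string over A, C, G, T, N.
#' @param min_len_aa Minimum peptide length in residues (start codon included).
#' @return `data.frame` with columns `transcript_id`, `start`, `end`, `strand`,
#'   `cds_length_nt`, `length_aa`, `complete`, `peptide`, `mw_kda`, sorted by
#'   decreasing CDS length.
#' @export
find_orfs <- function(id, sequence, min_len_aa = 100L) {
  stopifnot(min_len_aa >= 1L)
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence of '", id, "' contains characters outside {A,C,G,T,N}")
  }
  n <- nchar(sequence)
  res <- list()
  if (n >= 3L) {
    for (fr in 0:2) {
      d <- .scan_frame(sequence, fr, min_len_aa)
      if (!is.null(d)) {
        d$strand <- "+"
        res[[length(res) + 1L]] <- d
      }
    }
    rc <- .revcomp(sequence)
    for (fr in 0:2) {
      d <- .scan_frame(rc, fr, min_len_aa)
      if (!is.null(d)) {
        # mirror coordinates back onto the forward sequence
        s <- n - d$end
        e <- n - d$start
        d$start <- s
        d$end <- e
        d$strand <- "-"
        res[[length(res) + 1L]] <- d
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(
      transcript_id = character(), start = integer(), end = integer(),
      strand = character(), cds_length_nt = integer(), length_aa = integer(),
      complete = logical(), peptide = character(), mw_kda = numeric()
    ))
  }
  d <- do.call(rbind, res)
  d$transcript_id <- id
  # translate each ORF
  seqs <- ifelse(
    d$strand == "+",
    substring(sequence, d$start + 1L, d$start + d$cds_length_nt),
    NA_character_
  )
  for (i in which(d$strand == "-")) {
    seqs[i] <- substring(
      .revcomp(substring(sequence, d$start[i] + 1L, d$end[i])),
      1L, d$cds_length_nt[i]
    )
  }
  d$peptide <- vapply(seqs, .translate_cds, character(1), USE.NAMES = FALSE)
  d$length_aa <- as.integer(d$cds_length_nt / 3L)
  d$mw_kda <- vapply(d$peptide, function(p) {
    if (grepl("X", p, fixed = TRUE)) NA_real_ else peptide_mw(p)
  }, numeric(1), USE.NAMES = FALSE)
  d <- d[order(-d$cds_length_nt, d$start, d$strand), , drop = FALSE]
  rownames(d) <- NULL
  d[, c("transcript_id", "start", "end", "strand", "cds_length_nt",
        "length_aa", "complete", "peptide", "mw_kda")]
}

#' Representative peptides for a transcript set
#'
#' Runs [find_orfs()] on every transcript and marks the longest ORF of each as
#' its representative peptide (ties broken by start coordinate, then strand).
#' Other ORFs are retained with `representative = FALSE`.
#'
#' @param transcripts Named character vector of nucleotide sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param min_len_aa Minimum peptide length in residues.
#' @return `data.frame` as from [find_orfs()] with a `representative` column.
#' @export
predict_peptides <- function(transcripts, min_len_aa = 50L) {
  if (methods::is(transcripts, "DNAStringSet")) {
    transcripts <- as.character(transcripts)
  }
  stopifnot(!is.null(names(transcripts)), !anyDuplicated(names(transcripts)))
  per <- lapply(names(transcripts), function(id) {
    d <- find_orfs(id, transcripts[[id]], min_len_aa = min_len_aa)
    if (nrow(d) > 0L) {
      d$representative <- seq_len(nrow(d)) == 1L
    } else {
      d$representative <- logical(0)
    }
    d
  })
  out <- do.call(rbind, per)
  rownames(out) <- NULL
  out
}

#' Representative-peptide summary table
#'
#' One row per transcript with an ORF: the representative (longest) ORF with
#' its peptide, residue length and molecular weight.
#'
#' @param peptides Output of [predict_peptides()].
#' @return `data.frame`, one row per transcript.
#' @export
representative_peptides <- function(peptides) {
  out <- peptides[peptides$representative, , drop = FALSE]
  rownames(out) <- NULL
  out
}
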