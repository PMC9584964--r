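# Annotation evidence filtering, integration and decontamination.
#
# Three evidence streams feed the integrated annotation: protein alignment
# hits (identity/coverage thresholds, both inclusive), protein-family domain
# hits (strict E-value bound) and functional-classifier predictions (PPV floor
# plus a per-ORF relative cutoff). Taxonomy rides on the alignment hits as a
# lineage string and drives decontamination.

#' Filter protein alignment hits by identity and query coverage
#'
#' Keeps hits with percent identity >= `min_identity` and alignment
#' length / query length >= `min_coverage`; both bounds inclusive. The
#' coverage denominator is the query protein length.
#'
#' @param hits `data.frame` with columns `qseqid`, `sseqid`, `pident`,
#'   `length` (alignment length, aa), `evalue`, `qlen` and optionally
#'   `stitle`, `lineage`.
#' @param min_identity Minimum percent identity (0-100), inclusive.
#' @param min_coverage Minimum query coverage (0-1), inclusive.
#' @return Filtered `data.frame`, same columns.
#' @export
filter_blast <- function(hits, min_identity = 80, min_coverage = 0.5) {
  need <- c("qseqid", "pident", "length", "qlen")
  missing_cols <- setdiff(need, names(hits))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (anyNA(hits$qlen)) stop("query length missing for some hits")
  keep <- hits$pident >= min_identity &
    hits$length / hits$qlen >= min_coverage
  out <- hits[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter protein-domain hits by domain E-value
#'
#' Keeps hits with a domain E-value strictly below `max_evalue`.
#'
#' @param hits `data.frame` with columns `qseqid`, `pfam_acc`, `evalue` and
#'   optionally `description`.
#' @param max_evalue Strict upper bound on the domain E-value.
#' @return Filtered `data.frame`.
#' @export
filter_hmm <- function(hits, max_evalue = 1e-20) {
  stopifnot(all(c("qseqid", "pfam_acc", "evalue") %in% names(hits)))
  if (any(hits$evalue < 0)) stop("negative E-value")
  out <- hits[hits$evalue < max_evalue, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Screen classifier predictions by PPV
#'
#' Two-stage screen within each ORF: predictions with PPV below `floor` are
#' dropped, then predictions with PPV below `rel` times the maximum PPV of the
#' ORF's surviving predictions are dropped. Both bounds inclusive.
#'
#' @param preds `data.frame` with columns `qseqid`, `description`, `go_terms`,
#'   `ec` (possibly empty strings), `ppv`.
#' @param floor PPV floor, inclusive.
#' @param rel Relative cutoff as a fraction of the per-ORF maximum PPV.
#' @return Filtered `data.frame`.
#' @export
screen_pannzer <- function(preds, floor = 0.5, rel = 0.9) {
  stopifnot(all(c("qseqid", "ppv") %in% names(preds)))
  stopifnot(all(preds$ppv >= 0 & preds$ppv <= 1))
  out <- preds[preds$ppv >= floor, , drop = FALSE]
  if (nrow(out) > 0L) {
    mx <- stats::ave(out$ppv, out$qseqid, FUN = max)
    out <- out[out$ppv >= rel * mx, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

KINGDOM_MAP <- c(
  Bacteria = "Bacteria", Opisthokonta = "Opisthokonta",
  Fungi = "Opisthokonta", Metazoa = "Opisthokonta", Animalia = "Opisthokonta",
  Viridiplantae = "Viridiplantae"
)

#' Resolve a lineage string to a kingdom-level label
#'
#' The first recognized lineage token decides the label (Bacteria,
#' Opisthokonta -- covering fungi and animals -- or Viridiplantae).
#' Unrecognized or empty lineages yield `NA`, which counts as no taxonomic
#' evidence downstream.
#'
#' @param lineage Character vector of semicolon-separated lineage strings.
#' @return Character vector of kingdom labels or `NA`.
#' @export
resolve_kingdom <- function(lineage) {
  vapply(lineage, function(x) {
    if (is.na(x) || !nzchar(x)) return(NA_character_)
    toks <- trimws(strsplit(x, ";", fixed = TRUE)[[1]])
    hit <- KINGDOM_MAP[toks]
    hit <- hit[!is.na(hit)]
    if (length(hit) == 0L) NA_character_ else hit[[1L]]
  }, character(1), USE.NAMES = FALSE)
}

.collapse <- function(x) {
  x <- unique(unlist(strsplit(x[!is.na(x) & nzchar(x)], ";", fixed = TRUE)))
  x <- trimws(x)
  x <- sort(x[nzchar(x)])
  paste(x, collapse = ";")
}

#' Integrate filtered annotation evidence per transcript
#'
#' Merges the three (already filtered) evidence streams to one row per
#' transcript with GO/EC/PFAM unions, best-hit taxonomy, the set of kingdoms
#' observed across taxon-bearing hits, and an `annotated` flag that is true
#' iff at least one stream contributed. EC numbers with all four fields
#' determined are collected separately in `ec_full`.
#'
#' @param blast Output of [filter_blast()].
#' @param hmm Output of [filter_hmm()].
#' @param pannzer Output of [screen_pannzer()]; `qseqid` may be ORF ids.
#' @param orf_map Optional `data.frame` with columns `orf_id`,
#'   `transcript_id` lifting ORF-level predictions to their transcript; ids
#'   already at transcript level pass through.
#' @param transcript_ids Optional character vector giving the full transcript
#'   universe, so transcripts with no surviving evidence appear with
#'   `annotated = FALSE`.
#' @return `data.frame` with one row per transcript: `transcript_id`,
#'   `annotated`, `go_terms`, `ec_numbers`, `ec_full`, `pfam_accs`,
#'   `kingdoms`, `best_hit_kingdom`, `description`.
#' @export
integrate_annotations <- function(blast, hmm, pannzer, orf_map = NULL,
                                  transcript_ids = NULL) {
  pz <- pannzer
  if (!is.null(orf_map) && nrow(pz) > 0L) {
    idx <- match(pz$qseqid, orf_map$orf_id)
    pz$qseqid <- ifelse(is.na(idx), pz$qseqid, orf_map$transcript_id[idx])
  }
  ids <- unique(c(blast$qseqid, hmm$qseqid, pz$qseqid, transcript_ids))
  if (anyDuplicated(transcript_ids)) stop("duplicate transcript ids")
  ids <- sort(ids)
  if (!"lineage" %in% names(blast)) blast$lineage <- NA_character_
  blast$kingdom <- resolve_kingdom(blast$lineage)

  rows <- lapply(ids, function(id) {
    b <- blast[blast$qseqid == id, , drop = FALSE]
    h <- hmm[hmm$qseqid == id, , drop = FALSE]
    p <- pz[pz$qseqid == id, , drop = FALSE]
    ecs <- .collapse(p$ec)
    ec_vec <- strsplit(ecs, ";", fixed = TRUE)[[1]]
    full <- ec_vec[vapply(ec_vec, function(e) {
      parts <- strsplit(e, ".", fixed = TRUE)[[1]]
      length(parts) == 4L && !any(parts %in% c("-", ""))
    }, logical(1))]
    king <- b$kingdom[!is.na(b$kingdom)]
    best <- if (nrow(b) > 0L) {
      bk <- b$kingdom[order(b$evalue)]
      bk <- bk[!is.na(bk)]
      if (length(bk) > 0L) bk[[1L]] else NA_character_
    } else NA_character_
    desc <- c(
      if (nrow(p) > 0L && "description" %in% names(p)) p$description,
      if (nrow(b) > 0L && "stitle" %in% names(b)) b$stitle
    )
    desc <- desc[!is.na(desc) & nzchar(desc)]
    data.frame(
      transcript_id = id,
      annotated = nrow(b) + nrow(h) + nrow(p) > 0L,
      go_terms = if (nrow(p) > 0L && "go_terms" %in% names(p))
        .collapse(p$go_terms) else "",
      ec_numbers = ecs,
      ec_full = paste(full, collapse = ";"),
      pfam_accs = .collapse(h$pfam_acc),
      kingdoms = paste(sort(unique(king)), collapse = ";"),
      best_hit_kingdom = best,
      description = if (length(desc) > 0L) desc[[1L]] else ""
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Remove transcripts of non-plant origin
#'
#' A transcript is removed iff it has at least one taxon-bearing annotation
#' and every taxon-bearing annotation is Bacteria or Opisthokonta (fungi and
#' animals). Transcripts with no taxonomic evidence are kept.
#'
#' @param ann Output of [integrate_annotations()].
#' @return List with character vectors `kept` and `removed`.
#' @export
decontaminate <- function(ann) {
  kings <- strsplit(ann$kingdoms, ";", fixed = TRUE)
  removed <- vapply(kings, function(k) {
    k <- k[nzchar(k)]
    length(k) > 0L && all(k %in% c("Bacteria", "Opisthokonta"))
  }, logical(1))
  list(kept = ann$transcript_id[!removed], removed = ann$transcript_id[removed])
}

# ---- readers / writers -----------------------------------------------------

#' Read a tabular protein-alignment hit file
#'
#' Tab-separated with a header; expects at least `qseqid`, `sseqid`,
#' `pident`, `length`, `evalue`, `qlen`, optionally `stitle` and `lineage`.
#'
#' @param path File path.
#' @return `data.frame` of hits.
#' @export
read_blast_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a per-domain hit table
#' @param path File path.
#' @return `data.frame` with `qseqid`, `pfam_acc`, `evalue`, `description`.
#' @export
read_hmm_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Read a classifier prediction table
#' @param path File path.
#' @return `data.frame` with `qseqid`, `description`, `go_terms`, `ec`, `ppv`.
#' @export
read_pannzer_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
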