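# Declarative per-enzyme filter cascades for pathway candidate mining.
#
# Each enzyme of the coniine pathway without a known sequence (PKR, AAT, CR,
# CSAM) is mined by a cascade over an initial seed set (protein-family match
# and/or homology-search union): co-expression with the pathway entry enzyme
# (presence in flower and developing fruit), a molecular-weight window on the
# representative peptide, a cofactor requirement, and an EC-class filter. The
# entry enzyme itself (CPKS5, the one with a known sequence) is selected by
# Pareto dominance on (identity, alignment length) of its homology hits.

#' Declarative enzyme cascade specification
#'
#' @param label Enzyme label.
#' @param bait_ids Optional bait sequence identifiers (homology seeding).
#' @param pfam Optional PFAM accession set seeding the initial candidate set.
#' @param organs Organs in which candidates must be expressed.
#' @param mw_range Optional inclusive molecular-weight window in kDa.
#' @param cofactor Cofactor requirement: `"any"`, `"NADPH-only"` (NADPH
#'   strictly) or `"NADPH-or-both"` (NADPH or NADPH/NADH; NADH-only
#'   excluded).
#' @param ec_prefix Optional EC prefix; any annotated EC matching it passes.
#' @param ec_whitelist Optional exact EC whitelist (alternative to prefix).
#' @param alt_pfam_pass Optional PFAM accessions giving an alternate pass of
#'   the EC stage (dual admission route).
#' @param min_profile_cor Optional Pearson-correlation cutoff against a
#'   reference organ expression profile; off (`NULL`) by default.
#' @return Object of class `enzyme_seed_spec`.
#' @export
enzyme_seed_spec <- function(label, bait_ids = NULL, pfam = NULL,
                             organs = c("flower", "fruit"), mw_range = NULL,
                             cofactor = c("any", "NADPH-only",
                                          "NADPH-or-both"),
                             ec_prefix = NULL, ec_whitelist = NULL,
                             alt_pfam_pass = NULL, min_profile_cor = NULL) {
  cofactor <- match.arg(cofactor)
  if (is.null(bait_ids) && is.null(pfam)) {
    stop("spec needs bait sequences and/or a PFAM accession set")
  }
  if (!is.null(mw_range)) {
    stopifnot(length(mw_range) == 2L, mw_range[1] <= mw_range[2])
  }
  structure(
    list(label = label, bait_ids = bait_ids, pfam = pfam, organs = organs,
         mw_range = mw_range, cofactor = cofactor, ec_prefix = ec_prefix,
         ec_whitelist = ec_whitelist, alt_pfam_pass = alt_pfam_pass,
         min_profile_cor = min_profile_cor),
    class = "enzyme_seed_spec"
  )
}

#' Default cascade presets for the five pathway enzymes
#'
#' CPKS5 is homology-seeded (Pareto selection over hits of the known
#' sequence); PKR is seeded by the ketoreductase KR domain; AAT by the three
#' aminotransferase families with a 45-65 kDa window and an
#' alanine-aminotransferase EC whitelist (class-III family membership as the
#' alternate route); CR by the NAD(P)H-oxidoreductase families with an
#' NADPH/NADPH-NADH cofactor requirement and EC 1.3.1; CSAM by the
#' SAM-dependent carboxyl methyltransferase family and EC 2.1.1.49.
#'
#' @return Named list of [enzyme_seed_spec()] objects.
#' @export
default_enzyme_specs <- function() {
  list(
    cpks5 = enzyme_seed_spec("cpks5", bait_ids = "CPKS5"),
    pkr = enzyme_seed_spec("pkr", pfam = "PF08659"),
    aat = enzyme_seed_spec(
      "aat", pfam = c("PF00155", "PF00202", "PF00266"),
      mw_range = c(45, 65),
      ec_whitelist = c("2.6.1.2", "2.6.1.4", "2.6.1.12", "2.6.1.44"),
      alt_pfam_pass = "PF00202"
    ),
    cr = enzyme_seed_spec(
      "cr", pfam = c("PF00106", "PF08659", "PF13561"),
      cofactor = "NADPH-or-both", ec_prefix = "1.3.1"
    ),
    csam = enzyme_seed_spec("csam", pfam = "PF03492",
                            ec_prefix = "2.1.1.49")
  )
}

#' Pareto-optimal homology candidates
#'
#' Returns the hits not dominated in (percent identity, alignment length):
#' the candidates in the top-right corner of the identity-vs-length scatter.
#' A hit is dominated if another hit is at least as good on both axes and
#' strictly better on one.
#'
#' @param hits `data.frame` with `pident` and `length` columns plus an id
#'   column.
#' @param id_col Name of the column holding the candidate transcript id.
#' @return The Pareto-optimal rows, ordered by alignment length then identity
#'   (both descending).
#' @export
select_pks_candidates <- function(hits, id_col = "sseqid") {
  if (nrow(hits) == 0L) {
    warning("empty hit list")
    return(hits)
  }
  dominated <- vapply(seq_len(nrow(hits)), function(i) {
    any(hits$pident >= hits$pident[i] & hits$length >= hits$length[i] &
          (hits$pident > hits$pident[i] | hits$length > hits$length[i]))
  }, logical(1))
  out <- hits[!dominated, , drop = FALSE]
  out <- out[order(-out$length, -out$pident), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Union of homology and protein-family search results
#'
#' The initial candidate list of a cascade is the union of the transcripts
#' found by the two homology searches and the protein-family search, with
#' per-id provenance flags recording which searches found it.
#'
#' @param blast_uniprot,blast_pdb,hmm_ids Character vectors of transcript ids
#'   found by each (pre-filtered) search.
#' @return `data.frame` with `transcript_id` and logical provenance columns
#'   `in_blast_uniprot`, `in_blast_pdb`, `in_hmm`.
#' @export
search_union <- function(blast_uniprot, blast_pdb, hmm_ids) {
  ids <- sort(unique(c(blast_uniprot, blast_pdb, hmm_ids)))
  data.frame(
    transcript_id = ids,
    in_blast_uniprot = ids %in% blast_uniprot,
    in_blast_pdb = ids %in% blast_pdb,
    in_hmm = ids %in% hmm_ids
  )
}

.ec_matches_prefix <- function(ecs, prefix) {
  pf <- strsplit(prefix, ".", fixed = TRUE)[[1]]
  vapply(ecs, function(e) {
    f <- strsplit(e, ".", fixed = TRUE)[[1]]
    length(f) >= length(pf) && all(f[seq_along(pf)] == pf)
  }, logical(1))
}

.split_field <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

#' Apply an enzyme filter cascade
#'
#' Stages, in canonical order: (1) initial seed set (PFAM accession match on
#' the integrated annotation, united with any `initial` ids, e.g. from
#' [search_union()]); (2) expression -- present in every organ the spec
#' requires; (3) molecular-weight window on the representative peptide,
#' inclusive; (4) cofactor requirement on supplied cofactor labels; (5)
#' EC-class filter (prefix or whitelist, with an optional alternate
#' protein-family pass). Stage membership is evaluated independently, so the
#' surviving set does not depend on stage order; the audit trail and
#' stage-wise survivor counts report the canonical order.
#'
#' @param spec An [enzyme_seed_spec()].
#' @param ann Integrated annotation table ([integrate_annotations()]).
#' @param peptides Representative peptide table
#'   ([representative_peptides()]).
#' @param presence Output of [organ_presence()].
#' @param cofactor_labels Named character vector transcript ->
#'   `"NADPH"`, `"NADPH/NADH"` or `"NADH"`; cofactors are pipeline inputs,
#'   never predicted here.
#' @param initial Optional extra seed transcript ids.
#' @param reference_profile Optional named numeric organ profile for the
#'   correlation criterion (used only when the spec sets
#'   `min_profile_cor`).
#' @return List with `candidates` (Table-1-like rows, identical peptides
#'   merged), `audit` (per-transcript stage passes), and `stage_counts`
#'   (survivors after each canonical stage).
#' @export
apply_cascade <- function(spec, ann, peptides, presence,
                          cofactor_labels = NULL, initial = NULL,
                          reference_profile = NULL) {
  stopifnot(inherits(spec, "enzyme_seed_spec"))
  pres <- presence$presence
  if (!all(spec$organs %in% colnames(pres))) {
    stop("spec requires organs absent from the presence calls: ",
         paste(setdiff(spec$organs, colnames(pres)), collapse = ", "))
  }
  pfams <- lapply(ann$pfam_accs, .split_field)
  names(pfams) <- ann$transcript_id
  ecs <- lapply(ann$ec_numbers, .split_field)
  names(ecs) <- ann$transcript_id

  seed_ids <- character(0)
  if (!is.null(spec$pfam)) {
    hit <- vapply(pfams, function(p) any(p %in% spec$pfam), logical(1))
    seed_ids <- ann$transcript_id[hit]
  }
  seed_ids <- sort(unique(c(seed_ids, initial)))

  pass_expr <- function(id) {
    id %in% rownames(pres) && all(pres[id, spec$organs])
  }
  pass_mw <- function(id) {
    if (is.null(spec$mw_range)) return(TRUE)
    i <- match(id, peptides$transcript_id)
    !is.na(i) && !is.na(peptides$mw_kda[i]) &&
      peptides$mw_kda[i] >= spec$mw_range[1] &&
      peptides$mw_kda[i] <= spec$mw_range[2]
  }
  pass_cof <- function(id) {
    if (spec$cofactor == "any") return(TRUE)
    lab <- cofactor_labels[id]
    if (is.null(lab) || is.na(lab)) return(FALSE)
    if (spec$cofactor == "NADPH-only") lab == "NADPH"
    else lab %in% c("NADPH", "NADPH/NADH")
  }
  pass_ec <- function(id) {
    if (is.null(spec$ec_prefix) && is.null(spec$ec_whitelist) &&
        is.null(spec$alt_pfam_pass)) return(TRUE)
    e <- ecs[[id]]
    ok <- FALSE
    if (!is.null(spec$ec_prefix) && length(e) > 0L) {
      ok <- ok || any(.ec_matches_prefix(e, spec$ec_prefix))
    }
    if (!is.null(spec$ec_whitelist)) ok <- ok || any(e %in% spec$ec_whitelist)
    if (!is.null(spec$alt_pfam_pass)) {
      ok <- ok || any(pfams[[id]] %in% spec$alt_pfam_pass)
    }
    ok
  }
  pass_cor <- function(id) {
    if (is.null(spec$min_profile_cor)) return(TRUE)
    if (is.null(reference_profile)) stop("correlation cutoff set but no ",
                                         "reference profile supplied")
    prof <- presence$organ_means[id, names(reference_profile)]
    stats::cor(prof, reference_profile) >= spec$min_profile_cor
  }

  audit <- data.frame(
    transcript_id = seed_ids,
    seed = TRUE,
    expression = vapply(seed_ids, pass_expr, logical(1)),
    mw = vapply(seed_ids, pass_mw, logical(1)),
    cofactor = vapply(seed_ids, pass_cof, logical(1)),
    ec = vapply(seed_ids, pass_ec, logical(1)),
    profile_cor = vapply(seed_ids, pass_cor, logical(1))
  )
  stage_cols <- c("seed", "expression", "mw", "cofactor", "ec", "profile_cor")
  cum <- rep(TRUE, nrow(audit))
  stage_counts <- integer(length(stage_cols))
  names(stage_counts) <- stage_cols
  for (i in seq_along(stage_cols)) {
    cum <- cum & audit[[stage_cols[i]]]
    stage_counts[i] <- sum(cum)
  }
  audit$final <- cum
  survivors <- audit$transcript_id[audit$final]

  cand <- data.frame(
    enzyme = character(0), transcript_id = character(0), ec = character(0),
    pfam = character(0), cds_length_nt = integer(0), length_aa = integer(0),
    mw_kda = numeric(0)
  )
  if (length(survivors) > 0L) {
    i <- match(survivors, peptides$transcript_id)
    pep_seq <- ifelse(is.na(i), survivors, peptides$peptide[i])
    rows <- lapply(split(seq_along(survivors), pep_seq), function(grp) {
      ids <- sort(survivors[grp])
      j <- match(ids[1], peptides$transcript_id)
      data.frame(
        enzyme = spec$label,
        transcript_id = paste(ids, collapse = "/"),
        ec = paste(sort(unique(unlist(ecs[ids]))), collapse = ";"),
        pfam = paste(sort(unique(unlist(pfams[ids]))), collapse = ";"),
        cds_length_nt = if (is.na(j)) NA_integer_
                        else peptides$cds_length_nt[j],
        length_aa = if (is.na(j)) NA_integer_ else peptides$length_aa[j],
        mw_kda = if (is.na(j)) NA_real_ else peptides$mw_kda[j]
      )
    })
    cand <- do.call(rbind, rows)
    cand <- cand[order(cand$transcript_id), , drop = FALSE]
    rownames(cand) <- NULL
  }
  list(candidates = cand, audit = audit, stage_counts = stage_counts)
}

#' Cross-species shared protein-family counts
#'
#' For each (bacterial seed gene, PFAM accession) pair, counts the distinct
#' transcripts whose accepted domain set contains that accession -- the
#' cross-species seeding table matching plant transcripts to the bacterial
#' koreenceine pathway genes by shared PFAM domains.
#'
#' @param seeds `data.frame` with columns `gene` and `pfam` (one row per
#'   pair); see [default_kec_seeds()].
#' @param ann Integrated annotation table.
#' @return `data.frame` with `gene`, `pfam`, `n_transcripts`.
#' @export
shared_pfam_counts <- function(seeds, ann) {
  pfams <- lapply(ann$pfam_accs, .split_field)
  seeds$n_transcripts <- vapply(seeds$pfam, function(acc) {
    sum(vapply(pfams, function(p) acc %in% p, logical(1)))
  }, integer(1))
  rownames(seeds) <- NULL
  seeds
}

#' Koreenceine pathway seed domains
#'
#' The bacterial analog pathway genes and their PFAM domains used for
#' cross-species seeding: the transaminase kecF carries the class-III
#' aminotransferase domain; the ketoreductase kecG and the NAD(P)H
#' oxidoreductase kecH carry the short-chain dehydrogenase, KR-domain and
#' enoyl-reductase families.
#'
#' @return `data.frame` with columns `gene`, `pfam`.
#' @export
default_kec_seeds <- function() {
  data.frame(
    gene = c("kecF", "kecG", "kecG", "kecG", "kecH", "kecH", "kecH"),
    pfam = c("PF00202", "PF00106", "PF08659", "PF13561",
             "PF00106", "PF08659", "PF13561")
  )
}

#' Read enzyme cascade specs from a YAML file
#'
#' @param path YAML file: a mapping of enzyme label to the fields of
#'   [enzyme_seed_spec()].
#' @return Named list of `enzyme_seed_spec` objects.
#' @export
read_enzyme_specs <- function(path) {
  raw <- yaml::read_yaml(path)
  out <- lapply(names(raw), function(nm) {
    args <- raw[[nm]]
    args$label <- nm
    if (!is.null(args$mw_range)) args$mw_range <- as.numeric(args$mw_range)
    do.call(enzyme_seed_spec, args)
  })
  names(out) <- names(raw)
  out
}
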