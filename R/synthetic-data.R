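# Synthetic transcriptome study generator with planted ground truth.
#
# The generator emulates the study design the pipeline is built for: five
# organs in two replicates, a transcript population with organ-structured
# expression, a contaminant fraction carrying non-plant best-hit taxonomy,
# and, per enzyme family, planted pathway candidates that satisfy every
# criterion of their family's cascade plus near-miss decoys that each violate
# exactly one criterion. All outputs are deterministic for a fixed seed.

FAMILY_PARAMS <- list(
  cpks5 = list(criteria = "dominated", aa_len = c(390, 400)),
  pkr   = list(criteria = c("domain", "expression"),
               pfam = "PF08659", ec = "1.1.1.100", wrong_ec = "1.1.1.1",
               aa_len = c(300, 340)),
  aat   = list(criteria = c("domain", "expression", "mw", "ec"),
               pfam = "PF00155", ec = "2.6.1.2", wrong_ec = "2.6.1.1",
               aa_len = c(470, 510), mw_violation_aa = 360),
  cr    = list(criteria = c("domain", "expression", "cofactor", "ec"),
               pfam = "PF00106", ec = "1.3.1.33", wrong_ec = "1.1.1.1",
               aa_len = c(280, 320)),
  csam  = list(criteria = c("domain", "expression", "ec"),
               pfam = "PF03492", ec = "2.1.1.49", wrong_ec = "2.1.1.6",
               aa_len = c(200, 260))
)

# accessions never used for background transcripts, so planted recovery has
# an unambiguous truth
RESERVED_PFAMS <- c("PF08659", "PF00155", "PF00202", "PF00266",
                    "PF00106", "PF13561", "PF03492")
BACKGROUND_PFAMS <- sprintf("PF9%04d", 1:15)
BACKGROUND_GOS <- sprintf("GO:00000%02d", 1:25)

#' Configuration of a synthetic transcriptome study
#'
#' @param n_transcripts Total number of transcripts, including contaminants,
#'   planted candidates and decoys.
#' @param n_contaminants Number of transcripts with exclusively non-plant
#'   best-hit taxonomy.
#' @param organs Organ labels.
#' @param replicates_per_organ Replicate samples per organ.
#' @param planted_specs Named integer vector: planted candidates per enzyme
#'   family (families: cpks5, pkr, aat, cr, csam).
#' @param decoys_per_family Single-violation decoys per family.
#' @param decoy_rule Assignment of violated criteria to decoys; `"cycle"`
#'   cycles through the family's applicable criteria.
#' @param length_range Nucleotide-length interval for background transcripts.
#' @param dispersion Negative-binomial dispersion of the counts.
#' @param seed Random seed; all outputs are reproducible given it.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 1000L, n_contaminants = 50L,
                       organs = c("root", "stem", "leaf", "flower", "fruit"),
                       replicates_per_organ = 2L,
                       planted_specs = c(cpks5 = 3L, pkr = 3L, aat = 3L,
                                         cr = 3L, csam = 3L),
                       decoys_per_family = 3L, decoy_rule = "cycle",
                       length_range = c(300L, 2000L), dispersion = 0.3,
                       seed = 1L) {
  if (length(organs) == 0L) stop("organs must be non-empty")
  if (n_transcripts <= 0L) stop("n_transcripts must be positive")
  if (n_contaminants < 0L || n_contaminants > n_transcripts) {
    stop("n_contaminants must be in [0, n_transcripts]")
  }
  if (replicates_per_organ <= 0L) stop("replicates_per_organ must be positive")
  if (any(planted_specs < 0L) || decoys_per_family < 0L) {
    stop("planted and decoy counts must be non-negative")
  }
  if (!all(names(planted_specs) %in% names(FAMILY_PARAMS))) {
    stop("unknown enzyme family in planted_specs")
  }
  if (length_range[1] < 60L || length_range[2] < length_range[1]) {
    stop("invalid length_range")
  }
  n_special <- sum(planted_specs) +
    decoys_per_family * length(planted_specs) + n_contaminants
  if (n_special > n_transcripts) {
    stop("n_transcripts too small for the planted/decoy/contaminant layout")
  }
  structure(
    list(n_transcripts = as.integer(n_transcripts),
         n_contaminants = as.integer(n_contaminants), organs = organs,
         replicates_per_organ = as.integer(replicates_per_organ),
         planted_specs = planted_specs,
         decoys_per_family = as.integer(decoys_per_family),
         decoy_rule = decoy_rule, length_range = as.integer(length_range),
         dispersion = dispersion, seed = as.integer(seed)),
    class = "sim_config"
  )
}

.random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

.sense_codons <- function() {
  bases <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  setdiff(all64, STOP_CODONS)
}

# Transcript carrying a designed CDS of n_aa residues (ATG..sense..TAA) with
# short random UTRs.
.designed_transcript <- function(n_aa) {
  cds <- paste0("ATG",
                paste(sample(.sense_codons(), n_aa - 1L, replace = TRUE),
                      collapse = ""),
                "TAA")
  paste0(.random_dna(sample(30:80, 1)), cds, .random_dna(sample(30:80, 1)))
}

.viridiplantae_lineage <- "Eukaryota; Viridiplantae; Streptophyta"
.contaminant_lineages <- c(
  "Bacteria; Pseudomonadota; Gammaproteobacteria",
  "Bacteria; Bacillota; Bacilli",
  "Eukaryota; Opisthokonta; Fungi; Ascomycota",
  "Eukaryota; Opisthokonta; Metazoa; Arthropoda"
)

#' Generate a synthetic transcriptome study
#'
#' Produces sequences, the three annotation evidence tables (in the dialects
#' the readers accept), cofactor labels, homology hits of the known pathway
#' entry enzyme against the transcripts, an organ-by-replicate count matrix,
#' and a ground-truth table assigning every transcript exactly one role:
#' pathway candidate (per family), decoy with its violated criterion,
#' contaminant with its lineage, or background. Planted candidates satisfy
#' every criterion of their family's cascade and are expressed in flower and
#' fruit; each decoy fails exactly its assigned criterion.
#'
#' @param config A [sim_config()].
#' @param dir Optional directory; when given, all outputs are also written as
#'   plain-text files (FASTA, tab-separated tables, JSON truth).
#' @return List with `transcripts` (named character), `lengths`, `blast`,
#'   `hmm`, `pannzer`, `cofactors`, `cpks5_hits`, `counts`,
#'   `sample_organs`, `truth`, `config`.
#' @export
generate_study <- function(config, dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  fams <- names(config$planted_specs)
  n_planted <- sum(config$planted_specs)
  n_decoy <- config$decoys_per_family * length(fams)
  n_bg <- config$n_transcripts - n_planted - n_decoy - config$n_contaminants

  ids <- sprintf("TRINITY_DN%05d_c0_g1_i1", seq_len(config$n_transcripts))
  roles <- data.frame(
    transcript_id = ids, role = "background", family = NA_character_,
    violated = NA_character_, lineage = NA_character_
  )
  # layout: planted, decoys, contaminants, background
  at <- 0L
  plan <- list()
  for (f in fams) {
    k <- config$planted_specs[[f]]
    if (k > 0L) {
      idx <- at + seq_len(k)
      roles$role[idx] <- "candidate"
      roles$family[idx] <- f
      at <- at + k
    }
  }
  for (f in fams) {
    crit <- FAMILY_PARAMS[[f]]$criteria
    for (j in seq_len(config$decoys_per_family)) {
      at <- at + 1L
      roles$role[at] <- "decoy"
      roles$family[at] <- f
      roles$violated[at] <- crit[((j - 1L) %% length(crit)) + 1L]
    }
  }
  if (config$n_contaminants > 0L) {
    idx <- at + seq_len(config$n_contaminants)
    roles$role[idx] <- "contaminant"
    roles$lineage[idx] <- sample(.contaminant_lineages,
                                 config$n_contaminants, replace = TRUE)
    at <- at + config$n_contaminants
  }

  # ---- sequences -----------------------------------------------------------
  transcripts <- character(config$n_transcripts)
  names(transcripts) <- ids
  for (i in seq_len(config$n_transcripts)) {
    if (roles$role[i] %in% c("candidate", "decoy")) {
      fp <- FAMILY_PARAMS[[roles$family[i]]]
      n_aa <- if (identical(roles$violated[i], "mw")) {
        fp$mw_violation_aa
      } else {
        sample(seq(fp$aa_len[1], fp$aa_len[2]), 1)
      }
      transcripts[i] <- .designed_transcript(n_aa)
    } else {
      transcripts[i] <- .random_dna(
        sample(seq(config$length_range[1], config$length_range[2]), 1)
      )
    }
  }
  lengths <- nchar(transcripts)

  # ---- annotation tables ---------------------------------------------------
  blast <- list(); hmm <- list(); pannzer <- list()
  cofactors <- character(0)
  add_blast <- function(q, pid, alen, qlen, ev, title, lineage) {
    blast[[length(blast) + 1L]] <<- data.frame(
      qseqid = q, sseqid = paste0("sp|", substr(title, 1, 6)), pident = pid,
      length = alen, evalue = ev, qlen = qlen, stitle = title,
      lineage = lineage
    )
  }
  add_hmm <- function(q, acc, ev, desc) {
    hmm[[length(hmm) + 1L]] <<- data.frame(
      qseqid = q, pfam_acc = acc, evalue = ev, description = desc
    )
  }
  add_pz <- function(q, desc, go, ec, ppv) {
    pannzer[[length(pannzer) + 1L]] <<- data.frame(
      qseqid = q, description = desc, go_terms = go, ec = ec, ppv = ppv
    )
  }

  for (i in seq_len(config$n_transcripts)) {
    id <- ids[i]
    role <- roles$role[i]
    if (role %in% c("candidate", "decoy")) {
      f <- roles$family[i]
      if (f == "cpks5") next  # handled via the bait hit table below
      fp <- FAMILY_PARAMS[[f]]
      viol <- roles$violated[i]
      dom_ev <- if (identical(viol, "domain")) 1e-10 else
        10^(-stats::runif(1, 25, 60))
      add_hmm(id, fp$pfam, dom_ev, paste(f, "family domain"))
      ec <- if (identical(viol, "ec")) fp$wrong_ec else fp$ec
      add_pz(id, paste(f, "like protein"),
             paste(sample(BACKGROUND_GOS, 2), collapse = ";"), ec,
             round(stats::runif(1, 0.9, 0.99), 3))
      add_blast(id, round(stats::runif(1, 85, 99), 1), 300, 400,
                10^(-stats::runif(1, 40, 90)),
                paste(f, "homolog"), .viridiplantae_lineage)
      if (f == "cr") {
        cofactors[id] <- if (identical(viol, "cofactor")) "NADH" else
          sample(c("NADPH", "NADPH/NADH"), 1)
      }
    } else if (role == "contaminant") {
      add_blast(id, round(stats::runif(1, 85, 99), 1), 250, 350,
                10^(-stats::runif(1, 30, 80)),
                "non-plant protein", roles$lineage[i])
      if (stats::runif(1) < 0.3) {
        add_hmm(id, sample(BACKGROUND_PFAMS, 1), 10^(-stats::runif(1, 21, 50)),
                "background domain")
      }
    } else {
      # background plant transcript
      if (stats::runif(1) < 0.6) {
        pid <- round(stats::runif(1, 55, 99), 1)
        alen <- sample(80:350, 1)
        qlen <- sample(200:400, 1)
        add_blast(id, pid, alen, qlen, 10^(-stats::runif(1, 10, 80)),
                  "plant protein", .viridiplantae_lineage)
      }
      if (stats::runif(1) < 0.4) {
        add_hmm(id, sample(BACKGROUND_PFAMS, 1), 10^(-stats::runif(1, 5, 45)),
                "background domain")
      }
      if (stats::runif(1) < 0.5) {
        n_pred <- sample(1:3, 1)
        for (p in seq_len(n_pred)) {
          add_pz(id, "predicted protein",
                 paste(sample(BACKGROUND_GOS, sample(1:3, 1)),
                       collapse = ";"),
                 if (stats::runif(1) < 0.1) "3.2.1.4" else "",
                 round(stats::runif(1, 0.2, 1), 3))
        }
      }
    }
  }
  blast <- do.call(rbind, blast)
  hmm <- do.call(rbind, hmm)
  pannzer <- do.call(rbind, pannzer)

  # ---- bait hits for the entry enzyme (Pareto structure) -------------------
  cpk_cand <- ids[roles$role == "candidate" & roles$family == "cpks5"]
  cpk_dec <- ids[roles$role == "decoy" & roles$family == "cpks5"]
  front <- data.frame(pident = c(99.2, 98.1, 97.3), length = c(380, 390, 400))
  dom <- data.frame(pident = c(96.5, 96.0, 95.5), length = c(378, 370, 360))
  bg_hit_ids <- sample(ids[roles$role == "background"],
                       min(30L, sum(roles$role == "background")))
  cpks5_hits <- rbind(
    if (length(cpk_cand) > 0L) data.frame(
      qseqid = "CPKS5", sseqid = cpk_cand,
      pident = front$pident[seq_along(cpk_cand)],
      length = front$length[seq_along(cpk_cand)], qlen = 400L
    ),
    if (length(cpk_dec) > 0L) data.frame(
      qseqid = "CPKS5", sseqid = cpk_dec,
      pident = dom$pident[seq_along(cpk_dec)],
      length = dom$length[seq_along(cpk_dec)], qlen = 400L
    ),
    if (length(bg_hit_ids) > 0L) data.frame(
      qseqid = "CPKS5", sseqid = bg_hit_ids,
      pident = round(stats::runif(length(bg_hit_ids), 30, 90), 1),
      length = sample(50:300, length(bg_hit_ids), replace = TRUE),
      qlen = 400L
    )
  )

  # ---- counts --------------------------------------------------------------
  organs <- config$organs
  reps <- config$replicates_per_organ
  samples <- paste(rep(organs, each = reps), rep(seq_len(reps), length(organs)),
                   sep = ".")
  sample_organs <- rep(organs, each = reps)
  counts <- matrix(0L, nrow = config$n_transcripts, ncol = length(samples),
                   dimnames = list(ids, samples))
  size <- 1 / config$dispersion
  for (i in seq_len(config$n_transcripts)) {
    role <- roles$role[i]
    if (role %in% c("candidate", "decoy")) {
      pat <- unique(c("flower", "fruit",
                      organs[stats::runif(length(organs)) < 0.3]))
      if (identical(roles$violated[i], "expression")) {
        pat <- setdiff(pat, "fruit")
      }
    } else if (role == "contaminant") {
      pat <- unique(c("root", organs[stats::runif(length(organs)) < 0.25]))
    } else {
      if (stats::runif(1) < 0.15) {
        pat <- organs
      } else {
        pat <- organs[stats::runif(length(organs)) < 0.55]
        if (length(pat) == 0L) pat <- sample(organs, 1)
      }
    }
    base <- stats::rlnorm(1, meanlog = 3.5, sdlog = 1)
    for (o in pat) {
      mu <- base * stats::rlnorm(1, 0, 0.3)
      cols <- which(sample_organs == o)
      x <- stats::rnbinom(length(cols), mu = mu, size = size)
      if (role %in% c("candidate", "decoy") && o %in% c("flower", "fruit")) {
        x <- pmax(x, 1L)  # planted pathway genes are expressed where required
      }
      counts[i, cols] <- x
    }
  }

  out <- list(
    transcripts = transcripts, lengths = lengths, blast = blast, hmm = hmm,
    pannzer = pannzer, cofactors = cofactors, cpks5_hits = cpks5_hits,
    counts = counts, sample_organs = sample_organs, truth = roles,
    config = config
  )
  if (!is.null(dir)) write_study(out, dir)
  out
}

#' Write a synthetic study to plain-text files
#'
#' @param study Output of [generate_study()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- Biostrings::DNAStringSet(study$transcripts)
  Biostrings::writeXStringSet(fa, file.path(dir, "transcripts.fasta"))
  tsv <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE
  )
  tsv(study$blast, "blast_hits.tsv")
  tsv(study$hmm, "hmm_domains.tsv")
  tsv(study$pannzer, "pannzer_predictions.tsv")
  tsv(study$cpks5_hits, "cpks5_hits.tsv")
  tsv(data.frame(transcript_id = names(study$cofactors),
                 cofactor = unname(study$cofactors)), "cofactors.tsv")
  write_count_matrix(study$counts, study$sample_organs,
                     file.path(dir, "counts.tsv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       dataframe = "rows", na = "null")
  invisible(dir)
}

#' Simulate a qPCR Ct plate with known fold changes
#'
#' Generates cycle-threshold values such that the expected comparative-Ct
#' fold change of each gene in each organ equals the configured value: the
#' housekeeping gene sits at a constant baseline, the gene of interest at a
#' calibrator baseline shifted by -log2(fold) in each organ, and Gaussian
#' noise of `noise_sd` cycles is added per technical replicate.
#'
#' @param genes Gene-of-interest labels.
#' @param organs Organ labels (must include `calibrator`).
#' @param true_fold_changes Named numeric vector organ -> fold (applied to
#'   every gene) or a named list gene -> such a vector. Missing organs get
#'   fold 1.
#' @param noise_sd Ct noise standard deviation, cycles.
#' @param hkg Housekeeping gene label to include.
#' @param calibrator Calibrator organ.
#' @param n_bio,n_tech Biological and technical replicates per cell.
#' @param seed Optional random seed.
#' @return Long-format Ct `data.frame` (`gene`, `organ`, `bio_rep`,
#'   `tech_rep`, `ct`).
#' @export
generate_ct_plate <- function(genes, organs, true_fold_changes,
                              noise_sd = 0, hkg = "ACT",
                              calibrator = "leaf", n_bio = 2L, n_tech = 3L,
                              seed = NULL) {
  stopifnot(noise_sd >= 0, calibrator %in% organs)
  if (!is.null(seed)) set.seed(seed)
  fold_for <- function(gene, organ) {
    v <- if (is.list(true_fold_changes)) true_fold_changes[[gene]]
         else true_fold_changes
    f <- if (organ %in% names(v)) v[[organ]] else 1
    if (f <= 0) stop("fold changes must be positive")
    f
  }
  rows <- list()
  for (g in c(genes, hkg)) {
    for (o in organs) {
      base <- if (g == hkg) 20 else {
        24 - log2(fold_for(g, o) / fold_for(g, calibrator))
      }
      for (b in seq_len(n_bio)) {
        ct <- base + stats::rnorm(n_tech, 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          gene = g, organ = o, bio_rep = b, tech_rep = seq_len(n_tech),
          ct = ct
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
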