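# End-to-end orchestration: annotate -> decontaminate -> express -> gsea ->
# mine -> qpcr, with per-stage tables, stage survivor counts and a manifest.

#' Pipeline configuration
#'
#' Defaults reproduce the study thresholds: 80% identity and 50% query
#' coverage for alignment hits, a strict 1e-20 domain E-value bound, PPV
#' floor 0.5 with a 0.9 relative cutoff, minimum gene-set size 15 at nominal
#' p < 0.01, and the enzyme cascade presets (including the 45-65 kDa
#' aminotransferase window).
#'
#' @param study Either a [sim_config()] (the study is generated) or a named
#'   list of input paths (`fasta`, `blast`, `hmm`, `pannzer`, `counts`,
#'   `cofactors`, `cpks5_hits`).
#' @param out_dir Output directory for the report bundle.
#' @param min_identity,min_coverage Alignment-hit thresholds.
#' @param max_evalue Domain E-value bound (strict).
#' @param ppv_floor,ppv_rel Classifier PPV screen.
#' @param min_set_size,n_perm,alpha Enrichment parameters.
#' @param min_len_aa Minimum ORF length for peptide prediction.
#' @param enzyme_specs Named list of [enzyme_seed_spec()]; defaults to
#'   [default_enzyme_specs()].
#' @param run_gsea,run_qpcr Toggle the optional stages.
#' @param qpcr_plate Optional Ct table for the qpcr stage; when `NULL` and
#'   `run_qpcr` is true, a noiseless plate with known folds is simulated.
#' @param seed Seed for stochastic stages.
#' @param verbose Log stage progress to stderr.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(study, out_dir = tempfile("conmine_run_"),
                            min_identity = 80, min_coverage = 0.5,
                            max_evalue = 1e-20, ppv_floor = 0.5,
                            ppv_rel = 0.9, min_set_size = 15L,
                            n_perm = 200L, alpha = 0.01, min_len_aa = 50L,
                            enzyme_specs = default_enzyme_specs(),
                            run_gsea = TRUE, run_qpcr = TRUE,
                            qpcr_plate = NULL, seed = 1L, verbose = TRUE) {
  structure(
    list(study = study, out_dir = out_dir, min_identity = min_identity,
         min_coverage = min_coverage, max_evalue = max_evalue,
         ppv_floor = ppv_floor, ppv_rel = ppv_rel,
         min_set_size = as.integer(min_set_size),
         n_perm = as.integer(n_perm), alpha = alpha,
         min_len_aa = as.integer(min_len_aa), enzyme_specs = enzyme_specs,
         run_gsea = run_gsea, run_qpcr = run_qpcr, qpcr_plate = qpcr_plate,
         seed = as.integer(seed), verbose = verbose),
    class = "pipeline_config"
  )
}

# small stable polynomial hash over the serialized object, for the manifest
.config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.stage <- function(name, verbose, expr) {
  if (verbose) message("[conmine] stage: ", name)
  tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full mining pipeline
#'
#' Executes the stages in order (annotate, decontaminate, express, gsea,
#' mine, qpcr), writes per-stage tab-separated tables and a JSON manifest
#' recording the configuration hash, seed and completed stages, and returns
#' all stage results.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all stage outputs and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  v <- config$verbose
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(d, f) utils::write.table(
    d, file.path(config$out_dir, f), sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  completed <- character(0)

  study <- .stage("inputs", v, {
    if (inherits(config$study, "sim_config")) {
      generate_study(config$study)
    } else {
      p <- config$study
      fa <- Biostrings::readDNAStringSet(p$fasta)
      cm <- read_count_matrix(p$counts)
      cof <- utils::read.delim(p$cofactors, stringsAsFactors = FALSE)
      list(
        transcripts = stats::setNames(as.character(fa), names(fa)),
        lengths = stats::setNames(nchar(as.character(fa)), names(fa)),
        blast = read_blast_table(p$blast),
        hmm = read_hmm_table(p$hmm),
        pannzer = read_pannzer_table(p$pannzer),
        cofactors = stats::setNames(cof$cofactor, cof$transcript_id),
        cpks5_hits = read_blast_table(p$cpks5_hits),
        counts = cm$counts, sample_organs = cm$sample_organs,
        truth = NULL, config = NULL
      )
    }
  })

  ann <- .stage("annotate", v, {
    fb <- filter_blast(study$blast, config$min_identity, config$min_coverage)
    fh <- filter_hmm(study$hmm, config$max_evalue)
    fp <- screen_pannzer(study$pannzer, config$ppv_floor, config$ppv_rel)
    integrate_annotations(fb, fh, fp,
                          transcript_ids = names(study$transcripts))
  })
  tsv(ann, "annotation.tsv")
  completed <- c(completed, "annotate")

  decon <- .stage("decontaminate", v, decontaminate(ann))
  tsv(data.frame(transcript_id = decon$removed), "contaminants_removed.tsv")
  completed <- c(completed, "decontaminate")

  expr <- .stage("express", v, {
    counts <- study$counts[decon$kept, , drop = FALSE]
    norm <- normalize_expression(counts, study$lengths[decon$kept])
    pres <- organ_presence(norm$tmm, study$sample_organs)
    sets <- organ_set_summary(pres$presence)
    list(norm = norm, presence = pres, set_summary = sets)
  })
  tsv(data.frame(sample = names(expr$norm$factors),
                 size_factor = as.numeric(expr$norm$factors)),
      "tmm_factors.tsv")
  tsv(expr$set_summary, "organ_set_summary.tsv")
  tsv(data.frame(transcript_id = rownames(expr$presence$presence),
                 expr$presence$presence, check.names = FALSE),
      "presence_calls.tsv")
  completed <- c(completed, "express")

  gsea <- NULL
  if (config$run_gsea) {
    gsea <- .stage("gsea", v, {
      go <- strsplit(ann$go_terms, ";", fixed = TRUE)
      names(go) <- ann$transcript_id
      terms <- sort(unique(unlist(go)))
      terms <- terms[nzchar(terms)]
      sets <- lapply(terms, function(tm) {
        ann$transcript_id[vapply(go, function(g) tm %in% g, logical(1))]
      })
      names(sets) <- terms
      organs <- unique(study$sample_organs)
      res <- lapply(organs, function(o) {
        rl <- ranked_list(expr$norm$tmm, study$sample_organs, o)
        r <- gsea_preranked(rl, sets, min_size = config$min_set_size,
                            n_perm = config$n_perm, alpha = config$alpha,
                            seed = config$seed, keep_all = TRUE)
        if (nrow(r) > 0L) r$organ <- o
        r
      })
      do.call(rbind, res)
    })
    tsv(gsea, "gsea_results.tsv")
    completed <- c(completed, "gsea")
  }

  mine <- .stage("mine", v, {
    peps <- representative_peptides(
      predict_peptides(study$transcripts[decon$kept],
                       min_len_aa = config$min_len_aa)
    )
    out <- list()
    for (nm in names(config$enzyme_specs)) {
      spec <- config$enzyme_specs[[nm]]
      if (!is.null(spec$bait_ids)) {
        hits <- study$cpks5_hits
        hits <- hits[hits$sseqid %in% decon$kept, , drop = FALSE]
        sel <- select_pks_candidates(hits)
        out[[nm]] <- list(
          candidates = data.frame(
            enzyme = nm,
            transcript_id = sel$sseqid,
            pident = sel$pident, length = sel$length
          ),
          stage_counts = c(hits = nrow(hits), pareto = nrow(sel))
        )
      } else {
        out[[nm]] <- apply_cascade(spec, ann, peps, expr$presence,
                                   cofactor_labels = study$cofactors)
      }
    }
    out
  })
  for (nm in names(mine)) {
    tsv(mine[[nm]]$candidates, paste0("candidates_", nm, ".tsv"))
    tsv(data.frame(stage = names(mine[[nm]]$stage_counts),
                   survivors = as.integer(mine[[nm]]$stage_counts)),
        paste0("stage_counts_", nm, ".tsv"))
  }
  completed <- c(completed, "mine")

  qpcr <- NULL
  if (config$run_qpcr) {
    qpcr <- .stage("qpcr", v, {
      plate <- config$qpcr_plate
      if (is.null(plate)) {
        plate <- generate_ct_plate(
          genes = c("CPKS5", "PKR1", "AAT1", "CR1", "CSAM1"),
          organs = unique(study$sample_organs),
          true_fold_changes = c(flower = 8, fruit = 4, stem = 2,
                                leaf = 1, root = 0.25),
          noise_sd = 0, seed = config$seed
        )
      }
      res <- lapply(unique(plate$gene[plate$gene != "ACT"]), function(g) {
        d <- delta_delta_ct(plate, g, "ACT", calibrator = "leaf")
        d$gene <- g
        d
      })
      do.call(rbind, res)
    })
    tsv(qpcr, "qpcr_relative_expression.tsv")
    completed <- c(completed, "qpcr")
  }

  manifest <- list(
    package = "conmine",
    config_hash = .config_hash(config[setdiff(names(config),
                                              c("out_dir", "verbose"))]),
    seed = config$seed,
    stages = completed,
    n_transcripts = length(study$transcripts),
    n_removed = length(decon$removed)
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(study = study, annotation = ann, decontamination = decon,
                 expression = expr, gsea = gsea, mining = mine, qpcr = qpcr,
                 manifest = manifest))
}
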