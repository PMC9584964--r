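#!/usr/bin/env Rscript
# Mine the pathway enzyme candidates: Pareto selection of the entry enzyme
# (CPKS5) by identity x alignment length of its homology hits, then the
# declarative cascades for PKR, AAT, CR and CSAM (protein-family seed,
# flower+fruit co-expression, 45-65 kDa window for AAT, NADPH cofactor and
# EC 1.3.1 for CR, EC 2.1.1.49 for CSAM). Recovery is scored against the
# planted truth.

library(conmine)

ann <- read.delim("results/02_annotation.tsv", stringsAsFactors = FALSE)
for (col in c("pfam_accs", "ec_numbers", "go_terms")) {
  ann[[col]][is.na(ann[[col]])] <- ""
}
kept <- readLines("results/02_kept_ids.txt")
fa <- Biostrings::readDNAStringSet("scratch/study/transcripts.fasta")
pres_tab <- read.delim("results/03_presence_calls.tsv", check.names = FALSE)
pres_mat <- as.matrix(pres_tab[, -1]) == "TRUE" | pres_tab[, -1] == TRUE
rownames(pres_mat) <- pres_tab$transcript_id
presence <- list(presence = pres_mat, organ_means = pres_mat * 1)
cof_tab <- read.delim("scratch/study/cofactors.tsv",
                      stringsAsFactors = FALSE)
cofactors <- setNames(cof_tab$cofactor, cof_tab$transcript_id)
truth <- jsonlite::read_json("scratch/study/truth.json",
                             simplifyVector = TRUE)

peps <- representative_peptides(
  predict_peptides(setNames(as.character(fa), names(fa))[kept],
                   min_len_aa = 50)
)

specs <- default_enzyme_specs()
rows <- list()
for (fam in names(specs)) {
  if (fam == "cpks5") {
    hits <- read_blast_table("scratch/study/cpks5_hits.tsv")
    sel <- select_pks_candidates(hits[hits$sseqid %in% kept, ])
    got <- sel$sseqid
    cand <- data.frame(enzyme = fam, transcript_id = got,
                       pident = sel$pident, length = sel$length)
    write.table(cand, sprintf("results/05_candidates_%s.tsv", fam),
                sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    out <- apply_cascade(specs[[fam]], ann, peps, presence,
                         cofactor_labels = cofactors)
    got <- unlist(strsplit(out$candidates$transcript_id, "/", fixed = TRUE))
    write.table(out$candidates, sprintf("results/05_candidates_%s.tsv", fam),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(stage = names(out$stage_counts),
                           survivors = as.integer(out$stage_counts)),
                sprintf("results/05_stage_counts_%s.tsv", fam), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  want <- truth$transcript_id[truth$role == "candidate" &
                                !is.na(truth$family) & truth$family == fam]
  tp <- length(intersect(got, want))
  rows[[fam]] <- data.frame(
    enzyme = fam, n_selected = length(got), n_planted = length(want),
    precision = tp / max(length(got), 1), recall = tp / max(length(want), 1)
  )
}
perf <- do.call(rbind, rows)
write.table(perf, "results/05_recovery.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message("planted-candidate recovery:")
for (i in seq_len(nrow(perf))) {
  message(sprintf("  %-6s precision %.2f recall %.2f (%d selected)",
                  perf$enzyme[i], perf$precision[i], perf$recall[i],
                  perf$n_selected[i]))
}
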