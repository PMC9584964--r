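#!/usr/bin/env Rscript
# Filter the three annotation evidence streams under the study thresholds
# (identity >= 80%, query coverage >= 50%, domain E-value < 1e-20, PPV >= 0.5
# then >= 0.9 x per-ORF max), integrate them per transcript, and remove the
# transcripts annotated exclusively with bacterial or opisthokont genes.

library(conmine)

blast <- filter_blast(read_blast_table("scratch/study/blast_hits.tsv"))
hmm <- filter_hmm(read_hmm_table("scratch/study/hmm_domains.tsv"))
pz <- screen_pannzer(read_pannzer_table("scratch/study/pannzer_predictions.tsv"))
fa <- Biostrings::readDNAStringSet("scratch/study/transcripts.fasta")

ann <- integrate_annotations(blast, hmm, pz, transcript_ids = names(fa))
decon <- decontaminate(ann)

write.table(ann, "results/02_annotation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
writeLines(decon$removed, "results/02_contaminants_removed.txt")
writeLines(decon$kept, "results/02_kept_ids.txt")

message(sum(ann$annotated), " of ", nrow(ann), " transcripts annotated (",
        round(100 * mean(ann$annotated), 1), "%); ",
        length(decon$removed), " removed as contaminants (",
        round(100 * length(decon$removed) / nrow(ann), 1), "%)")
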