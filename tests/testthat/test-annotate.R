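mk_blast <- function(pident, length, qlen, qseqid = "q", lineage = NA,
                     evalue = 1e-30) {
  data.frame(qseqid = qseqid, sseqid = "s", pident = pident, length = length,
             evalue = evalue, qlen = qlen, stitle = "subject",
             lineage = lineage)
}

test_that("alignment-hit thresholds are inclusive on both axes", {
  kept <- filter_blast(mk_blast(80.0, 50, 100))
  expect_equal(nrow(kept), 1L)
  expect_equal(nrow(filter_blast(mk_blast(79.9, 90, 100))), 0L)
  expect_equal(nrow(filter_blast(mk_blast(95, 49, 100))), 0L)
  expect_error(filter_blast(mk_blast(90, 50, NA)), "query length")
})

test_that("alignment filtering equals a row-by-row scan", {
  set.seed(101)
  hits <- data.frame(
    qseqid = sprintf("q%d", 1:1000), sseqid = "s",
    pident = runif(1000, 0, 100), length = sample(10:400, 1000, TRUE),
    evalue = 10^(-runif(1000, 0, 80)), qlen = sample(100:400, 1000, TRUE)
  )
  kept <- filter_blast(hits)
  manual <- hits[sapply(seq_len(nrow(hits)), function(i) {
    hits$pident[i] >= 80 && hits$length[i] / hits$qlen[i] >= 0.5
  }), ]
  rownames(manual) <- NULL
  expect_equal(kept, manual)
})

test_that("domain E-value bound is strict", {
  hits <- data.frame(qseqid = c("a", "b", "c"), pfam_acc = "PF00001",
                     evalue = c(1e-21, 1e-20, 1e-19))
  out <- filter_hmm(hits)
  expect_equal(out$qseqid, "a")
  expect_error(filter_hmm(data.frame(qseqid = "a", pfam_acc = "x",
                                     evalue = -1)), "negative")
})

test_that("PPV screen applies the floor then the per-ORF relative cutoff", {
  preds <- data.frame(qseqid = "orf1", description = "d", go_terms = "",
                      ec = "", ppv = c(0.95, 0.90, 0.60))
  expect_equal(sort(screen_pannzer(preds)$ppv), c(0.90, 0.95))
  expect_equal(nrow(screen_pannzer(
    data.frame(qseqid = "o", description = "", go_terms = "", ec = "",
               ppv = 0.40))), 0L)
  expect_equal(nrow(screen_pannzer(
    data.frame(qseqid = "o", description = "", go_terms = "", ec = "",
               ppv = 0.5))), 1L)
  # the relative cutoff uses the post-floor maximum
  two <- data.frame(qseqid = "o", description = "", go_terms = "", ec = "",
                    ppv = c(0.45, 0.48))
  expect_equal(nrow(screen_pannzer(two)), 0L)
})

test_that("stream filters are idempotent", {
  set.seed(55)
  hits <- data.frame(
    qseqid = sprintf("q%d", 1:50), sseqid = "s", pident = runif(50, 60, 100),
    length = sample(50:200, 50, TRUE), evalue = 10^(-runif(50, 0, 40)),
    qlen = 200
  )
  once <- filter_blast(hits)
  expect_equal(filter_blast(once), once)
  dhits <- data.frame(qseqid = sprintf("q%d", 1:50), pfam_acc = "PF1",
                      evalue = 10^(-runif(50, 10, 30)))
  donce <- filter_hmm(dhits)
  expect_equal(filter_hmm(donce), donce)
})

test_that("relaxing thresholds never shrinks the accepted set", {
  set.seed(56)
  hits <- data.frame(
    qseqid = sprintf("q%d", 1:200), sseqid = "s", pident = runif(200, 0, 100),
    length = sample(10:200, 200, TRUE), evalue = 10^(-runif(200, 0, 40)),
    qlen = 200
  )
  strict <- filter_blast(hits, 85, 0.6)$qseqid
  loose <- filter_blast(hits, 80, 0.5)$qseqid
  expect_true(all(strict %in% loose))
})

test_that("evidence unions integrate per transcript", {
  blast <- mk_blast(90, 120, 200, qseqid = "t1",
                    lineage = "Eukaryota; Viridiplantae")
  hmm <- data.frame(qseqid = c("t1", "t2"), pfam_acc = c("PF00001", "PF00002"),
                    evalue = 1e-30, description = "dom")
  pz <- data.frame(qseqid = "t1", description = "enzyme",
                   go_terms = "GO:1;GO:2", ec = "1.2.3.4;1.2.3", ppv = 0.9)
  ann <- integrate_annotations(blast, hmm, pz,
                               transcript_ids = c("t1", "t2", "t3"))
  t1 <- ann[ann$transcript_id == "t1", ]
  expect_true(t1$annotated)
  expect_equal(t1$pfam_accs, "PF00001")
  expect_setequal(strsplit(t1$go_terms, ";")[[1]], c("GO:1", "GO:2"))
  expect_equal(t1$ec_full, "1.2.3.4")  # only the fully determined EC
  expect_equal(t1$best_hit_kingdom, "Viridiplantae")
  t2 <- ann[ann$transcript_id == "t2", ]
  expect_true(t2$annotated)
  expect_equal(t2$pfam_accs, "PF00002")
  expect_equal(t2$ec_numbers, "")
  expect_false(ann$annotated[ann$transcript_id == "t3"])
})

test_that("decontamination removes exclusively non-plant transcripts", {
  blast <- rbind(
    mk_blast(90, 120, 200, qseqid = "bac", lineage = "Bacteria; Bacillota"),
    mk_blast(90, 120, 200, qseqid = "mix", lineage = "Bacteria; Bacillota"),
    mk_blast(92, 130, 200, qseqid = "mix",
             lineage = "Eukaryota; Viridiplantae"),
    mk_blast(92, 130, 200, qseqid = "fun",
             lineage = "Eukaryota; Opisthokonta; Fungi"),
    mk_blast(92, 130, 200, qseqid = "unk", lineage = "synthetic construct")
  )
  empty_pz <- data.frame(qseqid = character(), description = character(),
                         go_terms = character(), ec = character(),
                         ppv = numeric())
  empty_hmm <- data.frame(qseqid = character(), pfam_acc = character(),
                          evalue = numeric())
  ann <- integrate_annotations(blast, empty_hmm, empty_pz,
                               transcript_ids = c("bac", "mix", "fun",
                                                  "unk", "none"))
  d <- decontaminate(ann)
  expect_setequal(d$removed, c("bac", "fun"))
  expect_setequal(d$kept, c("mix", "unk", "none"))
  # fixed point: a second application removes nothing
  ann2 <- ann[ann$transcript_id %in% d$kept, ]
  expect_equal(length(decontaminate(ann2)$removed), 0L)
})

test_that("planted contaminants are exactly the transcripts removed", {
  st <- small_study(seed = 19, n = 300, contaminants = 50)
  ann <- integrate_annotations(
    filter_blast(st$blast), filter_hmm(st$hmm), screen_pannzer(st$pannzer),
    transcript_ids = names(st$transcripts)
  )
  d <- decontaminate(ann)
  want <- st$truth$transcript_id[st$truth$role == "contaminant"]
  expect_setequal(d$removed, want)
})
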