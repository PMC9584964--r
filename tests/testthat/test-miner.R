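test_that("Pareto selection keeps only non-dominated hits", {
  hits <- data.frame(sseqid = c("a", "b", "c"),
                     pident = c(99, 95, 99), length = c(400, 400, 200))
  sel <- select_pks_candidates(hits)
  expect_equal(sel$sseqid, "a")
  one <- data.frame(sseqid = "x", pident = 50, length = 100)
  expect_equal(select_pks_candidates(one)$sseqid, "x")
  expect_warning(sel0 <- select_pks_candidates(one[0, ]), "empty")
  expect_equal(nrow(sel0), 0L)
})

test_that("Pareto selection equals a pairwise dominance oracle", {
  set.seed(71)
  for (r in 1:5) {
    hits <- data.frame(sseqid = sprintf("t%03d", 1:100),
                       pident = round(runif(100, 30, 100), 1),
                       length = sample(50:450, 100, TRUE))
    sel <- select_pks_candidates(hits)
    dominated <- sapply(seq_len(nrow(hits)), function(i) {
      any(sapply(seq_len(nrow(hits)), function(j) {
        j != i && hits$pident[j] >= hits$pident[i] &&
          hits$length[j] >= hits$length[i] &&
          (hits$pident[j] > hits$pident[i] ||
             hits$length[j] > hits$length[i])
      }))
    })
    expect_setequal(sel$sseqid, hits$sseqid[!dominated])
    # deleting any dominated hit leaves the selection unchanged
    drop1 <- hits[-which(dominated)[1], ]
    expect_setequal(select_pks_candidates(drop1)$sseqid, sel$sseqid)
  }
})

test_that("search union records per-search provenance", {
  u <- search_union(c("a", "b"), c("b"), c("c"))
  expect_equal(u$transcript_id, c("a", "b", "c"))
  expect_equal(u$in_hmm, c(FALSE, FALSE, TRUE))
  expect_true(u$in_blast_uniprot[u$transcript_id == "a"])
  expect_equal(nrow(search_union(character(0), character(0), character(0))),
               0L)
})

test_that("cross-species shared-domain counts match a set scan", {
  ann <- data.frame(
    transcript_id = c("t1", "t2", "t3"),
    pfam_accs = c("PF00202", "PF00106;PF13561", "PF00202;PF00106")
  )
  tab <- shared_pfam_counts(default_kec_seeds(), ann)
  expect_equal(tab$n_transcripts[tab$gene == "kecF" & tab$pfam == "PF00202"],
               2L)
  # a transcript with two seed domains counts once per domain row
  expect_equal(tab$n_transcripts[tab$gene == "kecG" & tab$pfam == "PF00106"],
               2L)
  expect_equal(tab$n_transcripts[tab$gene == "kecG" & tab$pfam == "PF08659"],
               0L)
})

# fixture with one passing candidate and targeted single-violation decoys
cascade_fixture <- function() {
  ann <- data.frame(
    transcript_id = c("ok", "low_mw", "nadh", "wrong_ec"),
    pfam_accs = "PF00155",
    ec_numbers = c("2.6.1.2", "2.6.1.2", "1.3.1.33", "2.6.1.1"),
    go_terms = ""
  )
  peptides <- data.frame(
    transcript_id = c("ok", "low_mw", "nadh", "wrong_ec"),
    peptide = c("AAA", "CCC", "DDD", "EEE"),
    cds_length_nt = 1200L, length_aa = 400L,
    mw_kda = c(53, 44.9, 50, 50)
  )
  pres <- matrix(TRUE, nrow = 4, ncol = 2,
                 dimnames = list(ann$transcript_id, c("flower", "fruit")))
  list(ann = ann, peptides = peptides,
       presence = list(presence = pres,
                       organ_means = pres * 1))
}

test_that("cascade stages reject each single-criterion violation", {
  fx <- cascade_fixture()
  spec <- enzyme_seed_spec("aat", pfam = "PF00155", mw_range = c(45, 65),
                           ec_whitelist = c("2.6.1.2"))
  out <- apply_cascade(spec, fx$ann, fx$peptides, fx$presence)
  expect_equal(out$candidates$transcript_id, "ok")
  audit <- out$audit
  expect_false(audit$mw[audit$transcript_id == "low_mw"])    # 44.9 < 45
  expect_false(audit$ec[audit$transcript_id == "wrong_ec"])
  # survivor counts shrink monotonically along the canonical order
  expect_true(all(diff(out$stage_counts) <= 0))

  cr_spec <- enzyme_seed_spec("cr", pfam = "PF00155",
                              cofactor = "NADPH-or-both", ec_prefix = "1.3.1")
  cr <- apply_cascade(cr_spec, fx$ann, fx$peptides, fx$presence,
                      cofactor_labels = c(ok = "NADPH", low_mw = "NADPH",
                                          nadh = "NADH", wrong_ec = "NADPH"))
  expect_false(cr$audit$cofactor[cr$audit$transcript_id == "nadh"])
  expect_error(
    apply_cascade(enzyme_seed_spec("x", pfam = "PF00155",
                                   organs = c("flower", "nectar")),
                  fx$ann, fx$peptides, fx$presence),
    "organs absent"
  )
})

test_that("final cascade membership is independent of stage order", {
  # each stage is an independent predicate; permuting the order in which the
  # predicates are intersected cannot change the surviving set
  fx <- cascade_fixture()
  spec <- enzyme_seed_spec("aat", pfam = "PF00155", mw_range = c(45, 65),
                           ec_whitelist = "2.6.1.2")
  out <- apply_cascade(spec, fx$ann, fx$peptides, fx$presence)
  audit <- out$audit
  stages <- c("expression", "mw", "cofactor", "ec", "profile_cor")
  set.seed(72)
  for (r in 1:5) {
    perm <- sample(stages)
    surv <- audit$transcript_id
    for (s in perm) surv <- surv[audit[[s]][match(surv, audit$transcript_id)]]
    expect_setequal(surv, out$candidates$transcript_id)
  }
})

test_that("rows with identical peptides merge into one candidate", {
  fx <- cascade_fixture()
  fx$ann <- rbind(fx$ann, data.frame(
    transcript_id = "ok2", pfam_accs = "PF00155", ec_numbers = "2.6.1.2",
    go_terms = ""
  ))
  fx$peptides <- rbind(fx$peptides, data.frame(
    transcript_id = "ok2", peptide = "AAA", cds_length_nt = 1200L,
    length_aa = 400L, mw_kda = 53
  ))
  pres <- matrix(TRUE, nrow = 5, ncol = 2,
                 dimnames = list(fx$ann$transcript_id, c("flower", "fruit")))
  fx$presence <- list(presence = pres, organ_means = pres * 1)
  spec <- enzyme_seed_spec("aat", pfam = "PF00155", mw_range = c(45, 65),
                           ec_whitelist = "2.6.1.2")
  out <- apply_cascade(spec, fx$ann, fx$peptides, fx$presence)
  expect_equal(out$candidates$transcript_id, "ok/ok2")
})

test_that("every cascade recovers exactly its planted candidates", {
  st <- small_study(seed = 29, n = 400, contaminants = 25)
  ann <- integrate_annotations(
    filter_blast(st$blast), filter_hmm(st$hmm), screen_pannzer(st$pannzer),
    transcript_ids = names(st$transcripts)
  )
  kept <- decontaminate(ann)$kept
  norm <- normalize_expression(st$counts[kept, ], st$lengths[kept])
  pres <- organ_presence(norm$tmm, st$sample_organs)
  peps <- representative_peptides(
    predict_peptides(st$transcripts[kept], min_len_aa = 50)
  )
  specs <- default_enzyme_specs()
  for (fam in c("pkr", "aat", "cr", "csam")) {
    out <- apply_cascade(specs[[fam]], ann, peps, pres,
                         cofactor_labels = st$cofactors)
    got <- unlist(strsplit(out$candidates$transcript_id, "/", fixed = TRUE))
    want <- st$truth$transcript_id[st$truth$role == "candidate" &
                                     st$truth$family == fam]
    expect_setequal(got, want)
    expect_true(all(diff(out$stage_counts) <= 0))
  }
  sel <- select_pks_candidates(st$cpks5_hits)
  want5 <- st$truth$transcript_id[st$truth$role == "candidate" &
                                    st$truth$family == "cpks5"]
  expect_setequal(sel$sseqid, want5)
})

test_that("decoys are minimal: relaxing the violated criterion admits them", {
  st <- small_study(seed = 33, n = 350, contaminants = 10)
  ann_loose <- integrate_annotations(
    filter_blast(st$blast), filter_hmm(st$hmm, max_evalue = 1e-4),
    screen_pannzer(st$pannzer), transcript_ids = names(st$transcripts)
  )
  kept <- decontaminate(ann_loose)$kept
  norm <- normalize_expression(st$counts[kept, ], st$lengths[kept])
  pres <- organ_presence(norm$tmm, st$sample_organs)
  peps <- representative_peptides(
    predict_peptides(st$transcripts[kept], min_len_aa = 50)
  )
  tr <- st$truth
  for (fam in c("pkr", "aat", "cr", "csam")) {
    spec <- default_enzyme_specs()[[fam]]
    out <- apply_cascade(spec, ann_loose, peps, pres,
                         cofactor_labels = st$cofactors)
    got <- unlist(strsplit(out$candidates$transcript_id, "/", fixed = TRUE))
    dom_decoys <- tr$transcript_id[tr$role == "decoy" & tr$family == fam &
                                     tr$violated == "domain"]
    # with the domain criterion relaxed, domain decoys pass all other stages
    expect_true(all(dom_decoys %in% got))
    other_decoys <- tr$transcript_id[tr$role == "decoy" & tr$family == fam &
                                       tr$violated != "domain"]
    expect_false(any(other_decoys %in% got))
  }
})

test_that("enzyme specs load from the shipped YAML presets", {
  path <- system.file("extdata", "enzyme_specs.yaml", package = "conmine")
  specs <- read_enzyme_specs(path)
  expect_setequal(names(specs), c("cpks5", "pkr", "aat", "cr", "csam"))
  expect_equal(specs$aat$mw_range, c(45, 65))
  expect_equal(specs$cr$cofactor, "NADPH-or-both")
  expect_equal(specs$csam$ec_prefix, "2.1.1.49")
  expect_error(enzyme_seed_spec("bad"), "bait")
})
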