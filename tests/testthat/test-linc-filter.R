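cand_row <- function(id, length = 400, class_code = "u",
                     rpkm = c(2, 0.1, 0.3), coverage = NA, evalue = NA,
                     cpat = FALSE, cpc = FALSE) {
  data.frame(transcript = id, length = length, class_code = class_code,
             rpkm_1 = rpkm[1], rpkm_2 = rpkm[2], rpkm_3 = rpkm[3],
             sim_coverage = coverage, sim_evalue = evalue,
             cpat_coding = cpat, cpc_coding = cpc)
}

test_that("the filter truth table matches the published rules", {
  recs <- rbind(
    cand_row("ok"),
    cand_row("len200", length = 200),            # boundary: kept
    cand_row("len150", length = 150),            # below 200 nt: rejected
    cand_row("rpkm_one", rpkm = c(0.5, 0.1, 0)), # floor in one sample: kept
    cand_row("rpkm_none", rpkm = c(0.4, 0.4, 0.4)),
    cand_row("sim_both", coverage = 0.6, evalue = 1e-6),
    cand_row("sim_cov_only", coverage = 0.6, evalue = 1e-4),
    cand_row("sim_eval_only", coverage = 0.4, evalue = 1e-6),
    cand_row("coding1", cpat = TRUE),
    cand_row("coding2", cpc = TRUE),
    cand_row("not_intergenic", class_code = "i"))
  res <- filter_candidates(recs)
  expect_setequal(res$kept$transcript,
                  c("ok", "len200", "rpkm_one", "sim_cov_only",
                    "sim_eval_only"))
  reason <- setNames(res$rejected$reason, res$rejected$transcript)
  expect_equal(reason[["len150"]], "length")
  expect_equal(reason[["rpkm_none"]], "expression")
  expect_equal(reason[["sim_both"]], "protein_similarity")
  expect_equal(reason[["coding1"]], "coding_potential")
  expect_equal(reason[["coding2"]], "coding_potential")
  expect_equal(reason[["not_intergenic"]], "class")
  expect_equal(nrow(res$kept) + nrow(res$rejected), nrow(recs))
})

test_that("only the first failed rule is reported, but outcomes are order-free", {
  multi <- cand_row("multi", length = 150, class_code = "i", cpat = TRUE)
  res <- filter_candidates(multi)
  expect_equal(res$rejected$reason, "length")
  # outcome (kept vs rejected) identical under row permutations
  recs <- rbind(cand_row("a"), cand_row("b", length = 10),
                cand_row("c", cpat = TRUE), cand_row("d"))
  res1 <- filter_candidates(recs)
  res2 <- filter_candidates(recs[c(3, 1, 4, 2), ])
  expect_setequal(res1$kept$transcript, res2$kept$transcript)
  empty <- filter_candidates(recs[0, ])
  expect_equal(nrow(empty$kept), 0)
  expect_equal(nrow(empty$rejected), 0)
})

test_that("the synthetic candidate panel is classified exactly per its labels", {
  cand <- simulate_candidate_transcripts(sim_config(seed = 5))
  res <- filter_candidates(cand)
  got <- rep("keep", nrow(cand))
  names(got) <- cand$transcript
  got[res$rejected$transcript] <- paste0("reject: ", res$rejected$reason)
  expect_equal(unname(got[cand$transcript]), cand$expected)
})

write_feature_fixture <- function(dir) {
  # two sequences; five transcripts of known structure
  gtf <- c(
    'chr1\ttest\texon\t1\t100\t.\t+\t.\ttranscript_id "tx1"; transcript_biotype "lincRNA";',
    'chr1\ttest\texon\t201\t250\t.\t+\t.\ttranscript_id "tx1"; transcript_biotype "lincRNA";',
    'chr1\ttest\texon\t301\t340\t.\t-\t.\ttranscript_id "tx2"; transcript_biotype "lincRNA";',
    'chr2\ttest\texon\t1\t30\t.\t+\t.\ttranscript_id "tx3"; transcript_biotype "protein_coding";',
    'chr2\ttest\texon\t41\t60\t.\t+\t.\ttranscript_id "tx4"; transcript_biotype "protein_coding";',
    'chr2\ttest\texon\t71\t90\t.\t+\t.\ttranscript_id "tx4"; transcript_biotype "protein_coding";',
    'chr2\ttest\texon\t101\t110\t.\t+\t.\ttranscript_id "tx5"; transcript_biotype "protein_coding";')
  gtf_path <- file.path(dir, "fx.gtf")
  writeLines(gtf, gtf_path)
  chr1 <- paste(rep("ACGT", 100), collapse = "")      # 400 nt, GC 0.5
  chr2 <- paste0(paste(rep("A", 60), collapse = ""),
                 paste(rep("G", 40), collapse = ""),
                 paste(rep("N", 10), collapse = ""),
                 paste(rep("C", 10), collapse = ""))  # 120 nt
  fa_path <- file.path(dir, "fx.fa")
  writeLines(c(">chr1", chr1, ">chr2", chr2), fa_path)
  list(gtf = gtf_path, fasta = fa_path)
}

test_that("exon summaries match a hand-computed fixture", {
  d <- withr::local_tempdir()
  fx <- write_feature_fixture(d)
  s <- exon_summaries(fx$gtf)
  linc <- s$exon_lengths[s$exon_lengths$biotype == "lincRNA", ]
  expect_setequal(linc$length[linc$transcript == "tx1"], c(100, 50))
  expect_equal(linc$length[linc$transcript == "tx2"], 40)
  pc <- s$exon_count_proportions[
    s$exon_count_proportions$biotype == "protein_coding", ]
  # tx3: 1 exon, tx4: 2 exons, tx5: 1 exon -> 2/3 single-exon
  expect_equal(pc$proportion[pc$n_exons == 1], 2 / 3)
  expect_equal(pc$proportion[pc$n_exons == 2], 1 / 3)
  lp <- s$exon_count_proportions[
    s$exon_count_proportions$biotype == "lincRNA", ]
  expect_equal(lp$proportion[lp$n_exons == 1], 1 / 2)
  expect_equal(lp$proportion[lp$n_exons == 2], 1 / 2)
})

test_that("GC content is computed over exonic A/C/G/T only", {
  d <- withr::local_tempdir()
  fx <- write_feature_fixture(d)
  gc <- gc_content(fx$fasta, fx$gtf)
  gc_of <- function(tx) gc$gc[gc$transcript == tx]
  expect_equal(gc_of("tx1"), 0.5)        # ACGT repeats
  expect_equal(gc_of("tx3"), 0)          # all A
  expect_equal(gc_of("tx4"), 20 / 40)    # 20 A + 20 G
  # tx5 overlaps N run (101..110): all N -> excluded entirely
  expect_true(is.na(gc_of("tx5")))
  # exon beyond the sequence end names the transcript
  bad <- c('chr2\ttest\texon\t100\t500\t.\t+\t.\ttranscript_id "oops"; transcript_biotype "lincRNA";')
  writeLines(bad, file.path(d, "bad.gtf"))
  expect_error(gc_content(fx$fasta, file.path(d, "bad.gtf")),
               "oops.*outside sequence bounds")
})
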