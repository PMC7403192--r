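# A small mutation-free cohort used by several blocks.
mu0 <- simulateCohort(simulationConfig(n_patients = 2, cells_per_patient = 5,
                                       shm_rate = 0, trim_max = 0,
                                       n_insert_max = 0,
                                       incomplete_fraction = 0, seed = 31),
                      toy_db)
mu0_rec <- annotateVdj(mu0$sequences, toy_db, verbose = FALSE)
mu0_m <- merge(mu0_rec, mu0$truth, by = "sequence_id",
               suffixes = c("", ".t"))

test_that("mutation-free untrimmed chains are recovered exactly", {
  expect_equal(nrow(mu0_m), length(mu0$sequences))
  expect_equal(mu0_m$v_call, mu0_m$v_call.t)
  expect_equal(mu0_m$j_call, mu0_m$j_call.t)
  heavy <- mu0_m$locus == "IGH"
  expect_equal(mu0_m$d_call[heavy], mu0_m$d_call.t[heavy])
  expect_equal(mu0_m$junction, mu0_m$junction.t)
  expect_equal(mu0_m$junction_start, mu0_m$junction_start.t)
  expect_equal(mu0_m$junction_end, mu0_m$junction_end.t)
  expect_true(all(mu0_m$v_mutation_count == 0))
  expect_true(all(mu0_m$productive))
  # span ordering invariant: V before J, D strictly between
  expect_true(all(mu0_m$v_q_end < mu0_m$j_q_start))
  d <- !is.na(mu0_m$d_q_start)
  expect_true(all(mu0_m$d_q_start[d] > mu0_m$v_q_end[d]))
  expect_true(all(mu0_m$d_q_end[d] < mu0_m$j_q_start[d]))
})

test_that("planted V-region substitutions are counted exactly", {
  sid <- mu0_m$sequence_id[mu0_m$locus == "IGH"][1]
  seq <- mu0$sequences[[sid]]
  for (p in c(50, 120, 200)) {
    old <- substr(seq, p, p)
    substr(seq, p, p) <- setdiff(c("A", "C", "G", "T"), old)[1]
  }
  rec <- annotateVdj(c(x = seq), toy_db, verbose = FALSE)
  expect_equal(rec$v_mutation_count, 3L)
  expect_equal(rec$mutation_rate, 3 / rec$v_germline_aligned_length)
  expect_equal(rec$v_call, mu0_m$v_call[mu0_m$sequence_id == sid])
})

test_that("a query equidistant from two alleles reports both, lexicographically", {
  # IGLV1-40*01 and *02 differ at exactly two sites; flipping one of them
  # leaves the query one mismatch from each allele
  s01 <- as.character(germlineSegments(toy_db, "IGL", "V"))[["IGLV1-40*01"]]
  s02 <- as.character(germlineSegments(toy_db, "IGL", "V"))[["IGLV1-40*02"]]
  diffs <- which(strsplit(s01, "")[[1]] != strsplit(s02, "")[[1]])
  expect_length(diffs, 2)
  # build a full light chain on the *01 germline, then flip one
  # distinguishing site to the *02 base
  jseq <- as.character(germlineSegments(toy_db, "IGL", "J"))[["IGLJ3*02"]]
  seq <- paste0(substr(s01, 1, 288), revTranslate("CQSYDRSLSGYWVF"),
                substr(jseq, 25, nchar(jseq)))
  substr(seq, diffs[1], diffs[1]) <- substr(s02, diffs[1], diffs[1])
  rec <- annotateVdj(c(x = seq), toy_db, verbose = FALSE)
  expect_equal(rec$v_call, "IGLV1-40*01,IGLV1-40*02")
})

test_that("a mutated cys anchor flags the junction but keeps the record", {
  sid <- mu0_m$sequence_id[mu0_m$locus == "IGH"][2]
  seq <- mu0$sequences[[sid]]
  cys <- mu0_m$junction_start[mu0_m$sequence_id == sid]
  substr(seq, cys, cys) <- "C"  # TGT -> CGT (Arg)
  rec <- annotateVdj(c(x = seq), toy_db, verbose = FALSE)
  expect_equal(nrow(rec), 1)
  expect_equal(rec$junction, "")
  expect_equal(rec$cdr3_aa, "")
  expect_false(rec$productive)
})

test_that("a stop codon planted inside the CDR3 makes the chain non-productive", {
  sid <- mu0_m$sequence_id[mu0_m$locus == "IGH"][3]
  seq <- mu0$sequences[[sid]]
  start <- mu0_m$junction_start[mu0_m$sequence_id == sid]
  substr(seq, start + 3, start + 5) <- "TAA"
  rec <- annotateVdj(c(x = seq), toy_db, verbose = FALSE)
  expect_false(rec$productive)
  expect_match(rec$junction_aa, "\\*")
})

test_that("frameshifted junctions are non-productive", {
  sim <- simulateCohort(simulationConfig(n_patients = 1,
                                         cells_per_patient = 6,
                                         shm_rate = 0,
                                         productive_fraction = 0,
                                         incomplete_fraction = 0, seed = 32),
                        toy_db)
  rec <- annotateVdj(sim$sequences, toy_db, verbose = FALSE)
  expect_true(all(!rec$productive))
  expect_true(all(nchar(rec$junction) %% 3 != 0))
  expect_true(all(rec$junction_aa == ""))
})

test_that("classifyProductive applies the in-frame, stop-free rule", {
  expect_true(classifyProductive("TGTGCGAGATGG"))
  expect_false(classifyProductive("TGTGCGAGATG"))      # 11 nt: frameshift
  expect_false(classifyProductive("TGTTAAAGATGG"))     # internal stop
  expect_false(classifyProductive(""))                 # undefined junction
  expect_false(classifyProductive("TGTGCGAGATGG", "MA*W"))
})

test_that("reverse-complement reads are recognised and re-oriented", {
  sid <- mu0_m$sequence_id[1]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(mu0$sequences[[sid]])))
  rec <- annotateVdj(c(x = rc), toy_db, verbose = FALSE)
  expect_true(rec$rev_comp)
  expect_equal(rec$v_call, mu0_m$v_call[1])
  expect_equal(rec$junction, mu0_m$junction[1])
})

test_that("queries with no credible V hit are reported unannotatable", {
  set.seed(33)
  junk <- setNames(replicate(3, rand_seq(300)), c("a", "b", "c"))
  expect_message(rec <- annotateVdj(junk, toy_db),
                 "3 unannotatable")
  expect_equal(nrow(rec), 0)
  expect_equal(sort(attr(rec, "unannotated")), c("a", "b", "c"))
})
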