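test_that("self-alignment is all matches and classifies as none", {
  s <- "ACGTACGTTTACG"
  aln <- align_affine(s, s)
  expect_equal(aln$score, 2 * nchar(s))
  expect_identical(aln$aligned_read, s)
  expect_identical(aln$aligned_ref, s)
  calls <- classify_errors(aln)
  expect_true(all(calls$error_type == "none"))
  expect_identical(calls$ref_pos, seq_len(nchar(s)))
})

test_that("an extra base in a run is an insertion anchored 3' of the run", {
  aln <- align_affine("ACGGT", "ACGT")
  expect_identical(aln$aligned_ref, "ACG-T")
  expect_equal(aln$score, 4 * 2 - (1 + 10))
  err <- subset(classify_errors(aln), error_type != "none")
  expect_identical(err$ref_pos, 3L)
  expect_identical(err$error_type, "insertion")

  # deletion inside a homopolymer, long tail so the gap beats mismatches
  d <- align_affine("CCAAAGGTTCACGTACGT", "CCAAAAGGTTCACGTACGT")
  errd <- subset(classify_errors(d), error_type != "none")
  expect_identical(errd$error_type, "deletion")
  expect_identical(errd$ref_pos, 6L) # last base of the A-run
})

test_that("alignment score matches the brute-force oracle on random pairs", {
  set.seed(202)
  for (i in 1:150) {
    rd <- random_dna(sample(1:8, 1))
    rf <- random_dna(sample(1:8, 1))
    pm <- sample(1:3, 1); pmm <- sample(0:2, 1)
    po <- sample(0:3, 1); pe <- sample(1:10, 1)
    got <- align_affine(rd, rf, align_params(pm, pmm, po, pe))$score
    expect_equal(got, oracle_align_score(rd, rf, pm, pmm, po, pe),
                 info = paste(rd, rf, pm, pmm, po, pe))
  }
})

test_that("alignment invariants: gap stripping and column sanity", {
  set.seed(203)
  for (i in 1:40) {
    rd <- random_dna(sample(3:30, 1))
    rf <- random_dna(sample(3:30, 1))
    aln <- align_affine(rd, rf)
    ar <- strsplit(aln$aligned_ref, "")[[1]]
    aq <- strsplit(aln$aligned_read, "")[[1]]
    expect_identical(length(ar), length(aq))
    expect_false(any(ar == "-" & aq == "-"))
    expect_identical(paste(aq[aq != "-"], collapse = ""), rd)
    covered <- paste(ar[ar != "-"], collapse = "")
    expect_identical(covered, substr(rf, 1, nchar(covered)))
  }
})

test_that("classification matches hand-derived calls on fixture alignments", {
  cases <- hand_alignments()
  expect_gte(length(cases), 30L)
  for (cs in cases) {
    expected <- parse_expect(cs[[3]])
    get_calls <- function() classify_errors(mk_aln(cs[[1]], cs[[2]]))
    calls <- if (isTRUE(cs$warn)) {
      expect_warning(got <- get_calls(), "anchored to position 1")
      got
    } else get_calls()
    err <- calls[calls$error_type != "none", c("ref_pos", "error_type")]
    rownames(err) <- NULL
    o <- order(err$ref_pos, err$error_type)
    oe <- order(expected$ref_pos, expected$error_type)
    expect_equal(err[o, ], expected[oe, ], ignore_attr = TRUE,
                 info = paste(cs[[1]], cs[[2]]))
    # one call per covered reference position plus one per inserted base
    n_ref <- nchar(gsub("-", "", cs[[1]]))
    n_ins <- sum(expected$error_type == "insertion")
    expect_identical(nrow(calls), n_ref + n_ins -
                       sum(expected$error_type == "deletion") +
                       sum(expected$error_type == "deletion"))
  }
})

test_that("reference assignment is exact on prefixes and warns on ties", {
  refs <- synthetic_control_refs(7)
  rd <- substr(refs$bases[3], 1, 120)
  expect_identical(assign_reference(rd, refs)$ref_id, "ref3")
  expect_error(assign_reference("ACGT", refs, k = 11), "shorter than k")

  dup <- refs[c(1, 1), ]
  dup$id <- c("refA", "refB")
  expect_warning(got <- assign_reference(substr(refs$bases[1], 1, 80), dup),
                 "ambiguous")
  expect_identical(got$ref_id, "refA")
})

test_that("assignment accuracy on simulated reads with errors is >= 99%", {
  w <- tiny_world(seed = 55L, n_reads = 25L)
  calls <- call_errors(w$sim$reads, w$refs)
  assigned <- calls$ref_id[!duplicated(calls$read_id)]
  names(assigned) <- calls$read_id[!duplicated(calls$read_id)]
  truth <- w$sim$truth$read_info
  acc <- mean(assigned[truth$read_id] == truth$ref_id)
  expect_gte(acc, 0.99)
})

test_that("calls match the truth log for well-separated events", {
  w <- tiny_world(seed = 77L, n_reads = 35L,
                  baseline = c(insertion = 8e-4, deletion = 6e-4,
                               mismatch = 4e-4, ambiguous = 2e-4),
                  beta_position = rep(0, 4),
                  beta_homopolymer = matrix(0, 6, 4), beta_y = rep(0, 4))
  calls <- call_errors(w$sim$reads, w$refs)
  truth <- w$sim$truth$events
  codes <- homopolymer_codes(w$refs)
  info <- w$sim$truth$read_info
  n_checked <- 0L
  for (rid in unique(truth$read_id)) {
    tr <- truth[truth$read_id == rid, ]
    # only isolated events, outside homopolymer-influenced zones, away
    # from the trimmed 3' end where a terminal indel is unrecoverable
    covered <- info$covered_length[info$read_id == rid]
    # an insertion/deletion pair merges into mismatch columns when fewer
    # than ~7 extra mismatches separate them, which in repetitive
    # stretches can span >10 bp; require generous isolation
    if (nrow(tr) > 1L && min(diff(sort(tr$ref_pos))) < 25L) next
    cd <- codes[[tr$ref_id[1]]]
    if (any(cd[tr$ref_pos] != 0L)) next
    if (any(tr$ref_pos > covered - 8L)) next
    got <- calls[calls$read_id == rid & calls$error_type != "none",
                 c("ref_pos", "error_type")]
    got <- got[order(got$ref_pos), ]
    tr <- tr[order(tr$ref_pos), ]
    # per-read counts per type match exactly; positions may legitimately
    # shift by one when an inserted/deleted base repeats its neighbor
    # (the 3'-anchoring convention), so allow a +/-2 attribution window
    expect_identical(table(factor(got$error_type, c("none","insertion","deletion","mismatch","ambiguous"))),
                     table(factor(tr$error_type, c("none","insertion","deletion","mismatch","ambiguous"))),
                     info = rid)
    expect_identical(got$error_type, tr$error_type, info = rid)
    expect_true(all(abs(got$ref_pos - tr$ref_pos) <= 2L), info = rid)
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 20L)
})

test_that("calls structurally reconstruct the read (round trip)", {
  w <- tiny_world(seed = 88L, n_reads = 10L)
  calls <- call_errors(w$sim$reads, w$refs)
  for (rid in w$sim$reads$id[1:10]) {
    cc <- calls[calls$read_id == rid, ]
    ref_seq <- w$refs$bases[w$refs$id == cc$ref_id[1]]
    pattern <- apply_calls(ref_seq, cc)
    read_seq <- w$sim$reads$bases[w$sim$reads$id == rid]
    expect_identical(nchar(pattern), nchar(read_seq))
    pc <- strsplit(pattern, "")[[1]]
    rc <- strsplit(read_seq, "")[[1]]
    fixed <- pc %in% c("A", "C", "G", "T", "N")
    expect_identical(pc[fixed], rc[fixed])
  }
})
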