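# Hand-constructed alignment fixtures: gapped reference, gapped read, and
# the hand-derived error calls as "refpos:type" tokens (none rows implied).
# Conventions under test: insertions anchored to the preceding reference
# base (position 1 if none, with a warning), one call per inserted base,
# deletions at the reference position of the gapped base, read N =
# ambiguous (unless the N sits in an inserted column), identical = none.
hand_alignments <- function() {
  list(
    list("ACGT",     "ACGT",     character(0)),
    list("ACG-T",    "ACGGT",    "3:insertion"),
    list("AC-GT",    "ACGGT",    "2:insertion"),
    list("ACGT",     "A-GT",     "2:deletion"),
    list("ACGT",     "ACNT",     "3:ambiguous"),
    list("ACGT",     "ACTT",     "3:mismatch"),
    list("-ACG",     "TACG",     "1:insertion", warn = TRUE),
    list("AC--GT",   "ACTTGT",   c("2:insertion", "2:insertion")),
    list("ACGT--",   "ACGTTT",   c("4:insertion", "4:insertion")),
    list("AACCGG",   "A-C-GG",   c("2:deletion", "4:deletion")),
    list("AAAA",     "AA-A",     "3:deletion"),
    list("AAA-C",    "AAAAC",    "3:insertion"),
    list("GATTACA",  "GA-TACA",  "3:deletion"),
    list("GATTACA",  "GATTNCA",  "5:ambiguous"),
    list("GATTACA",  "GCTTACA",  "2:mismatch"),
    list("AC-GT",    "ACNGT",    "2:insertion"),
    list("ACGT",     "-CGT",     "1:deletion"),
    list("--ACGT",   "GGACGT",   c("1:insertion", "1:insertion"), warn = TRUE),
    list("ACGT",     "ACG-",     "4:deletion"),
    list("AAACCC",   "AAA-CC",   "4:deletion"),
    list("AAACCC",   "AA-CCC",   "3:deletion"),
    list("AAA--CCC", "AAAGGCCC", c("3:insertion", "3:insertion")),
    list("ACGTACGT", "ACGTACG-", "8:deletion"),
    list("ACGTAC",   "NCGTAC",   "1:ambiguous"),
    list("ACGTAC",   "ANGTAC",   "2:ambiguous"),
    list("TTTGGA",   "TTTGCA",   "5:mismatch"),
    list("A-CGT",    "AACGT",    "1:insertion"),
    list("ACG--T",   "ACGCAT",   c("3:insertion", "3:insertion")),
    list("AACC",     "GACC",     "1:mismatch"),
    list("ACGTG",    "AC-TG",    "3:deletion"),
    list("GG-TT",    "GGATT",    "2:insertion"),
    list("CCCC",     "C--C",     c("2:deletion", "3:deletion")),
    list("GATTACA",  "GAT-ANA",  c("4:deletion", "6:ambiguous")),
    list("AC-GTA",   "ACGG-A",   c("2:insertion", "4:deletion"))
  )
}

parse_expect <- function(tokens) {
  if (length(tokens) == 0L) {
    return(data.frame(ref_pos = integer(0), error_type = character(0)))
  }
  parts <- strsplit(tokens, ":", fixed = TRUE)
  data.frame(ref_pos = as.integer(vapply(parts, `[`, "", 1L)),
             error_type = vapply(parts, `[`, "", 2L),
             stringsAsFactors = FALSE)
}

# small deterministic simulated world shared by several test files
tiny_world <- function(seed = 99L, n_reads = 40L, plates = "plate1", ...) {
  refs <- synthetic_control_refs(7)
  cfg <- sim_config(n_reads = n_reads, plates = plates, seed = seed, ...)
  sim <- simulate_reads(refs, cfg)
  list(refs = refs, sim = sim)
}
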