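test_that("generate_reference honors structure constraints", {
  ref <- generate_reference(500, 0.55, 20, seed = 3L)
  expect_identical(ref$length, 500L)
  expect_identical(count_homopolymers(ref), 20L)
  gc <- mean(strsplit(ref$bases, "")[[1]] %in% c("C", "G"))
  expect_lte(abs(gc - 0.55), 0.02)

  # homopolymers at least 3 apart: gaps between coded runs
  chars <- strsplit(ref$bases, "")[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  runs <- which(r$lengths >= 3L)
  expect_true(all(diff(c(rbind(starts[runs], ends[runs])))[c(FALSE, TRUE)] > 3L))

  none <- generate_reference(80, 0.5, 0, seed = 4L)
  expect_identical(count_homopolymers(none), 0L)

  expect_identical(generate_reference(300, 0.6, 12, seed = 9L)$bases,
                   generate_reference(300, 0.6, 12, seed = 9L)$bases)
  expect_error(generate_reference(50, 0.5, 20), "infeasible")
})

test_that("same sim_config reproduces reads and truth bit for bit", {
  w1 <- tiny_world(seed = 5L, n_reads = 15L)
  w2 <- tiny_world(seed = 5L, n_reads = 15L)
  expect_identical(w1$sim$reads, w2$sim$reads)
  expect_identical(w1$sim$truth, w2$sim$truth)
  w3 <- tiny_world(seed = 6L, n_reads = 15L)
  expect_false(identical(w1$sim$reads$bases, w3$sim$reads$bases))
})

test_that("zero error probabilities give clean reference prefixes", {
  refs <- synthetic_control_refs(7)
  cfg <- sim_config(n_reads = 10L, plates = "p1",
                    baseline = c(insertion = 0, deletion = 0,
                                 mismatch = 0, ambiguous = 0),
                    beta_position = rep(0, 4),
                    beta_homopolymer = matrix(0, 6, 4),
                    beta_y = rep(0, 4), seed = 8L)
  sim <- simulate_reads(refs, cfg)
  expect_identical(nrow(sim$truth$events), 0L)
  info <- sim$truth$read_info
  for (i in seq_len(nrow(sim$reads))) {
    ref <- refs$bases[refs$id == info$ref_id[i]]
    expect_identical(sim$reads$bases[i],
                     substr(ref, 1L, info$covered_length[i]))
  }
})

test_that("with zero slopes the per-type rates converge to the baselines", {
  refs <- generate_reference(500, 0.55, 20, seed = 12L, id = "refA")
  p_ins <- 0.01
  cfg <- sim_config(n_reads = 300L, plates = "p1",
                    baseline = c(insertion = p_ins, deletion = 0,
                                 mismatch = 0, ambiguous = 0),
                    beta_position = rep(0, 4),
                    beta_homopolymer = matrix(0, 6, 4),
                    beta_y = rep(0, 4),
                    full_length_prob = 1, seed = 13L)
  sim <- simulate_reads(refs, cfg)
  n_pos <- sum(sim$truth$read_info$covered_length)
  expect_gte(n_pos, 1e5)
  obs <- nrow(sim$truth$events) / n_pos
  se <- sqrt(p_ins * (1 - p_ins) / n_pos)
  expect_lt(abs(obs - p_ins), 3 * se)
  expect_true(all(sim$truth$events$error_type == "insertion"))
})

test_that("a homopolymer-code effect of +1 shifts the odds by e", {
  refs <- generate_reference(400, 0.5, 30, homopolymer_lengths = 3,
                             seed = 21L, id = "refB")
  codes <- as.integer(annotate_homopolymers(refs[1, ]))
  bh <- matrix(0, 6, 4)
  bh[3, 2] <- 1 # code 3, deletion type
  p0 <- 0.01
  cfg <- sim_config(n_reads = 1500L, plates = "p1",
                    baseline = c(insertion = 0, deletion = p0,
                                 mismatch = 0, ambiguous = 0),
                    beta_position = rep(0, 4), beta_homopolymer = bh,
                    beta_y = rep(0, 4), full_length_prob = 1, seed = 22L)
  sim <- simulate_reads(refs, cfg)
  ev <- sim$truth$events
  n_reads <- nrow(sim$reads)
  at3 <- which(codes == 3L)
  at0 <- which(codes == 0L)
  rate3 <- sum(ev$ref_pos %in% at3) / (n_reads * length(at3))
  rate0 <- sum(ev$ref_pos %in% at0) / (n_reads * length(at0))
  odds <- function(p) p / (1 - p)
  ratio <- odds(rate3) / odds(rate0)
  # sampling tolerance: log odds-ratio within 3 SE of 1
  se_log <- sqrt(1 / sum(ev$ref_pos %in% at3) + 1 / sum(ev$ref_pos %in% at0))
  expect_lt(abs(log(ratio) - 1), 3.2 * se_log)
})

test_that("event probabilities summing above one are rejected, not clipped", {
  refs <- generate_reference(100, 0.5, 4, seed = 31L)
  cfg <- sim_config(n_reads = 5L, plates = "p1",
                    baseline = c(insertion = 0.4, deletion = 0.4,
                                 mismatch = 0.3, ambiguous = 0.1),
                    beta_position = rep(0, 4),
                    beta_homopolymer = matrix(0, 6, 4),
                    beta_y = rep(0, 4), seed = 32L)
  expect_error(simulate_reads(refs, cfg), "sum to.*> 1")
})

test_that("read lengths follow the covered length and injected indels", {
  w <- tiny_world(seed = 41L, n_reads = 30L)
  ev <- w$sim$truth$events
  info <- w$sim$truth$read_info
  d_ins <- table(factor(ev$read_id[ev$error_type == "insertion"],
                        levels = info$read_id))
  d_del <- table(factor(ev$read_id[ev$error_type == "deletion"],
                        levels = info$read_id))
  expect_identical(w$sim$reads$length[match(info$read_id, w$sim$reads$id)],
                   as.integer(info$covered_length + as.integer(d_ins) -
                                as.integer(d_del)))
})
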