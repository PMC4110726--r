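test_that("genome simulation is seeded-deterministic and plants repeats", {
  g1 <- simulate_genome(10000, seed = 5)
  g2 <- simulate_genome(10000, seed = 5)
  expect_identical(g1$sequences, g2$sequences)
  expect_equal(nchar(g1$sequences[[1]]), 10000)

  rep0 <- data.frame(src_start = 1000, len = 500, dest_start = 8000,
                     divergence = 0)
  g <- simulate_genome(10000, repeats = rep0, seed = 7)
  s <- g$sequences[[1]]
  expect_identical(substr(s, 1001, 1500), substr(s, 8001, 8500))

  # 2% divergence: copy differs by Binomial(500, 0.02 * 3/4 effective? no:
  # each hit substitutes to a different base, so expected mismatches = 10
  rep2 <- data.frame(src_start = 1000, len = 500, dest_start = 8000,
                     divergence = 0.02)
  gd <- simulate_genome(10000, repeats = rep2, seed = 9)
  sd_ <- gd$sequences[[1]]
  d <- loop_hamming(substr(sd_, 1001, 1500), substr(sd_, 8001, 8500))
  sigma <- sqrt(500 * 0.02 * 0.98)
  expect_lt(abs(d - 10), 3 * sigma + 1)

  expect_error(simulate_genome(2000, repeats = data.frame(
    src_start = 1900, len = 500, dest_start = 0, divergence = 0)), "exceeds")
  expect_error(simulate_genome(500), ">= 1000")
})

test_that("error profile ramps along the read, scales and caps", {
  p1 <- error_profile(1)
  expect_length(p1, 80)
  expect_true(all(diff(p1) >= 0))  # non-decreasing along the read
  expect_equal(p1[1], 0.001)
  expect_equal(p1[80], 0.01)
  p10 <- error_profile(10)
  expect_equal(as.numeric(p10), pmin(as.numeric(p1) * 10, 0.75))
  expect_true(all(error_profile(1000) <= 0.75))
})

test_that("read simulation honours the profile and records truth exactly", {
  g <- simulate_genome(20000, seed = 11)
  # zero error rate: every read is an exact (possibly reverse-complemented)
  # substring of the genome at its recorded origin
  sim0 <- simulate_reads(g, 50, profile = error_profile(0), seed = 13)
  expect_equal(sim0$truth$n_errors, rep(0L, 50))
  s <- g$sequences[[1]]
  for (i in 1:50) {
    win <- substr(s, sim0$truth$pos[i] + 1, sim0$truth$pos[i] + 80)
    if (sim0$truth$strand[i] == "-") win <- revcomp(win)
    expect_identical(sim0$reads$seq[i], win)
  }
  # planted error counts equal the Hamming distance to the origin window
  sim10 <- simulate_reads(g, 50, profile = error_profile(10), seed = 15)
  for (i in 1:50) {
    win <- substr(s, sim10$truth$pos[i] + 1, sim10$truth$pos[i] + 80)
    if (sim10$truth$strand[i] == "-") win <- revcomp(win)
    expect_equal(loop_hamming(sim10$reads$seq[i], win),
                 sim10$truth$n_errors[i])
  }
})

test_that("mean planted errors match the binomial expectation of the curve", {
  g <- simulate_genome(50000, seed = 21)
  prof <- error_profile(10)
  sim <- simulate_reads(g, 2000, profile = prof, seed = 23)
  mu <- sum(prof)
  sigma <- sqrt(sum(prof * (1 - prof)))
  expect_lt(abs(mean(sim$truth$n_errors) - mu), 3 * sigma / sqrt(2000))
})

test_that("read simulation is byte-identical under a fixed seed", {
  g <- simulate_genome(5000, seed = 31)
  a <- simulate_reads(g, 30, profile = error_profile(2), seed = 33)
  b <- simulate_reads(g, 30, profile = error_profile(2), seed = 33)
  expect_identical(a, b)
  p1 <- tempfile(fileext = ".fq"); p2 <- tempfile(fileext = ".fq")
  write_fastq(a$reads, p1); write_fastq(b$reads, p2)
  expect_identical(readLines(p1), readLines(p2))
  back <- read_fastq(p1)
  expect_equal(back$seq, a$reads$seq)
  expect_equal(back$read_id, a$reads$read_id)
  unlink(c(p1, p2))
})

test_that("classify_error separates correct, incorrect and unrecoverable", {
  # two diverged copies; a read from the source whose planted errors drag it
  # toward the copy becomes unrecoverable by construction
  g <- simulate_genome(6000, repeats = data.frame(
    src_start = 1000, len = 200, dest_start = 4000, divergence = 0.05),
    seed = 41)
  s <- g$sequences[[1]]
  src <- substr(s, 1051, 1110)
  copy <- substr(s, 4051, 4110)
  truth <- list(chrom = "synth1", pos = 1050, strand = "+", seq = src)

  # mapped at the true origin
  ok <- classify_error(list(chrom = "synth1", pos = 1050, strand = "+"),
                       truth, g)
  expect_equal(ok$status, "correct")
  expect_true(ok$recoverable)

  # absent mapping
  sk <- classify_error(NULL, truth, g)
  expect_equal(sk$status, "skipped")

  # read mutated onto the copy: the copy is now strictly closer than the
  # origin, so a mapping there is incorrect AND unrecoverable
  diffs <- which(strsplit(src, "")[[1]] != strsplit(copy, "")[[1]])
  read_bad <- src
  for (p in diffs) substr(read_bad, p, p) <- substr(copy, p, p)
  truth_bad <- list(chrom = "synth1", pos = 1050, strand = "+",
                    seq = read_bad)
  bad <- classify_error(list(chrom = "synth1", pos = 4050, strand = "+"),
                        truth_bad, g)
  expect_equal(bad$status, "incorrect")
  expect_false(bad$recoverable)

  # a unique-origin read mapped elsewhere is incorrect but recoverable
  rec <- classify_error(list(chrom = "synth1", pos = 2222, strand = "+"),
                        truth, g)
  expect_equal(rec$status, "incorrect")
  expect_true(rec$recoverable)
})

test_that("evaluate_mappings tabulates statuses and potential accuracy", {
  g <- simulate_genome(5000, seed = 51)
  sim <- simulate_reads(g, 20, profile = error_profile(0), seed = 53)
  perfect <- data.frame(read_id = sim$truth$read_id, chrom = sim$truth$chrom,
                        pos = sim$truth$pos, strand = sim$truth$strand,
                        stringsAsFactors = FALSE)
  rep <- evaluate_mappings(perfect, sim$truth, g)
  expect_equal(rep$accuracy, 100)
  expect_equal(rep$n_correct + rep$n_incorrect + rep$n_skipped, rep$n_reads)

  # half the reads dropped: accuracy 50, skipped error-free reads all
  # recoverable
  half <- perfect[1:10, ]
  rep2 <- evaluate_mappings(half, sim$truth, g)
  expect_equal(rep2$accuracy, 50)
  expect_equal(rep2$n_skipped, 10)
  expect_equal(rep2$breakdown$potential_accuracy[
    rep2$breakdown$subset == "skipped"], 100)
  expect_true(rep2$n_unrecoverable <= rep2$n_incorrect + rep2$n_skipped)

  expect_error(evaluate_mappings(rbind(perfect, perfect[1, ]), sim$truth, g),
               "duplicate")
})

test_that("sliding_hamming agrees with a plain R window scan", {
  g <- simulate_genome(1200, seed = 61)
  s <- g$sequences[[1]]
  read <- substr(s, 101, 130)
  dv <- sliding_hamming(s, read)
  expect_length(dv, 1200 - 30 + 1)
  expect_equal(dv[101], 0)
  set.seed(62)
  for (pos in sample(length(dv), 20)) {
    expect_equal(dv[pos], loop_hamming(substr(s, pos, pos + 29), read))
  }
})

test_that("truth tables round-trip through TSV", {
  g <- simulate_genome(2000, seed = 71)
  sim <- simulate_reads(g, 10, read_len = 40,
                        profile = error_profile(1, read_len = 40), seed = 73)
  path <- tempfile(fileext = ".tsv")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$read_id, sim$truth$read_id)
  expect_equal(back$pos, sim$truth$pos)
  expect_equal(back$seq, sim$truth$seq)
  unlink(path)
})
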