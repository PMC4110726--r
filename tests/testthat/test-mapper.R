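# Small genomes keep the exhaustive oracles cheap; the index itself is
# exercised at realistic scale by the acceptance suite.

small_index <- function(len = 3000, seed = 7, k = 8,
                        params = apf_params(tau = "auto", m = 0.1, D = 2,
                                            leaf_size = 16, seed = 3)) {
  g <- simulate_genome(len, seed = seed)
  list(genome = g, index = reference_index(g, k = k, params = params))
}

test_that("extract_kmers enumerates windows and both strands", {
  pts <- extract_kmers(c(chr1 = "acgtacgt"), k = 4, strands = "+")
  expect_equal(nrow(pts), 5)  # L - k + 1
  expect_equal(pts$seq[1], "acgt")
  expect_equal(pts$start, 0:4)
  # reverse strand stores the reverse complement at forward coordinates
  both <- extract_kmers(c(chr1 = "acgt"), k = 4)
  expect_equal(nrow(both), 2)
  expect_setequal(both$strand, c("+", "-"))
  expect_equal(both$seq[both$strand == "-"], revcomp("acgt"))
  # windows overlapping an N are skipped
  withN <- extract_kmers(c(chr1 = "acgtnacgtacg"), k = 4, strands = "+")
  expect_false(any(grepl("n", withN$seq)))
  expect_equal(nrow(withN), 5)  # only the 5 windows right of the N
  expect_warning(expect_warning(extract_kmers(c(chr1 = "acg"), k = 4),
                                "shorter"),
                 "no k-mers")
})

test_that("kmer point sequences equal the genome substring at their coordinates", {
  g <- simulate_genome(1500, seed = 11)
  pts <- extract_kmers(g, k = 8)
  s <- g$sequences[[1]]
  set.seed(12)
  for (i in sample(nrow(pts), 50)) {
    win <- substr(s, pts$start[i] + 1, pts$start[i] + 8)
    expect_equal(pts$seq[i], if (pts$strand[i] == "+") win else revcomp(win))
  }
})

test_that("reads matching a unique substring map exactly there", {
  si <- small_index()
  s <- si$genome$sequences[[1]]
  read <- substr(s, 501, 560)
  mr <- map_read(read, si$index, r = 2)
  expect_equal(mr$status, "unique")
  expect_equal(mr$pos, 500)
  expect_equal(mr$strand, "+")
  expect_equal(mr$distance, 0)
  # and its reverse complement maps to the same spot on the minus strand
  mr2 <- map_read(revcomp(read), si$index, r = 2)
  expect_equal(mr2$pos, 500)
  expect_equal(mr2$strand, "-")
  expect_equal(mr2$distance, 0)
})

test_that("reads from planted exact repeats tie and pick reproducibly", {
  g <- simulate_genome(4000, repeats = data.frame(
    src_start = 200, len = 400, dest_start = 3000, divergence = 0),
    seed = 21)
  idx <- reference_index(g, k = 8,
                         params = apf_params(tau = "auto", m = 0.1, D = 2,
                                             leaf_size = 16, seed = 3))
  read <- substr(g$sequences[[1]], 301, 360)  # inside the duplicated block
  mr <- map_read(read, idx, r = 2, seed = 5)
  expect_equal(mr$status, "tied_random")
  expect_equal(mr$n_candidates, 2)
  expect_equal(mr$mapq, 0)
  expect_true(mr$pos %in% c(300, 3100))
  mr2 <- map_read(read, idx, r = 2, seed = 5)
  expect_identical(mr, mr2)
})

test_that("mapper distance equals the exhaustive sliding-window oracle", {
  si <- small_index(len = 2000, seed = 31)
  sim <- simulate_reads(si$genome, 25, read_len = 40,
                        profile = error_profile(10, read_len = 40), seed = 33)
  mr <- map_reads(sim$reads, si$index, r = 6, seed = 35)
  for (i in seq_len(nrow(mr))) {
    oracle <- loop_best_placement(si$genome$sequences, sim$reads$seq[i])
    if (mr$status[i] == "unmapped") {
      expect_gt(oracle$best, 6)
    } else {
      expect_equal(mr$distance[i], oracle$best)
    }
  }
})

test_that("reads shorter than the seed length are unmapped with reason", {
  si <- small_index()
  mr <- map_read("acgt", si$index, r = 2)
  expect_equal(mr$status, "unmapped")
  expect_equal(mr$n_candidates, 0)
})

test_that("trailing bases are covered by an overlapping final seed", {
  si <- small_index()  # k = 8
  s <- si$genome$sequences[[1]]
  read <- substr(s, 1001, 1019)  # length 19 = 2 full seeds + 3 trailing
  # plant an error inside each full seed; only the trailing seed is clean
  substr(read, 2, 2) <- setdiff(ALPH, substr(read, 2, 2))[1]
  substr(read, 10, 10) <- setdiff(ALPH, substr(read, 10, 10))[1]
  mr <- map_read(read, si$index, r = 4)
  expect_equal(mr$status, "unique")
  expect_equal(mr$pos, 1000)
  expect_equal(mr$distance, 2)
})

test_that("SAM records round-trip and encode strand by FLAG 16", {
  si <- small_index()
  s <- si$genome$sequences[[1]]
  reads <- c(r1 = substr(s, 101, 160), r2 = revcomp(substr(s, 201, 260)),
             r3 = strrep("a", 60))
  mr <- map_reads(reads, si$index, r = 2, seed = 1)
  rec <- mappings_to_sam(mr, reads)
  expect_equal(rec$flag, c(0L, 16L, 4L))
  expect_equal(rec$pos[1], 101L)  # 1-based in SAM
  expect_equal(rec$seq[2], substr(s, 201, 260))  # written reference-forward
  path <- tempfile(fileext = ".sam")
  write_sam(rec, si$genome, path)
  back <- read_sam(path)
  expect_equal(back$qname, rec$qname)
  expect_equal(back$flag, rec$flag)
  expect_equal(back$pos, rec$pos)
  expect_equal(back$mapq, rec$mapq)
  maps <- sam_to_mappings(back)
  expect_equal(maps$pos[1], 100L)  # back to 0-based
  expect_equal(maps$strand[2], "-")
  expect_true(is.na(maps$chrom[3]))
  unlink(path)
})

test_that("the stub aligner maps clean reads and fumbles noisy ones", {
  g <- simulate_genome(3000, seed = 41)
  clean <- simulate_reads(g, 20, read_len = 40,
                          profile = error_profile(0, read_len = 40), seed = 43)
  sam <- heuristic_stub_align(clean$reads, g, k = 12)
  expect_true(all(bitwAnd(sam$flag, 4L) == 0L))
  expect_true(all(sam$mapq >= 30))
  rep <- evaluate_mappings(sam_to_mappings(sam), clean$truth, g)
  expect_equal(rep$accuracy, 100)
  # heavy noise: some reads must come out unmapped or low-confidence
  noisy <- simulate_reads(g, 60, read_len = 40,
                          profile = error_profile(60, read_len = 40), seed = 45)
  sam2 <- heuristic_stub_align(noisy$reads, g, k = 12)
  expect_gt(sum(bitwAnd(sam2$flag, 4L) != 0L | sam2$mapq < 14), 0)
})

test_that("rescue re-maps exactly the low-MAPQ and unmapped records", {
  si <- small_index()
  s <- si$genome$sequences[[1]]
  reads <- c(r1 = substr(s, 101, 160), r2 = substr(s, 301, 360),
             r3 = substr(s, 501, 560), r4 = substr(s, 701, 760))
  sam <- data.frame(qname = names(reads), flag = c(0L, 0L, 0L, 4L),
                    rname = c("synth1", "synth1", "synth1", "*"),
                    pos = c(999L, 999L, 302L, 0L),
                    mapq = c(0L, 13L, 14L, 0L),
                    cigar = c("60M", "60M", "60M", "*"),
                    seq = unname(reads), qual = strrep("I", 60),
                    stringsAsFactors = FALSE)
  merged <- rescue_pipeline(sam, reads, si$index, ensemble_params(mapq_cutoff = 14))
  expect_equal(merged$qname, names(reads))
  expect_equal(merged$rescued, c(TRUE, TRUE, FALSE, TRUE))
  # records at or above the cutoff pass through untouched (wrong pos kept)
  expect_equal(merged$pos[3], 302L)
  # rescued records are corrected
  expect_equal(merged$pos[1], 101L)
  expect_equal(merged$pos[2], 301L)
  expect_equal(merged$pos[4], 701L)
})

test_that("rescue with all-confident input is the identity", {
  si <- small_index()
  s <- si$genome$sequences[[1]]
  reads <- c(r1 = substr(s, 101, 160), r2 = substr(s, 301, 360))
  sam <- heuristic_stub_align(reads, si$genome, k = 8)
  expect_true(all(sam$mapq >= 14))
  merged <- rescue_pipeline(sam, reads, si$index, ensemble_params())
  expect_equal(merged$pos, sam$pos)
  expect_false(any(merged$rescued))
})

test_that("a read present in the SAM but missing from the read set errors", {
  si <- small_index()
  sam <- data.frame(qname = "ghost", flag = 4L, rname = "*", pos = 0L,
                    mapq = 0L, cigar = "*", seq = strrep("a", 20),
                    qual = strrep("I", 20), stringsAsFactors = FALSE)
  expect_error(rescue_pipeline(sam, c(r1 = strrep("a", 20)), si$index),
               "absent")
})
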