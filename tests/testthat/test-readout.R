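test_that("demultiplexing conserves every read and tolerates one index
           substitution", {
  truth <- random_grid(21)
  sets <- lapply(1:5, function(i)
    simulate_plate(truth, noiseless_params(15), fix_codes,
                   fix_index[i, ], seed = i))
  pool <- pool_images(sets, seed = 3)
  dm <- demultiplex(pool, fix_index)
  assigned <- sum(vapply(dm$images, nrow, integer(1)))
  expect_equal(assigned + nrow(dm$unassigned), nrow(pool))
  expect_equal(assigned, nrow(pool))  # error-free reads all assign

  # single i7 substitution still assigns to the right image
  r <- make_read("C3", excised = TRUE, index = fix_index[4, ])
  substr(r, 1, 1) <- setdiff(c("A", "C", "G", "T"), substr(r, 1, 1))[1]
  dm1 <- demultiplex(read_set("r1", r), fix_index, max_mismatch = 1)
  expect_identical(names(dm1$images), fix_index$image[4])

  # a foreign index pair goes to unassigned
  foreign <- paste0(strrep("T", 8), substring(make_read("A1"), 9))
  foreign <- paste0(substr(foreign, 1, nchar(foreign) - 8), strrep("G", 8))
  dm2 <- demultiplex(read_set("r2", foreign), fix_index, max_mismatch = 1)
  expect_equal(length(dm2$images), 0)
  expect_equal(nrow(dm2$unassigned), 1)

  # truncated garbage is counted as malformed, never dropped silently
  dm3 <- demultiplex(read_set("r3", "ACGT"), fix_index)
  expect_equal(nrow(dm3$unassigned), 1)
  expect_equal(dm3$summary$reads[dm3$summary$image == "malformed"], 1)
})

test_that("read classification finds the excision junction and the intact
           locus, and random bases are ambiguous", {
  r_exc <- make_read("B2", excised = TRUE)
  r_int <- make_read("B2", excised = FALSE)
  cl <- classify_reads(read_set(c("a", "b"), c(r_exc, r_int)), fix_codes)
  expect_identical(cl$class, c("EXCISED", "INTACT"))
  expect_identical(cl$well, c("B2", "B2"))
  expect_identical(cl$channel, c("blue", "blue"))

  set.seed(13)
  junk <- paste(sample(c("A", "C", "G", "T"), nchar(r_int), TRUE),
                collapse = "")
  clj <- classify_reads(read_set("j", junk), fix_codes)
  expect_identical(clj$class, "AMBIGUOUS")

  # a substitution inside the signature window, within budget, still
  # classifies: window sits after i7+pad+code+left_flank+loxP = 88 bases
  r_err <- r_exc
  substr(r_err, 90, 90) <- setdiff(c("A", "C", "G", "T"),
                                   substr(r_err, 90, 90))[1]
  expect_identical(classify_reads(read_set("e", r_err), fix_codes)$class,
                   "EXCISED")
})

test_that("ratio values are the bounded excision fraction of hand-built
           read lists", {
  reads <- read_set(
    paste0("r", 1:20),
    c(replicate(7, make_read("D4", excised = TRUE)),
      replicate(3, make_read("D4", excised = FALSE)),
      replicate(10, make_read("E5", excised = TRUE))))
  rt <- count_and_ratio(reads, fix_codes)
  d4 <- rt[rt$well == "D4", ]
  e5 <- rt[rt$well == "E5", ]
  expect_equal(d4$n_excised, 7)
  expect_equal(d4$n_intact, 3)
  expect_equal(d4$value, 0.7)
  expect_equal(e5$value, 1.0)
  a1 <- rt[rt$well == "A1", ]
  expect_true(a1$missing)
  expect_true(is.na(a1$value))
  # counting partitions are exhaustive and disjoint
  expect_equal(sum(rt$n_excised + rt$n_intact + rt$n_ambiguous), 20)
})

test_that("blue and red channels never cross-contaminate without errors", {
  truth_b <- random_grid(31)
  truth_r <- random_grid(32)
  rb <- simulate_plate(truth_b, noiseless_params(12), fix_codes,
                       fix_index[1, ], color = "blue", seed = 1)
  rr <- simulate_plate(truth_r, noiseless_params(12), fix_codes,
                       fix_index[1, ], color = "red", seed = 2)
  pool <- pool_images(list(rb, rr), seed = 3)
  rt <- count_and_ratio(pool, fix_codes)
  blue <- rt[rt$channel == "blue", ]
  red <- rt[rt$channel == "red", ]
  expect_equal(sum(blue$coverage), nrow(rb))
  expect_equal(sum(red$coverage), nrow(rr))
  # each channel's ratios reflect its own truth exactly
  expect_identical(as.integer(blue$value[match(attr(rb, "sidecar")$well,
                                               blue$well)]),
                   attr(rb, "sidecar")$true_bit)
  expect_identical(as.integer(red$value[match(attr(rr, "sidecar")$well,
                                              red$well)]),
                   attr(rr, "sidecar")$true_bit)
})

test_that("FASTQ round-trips losslessly, including gzip", {
  truth <- random_grid(41)
  reads <- simulate_plate(truth, noiseless_params(5), fix_codes,
                          fix_index[1, ], seed = 6)
  for (ext in c(".fastq", ".fastq.gz")) {
    f <- withr::local_tempfile(fileext = ext)
    write_fastq(reads, f)
    back <- read_fastq(f)
    expect_identical(back$seq, reads$seq)
    expect_identical(back$id, reads$id)
    expect_identical(back$qual, reads$qual)
  }
  # a hand-written 4-line record parses to the expected fields
  f <- withr::local_tempfile(fileext = ".fastq")
  writeLines(c("@readA", "ACGTACGT", "+", "IIIIIIII"), f)
  one <- read_fastq(f)
  expect_identical(one$id, "readA")
  expect_identical(one$seq, "ACGTACGT")
  expect_identical(one$qual, "IIIIIIII")
})
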