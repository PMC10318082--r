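test_that("degenerate channel yields exactly the prescribed reads", {
  truth <- random_grid(3)
  reads <- simulate_plate(truth, noiseless_params(10), fix_codes,
                          fix_index[1, ], seed = 4)
  expect_equal(nrow(reads), 960)
  sc <- attr(reads, "sidecar")
  expect_identical(sc$depth, rep(10, 96))
  expect_identical(sc$n_excised, ifelse(sc$true_bit == 1, 10L, 10L * 0L))
  # every read classifies cleanly and agrees with its well's bit
  cl <- classify_reads(reads, fix_codes)
  expect_false(any(cl$class == "AMBIGUOUS"))
  bit_of <- sc$true_bit[match(cl$well, sc$well)]
  expect_identical(cl$class == "EXCISED", bit_of == 1L)
})

test_that("an all-OFF noiseless plate emits zero excised reads", {
  truth <- pattern_grid("OFF")
  reads <- simulate_plate(truth, noiseless_params(10), fix_codes,
                          fix_index[1, ], seed = 5)
  cl <- classify_reads(reads, fix_codes)
  expect_equal(sum(cl$class == "EXCISED"), 0)
  expect_equal(sum(cl$class == "INTACT"), nrow(reads))
})

test_that("latent Beta fractions are recovered by deep sequencing", {
  truth <- random_grid(8)
  params <- channel_params(f_on = c(9, 1), f_off = c(1, 9), depth_mean = 500,
                           depth_dispersion = 5, sub_error_rate = 0)
  reads <- simulate_plate(truth, params, fix_codes, fix_index[1, ], seed = 7)
  sc <- attr(reads, "sidecar")
  # empirical well means match Beta means within 3 standard errors
  for (state in 0:1) {
    f <- sc$f_w[sc$true_bit == state]
    mu <- if (state == 1) 9 / 10 else 1 / 10
    sd_beta <- sqrt(9 / (10^2 * 11))
    expect_lt(abs(mean(f) - mu), 3 * sd_beta / sqrt(length(f)))
  }
  # per-well empirical excised fraction tracks the stored latent value
  ratios <- count_and_ratio(reads, fix_codes)
  m <- match(ratios$well, sc$well)
  keep <- ratios$coverage > 100
  expect_lt(max(abs(ratios$value[keep] - sc$n_excised[m][keep] /
                      sc$depth[m][keep])), 1e-12)
})

test_that("pooling conserves reads and per-index counts", {
  truth <- random_grid(1)
  sets <- lapply(1:3, function(i)
    simulate_plate(truth, noiseless_params(20), fix_codes,
                   fix_index[i, ], seed = i))
  pool <- pool_images(sets, seed = 1)
  expect_equal(nrow(pool), sum(vapply(sets, nrow, integer(1))))
  expect_identical(sort(pool$seq), sort(unlist(lapply(sets, `[[`, "seq"))))
  one <- pool_images(sets[1], seed = 2)
  expect_identical(sort(one$id), sort(sets[[1]]$id))
  # per-index counts conserved through the pool
  dm <- demultiplex(pool, fix_index)
  for (i in 1:3) {
    expect_equal(nrow(dm$images[[fix_index$image[i]]]), nrow(sets[[i]]))
  }
})

test_that("dilution is binomial thinning and factor 1 is the identity", {
  truth <- random_grid(2)
  pool <- simulate_plate(truth, noiseless_params(105), fix_codes,
                         fix_index[1, ], seed = 2)
  expect_identical(dilute(pool, 1, seed = 1)$seq, pool$seq)
  n <- nrow(pool)  # 10,080 reads
  kept <- vapply(1:5, function(s) nrow(dilute(pool, 10, seed = s)),
                 integer(1))
  ci <- qbinom(c(0.005, 0.995), n, 1 / 10)
  expect_true(all(kept >= ci[1] & kept <= ci[2]))
})

test_that("random access keeps only target-index reads at rate 0 and warns
           when the target is absent", {
  truth <- random_grid(4)
  sets <- lapply(1:3, function(i)
    simulate_plate(truth, noiseless_params(20), fix_codes,
                   fix_index[i, ], seed = i))
  pool <- pool_images(sets, seed = 9)
  enr <- random_access(pool, fix_index[2, ], amplification = 3,
                       off_target_rate = 0, seed = 5)
  expect_equal(nrow(enr), 3 * nrow(sets[[2]]))
  idx7 <- substr(enr$seq, 1, 8)
  expect_true(all(idx7 == fix_index$i7[2]))
  expect_warning(
    empty <- random_access(pool, fix_index[9, ], amplification = 2, seed = 1),
    "absent")
  expect_equal(nrow(empty), 0)
})

test_that("paired-end mates carry the indexes and classify like single-end", {
  truth <- random_grid(6)
  pe <- simulate_plate(truth, noiseless_params(10), fix_codes,
                       fix_index[1, ], seed = 11, paired = TRUE,
                       read_length = 120)
  expect_s3_class(pe, "paired_reads")
  expect_equal(nrow(pe$r1), nrow(pe$r2))
  cl <- classify_reads(pe, fix_codes)
  expect_false(any(cl$class == "AMBIGUOUS"))
  sc <- attr(pe, "sidecar")
  bit_of <- sc$true_bit[match(cl$well, sc$well)]
  expect_identical(cl$class == "EXCISED", bit_of == 1L)
  dm <- demultiplex(pe, fix_index)
  expect_equal(nrow(dm$images[[fix_index$image[1]]]$r1), nrow(pe$r1))
})
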