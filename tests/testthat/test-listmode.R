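randomCoincidences <- function(n, seed = 1) {
  set.seed(seed)
  ids <- t(apply(matrix(sample.int(24408L, 2 * n, replace = TRUE) - 1L,
                        n, 2), 1, sort))
  ids[ids[, 1] == ids[, 2], 2] <- ids[ids[, 1] == ids[, 2], 2] + 1L
  data.frame(id_a = ids[, 1], id_b = ids[, 2],
             e_a = sample(100:650, n, replace = TRUE),
             e_b = sample(100:650, n, replace = TRUE),
             t_ns = round(sort(runif(n, 0, 3.6e12)) * 1000) / 1000,
             ev_a = 1L, ev_b = 1L, sc_a = 0L, sc_b = 0L,
             stream = sample(c("prompt", "delayed"), n, replace = TRUE),
             truth = sample(c("true", "scattered", "random"), n,
                            replace = TRUE))
}

test_that("list-mode files have the documented fixed-size layout", {
  g <- buildGeometry()
  cc <- randomCoincidences(1000)
  f <- tempfile(fileext = ".lm")
  nb <- writeListmode(cc, f, g)
  expect_equal(file.info(f)$size, 64 + 24 * 1000)
  expect_equal(nb, 64 + 24 * 1000)
  # payload rate arithmetic: 132 kHz prompts -> 3.168e6 bytes/s
  expect_equal(listmodeDataRate(132000), 3.168e6)
})

test_that("list-mode round trip is lossless", {
  g <- buildGeometry()
  cc <- randomCoincidences(20000, seed = 2)
  f <- tempfile(fileext = ".lm")
  writeListmode(cc, f, g)
  back <- readListmode(f, g)
  expect_equal(back$id_a, cc$id_a)
  expect_equal(back$id_b, cc$id_b)
  expect_equal(back$e_a, as.numeric(cc$e_a))
  expect_equal(back$t_ns, cc$t_ns)  # ps-quantized timestamps round trip
  expect_equal(back$stream, cc$stream)
  expect_equal(back$truth, cc$truth)
})

test_that("corrupt list-mode files are rejected", {
  g <- buildGeometry()
  cc <- randomCoincidences(10)
  f <- tempfile(fileext = ".lm")
  writeListmode(cc, f, g)
  # truncated payload
  r <- readBin(f, "raw", 64 + 24 * 10)
  f2 <- tempfile()
  writeBin(r[1:(64 + 24 * 9 + 7)], f2)
  expect_error(readListmode(f2), "truncated")
  # bad magic
  r2 <- r
  r2[1] <- as.raw(0)
  f3 <- tempfile()
  writeBin(r2, f3)
  expect_error(readListmode(f3), "magic")
  # geometry hash mismatch
  g2 <- buildGeometry(sectorGap = 1)
  expect_error(readListmode(f, g2), "hash")
})

test_that("LOR histogramming counts prompts and subtracts delayed", {
  g <- toyGeometry()
  cc <- data.frame(id_a = c(0L, 0L, 0L, 5L), id_b = c(20L, 20L, 20L, 30L),
                   e_a = 511, e_b = 511, t_ns = 1:4,
                   ev_a = 1L, ev_b = 1L, sc_a = 0L, sc_b = 0L,
                   stream = c("prompt", "prompt", "delayed", "prompt"))
  lc <- binListmode(cc, g)
  row <- lc[lc$id_a == 0, ]
  expect_equal(row$prompts, 2)
  expect_equal(row$delayed, 1)
  expect_equal(row$net, 1)
  # empty stream
  lc0 <- binListmode(cc[0, ], g)
  expect_equal(nrow(lc0), 0L)
})

test_that("delayed-window subtraction is unbiased on a randoms-only stream", {
  g <- toyGeometry()
  ct <- crystalTable(g)
  idA <- ct$flat_id[ct$sector == 0][1]
  idB <- ct$flat_id[ct$sector == 3][1]
  a <- poissonSingles(2e5, 0.3, tile = idA %/% 13L, flat_id = idA, seed = 14)
  b <- poissonSingles(2e5, 0.3, tile = idB %/% 13L, flat_id = idB, seed = 15)
  b$event_id <- b$event_id + nrow(a)  # different decays: all pairs random
  cc <- sortCoincidences(mergeSingles(a, b), g,
                         acquisitionConfig(energyWindow = NULL))
  lc <- binListmode(cc, g)
  np <- sum(lc$prompts)
  nd <- sum(lc$delayed)
  expect_gt(np, 50)
  expect_lt(abs(np - nd), 3 * sqrt(np + nd))
})
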