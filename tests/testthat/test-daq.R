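test_that("paralyzable dead time reproduces the r*exp(-r*tau) response", {
  tau_us <- 17.2
  r <- 1 / (tau_us * 1e-6)  # at r = 1/tau survivors are r/e
  df <- poissonSingles(r, 0.2, seed = 3)
  acq <- acquisitionConfig(deadTime = tau_us)
  out <- applyDeadTime(df, acq)
  expected <- r * exp(-1) * 0.2
  expect_lt(abs(nrow(out) - expected), 3 * sqrt(expected))
  # survivors are a subset, non-increasing in tau
  expect_true(all(out$t_ns %in% df$t_ns))
  out2 <- applyDeadTime(df, acquisitionConfig(deadTime = 2 * tau_us))
  expect_lte(nrow(out2), nrow(out))
  # tau = 0: identity
  expect_equal(nrow(applyDeadTime(df, acquisitionConfig(deadTime = 0))),
               nrow(df))
})

test_that("dead-time scope and model behave as specified", {
  # two hits 10 us apart in the same tile with tau = 17.2 us: second removed
  df <- data.frame(t_ns = c(0, 10000), flat_id = c(0L, 1L), tile = c(0L, 0L),
                   energy = 511, event_id = 1:2, scattered = 0L, photon = 0L)
  out <- applyDeadTime(df, acquisitionConfig(deadTime = 17.2))
  expect_equal(nrow(out), 1L)
  # different tiles: both survive
  df2 <- df
  df2$tile <- c(0L, 5L)
  expect_equal(nrow(applyDeadTime(df2, acquisitionConfig(deadTime = 17.2))), 2L)
  # nonparalyzable: three hits at 0, 10, 20 us with tau 17.2: keeps 1st and 3rd
  df3 <- data.frame(t_ns = c(0, 10000, 20000), flat_id = 0L, tile = 0L,
                    energy = 511, event_id = 1:3, scattered = 0L, photon = 0L)
  np <- applyDeadTime(df3, acquisitionConfig(deadTime = 17.2,
                                             deadTimeModel = "nonparalyzable"))
  expect_equal(np$t_ns, c(0, 20000))
  # paralyzable: the second (dead) hit extends the dead period, 3rd removed too
  p <- applyDeadTime(df3, acquisitionConfig(deadTime = 17.2))
  expect_equal(p$t_ns, 0)
  expect_error(applyDeadTime(df3[c(2, 1, 3), ], acquisitionConfig()),
               "sorted")
})

test_that("coincidence window pairs and rejects as specified", {
  g <- toyGeometry()
  ct <- crystalTable(g)
  idA <- ct$flat_id[ct$sector == 0][1]
  idB <- ct$flat_id[ct$sector == 3][1]
  mk <- function(dt_ns) data.frame(
    t_ns = c(1000, 1000 + dt_ns), flat_id = c(idA, idB),
    tile = c(idA, idB) %/% 13L, energy = 511, event_id = c(1L, 1L),
    scattered = 0L, photon = 0:1)
  acq <- acquisitionConfig(energyWindow = NULL)
  expect_equal(sum(sortCoincidences(mk(3), g, acq)$stream == "prompt"), 1L)
  expect_equal(sum(sortCoincidences(mk(7), g, acq)$stream == "prompt"), 0L)
  # canonical ordering
  cc <- sortCoincidences(mk(3), g, acq)
  expect_true(all(cc$id_a < cc$id_b))
  # window with three singles is discarded
  df3 <- rbind(mk(3), mk(3)[2, ])
  df3$t_ns <- c(1000, 1002, 1004)
  expect_equal(sum(sortCoincidences(df3, g, acq)$stream == "prompt"), 0L)
  # wider window accepts at least as many prompts
  r <- poissonSingles(2e5, 0.05, tile = idA %/% 13L, flat_id = idA, seed = 8)
  r2 <- poissonSingles(2e5, 0.05, tile = idB %/% 13L, flat_id = idB, seed = 9)
  m <- mergeSingles(r, r2)
  n1 <- sum(sortCoincidences(m, g, acquisitionConfig(coincidenceWindow = 3,
                                                     energyWindow = NULL))$stream == "prompt")
  n2 <- sum(sortCoincidences(m, g, acquisitionConfig(coincidenceWindow = 6,
                                                     energyWindow = NULL))$stream == "prompt")
  expect_lte(n1, n2)
})

test_that("delayed-window rate matches the 2*tau*r1*r2 closed form", {
  g <- toyGeometry()
  ct <- crystalTable(g)
  idA <- ct$flat_id[ct$sector == 0][1]
  idB <- ct$flat_id[ct$sector == 3][1]
  r1 <- 5e4; r2 <- 8e4; dur <- 0.4
  a <- poissonSingles(r1, dur, tile = idA %/% 13L, flat_id = idA, seed = 10)
  b <- poissonSingles(r2, dur, tile = idB %/% 13L, flat_id = idB, seed = 11)
  b$event_id <- b$event_id + nrow(a)
  m <- mergeSingles(a, b)
  w <- 5
  cc <- sortCoincidences(m, g, acquisitionConfig(coincidenceWindow = w,
                                                 energyWindow = NULL))
  nd <- sum(cc$stream == "delayed")
  expected <- 2 * (w * 1e-9) * r1 * r2 * dur
  expect_lt(abs(nd - expected), 3 * sqrt(expected))
  # the delayed estimate agrees with ground-truth randoms in the prompts
  cr <- countRates(classifyCoincidences(cc), dur)
  expect_lt(abs(cr$randoms - cr$randoms_delayed),
            3 * sqrt(cr$randoms_delayed / dur + cr$randoms / dur) + 1e-9)
})

test_that("ground-truth classification follows the event ledger", {
  base <- data.frame(id_a = 0L, id_b = 100L, e_a = 511, e_b = 511, t_ns = 0,
                     stream = "prompt")
  mk <- function(ea, eb, sa, sb)
    cbind(base, ev_a = ea, ev_b = eb, sc_a = sa, sc_b = sb)[
      , c("id_a", "id_b", "e_a", "e_b", "t_ns", "ev_a", "ev_b", "sc_a",
          "sc_b", "stream")]
  expect_equal(classifyCoincidences(mk(1L, 1L, 0L, 0L))$truth, "true")
  expect_equal(classifyCoincidences(mk(1L, 1L, 1L, 0L))$truth, "scattered")
  expect_equal(classifyCoincidences(mk(1L, 2L, 0L, 0L))$truth, "random")
  miss <- mk(NA_integer_, 1L, 0L, 0L)
  expect_error(classifyCoincidences(miss), "ledger")
})

test_that("count-rate summary implements the NECR and SF formulas", {
  cc <- data.frame(id_a = 0L, id_b = 1L, e_a = 511, e_b = 511,
                   t_ns = seq_len(130), ev_a = 1L, ev_b = 1L, sc_a = 0L,
                   sc_b = 0L, stream = "prompt",
                   truth = rep(c("true", "scattered", "random"),
                               c(100, 20, 10)))
  cr <- countRates(cc, duration = 1)
  expect_equal(cr$necr, 100^2 / 130, tolerance = 1e-12)
  expect_equal(cr$prompts, 130)
  cc2 <- cc[1:100, ]
  cc2$truth <- rep(c("scattered", "true"), c(25, 75))
  expect_equal(countRates(cc2, 1)$sf, 25, tolerance = 1e-12)
  # NECR <= T and equality as S,R -> 0
  cc3 <- cc[cc$truth == "true", ]
  expect_equal(countRates(cc3, 1)$necr, countRates(cc3, 1)$trues)
  expect_lte(cr$necr, cr$trues)
  expect_error(countRates(cc, 0), "duration")
})
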