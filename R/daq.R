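#' Apply detector dead time to a singles stream
#'
#' The paralyzable model keeps a hit only if no prior hit in the same scope
#' (tile by default: one readout ASIC serves one tile) arrived within the
#' dead time; every hit, kept or not, extends the dead period.  The
#' nonparalyzable alternative blocks arrivals during a fixed window after
#' each accepted hit.
#'
#' @param stream a \code{SinglesStream} or singles data.frame (time-sorted).
#' @param acq an \code{\link{acquisitionConfig}}.
#' @return the surviving stream (same type as the input).
#' @export
applyDeadTime <- function(stream, acq = acquisitionConfig()) {
  df <- if (is(stream, "SinglesStream")) stream@singles else stream
  if (nrow(df) == 0 || acq$deadTime <= 0) return(stream)
  if (is.unsorted(df$t_ns))
    stop("singles stream must be time-sorted")
  scope <- switch(acq$deadTimeScope,
                  per_tile = df$tile,
                  per_module = df$tile %/% 4L,
                  global = rep(0L, nrow(df)))
  keep <- cpp_dead_time(df$t_ns, as.integer(scope), acq$deadTime * 1000,
                        acq$deadTimeModel == "paralyzable")
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (is(stream, "SinglesStream")) {
    stream@singles <- out
    stream
  } else out
}

#' Sort singles into prompt and delayed coincidences
#'
#' The energy window (if any) is applied to singles first; surviving singles
#' are grouped into coincidence windows (a window containing more than two
#' singles is discarded), and pairs failing the geometric criterion
#' (identical crystal or sector separation below the configured minimum) are
#' dropped.  The delayed stream re-pairs each single against singles shifted
#' by the delayed-window offset and estimates the random rate.
#'
#' @param stream a \code{SinglesStream} or singles data.frame (time-sorted,
#'   dead time already applied).
#' @param geom the \code{ScannerGeometry} (for the sector criterion).
#' @param acq an \code{\link{acquisitionConfig}}.
#' @return data.frame of coincidences: \code{id_a}, \code{id_b} (canonical
#'   order, 0-based flat ids), \code{e_a}, \code{e_b} (keV), \code{t_ns},
#'   \code{ev_a}, \code{ev_b}, \code{sc_a}, \code{sc_b}, \code{stream}
#'   ("prompt"/"delayed").
#' @export
sortCoincidences <- function(stream, geom, acq = acquisitionConfig()) {
  df <- if (is(stream, "SinglesStream")) stream@singles else stream
  empty <- data.frame(id_a = integer(0), id_b = integer(0), e_a = numeric(0),
                      e_b = numeric(0), t_ns = numeric(0), ev_a = integer(0),
                      ev_b = integer(0), sc_a = integer(0), sc_b = integer(0),
                      stream = character(0))
  if (nrow(df) == 0) return(empty)
  if (is.unsorted(df$t_ns)) stop("singles stream must be time-sorted")
  if (!is.null(acq$energyWindow))
    df <- df[df$energy >= acq$energyWindow[1] & df$energy <= acq$energyWindow[2], ,
             drop = FALSE]
  n <- nrow(df)
  if (n < 2) return(empty)
  w <- acq$coincidenceWindow

  pairUp <- function(ia, ib) {
    swap <- df$flat_id[ia] > df$flat_id[ib]
    a <- ifelse(swap, ib, ia)
    b <- ifelse(swap, ia, ib)
    ok <- df$flat_id[a] != df$flat_id[b] &
      sectorDifference(geom, df$flat_id[a], df$flat_id[b]) >= acq$minSectorDifference
    a <- a[ok]; b <- b[ok]
    data.frame(id_a = df$flat_id[a], id_b = df$flat_id[b],
               e_a = df$energy[a], e_b = df$energy[b],
               t_ns = pmin(df$t_ns[a], df$t_ns[b]),
               ev_a = df$event_id[a], ev_b = df$event_id[b],
               sc_a = df$scattered[a], sc_b = df$scattered[b])
  }

  # prompt: cluster singles whose consecutive gaps are within the window
  cl <- cumsum(c(1L, as.integer(diff(df$t_ns) > w)))
  sz <- tabulate(cl)
  firsts <- which(c(TRUE, diff(cl) > 0))
  pairIdx <- firsts[sz[cl[firsts]] == 2L]
  prompts <- pairUp(pairIdx, pairIdx + 1L)
  if (nrow(prompts)) prompts$stream <- "prompt"

  # delayed: singles i paired with singles j in [t_i + d, t_i + d + w]
  d <- acq$delayedWindowOffset
  lo <- findInterval(df$t_ns + d, df$t_ns)
  hi <- findInterval(df$t_ns + d + w, df$t_ns)
  cnt <- hi - lo
  ia <- rep.int(seq_len(n), cnt)
  ib <- unlist(lapply(which(cnt > 0), function(i) (lo[i] + 1):hi[i]),
               use.names = FALSE)
  delayed <- if (length(ia)) pairUp(ia, ib) else empty[0, 1:9]
  if (nrow(delayed)) delayed$stream <- "delayed"

  out <- rbind(if (nrow(prompts)) prompts else NULL,
               if (nrow(delayed)) delayed else NULL)
  if (is.null(out) || nrow(out) == 0) return(empty)
  out <- out[order(out$t_ns), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ground-truth classification of coincidences
#'
#' A pair from two different decays is random; a pair from one decay with any
#' phantom-scattered photon is scattered; otherwise true.
#'
#' @param coinc coincidence data.frame from \code{\link{sortCoincidences}}.
#' @return the same data.frame with a \code{truth} column
#'   ("true"/"scattered"/"random").
#' @export
classifyCoincidences <- function(coinc) {
  if (nrow(coinc) == 0) {
    coinc$truth <- character(0)
    return(coinc)
  }
  if (any(is.na(coinc$ev_a)) || any(is.na(coinc$ev_b)))
    stop("ground-truth ledger missing for some singles")
  coinc$truth <- ifelse(coinc$ev_a != coinc$ev_b, "random",
                        ifelse(coinc$sc_a > 0 | coinc$sc_b > 0,
                               "scattered", "true"))
  coinc
}

#' Count-rate summary
#'
#' Rates of true, scattered and random prompts (from ground truth), the
#' delayed-window randoms estimate, the scatter fraction
#' SF = S / (S + T) and the noise-equivalent count rate
#' NECR = T^2 / (T + S + R).
#'
#' @param coinc classified coincidence data.frame.
#' @param duration acquisition time, s.
#' @param activity_mbq activity at acquisition, MBq (carried through).
#' @param randoms "truth" (default) or "delayed": which randoms estimate
#'   enters the NECR denominator.
#' @return one-row data.frame: \code{activity_mbq}, \code{trues},
#'   \code{scattered}, \code{randoms}, \code{randoms_delayed},
#'   \code{prompts} (all cps), \code{necr} (cps), \code{sf} (percent).
#' @export
countRates <- function(coinc, duration, activity_mbq = NA_real_,
                       randoms = c("truth", "delayed")) {
  stopifnot(duration > 0)
  randoms <- match.arg(randoms)
  pr <- coinc[coinc$stream == "prompt", , drop = FALSE]
  tb <- table(factor(pr$truth, levels = c("true", "scattered", "random")))
  T <- as.numeric(tb["true"]) / duration
  S <- as.numeric(tb["scattered"]) / duration
  R <- as.numeric(tb["random"]) / duration
  Rd <- sum(coinc$stream == "delayed") / duration
  Rn <- if (randoms == "truth") R else Rd
  P <- T + S + R
  data.frame(activity_mbq = activity_mbq, trues = T, scattered = S,
             randoms = R, randoms_delayed = Rd, prompts = P,
             necr = if (T + S + Rn > 0) T^2 / (T + S + Rn) else 0,
             sf = if (S + T > 0) 100 * S / (S + T) else NA_real_)
}
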