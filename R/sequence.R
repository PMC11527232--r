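#' Sequence configuration for the CKI acquisition
#'
#' Holds every timing and pulse constant of one repetition of the CKI
#' flip-angle pattern: four 200-excitation sinusoidal blocks, alternating
#' RF phase, inversion preparation before each block and a relaxation pause
#' after it. All durations are in seconds, flips in degrees, frequencies in
#' Hz unless noted.
#'
#' @param n_per_block excitations per block (4 blocks total).
#' @param amp peak flip angle A (degrees) per block; blocks 1 and 3 excite
#'   PCr, blocks 2 and 4 excite gamma-ATP.
#' @param flip_exponent exponent of the sinusoidal envelope
#'   `A * sin(pi/n * x)^flip_exponent`.
#' @param tr1 base repetition time (s); PCr excitations alternate between
#'   `tr1` and `tr1 + te_plus`.
#' @param te acquisition delay from end of RF pulse to start of readout (s).
#' @param te_plus additional delay carried by every second PCr excitation (s).
#' @param pulse_dur,pulse_fwhm_hz duration (s) and spectral full width at
#'   half maximum (Hz) of the Gaussian excitation pulse.
#' @param inv_dur,inv_delay,crusher_dur preparation timing (s): asymmetric
#'   inversion pulse, post-inversion delay, crusher gradient.
#' @param block_pause pause after each block (s).
#' @param readout_dur,refocus_dur spiral readout duration and refocusing
#'   delay (s); used only by the feasibility audit, not by the signal model.
#' @param prep_carrier_ppm carrier offset of each preparation pulse relative
#'   to PCr (ppm).
#' @param prep_eff per-preparation inversion efficiencies, a list with
#'   numeric vectors `pcr`, `atp` (and optionally `pi`) of length 4, each
#'   entry in \eqn{[-1, 1]}. The default follows the asymmetric-profile
#'   reading of the preparation pulses: prep 1 (carrier +1.25 ppm) inverts
#'   both metabolites, preps 2 and 4 (carrier -1.25 ppm, opposite profile)
#'   invert PCr only, prep 3 (carrier -1.25 ppm, same profile as prep 1)
#'   inverts gamma-ATP only — each readout block is preceded by inversion
#'   of its exchange partner (magnetization transfer), with
#'   inversion-recovery T1 weighting applied to PCr.
#' @param prep_timing where within the inversion pulse the efficiency is
#'   applied: "mid" (default), "start" or "end".
#' @param atp_ppm chemical shift of gamma-ATP relative to PCr (ppm).
#' @param larmor_hz_per_ppm Hz per ppm for 31P at the field strength used
#'   (120.67 Hz/ppm at 7 T).
#' @return A list of class `cki_config`.
#' @export
cki_config <- function(n_per_block = 200L,
                       amp = c(35, 25, 35, 25),
                       flip_exponent = 0.6,
                       tr1 = 19.82e-3,
                       te = 410e-6,
                       te_plus = 4e-3,
                       pulse_dur = 10e-3,
                       pulse_fwhm_hz = 170,
                       inv_dur = 40e-3,
                       inv_delay = 2e-3,
                       crusher_dur = 8e-3,
                       block_pause = 0.4,
                       readout_dur = 8.61e-3,
                       refocus_dur = 920e-6,
                       prep_carrier_ppm = c(1.25, -1.25, -1.25, -1.25),
                       prep_eff = list(pcr = c(-1, -1, 1, -1),
                                       atp = c(-1, 1, -1, 1)),
                       prep_timing = c("mid", "start", "end"),
                       atp_ppm = -2.52,
                       larmor_hz_per_ppm = 120.67) {
  prep_timing <- match.arg(prep_timing)
  cfg <- list(n_per_block = as.integer(n_per_block), amp = amp,
              flip_exponent = flip_exponent, tr1 = tr1, te = te,
              te_plus = te_plus, pulse_dur = pulse_dur,
              pulse_fwhm_hz = pulse_fwhm_hz, inv_dur = inv_dur,
              inv_delay = inv_delay, crusher_dur = crusher_dur,
              block_pause = block_pause, readout_dur = readout_dur,
              refocus_dur = refocus_dur,
              prep_carrier_ppm = prep_carrier_ppm, prep_eff = prep_eff,
              prep_timing = prep_timing, atp_ppm = atp_ppm,
              larmor_hz_per_ppm = larmor_hz_per_ppm)
  class(cfg) <- "cki_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  durs <- c(tr1 = cfg$tr1, te = cfg$te, pulse_dur = cfg$pulse_dur,
            inv_dur = cfg$inv_dur, inv_delay = cfg$inv_delay,
            crusher_dur = cfg$crusher_dur, block_pause = cfg$block_pause)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop("non-positive or non-finite duration in config: ",
         paste(names(durs)[!is.finite(durs) | durs <= 0], collapse = ", "))
  }
  if (cfg$te_plus < 0) stop("te_plus must be >= 0")
  if (cfg$n_per_block < 1) stop("n_per_block must be >= 1")
  if (length(cfg$amp) != 4 || any(cfg$amp < 0)) {
    stop("amp must be 4 non-negative peak flip angles")
  }
  if (cfg$tr1 <= cfg$pulse_dur + cfg$te) {
    stop("tr1 leaves no time after pulse and te")
  }
  for (nm in names(cfg$prep_eff)) {
    e <- cfg$prep_eff[[nm]]
    if (length(e) != 4 || any(abs(e) > 1)) {
      stop("prep_eff$", nm, " must be 4 efficiencies in [-1, 1]")
    }
  }
  invisible(cfg)
}

#' Flip-angle pattern of the CKI sequence
#'
#' The 800-excitation pattern: four sinusoidal blocks of `n_per_block` flips,
#' `flip(x) = A * sin(pi/n * x)^0.6` with A = 35 deg for the PCr blocks
#' (1 and 3) and A = 25 deg for the gamma-ATP blocks (2 and 4); RF phase
#' alternates 0/180 deg across the full pattern.
#'
#' @param config a [cki_config()].
#' @return A tibble with one row per excitation: `index` (1-based over the
#'   full pattern), `block`, `x` (1-based within the block), `target`
#'   ("PCr"/"ATP"), `flip_deg`, `rf_phase_deg`.
#' @export
build_fa_pattern <- function(config = cki_config()) {
  n <- config$n_per_block
  x <- seq_len(n)
  env <- sinpi(x / n)^config$flip_exponent
  blocks <- lapply(1:4, function(b) {
    tibble::tibble(
      block = b, x = x,
      target = if (b %% 2 == 1) "PCr" else "ATP",
      flip_deg = config$amp[b] * env
    )
  })
  out <- do.call(rbind, blocks)
  out$index <- seq_len(nrow(out))
  out$rf_phase_deg <- ifelse(out$index %% 2 == 1, 0, 180)
  out[, c("index", "block", "x", "target", "flip_deg", "rf_phase_deg")]
}

#' Build the timed acquisition schedule of one pattern repetition
#'
#' Expands the flip-angle pattern into the fully ordered event list of one
#' repetition: per block an inversion pulse, delay and crusher, then
#' `n_per_block` excitations (Gaussian pulse, acquisition delay, readout
#' window), and a relaxation pause. PCr excitations alternate TR between
#' `tr1` and `tr1 + te_plus` (every second PCr excitation carries the extra
#' delay before the acquisition); ATP excitations use `tr1` throughout.
#'
#' @param config a [cki_config()].
#' @return An object of class `cki_schedule` with elements
#'   `excitations` (tibble: timing and metadata per excitation),
#'   `events` (tibble: every timed event), `plan` (internal step list used by
#'   the simulator) and `config`.
#' @export
build_schedule <- function(config = cki_config()) {
  validate_config(config)
  pat <- build_fa_pattern(config)
  larmor <- config$larmor_hz_per_ppm
  carrier <- ifelse(pat$target == "PCr", 0, config$atp_ppm * larmor)

  t <- 0
  ev <- list(); ex <- list(); plan <- list()
  add_ev <- function(kind, dur, block, detail = NA_character_) {
    ev[[length(ev) + 1]] <<- list(kind = kind, t_start = t, duration = dur,
                                  block = block, detail = detail)
    t <<- t + dur
  }
  add_plan <- function(.type, ...) {
    plan[[length(plan) + 1]] <<- c(list(type = .type), list(...))
  }

  for (b in 1:4) {
    ## preparation: inversion (efficiency applied per prep_timing), delay,
    ## crusher (transverse spoiled at end of the crusher window)
    pre <- switch(config$prep_timing,
                  start = 0, mid = config$inv_dur / 2, end = config$inv_dur)
    post <- config$inv_dur - pre
    add_ev("inversion", config$inv_dur, b,
           sprintf("carrier %+.2f ppm", config$prep_carrier_ppm[b]))
    if (pre > 0) add_plan("evolve", dur = pre)
    add_plan("prep", prep = b)
    if (post > 0) add_plan("evolve", dur = post)
    add_ev("delay", config$inv_delay, b)
    add_plan("evolve", dur = config$inv_delay)
    add_ev("crusher", config$crusher_dur, b)
    add_plan("evolve", dur = config$crusher_dur)
    add_plan("crush")

    rows <- which(pat$block == b)
    for (r in rows) {
      has_plus <- pat$target[r] == "PCr" && pat$x[r] %% 2 == 0
      te_tot <- config$te + if (has_plus) config$te_plus else 0
      tr <- config$tr1 + if (has_plus) config$te_plus else 0
      add_ev("excitation", config$pulse_dur, b,
             sprintf("flip %.3f deg, phase %d", pat$flip_deg[r],
                     pat$rf_phase_deg[r]))
      add_plan("evolve", dur = config$pulse_dur)
      t_pulse_end <- t
      add_plan("rf", exc = r, t = t_pulse_end)
      add_ev("delay", te_tot, b, if (has_plus) "te + te_plus" else "te")
      add_plan("evolve", dur = te_tot)
      t_sample <- t
      add_plan("sample", exc = r, t = t_sample)
      rem <- tr - config$pulse_dur - te_tot
      add_ev("readout", rem, b, "spiral readout + refocus window")
      add_plan("evolve", dur = rem)
      ex[[length(ex) + 1]] <- list(
        index = pat$index[r], block = b, x = pat$x[r],
        target = pat$target[r], flip = pat$flip_deg[r],
        rf_phase = pat$rf_phase_deg[r], tr = tr, te = te_tot,
        has_te_plus = has_plus, carrier_hz = carrier[r],
        t_pulse_end = t_pulse_end, t_sample = t_sample)
    }
    add_ev("delay", config$block_pause, b, "block pause")
    add_plan("evolve", dur = config$block_pause)
  }

  events <- tibble::as_tibble(do.call(rbind, lapply(ev, function(e) {
    data.frame(kind = e$kind, t_start = e$t_start, duration = e$duration,
               block = e$block, detail = e$detail,
               stringsAsFactors = FALSE)
  })))
  excitations <- tibble::as_tibble(do.call(rbind, lapply(ex, function(e) {
    data.frame(index = e$index, block = e$block, x = e$x, target = e$target,
               flip_deg = e$flip, rf_phase_deg = e$rf_phase, tr_s = e$tr,
               te_s = e$te, has_te_plus = e$has_te_plus,
               carrier_hz = e$carrier_hz, t_pulse_end = e$t_pulse_end,
               t_sample = e$t_sample, stringsAsFactors = FALSE)
  })))

  ## pre-compiled op stream for the simulator: positive ops index the
  ## per-parameter duration propagators, negative ops the shared cube
  ## [prep 1..4, crusher (5), rotations (6..)], zero marks a sample
  types <- vapply(plan, `[[`, "", "type")
  durs <- vapply(plan,
                 function(s) if (s$type == "evolve") s$dur else NA_real_, 0)
  udur <- sort(unique(durs[!is.na(durs)]))
  ops <- integer(length(plan))
  for (i in seq_along(plan)) {
    s <- plan[[i]]
    ops[i] <- switch(s$type,
                     evolve = match(s$dur, udur),
                     prep = -s$prep,
                     crush = -5L,
                     rf = -(5L + s$exc),
                     sample = 0L)
  }
  ## receiver demodulation at the active carrier; the receiver phase follows
  ## the alternating excitation phase (phase-cycled acquisition), so the
  ## recorded evolutions vary smoothly rather than alternating sign
  demod <- exp(-1i * (2 * pi * excitations$carrier_hz * excitations$t_sample +
                        excitations$rf_phase_deg * pi / 180))
  compiled <- list(udur = udur, ops = as.integer(ops), demod = demod)

  structure(list(excitations = excitations, events = events, plan = plan,
                 compiled = compiled, total_duration = t, config = config),
            class = "cki_schedule")
}

#' @export
print.cki_schedule <- function(x, ...) {
  cat("CKI acquisition schedule:", nrow(x$excitations), "excitations in 4",
      "blocks\n  total duration", sprintf("%.3f s", x$total_duration),
      "\n  TR (PCr)", sprintf("%.2f/%.2f ms", 1e3 * x$config$tr1,
                              1e3 * (x$config$tr1 + x$config$te_plus)),
      " TR (ATP)", sprintf("%.2f ms", 1e3 * x$config$tr1), "\n")
  invisible(x)
}

#' Feasibility audit of a schedule
#'
#' Checks, per excitation, that the time left between the end of the
#' acquisition delay and the next pulse accommodates the spiral readout and
#' the refocusing delay: `tr - te - pulse_dur >= readout_dur + refocus_dur`.
#' The printed protocol timings leave this short by 0.12 ms; the audit
#' reports rather than enforces.
#'
#' @param schedule a [build_schedule()] result.
#' @return Tibble with `index`, `slack_s` (negative = infeasible), `ok`.
#' @export
audit_schedule <- function(schedule) {
  cfg <- schedule$config
  ex <- schedule$excitations
  slack <- ex$tr_s - ex$te_s - cfg$pulse_dur -
    (cfg$readout_dur + cfg$refocus_dur)
  tibble::tibble(index = ex$index, slack_s = slack, ok = slack >= 0)
}

#' Write / read a schedule configuration as plain-text key-value pairs
#'
#' The serialized form allows alternative flip-angle patterns and timings to
#' be loaded without touching code (the readout pattern is exchangeable).
#'
#' @param config a [cki_config()].
#' @param path file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns a
#'   [cki_config()].
#' @export
write_config <- function(config, path) {
  num <- function(v) paste(format(v, digits = 17), collapse = ",")
  lines <- c(
    sprintf("n_per_block=%d", config$n_per_block),
    sprintf("amp=%s", num(config$amp)),
    sprintf("flip_exponent=%s", num(config$flip_exponent)),
    sprintf("tr1=%s", num(config$tr1)),
    sprintf("te=%s", num(config$te)),
    sprintf("te_plus=%s", num(config$te_plus)),
    sprintf("pulse_dur=%s", num(config$pulse_dur)),
    sprintf("pulse_fwhm_hz=%s", num(config$pulse_fwhm_hz)),
    sprintf("inv_dur=%s", num(config$inv_dur)),
    sprintf("inv_delay=%s", num(config$inv_delay)),
    sprintf("crusher_dur=%s", num(config$crusher_dur)),
    sprintf("block_pause=%s", num(config$block_pause)),
    sprintf("readout_dur=%s", num(config$readout_dur)),
    sprintf("refocus_dur=%s", num(config$refocus_dur)),
    sprintf("prep_carrier_ppm=%s", num(config$prep_carrier_ppm)),
    sprintf("prep_eff_pcr=%s", num(config$prep_eff$pcr)),
    sprintf("prep_eff_atp=%s", num(config$prep_eff$atp)),
    sprintf("prep_timing=%s", config$prep_timing),
    sprintf("atp_ppm=%s", num(config$atp_ppm)),
    sprintf("larmor_hz_per_ppm=%s", num(config$larmor_hz_per_ppm))
  )
  if (!is.null(config$prep_eff$pi)) {
    lines <- c(lines, sprintf("prep_eff_pi=%s", num(config$prep_eff$pi)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(p) paste(p[-1], collapse = "="), "")
  get <- function(k, f = as.numeric) {
    i <- match(k, keys)
    if (is.na(i)) return(NULL)
    f(strsplit(vals[i], ",", fixed = TRUE)[[1]])
  }
  prep_eff <- list(pcr = get("prep_eff_pcr"), atp = get("prep_eff_atp"))
  if ("prep_eff_pi" %in% keys) prep_eff$pi <- get("prep_eff_pi")
  cki_config(
    n_per_block = get("n_per_block", as.integer), amp = get("amp"),
    flip_exponent = get("flip_exponent"), tr1 = get("tr1"), te = get("te"),
    te_plus = get("te_plus"), pulse_dur = get("pulse_dur"),
    pulse_fwhm_hz = get("pulse_fwhm_hz"), inv_dur = get("inv_dur"),
    inv_delay = get("inv_delay"), crusher_dur = get("crusher_dur"),
    block_pause = get("block_pause"), readout_dur = get("readout_dur"),
    refocus_dur = get("refocus_dur"),
    prep_carrier_ppm = get("prep_carrier_ppm"), prep_eff = prep_eff,
    prep_timing = get("prep_timing", identity), atp_ppm = get("atp_ppm"),
    larmor_hz_per_ppm = get("larmor_hz_per_ppm"))
}
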