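# Canonical 184-feature registry and whole-session extraction.

REGISTRY_VERSION <- "1.0"

tenmwt_feature_names <- function() {
  c("Mean Vertical Displacement", "Mean Stance Time", "Mean Step Time",
    "Mean Stride Time", "Mean Swing Time", "Mean Step Length",
    "Maximum Power Frequency", "Stance Time Symmetry Ratio",
    "Step Length Symmetry Ratio", "Duration", "Mean Velocity", "N Steps")
}

.bbs_units <- function(nm) {
  base <- sub(" (AP|ML)$", "", nm)
  switch(base,
         "F50%" = , "F95%" = , "SC" = "Hz",
         "Max Acc" = , "Mean Acc" = , "RMS" = , "SPathA" = "m/s^2",
         "Ellipse Angle" = "deg",
         "Ellipse Axis" = "m/s^2",
         "Jerk" = "m/s^3",
         "SwayV" = "m/s",
         "95% Ellipse Area" = "m^2/s^4",
         stop("unknown balance feature: ", nm))
}

.tenmwt_units <- function(nm) {
  switch(nm,
         "Mean Vertical Displacement" = "m",
         "Mean Stance Time" = , "Mean Step Time" = , "Mean Stride Time" = ,
         "Mean Swing Time" = , "Duration" = "s",
         "Mean Step Length" = "cm",
         "Maximum Power Frequency" = "(m/s^2)^2/Hz",
         "Stance Time Symmetry Ratio" = , "Step Length Symmetry Ratio" = ,
         "N Steps" = "unitless",
         "Mean Velocity" = "m/s",
         stop("unknown 10MWT feature: ", nm))
}

.tug_units <- function(nm) {
  if (grepl("Pitch Vel|Yaw Vel", nm)) return("deg/s")
  if (grepl("Pitch Acc|Yaw Acc", nm)) return("deg/s^2")
  if (grepl("Acc", nm)) return("m/s^2")
  if (grepl("Duration", nm)) return("s")
  if (grepl("Step Time", nm)) return("s")
  if (nm == "N Steps") return("unitless")
  stop("unknown TUG feature: ", nm)
}

#' The canonical feature registry
#'
#' Ordered table of every feature the pipeline emits for a complete session:
#' 23 for each of the five static balance conditions (115), 12 for each
#' 10 m walk condition plus the between-condition velocity difference (25),
#' 13 + 13 for sit-to-stand/stand-to-sit, 5 + 5 for the turns and 7 for the
#' pooled walk of the Timed Up and Go (43), and the naturalistic-walk step
#' count (1): 184 rows with unique (test, condition, feature_name) keys.
#'
#' @return data frame with columns `test, condition, feature_name, units`.
#' @export
feature_registry <- function() {
  rows <- list()
  add <- function(test, condition, names, units) {
    rows[[length(rows) + 1L]] <<- data.frame(
      test = test, condition = condition, feature_name = names,
      units = units, stringsAsFactors = FALSE)
  }
  for (cond in c("SU", "SEC", "SFT", "ST", "SOL")) {
    nm <- bbs_feature_names()
    add("BBS", cond, nm, vapply(nm, .bbs_units, character(1)))
  }
  for (cond in c("SSV", "FV")) {
    nm <- tenmwt_feature_names()
    add("10MWT", cond, nm, vapply(nm, .tenmwt_units, character(1)))
  }
  add("10MWT", "FV-SSV", "Velocity Difference", "m/s")
  for (cond in c("STS", "StS")) {
    nm <- tug_sit_feature_names()
    add("TUG", cond, nm, vapply(nm, .tug_units, character(1)))
  }
  for (cond in c("TURN1", "TURN2")) {
    nm <- tug_turn_feature_names()
    add("TUG", cond, nm, vapply(nm, .tug_units, character(1)))
  }
  nm <- tug_walk_feature_names()
  add("TUG", "WALK", nm, vapply(nm, .tug_units, character(1)))
  add("NATWALK", "", "N Steps", "unitless")
  out <- do.call(rbind, rows)
  attr(out, "registry_version") <- REGISTRY_VERSION
  out
}

# power spectral density (one-sided periodogram, density scaling)
.psd <- function(x, fs) {
  x <- x - mean(x)
  n <- length(x)
  P <- Mod(stats::fft(x))^2 / (n * fs)
  half <- seq(2L, floor(n / 2) + 1L)
  list(f = (half - 1L) * fs / n, P = 2 * P[half])
}

# features for a single preprocessed walking trial
.walk_trial_features <- function(sig, model, duration, config) {
  fs <- attr(sig, "fs")
  t0 <- sig$t[1L]
  out <- stats::setNames(rep(NA_real_, 12L), tenmwt_feature_names())
  out["Duration"] <- duration
  ev <- withCallingHandlers(
    detect_contacts(sig$aV_f, fs, t0 = t0, config = config),
    warning = function(w) invokeRestart("muffleWarning"))
  if (!length(ev$t_ic)) return(out)
  ev <- assign_sides(ev, sig$yaw_f, fs, t0 = t0)
  tp <- temporal_params(ev)
  sl <- trial_step_lengths(sig$aV, ev, fs, L = model$L, K = model$K,
                           S = model$S, t0 = t0,
                           hurst_cutoff = config$hurst_cutoff)
  out["N Steps"] <- tp$n_steps
  if (length(tp$t_step)) {
    out["Mean Stance Time"] <- mean(tp$t_stance, na.rm = TRUE)
    out["Mean Step Time"] <- mean(tp$t_step, na.rm = TRUE)
    out["Mean Stride Time"] <- mean(tp$t_stride, na.rm = TRUE)
    out["Mean Swing Time"] <- mean(tp$t_swing, na.rm = TRUE)
    sideA <- tp$side == "A"
    mA <- mean(tp$t_stance[sideA], na.rm = TRUE)
    mB <- mean(tp$t_stance[!sideA], na.rm = TRUE)
    if (is.finite(mA) && is.finite(mB) && mB != 0) {
      out["Stance Time Symmetry Ratio"] <- mA / mB
    }
  }
  if (length(sl$h)) {
    out["Mean Vertical Displacement"] <- mean(sl$h, na.rm = TRUE)
    out["Mean Step Length"] <- 100 * mean(sl$length, na.rm = TRUE)
    out["Mean Velocity"] <- mean(sl$velocity, na.rm = TRUE)
    step_side <- ev$side[seq_along(sl$length)]
    lA <- mean(sl$length[step_side == "A"], na.rm = TRUE)
    lB <- mean(sl$length[step_side == "B"], na.rm = TRUE)
    if (is.finite(lA) && is.finite(lB) && lB != 0) {
      out["Step Length Symmetry Ratio"] <- lA / lB
    }
  }
  ps <- .psd(sig$aV_f, fs)
  out["Maximum Power Frequency"] <- max(ps$P)
  out
}

#' 10 m Walk Test features for one speed condition
#'
#' Runs event detection and the step-length model on each annotated trial of
#' the condition and averages the per-trial features.
#'
#' @param sigs list of `"aligned_signal"` trial windows (walking filters
#'   applied; see [preprocess_trial()]).
#' @param condition `"SSV"` or `"FV"` (selects K when `model$K` is `NULL`).
#' @param model list with `L` (pendulum length, m), `S` (shoe size) and
#'   optionally `K`.
#' @param durations annotated trial durations, s (one per trial).
#' @param config an [lg_config()].
#' @return named numeric vector of the 12 condition features.
#' @export
extract_10mwt <- function(sigs, condition, model, durations,
                          config = lg_config()) {
  if (!length(sigs)) {
    return(stats::setNames(rep(NA_real_, 12L), tenmwt_feature_names()))
  }
  K <- model$K %||% config$K[[condition]]
  m <- list(L = model$L, K = K, S = model$S)
  per <- mapply(function(sig, dur) {
    .walk_trial_features(sig, m, dur, config)
  }, sigs, durations)
  rowMeans(per, na.rm = TRUE)
}

#' Extract the complete 184-feature table for one session
#'
#' Orchestrates preprocessing and all four test pipelines over the annotated
#' trials and returns one row per registry entry.  Conditions without usable
#' trials keep their rows with `NA` values, so a complete registry shape is
#' always returned.
#'
#' @param recordings named list of [imu_recording()] keyed by `trial_id`.
#' @param annotations data frame `trial_id, test, t_start, t_end`; `test`
#'   must be one of `10MWT_SSV, 10MWT_FV, BBS_SU, BBS_SEC, BBS_SFT, BBS_ST,
#'   BBS_SOL, TUG, NATWALK`.
#' @param meta subject metadata list (see [read_subject_meta()]).
#' @param config an [lg_config()].
#' @return a `feature_table` data frame with columns
#'   `subject_id, test, condition, feature_name, value, units` (184 rows).
#' @export
extract_session <- function(recordings, annotations, meta,
                            config = lg_config()) {
  known <- c("10MWT_SSV", "10MWT_FV", "BBS_SU", "BBS_SEC", "BBS_SFT",
             "BBS_ST", "BBS_SOL", "TUG", "NATWALK")
  bad <- setdiff(unique(annotations$test), known)
  if (length(bad)) {
    stop("unknown test label(s) in annotations: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  reg <- feature_registry()
  values <- stats::setNames(rep(NA_real_, nrow(reg)),
                            paste(reg$test, reg$condition, reg$feature_name,
                                  sep = "|"))
  set_val <- function(test, condition, nm, v) {
    key <- paste(test, condition, nm, sep = "|")
    stopifnot(all(key %in% names(values)))
    values[key] <<- v
  }
  trials_of <- function(label) {
    a <- annotations[annotations$test == label, , drop = FALSE]
    a[a$trial_id %in% names(recordings), , drop = FALSE]
  }
  prep <- function(row, walking) {
    preprocess_trial(recordings[[row$trial_id]],
                     window = c(row$t_start, row$t_end),
                     walking = walking, config = config)
  }

  # --- 10MWT ---
  model <- list(L = meta$sensor_to_ground_m, S = meta$shoe_size)
  for (cond in c("SSV", "FV")) {
    tr <- trials_of(paste0("10MWT_", cond))
    if (nrow(tr)) {
      sigs <- lapply(seq_len(nrow(tr)), function(i) prep(tr[i, ], TRUE))
      vals <- extract_10mwt(sigs, cond, model,
                            tr$t_end - tr$t_start, config)
      set_val("10MWT", cond, names(vals), vals)
    }
  }
  v_ssv <- values[["10MWT|SSV|Mean Velocity"]]
  v_fv <- values[["10MWT|FV|Mean Velocity"]]
  set_val("10MWT", "FV-SSV", "Velocity Difference", v_fv - v_ssv)

  # --- BBS ---
  for (cond in c("SU", "SEC", "SFT", "ST", "SOL")) {
    tr <- trials_of(paste0("BBS_", cond))
    if (nrow(tr)) {
      per <- vapply(seq_len(nrow(tr)), function(i) {
        bbs_condition_features(prep(tr[i, ], FALSE), cond, config)
      }, numeric(23L))
      vals <- rowMeans(matrix(per, nrow = 23L), na.rm = TRUE)
      set_val("BBS", cond, bbs_feature_names(), vals)
    }
  }

  # --- TUG ---
  tr <- trials_of("TUG")
  if (nrow(tr)) {
    per <- lapply(seq_len(nrow(tr)), function(i) {
      sig <- prep(tr[i, ], TRUE)
      fs <- attr(sig, "fs")
      tryCatch({
        ph <- detect_phases(sig$pitch, sig$yaw, fs, t0 = sig$t[1L],
                            config = config)
        ev <- tug_gait_events(sig, ph, config)
        tug_features(sig, ph, ev)
      }, error = function(e) {
        warning("TUG trial ", tr$trial_id[i], " skipped: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    })
    per <- Filter(Negate(is.null), per)
    if (length(per)) {
      vals <- rowMeans(do.call(cbind, per), na.rm = TRUE)
      cond <- sub(": .*$", "", names(vals))
      nm <- sub("^[^:]+: ", "", names(vals))
      set_val("TUG", cond, nm, vals)
    }
  }

  # --- naturalistic walking ---
  tr <- trials_of("NATWALK")
  if (nrow(tr)) {
    counts <- vapply(seq_len(nrow(tr)), function(i) {
      sig <- prep(tr[i, ], TRUE)
      ev <- withCallingHandlers(
        detect_contacts(sig$aV_f, attr(sig, "fs"), t0 = sig$t[1L],
                        config = config),
        warning = function(w) invokeRestart("muffleWarning"))
      length(ev$t_ic)
    }, numeric(1))
    set_val("NATWALK", "", "N Steps", mean(counts))
  }

  out <- data.frame(subject_id = meta$subject_id %||% NA_character_,
                    reg, value = unname(values),
                    stringsAsFactors = FALSE)
  attr(out, "registry_version") <- REGISTRY_VERSION
  class(out) <- c("feature_table", "data.frame")
  out
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features, %d missing (registry %s)\n",
              nrow(x), sum(is.na(x$value)),
              attr(x, "registry_version") %||% "?"))
  invisible(x)
}
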