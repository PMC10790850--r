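# Shared helpers: tiny in-memory fixtures built at test time.

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# A small recording with known content: deterministic sinusoids per channel.
toy_recording <- function(n_ch = 6, dur_s = 10, srate = 250,
                          labels = c("Fz", "Cz", "Pz", "Oz9", "TP9", "TP10")[1:n_ch]) {
  t <- seq(0, dur_s - 1 / srate, by = 1 / srate)
  data <- t(sapply(seq_len(n_ch), function(i) sin(2 * pi * i * t) * i))
  mont <- default_montage()
  labs <- if (all(labels %in% mont$label)) labels else mont$label[seq_len(n_ch)]
  new_recording(data, srate, labs, mont[match(labs, mont$label), ],
                reference = "Fz")
}

# Event table with explicit fields.
toy_events <- function(onsets, category = "alarm", condition = "narrow",
                       overlap = FALSE) {
  data.frame(onset_s = onsets, category = category, condition = condition,
             direction_deg = 45, overlap = overlap,
             is_target = (category == "alarm" & condition == "narrow") |
               (category == "beep" & condition == "wide"),
             stringsAsFactors = FALSE)
}

# Epoch set built directly from an array (bypassing make_epochs).
toy_epochs <- function(arr, srate = 250, tmin = -0.2,
                       labels = paste0("ch", seq_len(dim(arr)[2])),
                       condition = "narrow") {
  nt <- dim(arr)[3]
  structure(list(
    data = arr, times = seq.int(round(tmin * srate),
                                round(tmin * srate) + nt - 1L) / srate,
    srate_hz = srate, labels = labels,
    window = c(tmin, tmin + nt / srate), baseline = c(tmin, 0),
    trial_meta = data.frame(condition = rep(condition, dim(arr)[1]))),
    class = "epoch_set")
}

# Single-segment segment_set from raw matrices.
toy_segset <- function(eeg, env, srate = 250, labels = NULL) {
  structure(list(segments = list(list(eeg = eeg, env = env)),
                 srate_hz = srate, total_s = length(env) / srate,
                 starts_s = 0,
                 labels = labels %||% paste0("ch", seq_len(nrow(eeg)))),
            class = "segment_set")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
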