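# Shared fixtures, built in code. Sessions are kept small; the acceptance
# tests build their own larger ones.

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# a mid-sized session with planted ensembles, cached per test run
planted_session <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- session_config(session_duration_s = 3600, n_spn = 36, n_fsi = 4,
                            n_ensembles = 3, ensemble_sizes = c(5, 6, 7),
                            response_profiles = c("step_up",
                                                  "transient_start",
                                                  "transient_end"),
                            seed = 101)
      cache <<- simulate_session(cfg)
    }
    cache
  }
})

# brute-force interval IoU on a frame grid (independent oracle)
frame_iou <- function(a, b, total_s, fps = 125) {
  tt <- (seq_len(floor(total_s * fps)) - 1) / fps
  ina <- rep(FALSE, length(tt)); inb <- ina
  for (i in seq_len(nrow(a))) ina <- ina | (tt >= a$start_s[i] & tt < a$end_s[i])
  for (i in seq_len(nrow(b))) inb <- inb | (tt >= b$start_s[i] & tt < b$end_s[i])
  if (!any(ina) && !any(inb)) return(1)
  sum(ina & inb) / sum(ina | inb)
}

# random non-overlapping bout set on [0, total]
random_bouts <- function(n, total_s) {
  if (n == 0) return(grooming_bouts())
  edges <- sort(runif(2 * n, 0, total_s))
  grooming_bouts(edges[seq(1, 2 * n, 2)], edges[seq(2, 2 * n, 2)])
}

# exhaustive-pair AUC oracle
auc_bruteforce <- function(x, y) {
  s <- 0
  for (xi in x) for (yi in y)
    s <- s + (xi > yi) + 0.5 * (xi == yi)
  s / (length(x) * length(y))
}
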