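# shared fixtures and independent oracles

# increment-series object built directly from raw increments, for algebra
# tests that do not need a parent waveform
make_increments <- function(dU, dlnA, dt_ms = 1, U0 = 0, lnA0 = log(500)) {
  structure(list(dU = dU, dlnA = dlnA,
                 t_mid = dt_ms * (seq_along(dU) - 0.5),
                 dt_ms = dt_ms, U0 = U0, lnA0 = lnA0),
            class = "increment_series")
}

# loop object built directly, for window-search tests
make_loop <- function(lnA, U, dt = 1) {
  structure(list(t = dt * (seq_along(U) - 1), U = U, lnA = lnA,
                 foot_index = 1L, peak_u_index = length(U)),
            class = "ulna_loop")
}

# brute-force window selection: enumerate every admissible window, score it
# with stats::cor, apply the same tie rule (within 1e-12 of the maximum,
# then longest, then earliest)
oracle_select_window <- function(loop, min_len_ms = 20,
                                 search_start = loop$foot_index,
                                 search_end = loop$peak_u_index) {
  dt <- mean(diff(loop$t))
  min_pts <- max(3L, as.integer(round(min_len_ms / dt)) + 1L)
  a <- search_start; b <- search_end
  rows <- list()
  for (i in a:(b - min_pts + 1L)) {
    for (j in (i + min_pts - 1L):b) {
      x <- loop$lnA[i:j]; y <- loop$U[i:j]
      r2 <- if (var(x) <= 0 || var(y) <= 0) -Inf else cor(x, y)^2
      rows[[length(rows) + 1L]] <- c(i, j, r2)
    }
  }
  m <- do.call(rbind, rows)
  best <- max(m[, 3])
  tied <- m[m[, 3] >= best - 1e-12, , drop = FALSE]
  tied <- tied[tied[, 2] - tied[, 1] == max(tied[, 2] - tied[, 1]), ,
               drop = FALSE]
  pick <- tied[which.min(tied[, 1]), ]
  list(start = as.integer(pick[1]), end = as.integer(pick[2]), r2 = pick[3])
}

# two-way ANOVA mean squares via stats::aov, an independent route to the
# ICC decomposition
oracle_icc21 <- function(m) {
  df <- data.frame(v = as.vector(m),
                   s = factor(rep(seq_len(nrow(m)), ncol(m))),
                   r = factor(rep(seq_len(ncol(m)), each = nrow(m))))
  tab <- summary(stats::aov(v ~ s + r, data = df))[[1]]
  MSR <- tab["s", "Mean Sq"]; MSC <- tab["r", "Mean Sq"]
  MSE <- tab["Residuals", "Mean Sq"]
  n <- nrow(m); k <- ncol(m)
  (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
}

# volunteer-like template series written to a temporary CSV
write_template_csv <- function(path, seed = 1, ...) {
  gen <- generate_waveforms(synthetic_spec(seed = seed, ...))
  write_waveforms(gen$series, path)
  gen
}
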