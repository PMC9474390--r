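# Shared fixture builders (all generated in code; nothing on disk).

# Normalized 61-point waveform family around one of the built-in templates.
make_waveform_family <- function(n, kind = c("biphasic", "triphasic"),
                                 noise_sd = 0.05, seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  tgrid <- ((1:61) - 21) / 20000
  tmpl <- switch(kind,
                 biphasic = orgephys:::spike_template(tgrid),
                 triphasic = orgephys:::spike_template_triphasic(tgrid))
  t(vapply(seq_len(n), function(k) {
    w <- tmpl + stats::rnorm(61, 0, noise_sd)
    w / -min(w)
  }, numeric(61)))
}

# Small synthetic EF set on a common channel grid for tracking tests.
make_ef_day <- function(n_units, seed, base = NULL, gain = 1,
                        noise_frac = 0, id_offset = 0L) {
  set.seed(seed)
  ch <- data.frame(electrode_id = 0:4, x = (0:4) * 17.5, y = 0)
  lapply(seq_len(n_units), function(u) {
    wf <- if (is.null(base)) matrix(stats::rnorm(5 * 30), 5, 30)
    else base[[u]]$waveform
    wf <- wf * gain
    if (noise_frac > 0)
      wf <- wf + matrix(stats::rnorm(length(wf), 0, noise_frac * stats::sd(wf)),
                        nrow(wf))
    electrical_footprint(id_offset + u, wf, ch, 20000)
  })
}

# Exhaustive assignment oracle: best one-to-one matching maximizing total
# similarity (n <= 8).
exhaustive_assignment <- function(sim) {
  n <- nrow(sim)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_val <- -Inf
  for (p in perms(seq_len(n))) {
    val <- sum(sim[cbind(seq_len(n), p)])
    if (val > best_val) { best_val <- val; best <- p }
  }
  list(assignment = best, total = best_val)
}

# Plug-in transfer entropy by explicit joint-pattern histogram over string
# keys — an implementation independent of the package's bit-coded path.
te_histogram_oracle <- function(src, tgt, k = 1, l = 4, delay = 1) {
  n <- length(tgt)
  first <- max(k, delay + l - 1) + 1
  j <- character(0); jh <- character(0); ih <- character(0)
  for (t in first:n) {
    j <- c(j, as.character(tgt[t]))
    jh <- c(jh, paste(tgt[(t - k):(t - 1)], collapse = ""))
    ih <- c(ih, paste(src[(t - delay - l + 1):(t - delay)], collapse = ""))
  }
  N <- length(j)
  c3 <- table(paste(j, jh, ih))
  c2 <- table(paste(jh, ih))
  cjh <- table(paste(j, jh))
  ch <- table(jh)
  te <- 0
  for (kk in names(c3)) {
    parts <- strsplit(kk, " ")[[1]]
    p3 <- c3[[kk]] / N
    pf <- c3[[kk]] / c2[[paste(parts[2], parts[3])]]
    ph <- cjh[[paste(parts[1], parts[2])]] / ch[[parts[2]]]
    te <- te + p3 * log2(pf / ph)
  }
  unname(te)
}
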