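# Shared fixtures and independent oracles for the test suite. Everything
# is generated in code; nothing is read from disk.

# fraction of correctly labelled clips over phase positions only
phase_accuracy <- function(gt, pred) {
  g <- as.integer(unclass(gt))
  p <- as.integer(unclass(pred))
  keep <- g %in% 1:5
  mean(p[keep] == g[keep])
}

# small synthetic video cache (built once per test run)
.fixtures <- new.env(parent = emptyenv())

tiny_video <- function(i, feature_dim = 16) {
  key <- sprintf("video_%d_%d", i, feature_dim)
  if (is.null(.fixtures[[key]])) {
    .fixtures[[key]] <- simulate_video(
      workflow_sim_config(seed = 5000 + i),
      emitter_config(feature_dim = feature_dim, seed = 6000 + i))
  }
  .fixtures[[key]]
}

# a short hand-built video record (length n clips) for fast training tests
toy_video <- function(n = 60, feature_dim = 6, seed = 1) {
  stopifnot(n >= 40)
  set.seed(seed)
  labs <- unlist(mapply(rep, c(1L, 6L, 2L, 6L, 3L),
                        c(18L, 3L, 15L, 3L, n - 39L), SIMPLIFY = FALSE))
  clips <- clip_labels(labs)
  list(features = emit_features(clips, emitter_config(feature_dim = feature_dim,
                                                      seed = seed)),
       labels = clips,
       fine_preds = emit_fine_predictions(clips,
         emitter_config(feature_dim = feature_dim, seed = seed + 1)))
}

# ---- independent brute-force Ward oracle -----------------------------
# Enumerates events by index-set scanning and classifies each event from
# explicit overlap sets; shares no code with ward_score().

oracle_events <- function(x, cl) {
  idx <- which(x == cl)
  if (length(idx) == 0L) return(list())
  groups <- split(idx, cumsum(c(1L, diff(idx) != 1L)))
  lapply(groups, function(g) range(g))
}

oracle_ward <- function(gt, pred, classes) {
  g <- as.integer(unclass(gt)); p <- as.integer(unclass(pred))
  cnt <- c(C = 0L, D = 0L, F = 0L, M = 0L, FM = 0L,
           Ip = 0L, Fp = 0L, Mp = 0L, FMp = 0L)
  n_gt <- 0L; n_pred <- 0L
  for (cl in classes) {
    ge <- oracle_events(g, cl)
    pe <- oracle_events(p, cl)
    n_gt <- n_gt + length(ge); n_pred <- n_pred + length(pe)
    inter <- function(a, b) length(intersect(seq(a[1], a[2]), seq(b[1], b[2]))) > 0
    # overlap sets by full pairwise enumeration
    gp <- lapply(ge, function(e) which(vapply(pe, inter, logical(1), a = e)))
    pg <- lapply(pe, function(e) which(vapply(ge, inter, logical(1), a = e)))
    for (i in seq_along(ge)) {
      ov <- gp[[i]]
      fragmented <- length(ov) > 1L
      merged <- any(vapply(ov, function(j) length(pg[[j]]) > 1L, logical(1)))
      lab <- if (length(ov) == 0L) "D" else if (fragmented && merged) "FM" else
        if (fragmented) "F" else if (merged) "M" else "C"
      cnt[lab] <- cnt[lab] + 1L
    }
    for (j in seq_along(pe)) {
      ov <- pg[[j]]
      merging <- length(ov) > 1L
      fragging <- any(vapply(ov, function(i) length(gp[[i]]) > 1L, logical(1)))
      lab <- if (length(ov) == 0L) "Ip" else if (merging && fragging) "FMp" else
        if (merging) "Mp" else if (fragging) "Fp" else NA_character_
      if (!is.na(lab)) cnt[lab] <- cnt[lab] + 1L
    }
  }
  list(counts = as.list(cnt), n_gt_events = n_gt, n_pred_events = n_pred,
       event_ratio = if (n_pred == 0L) 0 else n_gt / n_pred)
}

# brute-force sliding mode for checking mode_average_filter
oracle_mode_filter <- function(x, width) {
  half <- (width - 1) / 2
  sapply(seq_along(x), function(t) {
    w <- x[max(1, t - half):min(length(x), t + half)]
    tb <- table(w)
    min(as.integer(names(tb)[tb == max(tb)]))
  })
}

# cache for models trained inside the acceptance suite (trained once,
# reused by later blocks)
.trained <- new.env(parent = emptyenv())
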