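# Independent oracles used by the unit and acceptance tests. These stay
# deliberately separate from the package's own code paths.

# Full-enumeration permutation p-value for the two-sided Spearman test:
# enumerate every permutation of y (n <= 7) and count coefficients at least
# as large in magnitude as the observed one.
enumerate_spearman_p <- function(x, y) {
  n <- length(x)
  stopifnot(n == length(y), n <= 7)
  rx <- rank(x)
  obs <- abs(stats::cor(rx, rank(y)))
  perms <- all_permutations(n)
  rho_all <- apply(perms, 1, function(idx) stats::cor(rx, rank(y[idx])))
  mean(abs(rho_all) >= obs - 1e-12)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    rest <- setdiff(seq_len(n), i)
    out[[i]] <- cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }
  do.call(rbind, out)
}

# Brute-force two-sided Mann-Whitney p by direct pair counting over all
# group assignments (independent of rank-sum formulas).
brute_force_mw_p <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  pooled <- c(a, b)
  u_of <- function(grp_a) {
    av <- pooled[grp_a]
    bv <- pooled[-grp_a]
    sum(outer(av, bv, ">")) + 0.5 * sum(outer(av, bv, "=="))
  }
  obs <- u_of(seq_len(n1))
  mu <- n1 * n2 / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, u_of)
  mean(abs(u_all - mu) >= abs(obs - mu) - 1e-9)
}

# Hand-constructable eye signal: baseline with rectangular dips at the given
# onset frames.
toy_eye_signal <- function(n_frames, onsets, dip_frames = 3, baseline = 0.35,
                           depth = 0.1) {
  s <- rep(baseline, n_frames)
  for (o in onsets) s[o:min(n_frames, o + dip_frames - 1)] <- depth
  s
}

# PSQI item sheets at the instrument floor and ceiling.
psqi_best_items <- function() {
  c(list(bedtime = "23:00", latency_min = 5, waketime = "07:00",
         sleep_hours = 8, dist_latency = 0),
    stats::setNames(as.list(rep(0, 9)), createlab:::PSQI_DISTURBANCE_ITEMS),
    list(quality = 0, medication = 0, awake_trouble = 0, enthusiasm = 0))
}

psqi_worst_items <- function() {
  c(list(bedtime = "22:00", latency_min = 90, waketime = "06:00",
         sleep_hours = 4, dist_latency = 3),
    stats::setNames(as.list(rep(3, 9)), createlab:::PSQI_DISTURBANCE_ITEMS),
    list(quality = 3, medication = 3, awake_trouble = 3, enthusiasm = 3))
}

# Small ratings table: 2 participants x 3 stimuli with known group means.
toy_ratings <- function() {
  data.frame(
    participant_id = rep(c("a", "b"), each = 3),
    stimulus_id = rep(c("s1", "s2", "s3"), 2),
    valence = c(8, 8, 2, 6, 8, 2),
    arousal = c(8, 8, 8, 6, 8, 2),
    stringsAsFactors = FALSE
  )
}
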