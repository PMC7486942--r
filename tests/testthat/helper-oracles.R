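# Independent brute-force oracles used to pin expected values.

# Enumerate every maximal qualifying monotone run of a trace, directly
# from the declarative definition: all non-zero steps share a sign and
# every complete sliding w-frame window changes by at least delta.
oracle_fluctuations <- function(x, amp_min = 0.12, delta = 0.005,
                                w = 3, tol = 1e-12) {
  n <- length(x)
  qual <- function(s, e) {
    if (e <= s) return(FALSE)
    sg <- sign(diff(x[s:e]))
    sg <- sg[sg != 0]
    if (length(unique(sg)) > 1) return(FALSE)
    if (e - s + 1 >= w) {
      for (i in s:(e - w + 1)) {
        if (abs(x[i + w - 1] - x[i]) < delta - tol) return(FALSE)
      }
    }
    TRUE
  }
  out <- NULL
  for (s in seq_len(n - 1)) {
    for (e in (s + 1):n) {
      if (!qual(s, e)) next
      maximal <- !((s > 1 && qual(s - 1, e)) ||
                     (e < n && qual(s, e + 1)))
      if (!maximal) next
      amp <- x[e] - x[s]
      if (abs(amp) >= amp_min - tol && amp != 0) {
        out <- rbind(out, data.frame(
          start_frame = s, end_frame = e,
          direction = if (amp > 0) "increase" else "decrease",
          amplitude = abs(amp)))
      }
    }
  }
  if (is.null(out))
    return(data.frame(start_frame = integer(), end_frame = integer(),
                      direction = character(), amplitude = numeric()))
  out[order(out$start_frame), , drop = FALSE]
}

# Minimum-cost assignment by exhaustive permutation (square matrices).
oracle_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  best <- NULL; best_cost <- Inf
  for (p in perms(seq_len(n))) {
    cst <- sum(cost[cbind(seq_len(n), p)])
    if (cst < best_cost) { best_cost <- cst; best <- p }
  }
  list(assignment = best, cost = best_cost)
}

# Closed-form 2D diffusion of a Gaussian bleach profile (infinite
# domain): 1 - K * s0^2/(s0^2 + 2 D t) * exp(-r^2 / (2 (s0^2 + 2 D t))).
oracle_gaussian_diffusion <- function(r, t, D, depth, sigma0) {
  s2 <- sigma0^2 + 2 * D * t
  1 - depth * (sigma0^2 / s2) * exp(-r^2 / (2 * s2))
}

# Simple synthetic nucleus image helpers used across tests.
disk_image <- function(size, centres, radius, fg = 200, bg = 20) {
  m <- matrix(bg, size, size)
  g <- expand.grid(y = seq_len(size), x = seq_len(size))
  for (i in seq_len(nrow(centres))) {
    d <- sqrt((g$y - centres[i, 1])^2 + (g$x - centres[i, 2])^2)
    m[d <= radius] <- fg
  }
  m
}
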