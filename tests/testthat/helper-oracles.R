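# Independent oracles used across tests.  These deliberately use different
# algorithms than the package internals they check.

# All permutations of 1..n by repeated insertion (distinct from the
# package's block-recursion construction).
.perm_oracle_cache <- new.env(parent = emptyenv())

perms_by_insertion <- function(n) {
  key <- as.character(n)
  if (!is.null(.perm_oracle_cache[[key]])) return(.perm_oracle_cache[[key]])
  out <- list(1L)
  for (m in 2:n) {
    nxt <- vector("list", length(out) * m)
    q <- 0L
    for (p in out) {
      for (pos in 0:(m - 1L)) {
        q <- q + 1L
        nxt[[q]] <- append(p, m, after = pos)
      }
    }
    out <- nxt
  }
  .perm_oracle_cache[[key]] <- out
  out
}

# Exhaustive-enumeration Spearman oracle for untied data: rho via the
# classical 1 - 6*sum(d^2)/(n(n^2-1)) identity, two-sided permutation p by
# direct counting.
spearman_brute <- function(x, y) {
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  rho_of <- function(r1, r2) 1 - 6 * sum((r1 - r2)^2) / (n * (n^2 - 1))
  rho <- rho_of(rx, ry)
  perms <- perms_by_insertion(n)
  rho_all <- vapply(perms, function(p) rho_of(rx, ry[p]), numeric(1))
  list(rho = rho, p_value = mean(abs(rho_all) >= abs(rho) - 1e-8))
}

# Dense-grid crossing search over the linear interpolant of a sampled
# signal: brute-force counterpart of the segmenter's interpolated
# crossings.
brute_crossing <- function(time_s, d, level, direction = "up",
                           factor = 1000) {
  tt <- seq(time_s[1], time_s[length(time_s)],
            length.out = length(time_s) * factor)
  dd <- stats::approx(time_s, d, xout = tt)$y
  hit <- if (direction == "up") {
    which(dd[-1] > level & dd[-length(dd)] <= level)
  } else {
    which(dd[-1] < level & dd[-length(dd)] >= level)
  }
  tt[hit] + (level - dd[hit]) / (dd[hit + 1L] - dd[hit]) *
    (tt[hit + 1L] - tt[hit])
}

canonical_profile <- function() {
  tug_profile(sit_up_s = 4.51, walk_forward_s = 3.78, turn_s = 3.00,
              walk_back_s = 4.41, sit_down_s = 4.59)
}

subtask_vec <- function(st) {
  unlist(st[c("sit_up_s", "walk_forward_s", "turn_s", "walk_back_s",
              "sit_down_s")])
}
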