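# Independent brute-force block-matching oracle: plain-R exhaustive scan
# over every integer lag in the search window, NCC computed from first
# principles. Deliberately naive and separate from the package's
# implementation.
oracle_ncc <- function(a, b, ci, cj, h, di, dj) {
  ka <- a[(ci - h):(ci + h), (cj - h):(cj + h)]
  kb <- b[(ci + di - h):(ci + di + h), (cj + dj - h):(cj + dj + h)]
  ka <- ka - mean(ka)
  kb <- kb - mean(kb)
  va <- sum(ka^2)
  vb <- sum(kb^2)
  if (va <= 1e-12 || vb <= 1e-12) return(0)
  sum(ka * kb) / sqrt(va * vb)
}

oracle_best_lag <- function(a, b, ci, cj, h, radius) {
  best <- -Inf
  best_lag <- c(0L, 0L)
  for (di in -radius:radius) {
    for (dj in -radius:radius) {
      s <- oracle_ncc(a, b, ci, cj, h, di, dj)
      better <- s > best + 1e-12
      tie <- abs(s - best) <= 1e-12 &&
        (di^2 + dj^2) < sum(best_lag^2)
      if (better || tie) {
        best <- s
        best_lag <- c(di, dj)
      }
    }
  }
  list(di = best_lag[1], dj = best_lag[2], score = best)
}
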