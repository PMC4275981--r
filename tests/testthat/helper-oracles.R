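# Quiet audit logging during tests
options(g4screen.verbose = FALSE)

rand_seq <- function(n, gc = 0.4) {
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(gc / 2, gc / 2, (1 - gc) / 2, (1 - gc) / 2)),
        collapse = "")
}

# Brute-force maximal-run finder: walk the characters.
oracle_g_runs <- function(seq, min_len, letter = "G") {
  chars <- strsplit(seq, "")[[1]]
  r <- rle(chars)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  keep <- r$values == letter & r$lengths >= min_len
  data.frame(start = starts[keep], length = r$lengths[keep])
}

# Brute-force oracle for the motif pattern: list maximal G-runs (islands)
# with the rle-based enumerator, then walk them one by one with an explicit
# loop, closing a chain whenever the next island is more than max_loop away
# and emitting it if it holds >= min_islands islands. Loops between listed
# islands can only contain G-runs shorter than min_g (the runs are
# maximal), matching the island/loop definition. Independent of the
# vectorised chaining in the scanner.
oracle_scan_plus <- function(seq, min_g = 3, max_loop = 25, min_islands = 4) {
  runs <- oracle_g_runs(seq, min_g, "G")
  out <- data.frame(start = integer(), end = integer())
  chain <- integer() # row indices of the open chain
  emit <- function(chain) {
    if (length(chain) >= min_islands) {
      first <- chain[1]; last <- chain[length(chain)]
      out[nrow(out) + 1L, ] <<- c(runs$start[first],
                                  runs$start[last] + runs$length[last])
    }
  }
  for (i in seq_len(nrow(runs))) {
    if (length(chain) == 0L) {
      chain <- i
    } else {
      prev <- chain[length(chain)]
      gap <- runs$start[i] - (runs$start[prev] + runs$length[prev])
      if (gap <= max_loop) {
        chain <- c(chain, i)
      } else {
        emit(chain)
        chain <- i
      }
    }
  }
  emit(chain)
  out
}

revcomp_chr <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Minus-strand oracle: scan the reverse complement with the regex oracle
# and mirror coordinates back to the reference.
oracle_scan_minus <- function(seq, ...) {
  L <- nchar(seq)
  hits <- oracle_scan_plus(revcomp_chr(seq), ...)
  if (!nrow(hits)) return(hits)
  out <- data.frame(start = L - hits$end, end = L - hits$start)
  out[order(out$start), , drop = FALSE]
}

# Quadratic all-pairs association counter (gap rule written out directly).
oracle_count_associated <- function(query, subject, window) {
  hit_one <- function(i) {
    for (j in seq_len(nrow(subject))) {
      if (query$chrom[i] != subject$chrom[j]) next
      ov <- query$start[i] < subject$end[j] && subject$start[j] < query$end[i]
      if (window == 0) {
        if (ov) return(TRUE)
      } else {
        gap <- max(subject$start[j] - query$end[i],
                   query$start[i] - subject$end[j], 0)
        if (ov || gap <= window) return(TRUE)
      }
    }
    FALSE
  }
  sum(vapply(seq_len(nrow(query)), hit_one, NA))
}

# Exhaustive two-sided Fisher by hypergeometric enumeration over all
# feasible tables with the observed margins (point-probability rule,
# relative tie tolerance 1e-7).
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- dhyper(lo:hi, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided signed-rank P by enumerating all 2^n sign assignments.
oracle_signed_rank <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  stopifnot(n <= 12)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), n))
  v_all <- as.matrix(signs) %*% r
  ev <- n * (n + 1) / 4
  p <- mean(abs(v_all - ev) >= abs(v_obs - ev) - 1e-9)
  min(1, p)
}
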