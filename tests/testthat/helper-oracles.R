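# Independent brute-force oracles used to pin down expected values. These
# deliberately share no code with the implementation they check.

# consensus by pair enumeration: labels is a named character vector
# (source -> reported family); returns the called family or NA
oracle_consensus <- function(labels) {
  sources <- names(labels)
  agreeing <- character()
  if (length(sources) >= 2L) {
    pairs <- utils::combn(sources, 2L)
    for (j in seq_len(ncol(pairs))) {
      a <- pairs[1, j]; b <- pairs[2, j]
      if (labels[[a]] == labels[[b]])
        agreeing <- c(agreeing, labels[[a]])
    }
  }
  if (!length(agreeing)) return(NA_character_)
  for (src in c("HMMER", "eCAMI", "DIAMOND")) {
    if (src %in% sources && labels[[src]] %in% agreeing)
      return(labels[[src]])
  }
  NA_character_
}

# brute-force CGC detection: enumerate every window, keep valid ones not
# strictly contained in another valid window; returns "first-last" spans
oracle_cgc_windows <- function(roles, max_gap = 2L) {
  n <- length(roles)
  sig <- roles %in% c("CAZyme", "TC", "TF", "STP")
  valid <- list()
  for (a in seq_len(n)) {
    for (b in a:n) {
      if (!sig[a] || !sig[b]) next
      inner <- roles[a:b]
      isig <- sig[a:b]
      # no run of more than max_gap consecutive non-signature genes inside
      runs <- rle(!isig)
      if (any(runs$values & runs$lengths > max_gap)) next
      if (!any(inner == "CAZyme")) next
      if (!any(isig & inner != "CAZyme")) next
      valid[[length(valid) + 1L]] <- c(a, b)
    }
  }
  if (!length(valid)) return(character())
  keep <- vapply(seq_along(valid), function(i) {
    w <- valid[[i]]
    !any(vapply(seq_along(valid), function(j) {
      v <- valid[[j]]
      j != i && v[1] <= w[1] && v[2] >= w[2]
    }, logical(1)))
  }, logical(1))
  spans <- vapply(valid[keep], function(w) paste(w[1], w[2], sep = "-"),
                  character(1))
  sort(spans)
}

# exact two-sided rank-sum test by full enumeration of group assignments
oracle_ranksum_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  ws <- apply(combs, 2L, function(idx)
    sum(ranks[idx]) - nx * (nx + 1) / 2)
  p <- min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
  list(statistic = w_obs, p_value = p)
}

# Kruskal-Wallis H statistic from its rank definition with tie correction
oracle_kruskal_h <- function(values, groups) {
  r <- rank(values)
  N <- length(values)
  h <- 12 / (N * (N + 1)) *
    sum(tapply(r, groups, function(ri) length(ri) * mean(ri)^2)) -
    3 * (N + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (N^3 - N))
}

oracle_bray <- function(x, y) sum(abs(x - y)) / sum(x + y)

oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE))
}
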