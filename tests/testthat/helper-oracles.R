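# Independent brute-force oracles, written from first-principles formulas
# and kept free of the package's own code paths.

# Welch two-sided p from the textbook formula
oracle_welch_p <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  2 * stats::pt(-abs(t), df)
}

# brute-force GMPL caller: plain loops over a values matrix
oracle_gmpl <- function(values, groups, conv, gf, diet, fd_threshold,
                        alpha, pseudocount) {
  ic <- which(groups == conv)
  ig <- which(groups == gf)
  id <- which(groups == diet)
  t(vapply(seq_len(nrow(values)), function(i) {
    v <- values[i, ]
    m_c <- sum(v[ic]) / length(ic)
    m_g <- sum(v[ig]) / length(ig)
    m_d <- sum(v[id]) / length(id)
    fd_cg <- (m_c + pseudocount) / (m_g + pseudocount)
    fd_cd <- (m_c + pseudocount) / (m_d + pseudocount)
    p <- oracle_welch_p(
      log(v[ic] + pseudocount), log(v[ig] + pseudocount)
    )
    c(
      fd_cg = fd_cg, fd_cd = fd_cd, p = p,
      sig = as.numeric(fd_cg > fd_threshold & fd_cd > fd_threshold &
        p < alpha)
    )
  }, numeric(4L)))
}

# two-sided Fisher exact p by exhaustive hypergeometric enumeration
oracle_fisher_two_sided <- function(a, b, c, d) {
  m <- a + b # row 1 total
  n <- c + d # row 2 total
  k <- a + c # col 1 total
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Venn partition by per-id loop over membership patterns
oracle_venn <- function(sets) {
  ids <- sort(unique(unlist(sets)))
  patterns <- vapply(ids, function(id) {
    inset <- vapply(sets, function(s) id %in% s, logical(1L))
    paste(names(sets)[inset], collapse = "&")
  }, character(1L))
  split(ids, patterns)
}

# exhaustive two-group PERMANOVA by explicit double loops
oracle_permanova_2group <- function(dm, labels) {
  n <- nrow(dm)
  gs <- unique(labels)
  stopifnot(length(gs) == 2L)
  n1 <- sum(labels == gs[1L])
  f_of <- function(idx1) {
    idx2 <- setdiff(seq_len(n), idx1)
    ss_tot <- 0
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) ss_tot <- ss_tot + dm[i, j]^2
    }
    ss_tot <- ss_tot / n
    ssw <- 0
    for (grp in list(idx1, idx2)) {
      s <- 0
      for (i in grp) {
        for (j in grp) {
          if (i < j) s <- s + dm[i, j]^2
        }
      }
      ssw <- ssw + s / length(grp)
    }
    ((ss_tot - ssw) / 1) / (ssw / (n - 2))
  }
  obs <- f_of(which(labels == gs[1L]))
  combos <- utils::combn(n, n1, simplify = FALSE)
  fs <- vapply(combos, f_of, numeric(1L))
  list(
    pseudo_F = obs,
    p = mean(fs >= obs - 1e-12),
    f_all = fs
  )
}
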