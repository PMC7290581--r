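# Independent brute-force oracles used across test files. These deliberately
# avoid the package's implementation paths (and the survival package), so
# agreement is a genuine cross-check.

# product-limit restricted mean by direct enumeration of risk sets;
# deaths precede censorings at tied values
oracle_km_rmean <- function(value, censored) {
  ord <- order(value, censored)   # FALSE (death) before TRUE (censor) at ties
  v <- value[ord]; cen <- censored[ord]
  n <- length(v)
  surv <- 1
  t_prev <- min(v)
  area <- 0
  s_cur <- 1
  at_risk <- n
  i <- 1
  while (i <= n) {
    ti <- v[i]
    # deaths at ti
    d <- sum(v == ti & !cen)
    c_ <- sum(v == ti & cen)
    area <- area + s_cur * (ti - t_prev)
    if (d > 0) s_cur <- s_cur * (1 - d / at_risk)
    at_risk <- at_risk - d - c_
    t_prev <- ti
    i <- i + d + c_
  }
  min(value) + area
}

# two-group log-rank chi-square by direct risk-set summation
oracle_logrank <- function(value, censored, group) {
  groups <- sort(unique(group))
  stopifnot(length(groups) == 2)
  times <- sort(unique(value[!censored]))
  o_minus_e <- 0
  v_sum <- 0
  for (t in times) {
    at_risk <- value >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == groups[1])
    d <- sum(value == t & !censored)
    d1 <- sum(value == t & !censored & group == groups[1])
    if (n < 2 || d == 0) next
    e1 <- d * n1 / n
    v1 <- d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    o_minus_e <- o_minus_e + (d1 - e1)
    v_sum <- v_sum + v1
  }
  o_minus_e^2 / v_sum
}

# weighted Breslow partial log-likelihood for (start, stop] counting-process
# records with a single covariate column x
oracle_wpl <- function(beta, start, stop, event, x, w) {
  ll <- 0
  for (i in which(event == 1)) {
    t <- stop[i]
    risk <- start < t & stop >= t
    ll <- ll + w[i] * (beta * x[i] -
                         log(sum(w[risk] * exp(beta * x[risk]))))
  }
  ll
}

oracle_wpl_argmax <- function(start, stop, event, x, w,
                              grid = seq(-4, 4, by = 5e-4)) {
  ll <- vapply(grid, oracle_wpl, numeric(1), start, stop, event, x, w)
  grid[which.max(ll)]
}

# exhaustive-count reclassification oracles
oracle_cnri <- function(ro, rn, ev, w = rep(1, length(ev))) {
  ev <- as.logical(ev)
  up <- rn > ro; dn <- rn < ro
  pe <- function(flag) sum(w[ev & flag]) / sum(w[ev])
  pn <- function(flag) sum(w[!ev & flag]) / sum(w[!ev])
  100 * ((pe(up) - pe(dn)) + (pn(dn) - pn(up)))
}

oracle_catnri <- function(ro, rn, ev, cut = 0.10, w = rep(1, length(ev))) {
  co <- as.integer(ro >= cut); cn <- as.integer(rn >= cut)
  oracle_cnri(co, cn, ev, w)
}

oracle_idi <- function(ro, rn, ev, w = rep(1, length(ev))) {
  ev <- as.logical(ev)
  d <- rn - ro
  sum(w[ev] * d[ev]) / sum(w[ev]) - sum(w[!ev] * d[!ev]) / sum(w[!ev])
}

oracle_cindex <- function(risk, time, ev, w = rep(1, length(ev))) {
  ev <- as.logical(ev)
  num <- 0; den <- 0
  n <- length(ev)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || !ev[i]) next
      usable <- time[j] > time[i] || (time[j] == time[i] && !ev[j])
      if (!usable) next
      wij <- w[i] * w[j]
      den <- den + wij
      if (risk[i] > risk[j]) num <- num + wij
      else if (risk[i] == risk[j]) num <- num + 0.5 * wij
    }
  }
  if (den == 0) NA_real_ else num / den
}

# exact hypergeometric upper tail by enumerating all size-n draws
oracle_hyper <- function(N, K, n, k) {
  draws <- combn(N, n)
  in_set <- draws <= K              # label genes 1..K as the set
  mean(colSums(in_set) >= k)
}

# step-up BH from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# small raw ct_matrix with planted plate offsets, used by several files
make_plate_fixture <- function(n_per_plate = 30, n_plates = 4, n_mir = 6,
                               offsets = NULL, noise = 0.4, seed = 42) {
  set.seed(seed)
  if (is.null(offsets)) offsets <- rnorm(n_plates, 0, 1)
  n <- n_per_plate * n_plates
  plate <- rep(sprintf("P%d", seq_len(n_plates)), each = n_per_plate)
  base <- seq(24, 30, length.out = n_mir)
  values <- matrix(base, n, n_mir, byrow = TRUE) +
    offsets[rep(seq_len(n_plates), each = n_per_plate)] +
    matrix(rnorm(n * n_mir, 0, noise), n, n_mir)
  dimnames(values) <- list(sprintf("s%03d", 1:n),
                           sprintf("m%02d", 1:n_mir))
  ct_matrix(values, plate)
}
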