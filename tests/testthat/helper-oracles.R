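# Independent oracles. These deliberately avoid the closed-form estimators
# and code paths used by the package.

# --- one-sided binomial LRT by grid maximization (10^-6 resolution) --------

# log-likelihood with the 0 * log(0) := 0 convention, written without the
# package's helpers
oracle_ll <- function(x, n, p) {
  t1 <- if (x == 0) 0 else x * log(p)
  t2 <- if (n - x == 0) 0 else (n - x) * log(1 - p)
  t1 + t2
}

# maximize oracle_ll over p in [0, 1] by a coarse grid then a 10^-6 local
# refinement (the log-likelihood is concave, so refinement is safe); returns
# c(max, argmax)
oracle_max_1d <- function(x, n) {
  g <- c(0, seq(1e-4, 1 - 1e-4, by = 1e-3), 1)
  v <- vapply(g, function(p) oracle_ll(x, n, p), numeric(1))
  p0 <- g[which.max(v)]
  g2 <- unique(pmin(1, pmax(0, seq(p0 - 2e-3, p0 + 2e-3, by = 1e-6))))
  v2 <- vapply(g2, function(p) oracle_ll(x, n, p), numeric(1))
  c(max = max(v2), arg = g2[which.max(v2)])
}

# maximize the joint log-likelihood along the null boundary p_e = p_i = p
oracle_max_boundary <- function(x_e, n_e, x_i, n_i) {
  f <- function(p) oracle_ll(x_e, n_e, p) + oracle_ll(x_i, n_i, p)
  g <- c(0, seq(1e-4, 1 - 1e-4, by = 1e-3), 1)
  v <- vapply(g, f, numeric(1))
  p0 <- g[which.max(v)]
  g2 <- unique(pmin(1, pmax(0, seq(p0 - 2e-3, p0 + 2e-3, by = 1e-6))))
  max(vapply(g2, f, numeric(1)))
}

# -2 ln(lambda) for H0: p_e <= p_i. The unconstrained maximum separates into
# two 1D problems; the null maximum is the unconstrained one when its argmax
# already satisfies the constraint, otherwise (by concavity / KKT) it lies on
# the boundary p_e = p_i.
oracle_lrt_statistic <- function(x_e, n_e, x_i, n_i) {
  me <- oracle_max_1d(x_e, n_e)
  mi <- oracle_max_1d(x_i, n_i)
  ll_alt <- me[["max"]] + mi[["max"]]
  ll_null <- if (me[["arg"]] <= mi[["arg"]] + 1e-9) {
    ll_alt
  } else {
    oracle_max_boundary(x_e, n_e, x_i, n_i)
  }
  max(0, 2 * (ll_alt - ll_null))
}

# --- Storey q-values, independent formulation -----------------------------

# pi0 by the smoother method (the algorithm the package implements, required
# for agreement); q-values via the direct min-over-larger-p definition
# q(p_(k)) = min_{j >= k} pi0 * m * p_(j) / j, instead of the cumulative-min
# recursion.
oracle_storey <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  if (m < 100) {
    pi0 <- min(1, 2 * mean(p))
  } else {
    pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
    pi0 <- stats::predict(stats::smooth.spline(lambda, pi0_l, df = 3),
                          x = max(lambda))$y
    pi0 <- min(1, max(pi0, .Machine$double.eps))
  }
  o <- order(p)
  ps <- p[o]
  qs <- vapply(seq_len(m), function(k) {
    min(1, min(pi0 * m * ps[k:m] / (k:m)))
  }, numeric(1))
  out <- numeric(m)
  out[o] <- qs
  out
}

# --- NG86 dN/dS by full enumeration ---------------------------------------

oracle_codon_table <- as.list(Biostrings::GENETIC_CODE)
oracle_stops <- names(oracle_codon_table)[unlist(oracle_codon_table) == "*"]

oracle_aa <- function(codon) oracle_codon_table[[codon]]

oracle_syn_sites <- function(codon) {
  ch <- strsplit(codon, "")[[1]]
  total <- 0
  for (pos in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == ch[pos]) next
      mut <- ch
      mut[pos] <- b
      m <- paste0(mut, collapse = "")
      if (!(m %in% oracle_stops) && oracle_aa(m) == oracle_aa(codon)) {
        total <- total + 1
      }
    }
  }
  total / 3
}

oracle_perm_orders <- list(
  matrix(1L, 1, 1),
  rbind(c(1L, 2L), c(2L, 1L)),
  rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
        c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

oracle_codon_diffs <- function(ca, cb) {
  a <- strsplit(ca, "")[[1]]
  b <- strsplit(cb, "")[[1]]
  dpos <- which(a != b)
  k <- length(dpos)
  if (k == 0) return(c(0, 0))
  orders <- oracle_perm_orders[[k]]
  ok <- list(); blocked <- list()
  for (r in seq_len(nrow(orders))) {
    cur <- a
    sd <- 0; nd <- 0; through_stop <- FALSE
    for (s in seq_len(k)) {
      pos <- dpos[orders[r, s]]
      nxt <- cur
      nxt[pos] <- b[pos]
      codon_from <- paste0(cur, collapse = "")
      codon_to <- paste0(nxt, collapse = "")
      if (s < k && codon_to %in% oracle_stops) through_stop <- TRUE
      syn <- !(codon_to %in% oracle_stops) &&
        oracle_aa(codon_from) == oracle_aa(codon_to)
      if (syn) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    rec <- c(sd, nd)
    if (through_stop) blocked[[length(blocked) + 1]] <- rec
    else ok[[length(ok) + 1]] <- rec
  }
  use <- if (length(ok) > 0) ok else blocked
  colMeans(do.call(rbind, use))
}

oracle_ng86 <- function(seq_a, seq_b) {
  split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
  ca <- split3(toupper(seq_a))
  cb <- split3(toupper(seq_b))
  keep <- !(ca %in% oracle_stops) & !(cb %in% oracle_stops)
  ca <- ca[keep]; cb <- cb[keep]
  S <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    S <- S + (oracle_syn_sites(ca[i]) + oracle_syn_sites(cb[i])) / 2
    d <- oracle_codon_diffs(ca[i], cb[i])
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  N <- 3 * length(ca) - S
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  list(N = N, S = S, Nd = Nd, Sd = Sd, dN = jc(pN), dS = jc(pS))
}

# --- Fisher exact by log-factorial summation ------------------------------

oracle_fisher <- function(a, b, c, d) {
  lf <- lfactorial
  logp <- function(k) {
    # probability of k duplicated among the significant margin
    m <- a + c; n <- b + d; kk <- a + b
    lf(m) - lf(k) - lf(m - k) + lf(n) - lf(kk - k) - lf(n - kk + k) -
      (lf(m + n) - lf(kk) - lf(m + n - kk))
  }
  supp <- max(0, (a + b) - (b + d)):min(a + b, a + c)
  lp <- vapply(supp, logp, numeric(1))
  obs <- logp(a)
  one <- sum(exp(lp[supp >= a]))
  two <- sum(exp(lp[lp <= obs + 1e-7]))
  list(one_sided = one, two_sided = min(1, two))
}
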