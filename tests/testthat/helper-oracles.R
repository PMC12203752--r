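# Independent reference implementations used to check the package's
# computations. These are deliberately written from first principles (loops,
# literal formulas) and share no code with the implementation paths they test.

# Step-up FDR adjustment computed literally: sort, apply m * p_(j) / j, take
# the running minimum from the largest rank down, cap at 1, restore order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- numeric(m)
  cur <- Inf
  for (j in m:1) {
    cur <- min(cur, m * ps[j] / j)
    adj[j] <- min(cur, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# One-tailed (greater) Fisher p as an explicit hypergeometric tail sum over
# all tables at least as extreme in the a cell, margins fixed.
fisher_tail_oracle <- function(a, b, c, d) {
  m1 <- a + b   # DEG margin (draws)
  k1 <- a + c   # genes with a site (white balls)
  n  <- a + b + c + d
  kmax <- min(m1, k1)
  sum(vapply(a:kmax, function(k) stats::dhyper(k, k1, n - k1, m1), 0))
}

# All-pairs brute-force overlap counts in 1-based inclusive coordinates.
overlap_oracle <- function(windows, intervals) {
  vapply(seq_len(nrow(windows)), function(i) {
    sum(intervals$chrom == windows$chrom[i] &
          pmax(intervals$start, windows$start[i]) <=
          pmin(intervals$end, windows$end[i]))
  }, 0)
}

# Newton-Raphson maximiser of the Cox partial likelihood for UNTIED event
# times (where Breslow, Efron and the exact likelihood coincide).
cox_nr_oracle <- function(X, time, event, tol = 1e-12, max_iter = 50) {
  X <- as.matrix(X)
  ord <- order(time)
  X <- X[ord, , drop = FALSE]
  event <- event[ord]
  n <- nrow(X)
  p <- ncol(X)
  beta <- rep(0, p)
  for (it in seq_len(max_iter)) {
    U <- rep(0, p)
    H <- matrix(0, p, p)
    for (i in which(event == 1)) {
      risk <- i:n            # risk set: all with time >= t_i (untied, sorted)
      w <- exp(X[risk, , drop = FALSE] %*% beta)
      sw <- sum(w)
      xbar <- colSums(X[risk, , drop = FALSE] * as.numeric(w)) / sw
      U <- U + X[i, ] - xbar
      xc <- sweep(X[risk, , drop = FALSE], 2, xbar)
      H <- H + t(xc) %*% (xc * as.numeric(w)) / sw
    }
    step <- solve(H, U)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

# Brute-force median-of-ratios size factors.
size_factor_oracle <- function(m) {
  keep <- apply(m, 1, function(r) all(r > 0))
  geo <- apply(m[keep, , drop = FALSE], 1, function(r) exp(mean(log(r))))
  vapply(seq_len(ncol(m)), function(s)
    stats::median(m[keep, s] / geo), 0)
}

# A small cohort configuration for fast end-to-end tests.
small_sim_config <- function(n_genes = 600, seed = 1L, ...) {
  sim_config(n_genes = n_genes,
             n_met_up = 20, n_met_down = 20,
             n_tissue_specific = c(liver = 10, adrenal = 8, bone = 10),
             n_prognostic = 3, seed = seed, ...)
}

# Sample design with n_pat matched patients (one primary + two metastases
# each) plus minimal controls, for hand-crafted count matrices.
matched_design <- function(n_pat = 6) {
  rows <- list()
  for (i in seq_len(n_pat)) {
    p <- sprintf("P%02d", i)
    rows[[length(rows) + 1]] <- data.frame(
      sample_id = c(sprintf("%s_pri1", p), sprintf("%s_met1", p), sprintf("%s_met2", p)),
      patient_id = p, category = c("primary", "metastasis", "metastasis"),
      tissue = c("prostate", "liver", "bone"), stringsAsFactors = FALSE)
  }
  rows[[length(rows) + 1]] <- data.frame(
    sample_id = c("N1", "N2", "B1", "B2"),
    patient_id = c("D1", "D2", "D3", "D4"),
    category = c("normal", "normal", "bph", "bph"),
    tissue = c("liver", "liver", "prostate", "prostate"), stringsAsFactors = FALSE)
  do.call(rbind, rows)
}
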