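# Independent oracles used to verify the package's statistics and interval
# logic. These deliberately avoid the code paths (and, where feasible, the
# base-R functions) they are checking: tail probabilities come from explicit
# enumeration over small universes, and interval logic from all-pairs scans.

# P(overlap >= k) (or <= k) by enumerating every possible draw of set_b
# from a universe of size N in which set_a is the first `a` elements.
oracle_hypergeom <- function(k, a, b, N, tail = "greater") {
  draws <- utils::combn(N, b)
  ov <- colSums(draws <= a)
  if (tail == "greater") mean(ov >= k) else mean(ov <= k)
}

# One-sided (greater in the (1,1) cell) Fisher p by enumerating all tables
# with the observed margins; table probabilities from the closed-form
# ratio of binomial coefficients.
oracle_fisher_greater <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  c1 <- sum(tab[, 1])
  N <- sum(tab)
  ks <- max(0, c1 - (N - r1)):min(r1, c1)
  pk <- choose(r1, ks) * choose(N - r1, c1 - ks) / choose(N, c1)
  sum(pk[ks >= a])
}

# Exact two-sided rank-sum p by enumerating all C(m+n, m) assignments of
# the pooled ranks to the first sample (requires no ties).
oracle_wilcoxon_exact <- function(x, y) {
  m <- length(x)
  n <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  sets <- utils::combn(m + n, m)
  ranks_all <- seq_len(m + n)
  u_all <- colSums(matrix(ranks_all[sets], nrow = m)) - m * (m + 1) / 2
  if (u_obs > m * n / 2) {
    min(1, 2 * mean(u_all >= u_obs))
  } else {
    min(1, 2 * mean(u_all <= u_obs))
  }
}

# Step-up BH by its definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- pmin(adj, 1)
  out
}

# Yates-corrected one-sided (p1 > p2) two-proportion z-test, transcribed
# from the textbook formula.
oracle_prop_greater <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1
  p2 <- x2 / n2
  pbar <- (x1 + x2) / (n1 + n2)
  delta <- p1 - p2
  yates <- min(0.5, abs(x1 - n1 * pbar))
  stat <- sum((abs(c(x1, n1 - x1, x2, n2 - x2) -
                     c(n1 * pbar, n1 * (1 - pbar),
                       n2 * pbar, n2 * (1 - pbar))) - yates)^2 /
                c(n1 * pbar, n1 * (1 - pbar), n2 * pbar, n2 * (1 - pbar)))
  z <- sign(delta) * sqrt(stat)
  stats::pnorm(z, lower.tail = FALSE)
}

# Hand-coded IRLS logistic regression; deviance used for an independent
# likelihood-ratio test.
oracle_irls_logistic <- function(X, y, tol = 1e-13, maxit = 200) {
  beta <- rep(0, ncol(X))
  dev <- Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    beta <- drop(solve(crossprod(X, X * w), crossprod(X, w * z)))
    dev_new <- -2 * sum(y * log(mu) + (1 - y) * log(1 - mu))
    if (abs(dev_new - dev) < tol * (abs(dev_new) + 0.1)) {
      dev <- dev_new
      break
    }
    dev <- dev_new
  }
  eta <- drop(X %*% beta)
  mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-12), 1 - 1e-12)
  list(beta = beta,
       deviance = -2 * sum(y * log(mu) + (1 - y) * log(1 - mu)))
}

oracle_lr_pvalue <- function(a, y, logd) {
  full <- oracle_irls_logistic(cbind(1, logd, a), y)
  null <- oracle_irls_logistic(cbind(1, logd), y)
  stats::pchisq(max(null$deviance - full$deviance, 0), df = 1,
                lower.tail = FALSE)
}

# O(n * m) nearest-TSS scan with the package's distance convention
# re-derived by hand (gap to the half-open interval boundary).
oracle_nearest_gene <- function(peaks, genes) {
  out <- list()
  for (i in seq_len(nrow(peaks))) {
    gi <- which(genes$chrom == peaks$chrom[i])
    if (length(gi) == 0) next
    best_mag <- Inf
    best_gene <- NULL
    for (g in gi) {
      tss <- genes$tss[g]
      mag <- if (tss >= peaks$start[i] && tss <= peaks$end[i]) {
        0
      } else if (tss < peaks$start[i]) {
        peaks$start[i] - tss
      } else {
        tss - peaks$end[i]
      }
      if (mag < best_mag ||
          (mag == best_mag && genes$gene_id[g] < best_gene)) {
        best_mag <- mag
        best_gene <- genes$gene_id[g]
      }
    }
    out[[peaks$id[i]]] <- list(gene = best_gene, mag = best_mag)
  }
  out
}

# All-pairs interval overlap under the query-frame fraction rule.
oracle_common_peaks <- function(a, b, min_fraction = 0.5) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov > 0 && ov / (a$end[i] - a$start[i]) >= min_fraction) {
        keep[i] <- TRUE
        break
      }
    }
  }
  a$id[keep]
}

# All-pairs >= 1 bp overlap.
oracle_min_bp_overlap <- function(a, b, min_bp = 1) {
  keep <- logical(nrow(a))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_bp) {
        keep[i] <- TRUE
        break
      }
    }
  }
  a$id[keep]
}

# Exhaustive PWM threshold: enumerate all 4^L windows, score with the same
# discretized integer log-odds, and find the smallest score whose exact
# null tail is <= p_cutoff.
oracle_pwm_threshold <- function(p, p_cutoff, bg = rep(0.25, 4)) {
  probs <- pmax(p$probs, 1e-10)
  m <- round(log2(probs / bg) / 1e-3)
  L <- ncol(m)
  grid <- as.matrix(expand.grid(rep(list(1:4), L)))
  scores <- vapply(seq_len(nrow(grid)), function(r) {
    sum(m[cbind(grid[r, ], seq_len(L))])
  }, numeric(1))
  wprob <- vapply(seq_len(nrow(grid)), function(r) {
    prod(bg[grid[r, ]])
  }, numeric(1))
  cand <- sort(unique(scores))
  tails <- vapply(cand, function(t) sum(wprob[scores >= t]), numeric(1))
  ok <- which(tails <= p_cutoff)
  if (length(ok) == 0) max(scores) + 1L else cand[ok[1]]
}

# Random small interval set on a shared chromosome namespace.
random_peak_set <- function(n, prefix, chroms = c("c1", "c2"),
                            max_pos = 500, max_w = 60) {
  st <- sample.int(max_pos, n, replace = TRUE)
  peak_set(sample(chroms, n, replace = TRUE), st,
           st + sample.int(max_w, n, replace = TRUE),
           paste0(prefix, seq_len(n)))
}

# Random PWM with moderate information content (decoy motifs).
random_pwm <- function(id, L = 10) {
  probs <- matrix(stats::rgamma(4 * L, 1), 4, L)
  probs <- sweep(probs, 2, colSums(probs), "/")
  pwm(id, id, probs)
}
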