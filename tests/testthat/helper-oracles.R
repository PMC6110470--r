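# Independent brute-force oracles. These never call the package code paths
# they are used to check.

# Enumerate all 3^n state paths of the 3-state CNV HMM (states 1=DIP,
# 2=DEL, 3=DUP) and return total data likelihood, the Viterbi optimum and
# tail probabilities by direct summation.
oracle_hmm_enumerate <- function(z, targets, params) {
  n <- length(z)
  stopifnot(n <= 9)
  means <- c(0, params$del_mean, params$dup_mean)
  p <- params$p_cnv
  q <- 1 / params$mean_cnv_targets
  init <- c(1 - 2 * p, p, p)
  gaps <- if (n > 1) pmax(0, targets$start[-1] - targets$end[-n]) else numeric(0)
  trans <- lapply(gaps, function(d) {
    f <- exp(-d / params$attrition_dist_bp)
    matrix(c(1 - 2 * p, p, p,
             f * q + (1 - f) * (1 - 2 * p), f * (1 - q) + (1 - f) * p, (1 - f) * p,
             f * q + (1 - f) * (1 - 2 * p), (1 - f) * p, f * (1 - q) + (1 - f) * p),
           3, 3, byrow = TRUE)
  })
  emis <- sapply(1:3, function(s) dnorm(z, means[s], params$emission_sd, log = TRUE))
  paths <- as.matrix(expand.grid(rep(list(1:3), n)))
  logp <- log(init[paths[, 1]]) + emis[cbind(1, paths[, 1])]
  if (n > 1) {
    for (t in 2:n) {
      logp <- logp + log(trans[[t - 1]][cbind(paths[, t - 1], paths[, t])]) +
        emis[cbind(t, paths[, t])]
    }
  }
  m <- max(logp)
  list(paths = paths, logp = logp,
       loglik = m + log(sum(exp(logp - m))),
       viterbi_logp = max(logp),
       viterbi_path = paths[which.max(logp), ])
}

# P(at least one target in t1..t2 occupies `state` | data), by summation
# over enumerated paths.
oracle_p_some <- function(enum, t1, t2, state) {
  seg <- enum$paths[, t1:t2, drop = FALSE]
  hit <- apply(seg == state, 1, any)
  m <- max(enum$logp)
  sum(exp(enum$logp[hit] - m)) / sum(exp(enum$logp - m))
}

# Truth-table evaluation of the composite deleteriousness rule.
oracle_deleterious <- function(effect, n_hits, cadd, cons_count,
                               min_hits = 5, cadd_min = 4.5, min_cons = 2) {
  c2 <- effect %in% c("splicing", "stopgain", "stoploss")
  c3 <- effect %in% c("insertion", "deletion")
  c1 <- effect != "synonymous" &&
    (n_hits >= min_hits || cadd > cadd_min || cons_count >= min_cons)
  c1 || c2 || c3
}

# Exhaustive rank-split two-sided rank-sum p-value (no ties assumed),
# following the exact two-sided convention 2*min(tail) capped at 1.
oracle_rank_sum_p <- function(a, b) {
  n <- length(a)
  m <- length(b)
  pooled <- c(a, b)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  splits <- combn(n + m, n)
  w_all <- apply(splits, 2, function(idx) sum(ranks[idx]) - n * (n + 1) / 2)
  p_low <- mean(w_all <= w_obs)
  p_high <- mean(w_all >= w_obs)
  if (w_obs > n * m / 2) min(2 * p_high, 1) else min(2 * p_low, 1)
}

# Hypergeometric upper tail by direct mass summation.
oracle_hyper_upper <- function(k, n, K, N) {
  if (k == 0) return(1)
  sum(vapply(k:min(n, K), function(x) dhyper(x, K, N - K, n), numeric(1)))
}

# Compound-het screen by brute-force triple loop.
oracle_comphet <- function(deleted, variants, edges) {
  out <- list()
  has_edge <- function(a, b) {
    any((edges$from == a & edges$to == b) | (edges$from == b & edges$to == a))
  }
  for (i in seq_len(nrow(variants))) {
    for (j in seq_len(nrow(deleted))) {
      if (variants$sample[i] != deleted$sample[j]) next
      vg <- variants$gene[i]
      dg <- deleted$gene[j]
      if (vg == dg) {
        out[[length(out) + 1]] <- data.frame(sample = variants$sample[i],
                                             variant_gene = vg,
                                             deleted_gene = dg,
                                             relation = "same_gene")
      } else if (has_edge(vg, dg)) {
        out[[length(out) + 1]] <- data.frame(sample = variants$sample[i],
                                             variant_gene = vg,
                                             deleted_gene = dg,
                                             relation = "first_order")
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(sample = character(), variant_gene = character(),
                      deleted_gene = character(), relation = character()))
  }
  res <- do.call(rbind, out)
  res <- unique(res)
  res[order(res$sample, res$variant_gene, res$deleted_gene), , drop = FALSE]
}

# Small target scaffold on one chromosome.
make_targets <- function(n, chrom = "chr1", len = 150, gap = 2000) {
  start <- 10001 + (0:(n - 1)) * (len + gap)
  tibble::tibble(chrom = chrom, start = start, end = start + len)
}

random_hmm_instance <- function(n) {
  tg <- make_targets(n, gap = round(runif(1, 200, 50000)))
  z <- rnorm(n, sample(c(0, -3, -4, 3), n, replace = TRUE,
                       prob = c(0.6, 0.2, 0.1, 0.1)))
  list(z = z, targets = tg)
}
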