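# Three-state HMM (diploid / deletion / duplication) over per-target
# normalized depth z-scores, with distance-dependent transitions: Viterbi
# segmentation and forward-backward segment qualities. States are indexed
# 1 = DIP, 2 = DEL, 3 = DUP throughout; ties in the Viterbi recursion break
# toward the lowest state index for determinism.

#' HMM parameters for read-depth CNV segmentation
#'
#' Defaults follow the published defaults of the PCA+HMM exome-CNV method
#' this caller re-implements: CNV entry probability 1e-8, expected CNV
#' length 6 targets (per-target exit rate q = 1/6), attrition distance
#' D = 70 kb (the chain relaxes toward diploid between distant targets as
#' f = exp(-d / D)), Gaussian emissions with means 0 / -3 / +3 and unit sd.
#'
#' @param p_cnv Probability of entering a CNV state between adjacent targets.
#' @param mean_cnv_targets Expected CNV length in targets (exit rate 1/t).
#' @param attrition_dist_bp Attrition distance D in bp.
#' @param del_mean,dup_mean Emission means of the deletion and duplication
#'   states on the z scale.
#' @param emission_sd Common emission standard deviation.
#' @return List of class `exodel_hmm_params`.
#' @export
hmm_params <- function(p_cnv = 1e-8, mean_cnv_targets = 6,
                       attrition_dist_bp = 70000,
                       del_mean = -3, dup_mean = 3, emission_sd = 1) {
  stopifnot(p_cnv > 0, p_cnv < 0.5, mean_cnv_targets >= 1,
            attrition_dist_bp > 0, emission_sd > 0)
  structure(list(p_cnv = p_cnv, mean_cnv_targets = mean_cnv_targets,
                 attrition_dist_bp = attrition_dist_bp, del_mean = del_mean,
                 dup_mean = dup_mean, emission_sd = emission_sd),
            class = "exodel_hmm_params")
}

#' Distance-dependent transition matrix
#'
#' @param params [hmm_params()].
#' @param dist_bp Non-negative gap (bp) between consecutive targets.
#' @return 3x3 row-stochastic matrix, rows/cols ordered DIP, DEL, DUP.
#' @export
hmm_transition_matrix <- function(params, dist_bp) {
  p <- params$p_cnv
  q <- 1 / params$mean_cnv_targets
  f <- exp(-dist_bp / params$attrition_dist_bp)
  matrix(c(
    1 - 2 * p,                     p,                     p,
    f * q + (1 - f) * (1 - 2 * p), f * (1 - q) + (1 - f) * p, (1 - f) * p,
    f * q + (1 - f) * (1 - 2 * p), (1 - f) * p,           f * (1 - q) + (1 - f) * p
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("DIP", "DEL", "DUP"), c("DIP", "DEL", "DUP")))
}

hmm_initial <- function(params) {
  c(DIP = 1 - 2 * params$p_cnv, DEL = params$p_cnv, DUP = params$p_cnv)
}

# gaps between consecutive targets of one chromosome
target_gaps <- function(targets) {
  if (nrow(targets) < 2) return(numeric(0))
  pmax(0, targets$start[-1] - targets$end[-nrow(targets)])
}

emission_logdens <- function(z, params) {
  rbind(DIP = dnorm(z, 0, params$emission_sd, log = TRUE),
        DEL = dnorm(z, params$del_mean, params$emission_sd, log = TRUE),
        DUP = dnorm(z, params$dup_mean, params$emission_sd, log = TRUE))
}

# Viterbi over one chromosome for a batch of samples.
# Z: n_samples x T matrix of z-scores; gaps: length T-1.
# Returns an n_samples x T integer matrix of decoded states.
viterbi_chrom_batch <- function(Z, gaps, params) {
  n <- nrow(Z)
  Tn <- ncol(Z)
  log_init <- log(hmm_initial(params))
  V <- matrix(log_init, n, 3, byrow = TRUE)
  for (s in 1:3) {
    V[, s] <- V[, s] + dnorm(Z[, 1], c(0, params$del_mean, params$dup_mean)[s],
                             params$emission_sd, log = TRUE)
  }
  ptr <- array(1L, dim = c(n, Tn, 3))
  means <- c(0, params$del_mean, params$dup_mean)
  for (t in seq_len(Tn)[-1]) {
    logA <- log(hmm_transition_matrix(params, gaps[t - 1]))
    Vnew <- matrix(0, n, 3)
    for (s in 1:3) {
      best <- V[, 1] + logA[1, s]
      arg <- rep(1L, n)
      for (k in 2:3) {
        cand <- V[, k] + logA[k, s]
        upd <- cand > best  # strict: ties keep the lower state index
        arg[upd] <- k
        best[upd] <- cand[upd]
      }
      Vnew[, s] <- best + dnorm(Z[, t], means[s], params$emission_sd, log = TRUE)
      ptr[, t, s] <- arg
    }
    V <- Vnew
  }
  states <- matrix(1L, n, Tn)
  last <- rep(1L, n)
  best <- V[, 1]
  for (k in 2:3) {
    upd <- V[, k] > best
    last[upd] <- k
    best[upd] <- V[, k][upd]
  }
  states[, Tn] <- last
  if (Tn > 1) {
    for (t in Tn:2) {
      last <- ptr[cbind(seq_len(n), t, last)]
      states[, t - 1] <- last
    }
  }
  attr(states, "log_prob") <- best
  states
}

states_to_calls <- function(states_row, targets) {
  r <- rle(states_row)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values != 1L)
  if (length(keep) == 0) return(empty_calls_tbl())
  tibble(
    chrom = targets$chrom[starts[keep]],
    start = targets$start[starts[keep]],
    end = targets$end[ends[keep]],
    type = c("DIP", "DEL", "DUP")[r$values[keep]],
    n_targets = r$lengths[keep],
    t_first = starts[keep],
    t_last = ends[keep]
  )
}

empty_calls_tbl <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric(),
         type = character(), n_targets = integer(),
         t_first = integer(), t_last = integer())
}

#' Segment one sample's z-scores into CNV calls (Viterbi path)
#'
#' Decodes the most probable state path of the 3-state HMM per chromosome
#' and returns maximal runs of non-diploid states as unscored calls.
#'
#' @param z Numeric vector of per-target z-scores for one sample.
#' @param targets Tibble (chrom, start, end) aligned with `z`, sorted by
#'   chrom then start.
#' @param params [hmm_params()].
#' @return Tibble of calls: chrom, start, end, type, n_targets, t_first,
#'   t_last (target indices into `targets`).
#' @export
viterbi_segment <- function(z, targets, params = hmm_params()) {
  if (length(z) != nrow(targets)) abort("length(z) must equal nrow(targets)")
  if (any(!is.finite(z))) abort("z must be finite")
  out <- purrr::map(split(seq_len(nrow(targets)), factor(targets$chrom, unique(targets$chrom))),
    function(idx) {
      tg <- targets[idx, ]
      states <- viterbi_chrom_batch(matrix(z[idx], nrow = 1), target_gaps(tg), params)
      calls <- states_to_calls(states[1, ], tg)
      calls$t_first <- idx[calls$t_first]
      calls$t_last <- idx[calls$t_last]
      calls
    })
  bind_rows(out)
}

# Forward-backward over one chromosome for one sample (log space).
# Returns log_alpha, log_beta (3 x T) and the data log-likelihood.
forward_backward <- function(z, gaps, params) {
  Tn <- length(z)
  E <- emission_logdens(z, params)
  la <- matrix(-Inf, 3, Tn)
  lb <- matrix(0, 3, Tn)
  la[, 1] <- log(hmm_initial(params)) + E[, 1]
  logA <- lapply(seq_len(max(Tn - 1, 0)), function(t)
    log(hmm_transition_matrix(params, gaps[t])))
  if (Tn > 1) {
    for (t in 2:Tn) {
      A <- logA[[t - 1]]
      for (s in 1:3) la[s, t] <- logsumexp(la[, t - 1] + A[, s]) + E[s, t]
    }
    for (t in (Tn - 1):1) {
      A <- logA[[t]]
      for (s in 1:3) lb[s, t] <- logsumexp(A[s, ] + E[, t + 1] + lb[, t + 1])
    }
  }
  list(log_alpha = la, log_beta = lb, loglik = logsumexp(la[, Tn]),
       log_trans = logA, log_emis = E)
}

#' Per-target posterior state probabilities
#'
#' @inheritParams viterbi_segment
#' @return Matrix (targets x 3, columns DIP/DEL/DUP) of posteriors; each row
#'   sums to 1.
#' @export
state_posteriors <- function(z, targets, params = hmm_params()) {
  if (length(z) != nrow(targets)) abort("length(z) must equal nrow(targets)")
  out <- matrix(NA_real_, length(z), 3,
                dimnames = list(NULL, c("DIP", "DEL", "DUP")))
  for (idx in split(seq_len(nrow(targets)), factor(targets$chrom, unique(targets$chrom)))) {
    fb <- forward_backward(z[idx], target_gaps(targets[idx, ]), params)
    lp <- fb$log_alpha + fb$log_beta - fb$loglik
    out[idx, ] <- t(exp(lp))
  }
  out
}

# log P(data, no target in t_first..t_last occupies state `state`)
# fb: result of forward_backward over the same chromosome-local coordinates.
log_prob_excluding_state <- function(fb, t_first, t_last, state) {
  keep <- setdiff(1:3, state)
  E <- fb$log_emis
  # restricted forward through the segment
  if (t_first == 1) {
    ap <- fb$log_init + E[, 1]
  } else {
    A <- fb$log_trans[[t_first - 1]]
    ap <- vapply(1:3, function(s)
      logsumexp(fb$log_alpha[, t_first - 1] + A[, s]), numeric(1)) + E[, t_first]
  }
  ap[state] <- -Inf
  if (t_last > t_first) {
    for (t in (t_first + 1):t_last) {
      A <- fb$log_trans[[t - 1]]
      ap_new <- vapply(1:3, function(s)
        logsumexp(ap[keep] + A[keep, s]), numeric(1)) + E[, t]
      ap_new[state] <- -Inf
      ap <- ap_new
    }
  }
  logsumexp(ap[keep] + fb$log_beta[keep, t_last])
}

#' Score a CNV call with a phred-scaled segment quality
#'
#' Computes `q_some`, the phred-scaled posterior probability that at least
#' one target inside the call is in the call's CNV state (capped at 99 per
#' convention), and `z_mean`, the arithmetic mean z over the call's targets.
#' All probabilities are handled in log space, so extreme evidence never
#' underflows.
#'
#' @inheritParams viterbi_segment
#' @param call One-row tibble as produced by [viterbi_segment()] (fields
#'   type, t_first, t_last).
#' @return The call with `q_some` (integer 0-99) and `z_mean` columns added.
#' @export
score_call <- function(z, targets, params = hmm_params(), call) {
  stopifnot(nrow(call) == 1, call$t_first >= 1, call$t_last <= length(z),
            call$t_first <= call$t_last)
  chrom_idx <- which(targets$chrom == targets$chrom[call$t_first])
  fb <- forward_backward(z[chrom_idx], target_gaps(targets[chrom_idx, ]), params)
  fb$log_init <- log(hmm_initial(params))
  state <- match(call$type, c("DIP", "DEL", "DUP"))
  lp_none <- log_prob_excluding_state(
    fb, match(call$t_first, chrom_idx), match(call$t_last, chrom_idx), state)
  q <- -10 * (lp_none - fb$loglik) / log(10)
  call$q_some <- as.integer(min(99, max(0, round(q))))
  call$z_mean <- mean(z[call$t_first:call$t_last])
  call
}

#' Call and score deletions/duplications for every sample of a cohort
#'
#' Runs Viterbi segmentation per sample (batched across samples per
#' chromosome) and forward-backward scoring for each resulting call.
#'
#' @param norm An `exodel_norm` object from [pca_normalize()].
#' @param params [hmm_params()].
#' @return Tibble of scored calls: sample, phenotype, chrom, start, end,
#'   type, n_targets, z_mean, q_some, length_bp.
#' @export
call_cnvs <- function(norm, params = hmm_params()) {
  z <- norm$z
  targets <- norm$targets
  chrom_split <- split(seq_len(nrow(targets)), factor(targets$chrom, unique(targets$chrom)))
  per_sample_calls <- vector("list", length(chrom_split))
  for (ci in seq_along(chrom_split)) {
    idx <- chrom_split[[ci]]
    tg <- targets[idx, ]
    states <- viterbi_chrom_batch(z[, idx, drop = FALSE], target_gaps(tg), params)
    calls <- purrr::map(seq_len(nrow(z)), function(r) {
      cc <- states_to_calls(states[r, ], tg)
      if (nrow(cc) == 0) return(NULL)
      cc$sample <- rownames(z)[r]
      cc$.row <- r
      cc$.chrom_idx <- ci
      cc
    })
    per_sample_calls[[ci]] <- bind_rows(calls)
  }
  calls <- bind_rows(per_sample_calls)
  if (nrow(calls) == 0) {
    return(tibble(sample = character(), phenotype = character(),
                  chrom = character(), start = numeric(), end = numeric(),
                  type = character(), n_targets = integer(),
                  z_mean = numeric(), q_some = integer(), length_bp = numeric()))
  }
  scored <- vector("list", nrow(calls))
  fb_cache_key <- ""
  fb <- NULL
  ord <- order(calls$.row, calls$.chrom_idx)
  calls <- calls[ord, ]
  for (i in seq_len(nrow(calls))) {
    idx <- chrom_split[[calls$.chrom_idx[i]]]
    tg <- targets[idx, ]
    key <- paste(calls$.row[i], calls$.chrom_idx[i])
    if (key != fb_cache_key) {
      fb <- forward_backward(z[calls$.row[i], idx], target_gaps(tg), params)
      fb$log_init <- log(hmm_initial(params))
      fb_cache_key <- key
    }
    state <- match(calls$type[i], c("DIP", "DEL", "DUP"))
    lp_none <- log_prob_excluding_state(fb, calls$t_first[i], calls$t_last[i], state)
    q <- -10 * (lp_none - fb$loglik) / log(10)
    scored[[i]] <- tibble(
      q_some = as.integer(min(99, max(0, round(q)))),
      z_mean = mean(z[calls$.row[i], idx[calls$t_first[i]:calls$t_last[i]]])
    )
  }
  sc <- bind_rows(scored)
  out <- calls
  out$q_some <- sc$q_some
  out$z_mean <- sc$z_mean
  out$length_bp <- out$end - out$start
  out <- left_join(out, norm$samples, by = "sample")
  out %>%
    select("sample", "phenotype", "chrom", "start", "end", "type",
           "n_targets", "z_mean", "q_some", "length_bp") %>%
    arrange(.data$sample, .data$chrom, .data$start)
}
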