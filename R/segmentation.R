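#' Bernoulli log-likelihood of one segment
#'
#' For a segment of `m` positions containing `k` labels the maximized
#' Bernoulli log-likelihood is `k*log(k/m) + (m-k)*log(1-k/m)`, with the
#' `0*log(0) = 0` convention, so pure segments (rate 0 or 1) score 0.
#'
#' @param k label count, `0 <= k <= m`.
#' @param m segment length, `m >= 1`.
#' @return the segment log-likelihood (a non-positive real).
#' @export
segment_loglik <- function(k, m) {
  if (any(m < 1)) stop("segment length m must be >= 1")
  if (any(k < 0) || any(k > m)) stop("label count k must satisfy 0 <= k <= m")
  .seg_ll(k, m)
}

# vectorized, no validation
.seg_ll <- function(k, m) {
  r <- k / m
  out <- numeric(length(r))
  pos <- k > 0
  out[pos] <- k[pos] * log(r[pos])
  neg <- (m - k) > 0
  out[neg] <- out[neg] + (m - k)[neg] * log(1 - r[neg])
  out
}

.lse <- function(x) {
  mx <- max(x)
  if (!is.finite(mx)) return(-Inf)
  mx + log(sum(exp(x - mx)))
}

# information-criterion penalty term (the part added to -2*logLik) for a
# model with s segments on n positions; parameter count = s rates plus
# s-1 breakpoints = 2s - 1
.ic_penalty <- function(s, n, criterion) {
  kpar <- 2 * s - 1
  switch(criterion,
    BIC = kpar * log(n),
    AIC = 2 * kpar,
    AICc = {
      denom <- n - kpar - 1
      ifelse(denom > 0, 2 * kpar + 2 * kpar * (kpar + 1) / denom, Inf)
    },
    stop("criterion must be one of BIC, AIC, AICc"))
}

# weighted lower/upper quantile of a discrete distribution: the smallest
# value whose cumulative weight reaches q * total (small tolerance keeps
# the exhaustive and DP paths in bit-level agreement)
.wquant <- function(values, weights, probs, tol = 1e-9) {
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o])
  z <- cw[length(cw)]
  vapply(probs, function(q) v[which(cw >= q * z - tol * z)[1L]], numeric(1))
}

#' Enumerate all contiguous segmentation models of a 0/1 vector
#'
#' One model per composition of `n` positions into at most `max_segments`
#' contiguous segments (there are `2^(n-1)` in total), each with its
#' maximum-likelihood per-segment rates, log-likelihood, and information
#' criterion.  Exhaustive enumeration is restricted to `n <= 20`; longer
#' vectors must go through [dp_model_average()].
#'
#' @param labels 0/1 vector.
#' @param max_segments maximum number of segments.
#' @param criterion `"BIC"` (default), `"AIC"`, or `"AICc"`.
#' @return list of `segmentation_model` objects: `breakpoints` (positions
#'   after which a new segment starts; empty for the 1-segment model),
#'   `segment_rates`, `log_likelihood`, `ic_value`, `n_segments`.
#' @export
enumerate_models <- function(labels, max_segments = length(labels),
                             criterion = "BIC") {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n == 0) stop("labels must be nonempty")
  if (n > 20) stop("exhaustive enumeration is limited to n <= 20; ",
                   "use dp_model_average() for longer vectors")
  stopifnot(all(labels %in% c(0L, 1L)), max_segments >= 1)
  cs <- c(0L, cumsum(labels))
  models <- list()
  for (s in seq_len(min(max_segments, n))) {
    bps <- if (s == 1) matrix(integer(0), nrow = 0, ncol = 1) else
      utils::combn(n - 1L, s - 1L)
    for (j in seq_len(ncol(bps))) {
      bp <- bps[, j]
      starts <- c(1L, bp + 1L)
      ends <- c(bp, n)
      k <- cs[ends + 1L] - cs[starts]
      m <- ends - starts + 1L
      ll <- sum(.seg_ll(k, m))
      models[[length(models) + 1L]] <- structure(list(
        breakpoints = bp,
        segment_rates = k / m,
        log_likelihood = ll,
        ic_value = -2 * ll + .ic_penalty(s, n, criterion),
        n_segments = s
      ), class = "segmentation_model")
    }
  }
  models
}

.new_profile <- function(rate, lower, upper, criterion, model_count, method) {
  # the envelope always contains the model-averaged point estimate
  out <- data.frame(position = seq_along(rate), rate = rate,
                    lower95 = pmin(lower, rate), upper95 = pmax(upper, rate))
  attr(out, "criterion") <- criterion
  attr(out, "model_count") <- model_count
  attr(out, "method") <- method
  class(out) <- c("cluster_profile", "data.frame")
  out
}

#' Model-averaged clustering profile (exhaustive)
#'
#' Averages the per-position maximum-likelihood label rate over all
#' segmentation models, weighting model `i` by
#' `exp(-(IC_i - IC_min)/2)` (normalized).  The 95% envelope is the
#' weighted 2.5%/97.5% quantile of the per-position rate across models.
#' Models further than `prune_threshold` IC units from the best are dropped
#' only when their collective normalized weight is below 1e-8.
#'
#' @inheritParams enumerate_models
#' @param prune_threshold IC distance beyond which models may be pruned.
#' @return a `cluster_profile` data.frame: `position`, `rate`, `lower95`,
#'   `upper95`, with attributes `criterion`, `model_count`, `method`.
#' @export
model_average <- function(labels, criterion = "BIC",
                          max_segments = length(labels),
                          prune_threshold = 50) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n == 0) stop("labels must be nonempty")
  models <- enumerate_models(labels, max_segments, criterion)
  ic <- vapply(models, `[[`, numeric(1), "ic_value")
  delta <- ic - min(ic[is.finite(ic)])
  w <- exp(-delta / 2)
  w <- w / sum(w)
  drop <- delta > prune_threshold
  if (any(drop) && sum(w[drop]) < 1e-8) {
    models <- models[!drop]
    w <- w[!drop] / sum(w[!drop])
  }
  rates <- matrix(0, nrow = length(models), ncol = n)
  for (i in seq_along(models)) {
    mo <- models[[i]]
    seg_len <- diff(c(0L, mo$breakpoints, n))
    rates[i, ] <- rep(mo$segment_rates, seg_len)
  }
  rate <- as.numeric(crossprod(w, rates))
  qs <- apply(rates, 2, function(col) .wquant(col, w, c(0.025, 0.975)))
  .new_profile(rate, qs[1, ], qs[2, ], criterion, length(models),
               "exhaustive")
}

#' Model-averaged clustering profile (dynamic programming)
#'
#' Same contract as [model_average()] restricted to models with at most
#' `max_segments` segments, computed exactly by dynamic programming over
#' (position, segment count) with log-sum-exp accumulation, which scales to
#' chromosome-length vectors.  Per-position averaged rates are exact; the
#' 95% envelope is exact for `n <= 64` and computed on a 1024-bin rate grid
#' (resolution ~0.001) for longer vectors.
#'
#' @inheritParams enumerate_models
#' @param max_segments maximum number of segments (default 30).
#' @param .exact_envelope force the exact (`TRUE`) or binned (`FALSE`)
#'   envelope path; `NULL` (default) picks exact for `n <= 64`.  Intended
#'   for validation.
#' @return a `cluster_profile` (see [model_average()]).
#' @export
dp_model_average <- function(labels, criterion = "BIC", max_segments = 30L,
                             .exact_envelope = NULL) {
  labels <- as.integer(labels)
  n <- length(labels)
  if (n == 0) stop("labels must be nonempty")
  if (max_segments < 1) stop("max_segments must be >= 1")
  stopifnot(all(labels %in% c(0L, 1L)))
  S <- as.integer(min(max_segments, n))
  cs <- c(0, cumsum(labels))
  pen <- .ic_penalty(seq_len(S), n, criterion)

  # prefix DP: pre[j+1, s+1] = log sum of model likelihoods over partitions
  # of positions 1..j into s segments
  pre <- matrix(-Inf, n + 1L, S + 1L)
  pre[1L, 1L] <- 0
  for (j in seq_len(n)) {
    a <- seq_len(j)
    llcol <- .seg_ll(cs[j + 1L] - cs[a], j - a + 1)
    for (s in seq_len(min(S, j))) {
      pre[j + 1L, s + 1L] <- .lse(pre[a, s] + llcol)
    }
  }
  # suffix DP: suf[b, s+1] = partitions of positions b..n into s segments
  suf <- matrix(-Inf, n + 1L, S + 1L)
  suf[n + 1L, 1L] <- 0
  for (b in n:1) {
    e <- b:n
    llrow <- .seg_ll(cs[e + 1L] - cs[b], e - b + 1)
    for (s in seq_len(min(S, n - b + 1L))) {
      suf[b, s + 1L] <- .lse(llrow + suf[e + 1L, s])
    }
  }
  logZ <- .lse(pre[n + 1L, -1L] - pen / 2)

  # SP[b, s1+1] = lse over s2 of suf[b, s2+1] - pen(s1+s2+1)/2
  SP <- matrix(-Inf, n + 1L, S)
  for (s1 in 0:(S - 1L)) {
    s2 <- 0:(S - 1L - s1)
    block <- sweep(suf[, s2 + 1L, drop = FALSE], 2, pen[s1 + 1L + s2] / 2)
    SP[, s1 + 1L] <- apply(block, 1, .lse)
  }

  # rows of pre used for segment starts a: prefix length a-1, s1 = 0..S-1
  preA <- pre[seq_len(n), seq_len(S), drop = FALSE]
  ra <- apply(preA, 1, max)
  Pm <- exp(preA - ifelse(is.finite(ra), ra, 0))
  Pm[!is.finite(ra), ] <- 0

  exact <- .exact_envelope %||% (n <= 64L)   # exact needs a single chunk
  if (exact && n > 512L) stop("exact envelope requires n <= 512")
  n_bins <- 1024L
  if (exact) {
    Wfull <- NULL
    Rfull <- NULL
  } else {
    d1 <- matrix(0, n_bins, n)        # start-side scatter (by bin, col a)
    d2 <- matrix(0, n_bins, n + 1L)   # end-side scatter (by bin, col b+1)
  }
  dd <- numeric(n + 1L)               # difference array for the mean rate

  chunk <- 512L
  for (b0 in seq(1L, n, by = chunk)) {
    b1 <- min(n, b0 + chunk - 1L)
    bs <- b0:b1
    nb <- length(bs)
    # T(a, b) = lse_{s1} preA[a, s1] + SP[b+1, s1]
    SPb <- SP[bs + 1L, , drop = FALSE]
    qb <- apply(SPb, 1, max)
    Qm <- exp(SPb - ifelse(is.finite(qb), qb, 0))
    Qm[!is.finite(qb), ] <- 0
    Tm <- tcrossprod(Pm, Qm)                       # n x nb
    logT <- log(Tm) + outer(ifelse(is.finite(ra), ra, -Inf),
                            ifelse(is.finite(qb), qb, -Inf), `+`)
    # segment stats for a <= b
    amat <- matrix(seq_len(n), n, nb)
    bmat <- matrix(bs, n, nb, byrow = TRUE)
    valid <- amat <= bmat
    kmat <- matrix(cs[bs + 1L], n, nb, byrow = TRUE) - matrix(cs[seq_len(n)], n, nb)
    mmat <- bmat - amat + 1L
    llmat <- matrix(-Inf, n, nb)
    llmat[valid] <- .seg_ll(kmat[valid], mmat[valid])
    logW <- llmat + logT - logZ
    W <- exp(logW)
    W[!valid] <- 0
    ratemat <- matrix(0, n, nb)
    ratemat[valid] <- kmat[valid] / mmat[valid]

    val <- W * ratemat
    dd[seq_len(n)] <- dd[seq_len(n)] + rowSums(val)
    dd[bs + 1L] <- dd[bs + 1L] - colSums(val)

    if (exact) {
      Wfull <- W
      Rfull <- ratemat
    } else {
      binmat <- matrix(1L, n, nb)
      binmat[valid] <- 1L + as.integer(round(ratemat[valid] * (n_bins - 1L)))
      # start-side: key by (bin, a)
      ii <- which(valid & W > 0)
      if (length(ii)) {
        a_idx <- amat[ii]; b_idx <- bmat[ii]
        keys <- (binmat[ii] - 1L) * (n + 1L) + a_idx
        agg <- rowsum(W[ii], keys)
        kk <- as.integer(rownames(agg))
        d1[cbind((kk - 1L) %/% (n + 1L) + 1L, (kk - 1L) %% (n + 1L) + 1L)] <-
          d1[cbind((kk - 1L) %/% (n + 1L) + 1L, (kk - 1L) %% (n + 1L) + 1L)] +
          agg[, 1L]
        keys2 <- (binmat[ii] - 1L) * (n + 2L) + (b_idx + 1L)
        agg2 <- rowsum(W[ii], keys2)
        kk2 <- as.integer(rownames(agg2))
        idx2 <- cbind((kk2 - 1L) %/% (n + 2L) + 1L,
                      (kk2 - 1L) %% (n + 2L) + 1L)
        d2[idx2] <- d2[idx2] + agg2[, 1L]
      }
    }
  }

  rate <- cumsum(dd)[seq_len(n)]
  lower <- numeric(n)
  upper <- numeric(n)
  if (exact) {
    for (p in seq_len(n)) {
      w <- Wfull[seq_len(p), p:n, drop = FALSE]
      r <- Rfull[seq_len(p), p:n, drop = FALSE]
      qs <- .wquant(as.numeric(r), as.numeric(w), c(0.025, 0.975))
      lower[p] <- qs[1]
      upper[p] <- qs[2]
    }
  } else {
    diffm <- d1 - d2[, seq_len(n), drop = FALSE]
    M <- t(apply(diffm, 1, cumsum))      # bin x position cumulative over pos
    cw <- apply(M, 2, cumsum)            # cumulative over bins per position
    z <- cw[n_bins, ]
    grid <- (seq_len(n_bins) - 1) / (n_bins - 1)
    for (p in seq_len(n)) {
      lo_i <- which(cw[, p] >= 0.025 * z[p] - 1e-9 * z[p])[1L]
      hi_i <- which(cw[, p] >= 0.975 * z[p] - 1e-9 * z[p])[1L]
      lower[p] <- grid[lo_i]
      upper[p] <- grid[hi_i]
    }
  }
  rate <- pmin(1, pmax(0, rate))
  model_count <- sum(vapply(seq_len(S), function(s) choose(n - 1, s - 1),
                            numeric(1)))
  .new_profile(rate, lower, upper, criterion, model_count, "dp")
}
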