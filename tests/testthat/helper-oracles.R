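# Independent oracle implementations used to cross-check the package.
# Each is a deliberately naive re-derivation (loops, lm(), direct sums),
# kept separate from the implementation paths they verify.

oracle_block_means <- function(x, block) {
  nb <- length(x) %/% block
  vapply(seq_len(nb), function(i) mean(x[((i - 1) * block + 1):(i * block)]),
         numeric(1))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  num <- n * sum(x * y) - sx * sy
  den <- sqrt(n * sum(x^2) - sx^2) * sqrt(n * sum(y^2) - sy^2)
  num / den
}

# exhaustive two-segment split search with lm() per side
oracle_find_lla <- function(abp, ldf, grid = 1, min_pts = 3) {
  o <- order(abp); x <- abp[o]; y <- ldf[o]
  cand <- seq(ceiling(min(x)), floor(max(x)), by = grid)
  best <- NULL
  for (cpt in cand) {
    left <- x < cpt
    if (sum(left) < min_pts || sum(!left) < min_pts) next
    fl <- lm(y[left] ~ x[left])
    fr <- lm(y[!left] ~ x[!left])
    sse <- sum(resid(fl)^2) + sum(resid(fr)^2)
    if (is.null(best) || sse < best$sse - 1e-12)
      best <- list(sse = sse, cl = coef(fl), cr = coef(fr), cpt = cpt)
  }
  lla <- (best$cr[1] - best$cl[1]) / (best$cl[2] - best$cr[2])
  list(lla = unname(lla), sse = best$sse, breakpoint = best$cpt)
}

# weighted quadratic by explicit normal equations
oracle_quad_fit <- function(x, z, w) {
  X <- cbind(1, x, x^2)
  beta <- solve(t(X * w) %*% X, t(X * w) %*% z)
  list(a = beta[3], b = beta[2], c = beta[1],
       vertex = -beta[2] / (2 * beta[3]))
}

# Mann-Whitney concordance AUC
oracle_auc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]; neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# DeLong variance of the AUC difference by direct structural enumeration
oracle_delong_var <- function(sa, sb, labels) {
  labels <- as.logical(labels)
  pos <- which(labels); neg <- which(!labels)
  m <- length(pos); n <- length(neg)
  comp <- function(s) {
    v10 <- vapply(pos, function(i)
      mean((s[i] > s[neg]) + 0.5 * (s[i] == s[neg])), numeric(1))
    v01 <- vapply(neg, function(j)
      mean((s[pos] > s[j]) + 0.5 * (s[pos] == s[j])), numeric(1))
    list(v10 = v10, v01 = v01)
  }
  ca <- comp(sa); cb <- comp(sb)
  var(ca$v10 - cb$v10) / m + var(ca$v01 - cb$v01) / n
}

# continuous wavelet transform by direct summation (Torrence-Compo
# normalization, as in the package)
oracle_cwt_point <- function(x, dt, s, n0, omega0 = 6) {
  n <- length(x)
  xm <- x - mean(x)
  eta <- ((seq_len(n) - n0) * dt) / s
  psi <- pi^(-0.25) * exp(1i * omega0 * eta) * exp(-eta^2 / 2)
  sum(xm * Conj(psi)) * sqrt(dt / s)
}

# assemble a slow_waves_df from epoch vectors
make_sw <- function(...) {
  ch <- list(...)
  n <- length(ch[[1]])
  need <- c("abp", "icp", "rso2", "rthb", "ldf")
  for (nm in need) if (is.null(ch[[nm]])) ch[[nm]] <- rep(0, n)
  df <- data.frame(time_s = seq_len(n) * 10,
                   abp = ch$abp, icp = ch$icp, rso2 = ch$rso2,
                   rthb = ch$rthb, ldf = ch$ldf)
  attr(df, "epoch_s") <- 10
  class(df) <- c("slow_waves_df", "data.frame")
  df
}
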