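# Independent brute-force oracles. These deliberately re-derive every
# quantity with the most literal possible code (double loops, explicit
# enumeration) so they share nothing with the package implementation.

make_voi <- function(values, dim3, mask = NULL, spacing = c(1, 1, 1)) {
  img <- array(values, dim = dim3)
  if (is.null(mask)) mask <- array(TRUE, dim = dim3)
  voi(img, array(as.logical(mask), dim = dim3), spacing = spacing)
}

random_quantized_grid <- function(dims, n_levels, p_mask = 0.8) {
  q <- array(sample.int(n_levels, prod(dims), replace = TRUE), dim = dims)
  q[array(runif(prod(dims)) > p_mask, dim = dims)] <- NA_integer_
  q
}

# pair enumeration GLCM: symmetrized, normalized, summed over slices
oracle_glcm <- function(q, offset, n_levels) {
  cnt <- matrix(0, n_levels, n_levels)
  d <- dim(q)
  for (z in seq_len(d[3])) for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    i2 <- i + offset[1]; j2 <- j + offset[2]
    if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2]) next
    a <- q[i, j, z]; b <- q[i2, j2, z]
    if (is.na(a) || is.na(b)) next
    cnt[a, b] <- cnt[a, b] + 1
    cnt[b, a] <- cnt[b, a] + 1
  }
  cnt / sum(cnt)
}

# literal Haralick formulas, double loops
oracle_glcm_stats <- function(p) {
  L <- nrow(p)
  asm <- 0; con <- 0; idm <- 0; ent <- 0; dis <- 0; sos <- 0; cor_num <- 0
  px <- rowSums(p)
  mu <- 0
  for (i in 1:L) mu <- mu + i * px[i]
  sig2 <- 0
  for (i in 1:L) sig2 <- sig2 + (i - mu)^2 * px[i]
  psum <- rep(0, 2 * L); pdif <- rep(0, L)
  for (i in 1:L) for (j in 1:L) {
    v <- p[i, j]
    asm <- asm + v^2
    con <- con + (i - j)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    dis <- dis + abs(i - j) * v
    if (v > 0) ent <- ent - v * log(v)
    cor_num <- cor_num + i * j * v
    psum[i + j] <- psum[i + j] + v
    pdif[abs(i - j) + 1] <- pdif[abs(i - j) + 1] + v
  }
  sa <- 0
  for (k in 2:(2 * L)) sa <- sa + k * psum[k]
  sv <- 0
  for (k in 2:(2 * L)) sv <- sv + (k - sa)^2 * psum[k]
  se <- 0
  for (k in 2:(2 * L)) if (psum[k] > 0) se <- se - psum[k] * log(psum[k])
  da <- 0
  for (k in 0:(L - 1)) da <- da + k * pdif[k + 1]
  dv <- 0
  for (k in 0:(L - 1)) dv <- dv + (k - da)^2 * pdif[k + 1]
  de <- 0
  for (k in 0:(L - 1)) if (pdif[k + 1] > 0) de <- de - pdif[k + 1] * log(pdif[k + 1])
  cr <- if (sig2 > 0) (cor_num - mu^2) / sig2 else 0
  c(AngScMom = asm, Contrast = con, Correlat = cr, SumOfSqs = sig2,
    InvDfMom = idm, SumAverg = sa, SumVarnc = sv, SumEntrp = se,
    Entropy = ent, DifVarnc = dv, DifEntrp = de, Dissimlr = dis)
}

# explicit line-walking run scan for one direction
oracle_glrlm <- function(q, direction, n_levels) {
  d <- dim(q)
  step <- switch(direction,
                 "0" = c(0, 1), "90" = c(1, 0),
                 "45" = c(-1, 1), "135" = c(1, 1))
  cnt <- matrix(0, n_levels, max(d[1], d[2]))
  for (z in seq_len(d[3])) {
    starts <- list()
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
      pi_ <- i - step[1]; pj <- j - step[2]
      inside <- pi_ >= 1 && pi_ <= d[1] && pj >= 1 && pj <= d[2]
      if (!inside) starts[[length(starts) + 1]] <- c(i, j)
    }
    for (s in starts) {
      i <- s[1]; j <- s[2]
      cur <- NA_integer_; len <- 0
      while (i >= 1 && i <= d[1] && j >= 1 && j <= d[2]) {
        v <- q[i, j, z]
        if (!is.na(v) && !is.na(cur) && v == cur) {
          len <- len + 1
        } else {
          if (!is.na(cur)) cnt[cur, len] <- cnt[cur, len] + 1
          cur <- v; len <- if (is.na(v)) 0 else 1
        }
        i <- i + step[1]; j <- j + step[2]
      }
      if (!is.na(cur)) cnt[cur, len] <- cnt[cur, len] + 1
    }
  }
  cnt
}

# sort-and-interpolate quantile (linear interpolation between order stats)
oracle_quantile <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  if (lo >= n) return(s[n])
  s[lo] + (h - lo) * (s[lo + 1] - s[lo])
}

# exhaustive pair counting AUC with 1/2 for ties
oracle_auc <- function(scores, positive) {
  sp <- scores[positive]; sn <- scores[!positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
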