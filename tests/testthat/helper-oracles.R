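# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths (and, where possible, the libraries) they check.

# connected components of a logical matrix by queue-based flood fill
# (4-connectivity; planted objects are disjoint so connectivity convention
# does not change the count)
flood_fill_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  seen <- matrix(FALSE, nr, nc)
  ncomp <- 0L
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    ncomp <- ncomp + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      cur <- queue[length(queue)]
      queue <- queue[-length(queue)]
      r <- ((cur - 1L) %% nr) + 1L
      c <- ((cur - 1L) %/% nr) + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        rr <- r + d[1]; cc <- c + d[2]
        if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc) {
          idx <- rr + (cc - 1L) * nr
          if (mask[idx] && !seen[idx]) {
            seen[idx] <- TRUE
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  ncomp
}

# closed-form 2x2 Pearson chi-square: N(ad-bc)^2 / (r1 r2 c1 c2)
chi2_2x2_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# Kruskal-Wallis H with tie correction, from first principles
kw_oracle <- function(groups) {
  values <- unlist(groups)
  n <- length(values)
  r <- rank(values)
  gi <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) * sum(tapply(r, gi, sum)^2 / lengths(groups)) - 3 * (n + 1)
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n^3 - n))
}

# Mann-Whitney U by O(n*m) pair counting
u_oracle <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# Pearson r from the covariance formula
pearson_oracle <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# two-group log-rank chi-square from the risk-table definition
logrank_oracle <- function(time, event, group) {
  g <- as.integer(factor(group))
  o_minus_e <- 0; v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g == 1L)
    n_t <- sum(at_risk)
    n1 <- sum(at_risk & g == 1L)
    e1 <- d * n1 / n_t
    o_minus_e <- o_minus_e + (d1 - e1)
    if (n_t > 1) {
      v <- v + d * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d) / (n_t - 1)
    }
  }
  o_minus_e^2 / v
}

# Cox partial likelihood (no ties) maximized directly on a coefficient grid
cox_beta_oracle <- function(time, event, x) {
  logpl <- function(beta) {
    s <- 0
    for (i in which(event == 1)) {
      at_risk <- time >= time[i]
      s <- s + beta * x[i] - log(sum(exp(beta * x[at_risk])))
    }
    s
  }
  stats::optimize(logpl, c(-8, 8), maximum = TRUE, tol = 1e-10)$maximum
}

# shared small-field geometry for image tests: same physical field and
# object density as the reference acquisition, at 4x-binned resolution
small_field_params <- function(seed, ...) {
  image_sim_params(
    width_px = 640L, height_px = 480L, pixel_size_um = 0.44,
    seed = seed, ...
  )
}
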