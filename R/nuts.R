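# No-U-Turn sampler (dynamic Hamiltonian Monte Carlo) with dual-averaging
# step-size adaptation and diagonal mass-matrix estimation during warmup.
# `lp_grad(theta)` must return list(logp, grad). Used by fit_bmsr/fit_bmsmtr;
# generic over the target.

nuts_chain <- function(lp_grad, theta0, n_warmup, n_iter, seed,
                       max_treedepth = 10L, target_accept = 0.8,
                       delta_max = 1000) {
  set.seed(seed)
  P <- length(theta0)
  inv_mass <- rep(1, P)
  sqrt_mass <- rep(1, P)

  cur <- lp_grad(theta0)
  if (!is.finite(cur$logp)) stop_input("non-finite log-posterior at initial values")
  theta <- theta0

  leapfrog <- function(theta, r, grad, eps) {
    r1 <- r + 0.5 * eps * grad
    th1 <- theta + eps * inv_mass * r1
    lg <- lp_grad(th1)
    r1 <- r1 + 0.5 * eps * lg$grad
    list(theta = th1, r = r1, logp = lg$logp, grad = lg$grad)
  }
  joint <- function(logp, r) logp - 0.5 * sum(inv_mass * r * r)

  find_epsilon <- function(theta, state) {
    eps <- 0.1
    r <- rnorm(P) * sqrt_mass
    h0 <- joint(state$logp, r)
    st <- leapfrog(theta, r, state$grad, eps)
    h1 <- joint(st$logp, st$r)
    if (!is.finite(h1)) { # back off until the step is finite
      while (!is.finite(h1) && eps > 1e-10) {
        eps <- eps / 2
        st <- leapfrog(theta, r, state$grad, eps)
        h1 <- joint(st$logp, st$r)
      }
      return(eps)
    }
    a <- if (h1 - h0 > log(0.5)) 1 else -1
    while (a * (joint(st$logp, st$r) - h0) > -a * log(2)) {
      eps <- eps * 2^a
      if (eps > 1e7 || eps < 1e-10) break
      st <- leapfrog(theta, r, state$grad, eps)
      if (!is.finite(joint(st$logp, st$r))) { eps <- eps / 2; break }
    }
    eps
  }

  # recursive doubling with slice variable (Hoffman & Gelman, efficient NUTS)
  n_div <- 0L
  build_tree <- function(theta, r, grad, logu, v, j, eps, h0) {
    if (j == 0L) {
      st <- leapfrog(theta, r, grad, v * eps)
      h <- joint(st$logp, st$r)
      if (!is.finite(h)) h <- -Inf
      n_ok <- as.integer(logu <= h)
      s_ok <- as.integer(logu < h + delta_max)
      if (s_ok == 0L) n_div <<- n_div + 1L
      alpha <- min(1, exp(h - h0))
      list(minus = st, plus = st, prop = st, n = n_ok, s = s_ok,
           alpha = alpha, n_alpha = 1)
    } else {
      t1 <- build_tree(theta, r, grad, logu, v, j - 1L, eps, h0)
      if (t1$s == 1L) {
        if (v == -1) {
          t2 <- build_tree(t1$minus$theta, t1$minus$r, t1$minus$grad,
                           logu, v, j - 1L, eps, h0)
          t1$minus <- t2$minus
        } else {
          t2 <- build_tree(t1$plus$theta, t1$plus$r, t1$plus$grad,
                           logu, v, j - 1L, eps, h0)
          t1$plus <- t2$plus
        }
        if (t2$n > 0L && runif(1) < t2$n / max(t1$n + t2$n, 1L))
          t1$prop <- t2$prop
        dtheta <- t1$plus$theta - t1$minus$theta
        turn <- (sum(dtheta * (inv_mass * t1$minus$r)) >= 0) &&
                (sum(dtheta * (inv_mass * t1$plus$r)) >= 0)
        t1$s <- t2$s * as.integer(turn)
        t1$n <- t1$n + t2$n
        t1$alpha <- t1$alpha + t2$alpha
        t1$n_alpha <- t1$n_alpha + t2$n_alpha
      }
      t1
    }
  }

  eps <- find_epsilon(theta, cur)
  mu <- log(10 * eps)
  log_eps_bar <- 0; h_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75

  total <- n_warmup + n_iter
  draws <- matrix(NA_real_, n_iter, P)
  accept_stat <- numeric(n_iter)
  treedepth <- integer(n_iter)
  # warmup window used for mass estimation
  win_lo <- max(1L, floor(n_warmup * 0.25)); win_hi <- floor(n_warmup * 0.5)
  warm_buf <- matrix(NA_real_, max(win_hi - win_lo + 1L, 1L), P)
  adapt_count <- 0L

  for (it in seq_len(total)) {
    r0 <- rnorm(P) * sqrt_mass
    h0 <- joint(cur$logp, r0)
    logu <- h0 + log(runif(1))
    minus <- list(theta = theta, r = r0, logp = cur$logp, grad = cur$grad)
    plus <- minus
    prop <- minus
    j <- 0L; n <- 1L; s <- 1L
    alpha_sum <- 0; n_alpha <- 0
    while (s == 1L && j < max_treedepth) {
      v <- if (runif(1) < 0.5) -1 else 1
      if (v == -1) {
        t2 <- build_tree(minus$theta, minus$r, minus$grad, logu, v, j, eps, h0)
        minus <- t2$minus
      } else {
        t2 <- build_tree(plus$theta, plus$r, plus$grad, logu, v, j, eps, h0)
        plus <- t2$plus
      }
      if (t2$s == 1L && runif(1) < t2$n / max(n, 1L)) prop <- t2$prop
      n <- n + t2$n
      dtheta <- plus$theta - minus$theta
      turn <- (sum(dtheta * (inv_mass * minus$r)) >= 0) &&
              (sum(dtheta * (inv_mass * plus$r)) >= 0)
      s <- t2$s * as.integer(turn)
      alpha_sum <- alpha_sum + t2$alpha
      n_alpha <- n_alpha + t2$n_alpha
      j <- j + 1L
    }
    theta <- prop$theta
    cur <- list(logp = prop$logp, grad = prop$grad)
    a_stat <- if (n_alpha > 0) alpha_sum / n_alpha else 0

    if (it <= n_warmup) {
      adapt_count <- adapt_count + 1L
      frac <- 1 / (adapt_count + t0)
      h_bar <- (1 - frac) * h_bar + frac * (target_accept - a_stat)
      log_eps <- mu - sqrt(adapt_count) / gamma * h_bar
      eta <- adapt_count^(-kappa)
      log_eps_bar <- eta * log_eps + (1 - eta) * log_eps_bar
      eps <- exp(log_eps)
      if (it >= win_lo && it <= win_hi) warm_buf[it - win_lo + 1L, ] <- theta
      if (it == win_hi && win_hi > win_lo + 10L) {
        v <- apply(warm_buf[seq_len(win_hi - win_lo + 1L), , drop = FALSE], 2L, var)
        v[!is.finite(v) | v <= 0] <- 1
        inv_mass <- v
        sqrt_mass <- 1 / sqrt(v)
        # restart step-size adaptation under the new metric
        cur <- lp_grad(theta)
        eps <- find_epsilon(theta, cur)
        mu <- log(10 * eps)
        log_eps_bar <- 0; h_bar <- 0; adapt_count <- 0L
      }
      if (it == n_warmup) eps <- exp(log_eps_bar)
    } else {
      k <- it - n_warmup
      draws[k, ] <- theta
      accept_stat[k] <- a_stat
      treedepth[k] <- j
    }
  }
  list(draws = draws, accept_stat = accept_stat, treedepth = treedepth,
       n_divergent = n_div, step_size = eps, inv_mass = inv_mass)
}

# Split-Rhat (potential scale reduction on split chains) for a draws matrix
# of shape (iterations x chains).
split_rhat <- function(x) {
  n <- nrow(x)
  if (n < 4L) return(NA_real_)
  half <- floor(n / 2)
  sub <- cbind(x[seq_len(half), , drop = FALSE],
               x[(n - half + 1):n, , drop = FALSE])
  m <- ncol(sub)
  means <- colMeans(sub)
  vars <- apply(sub, 2L, var)
  w <- mean(vars)
  b <- half * var(means)
  if (w <= 0) return(NA_real_)
  sqrt(((half - 1) / half * w + b / half) / w)
}

# Effective sample size via Geyer's initial positive sequence, pooled over
# chains (x: iterations x chains).
ess_basic <- function(x) {
  n <- nrow(x); m <- ncol(x)
  if (n < 4L) return(NA_real_)
  acov <- sapply(seq_len(m), function(j) {
    v <- x[, j] - mean(x[, j])
    a <- stats::acf(v, lag.max = min(n - 1L, 200L), plot = FALSE,
                    demean = FALSE)$acf[, 1, 1]
    a * sum(v^2) / n
  })
  acov <- rowMeans(acov)
  var0 <- acov[1] * n / (n - 1)
  if (var0 <= 0) return(NA_real_)
  rho <- acov / var0
  # sum consecutive pairs while positive
  ess_sum <- rho[1]
  k <- 2L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (!is.finite(pair) || pair <= 0) break
    ess_sum <- ess_sum + 2 * pair
    k <- k + 2L
  }
  max(1, m * n / max(ess_sum, 1e-12))
}
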