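# Straight-loop reference implementation of the fixed-point updates and the
# information accounting: explicit sums over every index, no vectorization,
# transcribed directly from the update equations. Only usable on small tasks.

oracle_solve <- function(task, beta1, beta2, max_iter = 2000, tol = 1e-12,
                         eps = 0.01) {
  M <- task$n_s1; nA <- task$n_a; nS2 <- task$n_s2; nW <- task$n_w
  U <- utility_matrix(task)
  ps1 <- task$p_s1
  ps2 <- task$p_s2_given_s1

  P1 <- matrix(eps / (M - 1), M, M); diag(P1) <- 1 - eps
  pm <- numeric(M)
  for (m in 1:M) for (i in 1:M) pm[m] <- pm[m] + ps1[i] * P1[m, i]
  PA <- array(1 / nA, c(nA, M, nS2))
  pa <- rep(1 / nA, nA)

  for (it in 1:max_iter) {
    d <- 0
    ## p(w | m, s2) by marginalizing the joint over s1
    Q <- array(0, c(nW, M, nS2))
    for (k in 1:nS2) {
      pri <- numeric(nW)
      for (i in 1:M) if (ps2[i, k] > 0) {
        w <- task$w_of[i, k]
        pri[w] <- pri[w] + ps1[i] * ps2[i, k]
      }
      pri <- pri / sum(pri)
      for (m in 1:M) {
        num <- numeric(nW)
        for (i in 1:M) if (ps2[i, k] > 0) {
          w <- task$w_of[i, k]
          num[w] <- num[w] + ps1[i] * ps2[i, k] * P1[m, i]
        }
        z <- sum(num)
        Q[, m, k] <- if (z > 0) num / z else pri
      }
    }
    ## p(a | m, s2) softmax of log p(a) + beta2 sum_w p(w|m,s2) U(w,a)
    for (k in 1:nS2) for (m in 1:M) {
      lg <- numeric(nA)
      for (a in 1:nA) {
        ev <- 0
        for (w in 1:nW) ev <- ev + Q[w, m, k] * U[w, a]
        lg[a] <- log(pa[a]) + beta2 * ev
      }
      newp <- exp(lg - max(lg)); newp <- newp / sum(newp)
      d <- max(d, max(abs(newp - PA[, m, k])))
      PA[, m, k] <- newp
    }
    ## p(a) marginal
    pa_new <- numeric(nA)
    for (a in 1:nA) for (k in 1:nS2) for (m in 1:M) for (i in 1:M)
      pa_new[a] <- pa_new[a] +
        PA[a, m, k] * P1[m, i] * ps2[i, k] * ps1[i]
    pa_new <- pa_new / sum(pa_new)
    d <- max(d, max(abs(pa_new - pa)))
    pa <- pa_new
    ## Delta F(m, s1) and memory channel
    DF <- matrix(0, M, M)
    for (m in 1:M) for (i in 1:M) {
      v <- 0
      for (k in 1:nS2) if (ps2[i, k] > 0) {
        w <- task$w_of[i, k]
        hit <- 0; kl <- 0
        for (a in 1:nA) {
          hit <- hit + PA[a, m, k] * U[w, a]
          kl <- kl + PA[a, m, k] * log(PA[a, m, k] / pa[a])
        }
        v <- v + ps2[i, k] * (hit - kl / beta2)
      }
      DF[m, i] <- v
    }
    for (i in 1:M) {
      lg <- log(pm) + beta1 * DF[, i]
      newp <- exp(lg - max(lg)); newp <- newp / sum(newp)
      d <- max(d, max(abs(newp - P1[, i])))
      P1[, i] <- newp
    }
    pm_new <- numeric(M)
    for (m in 1:M) for (i in 1:M) pm_new[m] <- pm_new[m] + ps1[i] * P1[m, i]
    d <- max(d, max(abs(pm_new - pm)))
    pm <- pm_new
    if (d < tol) break
  }
  list(P1 = P1, pm = pm, PA = PA, pa = pa, n_iter = it)
}

oracle_information <- function(task, P1, pm, PA, pa) {
  M <- task$n_s1; nA <- task$n_a; nS2 <- task$n_s2; nW <- task$n_w
  U <- utility_matrix(task)
  ps1 <- task$p_s1; ps2 <- task$p_s2_given_s1
  n_c <- task$n_conditions
  ln2 <- log(2)

  ## p(s2 | m) and p(a | m)
  pms2 <- matrix(0, M, nS2)
  for (m in 1:M) for (k in 1:nS2) for (i in 1:M)
    pms2[m, k] <- pms2[m, k] + ps1[i] * ps2[i, k] * P1[m, i]
  pam <- matrix(0, nA, M)
  for (m in 1:M) {
    for (k in 1:nS2) for (a in 1:nA)
      pam[a, m] <- pam[a, m] + (pms2[m, k] / pm[m]) * PA[a, m, k]
  }

  I1 <- numeric(n_c); I2H0 <- numeric(n_c); I2H1 <- numeric(n_c)
  for (ci in 1:n_c) {
    ss <- which(task$s1_condition == ci)
    Nc <- length(ss)
    for (i in ss) {
      for (m in 1:M) {
        if (P1[m, i] > 0)
          I1[ci] <- I1[ci] + (1 / Nc) * P1[m, i] * log(P1[m, i] / pm[m])
        klm <- 0
        for (a in 1:nA) if (pam[a, m] > 0)
          klm <- klm + pam[a, m] * log(pam[a, m] / pa[a])
        I2H0[ci] <- I2H0[ci] + (1 / Nc) * P1[m, i] * klm
        for (k in 1:nS2) if (ps2[i, k] > 0) {
          kl <- 0
          for (a in 1:nA) if (PA[a, m, k] > 0)
            kl <- kl + PA[a, m, k] * log(PA[a, m, k] / pa[a])
          I2H1[ci] <- I2H1[ci] + (1 / Nc) * P1[m, i] * ps2[i, k] * kl
        }
      }
    }
  }
  I2H1 <- I2H1 * nts_multiplier(task$conditions$cT)

  eu <- 0
  for (i in 1:M) for (k in 1:nS2) if (ps2[i, k] > 0) {
    w <- task$w_of[i, k]
    for (m in 1:M) for (a in 1:nA)
      eu <- eu + ps1[i] * ps2[i, k] * P1[m, i] * PA[a, m, k] * U[w, a]
  }

  ## global mutual informations from the joint
  I_ms1 <- 0
  for (i in 1:M) for (m in 1:M) if (P1[m, i] > 0)
    I_ms1 <- I_ms1 + ps1[i] * P1[m, i] * log(P1[m, i] / pm[m])
  I_am <- 0
  for (m in 1:M) for (a in 1:nA) if (pam[a, m] > 0)
    I_am <- I_am + pm[m] * pam[a, m] * log(pam[a, m] / pa[a])
  I_ams2 <- 0
  for (m in 1:M) for (k in 1:nS2) for (a in 1:nA) if (PA[a, m, k] > 0)
    I_ams2 <- I_ams2 + pms2[m, k] * PA[a, m, k] * log(PA[a, m, k] / pa[a])

  list(I1 = I1 / ln2, I2H0 = I2H0 / ln2, I2H1 = I2H1 / ln2, EU = eu,
       I_M_S1 = I_ms1 / ln2, I_A_M = I_am / ln2, I_A_MS2 = I_ams2 / ln2)
}
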