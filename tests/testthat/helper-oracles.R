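# Independent reference implementations used as oracles. Deliberately naive
# and written from the definitions, not from the package code paths.

# O(n^3) UPGMA: returns merge heights in order and the cophenetic matrix,
# which together determine the dendrogram.
naive_upgma <- function(dmat) {
  dmat <- as.matrix(dmat)
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  active <- rep(TRUE, length(clusters))
  d <- dmat
  heights <- numeric(0)
  coph <- matrix(0, n, n)
  while (sum(active) > 1L) {
    idx <- which(active)
    best <- c(NA, NA); best_d <- Inf
    for (a in idx) for (b in idx) if (a < b && d[a, b] < best_d) {
      best <- c(a, b); best_d <- d[a, b]
    }
    a <- best[1]; b <- best[2]
    heights <- c(heights, best_d)
    coph[clusters[[a]], clusters[[b]]] <- best_d
    coph[clusters[[b]], clusters[[a]]] <- best_d
    na <- length(clusters[[a]]); nb <- length(clusters[[b]])
    merged <- c(clusters[[a]], clusters[[b]])
    clusters[[length(clusters) + 1L]] <- merged
    d <- rbind(cbind(d, 0), 0)
    for (k in which(active)) {
      if (k == a || k == b) next
      d[length(clusters), k] <- d[k, length(clusters)] <-
        (na * d[a, k] + nb * d[b, k]) / (na + nb)
    }
    active[c(a, b)] <- FALSE
    active <- c(active, TRUE)
  }
  list(heights = heights, cophenetic = coph)
}

# ARI straight from the contingency-table formula
naive_ari <- function(p1, p2) {
  tab <- table(p1, p2)
  n <- sum(tab)
  ch2 <- function(v) sum(choose(v, 2))
  e <- ch2(rowSums(tab)) * ch2(colSums(tab)) / choose(n, 2)
  (ch2(as.vector(tab)) - e) / ((ch2(rowSums(tab)) + ch2(colSums(tab))) / 2 - e)
}

# hand product-limit estimate at each death time
naive_km <- function(time, event) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]
  times <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = times, survival = NA_real_)
  for (i in seq_along(times)) {
    at_risk <- sum(time >= times[i])
    deaths <- sum(time == times[i] & event == 1)
    s <- s * (1 - deaths / at_risk)
    out$survival[i] <- s
  }
  out
}

# brute-force k-group log-rank: accumulate observed minus expected events
# (and the hypergeometric variance) over pooled event times
naive_logrank <- function(time, event, group) {
  group <- as.factor(group)
  levs <- levels(group)
  k <- length(levs)
  times <- sort(unique(time[event == 1]))
  O <- E <- rep(0, k)
  V <- matrix(0, k, k)
  for (t in times) {
    n_t <- sum(time >= t)
    d_t <- sum(time == t & event == 1)
    for (i in seq_len(k)) {
      n_it <- sum(time >= t & group == levs[i])
      O[i] <- O[i] + sum(time == t & event == 1 & group == levs[i])
      E[i] <- E[i] + d_t * n_it / n_t
    }
    for (i in seq_len(k)) for (j in seq_len(k)) {
      n_it <- sum(time >= t & group == levs[i])
      n_jt <- sum(time >= t & group == levs[j])
      delta <- as.numeric(i == j)
      if (n_t > 1)
        V[i, j] <- V[i, j] + d_t * (n_it / n_t) * (delta - n_jt / n_t) *
          (n_t - d_t) / (n_t - 1)
    }
  }
  u <- (O - E)[-1]
  stat <- as.numeric(t(u) %*% solve(V[-1, -1]) %*% u)
  list(statistic = stat, df = k - 1,
       p_value = pchisq(stat, k - 1, lower.tail = FALSE))
}

# SAM d from the definition, gene by gene
naive_sam_d <- function(x1, x2, s0) {
  m1 <- mean(x1); m2 <- mean(x2)
  n1 <- length(x1); n2 <- length(x2)
  si <- sqrt((1 / n1 + 1 / n2) *
               (sum((x1 - m1)^2) + sum((x2 - m2)^2)) / (n1 + n2 - 2))
  (m1 - m2) / (si + s0)
}

# small labeled matrix with three perfectly separated groups
tiny_grouped_matrix <- function(n_per = 5L, n_genes = 6L, shift = 10,
                                noise = 0, seed = 42L) {
  set.seed(seed)
  groups <- rep(c("A", "B", "C"), each = n_per)
  n <- length(groups)
  m <- matrix(rnorm(n * n_genes, sd = max(noise, 1e-12)), n, n_genes)
  m[groups == "B", 1:2] <- m[groups == "B", 1:2] + shift
  m[groups == "C", 3:4] <- m[groups == "C", 3:4] + shift
  rownames(m) <- sprintf("s%02d", seq_len(n))
  colnames(m) <- sprintf("g%d", seq_len(n_genes))
  list(x = expression_matrix(m),
       labels = setNames(groups, rownames(m)))
}
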