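# Independent oracle implementations used across tests. These deliberately
# avoid the package's code paths: brute-force or textbook constructions only.

# small, fast cohort configuration for structural tests
small_config <- function(...) {
  cohort_config(
    group_sizes = c("AD+sLATE-" = 40, "AD+sLATE+" = 20,
                    "AD-sLATE+" = 10, "Abeta-CU" = 40),
    visit_schedule = 0:3, ...)
}

# configuration with cleanly separated HV clusters whose low fraction matches
# the quartile geometry (25% of the amyloid-positive sample)
separated_config <- function() {
  cohort_config(
    group_sizes = c("AD+sLATE-" = 150, "AD+sLATE+" = 50,
                    "AD-sLATE+" = 20, "Abeta-CU" = 100),
    hv_group_means = c("AD+sLATE-" = 3250, "AD+sLATE+" = 2150,
                       "AD-sLATE+" = 2100, "Abeta-CU" = 3300),
    hv_group_sds = c("AD+sLATE-" = 80, "AD+sLATE+" = 80,
                     "AD-sLATE+" = 80, "Abeta-CU" = 120),
    visit_schedule = 0:2)
}

# brute-force TFCE: explicit per-threshold connected-component labelling on
# an edge list, O(K * n^2); signed maps handled by running both polarities
tfce_oracle <- function(values, edges, E, H, dh) {
  n <- length(values)
  one_sided <- function(v) {
    out <- numeric(n)
    vmax <- max(v)
    if (vmax < dh) return(out)
    for (h in seq(dh, vmax + 1e-12, by = dh)) {
      active <- which(v >= h - 1e-12)
      if (!length(active)) break
      comp <- seq_len(n)  # label propagation restricted to active set
      repeat {
        changed <- FALSE
        if (nrow(edges)) for (e in seq_len(nrow(edges))) {
          a <- edges[e, 1]; b <- edges[e, 2]
          if (a %in% active && b %in% active && comp[a] != comp[b]) {
            m <- min(comp[a], comp[b]); comp[a] <- m; comp[b] <- m
            changed <- TRUE
          }
        }
        if (!changed) break
      }
      for (vtx in active) {
        size <- sum(comp[active] == comp[vtx])
        out[vtx] <- out[vtx] + size^E * h^H * dh
      }
    }
    out
  }
  one_sided(pmax(values, 0)) - one_sided(pmax(-values, 0))
}

# exhaustive two-sided Fisher p by probability-mass ordering over the
# central hypergeometric distribution (fisher.test's tie tolerance)
fisher_p_oracle <- function(a, b, c_, d) {
  m <- a + b; n <- c_ + d; k <- a + c_
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# classic pooled-variance two-sample t statistic (group2 - group1)
pooled_t_oracle <- function(y, g) {
  y1 <- y[g == levels(factor(g))[1]]
  y2 <- y[g != levels(factor(g))[1]]
  sp2 <- (sum((y1 - mean(y1))^2) + sum((y2 - mean(y2))^2)) /
    (length(y1) + length(y2) - 2)
  (mean(y2) - mean(y1)) / sqrt(sp2 * (1 / length(y1) + 1 / length(y2)))
}

# independent linear-interpolation quantile (order-statistic formula
# h = (n - 1) p + 1), written without stats::quantile
quantile_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# rank-based brute-force group classifier: strict bottom quartile / strict
# top half of the amyloid-positive CI reference distribution
assign_oracle <- function(adj, abeta, impaired) {
  ref <- adj[impaired & abeta]
  q25 <- quantile_oracle(ref, 0.25)
  q50 <- quantile_oracle(ref, 0.50)
  out <- rep("UNCLASSIFIED", length(adj))
  out[impaired & abeta & adj < q25] <- "AD+sLATE+"
  out[impaired & abeta & adj > q50] <- "AD+sLATE-"
  out[impaired & abeta & adj >= q25 & adj <= q50] <- "EXCLUDED_Q2"
  out[impaired & !abeta & adj < q25] <- "AD-sLATE+"
  out[!impaired & !abeta] <- "Abeta-CU"
  out
}

# breadth-first search connectivity check on an edge list
bfs_connected <- function(n, edges) {
  if (n == 1) return(TRUE)
  adj <- vector("list", n)
  for (e in seq_len(nrow(edges))) {
    a <- edges[e, 1]; b <- edges[e, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  all(seen)
}

# all-pairs concordance AUC with midrank tie handling
auc_oracle <- function(scores, labels) {
  pos <- -scores[labels]   # higher = more suspect
  neg <- -scores[!labels]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}
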