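# Exhaustive individual-history likelihood, independent of the m-array route.
#
# For a newly marked individual released at its first detection t with
# transience probability tau, the history probability is
#   tau * [no detections after t] + (1 - tau) * P_resident
# where P_resident marginalizes over the last occasion alive L:
#   P(L) = prod(phi[t..L-1]) * (1 - phi[L]) (or survives to K),
#   P(detections | L) = prod over j in (t, L] of p[j]^h[j] (1-p[j])^(1-h[j]),
#   zero if any detection falls after L.
oracle_history_prob <- function(h, t, phi, p, tau) {
  K <- length(h)
  det_after <- which(h == 1L)
  det_after <- det_after[det_after > t]
  p_res <- 0
  for (L in t:K) {
    if (length(det_after) > 0 && max(det_after) > L) next
    p_surv <- if (L > t) prod(phi[t:(L - 1L)]) else 1
    p_die <- if (L < K) (1 - phi[L]) else 1
    p_det <- 1
    if (L > t) {
      for (j in (t + 1L):L) {
        p_det <- p_det * if (h[j] == 1L) p[j] else (1 - p[j])
      }
    }
    p_res <- p_res + p_surv * p_die * p_det
  }
  tau * as.numeric(length(det_after) == 0) + (1 - tau) * p_res
}

# dataset-level negative log-likelihood by brute force
oracle_nll <- function(data, phi, p, tau_by_group) {
  H <- history_matrix(data)
  K <- ncol(H)
  phi <- rep_len(phi, K - 1L)
  p <- rep_len(p, K)
  nll <- 0
  for (i in seq_len(nrow(H))) {
    t <- which(H[i, ] == 1L)[1L]
    tau <- if (t <= K - 1L) tau_by_group[[as.character(data$group[i])]] else 0
    nll <- nll - log(oracle_history_prob(H[i, ], t, phi, p, tau))
  }
  nll
}

# random tiny dataset for property sweeps (every history has >= 1 detection)
random_tiny_data <- function(K, n, groups = c("3", "5")) {
  H <- matrix(0L, n, K)
  for (i in seq_len(n)) {
    while (sum(H[i, ]) == 0) H[i, ] <- rbinom(K, 1L, 0.5)
  }
  encounter_data(H, group = sample(groups, n, replace = TRUE))
}

# theta on the link scale for a constant phi/p, per-group tau model
# (tau formula ~ 0 + group so coefficients are per-group logits)
theta_for <- function(phi, p, tau_by_group,
                      groups = c("3", "4", "5", "6", "7plus")) {
  c(qlogis(phi), qlogis(p), qlogis(unlist(tau_by_group)[groups]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
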