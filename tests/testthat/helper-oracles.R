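# Brute-force nested-loop reference implementations of the connectivity
# indices, kept deliberately naive and independent of the package's
# vectorized code paths.

sample_z <- function(x) (x - mean(x)) / sd(x)

oracle_ci <- function(land, A, alpha = 1) {
  P <- nrow(land$patches); Tn <- ncol(A)
  out <- matrix(0, P, Tn)
  for (i in seq_len(P)) for (t in seq_len(Tn)) {
    s <- 0
    for (j in seq_len(P)) {
      if (j != i && !is.na(A[j, t]))
        s <- s + exp(-alpha * land$d_pp[i, j]) * A[j, t]
    }
    out[i, t] <- s
  }
  out
}

oracle_inner <- function(land, A, alpha = 1) {
  H <- nrow(land$hilltops); Tn <- ncol(A)
  out <- matrix(0, H, Tn)
  for (j in seq_len(H)) for (t in seq_len(Tn)) {
    s <- 0
    for (k in seq_len(nrow(land$patches))) {
      if (!is.na(A[k, t]))
        s <- s + exp(-alpha * land$d_ph[k, j]) * A[k, t]
    }
    out[j, t] <- s
  }
  out
}

oracle_hci <- function(land, A, alpha = 1) {
  inner <- oracle_inner(land, A, alpha)
  z <- matrix(sample_z(as.vector(inner)), nrow(inner), ncol(inner))
  P <- nrow(land$patches); Tn <- ncol(A)
  out <- matrix(0, P, Tn)
  for (i in seq_len(P)) for (t in seq_len(Tn)) {
    s <- 0
    for (j in seq_len(nrow(land$hilltops)))
      s <- s + exp(-alpha * land$d_ph[i, j]) * z[j, t]
    out[i, t] <- s
  }
  out
}

oracle_eci <- function(land, A, alpha = 1, coefs = moth_pred_coefs(),
                       off = 1) {
  inner <- oracle_inner(land, A, alpha)
  z <- matrix(sample_z(log(as.vector(inner) + off)),
              nrow(inner), ncol(inner))
  P <- nrow(land$patches); Tn <- ncol(A)
  out <- matrix(0, P, Tn)
  for (i in seq_len(P)) for (t in seq_len(Tn)) {
    s <- 0
    for (j in seq_len(nrow(land$hilltops))) {
      m <- coefs$intercept + coefs$slope_ci * z[j, t] +
        coefs$slope_elev * land$hilltops$elevation_m[j]
      s <- s + exp(-alpha * land$d_ph[i, j]) * m
    }
    out[i, t] <- s
  }
  out
}

oracle_exposure <- function(land, counts, alpha = 1, off = 1) {
  P <- nrow(land$patches); Tn <- ncol(counts)
  out <- matrix(NA_real_, P, Tn)
  for (i in seq_len(P)) for (t in seq_len(Tn)) {
    s <- 0; any_obs <- FALSE
    for (j in seq_len(nrow(land$hilltops))) {
      if (!is.na(counts[j, t])) {
        any_obs <- TRUE
        s <- s + exp(-alpha * land$d_ph[i, j]) * log(counts[j, t] + off)
      }
    }
    if (any_obs) out[i, t] <- s
  }
  out
}
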