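# independent oracles, coded from the model definition and standard
# numerical formulas, never through the package's network compiler

# derivatives of the one-unit TL_TL network, written out longhand
oracle_rhs_one_unit <- function(state, g, kf_tx, kr_tx, kf_rbs, kr_rbs,
                                kf_nuc, kr_nuc, k_deg, k_mat, L, l,
                                b, k_toxin, thr) {
  s <- as.list(state)
  ntp_sat <- max(s$NTP, 0) / (g[["K_NTP"]] + max(s$NTP, 0))
  aa_sat <- max(s$AA, 0) / (g[["K_AA"]] + max(s$AA, 0))
  v_bind_tx <- kf_tx * s$DNA_gene * s$RNAP_T7
  v_unbind_tx <- kr_tx * s$Ctx_gene
  v_tx <- (g[["k_tx_elong"]] / L) * s$Ctx_gene * ntp_sat
  v_bind_tl <- kf_rbs * s$mRNA_gene * s$Ribo
  v_unbind_tl <- kr_rbs * s$Ctl_gene
  v_tl <- (g[["k_tl_elong"]] / l) * s$Ctl_gene * aa_sat
  v_bind_nuc <- kf_nuc * s$mRNA_gene * s$RNase
  v_unbind_nuc <- kr_nuc * s$Cdeg_gene
  v_deg <- k_deg * s$Cdeg_gene
  v_mat <- k_mat * s$P_gene
  gate <- 1 + tanh(s$toxin - thr)
  v_tox_deg <- k_toxin * gate * s$Ribo
  c(RNAP_native = 0,
    RNAP_T7 = -v_bind_tx + v_unbind_tx + v_tx,
    Ribo = -v_bind_tl + v_unbind_tl + v_tl - v_tox_deg,
    RNase = -v_bind_nuc + v_unbind_nuc + v_deg,
    NTP = -L * v_tx,
    AA = -l * v_tl,
    toxin = v_tl - b,
    DNA_gene = -v_bind_tx + v_unbind_tx + v_tx,
    Ctx_gene = v_bind_tx - v_unbind_tx - v_tx,
    mRNA_gene = v_tx - v_bind_tl + v_unbind_tl + v_tl - v_bind_nuc + v_unbind_nuc,
    Ctl_gene = v_bind_tl - v_unbind_tl - v_tl,
    Cdeg_gene = v_bind_nuc - v_unbind_nuc - v_deg,
    P_gene = v_tl - v_mat,
    F_gene = v_mat)
}

# classic fixed-step RK4 on an arbitrary derivative function
rk4_integrate <- function(deriv, y0, times, h) {
  y <- y0
  out <- matrix(NA_real_, length(times), length(y0),
                dimnames = list(NULL, names(y0)))
  t <- times[1]
  out[1, ] <- y
  for (i in 2:length(times)) {
    while (t < times[i] - 1e-9) {
      step <- min(h, times[i] - t)
      k1 <- deriv(y)
      k2 <- deriv(y + step / 2 * k1)
      k3 <- deriv(y + step / 2 * k2)
      k4 <- deriv(y + step * k3)
      y <- y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + step
    }
    out[i, ] <- y
  }
  out
}

# Spearman rank correlation via explicit sorting (average ranks for ties)
oracle_spearman <- function(a, b) {
  avg_rank <- function(v) {
    o <- order(v)
    r <- numeric(length(v))
    r[o] <- seq_along(v)
    for (val in unique(v)) r[v == val] <- mean(r[v == val])
    r
  }
  ra <- avg_rank(a); rb <- avg_rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}

# PRCC via inversion of the full rank correlation matrix:
# prcc_ij = -P_ij / sqrt(P_ii P_jj) with P the precision matrix of
# ranks of [x_1..x_p, y]
oracle_prcc <- function(X, y) {
  R <- apply(cbind(X, y), 2, rank)
  C <- stats::cor(R)
  P <- solve(C)
  p <- ncol(X)
  vapply(seq_len(p), function(j) {
    -P[j, p + 1] / sqrt(P[j, j] * P[p + 1, p + 1])
  }, numeric(1))
}
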