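# Independent statistical oracles used to validate the package's own
# implementations.

# Mann-Whitney two-sided p by brute-force enumeration of all C(n, na)
# group assignments of the pooled sample.
brute_mw_p <- function(a, b) {
  pool <- c(a, b)
  na <- length(a)
  rk <- rank(pool)
  mu <- na * length(b) / 2
  u_of <- function(ix) sum(rk[ix]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  us <- apply(utils::combn(length(pool), na), 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Fisher two-sided p by exhaustive enumeration over all 2x2 tables with
# the observed margins, probabilities from binomial coefficients directly.
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(r1, c1)
  logp <- lchoose(r1, support) + lchoose(r2, c1 - support) - lchoose(n, c1)
  p_obs <- logp[support == tab[1, 1]]
  sum(exp(logp[logp <= p_obs + 1e-7]))
}

# One synthetic null-model replicate: null fields, multipoint sampling,
# Mann-Whitney on normalized pressure, divergence-center detection and
# Fisher test. Cached because two test files assess different aspects of
# the same 200-replicate calibration.
null_calibration <- local({
  cache <- NULL
  function(n_seeds = 200) {
    if (!is.null(cache) && nrow(cache) >= n_seeds) {
      return(cache[seq_len(n_seeds), ])
    }
    cs <- default_case()
    inl <- define_inlet_plane(cs$mesh, cs$truth$inlet$origin,
                              cs$truth$inlet$normal,
                              cs$truth$inlet$thickness)
    snap <- select_peak_systole(synthetic_waveform(cs$spec), 2,
                                cs$spec$period_T_s)
    res <- data.frame(seed = seq_len(n_seeds), mw_p = NA_real_,
                      fisher_p = NA_real_)
    for (s in seq_len(n_seeds)) {
      fs <- make_null_fields(cs$mesh, cs$truth, seed = s)
      idx <- compute_index_fields(cs$mesh, fs, inl, snap)
      pts <- distribute_points(cs$mesh, c("bleb", "nonbleb"), 0.5,
                               seed = s)
      pts <- label_points(pts, cs$mesh)
      np <- measure_at_points(pts, cs$mesh, idx$normalized_pressure)
      res$mw_p[s] <- mann_whitney_u(np[pts$region == "bleb"],
                                    np[pts$region == "nonbleb"])$p
      k <- which.min(abs(fs$times - snap))
      tang <- tangential_projection(cs$mesh, fs$wss[, , k])
      dv <- surface_divergence(cs$mesh, tang)
      cen <- find_divergence_centers(cs$mesh, tang, dv,
                                     domain_label = c("bleb", "nonbleb"))
      pts <- flag_center_points(pts, cen)
      tab <- build_center_contingency(pts)
      res$fisher_p[s] <- fisher_exact_2x2(tab)
    }
    cache <<- res
    res
  }
})
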