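# Small in-code fixtures shared across test files.

make_orfs <- function(seqs, ids = sprintf("g%02d", seq_along(seqs))) {
  orf_set(ids, seqs, quiet = TRUE)
}

# One simulated dataset (in memory) for a preset, 28-nt reads only.
quick_sim <- function(preset = "null", n_genes = 50, seed = 1,
                      length_codons = c(100L, 200L), ...) {
  cfg <- sim_preset(preset,
    n_genes = n_genes, seed = seed,
    length_codons = length_codons, rfp_classes = "28nt", ...
  )
  go <- gen_orfs(cfg)
  gp <- gen_profiles(go$orfs, cfg)
  list(
    config = cfg, orfs = go$orfs, counts = gp$counts,
    orf_truth = go$truth, profile_truth = gp$truth
  )
}

# Independent brute-force PWM oracle: nested loops over genes, codons and
# positions, no shared code with codon_pwm().
oracle_pwm <- function(seqs, selector_fun = NULL) {
  nucs <- c("A", "C", "G", "T")
  bg <- table(factor(unlist(strsplit(paste(seqs, collapse = ""), "")), levels = nucs))
  bg <- as.numeric(bg) / sum(bg)
  obs <- matrix(0, 3, 4, dimnames = list(1:3, nucs))
  n_sel <- 0
  for (s in seqs) {
    k <- nchar(s) / 3
    for (i in 0:(k - 1)) {
      codon <- substr(s, 3 * i + 1, 3 * i + 3)
      prev <- if (i > 0) substr(s, 3 * i - 2, 3 * i) else NA
      if (!is.null(selector_fun) && !isTRUE(selector_fun(codon, prev, i))) next
      n_sel <- n_sel + 1
      for (p in 1:3) {
        nt <- substr(codon, p, p)
        obs[p, nt] <- obs[p, nt] + 1
      }
    }
  }
  f_obs <- obs / n_sel
  w <- log2(sweep(f_obs, 2, bg, "/"))
  w[f_obs == 0 | rep(bg == 0, each = 3)] <- NaN
  list(f_obs = f_obs, f_exp = bg, weights = w, n = n_sel)
}
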