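# shared fixtures built in code

# brute-force enumeration of the unambiguous deck: all 64 feature
# combinations, keeping cards whose three feature dimensions point to three
# pairwise-distinct targets (equivalently: no target matches >= 2 features)
enumerate_deck_bruteforce <- function() {
  targets <- wcst_targets()
  out <- list()
  for (col in targets$colour) for (sh in targets$shape) for (nu in 1:4) {
    card <- wcst_card(col, sh, nu)
    hits <- vapply(1:4, function(k)
      sum(targets$colour[k] == col, targets$shape[k] == sh,
          targets$number[k] == nu), integer(1))
    if (all(hits <= 1L)) out[[length(out) + 1L]] <- card
  }
  do.call(rbind, out)
}

card_key <- function(cards) {
  sort(paste(cards$colour, cards$shape, cards$number))
}

# minimal per-trial log for the error-taxonomy fixtures
make_log <- function(applied, feedback) {
  data.frame(applied_rule = applied, feedback = feedback,
             response = rep(1L, length(applied)),
             stringsAsFactors = FALSE)
}

# steady state of a standalone basal-ganglia layer under static cortical
# drive, built from the exported step functions
bg_layer_steady <- function(o_ctx, n_cycles = 300, params = wcst_params(),
                            beta_str = params$beta_str) {
  n <- length(o_ctx)
  w <- bg_weights()
  mk <- function(beta, alpha, negate = FALSE) {
    o <- logistic(0, beta, alpha)
    list(a = rep(0, n), o = rep(if (negate) -o else o, n))
  }
  d1 <- mk(params$beta_str, params$alpha_str)
  d2 <- mk(params$beta_str, params$alpha_str)
  stn <- mk(params$beta_stn, params$alpha_stn)
  gpe <- mk(params$beta_gpe, params$alpha_gpe)
  gpi <- mk(params$beta_gpi, params$alpha_gpi)
  thal <- mk(params$beta_thal, params$alpha_thal, negate = TRUE)
  for (k in seq_len(n_cycles)) {
    d2_prev <- d2$o; gpe_prev <- gpe$o
    d1 <- step_striatum(d1, o_ctx, beta_str, params)
    d2 <- step_striatum(d2, o_ctx, beta_str, params)
    stn <- step_stn(stn, o_ctx, gpe_prev, w, params)
    gpe <- step_gpe(gpe, stn$o, d2_prev, w, params)
    gpi <- step_gpi(gpi, stn$o, gpe$o, d1$o, w, params)
    thal <- step_thalamus(thal, gpi$o, params)
  }
  list(d1 = d1, d2 = d2, stn = stn, gpe = gpe, gpi = gpi, thal = thal)
}

# iterate a single nucleus update to its fixed point under constant input
steady_nucleus <- function(u, beta, alpha, delta = 0.6, n = 200) {
  a <- 0
  for (k in seq_len(n)) a <- delta * a + (1 - delta) * u
  logistic(a, beta, alpha)
}
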