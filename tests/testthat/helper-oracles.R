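# Independent straight-line re-implementation of the 'high in' decision,
# written row by row directly from the regulation's wording and kept free of
# any package internals. Used only as an oracle.
fop_oracle <- function(df, dv_satfat = 20, dv_sugars = 100, dv_sodium = 2300) {
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    ex <- df$exemptions[[i]]
    ra <- df$reference_amount_g[i]
    ss <- df$serving_size_g[i]
    if (length(ex) > 0) {
      out[[i]] <- data.frame(product_id = df$product_id[i], exempt = TRUE,
                             n_high = 0L, displays_symbol = FALSE,
                             high_satfat = NA, high_sugars = NA, high_sodium = NA)
      next
    }
    # basis: serving size or reference amount, whichever is greater
    basis <- if (is.na(ra)) ss else if (is.na(ss)) ra else max(ra, ss)
    # tier: main dishes with RA >= 200 g (170 g for 1-4 yr foods) -> 30 %;
    # small RA (or serving when RA absent) <= 30 g -> 10 %; otherwise 15 %
    md_cut <- if (df$age_group[i] == "young_child") 170 else 200
    thr <- if (isTRUE(df$is_main_dish[i]) && !is.na(ra) && ra >= md_cut) {
      30
    } else if ((if (is.na(ra)) ss else ra) <= 30) {
      10
    } else {
      15
    }
    scale <- if (is.na(ss)) 1 else basis / ss
    pct <- function(amount, dv) 100 * amount * scale / dv
    hs <- pct(df$saturated_fat_g[i], dv_satfat) >= thr
    hu <- pct(df$total_sugars_g[i], dv_sugars) >= thr
    ho <- pct(df$sodium_mg[i], dv_sodium) >= thr
    nh <- sum(c(hs, hu, ho), na.rm = TRUE)
    out[[i]] <- data.frame(product_id = df$product_id[i], exempt = FALSE,
                           n_high = as.integer(nh), displays_symbol = nh >= 1,
                           high_satfat = hs, high_sugars = hu, high_sodium = ho)
  }
  do.call(rbind, out)
}

# Full-enumeration Fisher oracle: hypergeometric probabilities from binomial
# coefficients, summed under the probability-mass rule.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c1 == n) return(1)
  support <- max(0, c1 - r2):min(c1, r1)
  probs <- choose(r1, support) * choose(r2, c1 - support) / choose(n, c1)
  p_obs <- probs[support == a]
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}
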